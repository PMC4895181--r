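#' Per-population allele frequencies
#'
#' Reference-allele frequency and allele count (2 x non-missing individuals)
#' per SNP per population. Cells where a population has no non-missing call
#' are `NA` (absent), not zero.
#'
#' @param x a [genotype_table()]
#' @return list of class `pop_freq_table`: `p` (populations x SNPs frequency
#'   matrix), `n` (allele-count matrix), `map` (the SNP map)
#' @export
pop_frequencies <- function(x) {
  pops <- sort(unique(x$pops))
  p <- matrix(NA_real_, length(pops), ncol(x$geno),
              dimnames = list(pops, x$map$snp))
  n <- matrix(0L, length(pops), ncol(x$geno), dimnames = dimnames(p))
  for (k in seq_along(pops)) {
    g <- x$geno[x$pops == pops[k], , drop = FALSE]
    n_obs <- colSums(!is.na(g))
    n[k, ] <- 2L * n_obs
    p[k, ] <- ifelse(n_obs > 0, colSums(g, na.rm = TRUE) / (2 * n_obs),
                     NA_real_)
  }
  structure(list(p = p, n = n, map = x$map), class = "pop_freq_table")
}

#' Identity-by-state distance matrix between individuals
#'
#' `distance(i, j) = 1 - mean over SNPs of (shared alleles / 2)`, where the
#' shared allele count between dosages `a` and `b` is `2 - |a - b|`; only
#' SNPs non-missing in both individuals enter the mean. A pair with no
#' jointly non-missing SNP is an error.
#'
#' @param x a [genotype_table()]
#' @return symmetric individuals x individuals distance matrix
#' @export
ibs_distance_matrix <- function(x) {
  g <- x$geno
  n <- nrow(g)
  stopifnot(n >= 2)
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0
  obs <- obs * 1
  # sum |a-b| over shared SNPs = a^2 + b^2 - 2ab summed trickery does not
  # apply to |.|; use dosage indicator decomposition instead:
  # |a-b| = a + b - 2*min(a,b); min via indicators of dosage >= 1 and == 2
  i1 <- (g0 >= 1) * obs
  i2 <- (g0 == 2) * obs
  # min(a,b) summed over shared SNPs = sum min(a,b) = sum_k [a>=k][b>=k]
  shared_min <- tcrossprod(i1) + tcrossprod(i2)
  n_shared <- tcrossprod(obs)
  if (any(n_shared[upper.tri(n_shared)] == 0)) {
    stop("individual pair(s) with zero jointly non-missing SNPs")
  }
  sum_a <- (g0 * obs) %*% t(obs)
  sum_b <- t(sum_a)
  sum_abs <- sum_a + sum_b - 2 * shared_min
  d <- sum_abs / (2 * n_shared)
  dimnames(d) <- list(x$ids, x$ids)
  diag(d) <- 0
  d
}

#' Classical (principal-coordinates) multidimensional scaling
#'
#' Torgerson scaling of a symmetric distance matrix: double-centering of
#' `-D^2/2`, top-`k` eigenpairs, coordinates scaled by the square root of
#' the eigenvalues. Dimensions with non-positive eigenvalues are dropped
#' with a warning, reducing the returned dimensionality.
#'
#' @param d square symmetric non-negative distance matrix
#' @param k requested number of dimensions (default 2)
#' @return list with `points` (n x k' coordinate matrix, `k' <= k`) and
#'   `eig` (all eigenvalues)
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(d >= 0))
  fit <- stats::cmdscale(d, k = min(k, nrow(d) - 1), eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " of ", k,
            " requested dimensions have positive eigenvalues")
  }
  if (is.null(pts) || ncol(pts) == 0) {
    pts <- matrix(0, nrow(d), 0)
  }
  rownames(pts) <- rownames(d)
  list(points = pts, eig = fit$eig)
}

#' Reynolds genetic distance between two populations
#'
#' Ratio-of-sums coancestry estimator on biallelic frequencies:
#' `theta = sum_l (p_il - p_jl)^2 / sum_l (p_il + p_jl - 2 p_il p_jl)`,
#' `D = -log(1 - theta)`. SNPs monomorphic in both populations jointly
#' (denominator term zero) contribute to neither sum; SNPs with an absent
#' frequency in either population are skipped. Under pure drift `D` is
#' additive along the population tree, which is why it serves as the branch
#' length unit.
#'
#' @param freqs a [pop_frequencies()] table
#' @param pop_i,pop_j population names
#' @param snps optional SNP subset (names or indices)
#' @param cap value substituted (with a warning) when `theta >= 1`
#'   (complete fixation; default 50)
#' @return non-negative distance
#' @export
reynolds_distance <- function(freqs, pop_i, pop_j, snps = NULL, cap = 50) {
  p1 <- freqs$p[pop_i, ]
  p2 <- freqs$p[pop_j, ]
  if (!is.null(snps)) {
    p1 <- p1[snps]
    p2 <- p2[snps]
  }
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]
  p2 <- p2[ok]
  if (!length(p1)) stop("no SNP with frequencies present in both populations")
  num <- sum((p1 - p2)^2)
  den <- sum(p1 + p2 - 2 * p1 * p2)
  if (den == 0) return(0)
  theta <- num / den
  if (theta >= 1) {
    warning("theta >= 1 (complete fixation); distance capped at ", cap)
    return(cap)
  }
  -log(1 - theta)
}

#' Pairwise Reynolds distance matrix
#'
#' @inheritParams reynolds_distance
#' @return symmetric populations x populations matrix
#' @export
reynolds_matrix <- function(freqs, snps = NULL, cap = 50) {
  pops <- rownames(freqs$p)
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) {
    for (j in seq_len(i - 1)) {
      d[i, j] <- d[j, i] <- reynolds_distance(freqs, pops[i], pops[j],
                                              snps = snps, cap = cap)
    }
  }
  d
}

#' Neighbor-joining population tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix, with negative
#' branch-length estimates floored at zero after construction, rooted by
#' midpoint unless an outgroup is named.
#'
#' @param d symmetric distance matrix over >= 3 populations
#' @param outgroup optional leaf name used for rooting instead of midpoint
#' @return rooted `phylo` object with non-negative branch lengths
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  stopifnot(nrow(d) >= 3)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    stopifnot(outgroup %in% tr$tip.label)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  } else {
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Kinship matrix from a rooted population tree
#'
#' `F[i, j]` is the total branch length shared by the root-to-leaf paths of
#' populations `i` and `j` (the depth of their most recent common ancestor);
#' `F[i, i]` is the root-to-leaf path length. With branch lengths in
#' Reynolds-distance (drift) units this is the expected covariance structure
#' of population allele frequencies under pure drift. An optional outgroup
#' is pruned before the matrix is formed.
#'
#' @param tree rooted `phylo` with non-negative branch lengths
#' @param outgroup optional leaf name excluded from the matrix
#' @return symmetric positive semidefinite matrix with population dimnames
#' @export
kinship_from_tree <- function(tree, outgroup = NULL) {
  is_star <- all(tree$edge[, 1] == length(tree$tip.label) + 1L)
  if (!ape::is.rooted(tree) && !is_star) stop("tree must be rooted")
  if (!is.null(outgroup)) {
    tree <- ape::drop.tip(tree, outgroup)
  }
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  FF <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(FF) <- depth[seq_len(n)]
  if (n >= 2) {
    mrca <- ape::mrca(tree)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        FF[i, j] <- FF[j, i] <- depth[mrca[i, j]]
      }
    }
  }
  FF
}

#' Neighbor-joining tree from a SNP subset (local tree)
#'
#' Reynolds distances restricted to the SNPs inside a genomic interval,
#' followed by neighbor joining. Contrasting a local tree against the
#' genome-wide tree shows which populations carry excess drift at a putative
#' sweep.
#'
#' @param freqs a [pop_frequencies()] table (carries the SNP map)
#' @param chrom,start,end interval (bp, 1-based inclusive); alternatively
#'   pass a single-row [sweep_set()] as `region`
#' @param region optional single-row [sweep_set()]
#' @param min_snps minimum SNPs required in the interval (default 10)
#' @param outgroup optional rooting outgroup
#' @return rooted `phylo`
#' @export
local_tree <- function(freqs, chrom = NULL, start = NULL, end = NULL,
                       region = NULL, min_snps = 10, outgroup = NULL) {
  if (!is.null(region)) {
    stopifnot(nrow(region) == 1)
    chrom <- region$chrom
    start <- region$start
    end <- region$end
  }
  sel <- which(freqs$map$chrom == chrom & freqs$map$pos >= start &
                 freqs$map$pos <= end)
  if (length(sel) < min_snps) {
    stop(sprintf("interval chr%s:%s-%s contains %d SNPs (< %d required)",
                 chrom, format(start, scientific = FALSE),
                 format(end, scientific = FALSE), length(sel), min_snps))
  }
  neighbor_joining(reynolds_matrix(freqs, snps = sel), outgroup = outgroup)
}
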