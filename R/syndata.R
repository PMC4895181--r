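#' Default sheep-like autosome lengths
#'
#' 26 autosome lengths in base pairs, decreasing linearly from 275 Mb to
#' 45 Mb, on the scale of the sheep autosomal karyotype.
#'
#' @param n_chromosomes number of autosomes (default 26)
#' @return numeric vector of lengths in bp
#' @export
default_chrom_lengths <- function(n_chromosomes = 26) {
  round(seq(275e6, 45e6, length.out = n_chromosomes))
}

#' Build a star-shaped drift tree over populations
#'
#' Rooted tree with one branch per population, each with drift coefficient
#' `c`: every population diverges independently from the common ancestor.
#' Branch lengths are drift coefficients, which on this model equal the
#' branch's expected contribution to the Reynolds distance.
#'
#' @param pop_names population (leaf) names
#' @param drift per-branch drift coefficient in (0, 1)
#' @return rooted `phylo` object with branch lengths = drift coefficients
#' @export
star_drift_tree <- function(pop_names, drift = 0.05) {
  n <- length(pop_names)
  stopifnot(n >= 2, drift > 0, drift < 1)
  tr <- ape::stree(n, type = "star", tip.label = pop_names)
  tr$edge.length <- rep(drift, nrow(tr$edge))
  tr
}

#' Simulation configuration
#'
#' Parameters of the tree-structured drift simulator. Populations diverge
#' from a common ancestor by pure drift: along each branch with coefficient
#' `c`, the descendant allele frequency is Beta-distributed with mean equal
#' to the parental frequency `p` and variance `c * p * (1 - p)`
#' (Balding-Nichols parameterization). A minority of loci can additionally
#' receive a deterministic post-drift frequency shift toward fixation in a
#' designated set of populations, emulating directional selection.
#'
#' @param n_pops number of populations (ignored when `tree` is supplied)
#' @param n_ind_per_pop diploid individuals per population; scalar or vector
#' @param n_snps number of SNPs
#' @param n_chromosomes number of autosomes (default 26)
#' @param chrom_lengths bp length per chromosome
#' @param ancestral_freq_range interval within (0,1) from which ancestral
#'   reference-allele frequencies are drawn uniformly (default `c(0.05, 0.95)`)
#' @param selected_loci list of entries `list(snp = index, pops = names,
#'   delta = shift)`; at each such locus the post-drift frequency in each
#'   target population is moved toward 1 by `delta * (1 - p)`
#' @param missing_rate per-genotype missingness probability
#' @param tree rooted `phylo` whose branch lengths are drift coefficients in
#'   (0,1); default: star tree with `drift` per branch
#' @param drift per-branch drift coefficient of the default star tree
#' @param seed integer seed; all random draws derive from it in a fixed,
#'   documented order (frequencies first, then map and genotypes)
#'
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_pops = 10, n_ind_per_pop = 25, n_snps = 10000,
                       n_chromosomes = 26,
                       chrom_lengths = default_chrom_lengths(n_chromosomes),
                       ancestral_freq_range = c(0.05, 0.95),
                       selected_loci = list(), missing_rate = 0.01,
                       tree = NULL, drift = 0.05, seed = 1) {
  if (is.null(tree)) {
    tree <- star_drift_tree(paste0("pop", seq_len(n_pops)), drift = drift)
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0) || any(tree$edge.length >= 1)) {
    stop("all drift coefficients must lie strictly inside (0, 1)")
  }
  pops <- tree$tip.label
  n_pops <- length(pops)
  if (length(n_ind_per_pop) == 1) n_ind_per_pop <- rep(n_ind_per_pop, n_pops)
  stopifnot(length(n_ind_per_pop) == n_pops, all(n_ind_per_pop >= 1))
  stopifnot(length(chrom_lengths) == n_chromosomes, all(chrom_lengths > 0))
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  stopifnot(missing_rate >= 0, missing_rate < 1)
  idx <- vapply(selected_loci, function(s) as.integer(s$snp), integer(1))
  if (length(idx)) {
    if (anyDuplicated(idx)) stop("selected_loci SNP indices must be distinct")
    if (any(idx < 1 | idx > n_snps)) stop("selected_loci index out of range")
    for (s in selected_loci) {
      if (!all(s$pops %in% pops)) {
        stop("selected_loci target population not in tree: ",
             paste(setdiff(s$pops, pops), collapse = ", "))
      }
      if (s$delta <= 0 || s$delta > 1) stop("delta must lie in (0, 1]")
    }
  }
  structure(
    list(tree = tree, pop_names = pops, n_pops = n_pops,
         n_ind_per_pop = n_ind_per_pop, n_snps = as.integer(n_snps),
         n_chromosomes = as.integer(n_chromosomes),
         chrom_lengths = chrom_lengths,
         ancestral_freq_range = ancestral_freq_range,
         selected_loci = selected_loci, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# One Balding-Nichols drift step: child ~ Beta(p(1-c)/c, (1-p)(1-c)/c).
# In the c -> 0 limit the child frequency equals the parent frequency.
drift_step <- function(p, c_drift, eps = 1e-6) {
  if (c_drift < 1e-12) return(p)
  lambda <- (1 - c_drift) / c_drift
  a <- p * lambda
  b <- (1 - p) * lambda
  bad <- !is.finite(a) | !is.finite(b) | a <= 0 | b <= 0
  if (any(bad)) {
    warning("non-finite Beta shapes at ", sum(bad),
            " loci; parent frequency clamped to [eps, 1-eps]")
    pc <- pmin(pmax(p[bad], eps), 1 - eps)
    a[bad] <- pc * lambda
    b[bad] <- (1 - pc) * lambda
  }
  q <- stats::rbeta(length(p), a, b)
  # rbeta can return exactly 0 or 1 for extreme shapes; keep strictly inside
  pmin(pmax(q, eps), 1 - eps)
}

#' Simulate per-population allele frequencies under tree-structured drift
#'
#' Draws the ancestral reference-allele frequency of every SNP uniformly from
#' `ancestral_freq_range`, then propagates it down the drift tree: along each
#' branch with drift coefficient `c` the descendant frequency is drawn from a
#' Beta distribution with mean the parental frequency `p` and variance
#' `c * p * (1 - p)`. After drift, each configured selected locus has its
#' frequency in the target populations shifted toward 1 by `delta * (1 - p)`
#' (truncated to the open unit interval at 1e-6).
#'
#' @param config a [sim_config()]
#' @return list with `ancestral` (length `n_snps`), `freqs` (matrix
#'   populations x SNPs, rownames = population names), `tree`
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- config$tree
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  p0 <- stats::runif(config$n_snps, config$ancestral_freq_range[1],
                     config$ancestral_freq_range[2])
  # propagate in parent-before-child edge order
  node_freq <- matrix(NA_real_, nrow = max(tr$edge), ncol = config$n_snps)
  node_freq[root, ] <- p0
  edges <- ape::reorder.phylo(tr, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    par <- edges$edge[e, 1]
    chd <- edges$edge[e, 2]
    node_freq[chd, ] <- drift_step(node_freq[par, ], edges$edge.length[e])
  }
  freqs <- node_freq[seq_len(n_tip), , drop = FALSE]
  rownames(freqs) <- tr$tip.label
  eps <- 1e-6
  for (s in config$selected_loci) {
    j <- as.integer(s$snp)
    p <- freqs[s$pops, j]
    freqs[s$pops, j] <- pmin(pmax(p + s$delta * (1 - p), eps), 1 - eps)
  }
  list(ancestral = p0, freqs = freqs, tree = tr)
}

# Random SNP map: per-chromosome SNP counts proportional to length,
# positions sampled without replacement then sorted (strictly increasing).
make_snp_map <- function(config) {
  L <- config$chrom_lengths
  n <- config$n_snps
  n_per <- floor(n * L / sum(L))
  rem <- n - sum(n_per)
  if (rem > 0) {
    extra <- order(n * L / sum(L) - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  chrom <- rep(seq_along(L), n_per)
  pos <- unlist(lapply(seq_along(L), function(ch) {
    sort(sample.int(L[ch], n_per[ch]))
  }))
  data.frame(snp = sprintf("snp%05d", seq_len(n)), chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

#' Simulate diploid genotypes from per-population frequencies
#'
#' Each individual's dosage at each SNP is Binomial(2, p) with `p` the
#' frequency of its population (Hardy-Weinberg equilibrium within
#' populations); genotypes are then set to missing independently with
#' probability `missing_rate`. A random SNP map over `n_chromosomes`
#' autosomes is generated (counts proportional to chromosome length,
#' positions uniform, sorted). Deterministic given `config$seed`.
#'
#' @param freqs result of [simulate_frequencies()], or a populations x SNPs
#'   frequency matrix with population rownames
#' @param config a [sim_config()]
#' @return a [genotype_table()]
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(freqs) && !is.null(freqs$freqs)) freqs <- freqs$freqs
  stopifnot(is.matrix(freqs), nrow(freqs) == config$n_pops,
            ncol(freqs) == config$n_snps)
  set.seed(config$seed + 1L)
  map <- make_snp_map(config)
  n_ind <- sum(config$n_ind_per_pop)
  pops <- rep(config$pop_names, config$n_ind_per_pop)
  geno <- matrix(0L, nrow = n_ind, ncol = config$n_snps)
  row0 <- 0L
  for (j in seq_len(config$n_pops)) {
    nj <- config$n_ind_per_pop[j]
    g <- stats::rbinom(nj * config$n_snps, 2L, rep(freqs[j, ], each = nj))
    geno[row0 + seq_len(nj), ] <- matrix(g, nrow = nj)
    row0 <- row0 + nj
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  genotype_table(map, geno, pops)
}

#' Simulate a complete genotype dataset
#'
#' Convenience wrapper: [simulate_frequencies()] then [simulate_genotypes()].
#'
#' @param config a [sim_config()]
#' @return list with `table` (a [genotype_table()]), `freqs`, `ancestral`,
#'   `tree`
#' @export
simulate_dataset <- function(config) {
  fr <- simulate_frequencies(config)
  tab <- simulate_genotypes(fr, config)
  list(table = tab, freqs = fr$freqs, ancestral = fr$ancestral, tree = fr$tree)
}
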