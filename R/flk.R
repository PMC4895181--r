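#' FLK test of a single SNP
#'
#' Contrasts the population allele-frequency vector `p` at one SNP with its
#' expectation under pure drift encoded by the kinship matrix `F`. The
#' ancestral frequency is estimated by generalized least squares,
#' `p0 = (1' F^-1 p) / (1' F^-1 1)`, the null covariance is
#' `V = p0 (1 - p0) F`, and `FLK = (p - p0)' V^-1 (p - p0)`, chi-square
#' distributed with `n_pops - 1` degrees of freedom under neutrality.
#' SNPs with `p0` outside (0, 1) or with all-equal frequencies return
#' statistic 0 and P = 1. Populations with an absent frequency at the SNP
#' are dropped (at least 2 must remain).
#'
#' @param p per-population reference-allele frequencies at one SNP (named
#'   by population when `F` has dimnames)
#' @param F kinship matrix from [kinship_from_tree()]
#' @return list with `stat`, `p_value`, `df`
#' @export
flk_statistic <- function(p, F) {
  ok <- !is.na(p)
  if (sum(ok) < 2) stop("need frequencies in at least 2 populations")
  p <- p[ok]
  F <- F[ok, ok, drop = FALSE]
  rc <- rcond(F)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("kinship matrix is numerically singular; ",
         "consider flooring zero-length branches")
  }
  Finv <- solve(F)
  w <- Finv %*% rep(1, length(p))
  p0 <- as.numeric(crossprod(w, p) / sum(w))
  df <- length(p) - 1
  if (p0 <= 0 || p0 >= 1 || max(p) - min(p) < .Machine$double.eps) {
    return(list(stat = 0, p_value = 1, df = df))
  }
  r <- p - p0
  stat <- as.numeric(crossprod(r, Finv %*% r)) / (p0 * (1 - p0))
  list(stat = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df)
}

#' FLK scan over all SNPs of a frequency table
#'
#' Vectorized [flk_statistic()] over the SNPs of a [pop_frequencies()]
#' table, with Benjamini-Hochberg q-values.
#'
#' @param freqs a [pop_frequencies()] table
#' @param F kinship matrix; rownames must match the table's populations
#' @return data.frame `snp`, `chrom`, `pos`, `stat`, `p_value`, `q_value`
#' @export
flk_scan <- function(freqs, F) {
  pops <- rownames(F)
  stopifnot(all(pops %in% rownames(freqs$p)))
  P <- freqs$p[pops, , drop = FALSE]
  rc <- rcond(F)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("kinship matrix is numerically singular; ",
         "consider flooring zero-length branches")
  }
  Finv <- solve(F)
  w <- as.numeric(Finv %*% rep(1, nrow(F)))
  L <- ncol(P)
  stat <- numeric(L)
  complete <- colSums(is.na(P)) == 0
  if (any(complete)) {
    Pc <- P[, complete, drop = FALSE]
    p0 <- as.numeric(crossprod(w, Pc)) / sum(w)
    R <- sweep(Pc, 2, p0)               # residuals
    qf <- colSums((Finv %*% R) * R)
    v <- p0 * (1 - p0)
    s <- ifelse(p0 > 0 & p0 < 1 & apply(Pc, 2, function(x) max(x) - min(x)) >
                  .Machine$double.eps, qf / v, 0)
    stat[complete] <- s
  }
  for (j in which(!complete)) {
    stat[j] <- flk_statistic(P[, j], F)$stat
  }
  df <- nrow(F) - 1
  p_value <- ifelse(stat > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)
  data.frame(snp = freqs$map$snp, chrom = freqs$map$chrom,
             pos = freqs$map$pos, stat = stat, p_value = p_value,
             q_value = fdr_qvalues(p_value), stringsAsFactors = FALSE)
}

# ---- haplotype-cluster HMM (fastPHASE-style) --------------------------------

# slot-sum helpers for (K, K, n) arrays
sum_slot1 <- function(A) colSums(A)                      # -> (K, n), sums k1
sum_slot2 <- function(A) colSums(aperm(A, c(2, 1, 3)))   # -> (K, n), sums k2

# apply matrix M (K x K) to slot 1: out[k1',k2,i] = sum_k1 M[k1',k1] A[k1,k2,i]
apply_slot1 <- function(A, M, K, n) {
  array(M %*% matrix(A, K, K * n), c(K, K, n))
}
apply_slot2 <- function(A, M, K, n) {
  aperm(apply_slot1(aperm(A, c(2, 1, 3)), M, K, n), c(2, 1, 3))
}

# emission arrays for one SNP: list of K x K matrices for dosage 0/1/2 and
# missing, from the K cluster allele frequencies th
emission_mats <- function(th) {
  q <- 1 - th
  list(outer(q, q), outer(th, q) + outer(q, th), outer(th, th),
       matrix(1, length(th), length(th)))
}

#' Fit the haplotype-cluster model (one EM run)
#'
#' Fits a fastPHASE-style hidden Markov model to unphased dosage genotypes:
#' each of the two haplotypes of an individual follows a Markov jump process
#' over `K` haplotype clusters (at each inter-SNP interval the chain stays
#' with probability `1 - rho` or jumps to a cluster drawn from the local
#' cluster weights), and the dosage is the sum of two Bernoulli draws with
#' cluster-specific allele frequencies `theta`. The forward-backward
#' recursions run over the K^2 ordered cluster pairs (factorized
#' transitions); chromosomes restart the chain. Parameters (`theta`, cluster
#' weights, per-interval jump probabilities) are estimated by EM until the
#' log-likelihood gain drops below `tol` or `max_iter` iterations; the
#' log-likelihood is checked to be non-decreasing (a decrease beyond
#' numerical tolerance is a hard failure).
#'
#' @param x a [genotype_table()] with SNPs ordered by position
#' @param K number of haplotype clusters (>= 2; the published analyses use
#'   20)
#' @param seed seed of the randomized initialization (distinct seeds give
#'   the independent EM fits averaged by [hapflk_statistic()])
#' @param max_iter maximum EM iterations (default 100)
#' @param tol log-likelihood convergence tolerance (default 1e-4)
#' @return object of class `cluster_fit`: `K`, `theta` (L x K), `weights`
#'   (L x K local cluster weights, each row sums to 1), `rho` (length L,
#'   jump probability into each SNP; 1 at chromosome starts), `loglik`
#'   (per-iteration trace), `memberships` (K x n x L posterior cluster
#'   membership array, slot-averaged so each column sums to 1), `map`,
#'   `pops`, `seed`
#' @export
fit_cluster_model <- function(x, K = 20, seed = 1, max_iter = 100,
                              tol = 1e-4) {
  if (K < 2) stop("K must be at least 2")
  ord <- order(x$map$chrom, x$map$pos)
  map <- x$map[ord, ]
  g <- x$geno[, ord, drop = FALSE]
  n <- nrow(g)
  L <- ncol(g)
  chrom_start <- c(TRUE, diff(map$chrom) != 0)
  set.seed(seed)
  p_marg <- colSums(g, na.rm = TRUE) / (2 * pmax(colSums(!is.na(g)), 1))
  theta <- matrix(pmin(pmax(p_marg + stats::runif(L * K, -0.2, 0.2),
                            0.02), 0.98), L, K)
  weights <- matrix(1 / K + stats::runif(L * K, 0, 0.1), L, K)
  weights <- weights / rowSums(weights)
  rho <- ifelse(chrom_start, 1, 0.05)
  gi <- ifelse(is.na(g), 4L, g + 1L)      # emission index per ind x SNP

  loglik_trace <- numeric(0)
  memb <- NULL
  for (iter in seq_len(max_iter)) {
    # E-step: forward
    Fw <- vector("list", L)
    ll <- 0
    for (l in seq_len(L)) {
      em <- emission_mats(theta[l, ])
      Earr <- array(unlist(em, use.names = FALSE), c(K, K, 4))[, , gi[, l],
                                                               drop = FALSE]
      if (chrom_start[l]) {
        A <- array(outer(weights[l, ], weights[l, ]), c(K, K, n)) * Earr
      } else {
        T1 <- (1 - rho[l]) * diag(K) + rho[l] *
          matrix(weights[l, ], K, K, byrow = TRUE)
        A <- apply_slot2(apply_slot1(Fw[[l - 1]], t(T1), K, n), t(T1), K, n)
        A <- A * Earr
      }
      cs <- colSums(matrix(A, K * K, n))
      if (any(cs <= 0)) stop("zero forward probability (degenerate model)")
      A <- A / rep(cs, each = K * K)
      ll <- ll + sum(log(cs))
      Fw[[l]] <- A
    }
    # guard: EM must not decrease the log-likelihood
    if (length(loglik_trace) &&
        ll < loglik_trace[length(loglik_trace)] - 1e-6 * (1 + abs(ll))) {
      stop("EM log-likelihood decreased (internal error)")
    }
    converged <- length(loglik_trace) &&
      ll - loglik_trace[length(loglik_trace)] < tol
    loglik_trace <- c(loglik_trace, ll)

    # backward + accumulation
    u <- matrix(0, L, K)        # expected reference alleles per cluster
    d <- matrix(0, L, K)        # expected observed chromosomes per cluster
    J <- matrix(0, L, K)        # expected jumps landing in cluster k
    memb <- array(0, c(K, n, L))
    B <- array(1 / (K * K), c(K, K, n))
    for (l in rev(seq_len(L))) {
      G <- Fw[[l]] * B
      gs <- colSums(matrix(G, K * K, n))
      G <- G / rep(gs, each = K * K)
      m1 <- sum_slot2(G)                 # marginal of slot-1 cluster (K x n)
      m2 <- sum_slot1(G)
      memb[, , l] <- (m1 + m2) / 2
      # theta stats on observed genotypes
      th <- theta[l, ]
      w1 <- outer(th, 1 - th)
      w1 <- w1 / (w1 + t(w1))            # P(slot1 allele = 1 | dosage 1)
      obs0 <- which(gi[, l] == 1L)
      obs1 <- which(gi[, l] == 2L)
      obs2 <- which(gi[, l] == 3L)
      if (length(obs2)) {
        u[l, ] <- u[l, ] + rowSums(m1[, obs2, drop = FALSE]) +
          rowSums(m2[, obs2, drop = FALSE])
      }
      if (length(obs1)) {
        Go <- G[, , obs1, drop = FALSE]
        u[l, ] <- u[l, ] +
          rowSums(sum_slot2(Go * array(w1, c(K, K, length(obs1))))) +
          rowSums(sum_slot1(Go * array(t(w1), c(K, K, length(obs1)))))
      }
      obs <- c(obs0, obs1, obs2)
      if (length(obs)) {
        d[l, ] <- d[l, ] + rowSums(m1[, obs, drop = FALSE]) +
          rowSums(m2[, obs, drop = FALSE])
      }
      # transition stats into SNP l
      if (chrom_start[l]) {
        J[l, ] <- rowSums(m1) + rowSums(m2)
      } else {
        em <- emission_mats(theta[l, ])
        Earr <- array(unlist(em, use.names = FALSE),
                      c(K, K, 4))[, , gi[, l], drop = FALSE]
        M <- Earr * B
        T1 <- (1 - rho[l]) * diag(K) + rho[l] *
          matrix(weights[l, ], K, K, byrow = TRUE)
        Fprev <- Fw[[l - 1]]
        fc <- sum_slot1(Fprev)           # K x n, sums over k1
        fr <- sum_slot2(Fprev)
        wv <- crossprod(T1, fc)          # K x n
        wv2 <- crossprod(T1, fr)
        warr <- aperm(array(wv, c(K, n, K)), c(3, 1, 2))
        j1 <- rho[l] * weights[l, ] * sum_slot2(M * warr)
        w2arr <- aperm(array(wv2, c(K, n, K)), c(1, 3, 2))
        j2 <- rho[l] * weights[l, ] * sum_slot1(M * w2arr)
        # per-individual normalizer of the (l-1 -> l) joint
        AA <- apply_slot2(apply_slot1(Fprev, t(T1), K, n), t(T1), K, n) * M
        Z <- colSums(matrix(AA, K * K, n))
        J[l, ] <- rowSums(sweep(j1 + j2, 2, Z, "/"))
        # backward recursion to l-1
        B <- apply_slot2(apply_slot1(M, T1, K, n), T1, K, n)
        bs <- colSums(matrix(B, K * K, n))
        B <- B / rep(bs, each = K * K)
      }
      if (chrom_start[l] && l > 1) {
        B <- array(1 / (K * K), c(K, K, n))
      }
    }
    if (converged) break
    # M-step
    theta <- pmin(pmax(u / pmax(d, 1e-12), 1e-6), 1 - 1e-6)
    jt <- rowSums(J)
    wnew <- J / pmax(jt, 1e-300)
    wnew <- pmax(wnew, 1e-8)
    weights <- wnew / rowSums(wnew)
    rho_new <- jt / (2 * n)
    rho <- ifelse(chrom_start, 1, pmin(pmax(rho_new, 1e-6), 1 - 1e-6))
  }
  structure(
    list(K = K, theta = theta, weights = weights, rho = rho,
         loglik = loglik_trace, memberships = memb, map = map,
         pops = x$pops, ids = x$ids, seed = seed),
    class = "cluster_fit")
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat("haplotype-cluster model: K =", x$K, ",", dim(x$memberships)[2],
      "individuals x", nrow(x$theta), "SNPs\n")
  cat("EM iterations:", length(x$loglik), " final log-likelihood:",
      format(x$loglik[length(x$loglik)], digits = 8), "\n")
  invisible(x)
}

#' hapFLK statistic from haplotype-cluster fits
#'
#' Extends FLK to local haplotype-cluster frequencies: for each EM fit and
#' each SNP, posterior cluster memberships are averaged within populations
#' to give per-population cluster frequencies, the ancestral cluster
#' frequencies are estimated by GLS, and an FLK-type quadratic form is
#' taken over the `K - 1` free cluster dimensions. Population space is
#' whitened by the inverse of `F + diag(1/n_j)` (kinship plus the
#' within-population sampling contribution of averaging `n_j` individuals);
#' cluster space is whitened by the pseudo-inverse of the pooled
#' within-population covariance of individual membership vectors, which
#' carries the same posterior shrinkage as the population means and keeps
#' the null scale comparable across SNPs. The statistic is averaged over
#' the `E` fits — runs of [fit_cluster_model()] from independent random
#' starts.
#'
#' @param fits a `cluster_fit` or list of them (same `K` and SNP map)
#' @param F kinship matrix over the populations to test (its rownames pick
#'   the populations; all must appear in the fits' labels)
#' @return data.frame `snp`, `chrom`, `pos`, `stat`
#' @export
hapflk_statistic <- function(fits, F) {
  if (inherits(fits, "cluster_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  K <- fits[[1]]$K
  L <- nrow(fits[[1]]$map)
  pops <- rownames(F)
  if (length(pops) < 2) stop("hapFLK needs at least 2 populations")
  miss <- setdiff(pops, unique(fits[[1]]$pops))
  if (length(miss)) {
    stop("population(s) absent from fit labels: ", paste(miss, collapse = ", "))
  }
  rc <- rcond(F)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("kinship matrix is numerically singular; ",
         "consider flooring zero-length branches")
  }
  n_j <- vapply(pops, function(pp) sum(fits[[1]]$pops == pp), numeric(1))
  Fstar <- F + diag(1 / n_j, nrow(F))
  Finv <- solve(Fstar)
  w <- as.numeric(Finv %*% rep(1, nrow(F)))
  sw <- sum(w)
  one <- rep(1, length(pops))
  stat <- numeric(L)
  for (fit in fits) {
    stopifnot(fit$K == K, nrow(fit$map) == L)
    pop_idx <- lapply(pops, function(pp) which(fit$pops == pp))
    s <- numeric(L)
    for (l in seq_len(L)) {
      m <- fit$memberships[, , l]        # K x n
      q <- t(vapply(pop_idx, function(ii) rowMeans(m[, ii, drop = FALSE]),
                    numeric(K)))         # npop x K
      # pooled within-population covariance of membership vectors
      S <- matrix(0, K, K)
      Nw <- 0
      for (ii in pop_idx) {
        mm <- m[, ii, drop = FALSE]
        S <- S + tcrossprod(mm - rowMeans(mm))
        Nw <- Nw + length(ii) - 1L
      }
      S <- S / max(Nw, 1)
      es <- eigen(S, symmetric = TRUE)
      pos <- es$values > max(es$values, 0) * 1e-8
      if (!any(pos)) next                # degenerate SNP: no information
      Sp <- es$vectors[, pos, drop = FALSE] %*%
        (t(es$vectors[, pos, drop = FALSE]) / es$values[pos])
      q0 <- as.numeric(crossprod(q, w)) / sw  # GLS ancestral cluster freqs
      R <- q - one %o% q0
      s[l] <- sum((Finv %*% R) * (R %*% Sp))
    }
    stat <- stat + s
  }
  stat <- stat / length(fits)
  data.frame(snp = fits[[1]]$map$snp, chrom = fits[[1]]$map$chrom,
             pos = fits[[1]]$map$pos, stat = stat, stringsAsFactors = FALSE)
}

#' Run the full hapFLK scan
#'
#' Fits `n_fits` independently seeded haplotype-cluster models (seeds
#' `seed, seed + 1, ...`), averages the hapFLK statistic over them (the
#' published analyses average 30 fits with K = 20), and converts the
#' statistic to raw P-values via the empirical null of
#' [empirical_pvalues()] and to q-values via [fdr_qvalues()].
#'
#' @param x a [genotype_table()] restricted to the populations under test
#' @param F kinship matrix (rownames = populations to test)
#' @param K cluster count (default 20)
#' @param n_fits number of EM fits averaged (default 30)
#' @param seed base seed
#' @param max_iter,tol EM controls, see [fit_cluster_model()]
#' @return data.frame `snp`, `chrom`, `pos`, `stat`, `p_value`, `q_value`;
#'   the empirical-null diagnostic is attached as attribute `"null_fit"`
#' @export
hapflk_scan <- function(x, F, K = 20, n_fits = 30, seed = 1,
                        max_iter = 100, tol = 1e-4) {
  keep <- x$pops %in% rownames(F)
  xt <- genotype_table(x$map, x$geno[keep, , drop = FALSE], x$pops[keep],
                       alleles = x$alleles, ids = x$ids[keep])
  fits <- lapply(seq_len(n_fits) - 1L, function(s) {
    fit_cluster_model(xt, K = K, seed = seed + s, max_iter = max_iter,
                      tol = tol)
  })
  res <- hapflk_statistic(fits, F)
  pv <- empirical_pvalues(res$stat)
  res$p_value <- as.numeric(pv)
  res$q_value <- fdr_qvalues(res$p_value)
  attr(res, "null_fit") <- attributes(pv)[c("df", "ks_stat", "hist_counts")]
  res
}

#' Raw P-values from the empirical null of a statistic
#'
#' Fits the null distribution of a genome-wide statistic robustly (so that
#' the minority of selected regions does not distort it): the statistic is
#' standardized by its median and a median-absolute-deviation-derived
#' scale, and referred to a chi-square distribution whose degrees of
#' freedom are chosen on a grid to minimize the Kolmogorov-Smirnov distance
#' between the mapped statistic and the candidate chi-square (each
#' candidate is aligned to the data by its own median and MAD, so the fit
#' is robust to a minority of true signals). A uniformity diagnostic
#' (10-bin histogram counts of the P-values and the one-sample
#' Kolmogorov-Smirnov statistic against Uniform(0,1)) is attached.
#'
#' @param stats per-SNP statistic values (at least 100; constant input is
#'   an error)
#' @return numeric vector of P-values (monotone nonincreasing in the
#'   statistic) with attributes `df`, `ks_stat`, `hist_counts`
#' @export
empirical_pvalues <- function(stats) {
  stopifnot(length(stats) >= 100)
  med <- stats::median(stats)
  sc <- stats::mad(stats, constant = 1)
  if (sc <= .Machine$double.eps) stop("degenerate (constant) statistics")
  z <- (stats - med) / sc
  p_at <- function(df) {
    s_ref <- stats::qchisq(0.5, df) + z * chisq_mad(df)
    stats::pchisq(pmax(s_ref, 0), df, lower.tail = FALSE)
  }
  df_grid <- exp(seq(log(0.5), log(400), length.out = 50))
  ks_at <- vapply(df_grid, function(df) {
    pv <- p_at(df)
    max(abs(sort(pv) - (seq_along(pv) - 0.5) / length(pv)))
  }, numeric(1))
  df <- df_grid[which.min(ks_at)]
  p <- p_at(df)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))$statistic
  structure(p, df = df, ks_stat = unname(ks),
            hist_counts = graphics::hist(p, breaks = seq(0, 1, 0.1),
                                         plot = FALSE)$counts)
}

# median absolute deviation of the chi-square(df) distribution
chisq_mad <- function(df) {
  m <- stats::qchisq(0.5, df)
  f <- function(t) {
    stats::pchisq(m + t, df) - stats::pchisq(max(m - t, 0), df) - 0.5
  }
  stats::uniroot(f, c(1e-9, m + 20 * sqrt(2 * df) + 10), tol = 1e-9)$root
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min over j >= i of
#' m * p_(j) / j` on the sorted P-values, mapped back to input order.
#'
#' @param p raw P-values in `[0, 1]`
#' @return q-values, elementwise `>= p`
#' @export
fdr_qvalues <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}
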