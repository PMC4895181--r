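#' FST from locus and population effects
#'
#' The scan decomposes the locus-by-population FST on the logit scale into a
#' locus-specific effect `alpha` (shared across populations) and a
#' population-specific effect `beta` (shared across loci):
#' `FST = 1 / (1 + exp(-(alpha + beta)))`.
#'
#' @param alpha locus effect (directional selection when > 0, balancing or
#'   purifying when < 0)
#' @param beta population effect
#' @return FST in (0, 1)
#' @export
fst_from_effects <- function(alpha, beta) {
  stats::plogis(alpha + beta)
}

#' Beta-binomial log-likelihood of one locus
#'
#' Population allele frequencies are modelled as Dirichlet (Beta in the
#' biallelic case) around an ancestral frequency `p`, with concentration
#' `theta = 1/FST - 1`; the observed reference-allele count of each
#' population is then marginally beta-binomial with shape parameters
#' `theta * p` and `theta * (1 - p)`. Contributions are summed over
#' populations; a population with `n = 0` contributes zero. FST values are
#' clamped to `[1e-8, 1 - 1e-8]`.
#'
#' @param a reference-allele counts per population
#' @param n allele totals per population (2 x individuals)
#' @param p ancestral reference-allele frequency in (0, 1)
#' @param fst per-population FST values (recycled if scalar)
#' @return log-likelihood (includes the binomial coefficient terms)
#' @export
locus_log_likelihood <- function(a, n, p, fst) {
  stopifnot(all(a >= 0), all(a <= n), p > 0, p < 1)
  fst <- rep_len(pmin(pmax(fst, 1e-8), 1 - 1e-8), length(a))
  theta <- 1 / fst - 1
  sum(lchoose(n, a) + lbeta(a + theta * p, n - a + theta * (1 - p)) -
        lbeta(theta * p, theta * (1 - p)))
}

# Vectorized beta-binomial log-likelihood without the binomial constant.
# a, n: loci x groups matrices; p: length-L vector; fst: loci x groups.
bb_loglik <- function(a, n, p, fst) {
  fst <- pmin(pmax(fst, 1e-8), 1 - 1e-8)
  theta <- 1 / fst - 1
  s1 <- theta * p
  s2 <- theta * (1 - p)
  lbeta(a + s1, n - a + s2) - lbeta(s1, s2)
}

#' MCMC configuration for the FST-outlier scan
#'
#' Defaults follow the published analysis settings: 20 pilot runs of 5,000
#' iterations for proposal tuning, 50,000 burn-in iterations, a thinning
#' interval of 10 with 5,000 retained samples (so 100,000 post-pilot
#' iterations in total), and a prior odds ratio of 10 in favour of the
#' neutral model (prior inclusion probability 1/11).
#'
#' @param n_pilot number of pilot runs
#' @param pilot_len iterations per pilot run
#' @param burn_in burn-in iterations
#' @param thinning iterations between retained samples
#' @param n_samples retained posterior samples
#' @param prior_odds prior odds of the neutral model over the selection
#'   model per locus
#' @param seed integer seed (the sampler is bit-reproducible given the seed)
#' @return object of class `mcmc_config`
#' @export
mcmc_config <- function(n_pilot = 20, pilot_len = 5000, burn_in = 50000,
                        thinning = 10, n_samples = 5000, prior_odds = 10,
                        seed = 1) {
  stopifnot(n_pilot >= 0, pilot_len > 0, burn_in >= 0, thinning > 0,
            n_samples > 0, prior_odds > 0)
  structure(list(n_pilot = as.integer(n_pilot),
                 pilot_len = as.integer(pilot_len),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_samples = as.integer(n_samples),
                 prior_odds = prior_odds, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Group allele counts from a genotype table
#'
#' Sums reference-allele counts and allele totals within groups of
#' populations (e.g. dairy vs non-dairy), the input of [run_rjmcmc()].
#'
#' @param x a [genotype_table()]
#' @param group_map named character vector or list mapping population name
#'   to group name
#' @return list with matrices `a` (counts) and `n` (totals), loci x groups
#' @export
group_allele_counts <- function(x, group_map) {
  miss <- setdiff(unique(x$pops), names(group_map))
  if (length(miss)) {
    stop("populations without a group assignment: ",
         paste(miss, collapse = ", "))
  }
  groups <- sort(unique(unlist(group_map)))
  L <- ncol(x$geno)
  a <- matrix(0, L, length(groups), dimnames = list(x$map$snp, groups))
  n <- a
  grp_of_ind <- unlist(group_map)[x$pops]
  for (g in groups) {
    gg <- x$geno[grp_of_ind == g, , drop = FALSE]
    n_obs <- colSums(!is.na(gg))
    a[, g] <- colSums(gg, na.rm = TRUE)
    n[, g] <- 2 * n_obs
  }
  list(a = a, n = n)
}

#' Reversible-jump MCMC FST-outlier scan
#'
#' Samples the posterior of the logistic FST decomposition (see
#' [fst_from_effects()]) with a beta-binomial likelihood per locus and
#' group (see [locus_log_likelihood()]). Each iteration performs
#' Metropolis-within-Gibbs random-walk updates of the ancestral frequencies
#' `p_i` (on the logit scale, uniform prior on `p`), of the locus effects
#' `alpha_i` for included loci (prior `Normal(0, 1)`), and of the group
#' effects `beta_j` (prior `Normal(-1, 1)`), followed by a reversible-jump
#' toggle of each locus's `alpha` inclusion with the prior as the
#' trans-dimensional proposal; the prior inclusion probability is
#' `1 / (1 + prior_odds)`. Pilot runs tune every proposal width into the
#' acceptance band `[0.25, 0.45]` (multiplicative updates x1.25 / /1.25).
#'
#' @param a loci x groups matrix of reference-allele counts
#'   (or a list with elements `a` and `n` from [group_allele_counts()])
#' @param n loci x groups matrix of allele totals
#' @param config an [mcmc_config()]
#' @return data.frame of class `outlier_result`: `locus`, `p_incl`
#'   (posterior inclusion probability), `post_odds` (with `p_incl` clamped
#'   at `1 - 1/n_samples`), `alpha_mean` (model-averaged posterior mean),
#'   `q_value` (see [q_values_from_posteriors()]), `decision`
#'   ("directional" if `alpha_mean > 0`, else "balancing")
#' @export
run_rjmcmc <- function(a, n = NULL, config = mcmc_config()) {
  if (is.list(a) && !is.null(a$a)) {
    n <- a$n
    a <- a$a
  }
  stopifnot(inherits(config, "mcmc_config"), is.matrix(a), is.matrix(n),
            all(dim(a) == dim(n)), all(a >= 0), all(a <= n))
  G <- ncol(a)
  if (G < 2) stop("at least 2 population groups are required")
  L <- nrow(a)
  set.seed(config$seed)
  pi_incl <- 1 / (1 + config$prior_odds)
  log_prior_ratio_add <- log(pi_incl) - log(1 - pi_incl)

  # state
  tot_a <- rowSums(a)
  tot_n <- rowSums(n)
  p_hat <- (tot_a + 0.5) / (tot_n + 1)
  x_p <- stats::qlogis(p_hat)              # logit ancestral frequency
  alpha <- numeric(L)
  incl <- rep(FALSE, L)
  beta <- rep(-1, G)
  sd_p <- rep(0.5, L)
  sd_a <- rep(0.5, L)
  sd_b <- rep(0.2, G)

  fst_mat <- function(alpha, beta) {
    stats::plogis(outer(alpha, beta, `+`))
  }
  ll <- bb_loglik(a, n, stats::plogis(x_p), fst_mat(alpha, beta))

  acc_p <- num_p <- numeric(L)
  acc_a <- num_a <- numeric(L)
  acc_b <- num_b <- numeric(G)

  sweep_iter <- function() {
    p_cur <- stats::plogis(x_p)
    # 1) ancestral frequencies, vectorized RW on logit scale
    x_new <- x_p + stats::rnorm(L, 0, sd_p)
    ll_new <- bb_loglik(a, n, stats::plogis(x_new), fst_mat(alpha, beta))
    log_r <- rowSums(ll_new) - rowSums(ll) +
      stats::dlogis(x_new, log = TRUE) - stats::dlogis(x_p, log = TRUE)
    acc <- log(stats::runif(L)) < log_r
    x_p[acc] <<- x_new[acc]
    ll[acc, ] <<- ll_new[acc, , drop = FALSE]
    num_p <<- num_p + 1
    acc_p <<- acc_p + acc
    p_cur <- stats::plogis(x_p)
    # 2) alpha RW for included loci
    idx <- which(incl)
    if (length(idx)) {
      a_new <- alpha
      a_new[idx] <- alpha[idx] + stats::rnorm(length(idx), 0, sd_a[idx])
      ll_new <- bb_loglik(a[idx, , drop = FALSE], n[idx, , drop = FALSE],
                          p_cur[idx], fst_mat(a_new[idx], beta))
      log_r <- rowSums(ll_new) - rowSums(ll[idx, , drop = FALSE]) +
        stats::dnorm(a_new[idx], 0, 1, log = TRUE) -
        stats::dnorm(alpha[idx], 0, 1, log = TRUE)
      acc <- log(stats::runif(length(idx))) < log_r
      ai <- idx[acc]
      alpha[ai] <<- a_new[ai]
      ll[ai, ] <<- ll_new[acc, , drop = FALSE]
      num_a[idx] <<- num_a[idx] + 1
      acc_a[ai] <<- acc_a[ai] + 1
    }
    # 3) reversible-jump toggle per locus; proposal for a new alpha is its
    #    prior, so proposal and prior terms cancel and only the likelihood
    #    ratio and the inclusion prior odds remain
    prop_alpha <- stats::rnorm(L, 0, 1)
    cand <- ifelse(incl, 0, prop_alpha)
    ll_new <- bb_loglik(a, n, p_cur, fst_mat(cand, beta))
    log_r <- rowSums(ll_new) - rowSums(ll) +
      ifelse(incl, -log_prior_ratio_add, log_prior_ratio_add)
    acc <- log(stats::runif(L)) < log_r
    alpha[acc] <<- cand[acc]
    incl[acc] <<- !incl[acc]
    ll[acc, ] <<- ll_new[acc, , drop = FALSE]
    # 4) beta per group
    for (j in seq_len(G)) {
      b_new <- beta[j] + stats::rnorm(1, 0, sd_b[j])
      llj <- bb_loglik(a[, j, drop = FALSE], n[, j, drop = FALSE], p_cur,
                       stats::plogis(alpha + b_new))
      log_r <- sum(llj) - sum(ll[, j]) +
        stats::dnorm(b_new, -1, 1, log = TRUE) -
        stats::dnorm(beta[j], -1, 1, log = TRUE)
      num_b[j] <<- num_b[j] + 1
      if (log(stats::runif(1)) < log_r) {
        beta[j] <<- b_new
        ll[, j] <<- llj
        acc_b[j] <<- acc_b[j] + 1
      }
    }
  }

  tune <- function(sd, acc, num) {
    rate <- ifelse(num > 0, acc / num, 0.35)
    sd[rate < 0.25] <- sd[rate < 0.25] / 1.25
    sd[rate > 0.45] <- sd[rate > 0.45] * 1.25
    sd
  }

  for (pr in seq_len(config$n_pilot)) {
    acc_p[] <- num_p[] <- acc_a[] <- num_a[] <- acc_b[] <- num_b[] <- 0
    for (it in seq_len(config$pilot_len)) sweep_iter()
    sd_p <- tune(sd_p, acc_p, num_p)
    sd_a <- tune(sd_a, acc_a, num_a)
    sd_b <- tune(sd_b, acc_b, num_b)
  }
  for (it in seq_len(config$burn_in)) sweep_iter()

  sum_incl <- numeric(L)
  sum_alpha <- numeric(L)
  beta_samples <- matrix(NA_real_, config$n_samples, G)
  for (s in seq_len(config$n_samples)) {
    for (it in seq_len(config$thinning)) sweep_iter()
    sum_incl <- sum_incl + incl
    sum_alpha <- sum_alpha + alpha
    beta_samples[s, ] <- beta
  }
  p_incl <- sum_incl / config$n_samples
  alpha_mean <- sum_alpha / config$n_samples
  p_clamped <- pmin(p_incl, 1 - 1 / config$n_samples)
  res <- data.frame(
    locus = if (!is.null(rownames(a))) rownames(a) else
      sprintf("locus%d", seq_len(L)),
    p_incl = p_incl,
    post_odds = p_clamped / (1 - p_clamped),
    alpha_mean = alpha_mean,
    q_value = q_values_from_posteriors(p_incl),
    decision = ifelse(alpha_mean > 0, "directional", "balancing"),
    stringsAsFactors = FALSE)
  class(res) <- c("outlier_result", "data.frame")
  attr(res, "beta_mean") <- colMeans(beta_samples)
  attr(res, "proposal_sd") <- list(p = sd_p, alpha = sd_a, beta = sd_b)
  res
}

#' q-values from posterior inclusion probabilities
#'
#' Ranks loci by decreasing posterior inclusion probability `P` and reports
#' for each locus the estimated false discovery rate if the list were cut
#' there: the mean of `1 - P` over all loci ranked at or above it. Ties in
#' `P` share the worse (larger) q-value.
#'
#' @param p posterior inclusion probabilities in `[0, 1]`
#' @return q-values in input order
#' @export
q_values_from_posteriors <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  ord <- order(p, decreasing = TRUE)
  q_sorted <- cumsum(1 - p[ord]) / seq_along(p)
  # ties share the worse q: take the max q within each tied block
  q_sorted <- stats::ave(q_sorted, p[ord], FUN = max)
  q <- numeric(length(p))
  q[ord] <- q_sorted
  q
}
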