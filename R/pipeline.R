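#' Pipeline run configuration
#'
#' Bundles every stage's settings. The defaults mirror the published
#' analysis design: two trait groups (dairy vs non-dairy) for the
#' FST-outlier scan, one strongly divergent population excluded from the
#' selection scans, K = 20 haplotype clusters averaged over 30 EM fits, and
#' a 10,000-shift circular permutation with 1 Mb windows around outlier
#' SNPs.
#'
#' @param sim optional [sim_config()]; when present the pipeline simulates
#'   its input data
#' @param qc a [qc_config()]
#' @param group_map named list/vector population -> group label for the
#'   FST-outlier scan
#' @param excluded_pops populations excluded from the selection scans (but
#'   kept in the structure stage)
#' @param mcmc an [mcmc_config()]
#' @param clusters haplotype cluster count K
#' @param em_fits number of EM fits averaged by hapFLK
#' @param em_max_iter,em_tol EM controls
#' @param region_alpha P-value threshold for sweep-region calling
#' @param max_gap_snps gap tolerance of [call_regions()]
#' @param outlier_q q-value threshold for FST outlier SNPs
#' @param window_mb half-window (Mb) around outlier SNPs in the overlap test
#' @param n_perm circular-permutation replicates
#' @param seed global seed; each stochastic stage uses a fixed offset of it
#' @param out_dir optional output directory for TSV/JSON artifacts
#' @return object of class `run_config`
#' @export
run_config <- function(sim = NULL, qc = qc_config(), group_map = NULL,
                       excluded_pops = character(0), mcmc = mcmc_config(),
                       clusters = 20, em_fits = 30, em_max_iter = 100,
                       em_tol = 1e-4, region_alpha = 0.05, max_gap_snps = 2,
                       outlier_q = 0.05, window_mb = 1, n_perm = 10000,
                       seed = 1, out_dir = NULL) {
  structure(list(sim = sim, qc = qc, group_map = group_map,
                 excluded_pops = excluded_pops, mcmc = mcmc,
                 clusters = clusters, em_fits = em_fits,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 region_alpha = region_alpha, max_gap_snps = max_gap_snps,
                 outlier_q = outlier_q, window_mb = window_mb,
                 n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `qc`, `mcmc` and
#' `sim` blocks mirror [qc_config()], [mcmc_config()] and [sim_config()]
#' fields.
#'
#' @param path YAML file
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$mcmc)) args$mcmc <- do.call(mcmc_config, y$mcmc)
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  do.call(run_config, args)
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Run the full selection-scan pipeline
#'
#' Sequences the analysis stages: (optional) simulation, SNP quality
#' control, population structure (frequencies, Reynolds distances,
#' neighbor-joining tree, kinship, identity-by-state MDS), the FST-outlier
#' reversible-jump MCMC scan on the configured trait groups, the FLK and
#' hapFLK scans, sweep-region calling, and the circular permutation test of
#' overlap between the FST-outlier windows and the hapFLK regions. Any
#' stage failure aborts with an error naming the stage. Re-running with the
#' same configuration and seed reproduces every number bit-for-bit.
#'
#' @param config a [run_config()]
#' @param table a [genotype_table()] (required unless `config$sim` is set)
#' @return list of class `pipeline_result` with elements `qc`, `structure`,
#'   `bayescan`, `flk`, `hapflk`, `regions`, `overlap`, and `report`
#'   (stage-by-stage summary including seeds and the config digest)
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  digest <- config_digest(config)
  report <- list(config_md5 = digest, seed = config$seed, stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    out
  }

  if (is.null(table)) {
    if (is.null(config$sim)) stop("either a genotype table or a sim config is required")
    sim <- stage("simulate", simulate_dataset(config$sim))
    table <- sim$table
    report$stages$simulate$n_snps <- ncol(table$geno)
  }
  bad <- setdiff(config$excluded_pops, unique(table$pops))
  if (length(bad)) {
    stop("excluded population(s) absent from the data: ",
         paste(bad, collapse = ", "))
  }

  qc <- stage("qc", apply_qc(table, config$qc))
  report$stages$qc$removed <- stats::setNames(qc$report$n_removed,
                                              qc$report$rule)
  report$stages$qc$n_snps_out <- ncol(qc$table$geno)
  tab <- qc$table

  struct <- stage("structure", {
    freqs <- pop_frequencies(tab)
    reyn <- reynolds_matrix(freqs)
    tree <- neighbor_joining(reyn)
    scan_pops <- setdiff(sort(unique(tab$pops)), config$excluded_pops)
    # Reynolds distance between two pure-drift populations is half their
    # total drift path, so NJ branch lengths are doubled to put the kinship
    # in drift-variance units (Var(p_i) = F_ii * p0 * (1 - p0))
    dtree <- tree
    dtree$edge.length <- dtree$edge.length * 2
    kin <- kinship_from_tree(dtree)[scan_pops, scan_pops]
    mds <- classical_mds(ibs_distance_matrix(tab), k = 2)
    list(freqs = freqs, reynolds = reyn, tree = tree, kinship = kin,
         mds = mds, scan_pops = scan_pops)
  })
  report$stages$structure$populations <- rownames(struct$reynolds)

  scan_tab <- tab
  keep <- tab$pops %in% struct$scan_pops
  scan_tab <- genotype_table(tab$map, tab$geno[keep, , drop = FALSE],
                             tab$pops[keep], alleles = tab$alleles,
                             ids = tab$ids[keep])

  bayescan <- stage("bayescan", {
    gm <- config$group_map
    if (is.null(gm)) stop("group_map is required for the FST-outlier scan")
    gm <- gm[names(gm) %in% struct$scan_pops]
    cfg <- config$mcmc
    cfg$seed <- config$seed + 100L
    run_rjmcmc(group_allele_counts(scan_tab, gm), config = cfg)
  })
  report$stages$bayescan$n_outliers <-
    sum(bayescan$q_value <= config$outlier_q)

  flk <- stage("flk", flk_scan(pop_frequencies(scan_tab), struct$kinship))
  report$stages$flk$n_sig_q <- sum(flk$q_value <= 0.05)

  hapflk <- stage("hapflk", hapflk_scan(
    scan_tab, struct$kinship, K = config$clusters, n_fits = config$em_fits,
    seed = config$seed + 200L, max_iter = config$em_max_iter,
    tol = config$em_tol))
  report$stages$hapflk$n_sig_raw <- sum(hapflk$p_value < 0.05)
  report$stages$hapflk$n_sig_q <- sum(hapflk$q_value <= 0.05)

  regions <- stage("regions", {
    hap_regions <- call_regions(hapflk$p_value, tab$map,
                                alpha = config$region_alpha,
                                max_gap_snps = config$max_gap_snps,
                                source = "hapflk")
    out_idx <- which(bayescan$q_value <= config$outlier_q)
    bs_windows <- snp_windows(tab$map$chrom[out_idx], tab$map$pos[out_idx],
                              w = config$window_mb * 1e6, merge = FALSE,
                              label = tab$map$snp[out_idx],
                              source = "fst_outliers")
    list(hapflk = hap_regions, bayescan_windows = bs_windows)
  })
  report$stages$regions$n_hapflk_regions <- nrow(regions$hapflk)
  report$stages$regions$n_outlier_windows <- nrow(regions$bayescan_windows)

  overlap <- stage("overlap_test", {
    if (nrow(regions$hapflk) == 0 || nrow(regions$bayescan_windows) == 0) {
      NULL
    } else {
      circular_permutation_test(regions$hapflk, regions$bayescan_windows,
                                tab$map, n_perm = config$n_perm,
                                seed = config$seed + 300L)
    }
  })
  if (!is.null(overlap)) {
    report$stages$overlap_test$observed <- overlap$observed
    report$stages$overlap_test$p_value <- overlap$p_value
  }
  report$total_seconds <- round(proc.time()[3] - t_all, 2)

  res <- structure(
    list(qc = qc, structure = struct, bayescan = bayescan, flk = flk,
         hapflk = hapflk, regions = regions, overlap = overlap,
         report = report),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# seed=%d config_md5=%s", config$seed,
                 res$report$config_md5)
  wt <- function(df, file) {
    path <- file.path(config$out_dir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(res$qc$report, "qc_report.tsv")
  wt(data.frame(pop = rownames(res$structure$reynolds),
                res$structure$reynolds), "reynolds.tsv")
  wt(data.frame(pop = rownames(res$structure$kinship),
                res$structure$kinship), "kinship.tsv")
  wt(res$bayescan, "fst_outliers.tsv")
  wt(res$flk, "flk.tsv")
  wt(res$hapflk, "hapflk.tsv")
  wt(as.data.frame(res$regions$hapflk), "hapflk_regions.tsv")
  wt(as.data.frame(res$regions$bayescan_windows), "outlier_windows.tsv")
  wt(data.frame(individual = rownames(res$structure$mds$points),
                pop = res$qc$table$pops,
                res$structure$mds$points), "mds.tsv")
  ape::write.tree(res$structure$tree,
                  file.path(config$out_dir, "genome_tree.nwk"))
  if (!is.null(res$overlap)) {
    jsonlite::write_json(
      list(observed = res$overlap$observed, n_perm = res$overlap$n_perm,
           p_value = res$overlap$p_value, seed = res$overlap$seed,
           config_md5 = res$report$config_md5),
      file.path(config$out_dir, "overlap_test.json"), auto_unbox = TRUE)
    wt(data.frame(count = res$overlap$counts), "overlap_counts.tsv")
  }
  jsonlite::write_json(res$report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, force = TRUE)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("selection-scan pipeline result\n")
  cat("  SNPs after QC:", ncol(x$qc$table$geno), "\n")
  cat("  FST outliers (q <= 0.05):",
      sum(x$bayescan$q_value <= 0.05), "\n")
  cat("  hapFLK regions called:", nrow(x$regions$hapflk), "\n")
  if (!is.null(x$overlap)) {
    cat("  overlap test: observed =", x$overlap$observed,
        ", P =", format(x$overlap$p_value, digits = 4), "\n")
  }
  invisible(x)
}
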