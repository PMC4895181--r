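#' Packaged reference sweep tables (Spanish sheep, Ovine 50K scan)
#'
#' Two published results tables from a selection scan of Spanish sheep
#' breeds genotyped on the Ovine 50K array ship with the package as TSV
#' fixtures: (a) the 39 outlier SNPs called by the Bayesian FST-outlier
#' method (chromosome, SNP name, position in Mb, posterior mean locus effect
#' alpha, q-value), together with the intervals from two earlier sheep scans
#' (a dairy-breed scan and a worldwide-breed scan) that co-localize with
#' some of the outliers; and (b) the 15 putative sweep regions from the
#' hapFLK analysis of the same data (region bounds in Mb, flanking SNPs,
#' SNP count, raw P-value, q-value, co-localizations, and whether the region
#' was also supported by the FST-outlier scan).
#'
#' Both loaders verify an MD5 checksum of the packaged file and fail hard on
#' a mismatch.
#'
#' @param path optional override of the packaged file (used in tests)
#' @return data.frame with the printed records; interval columns are
#'   strings of the form `"start-end"` in Mb (`NA`/empty when the printed
#'   cell was empty)
#' @export
sheep_bayescan_outliers <- function(path = NULL) {
  read_fixture(path, "spanish_sheep_bayescan_outliers.tsv",
               "6d9f71fd5faa19262bc0e94b87f3e172")
}

#' @rdname sheep_bayescan_outliers
#' @export
sheep_hapflk_sweeps <- function(path = NULL) {
  read_fixture(path, "spanish_sheep_hapflk_sweeps.tsv",
               "80f92c6b5ddb006e2d6cf7852f10bdee")
}

#' @rdname sheep_bayescan_outliers
#' @return `load_reference_sweep_tables`: list with elements `bayescan` and
#'   `hapflk`
#' @export
load_reference_sweep_tables <- function() {
  list(bayescan = sheep_bayescan_outliers(), hapflk = sheep_hapflk_sweeps())
}

read_fixture <- function(path, file, md5) {
  if (is.null(path)) {
    path <- system.file("extdata", file, package = "sweepscan", mustWork = TRUE)
  }
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5)) {
    stop("fixture checksum mismatch for ", basename(path),
         ": expected ", md5, ", got ", got)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# "a-b" (Mb) -> c(a, b), NA-safe
parse_mb_interval <- function(s) {
  if (is.na(s) || !nzchar(s)) return(c(NA_real_, NA_real_))
  as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
}

#' Prior-study intervals printed alongside the outlier table
#'
#' Collects the co-localization intervals from the two earlier-scan columns
#' of [sheep_bayescan_outliers()] into one merged [sweep_set()] in bp.
#'
#' @param tab the data.frame returned by [sheep_bayescan_outliers()]
#'   (defaults to loading the packaged fixture)
#' @return merged [sweep_set()] with coordinates in bp
#' @export
prior_study_intervals <- function(tab = sheep_bayescan_outliers()) {
  rows <- list()
  for (col in c("colocal_dairy_scan", "colocal_worldwide_scan")) {
    for (i in seq_len(nrow(tab))) {
      iv <- parse_mb_interval(tab[[col]][i])
      if (!is.na(iv[1])) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = tab$chrom[i], start = iv[1] * 1e6, end = iv[2] * 1e6,
          source = col)
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- unique(df[, c("chrom", "start", "end")])
  merge_sweep_set(sweep_set(df$chrom, df$start, df$end,
                            source = "prior_studies"))
}

#' Sweep sets derived from the packaged reference tables
#'
#' Returns the fixture records as 1-based inclusive bp interval sets:
#' `bayescan_windows` (half-window `w` around each outlier SNP, unmerged so
#' that co-localizations are counted per outlier), `hapflk_regions`, and
#' `prior_intervals` (merged intervals from the earlier scans).
#'
#' @param w half-window around outlier SNP positions, bp (default 1 Mb)
#' @return list of [sweep_set()] objects
#' @export
fixture_sweep_sets <- function(w = 1e6) {
  t1 <- sheep_bayescan_outliers()
  t2 <- sheep_hapflk_sweeps()
  list(
    bayescan_windows = snp_windows(t1$chrom, t1$pos_mb * 1e6, w = w,
                                   merge = FALSE, label = t1$snp,
                                   source = "fst_outliers"),
    hapflk_regions = sweep_set(t2$chrom, t2$start_mb * 1e6, t2$end_mb * 1e6,
                               label = sprintf("chr%d:%.6g-%.6gMb", t2$chrom,
                                               t2$start_mb, t2$end_mb),
                               source = "hapflk"),
    prior_intervals = prior_study_intervals(t1)
  )
}
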