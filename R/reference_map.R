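#' Synthetic uniformly spaced SNP map at the reference array scale
#'
#' Builds a map of `n_snps` evenly spaced SNPs over the 26 sheep autosomes,
#' the scale of the post-QC Ovine 50K dataset (43,343 SNPs). Chromosome
#' lengths are taken from the packaged reference sweep tables — the largest
#' coordinate observed on each chromosome (outlier positions, region bounds
#' and co-localization intervals) plus 10% — and fall back to the package's
#' default sheep-like autosome lengths for chromosomes those tables never
#' touch. SNP counts per chromosome are proportional to length. Used to
#' place published interval sets on a common SNP-index circle for the
#' overlap permutation test.
#'
#' @param n_snps total number of SNPs (default 43343)
#' @return data.frame with `snp`, `chrom`, `pos`
#' @export
reference_snp_map <- function(n_snps = 43343) {
  t1 <- sheep_bayescan_outliers()
  t2 <- sheep_hapflk_sweeps()
  obs <- rep(NA_real_, 26)
  note <- function(chrom, mb) {
    ok <- !is.na(mb) & !is.na(chrom)
    for (i in which(ok)) {
      obs[chrom[i]] <<- max(obs[chrom[i]], mb[i], na.rm = TRUE)
    }
  }
  note(t1$chrom, t1$pos_mb)
  note(t2$chrom, t2$end_mb)
  for (col in c("colocal_dairy_scan", "colocal_worldwide_scan")) {
    note(t1$chrom, vapply(t1[[col]], function(s) parse_mb_interval(s)[2],
                          numeric(1)))
    note(t2$chrom, vapply(t2[[col]], function(s) parse_mb_interval(s)[2],
                          numeric(1)))
  }
  len <- ifelse(is.na(obs), default_chrom_lengths(26), obs * 1.1 * 1e6)
  n_per <- floor(n_snps * len / sum(len))
  rem <- n_snps - sum(n_per)
  if (rem > 0) {
    extra <- order(n_snps * len / sum(len) - n_per,
                   decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  data.frame(
    snp = sprintf("ref%05d", seq_len(n_snps)),
    chrom = rep(seq_len(26), n_per),
    pos = unlist(lapply(seq_len(26), function(ch) {
      round(seq_len(n_per[ch]) * len[ch] / n_per[ch])
    })))
}
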