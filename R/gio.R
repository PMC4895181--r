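#' Read PLINK-text PED/MAP files into a genotype table
#'
#' PED columns: FID IID PAT MAT SEX PHENO followed by two allele symbols per
#' SNP ("0" = missing allele). MAP columns: chromosome, SNP identifier,
#' genetic distance (ignored), bp position. Genotypes are recoded to
#' reference-allele dosage per SNP, the reference being the first non-missing
#' allele symbol encountered (individuals scanned in file order); the
#' reference/alternative symbols are recorded in the returned table.
#'
#' @param ped,map paths to the PED and MAP files
#' @return a [genotype_table()]
#' @export
read_ped_map <- function(ped, map) {
  stopifnot(file.exists(ped), file.exists(map))
  mp <- utils::read.table(map, stringsAsFactors = FALSE,
                          col.names = c("chrom", "snp", "cm", "pos"),
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_field <- lengths(toks)
  want <- 6L + 2L * nrow(mp)
  if (any(n_field != want)) {
    stop("ragged PED row(s) ", paste(which(n_field != want), collapse = ", "),
         ": expected ", want, " fields")
  }
  n_ind <- length(toks)
  ids <- vapply(toks, `[`, "", 2L)
  fids <- vapply(toks, `[`, "", 1L)
  am <- matrix(unlist(lapply(toks, `[`, -(1:6))), nrow = n_ind, byrow = TRUE)
  a1 <- am[, seq(1, ncol(am), by = 2), drop = FALSE]
  a2 <- am[, seq(2, ncol(am), by = 2), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-missing genotype call(s) in PED")
  geno <- matrix(NA_integer_, n_ind, nrow(mp))
  ref <- character(nrow(mp))
  alt <- character(nrow(mp))
  for (j in seq_len(nrow(mp))) {
    obs <- c(rbind(a1[, j], a2[, j]))  # individual order, both alleles
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2) {
      stop("SNP ", mp$snp[j], " has more than two alleles: ",
           paste(seen, collapse = ", "))
    }
    ref[j] <- if (length(seen)) seen[1] else "A"
    alt[j] <- if (length(seen) == 2) seen[2] else "B"
    geno[, j] <- (a1[, j] == ref[j]) + (a2[, j] == ref[j])
  }
  chrom <- suppressWarnings(as.integer(mp$chrom))
  chrom[is.na(chrom)] <- vapply(mp$chrom[is.na(chrom)], function(s) {
    switch(toupper(s), X = 27L, Y = 28L, XY = 28L, MT = 29L, M = 29L, 0L)
  }, integer(1))
  gmap <- data.frame(snp = mp$snp, chrom = chrom, pos = mp$pos,
                     stringsAsFactors = FALSE)
  gt <- genotype_table(gmap, geno, pops = fids,
                       alleles = data.frame(ref = ref, alt = alt), ids = ids)
  gt
}

#' Write a genotype table as PLINK-text PED/MAP
#'
#' The PED family identifier column carries the population label; dosage 2
#' writes two reference alleles, 0 two alternative alleles, missing writes
#' "0 0". Companion to [read_ped_map()].
#'
#' @param x a [genotype_table()]
#' @param ped,map output paths
#' @return invisibly, `c(ped, map)`
#' @export
write_ped_map <- function(x, ped, map) {
  mp <- data.frame(x$map$chrom, x$map$snp, 0, x$map$pos)
  utils::write.table(mp, map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ref <- x$alleles$ref
  alt <- x$alleles$alt
  n <- nrow(x$geno)
  rows <- character(n)
  for (i in seq_len(n)) {
    g <- x$geno[i, ]
    A1 <- ifelse(is.na(g), "0", ifelse(g >= 1, ref, alt))
    A2 <- ifelse(is.na(g), "0", ifelse(g == 2, ref, alt))
    rows[i] <- paste(c(x$pops[i], x$ids[i], 0, 0, 0, -9,
                       rbind(A1, A2)), collapse = " ")
  }
  writeLines(rows, ped)
  invisible(c(ped, map))
}

#' Re-express dosages relative to a given reference allele
#'
#' Flips dosages (`2 - g`) at SNPs where the recorded reference differs from
#' the requested one; errors if allele symbols are irreconcilable.
#'
#' @param x a [genotype_table()]
#' @param ref desired reference allele symbol per SNP
#' @return a [genotype_table()] with aligned coding
#' @export
align_alleles <- function(x, ref) {
  stopifnot(length(ref) == ncol(x$geno))
  same <- x$alleles$ref == ref
  other <- x$alleles$alt == ref
  bad <- !(same | other)
  if (any(bad)) {
    stop("irreconcilable alleles at SNP(s): ",
         paste(utils::head(x$map$snp[bad], 5), collapse = ", "))
  }
  flip <- which(other & !same)
  if (length(flip)) {
    x$geno[, flip] <- 2L - x$geno[, flip]
    tmp <- x$alleles$ref[flip]
    x$alleles$ref[flip] <- x$alleles$alt[flip]
    x$alleles$alt[flip] <- tmp
  }
  x
}

#' Merge two genotype tables
#'
#' Takes the union of SNPs matched by identifier and concatenates the
#' individuals; genotypes at SNPs absent from one source are missing for
#' that source's individuals. Allele coding is reconciled per SNP identifier
#' by flipping dosages where the two sources used opposite reference
#' alleles; disjoint allele sets raise an error (strand flips are not
#' attempted). Duplicate individual identifiers across the sources are an
#' error.
#'
#' @param a,b [genotype_table()] objects
#' @return merged [genotype_table()]; SNPs ordered by chromosome, position
#' @export
merge_tables <- function(a, b) {
  if (length(intersect(a$ids, b$ids))) {
    stop("duplicate individual identifiers: ",
         paste(utils::head(intersect(a$ids, b$ids), 5), collapse = ", "))
  }
  common <- intersect(a$map$snp, b$map$snp)
  if (length(common)) {
    ja <- match(common, a$map$snp)
    jb <- match(common, b$map$snp)
    flip <- b$alleles$ref[jb] == a$alleles$alt[ja] &
      b$alleles$ref[jb] != a$alleles$ref[ja]
    compat <- mapply(function(kb_r, kb_a, ka_r, ka_a) {
      length(intersect(c(kb_r, kb_a), c(ka_r, ka_a))) > 0
    }, b$alleles$ref[jb], b$alleles$alt[jb], a$alleles$ref[ja], a$alleles$alt[ja])
    if (any(!compat)) {
      stop("irreconcilable alleles at SNP(s): ",
           paste(utils::head(common[!compat], 5), collapse = ", "))
    }
    if (any(flip)) {
      cols <- jb[flip]
      b$geno[, cols] <- 2L - b$geno[, cols]
      tmp <- b$alleles$ref[cols]
      b$alleles$ref[cols] <- b$alleles$alt[cols]
      b$alleles$alt[cols] <- tmp
    }
  }
  all_snps <- union(a$map$snp, b$map$snp)
  map <- rbind(a$map, b$map[!(b$map$snp %in% a$map$snp), ])
  map <- map[match(all_snps, map$snp), ]
  alle <- rbind(a$alleles, b$alleles[!(b$map$snp %in% a$map$snp), , drop = FALSE])
  rownames(alle) <- c(a$map$snp, b$map$snp[!(b$map$snp %in% a$map$snp)])
  alle <- alle[all_snps, , drop = FALSE]
  n_ind <- length(a$ids) + length(b$ids)
  geno <- matrix(NA_integer_, n_ind, length(all_snps))
  geno[seq_along(a$ids), match(a$map$snp, all_snps)] <- a$geno
  geno[length(a$ids) + seq_along(b$ids), match(b$map$snp, all_snps)] <- b$geno
  ord <- order(map$chrom, map$pos)
  gt <- genotype_table(map[ord, ], geno[, ord, drop = FALSE],
                       pops = c(a$pops, b$pops),
                       alleles = alle[ord, , drop = FALSE],
                       ids = c(a$ids, b$ids))
  gt
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided P-value for departure from Hardy-Weinberg proportions,
#' using the conditional distribution of the heterozygote count given the
#' allele counts, `P(h) proportional to N! / (nAA! h! naa!) * 2^h`
#' (Levene/Haldane). The P-value sums the probabilities of all heterozygote
#' counts at most as probable as the observed one (the convention used by
#' PLINK). Monomorphic SNPs return 1.
#'
#' @param nAA,nAa,naa genotype counts (non-negative, not all zero)
#' @return exact P-value in (0, 1]
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0, nAA + nAa + naa > 0)
  nA <- 2 * nAA + nAa
  nB <- 2 * naa + nAa
  if (nA == 0 || nB == 0) return(1.0)
  N <- nAA + nAa + naa
  h <- seq(nA %% 2, min(nA, nB), by = 2)
  lw <- lfactorial(N) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((nB - h) / 2) + h * log(2)
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' SNP quality-control configuration
#'
#' Thresholds of the three-step SNP filter applied by [apply_qc()]:
#' (1) drop unmapped SNPs and SNPs on sex chromosomes, (2) drop SNPs with a
#' genotyping call rate strictly below `min_call_rate` or a minor allele
#' frequency strictly below `min_maf`, (3) drop SNPs with a Hardy-Weinberg
#' exact P-value at or below `hwe_p_threshold` (pooled over all
#' individuals).
#'
#' @param min_call_rate minimum genotyping rate per SNP (default 0.90)
#' @param min_maf minimum minor allele frequency (default 0.05; SNPs with
#'   MAF exactly at the threshold are kept)
#' @param hwe_p_threshold HWE exact-test threshold (default 0.001,
#'   inclusive: P <= threshold is removed)
#' @param drop_unmapped drop SNPs with no map position (default TRUE)
#' @param drop_sex_chromosomes drop SNPs outside autosomes 1-26
#'   (default TRUE)
#' @return object of class `qc_config`
#' @export
qc_config <- function(min_call_rate = 0.90, min_maf = 0.05,
                      hwe_p_threshold = 0.001, drop_unmapped = TRUE,
                      drop_sex_chromosomes = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            hwe_p_threshold >= 0, hwe_p_threshold <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_threshold = hwe_p_threshold,
                 drop_unmapped = drop_unmapped,
                 drop_sex_chromosomes = drop_sex_chromosomes),
            class = "qc_config")
}

#' Apply SNP quality control
#'
#' Filters SNPs in three ordered steps (see [qc_config()]); each step sees
#' only the SNPs that survived the previous one, and the call rate / MAF /
#' HWE statistics are computed on non-missing genotypes pooled over all
#' individuals.
#'
#' @param x a [genotype_table()]
#' @param config a [qc_config()]
#' @return list with `table` (filtered [genotype_table()]) and `report`
#'   (data.frame `rule`, `n_removed`; rows sum to the total SNPs removed)
#' @export
apply_qc <- function(x, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  n0 <- ncol(x$geno)
  keep <- rep(TRUE, n0)
  # rule 1: unmapped / sex chromosomes (autosome codes 1-26)
  r1 <- rep(FALSE, n0)
  if (config$drop_unmapped) {
    r1 <- r1 | is.na(x$map$chrom) | x$map$chrom == 0 | is.na(x$map$pos) |
      x$map$pos <= 0
  }
  if (config$drop_sex_chromosomes) {
    r1 <- r1 | (!is.na(x$map$chrom) & (x$map$chrom < 1 | x$map$chrom > 26))
  }
  keep[r1] <- FALSE
  # rule 2: call rate / MAF on survivors
  r2 <- rep(FALSE, n0)
  idx2 <- which(keep)
  if (length(idx2)) {
    g <- x$geno[, idx2, drop = FALSE]
    n_obs <- colSums(!is.na(g))
    call_rate <- n_obs / nrow(g)
    p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_obs, 1))
    maf <- pmin(p, 1 - p)
    fail <- call_rate < config$min_call_rate | maf < config$min_maf |
      n_obs == 0
    r2[idx2[fail]] <- TRUE
    keep[r2] <- FALSE
  }
  # rule 3: HWE exact test, pooled individuals, on survivors
  r3 <- rep(FALSE, n0)
  idx3 <- which(keep)
  if (length(idx3)) {
    pv <- vapply(idx3, function(j) {
      g <- x$geno[, j]
      g <- g[!is.na(g)]
      hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
    }, numeric(1))
    r3[idx3[pv <= config$hwe_p_threshold]] <- TRUE
    keep[r3] <- FALSE
  }
  report <- data.frame(
    rule = c("unmapped_or_sex_chrom", "callrate_or_maf", "hwe"),
    n_removed = c(sum(r1), sum(r2), sum(r3)))
  if (!any(keep)) {
    stop("all SNPs removed by QC (removed per rule: ",
         paste(report$n_removed, collapse = ", "), ")")
  }
  out <- genotype_table(x$map[keep, , drop = FALSE],
                        x$geno[, keep, drop = FALSE], x$pops,
                        alleles = x$alleles[keep, , drop = FALSE],
                        ids = x$ids)
  list(table = out, report = report)
}
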