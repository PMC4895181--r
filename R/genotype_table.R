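#' Genotype table container
#'
#' Holds diploid biallelic genotypes as reference-allele dosages (0, 1, 2 or
#' `NA` for missing) for a set of individuals with population labels, together
#' with a SNP map (identifier, chromosome, base-pair position).
#'
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp).
#'   Positions must be strictly increasing within each chromosome.
#' @param geno integer matrix, individuals x SNPs, values in \{0, 1, 2, NA\}.
#' @param pops character vector of population labels, one per individual.
#' @param alleles optional data.frame with columns `ref`, `alt` giving the
#'   allele symbol counted by the dosage and its alternative, one row per SNP.
#'   Defaults to "A"/"B".
#' @param ids optional individual identifiers (default `ind1`, `ind2`, ...).
#'
#' @return An object of class `genotype_table`: a list with elements `map`,
#'   `geno`, `pops`, `alleles`, `ids`.
#' @export
genotype_table <- function(map, geno, pops, alleles = NULL, ids = NULL) {
  stopifnot(is.data.frame(map), all(c("snp", "chrom", "pos") %in% names(map)))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map)) {
    stop("geno has ", ncol(geno), " SNP columns but map has ", nrow(map), " rows")
  }
  if (length(pops) != nrow(geno)) {
    stop("pops must have one label per individual (row of geno)")
  }
  if (anyNA(pops) || any(!nzchar(pops))) {
    stop("every individual must have a non-empty population label")
  }
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  if (anyDuplicated(map$snp)) stop("duplicate SNP identifiers in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  if (is.null(alleles)) {
    alleles <- data.frame(ref = rep("A", nrow(map)), alt = rep("B", nrow(map)))
  }
  stopifnot(nrow(alleles) == nrow(map))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(geno)))
  if (anyDuplicated(ids)) stop("duplicate individual identifiers")
  rownames(geno) <- ids
  colnames(geno) <- map$snp
  structure(
    list(map = map, geno = geno, pops = as.character(pops),
         alleles = alleles, ids = as.character(ids)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$pops)),
                                    as.integer(table(x$pops))), collapse = ", "), "\n")
  cat("chromosomes:", length(unique(x$map$chrom)),
      " missing rate:", signif(mean(is.na(x$geno)), 3), "\n")
  invisible(x)
}

#' Number of individuals / SNPs in a genotype table
#' @param x a `genotype_table`
#' @return integer count
#' @export
n_individuals <- function(x) nrow(x$geno)

#' @rdname n_individuals
#' @export
n_snps <- function(x) ncol(x$geno)
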