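# small builders shared across test files

toy_map <- function(L, chrom = 1, spacing = 1000) {
  data.frame(snp = sprintf("s%04d", seq_len(L)), chrom = chrom,
             pos = seq_len(L) * spacing)
}

toy_table <- function(geno, pops, chrom = 1) {
  geno <- as.matrix(geno)
  genotype_table(toy_map(ncol(geno), chrom = chrom), geno, pops)
}

# pop_freq_table from a raw frequency matrix (rownames = populations)
freq_table <- function(p, n = 100, map = NULL) {
  if (is.null(map)) map <- toy_map(ncol(p))
  structure(list(p = p, n = matrix(n, nrow(p), ncol(p),
                                   dimnames = dimnames(p)), map = map),
            class = "pop_freq_table")
}

# independent HWE oracle: closed-form conditional probabilities
# P(h | nA, nB) = multinomial(N; nAA, h, naa) * 2^h / choose(2N, nA)
hwe_oracle <- function(nAA, nAa, naa) {
  nA <- 2 * nAA + nAa
  nB <- 2 * naa + nAa
  if (nA == 0 || nB == 0) return(1)
  N <- nAA + nAa + naa
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- vapply(hs, function(h) {
    exp(lchoose(N, (nA - h) / 2) + lchoose(N - (nA - h) / 2, h) +
          h * log(2) - lchoose(2 * N, nA))
  }, numeric(1))
  sum(pr[pr <= pr[match(nAa, hs)] * (1 + 1e-12)])
}
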