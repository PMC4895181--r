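test_that("PED/MAP round-trips dosage and missingness", {
  g <- rbind(c(2L, 1L, NA), c(0L, 2L, 1L))
  gt <- toy_table(g, pops = c("fam1", "fam2"))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(gt, ped, map)
  back <- read_ped_map(ped, map)
  # reader's reference is the first allele seen; align before comparing
  back <- align_alleles(back, gt$alleles$ref)
  expect_identical(unname(back$geno), unname(gt$geno))
  expect_equal(back$map$snp, gt$map$snp)
  expect_equal(back$map$pos, gt$map$pos)
  expect_equal(back$pops, gt$pops)
})

test_that("dosage counts the recorded reference allele", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("f1 i1 0 0 0 -9 A G", "f1 i2 0 0 0 -9 G G"), ped)
  writeLines("1\tsnp1\t0\t100", map)
  gt <- read_ped_map(ped, map)
  expect_equal(gt$alleles$ref, "A")
  expect_equal(unname(gt$geno[, 1]), c(1L, 0L))
})

test_that("malformed PED input is rejected with a useful message", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("f1 i1 0 0 0 -9 A G", "f1 i2 0 0 0 -9 G T"), ped)
  writeLines("1\tbadsnp\t0\t100", map)
  expect_error(read_ped_map(ped, map), "badsnp")
  writeLines(c("f1 i1 0 0 0 -9 A G A A", "f1 i2 0 0 0 -9 G G"), ped)
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200"), map)
  expect_error(read_ped_map(ped, map), "ragged")
})

test_that("merge_tables unions SNPs and concatenates individuals", {
  a <- toy_table(rbind(c(2L, 0L), c(1L, 1L)), pops = c("p1", "p1"))
  b <- a
  b$ids <- c("ind3", "ind4")
  rownames(b$geno) <- b$ids
  m <- merge_tables(a, b)
  expect_equal(nrow(m$geno), 4)
  expect_equal(ncol(m$geno), 2)
  expect_identical(unname(m$geno[3:4, ]), unname(a$geno))
  # duplicate individual ids refuse to merge
  expect_error(merge_tables(a, a), "duplicate individual")
})

test_that("merge marks SNPs absent from one source as missing", {
  a <- toy_table(rbind(c(2L, 0L), c(1L, 1L)), pops = c("p1", "p1"))
  bmap <- data.frame(snp = "s0001", chrom = 1, pos = 1000)
  b <- genotype_table(bmap, matrix(1L, 1, 1), pops = "p2", ids = "ind9")
  m <- merge_tables(a, b)
  expect_equal(ncol(m$geno), 2)
  expect_true(is.na(m$geno["ind9", "s0002"]))
  expect_equal(m$geno["ind9", "s0001"], 1L)
})

test_that("merge reconciles flipped alleles and rejects disjoint ones", {
  amap <- data.frame(snp = "s1", chrom = 1, pos = 100)
  a <- genotype_table(amap, matrix(c(2L, 1L), 2, 1), pops = c("p", "p"),
                      alleles = data.frame(ref = "A", alt = "G"),
                      ids = c("i1", "i2"))
  b <- genotype_table(amap, matrix(c(0L, 1L), 2, 1), pops = c("q", "q"),
                      alleles = data.frame(ref = "G", alt = "A"),
                      ids = c("i3", "i4"))
  m <- merge_tables(a, b)
  # b counted G; after reconciliation its dosages count A
  expect_equal(unname(m$geno[, "s1"]), c(2L, 1L, 2L, 1L))
  bad <- genotype_table(amap, matrix(c(0L, 1L), 2, 1), pops = c("q", "q"),
                        alleles = data.frame(ref = "C", alt = "T"),
                        ids = c("i3", "i4"))
  expect_error(merge_tables(a, bad), "irreconcilable")
})

test_that("HWE exact test agrees with full enumeration for N <= 20", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(5, 0, 0), 1.0)
  for (nhet in c(1, 2, 5, 10)) {
    expect_equal(hwe_exact_test(0, nhet, 0), hwe_oracle(0, nhet, 0))
  }
  for (N in 1:20) {
    for (nAA in 0:N) {
      for (nAa in 0:(N - nAA)) {
        naa <- N - nAA - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa),
                     hwe_oracle(nAA, nAa, naa), tolerance = 1e-10)
      }
    }
  }
})

test_that("clean data passes QC untouched with an all-zero report", {
  # every column has genotype counts (2 AA, 4 Aa, 2 aa): MAF 0.5, HWE-true
  g <- matrix(rep(c(2L, 1L, 1L, 0L, 2L, 1L, 1L, 0L), 4), nrow = 8)
  gt <- toy_table(g, pops = rep("p", 8))
  out <- apply_qc(gt, qc_config())
  expect_equal(ncol(out$table$geno), 4)
  expect_equal(out$report$n_removed, c(0, 0, 0))
})

test_that("QC applies the three rules in order with literal thresholds", {
  # 20 individuals; SNP columns: 1 unmapped, 2 sex chromosome, 3 call rate
  # 17/20, 4 MAF exactly 0.05 (kept: the threshold itself passes), 5 MAF 0,
  # 6 opposite homozygotes only (HWE exact P well below 0.001), 7 clean
  n <- 20
  g <- cbind(rep(1L, n),
             rep(1L, n),
             c(rep(NA, 3), rep(1L, 17)),
             c(1L, 1L, rep(0L, n - 2)),
             rep(0L, n),
             c(rep(2L, 10), rep(0L, 10)),
             rep(c(0L, 1L, 2L, 1L, 1L), 4))
  map <- data.frame(snp = paste0("s", 1:7),
                    chrom = c(0, 27, 1, 1, 1, 1, 1),
                    pos = c(100, 100, 100, 200, 300, 400, 500))
  gt <- genotype_table(map, g, pops = rep("p", n))
  out <- apply_qc(gt, qc_config())
  expect_equal(out$report$n_removed, c(2, 2, 1))
  expect_setequal(out$table$map$snp, c("s4", "s7"))
  expect_equal(sum(out$report$n_removed), 7 - ncol(out$table$geno))
})

test_that("QC removing everything is an error and defaults match design", {
  cfg <- qc_config()
  expect_equal(cfg$min_call_rate, 0.90)
  expect_equal(cfg$min_maf, 0.05)
  expect_equal(cfg$hwe_p_threshold, 0.001)
  g <- matrix(0L, 4, 2)  # monomorphic everywhere -> MAF filter kills all
  gt <- toy_table(g, pops = rep("p", 4))
  expect_error(apply_qc(gt, cfg), "all SNPs removed")
})
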