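test_that("pop_frequencies computes dosage means and flags absent cells", {
  g <- rbind(c(0L, NA), c(1L, NA), c(2L, NA))
  gt <- toy_table(g, pops = rep("p1", 3))
  fq <- pop_frequencies(gt)
  expect_equal(unname(fq$p["p1", 1]), 0.5)
  expect_true(is.na(fq$p["p1", 2]))     # all-missing cell is absent, not 0
  expect_equal(unname(fq$n["p1", ]), c(6L, 0L))
})

test_that("pop_frequencies matches a direct recomputation on simulated data", {
  cfg <- sim_config(n_pops = 3, n_ind_per_pop = 10, n_snps = 50,
                    n_chromosomes = 1, chrom_lengths = 1e7,
                    missing_rate = 0.1, seed = 21)
  gt <- simulate_dataset(cfg)$table
  fq <- pop_frequencies(gt)
  for (pp in c("pop1", "pop3")) {
    g <- gt$geno[gt$pops == pp, ]
    expect_equal(unname(fq$p[pp, ]),
                 unname(colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))))
  }
})

test_that("IBS distance has its closed-form values on constructed pairs", {
  gt <- toy_table(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L)),
                  pops = rep("p", 3))
  d <- ibs_distance_matrix(gt)
  expect_equal(unname(d[1, 2]), 0)          # identical individuals
  g2 <- toy_table(rbind(c(0L, 0L), c(2L, 2L)), pops = c("p", "p"))
  expect_equal(unname(ibs_distance_matrix(g2)[1, 2]), 1)  # opposite homs
  # hand computation: pairs (1,3): |0-2|,|1-1|,|2-0| -> (2+0+2)/(2*3) = 2/3
  expect_equal(unname(d[1, 3]), 2 / 3)
  # missing-only overlap errors
  g3 <- toy_table(rbind(c(1L, NA), c(NA, 1L)), pops = c("p", "p"))
  expect_error(ibs_distance_matrix(g3), "zero jointly non-missing")
})

test_that("classical MDS is exact for Euclidean distances", {
  suppressWarnings(m0 <- classical_mds(matrix(0, 3, 3), k = 2))
  expect_equal(m0$points, matrix(0, 3, 0), ignore_attr = TRUE)
  # 3 collinear points, distances 1, 1, 2: 1-D embedding reproduces them
  d <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  suppressWarnings(m <- classical_mds(d, k = 2))
  emb <- unname(as.matrix(dist(m$points)))
  expect_equal(emb, unname(d), tolerance = 1e-8)
  # random 2-D configuration: embedded distances equal originals to 1e-8
  set.seed(5)
  xy <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(xy))
  m2 <- classical_mds(d2, k = 2)
  expect_equal(as.matrix(dist(m2$points)), d2, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Reynolds distance follows the ratio-of-sums formula", {
  p <- rbind(a = c(0.6, 0.2), b = c(0.4, 0.2))
  fq <- freq_table(p)
  expect_equal(reynolds_distance(fq, "a", "a"), 0)
  # hand evaluation: theta = 0.04 / 0.84, D = -ln(1 - theta)
  expect_equal(reynolds_distance(fq, "a", "b"), -log(1 - 0.04 / 0.84),
               tolerance = 1e-12)
  # complete fixation hits the documented cap
  pf <- rbind(a = 1, b = 0)
  expect_warning(dcap <- reynolds_distance(freq_table(pf), "a", "b"),
                 "capped")
  expect_equal(dcap, 50)
  # jointly monomorphic SNPs contribute to neither sum: adding one leaves
  # the single-locus value theta = 0.04 / 0.52 unchanged
  p2 <- rbind(a = c(0.6, 0), b = c(0.4, 0))
  expect_equal(reynolds_distance(freq_table(p2), "a", "b"),
               -log(1 - 0.04 / 0.52), tolerance = 1e-12)
})

test_that("neighbor joining recovers additive distance matrices exactly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-8)
  # 3 taxa: branch lengths solve the three path equations exactly
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- neighbor_joining(d3)
  expect_equal(ape::cophenetic.phylo(tr3)[letters[1:3], letters[1:3]], d3,
               tolerance = 1e-8)
  # permuting labels yields an isomorphic tree
  perm <- c(3, 1, 4, 2)
  trp <- neighbor_joining(d[perm, perm])
  expect_equal(ape::cophenetic.phylo(trp)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-8)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("kinship from a tree is the shared root-path length", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  expect_equal(kinship_from_tree(tr),
               matrix(c(0.1, 0, 0, 0.1), 2, 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  tr2 <- ape::read.tree(text = "((A:0.05,B:0.05):0.1,C:0.2);")
  FF <- kinship_from_tree(tr2)
  expect_equal(FF["A", "B"], 0.1)
  expect_equal(FF["A", "A"], 0.15)
  expect_equal(FF["C", "C"], 0.2)
  expect_equal(FF["A", "C"], 0)
  # any valid tree: positive semidefinite
  set.seed(8)
  for (i in 1:5) {
    rt <- ape::rtree(6)
    ev <- eigen(kinship_from_tree(rt), symmetric = TRUE, only.values = TRUE)
    expect_true(all(ev$values > -1e-10))
  }
  # star tree kinship is diagonal
  st <- star_drift_tree(paste0("p", 1:5), drift = 0.07)
  Fs <- kinship_from_tree(st)
  expect_equal(Fs, diag(0.07, 5), ignore_attr = TRUE)
  # outgroup is excluded from the matrix
  expect_equal(rownames(kinship_from_tree(tr2, outgroup = "C")), c("A", "B"))
})

test_that("local trees use only the interval SNPs", {
  set.seed(2)
  p <- matrix(runif(60, 0.2, 0.8), 3, 20,
              dimnames = list(c("x", "y", "z"), NULL))
  fq <- freq_table(p, map = toy_map(20))
  whole <- local_tree(fq, chrom = 1, start = 1, end = 2e4, min_snps = 10)
  genome <- neighbor_joining(reynolds_matrix(fq))
  expect_equal(ape::cophenetic.phylo(whole)[c("x", "y", "z"), c("x", "y", "z")],
               ape::cophenetic.phylo(genome)[c("x", "y", "z"), c("x", "y", "z")],
               tolerance = 1e-10)
  expect_error(local_tree(fq, chrom = 1, start = 1, end = 3000),
               "contains 3 SNPs")
  expect_error(local_tree(fq, chrom = 2, start = 1, end = 2e4), "contains 0")
})

test_that("a selected population grows a longer local branch", {
  sel <- lapply(1:40, function(j) list(snp = j, pops = "pop3", delta = 0.7))
  cfg <- sim_config(n_pops = 4, n_ind_per_pop = 20, n_snps = 400,
                    n_chromosomes = 2, chrom_lengths = c(1e7, 1e7),
                    drift = 0.03, selected_loci = sel, missing_rate = 0,
                    seed = 31)
  d <- simulate_dataset(cfg)
  fq <- pop_frequencies(d$table)
  sel_snps <- which(fq$map$snp %in% sprintf("snp%05d", 1:40))
  loc <- reynolds_matrix(fq, snps = sel_snps)
  gen <- reynolds_matrix(fq)
  # mean distance of the selected population to the others is larger in the
  # sweep interval than genome-wide
  expect_gt(mean(loc["pop3", -3]), mean(gen["pop3", -3]))
})
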