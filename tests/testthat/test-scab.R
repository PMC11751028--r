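make_cpg <- function(bins, values) {
  out <- bins
  out$value <- values
  class(out) <- unique(c("bin_track", class(out)))
  out
}

test_that("scA/B of a bin is the mean CpG density of its contact partners", {
  bins <- make_bins(c(chrA = 1000), 100) # 10 bins
  cpg <- make_cpg(bins, seq(0.01, 0.1, by = 0.01))
  # bin 0 contacts partners in bins 3 (cpg 0.04) and 5 (cpg 0.06)
  cc <- tibble::tibble(
    barcode = "c1", chrom1 = "chrA", pos1 = c(50, 50),
    chrom2 = "chrA", pos2 = c(350, 550),
    is_trans = FALSE, distance = c(300, 500)
  )
  v <- scab_per_cell(cc, cpg, bins)
  expect_equal(v[1], mean(c(0.04, 0.06)))
  expect_equal(v[4], 0.01) # bin 3's partner is bin 0
  expect_true(all(is.na(v[c(2, 3, 5, 7:10)])))

  # a contact with both legs in one bin is excluded
  self_cc <- tibble::tibble(barcode = "c1", chrom1 = "chrA", pos1 = 10,
                            chrom2 = "chrA", pos2 = 90,
                            is_trans = FALSE, distance = 80)
  expect_true(all(is.na(scab_per_cell(self_cc, cpg, bins))))

  # empty cell is all-masked
  expect_true(all(is.na(scab_per_cell(cc[0, ], cpg, bins))))

  # raw values bounded by the CpG track range
  set.seed(4)
  cc2 <- random_contacts(200, chroms = c(chrA = 1000), seed = 5)
  cc2$pos1 <- (cc2$pos1 %% 1000) + 1
  cc2$pos2 <- (cc2$pos2 %% 1000) + 1
  cc2 <- canonicalize_contacts(cc2[, 1:7], "chrA")
  m <- scab_matrix(cc2, cpg, bins)
  expect_true(all(m >= 0.01 - 1e-12 & m <= 0.1 + 1e-12, na.rm = TRUE))
})

test_that("scA/B is invariant to contact order", {
  bins <- make_bins(c(chrA = 1000), 100)
  cpg <- make_cpg(bins, seq(0.01, 0.1, by = 0.01))
  cc <- random_contacts(100, chroms = c(chrA = 1000), seed = 6)
  cc$pos1 <- (cc$pos1 %% 1000) + 1
  cc$pos2 <- (cc$pos2 %% 1000) + 1
  cc <- canonicalize_contacts(cc[, 1:7], "chrA")
  v1 <- scab_matrix(cc, cpg, bins)
  set.seed(1)
  v2 <- scab_matrix(cc[sample(nrow(cc)), ], cpg, bins)
  expect_equal(v1[sort(rownames(v1)), ], v2[sort(rownames(v2)), ])
})

test_that("z-score normalization centers per cell over unmasked bins", {
  m <- matrix(c(1, 2, 3, NA, 5, 5), nrow = 2, byrow = TRUE)
  rownames(m) <- c("c1", "c2")
  sm <- structure(m, bins = NULL, normalization = "raw",
                  class = c("scab_matrix", "matrix"))
  z <- zscore_normalize(sm)
  expect_equal(as.numeric(z["c1", ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  # population sd: [1,2,3] -> +-1.2247
  expect_equal(as.numeric(z["c1", 3]), 1.224745, tolerance = 1e-5)
  # constant cell flagged and unchanged; masked entries stay masked
  expect_true("c2" %in% attr(z, "flagged_cells"))
  expect_equal(as.numeric(z["c2", ]), c(NA, 5, 5))
  expect_true(is.na(z["c2", 1]))
})

test_that("gene-level scA/B averages unmasked bins overlapped by the gene body", {
  bins <- make_bins(c(chrA = 1000), 100)
  m <- matrix(c(0.1, 0.3, NA, 0.5, rep(NA, 6)), nrow = 1,
              dimnames = list("c1", NULL))
  sm <- structure(m, bins = bins, normalization = "raw",
                  class = c("scab_matrix", "matrix"))
  genes <- tibble::tibble(gene = c("g_two", "g_one", "g_masked"),
                          chrom = "chrA",
                          start = c(0, 310, 200), end = c(200, 390, 300))
  gs <- gene_scab(sm, genes)
  expect_equal(gs["c1", "g_two"], 0.2)
  expect_equal(gs["c1", "g_one"], 0.5)
  expect_true(is.na(gs["c1", "g_masked"]))
  expect_warning(gene_bins(tibble::tibble(gene = "g", chrom = "chrZ",
                                          start = 0, end = 10), bins),
                 "chrZ")
})

test_that("marker-set scores average set bins and label clusters by argmax", {
  bins <- make_bins(c(chrA = 1000), 100)
  m <- matrix(c(1, -1, 0.2, rep(NA, 7)), nrow = 1, dimnames = list("c1", NULL))
  sm <- structure(m, bins = bins, normalization = "zscore",
                  class = c("scab_matrix", "matrix"))
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"), chrom = "chrA",
                          start = c(0, 100, 200), end = c(100, 200, 300))
  sets <- list(typeX = c("g1", "g2", "g3"))
  ms <- markerset_score(sm, sets, genes)
  expect_equal(unname(ms$scores["c1", "typeX"]), mean(c(1, -1, 0.2)),
               tolerance = 1e-12)

  # tie flagged, broken by type order
  sets2 <- list(t1 = "g1", t2 = "g1")
  ms2 <- markerset_score(sm, sets2, genes, clusters = c(c1 = "cl1"))
  expect_equal(ms2$cluster_labels$cell_type, "t1")
  expect_true(ms2$cluster_labels$tied)
})

test_that("per-cell scA/B tracks the planted compartments of simulated cells", {
  genome <- sim_genome(chrom_sizes = c(chr1 = 1e7, chr2 = 1e7), seed = 2)
  sim <- sim_cells(genome, n_cells = 6, contacts_meanlog = log(4000),
                   contacts_sdlog = 0.2, n_ambient = 0, dup_rate = 0,
                   barcode_error_rate = 0, seed = 2)
  cpg <- cpg_density(genome$fasta, genome$bins)
  cc <- canonicalize_contacts(sim$pairs, names(genome$chrom_sizes))
  truth_sign <- ifelse(genome$truth$compartment == "A", 1, -1)
  m <- scab_matrix(cc, cpg, genome$bins)
  rho <- apply(m, 1, function(v) {
    ok <- !is.na(v)
    suppressWarnings(cor(v[ok], truth_sign[ok], method = "spearman"))
  })
  expect_true(all(rho > 0.8))
})

test_that("pooled-cell scA/B converges to the ensemble value", {
  genome <- sim_genome(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6), seed = 3)
  sim <- sim_cells(genome, n_cells = 30, contacts_meanlog = log(800),
                   contacts_sdlog = 0.1, n_ambient = 0, dup_rate = 0,
                   barcode_error_rate = 0, seed = 3)
  cpg <- cpg_density(genome$fasta, genome$bins)
  cc <- canonicalize_contacts(sim$pairs, names(genome$chrom_sizes))
  m <- scab_matrix(cc, cpg, genome$bins)
  percell_mean <- colMeans(m, na.rm = TRUE)
  pooled <- cc
  pooled$barcode <- "pool"
  ens <- scab_per_cell(pooled, cpg, genome$bins)
  ok <- !is.na(percell_mean) & !is.na(ens)
  expect_gt(cor(percell_mean[ok], ens[ok]), 0.95)
})
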