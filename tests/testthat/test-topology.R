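test_that("aggregation mirrors both triangles and conserves contact mass", {
  bins <- make_bins(c(chrA = 300), 100)
  cc <- tibble::tibble(
    barcode = c("c1", "c2", "c1"),
    chrom1 = "chrA", pos1 = c(50, 150, 250),
    chrom2 = "chrA", pos2 = c(150, 50, 250),
    mapq1 = 60L, mapq2 = 60L
  )
  cc <- canonicalize_contacts(cc, "chrA")
  mats <- aggregate_contacts(cc, c(c1 = "g", c2 = "g"), bins)
  M <- as.matrix(mats$g$counts)
  expect_equal(M[1, 2], 2)
  expect_equal(M[2, 1], 2)
  expect_equal(M[3, 3], 1)
  expect_equal(matrix_mass(mats$g), 3)

  # two groups from one pool: masses sum to pool size
  mats2 <- aggregate_contacts(cc, c(c1 = "a", c2 = "b"), bins)
  expect_equal(matrix_mass(mats2$a) + matrix_mass(mats2$b), nrow(cc))

  # relabeling to one group reproduces the pooled matrix
  pooled <- aggregate_contacts(cc, c(c1 = "all", c2 = "all"), bins)
  expect_equal(as.matrix(pooled$all$counts),
               as.matrix(mats2$a$counts) + as.matrix(mats2$b$counts))
  # unlabeled barcodes are dropped and counted
  mats3 <- aggregate_contacts(cc, c(c1 = "a"), bins)
  expect_equal(attr(mats3, "n_unlabeled"), 1)
})

test_that("balancing finds the doubly-stochastic fixed point and 1/sqrt scaling", {
  bins <- make_bins(c(chrA = 300), 100)
  ds <- matrix(c(0.5, 0.5, 0, 0.5, 0.25, 0.25, 0, 0.25, 0.75), 3, 3)
  m <- balance_matrix(binned_matrix(Matrix::Matrix(ds, sparse = TRUE), bins),
                      mad_filter = Inf)
  expect_equal(unname(m$weights), rep(1, 3), tolerance = 1e-4, ignore_attr = TRUE)

  # diagonal matrix: weights proportional to 1/sqrt(row mass)
  dg <- Matrix::Diagonal(x = c(2, 1, 4))
  m2 <- balance_matrix(binned_matrix(dg, bins), mad_filter = Inf)
  expect_equal(unname(m2$weights), 1 / sqrt(c(2, 1, 4)), tolerance = 1e-4, ignore_attr = TRUE)

  # balanced marginals are equal on random sparse matrices
  for (seed in 1:20) {
    set.seed(seed)
    n <- 8
    A <- matrix(stats::rpois(n * n, 5), n, n)
    A <- A + t(A)
    bb <- make_bins(c(chrA = n * 100), 100)
    bm <- balance_matrix(binned_matrix(Matrix::Matrix(A, sparse = TRUE), bb),
                         mad_filter = Inf)
    W <- balanced_values(bm)
    expect_equal(unname(rowSums(W)), rep(1, n), tolerance = 1e-3)
  }
})

test_that("P(s) estimator is linear in counts and recovers the decay exponent", {
  cs <- c(chr1 = 2e7, chr2 = 2e7)
  one_d <- tibble::tibble(barcode = "c", chrom1 = "chr1", pos1 = 1,
                          chrom2 = "chr1", pos2 = 50001,
                          is_trans = FALSE, distance = 50000)
  ps1 <- ps_curve(one_d, cs, min_dist = 1e3, max_dist = 1e6, n_bins = 10)
  expect_equal(sum(!is.na(ps1$freq)), 1)

  two_d <- dplyr::bind_rows(one_d, one_d)
  ps2 <- ps_curve(two_d, cs, min_dist = 1e3, max_dist = 1e6, n_bins = 10)
  expect_equal(ps2$freq[!is.na(ps2$freq)], 2 * ps1$freq[!is.na(ps1$freq)])

  # slope recovery on a decay-only simulation (no compartment modulation)
  genome <- sim_genome(chrom_sizes = cs, seed = 4)
  sim <- sim_cells(genome, n_cells = 25, contacts_meanlog = log(5000),
                   contacts_sdlog = 0.1, n_ambient = 0, dup_rate = 0,
                   barcode_error_rate = 0, enrichment = 1, trans_rate = 0,
                   seed = 4)
  cc <- canonicalize_contacts(sim$pairs, names(cs))
  ps <- ps_curve(cc, cs, min_dist = 2e3, max_dist = 1e7, n_bins = 25)
  expect_equal(ps_slope(ps, fit_range = c(3e3, 5e6)), -1, tolerance = 0.1)
})

test_that("insulation is zero on uniform matrices and scale-invariant", {
  n <- 20
  bins <- make_bins(c(chrA = n * 1000), 1000)
  U <- matrix(1, n, n)
  m <- binned_matrix(Matrix::Matrix(U, sparse = TRUE), bins)
  tr <- insulation(m, window = 3000)
  interior <- !is.na(tr$score)
  expect_true(any(interior))
  expect_equal(tr$score[interior], rep(0, sum(interior)))
  # edges within a window of the chromosome ends are missing
  expect_true(is.na(tr$score[1]) && is.na(tr$score[n]))

  # scaling the matrix leaves the normalized track unchanged
  set.seed(8)
  A <- matrix(stats::rpois(n * n, 10) + 1, n, n)
  A <- A + t(A)
  m1 <- binned_matrix(Matrix::Matrix(A, sparse = TRUE), bins)
  m5 <- binned_matrix(Matrix::Matrix(5 * A, sparse = TRUE), bins)
  expect_equal(insulation(m1, 3000)$score, insulation(m5, 3000)$score)
})

test_that("two planted diagonal blocks put the insulation minimum at the junction", {
  n <- 30
  bins <- make_bins(c(chrA = n * 1000), 1000)
  A <- matrix(1, n, n)
  A[1:15, 1:15] <- 10
  A[16:30, 16:30] <- 10
  tr <- insulation(binned_matrix(Matrix::Matrix(A, sparse = TRUE), bins), 5000)
  expect_equal(which.min(tr$score), 16)

  bounds <- call_boundaries(tr, min_strength = 0.1)
  expect_equal(bounds$bin, 15) # 0-based ordinal of the junction bin
})

test_that("boundary calls respect prominence and mirror under coordinate reversal", {
  bins <- make_bins(c(chrA = 12000), 1000)
  mk_track <- function(score) {
    tr <- bins
    tr$raw_square <- 2^score
    tr$score <- score
    class(tr) <- unique(c("insulation_track", class(tr)))
    tr
  }
  dip <- c(0, 0.1, 0, -0.8, 0, 0.05, 0, -0.02, 0, 0.05, 0, 0)
  tr <- mk_track(dip)
  b <- call_boundaries(tr, min_strength = 0.1)
  expect_equal(b$bin, 3) # the deep dip only; the -0.02 dip is too weak
  expect_gt(b$strength, 0.7)

  # monotone track has no boundaries; flat track neither
  expect_equal(nrow(call_boundaries(mk_track(seq(1, 0, length.out = 12)))), 0)
  expect_equal(nrow(call_boundaries(mk_track(rep(0, 12)))), 0)

  # mirrored track yields mirrored boundary positions
  tr_rev <- mk_track(rev(dip))
  b_rev <- call_boundaries(tr_rev, min_strength = 0.1)
  expect_equal(b_rev$bin, 11 - 3)
})

test_that("boundary usage is the fraction of members with a boundary at the TSS bin", {
  bins <- make_bins(c(chrA = 10000), 1000)
  mk_set <- function(b) tibble::tibble(bin = b)
  sets <- c(replicate(4, mk_set(c(2L, 7L)), simplify = FALSE),
            replicate(6, mk_set(5L), simplify = FALSE))
  tss <- tibble::tibble(gene = c("gA", "gB", "gC"), chrom = "chrA",
                        pos = c(2500, 5500, 9500))
  u <- boundary_usage(sets, tss, bins)
  expect_equal(u$usage, c(0.4, 0.6, 0))
  # absent chromosome -> missing
  tss2 <- tibble::tibble(gene = "gZ", chrom = "chrZ", pos = 100)
  expect_true(is.na(boundary_usage(sets, tss2, bins)$usage))
})

test_that("melting scores are zero for identical tracks and antisymmetric in direction", {
  bins <- make_bins(c(chrA = 50 * 5e4), 5e4)
  mk_sq <- function(vals) {
    tr <- bins
    tr$raw_square <- vals
    tr$score <- log2(vals / mean(vals))
    class(tr) <- unique(c("insulation_track", class(tr)))
    tr
  }
  set.seed(12)
  a_vals <- stats::runif(50, 0.5, 1.5)
  a <- mk_sq(a_vals)
  genes <- tibble::tibble(gene = "bigGene", chrom = "chrA", start = 0, end = 2e6)

  same <- melting_score(a, mk_sq(a_vals), genes)
  expect_equal(same$score, 0)
  expect_equal(same$p, 1)

  halved <- melting_score(a, mk_sq(a_vals / 2), genes)
  expect_equal(halved$direction, "melted")
  expect_gt(halved$score, 3)

  raised <- melting_score(a, mk_sq(a_vals + 1), genes)
  expect_equal(raised$direction, "established")

  # swapping conditions flips the direction, not the score
  fwd <- melting_score(a, mk_sq(a_vals / 2), genes)
  rev_ <- melting_score(mk_sq(a_vals / 2), a, genes)
  expect_equal(fwd$score, rev_$score)
  expect_true(fwd$direction != rev_$direction)

  # genes at or under the length threshold are not scored
  short_gene <- tibble::tibble(gene = "short", chrom = "chrA", start = 0, end = 3e5)
  expect_equal(nrow(melting_score(a, mk_sq(a_vals / 2), short_gene)), 0)
})
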