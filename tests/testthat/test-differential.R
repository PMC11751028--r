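toy_scab <- function(values, barcodes) {
  m <- matrix(values, nrow = length(barcodes), byrow = TRUE,
              dimnames = list(barcodes, NULL))
  structure(m, bins = make_bins(c(chrA = ncol(m) * 100), 100),
            normalization = "raw", class = c("scab_matrix", "matrix"))
}

test_that("metacell values are per-bin medians over members with mask coverage", {
  m <- toy_scab(c(0.1, 0.4,
                  0.2, NA,
                  0.6, 0.3), c("b1", "b2", "b3"))
  meta <- tibble::tibble(barcode = c("b1", "b2", "b3"), metacell = "mc1")
  mt <- build_metacells(m, meta, contacts_per_cell = c(b1 = 10, b2 = 20, b3 = 30))
  expect_equal(unname(mt$values["mc1", 1]), 0.2)
  # bin 2: members {0.4, NA, 0.3} -> 2/3 unmasked >= half -> median 0.35
  expect_equal(unname(mt$values["mc1", 2]), 0.35)
  expect_equal(mt$meta$total_contacts, 60)
  expect_false(mt$meta$singleton)

  # fewer than half unmasked -> masked
  m2 <- toy_scab(c(0.1, NA, NA, NA, 0.3, NA), c("b1", "b2", "b3"))
  mt2 <- build_metacells(m2, meta)
  expect_equal(unname(mt2$values["mc1", 1]), 0.2)
  expect_true(is.na(mt2$values["mc1", 2]))

  # singleton metacells allowed but flagged
  mt3 <- build_metacells(m, tibble::tibble(barcode = "b1", metacell = "solo"))
  expect_true(mt3$meta$singleton)
})

test_that("rank-sum exact branch agrees with full enumeration for all sizes <= 6", {
  set.seed(31)
  for (nx in 1:6) {
    for (ny in 1:6) {
      # tie-free draws
      vals <- sample(seq(1, 1000), nx + ny)
      x <- vals[seq_len(nx)]
      y <- vals[nx + seq_len(ny)]
      rt <- ranksum_test(x, y)
      expect_true(rt$exact)
      expect_equal(rt$p, oracle_ranksum_p(x, y), tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
  # fully separated groups of 3: P(U <= 0) = 1/20 each tail
  rt <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$p, 0.1)
  # symmetry and identical samples
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6))$p,
               ranksum_test(c(4, 5, 6), c(1, 2, 3))$p)
  expect_equal(ranksum_test(c(1, 1, 2), c(1, 2, 1))$p, 1, tolerance = 1e-9)
  expect_equal(ranksum_test(rep(3, 4), rep(3, 5))$p, 1)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(17)
  for (rep in 1:100) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("differential compartments recover planted shifts and stay null under permutation", {
  sim <- sim_aging_cohort(seed = 7)
  mt <- build_metacells(sim$scab, sim$cell_meta)
  dt <- diff_compartment(mt, list(timepoint = "old"), list(timepoint = "young"))
  hits <- dt$bin[dt$retained]
  recall <- mean(sim$truth$shifted_bins %in% hits)
  expect_gte(recall, 0.9)
  fp <- length(setdiff(hits, sim$truth$shifted_bins))
  expect_lte(fp, 5)
  # planted direction is an scA/B increase in old
  expect_true(all(dt$direction[dt$bin %in% sim$truth$shifted_bins &
                                 dt$retained] %in% "increased"))
  # middle vs young is a planted null
  null_dt <- diff_compartment(mt, list(timepoint = "middle"),
                              list(timepoint = "young"))
  expect_lte(sum(null_dt$retained), 2)

  # monotone in alpha
  strict <- diff_compartment(mt, list(timepoint = "old"),
                             list(timepoint = "young"), alpha = 0.001)
  expect_lte(sum(strict$retained), sum(dt$retained))

  # |delta| filter excludes small shifts from the summary directions
  s <- attr(dt, "summary")
  expect_equal(s$n_increased + s$n_decreased,
               sum(!is.na(dt$direction)))
  expect_true(all(abs(dt$delta[!is.na(dt$direction)]) > 0.05))
})

test_that("bins with small effects are excluded from the delta summary", {
  set.seed(5)
  vals <- matrix(stats::rnorm(20 * 10, 0, 0.01), 20, 10)
  vals[1:10, 1] <- vals[1:10, 1] + 0.03  # significant but small delta
  vals[1:10, 2] <- vals[1:10, 2] + 0.30  # significant and large delta
  rownames(vals) <- sprintf("c%02d", 1:20)
  m <- structure(vals, bins = make_bins(c(chrA = 1000), 100),
                 normalization = "raw", class = c("scab_matrix", "matrix"))
  meta <- tibble::tibble(barcode = rownames(vals),
                         metacell = rownames(vals),
                         timepoint = rep(c("old", "young"), each = 10))
  mt <- build_metacells(m, meta)
  dt <- diff_compartment(mt, list(timepoint = "old"), list(timepoint = "young"))
  small <- dt[dt$bin == 0, ]
  expect_true(small$retained)
  expect_true(is.na(small$direction))
  big <- dt[dt$bin == 1, ]
  expect_equal(big$direction, "increased")
})

test_that("gene-module scores separate planted elevation by timepoint", {
  sim <- sim_aging_cohort(module_bins = 100:109, module_delta = 0.15, seed = 9)
  mt <- build_metacells(sim$scab, sim$cell_meta)
  genes <- tibble::tibble(gene = sprintf("mg%02d", 1:10), chrom = "chrS",
                          start = (100:109) * 5e5, end = (101:110) * 5e5)
  gm <- gene_module_score(mt, genes$gene, genes,
                          comparisons = list(c("old", "young"),
                                             c("middle", "young")))
  old_test <- gm$tests[gm$tests$target == "old", ]
  mid_test <- gm$tests[gm$tests$target == "middle", ]
  expect_true(old_test$significant)
  expect_gt(old_test$delta, 0.1)
  expect_false(mid_test$significant)

  # module of two genes averages gene-level values
  expect_equal(nrow(gm$scores), nrow(mt$values))
  expect_error(gene_module_score(mt, "absent_gene", genes), "maps")
})
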