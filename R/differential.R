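#' Build a metacell table from per-cell scA/B values
#'
#' Metacells pool architecturally similar single cells (sub-cluster
#' labels are supplied, clustering itself is external). Per metacell the
#' per-bin value is the median of member cells' unmasked scA/B values; a
#' bin is masked when fewer than half of the members have it unmasked.
#' Metacells, not single cells, are the unit of replication in the
#' downstream tests.
#'
#' @param m A `scab_matrix` (cells x bins; raw or z-scored).
#' @param cell_meta Tibble `barcode`, `metacell`, plus optional `cell_type`
#'   and `timepoint` columns carried through.
#' @param contacts_per_cell Optional named vector of per-cell contact
#'   counts, summed per metacell.
#' @return A `metacell_table` list: `values` (metacells x bins matrix),
#'   `meta` (tibble `metacell`, `n_cells`, `cell_type`, `timepoint`,
#'   `total_contacts`, `singleton`), `bins`.
#' @export
build_metacells <- function(m, cell_meta, contacts_per_cell = NULL) {
  stopifnot(all(c("barcode", "metacell") %in% names(cell_meta)))
  cell_meta <- cell_meta[cell_meta$barcode %in% rownames(m), , drop = FALSE]
  cell_meta$metacell <- as.character(cell_meta$metacell)
  mcs <- unique(cell_meta$metacell)
  vals <- matrix(NA_real_, nrow = length(mcs), ncol = ncol(m),
                 dimnames = list(mcs, NULL))
  meta <- purrr::map_dfr(mcs, function(mc) {
    members <- cell_meta$barcode[cell_meta$metacell == mc]
    sub <- m[members, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    med <- apply(sub, 2, stats::median, na.rm = TRUE)
    med[n_ok < length(members) / 2] <- NA_real_
    med[is.nan(med)] <- NA_real_
    vals[mc, ] <<- med
    row <- cell_meta[cell_meta$metacell == mc, , drop = FALSE][1, ]
    tibble::tibble(
      metacell = mc, n_cells = length(members),
      cell_type = if ("cell_type" %in% names(row)) row$cell_type else NA_character_,
      timepoint = if ("timepoint" %in% names(row)) row$timepoint else NA_character_,
      total_contacts = if (is.null(contacts_per_cell)) NA_real_ else
        sum(contacts_per_cell[members], na.rm = TRUE),
      singleton = length(members) == 1
    )
  })
  structure(list(values = vals, meta = meta, bins = attr(m, "bins")),
            class = "metacell_table")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test with midrank ties: exact enumeration when
#' `length(x) + length(y) <= 12` and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections. Identical
#' pooled values give p = 1.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return List `statistic` (Mann-Whitney U of `x`), `p`, `exact`.
#' @export
ranksum_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p = 1, exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `p_adj(i) = min_{j >= rank(i)} p(j) * m / rank(j)`,
#' capped at 1 and order-preserving.
#'
#' @param p Numeric vector of raw p-values in [0, 1] (NAs passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Differential compartmentalization between two groups of metacells
#'
#' Per bin, compares metacell scA/B values between groups A and B with
#' the Wilcoxon rank-sum test, adjusts p-values with Benjamini-Hochberg
#' over all tested bins, and retains bins with adjusted p below `alpha`.
#' The effect `delta` is `median(A) - median(B)`. The change summary
#' additionally requires `|delta| > min_delta` and splits retained bins
#' by sign into increased/decreased. Bins masked in more than half of
#' either group are not tested and recorded as such.
#'
#' @param mt A `metacell_table`.
#' @param group_a,group_b Metacell ids, or a named list/filter on
#'   `mt$meta` columns (e.g. `list(timepoint = "old")`).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param min_delta Minimum |delta| for the change summary (default 0.05).
#' @return A `diff_table` tibble: `bin`, `chrom`, `start`, `end`, `n_a`,
#'   `n_b`, `delta`, `stat`, `p_raw`, `p_adj`, `retained`, `direction`,
#'   `tested`; attribute `summary` counts increased/decreased bins
#'   passing both cutoffs.
#' @export
diff_compartment <- function(mt, group_a, group_b, alpha = 0.01, min_delta = 0.05) {
  ids_a <- resolve_group(mt, group_a)
  ids_b <- resolve_group(mt, group_b)
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each group needs at least 2 metacells", call. = FALSE)
  }
  A <- mt$values[ids_a, , drop = FALSE]
  B <- mt$values[ids_b, , drop = FALSE]
  nb <- ncol(mt$values)
  res <- purrr::map_dfr(seq_len(nb), function(j) {
    a <- A[, j]
    b <- B[, j]
    a_ok <- a[!is.na(a)]
    b_ok <- b[!is.na(b)]
    tested <- length(a_ok) >= length(ids_a) / 2 && length(b_ok) >= length(ids_b) / 2 &&
      length(a_ok) >= 1 && length(b_ok) >= 1
    if (!tested) {
      return(tibble::tibble(bin = j - 1L, n_a = length(a_ok), n_b = length(b_ok),
                            delta = NA_real_, stat = NA_real_, p_raw = NA_real_,
                            tested = FALSE))
    }
    rt <- ranksum_test(a_ok, b_ok)
    tibble::tibble(bin = j - 1L, n_a = length(a_ok), n_b = length(b_ok),
                   delta = stats::median(a_ok) - stats::median(b_ok),
                   stat = rt$statistic, p_raw = rt$p, tested = TRUE)
  })
  res$p_adj <- NA_real_
  res$p_adj[res$tested] <- bh_adjust(res$p_raw[res$tested])
  res$retained <- !is.na(res$p_adj) & res$p_adj < alpha
  res$direction <- dplyr::case_when(
    res$retained & res$delta > min_delta ~ "increased",
    res$retained & res$delta < -min_delta ~ "decreased",
    TRUE ~ NA_character_
  )
  binfo <- mt$bins
  res <- dplyr::left_join(res, binfo[c("bin", "chrom", "start", "end")], by = "bin") |>
    dplyr::select("bin", "chrom", "start", "end", dplyr::everything())
  attr(res, "summary") <- list(
    n_tested = sum(res$tested), n_retained = sum(res$retained),
    n_increased = sum(res$direction %in% "increased"),
    n_decreased = sum(res$direction %in% "decreased"),
    alpha = alpha, min_delta = min_delta
  )
  class(res) <- unique(c("diff_table", class(res)))
  res
}

resolve_group <- function(mt, group) {
  if (is.list(group) && !is.null(names(group))) {
    keep <- rep(TRUE, nrow(mt$meta))
    for (nm in names(group)) keep <- keep & mt$meta[[nm]] %in% group[[nm]]
    mt$meta$metacell[keep]
  } else {
    intersect(as.character(group), rownames(mt$values))
  }
}

#' Gene-module scA/B scores and timepoint tests
#'
#' The module score of a metacell is the mean raw scA/B over the bins of
#' the module's genes (raw, not z-scored, values are the module
#' currency). Pairwise Wilcoxon rank-sum tests compare timepoints, with
#' Benjamini-Hochberg adjustment over the comparisons; significance at
#' adjusted p < `alpha`.
#'
#' @param mt A `metacell_table` built from a raw `scab_matrix`.
#' @param module_genes Character vector of gene names in the module.
#' @param genes Gene interval tibble mapping genes to bins.
#' @param comparisons List of `c(target, reference)` timepoint pairs;
#'   default all pairs against the first (reference) timepoint level.
#' @param alpha Significance cutoff on adjusted p (default 0.01).
#' @return List: `scores` (tibble `metacell`, `timepoint`, `score`),
#'   `tests` (tibble `target`, `reference`, `delta`, `stat`, `p_raw`,
#'   `p_adj`, `significant`).
#' @export
gene_module_score <- function(mt, module_genes, genes, comparisons = NULL,
                              alpha = 0.01) {
  gb <- gene_bins(genes[genes$gene %in% module_genes, , drop = FALSE], mt$bins)
  if (nrow(gb) == 0) stop("no module gene maps to a bin", call. = FALSE)
  cols <- unique(gb$bin) + 1L
  score <- rowMeans(mt$values[, cols, drop = FALSE], na.rm = TRUE)
  score[is.nan(score)] <- NA_real_
  scores <- tibble::tibble(metacell = rownames(mt$values),
                           timepoint = mt$meta$timepoint[match(rownames(mt$values),
                                                               mt$meta$metacell)],
                           score = score)
  if (is.null(comparisons)) {
    tps <- unique(scores$timepoint)
    ref <- tps[1]
    comparisons <- purrr::map(setdiff(tps, ref), ~ c(.x, ref))
  }
  tests <- purrr::map_dfr(comparisons, function(cmp) {
    x <- scores$score[scores$timepoint == cmp[1] & !is.na(scores$score)]
    y <- scores$score[scores$timepoint == cmp[2] & !is.na(scores$score)]
    rt <- ranksum_test(x, y)
    tibble::tibble(target = cmp[1], reference = cmp[2],
                   delta = stats::median(x) - stats::median(y),
                   stat = rt$statistic, p_raw = rt$p)
  })
  tests$p_adj <- bh_adjust(tests$p_raw)
  tests$significant <- tests$p_adj < alpha
  list(scores = scores, tests = tests)
}
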