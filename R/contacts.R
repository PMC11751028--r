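#' Deduplication and filtering configuration
#'
#' @param dup_dist Two contacts of the same barcode and chromosome pair
#'   are duplicates when both legs lie within this many bp (default 100).
#' @param min_mapq Minimum mapping quality; pairs with either leg below
#'   this are discarded (default 20).
#' @param min_cis_distance Cis pairs at or below this distance are dropped
#'   as self-ligation/religation noise; contacts are counted as
#'   intra-chromosomal only beyond 1 kb (default 1000).
#' @return A `dedup_config` list.
#' @export
dedup_config <- function(dup_dist = 100, min_mapq = 20, min_cis_distance = 1000) {
  stopifnot(dup_dist >= 0, min_mapq >= 0, min_cis_distance >= 0)
  structure(list(dup_dist = dup_dist, min_mapq = min_mapq,
                 min_cis_distance = min_cis_distance),
            class = "dedup_config")
}

#' Extract filtered contacts from barcode-annotated read pairs
#'
#' Applies the read-level filters to aligned, barcode-tagged pairs:
#' either leg with mapq below `cfg$min_mapq` drops the pair; cis pairs at
#' distance `<= cfg$min_cis_distance` are dropped; trans pairs are always
#' distance-eligible. Legs are canonicalized (chrom order, then position).
#'
#' @param pairs Tibble with `barcode`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `mapq1`, `mapq2`; rows with `NA` positions are treated as unmapped
#'   and skipped (counted, not fatal).
#' @param chrom_levels Chromosome order (e.g. names of the sizes vector).
#' @param cfg A [dedup_config()].
#' @return Filtered canonical contact tibble; attribute `filter_counts`
#'   reports input/unmapped/low_mapq/short_cis/kept.
#' @export
extract_contacts <- function(pairs, chrom_levels, cfg = dedup_config()) {
  n_in <- nrow(pairs)
  unmapped <- is.na(pairs$pos1) | is.na(pairs$pos2) |
    is.na(pairs$chrom1) | is.na(pairs$chrom2) | is.na(pairs$barcode)
  pairs <- pairs[!unmapped, , drop = FALSE]
  low_mapq <- pairs$mapq1 < cfg$min_mapq | pairs$mapq2 < cfg$min_mapq
  pairs <- pairs[!low_mapq, , drop = FALSE]
  out <- canonicalize_contacts(pairs, chrom_levels)
  short_cis <- !out$is_trans & out$distance <= cfg$min_cis_distance
  out <- out[!short_cis, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    input = n_in, unmapped = sum(unmapped), low_mapq = sum(low_mapq),
    short_cis = sum(short_cis), kept = nrow(out)
  )
  out
}

#' Barcode-aware deduplication within a genomic-distance window
#'
#' Two contacts are duplicates iff they carry the same cell barcode, the
#' same chromosome pair, and both legs lie within `cfg$dup_dist` bp. The
#' barcode is part of the duplicate key, so identical coordinates in
#' different cells are distinct contacts. Duplicates are resolved greedily
#' against the retained representative in sort order: the first contact
#' seen is kept and later contacts within the window of any retained
#' contact are dropped.
#'
#' @param contacts Canonical contact tibble sorted by
#'   (`barcode`, `chrom1`, `chrom2`, `pos1`, `pos2`); unsorted input is an
#'   error. Use `sort_contacts()` first.
#' @param cfg A [dedup_config()].
#' @return Tibble of unique contacts with logical attribute-free column
#'   removed; attribute `dup_counts` is a tibble (`barcode`, `n_total`,
#'   `n_dup`).
#' @export
dedup_contacts <- function(contacts, cfg = dedup_config()) {
  if (nrow(contacts) == 0) {
    attr(contacts, "dup_counts") <- tibble::tibble(
      barcode = character(), n_total = integer(), n_dup = integer())
    return(contacts)
  }
  key <- order(contacts$barcode, contacts$chrom1, contacts$chrom2,
               contacts$pos1, contacts$pos2, method = "radix")
  if (!identical(key, seq_len(nrow(contacts)))) {
    stop("contacts are not sorted by (barcode, chrom1, chrom2, pos1, pos2); ",
         "call sort_contacts() first", call. = FALSE)
  }
  grp <- paste(contacts$barcode, contacts$chrom1, contacts$chrom2, sep = "\r")
  keep <- logical(nrow(contacts))
  idx_by_grp <- split(seq_len(nrow(contacts)), factor(grp, levels = unique(grp)))
  dd <- cfg$dup_dist
  for (idx in idx_by_grp) {
    p1 <- contacts$pos1[idx]
    p2 <- contacts$pos2[idx]
    kept1 <- numeric(0)
    kept2 <- numeric(0)
    lo <- 1L # kept representatives with pos1 < p1 - dd can never match again
    for (j in seq_along(idx)) {
      if (length(kept1) >= lo) {
        while (lo <= length(kept1) && kept1[lo] < p1[j] - dd) lo <- lo + 1L
      }
      active <- if (lo <= length(kept1)) seq.int(lo, length(kept1)) else integer(0)
      is_dup <- length(active) > 0 &&
        any(abs(kept1[active] - p1[j]) <= dd & abs(kept2[active] - p2[j]) <= dd)
      if (!is_dup) {
        kept1 <- c(kept1, p1[j])
        kept2 <- c(kept2, p2[j])
        keep[idx[j]] <- TRUE
      }
    }
  }
  out <- contacts[keep, , drop = FALSE]
  dup_counts <- tibble::tibble(barcode = contacts$barcode, dup = !keep) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(n_total = dplyr::n(), n_dup = sum(.data$dup))
  attr(out, "dup_counts") <- dup_counts
  out
}

#' Sort contacts into dedup order
#' @param contacts Contact tibble.
#' @return Tibble sorted by (barcode, chrom1, chrom2, pos1, pos2).
#' @export
sort_contacts <- function(contacts) {
  contacts[order(contacts$barcode, contacts$chrom1, contacts$chrom2,
                 contacts$pos1, contacts$pos2, method = "radix"), , drop = FALSE]
}

#' Per-barcode contact statistics
#'
#' Summarises deduplicated contacts per barcode: total and unique contact
#' counts, cis/trans split, duplication rate (1 - unique/total) and trans
#' rate (trans/unique). Feeds cell calling and QC.
#'
#' @param unique_contacts Deduplicated contact tibble (from
#'   [dedup_contacts()]); its `dup_counts` attribute supplies totals
#'   unless `totals` is given.
#' @param totals Optional tibble (`barcode`, `n_total`) overriding the
#'   attribute.
#' @return Tibble `barcode`, `n_total`, `n_unique`, `n_cis`, `n_trans`,
#'   `dup_rate`, `trans_rate`.
#' @export
per_cell_stats <- function(unique_contacts, totals = NULL) {
  if (nrow(unique_contacts) == 0) {
    return(tibble::tibble(barcode = character(), n_total = integer(),
                          n_unique = integer(), n_cis = integer(),
                          n_trans = integer(), dup_rate = double(),
                          trans_rate = double()))
  }
  uq <- unique_contacts |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      n_unique = dplyr::n(),
      n_cis = sum(!.data$is_trans),
      n_trans = sum(.data$is_trans)
    )
  if (is.null(totals)) {
    dc <- attr(unique_contacts, "dup_counts")
    totals <- if (!is.null(dc)) dc[, c("barcode", "n_total")] else
      tibble::tibble(barcode = uq$barcode, n_total = uq$n_unique)
  }
  uq |>
    dplyr::left_join(totals, by = "barcode") |>
    dplyr::mutate(
      n_total = dplyr::coalesce(.data$n_total, .data$n_unique),
      dup_rate = 1 - .data$n_unique / .data$n_total,
      trans_rate = .data$n_trans / .data$n_unique
    ) |>
    dplyr::select("barcode", "n_total", "n_unique", "n_cis", "n_trans",
                  "dup_rate", "trans_rate")
}
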