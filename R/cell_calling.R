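#' Barcode-rank curve
#'
#' Orders barcodes by descending contact count, the standard knee-plot
#' coordinates used to separate true cells from ambient droplet noise.
#' Ties keep stable (input) barcode order.
#'
#' @param counts Tibble (`barcode`, `n`) or a named numeric vector of
#'   per-barcode contact counts.
#' @return Tibble `rank` (1..N), `barcode`, `n`, non-increasing in `n`;
#'   attribute `degenerate` is `TRUE` when a knee is undefined (fewer
#'   than 2 barcodes or all counts equal).
#' @export
rank_curve <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(barcode = names(counts) %||% as.character(seq_along(counts)),
                             n = as.numeric(counts))
  } else {
    counts <- tibble::tibble(barcode = counts[[1]], n = as.numeric(counts[[2]]))
  }
  ord <- order(-counts$n) # stable for ties
  out <- tibble::tibble(rank = seq_len(nrow(counts)),
                        barcode = counts$barcode[ord], n = counts$n[ord])
  attr(out, "degenerate") <- nrow(out) < 2 || length(unique(out$n)) < 2
  class(out) <- unique(c("rank_curve", class(out)))
  out
}

#' Kneedle knee-point detection
#'
#' Detects the knee of a decreasing convex curve (the barcode-rank
#' cliff) on the kneedle difference curve: both axes are min-max
#' normalized, the curve is reflected to concave-increasing, and the
#' difference curve `d = y_n - x_n` is formed. Local maxima of `d` are
#' knee candidates, each scored by its prominence — the rise of `d` from
#' the preceding local minimum (or the curve start). Candidates whose
#' prominence is at most `sensitivity * mean(diff(x_n))`, the kneedle
#' noise floor, are discarded. The knee is placed at the steepest point
#' of the most prominent surviving rise: the index immediately before
#' the largest single-step increase of `d` on the way up to that
#' candidate. On barcode-rank curves the cliff between cells and ambient
#' noise produces a difference-curve rise orders of magnitude above the
#' noise kinks of the flanking plateaus, and the largest step of that
#' rise is the cliff itself, so the knee lands on the last barcode of
#' the cell shoulder; a first-passed-threshold rule would instead latch
#' onto the first noise kink of the upper plateau.
#'
#' @param x Strictly increasing numeric vector.
#' @param y Non-increasing numeric vector (same length).
#' @param sensitivity Kneedle sensitivity S; larger values demand a more
#'   pronounced knee and never move the knee earlier (the knee is
#'   unchanged while the maximal candidate survives the noise floor, and
#'   becomes `NA` beyond it).
#' @return Index of the knee in `x`, or `NA_integer_` when no candidate
#'   survives (straight lines, < 3 points).
#' @export
kneedle_knee <- function(x, y, sensitivity = 1) {
  n <- length(x)
  if (n < 3) return(NA_integer_)
  stopifnot(length(y) == n)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  xn <- (x - x[1]) / (x[n] - x[1])
  ry <- range(y)
  if (ry[1] == ry[2]) return(NA_integer_)
  yn <- (y - ry[1]) / (ry[2] - ry[1])
  # decreasing convex -> concave increasing
  yr <- 1 - yn
  d <- yr - xn
  if (all(abs(d) < 1e-12)) return(NA_integer_)
  interior <- 2:(n - 1)
  is_lmax <- d[interior] >= d[interior - 1] & d[interior] > d[interior + 1]
  lmax <- interior[is_lmax]
  if (length(lmax) == 0) return(NA_integer_)
  prev_end <- c(1L, lmax[-length(lmax)])
  prominence <- purrr::map2_dbl(lmax, prev_end, function(i, p) {
    d[i] - min(d[p:i])
  })
  floor_s <- sensitivity * mean(diff(xn))
  ok <- prominence > floor_s
  if (!any(ok)) return(NA_integer_)
  best <- which.max(ifelse(ok, prominence, -Inf))
  lm <- lmax[best]
  rise_start <- prev_end[best] - 1L + which.min(d[prev_end[best]:lm])
  if (rise_start >= lm) return(lm)
  steps <- d[(rise_start + 1L):lm] - d[rise_start:(lm - 1L)]
  rise_start + which.max(steps) - 1L
}

#' Adaptive knee-point cell calling
#'
#' Separates true cells from ambient barcodes by kneedle knee detection
#' on the log10-log10 barcode-rank curve, sweeping the sensitivity
#' parameter and selecting the value whose called barcodes most closely
#' retain over `target_retention` of all contacts: among sensitivities
#' reaching the target, the one with the smallest retained fraction wins;
#' if none reaches it, the largest retained fraction is returned with a
#' warning flag.
#'
#' @param counts Per-barcode contact counts (tibble `barcode`,`n` or
#'   named vector); typically `n_unique` from [per_cell_stats()].
#' @param s_range Integer sensitivities to sweep (default 1:10).
#' @param target_retention Minimum fraction of total contacts the called
#'   cells should retain (default 0.85).
#' @param log_axes Detect the knee on log10 rank vs log10 count
#'   (default `TRUE`); barcode-rank curves span orders of magnitude.
#' @return A `knee_result` list: `sensitivity`, `knee_rank`,
#'   `threshold_count`, `retained_fraction`, `called_barcodes`,
#'   `n_called`, `warning` (TRUE when the target was unreachable),
#'   `sweep` (per-sensitivity tibble), `curve` (the rank curve).
#' @export
adaptive_cell_call <- function(counts, s_range = 1:10, target_retention = 0.85,
                               log_axes = TRUE) {
  curve <- rank_curve(counts)
  if (isTRUE(attr(curve, "degenerate"))) {
    stop("degenerate barcode-rank curve (all counts equal); ",
         "set a manual threshold instead", call. = FALSE)
  }
  total <- sum(curve$n)
  if (total <= 0) stop("no contacts to call cells from", call. = FALSE)
  x <- if (log_axes) log10(curve$rank) else curve$rank
  y <- if (log_axes) log10(pmax(curve$n, 0.5)) else curve$n
  cum <- cumsum(curve$n)

  sweep <- purrr::map_dfr(s_range, function(S) {
    i <- kneedle_knee(x, y, sensitivity = S)
    if (is.na(i)) {
      return(tibble::tibble(sensitivity = S, knee_rank = NA_integer_,
                            threshold_count = NA_real_, retained_fraction = NA_real_))
    }
    thr <- curve$n[i]
    called <- curve$n >= thr # ties at the threshold count are called
    tibble::tibble(sensitivity = S, knee_rank = as.integer(i),
                   threshold_count = thr,
                   retained_fraction = sum(curve$n[called]) / total)
  })
  sel <- select_sensitivity(sweep, target_retention)
  chosen <- sel$chosen
  warn <- sel$warning
  called <- curve$barcode[curve$n >= chosen$threshold_count]
  structure(list(
    sensitivity = chosen$sensitivity,
    knee_rank = chosen$knee_rank,
    threshold_count = chosen$threshold_count,
    retained_fraction = chosen$retained_fraction,
    called_barcodes = called,
    n_called = length(called),
    warning = warn,
    target_retention = target_retention,
    sweep = sweep,
    curve = curve
  ), class = "knee_result")
}

#' Select the sensitivity that most closely retains the target fraction
#'
#' Among sensitivities whose knee retains at least `target_retention` of
#' all contacts, the one with the smallest retained fraction (closest
#' above the target) is chosen; when none reaches the target, the
#' largest retained fraction wins and a warning flag is set.
#'
#' @param sweep Tibble with columns `sensitivity`, `knee_rank`,
#'   `threshold_count`, `retained_fraction` (NA rows = no knee).
#' @param target_retention Retention target in (0, 1].
#' @return List `chosen` (one-row tibble) and `warning` (logical).
#' @export
select_sensitivity <- function(sweep, target_retention = 0.85) {
  ok <- sweep[!is.na(sweep$retained_fraction), , drop = FALSE]
  if (nrow(ok) == 0) {
    stop("no knee detected at any sensitivity; set a manual threshold", call. = FALSE)
  }
  reach <- ok[ok$retained_fraction >= target_retention, , drop = FALSE]
  warn <- nrow(reach) == 0
  chosen <- if (warn) {
    ok[which.max(ok$retained_fraction), ]
  } else {
    reach[which.min(reach$retained_fraction), ]
  }
  list(chosen = chosen, warning = warn)
}

#' Call cells at a fixed count threshold
#' @param counts Per-barcode counts (tibble or named vector).
#' @param threshold Minimum contact count to call a barcode a cell.
#' @return A `knee_result` with `sensitivity = NA`.
#' @export
threshold_cell_call <- function(counts, threshold) {
  curve <- rank_curve(counts)
  called <- curve$barcode[curve$n >= threshold]
  structure(list(
    sensitivity = NA_integer_, knee_rank = NA_integer_,
    threshold_count = threshold,
    retained_fraction = sum(curve$n[curve$n >= threshold]) / sum(curve$n),
    called_barcodes = called, n_called = length(called),
    warning = FALSE, target_retention = NA_real_,
    sweep = NULL, curve = curve
  ), class = "knee_result")
}

#' @rdname adaptive_cell_call
#' @param x A `knee_result`.
#' @param ... Unused.
#' @method print knee_result
#' @export
print.knee_result <- function(x, ...) {
  cat("Knee-point cell calling\n")
  cat(sprintf("  sensitivity:       %s\n", x$sensitivity))
  cat(sprintf("  knee rank:         %s\n", x$knee_rank))
  cat(sprintf("  threshold count:   %s\n", format(x$threshold_count)))
  cat(sprintf("  cells called:      %d\n", x$n_called))
  cat(sprintf("  contacts retained: %.1f%%\n", 100 * x$retained_fraction))
  if (isTRUE(x$warning)) cat("  warning: retention target not reached at any sensitivity\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-sensitivity sweep of a knee result
#' @param x A `knee_result`.
#' @param ... Unused.
#' @return Tibble with one row per sensitivity swept.
#' @export
tidy.knee_result <- function(x, ...) {
  if (is.null(x$sweep)) {
    return(tibble::tibble(sensitivity = x$sensitivity, knee_rank = x$knee_rank,
                          threshold_count = x$threshold_count,
                          retained_fraction = x$retained_fraction))
  }
  x$sweep
}

#' One-row summary of a knee result
#' @param x A `knee_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.knee_result <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity, knee_rank = x$knee_rank,
    threshold_count = x$threshold_count,
    retained_fraction = x$retained_fraction,
    n_called = x$n_called, warning = x$warning
  )
}
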