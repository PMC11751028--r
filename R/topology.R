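#' Aggregate contacts into binned matrices per group
#'
#' Pools contacts by group label (cell, metacell or pseudobulk) and bins
#' both legs, producing one symmetric contact-count matrix per group.
#' Each contact adds 1 to `counts[i, j]` and `counts[j, i]`; total matrix
#' mass (upper triangle plus diagonal) equals the number of labeled
#' contacts, so mass is conserved across groups.
#'
#' @param contacts Canonical contact tibble.
#' @param labels Named character vector group-per-barcode, or tibble
#'   (`barcode`, `group`). Contacts with unlabeled barcodes are dropped
#'   and counted.
#' @param bins A `genome_bins`.
#' @return Named list of `binned_matrix` objects (fields `counts` sparse
#'   symmetric, `bins`, `group_id`, `weights = NULL`); attribute
#'   `n_unlabeled` counts dropped contacts.
#' @export
aggregate_contacts <- function(contacts, labels, bins) {
  if (is.data.frame(labels)) labels <- stats::setNames(labels$group, labels$barcode)
  grp <- labels[contacts$barcode]
  unlabeled <- is.na(grp)
  cc <- contacts[!unlabeled, , drop = FALSE]
  grp <- grp[!unlabeled]
  nb <- nrow(bins)
  b1 <- bin_of(bins, cc$chrom1, cc$pos1)
  b2 <- bin_of(bins, cc$chrom2, cc$pos2)
  groups <- unique(unname(labels))
  out <- purrr::map(groups, function(g) {
    sel <- grp == g
    if (!any(sel)) {
      warning("group '", g, "' has no contacts", call. = FALSE)
      counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                     dims = c(nb, nb))
    } else {
      i <- pmin(b1[sel], b2[sel]) + 1L
      j <- pmax(b1[sel], b2[sel]) + 1L
      upper <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nb, nb))
      counts <- upper + Matrix::t(upper)
      Matrix::diag(counts) <- Matrix::diag(counts) / 2
    }
    binned_matrix(counts, bins, group_id = g)
  })
  names(out) <- groups
  attr(out, "n_unlabeled") <- sum(unlabeled)
  out
}

#' Construct a binned contact matrix
#' @param counts Symmetric nonnegative matrix (bins x bins).
#' @param bins A `genome_bins`.
#' @param group_id Group label.
#' @param weights Optional balancing weights per bin.
#' @return A `binned_matrix` list.
#' @export
binned_matrix <- function(counts, bins, group_id = NA_character_, weights = NULL) {
  structure(list(counts = counts, bins = bins, group_id = group_id,
                 weights = weights), class = "binned_matrix")
}

#' Total contact mass of a binned matrix
#' @param m A `binned_matrix`.
#' @return Number of contacts (upper triangle + diagonal).
#' @export
matrix_mass <- function(m) {
  (sum(m$counts) + sum(Matrix::diag(m$counts))) / 2
}

#' Iterative-correction (ICE) balancing weights
#'
#' Computes per-bin multiplicative weights so that the balanced matrix
#' `W[i,j] = w[i] w[j] C[i,j]` has equal row marginals (target 1).
#' Low-coverage bins are excluded beforehand by a MAD-max rule on log
#' marginals (a bin is filtered when its nonzero log10 marginal falls
#' more than `mad_filter` MADs below the median); filtered bins get `NA`
#' weights and stay masked downstream.
#'
#' @param m A `binned_matrix`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the marginal coefficient of
#'   variation (default 1e-5).
#' @param mad_filter MAD-max coverage filter (default 5; `Inf` disables).
#' @return `m` with `weights` set; attribute `converged` on the weights.
#' @export
balance_matrix <- function(m, max_iter = 200, tol = 1e-5, mad_filter = 5) {
  C <- as.matrix(m$counts)
  n <- nrow(C)
  marg <- rowSums(C)
  good <- marg > 0
  if (is.finite(mad_filter) && sum(good) > 2) {
    lm <- log10(marg[good])
    cut <- stats::median(lm) - mad_filter * stats::mad(lm)
    good[good] <- lm >= cut
  }
  w <- rep(NA_real_, n)
  if (sum(good) == 0) {
    m$weights <- w
    attr(m$weights, "converged") <- FALSE
    return(m)
  }
  Cg <- C[good, good, drop = FALSE]
  wg <- rep(1, nrow(Cg))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.numeric(Cg %*% wg) * wg
    cv <- stats::sd(s) / mean(s)
    if (!is.finite(cv)) break
    if (cv < tol) {
      converged <- TRUE
      break
    }
    adj <- s / mean(s)
    wg <- wg / sqrt(adj)
  }
  # scale so balanced marginals equal 1
  s <- as.numeric(Cg %*% wg) * wg
  wg <- wg / sqrt(mean(s))
  w[good] <- wg
  if (!converged) warning("balancing did not converge in ", max_iter, " iterations",
                          call. = FALSE)
  m$weights <- w
  attr(m$weights, "converged") <- converged
  m
}

#' Balanced matrix values
#' @param m A balanced `binned_matrix`.
#' @return Dense matrix `w_i w_j C_ij` with NA at filtered bins.
#' @export
balanced_values <- function(m) {
  if (is.null(m$weights)) stop("matrix is not balanced; run balance_matrix()", call. = FALSE)
  W <- as.matrix(m$counts) * outer(m$weights, m$weights)
  W
}

#' Contact-frequency distance-decay curve P(s)
#'
#' Bins cis contacts into log-spaced genomic-distance bands and divides
#' the observed count in each band by the number of locus pairs at those
#' distances, yielding contact frequency per possible pair as a function
#' of distance.
#'
#' @param contacts Canonical contact tibble (trans rows ignored).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param breaks Distance-band breakpoints in bp, or `n_bins` log-spaced
#'   bands between `min_dist` and `max_dist` when `NULL`.
#' @param min_dist,max_dist Band range when `breaks` is `NULL`.
#' @param n_bins Number of log-spaced bands (default 30).
#' @return Tibble `s` (geometric mid), `lo`, `hi`, `n_contacts`,
#'   `n_pairs`, `freq` (`NA` for empty bands); class `ps_curve`.
#' @export
ps_curve <- function(contacts, chrom_sizes, breaks = NULL,
                     min_dist = 1e3, max_dist = NULL, n_bins = 30) {
  cis <- contacts[!contacts$is_trans, , drop = FALSE]
  if (is.null(max_dist)) max_dist <- max(chrom_sizes)
  if (is.null(breaks)) {
    breaks <- 10^seq(log10(min_dist), log10(max_dist), length.out = n_bins + 1)
  }
  d <- cis$distance
  counts <- graphics::hist(d[d >= breaks[1] & d < breaks[length(breaks)]],
                           breaks = breaks, plot = FALSE, right = FALSE)$counts
  # pairs at distance s on one chromosome of length L: L - s
  n_pairs <- purrr::map_dbl(seq_len(length(breaks) - 1), function(k) {
    lo <- ceiling(breaks[k])
    hi <- ceiling(breaks[k + 1]) - 1 # integer distances in [lo, hi]
    if (hi < lo) return(0)
    sum(purrr::map_dbl(unname(chrom_sizes), function(L) {
      h <- min(hi, L - 1)
      if (h < lo) return(0)
      n <- h - lo + 1
      n * L - (lo + h) * n / 2
    }))
  })
  freq <- ifelse(n_pairs > 0 & counts > 0, counts / n_pairs, NA_real_)
  out <- tibble::tibble(
    s = sqrt(breaks[-length(breaks)] * breaks[-1]),
    lo = breaks[-length(breaks)], hi = breaks[-1],
    n_contacts = counts, n_pairs = n_pairs, freq = freq
  )
  class(out) <- unique(c("ps_curve", class(out)))
  out
}

#' Log-log slope of a P(s) curve
#' @param ps A `ps_curve` tibble.
#' @param fit_range Optional `c(lo, hi)` distance range for the fit.
#' @return Fitted slope of log10 freq on log10 s.
#' @export
ps_slope <- function(ps, fit_range = NULL) {
  keep <- !is.na(ps$freq)
  if (!is.null(fit_range)) keep <- keep & ps$s >= fit_range[1] & ps$s <= fit_range[2]
  stats::coef(stats::lm(log10(freq) ~ log10(s), data = ps[keep, ]))[[2]]
}

#' Insulation score track
#'
#' For each bin, the insulation square value is the mean balanced
#' interaction over the window x window square upstream x downstream of
#' the bin boundary (`[i-w, i) x [i, i+w)` in bins); the normalized score
#' is its log2 ratio to the chromosome mean, so uniform matrices score 0
#' and the track is invariant to global scaling. Bins within a window of
#' a chromosome end are missing. Minima of the normalized track mark TAD
#' boundaries.
#'
#' @param m A balanced `binned_matrix` (see [balance_matrix()]); an
#'   unbalanced matrix is used as-is with unit weights.
#' @param window Window size in bp (must be at least 2 bins).
#' @return Tibble `chrom`, `start`, `end`, `bin`, `raw_square`, `score`;
#'   class `insulation_track`.
#' @export
insulation <- function(m, window) {
  bins <- m$bins
  bs <- attr(bins, "bin_size")
  w <- as.integer(round(window / bs))
  if (w < 2) stop("window must span at least 2 bins", call. = FALSE)
  V <- if (is.null(m$weights)) as.matrix(m$counts) else balanced_values(m)
  out <- bins
  out$raw_square <- NA_real_
  out$score <- NA_real_
  for (chrom in unique(bins$chrom)) {
    idx <- which(bins$chrom == chrom)
    nc <- length(idx)
    if (nc < 2 * w) next
    sub <- V[idx, idx, drop = FALSE]
    raw <- rep(NA_real_, nc)
    for (j in seq.int(w + 1L, nc - w + 1L)) {
      sq <- sub[(j - w):(j - 1L), j:(j + w - 1L), drop = FALSE]
      raw[j] <- mean(sq, na.rm = TRUE)
    }
    raw[is.nan(raw)] <- NA_real_
    cm <- mean(raw, na.rm = TRUE)
    out$raw_square[idx] <- raw
    if (is.finite(cm) && cm > 0) out$score[idx] <- log2(raw / cm)
  }
  class(out) <- unique(c("insulation_track", class(out)))
  out
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the normalized insulation score whose
#' prominence — the smaller of the rises to the nearest flanking local
#' maxima — is at least `min_strength` (log2 units).
#'
#' @param track An `insulation_track`.
#' @param min_strength Minimum boundary prominence (default 0.1).
#' @return Tibble `chrom`, `start`, `end`, `bin`, `score`, `strength`.
#' @export
call_boundaries <- function(track, min_strength = 0.1) {
  res <- purrr::map_dfr(unique(track$chrom), function(chrom) {
    tr <- track[track$chrom == chrom, , drop = FALSE]
    v <- tr$score
    ok <- which(!is.na(v))
    if (length(ok) < 3) return(NULL)
    s <- v[ok]
    n <- length(s)
    inner <- 2:(n - 1)
    is_min <- s[inner] < s[inner - 1] & s[inner] <= s[inner + 1]
    mins <- inner[is_min]
    if (length(mins) == 0) return(NULL)
    strength <- purrr::map_dbl(mins, function(i) {
      left <- s[1:(i - 1)]
      right <- s[(i + 1):n]
      # rise to the highest point before the track next dips below s[i]
      lmax <- max(left[seq.int(max(which(left < s[i]), 0) + 1, length(left))], na.rm = TRUE)
      rlow <- which(right < s[i])
      rmax <- if (length(rlow) == 0) max(right) else
        if (rlow[1] == 1) -Inf else max(right[1:(rlow[1] - 1)])
      min(lmax, rmax) - s[i]
    })
    keep <- is.finite(strength) & strength >= min_strength
    if (!any(keep)) return(NULL)
    sel <- ok[mins[keep]]
    tibble::tibble(chrom = chrom, start = tr$start[sel], end = tr$end[sel],
                   bin = tr$bin[sel], score = tr$score[sel],
                   strength = strength[keep])
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          bin = integer(), score = double(), strength = double())
  }
  res
}

#' TAD boundary usage at gene TSSs
#'
#' Usage of a gene's TSS boundary in a cluster: the fraction of the
#' cluster's members (cells or metacells) whose boundary calls include
#' the TSS bin.
#'
#' @param boundary_sets List of boundary tibbles (from
#'   [call_boundaries()]), one per cluster member.
#' @param tss Tibble `gene`, `chrom`, `pos` (1-based TSS position).
#' @param bins A `genome_bins`.
#' @return Tibble `gene`, `tss_bin`, `usage` (`NA` for TSSs on absent
#'   chromosomes).
#' @export
boundary_usage <- function(boundary_sets, tss, bins) {
  sizes <- attr(bins, "chrom_sizes")
  known <- tss$chrom %in% names(sizes)
  tss_bin <- rep(NA_integer_, nrow(tss))
  tss_bin[known] <- bin_of(bins, tss$chrom[known], tss$pos[known])
  member_bins <- purrr::map(boundary_sets, "bin")
  usage <- purrr::map_dbl(tss_bin, function(b) {
    if (is.na(b)) return(NA_real_)
    mean(purrr::map_lgl(member_bins, ~ b %in% .x))
  })
  tibble::tibble(gene = tss$gene, tss_bin = tss_bin, usage = usage)
}

#' Domain melting scores for long genes
#'
#' Compares the distribution of per-bin insulation square values over
#' each long gene's domain between a reference and a target condition
#' with a two-sample Kolmogorov-Smirnov test. The melting score is
#' `-log10 p`; a domain is called melted when the insulation square
#' values decreased in the target condition (domain structure lost) and
#' established when they increased. Only genes longer than `min_len` are
#' scored; tracks are expected at `resolution`-bp bins.
#'
#' @param square_ref,square_target `insulation_track` tibbles (their
#'   `raw_square` column is used) on the same binning.
#' @param genes Gene interval tibble `gene`, `chrom`, `start`, `end`.
#' @param min_len Minimum gene length in bp (default 3e5, exclusive).
#' @param min_bins Minimum non-missing bins per condition (default 4).
#' @param score_cutoff Score above which a call is made (default 5).
#' @return Tibble `gene`, `n_bins`, `stat`, `p`, `score`, `direction`
#'   (melted/established), `called`, `flag`.
#' @export
melting_score <- function(square_ref, square_target, genes,
                          min_len = 3e5, min_bins = 4, score_cutoff = 5) {
  bins <- square_ref[c("chrom", "start", "end", "bin")]
  genes <- genes[genes$end - genes$start > min_len, , drop = FALSE]
  purrr::pmap_dfr(genes[c("gene", "chrom", "start", "end")],
                  function(gene, chrom, start, end) {
    sel <- bins$chrom == chrom & bins$start < end & bins$end > start
    a <- square_ref$raw_square[sel]
    b <- square_target$raw_square[sel]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < min_bins || length(b) < min_bins) {
      return(tibble::tibble(gene = gene, n_bins = sum(sel), stat = NA_real_,
                            p = NA_real_, score = NA_real_,
                            direction = NA_character_, called = FALSE,
                            flag = "underpowered"))
    }
    if (isTRUE(all.equal(sort(a), sort(b)))) {
      kt <- list(statistic = 0, p.value = 1)
    } else {
      kt <- suppressWarnings(stats::ks.test(a, b))
    }
    direction <- if (mean(b) < mean(a)) "melted" else "established"
    score <- -log10(max(kt$p.value, .Machine$double.xmin))
    tibble::tibble(gene = gene, n_bins = sum(sel),
                   stat = unname(kt$statistic), p = kt$p.value, score = score,
                   direction = direction, called = score >= score_cutoff,
                   flag = NA_character_)
  })
}
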