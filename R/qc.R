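#' Barnyard (species-mixing) collision analysis
#'
#' In a two-species mixing experiment, reads are assigned to a genome by
#' the chromosome-name prefix of the concatenated reference; a droplet
#' containing cells of both species shows reads from both genomes. The
#' mixing rate of a barcode is the smaller genome count over the total,
#' so it is symmetric in the two genomes and lies in [0, 0.5]. Barcodes
#' with mixing rate strictly above `threshold` are called doublets.
#'
#' @param counts Tibble with `barcode`, `n_genomeA`, `n_genomeB` (read or
#'   contact counts per genome).
#' @param threshold Doublet mixing-rate cutoff, strict `>` (default 0.20).
#' @return Tibble `barcode`, `n_genomeA`, `n_genomeB`, `mixing_rate`,
#'   `call` (singlet_A / singlet_B / doublet); attribute `summary` has
#'   `n_cells`, `n_doublets`, `doublet_fraction`, `n_excluded`
#'   (zero-count barcodes).
#' @export
barnyard_call <- function(counts, threshold = 0.20) {
  tot <- counts$n_genomeA + counts$n_genomeB
  excluded <- tot == 0
  out <- counts[!excluded, , drop = FALSE]
  tot <- tot[!excluded]
  smaller <- pmin(out$n_genomeA, out$n_genomeB)
  out$mixing_rate <- smaller / tot
  out$call <- dplyr::case_when(
    out$mixing_rate > threshold ~ "doublet",
    out$n_genomeA >= out$n_genomeB ~ "singlet_A",
    TRUE ~ "singlet_B"
  )
  out <- tibble::as_tibble(out)
  attr(out, "summary") <- list(
    n_cells = nrow(out),
    n_doublets = sum(out$call == "doublet"),
    doublet_fraction = mean(out$call == "doublet"),
    n_excluded = sum(excluded)
  )
  out
}

#' Default cell-cycle distance bands
#'
#' Cis-contact distance bands whose per-cell mass fractions phase the
#' cell cycle: condensed mitotic chromosomes are enriched for 2-12 Mb
#' contacts, interphase cells for shorter- and longer-range contacts.
#' Sub-25 kb contacts are excluded from all bands.
#' @return Named list of `c(lower, upper)` bp bounds (upper exclusive).
#' @export
cycle_bands <- function() {
  list(short = c(25e3, 2e6), mitotic = c(2e6, 12e6), far = c(12e6, Inf))
}

#' Distance-band cell-cycle metrics per cell
#'
#' Computes, per barcode, the trans-contact fraction and the fraction of
#' cis contacts falling in each configured distance band. Phase labels
#' are deliberately not assigned; supply your own rule table on top of
#' these metrics.
#'
#' @param contacts Deduplicated canonical contact tibble.
#' @param bands Named list of `c(lower, upper)` bp bands
#'   (default [cycle_bands()]); lower inclusive, upper exclusive.
#' @return Tibble `barcode`, `n_contacts`, `frac_trans`, and one
#'   `frac_<band>` column per band (NA when a cell has no cis contacts).
#' @export
cycle_metrics <- function(contacts, bands = cycle_bands()) {
  base <- contacts |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      n_contacts = dplyr::n(),
      n_cis = sum(!.data$is_trans),
      frac_trans = mean(.data$is_trans)
    )
  band_cols <- purrr::imap(bands, function(b, nm) {
    contacts |>
      dplyr::group_by(.data$barcode) |>
      dplyr::summarise(!!paste0("frac_", nm) := {
        cis_d <- .data$distance[!.data$is_trans]
        if (length(cis_d) == 0) NA_real_ else mean(cis_d >= b[1] & cis_d < b[2])
      })
  })
  out <- purrr::reduce(band_cols, dplyr::left_join, by = "barcode", .init = base)
  dplyr::select(out, -"n_cis")
}

#' Joint multiome QC configuration
#'
#' Strict-inequality thresholds for keeping a cell in the joint
#' chromatin + RNA assay: more than 500 UMIs, more than 400 genes, more
#' than 1000 contact pairs, mitochondrial content below 10%, and
#' trans-contact rate below 45%.
#' @param min_umis,min_genes,min_contacts Lower bounds (exclusive).
#' @param max_mito,max_trans_rate Upper bounds (exclusive).
#' @return A `joint_qc_config` list.
#' @export
joint_qc_config <- function(min_umis = 500, min_genes = 400, min_contacts = 1000,
                            max_mito = 0.10, max_trans_rate = 0.45) {
  structure(list(min_umis = min_umis, min_genes = min_genes,
                 min_contacts = min_contacts, max_mito = max_mito,
                 max_trans_rate = max_trans_rate),
            class = "joint_qc_config")
}

#' Joint cell-calling filter for multiome data
#'
#' @param cells Tibble with `umis`, `genes`, `contacts`, `mito_frac`,
#'   `trans_rate` per cell.
#' @param cfg A [joint_qc_config()].
#' @return `cells` with logical `pass` and character `fail_reason`
#'   (`NA` when passing, "incomplete" when any metric is missing).
#' @export
joint_qc_filter <- function(cells, cfg = joint_qc_config()) {
  need <- c("umis", "genes", "contacts", "mito_frac", "trans_rate")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  incomplete <- !stats::complete.cases(cells[need])
  checks <- list(
    umis = cells$umis > cfg$min_umis,
    genes = cells$genes > cfg$min_genes,
    contacts = cells$contacts > cfg$min_contacts,
    mito_frac = cells$mito_frac < cfg$max_mito,
    trans_rate = cells$trans_rate < cfg$max_trans_rate
  )
  fail_reason <- rep(NA_character_, nrow(cells))
  for (nm in rev(names(checks))) {
    fail_reason[!incomplete & !checks[[nm]] %in% TRUE] <- nm
  }
  fail_reason[incomplete] <- "incomplete"
  cells$pass <- !incomplete & purrr::reduce(checks, `&`)
  cells$fail_reason <- fail_reason
  tibble::as_tibble(cells)
}
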