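#' Per-cell scA/B compartment scores
#'
#' Scores each genomic bin of each cell by the mean CpG density of the
#' bin's contact partners: every contact contributes its other leg's CpG
#' density to each of its legs' bins (a contact with both legs in the
#' same bin is excluded). CpG-rich partners indicate A-compartment
#' (active) placement, CpG-poor partners B-compartment. Bins touched by
#' fewer than `min_partner_contacts` contacts are masked (`NA`), never
#' zero-filled.
#'
#' @param contacts Deduplicated canonical contact tibble; `barcode`
#'   groups cells.
#' @param cpg A `bin_track` from [cpg_density()] (CpG density per bin).
#' @param bins The `genome_bins` the track is defined on.
#' @param min_partner_contacts Minimum partner contacts per bin before
#'   masking (default 1).
#' @param cis_only Drop trans partners (default `FALSE`: both cis and
#'   trans partners contribute, weight 1 per contact).
#' @param min_dist Optional additional cis distance floor in bp.
#' @return A `scab_matrix`: numeric matrix cells x bins (rownames =
#'   barcodes), attributes `bins`, `normalization = "raw"`.
#' @export
scab_matrix <- function(contacts, cpg, bins, min_partner_contacts = 1,
                        cis_only = FALSE, min_dist = NULL) {
  stopifnot(nrow(cpg) == nrow(bins))
  cc <- contacts
  if (cis_only) cc <- cc[!cc$is_trans, , drop = FALSE]
  if (!is.null(min_dist)) cc <- cc[cc$is_trans | cc$distance >= min_dist, , drop = FALSE]
  barcodes <- unique(contacts$barcode)
  nb <- nrow(bins)
  out <- matrix(NA_real_, nrow = length(barcodes), ncol = nb,
                dimnames = list(barcodes, NULL))
  if (nrow(cc) > 0) {
    b1 <- bin_of(bins, cc$chrom1, cc$pos1)
    b2 <- bin_of(bins, cc$chrom2, cc$pos2)
    same <- b1 == b2
    # each contact contributes its other leg; self-bin contacts excluded
    long <- tibble::tibble(
      barcode = rep(cc$barcode[!same], 2L),
      bin = c(b1[!same], b2[!same]),
      partner_cpg = c(cpg$value[b2[!same] + 1L], cpg$value[b1[!same] + 1L])
    )
    agg <- long |>
      dplyr::group_by(.data$barcode, .data$bin) |>
      dplyr::summarise(n = dplyr::n(), m = mean(.data$partner_cpg), .groups = "drop") |>
      dplyr::filter(.data$n >= min_partner_contacts)
    out[cbind(match(agg$barcode, barcodes), agg$bin + 1L)] <- agg$m
  }
  structure(out, bins = bins, normalization = "raw", class = c("scab_matrix", "matrix"))
}

#' Per-cell scA/B vector for a single cell
#' @inheritParams scab_matrix
#' @return Numeric vector of length `n_bins(bins)` (NA = masked).
#' @export
scab_per_cell <- function(contacts, cpg, bins, min_partner_contacts = 1,
                          cis_only = FALSE, min_dist = NULL) {
  if (nrow(contacts) == 0) return(rep(NA_real_, nrow(bins)))
  contacts$barcode <- "cell"
  m <- scab_matrix(contacts, cpg, bins, min_partner_contacts, cis_only, min_dist)
  as.numeric(m["cell", ])
}

#' Z-score normalize an scA/B matrix per cell
#'
#' Centers and scales each cell's unmasked bins to mean 0, sd 1
#' (population sd). Z-scored values are used for bin-level downstream
#' comparison; raw values are kept for gene-module scores. Cells with
#' fewer than 2 unmasked bins, or constant values, are left raw and
#' flagged.
#'
#' @param m A raw `scab_matrix`.
#' @return The matrix z-scored per cell, `normalization = "zscore"`,
#'   attribute `flagged_cells` naming cells left unnormalized.
#' @export
zscore_normalize <- function(m) {
  out <- m
  flagged <- character()
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2 || stats::sd(v[ok]) == 0) {
      flagged <- c(flagged, rownames(m)[i])
      next
    }
    mu <- mean(v[ok])
    s <- sqrt(mean((v[ok] - mu)^2)) # population sd
    out[i, ok] <- (v[ok] - mu) / s
  }
  attr(out, "normalization") <- "zscore"
  attr(out, "flagged_cells") <- flagged
  out
}

#' Map gene intervals to bin ordinals
#'
#' Any-overlap of the gene body with a bin assigns the bin to the gene;
#' no flanking is added. Genes on chromosomes absent from the binning are
#' dropped with a warning.
#'
#' @param genes Tibble `gene`, `chrom`, `start`, `end` (0-based
#'   half-open, BED-style).
#' @param bins A `genome_bins`.
#' @return Tibble `gene`, `bin` (one row per overlapped bin).
#' @export
gene_bins <- function(genes, bins) {
  sizes <- attr(bins, "chrom_sizes")
  absent <- setdiff(unique(genes$chrom), names(sizes))
  if (length(absent) > 0) {
    warning("dropping gene(s) on absent chromosome(s): ",
            paste(absent, collapse = ", "), call. = FALSE)
    genes <- genes[genes$chrom %in% names(sizes), , drop = FALSE]
  }
  bs <- attr(bins, "bin_size")
  purrr::pmap_dfr(genes[c("gene", "chrom", "start", "end")], function(gene, chrom, start, end) {
    start <- max(0, start)
    end <- min(end, sizes[[chrom]])
    if (end <= start) return(NULL)
    first <- bin_of(bins, chrom, start + 1)
    last <- bin_of(bins, chrom, end) # end is exclusive; last covered base = end
    tibble::tibble(gene = gene, bin = seq.int(first, last))
  })
}

#' Gene-level scA/B scores
#'
#' Per cell and gene, the mean of unmasked scA/B values over the bins the
#' gene body overlaps; missing when all of a gene's bins are masked.
#'
#' @param m A `scab_matrix` (raw or z-scored).
#' @param genes Gene interval tibble (see [gene_bins()]).
#' @return Numeric matrix cells x genes.
#' @export
gene_scab <- function(m, genes) {
  gb <- gene_bins(genes, attr(m, "bins"))
  gene_names <- unique(gb$gene)
  out <- matrix(NA_real_, nrow = nrow(m), ncol = length(gene_names),
                dimnames = list(rownames(m), gene_names))
  for (g in gene_names) {
    cols <- gb$bin[gb$gene == g] + 1L
    vals <- m[, cols, drop = FALSE]
    out[, g] <- rowMeans(vals, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Marker-gene-set scA/B scores and cluster typing
#'
#' Scores each cell for each cell type as the mean scA/B over the bins of
#' the type's marker-gene set (top marker genes per type), then labels
#' each cluster with the type maximizing the mean score over the
#' cluster's cells. Ties are broken by type order and flagged.
#'
#' @param m A `scab_matrix` (z-scored recommended).
#' @param marker_sets Tibble `cell_type`, `gene` (long format), or a
#'   named list of gene vectors.
#' @param genes Gene interval tibble mapping genes to bins.
#' @param clusters Optional named vector cluster-per-cell (names =
#'   barcodes); when given, per-cluster argmax labels are attached.
#' @return List: `scores` (cells x types matrix), `cluster_labels`
#'   (tibble `cluster`, `cell_type`, `score`, `tied`) or `NULL`.
#' @export
markerset_score <- function(m, marker_sets, genes, clusters = NULL) {
  if (is.list(marker_sets) && !is.data.frame(marker_sets)) {
    marker_sets <- purrr::imap_dfr(marker_sets, ~ tibble::tibble(cell_type = .y, gene = .x))
  }
  gb <- gene_bins(genes, attr(m, "bins"))
  types <- unique(marker_sets$cell_type)
  scores <- matrix(NA_real_, nrow = nrow(m), ncol = length(types),
                   dimnames = list(rownames(m), types))
  for (ty in types) {
    gs <- marker_sets$gene[marker_sets$cell_type == ty]
    cols <- unique(gb$bin[gb$gene %in% gs]) + 1L
    if (length(cols) == 0) next
    scores[, ty] <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }
  scores[is.nan(scores)] <- NA_real_
  cluster_labels <- NULL
  if (!is.null(clusters)) {
    cluster_labels <- purrr::map_dfr(unique(clusters), function(cl) {
      cells <- names(clusters)[clusters == cl]
      ms <- colMeans(scores[cells, , drop = FALSE], na.rm = TRUE)
      best <- which.max(ms)
      tibble::tibble(cluster = cl, cell_type = types[best], score = ms[best],
                     tied = sum(ms == ms[best], na.rm = TRUE) > 1)
    })
  }
  list(scores = scores, cluster_labels = cluster_labels)
}
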