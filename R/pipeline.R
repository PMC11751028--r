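#' Run the droplet Hi-C processing pipeline
#'
#' Orchestrates the core stages over a pairs file: contact extraction
#' and filtering, barcode-aware deduplication, per-barcode statistics,
#' and adaptive knee-point cell calling. Stages never mutate their
#' inputs; every output is a new file under `out_dir`, and a JSON run
#' report records configuration and per-stage record counts.
#'
#' @param config Named list or path to a YAML file with entries:
#'   `pairs` (input pairs file), `out_dir`, optional `chrom_sizes`
#'   (TSV path; defaults to the pairs header), `dup_dist`, `min_mapq`,
#'   `min_cis_distance`, `target_retention`, `smin`, `smax`.
#' @param overrides Named list of config overrides (flags win over YAML).
#' @return Invisibly, a list with `stats`, `knee`, `report`.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config[names(overrides)] <- overrides
  defaults <- list(dup_dist = 100, min_mapq = 20, min_cis_distance = 1000,
                   target_retention = 0.85, smin = 1, smax = 10)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("pairs", "out_dir")) {
    if (is.null(config[[nm]])) stop("config entry '", nm, "' is required", call. = FALSE)
  }
  if (!file.exists(config$pairs)) {
    stop("input file not found: ", config$pairs, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pairs <- read_pairs(config$pairs)
  chrom_sizes <- attr(pairs, "chrom_sizes")
  if (!is.null(config$chrom_sizes)) chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  if (is.null(chrom_sizes)) {
    stop("chromosome sizes needed: provide config$chrom_sizes or a pairs header",
         call. = FALSE)
  }
  cfg <- dedup_config(config$dup_dist, config$min_mapq, config$min_cis_distance)

  contacts <- extract_contacts(pairs, names(chrom_sizes), cfg)
  uniq <- dedup_contacts(sort_contacts(contacts), cfg)
  stats_tbl <- per_cell_stats(uniq)
  knee <- adaptive_cell_call(
    stats_tbl[c("barcode", "n_unique")],
    s_range = seq(config$smin, config$smax),
    target_retention = config$target_retention
  )

  attr(uniq, "chrom_sizes") <- chrom_sizes
  write_pairs(uniq, file.path(config$out_dir, "contacts.dedup.pairs"))
  readr::write_tsv(stats_tbl, file.path(config$out_dir, "cell_stats.tsv"))
  readr::write_lines(knee$called_barcodes,
                     file.path(config$out_dir, "called_barcodes.txt"))

  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    stages = list(
      extract = as.list(attr(contacts, "filter_counts")),
      dedup = list(input = nrow(contacts), unique = nrow(uniq)),
      cellcall = list(
        sensitivity = knee$sensitivity, knee_rank = knee$knee_rank,
        threshold_count = knee$threshold_count,
        retained_fraction = knee$retained_fraction, n_called = knee$n_called,
        warning = knee$warning
      )
    )
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(stats = stats_tbl, knee = knee, report = report))
}
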