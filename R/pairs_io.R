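#' Canonicalize contact leg order
#'
#' Orders the two legs of each contact so that `chrom1` precedes `chrom2`
#' in genome order (the order of `chrom_levels`) and, for cis contacts,
#' `pos1 <= pos2`. Adds `is_trans` and the cis genomic `distance`
#' (`NA` for trans). Contacts are unstranded; mapq values travel with
#' their leg.
#'
#' @param contacts Tibble with columns `barcode`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2` and optionally `mapq1`, `mapq2`.
#' @param chrom_levels Character vector fixing chromosome order.
#' @return Tibble with canonical leg order, `is_trans`, `distance`.
#' @export
canonicalize_contacts <- function(contacts, chrom_levels) {
  unknown <- setdiff(unique(c(contacts$chrom1, contacts$chrom2)), chrom_levels)
  if (length(unknown) > 0) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  c1 <- match(contacts$chrom1, chrom_levels)
  c2 <- match(contacts$chrom2, chrom_levels)
  flip <- c1 > c2 | (c1 == c2 & contacts$pos1 > contacts$pos2)
  out <- contacts
  if (any(flip)) {
    swap <- function(a, b) {
      tmp <- out[[a]][flip]
      out[[a]][flip] <<- out[[b]][flip]
      out[[b]][flip] <<- tmp
    }
    swap("chrom1", "chrom2")
    swap("pos1", "pos2")
    if (all(c("mapq1", "mapq2") %in% names(out))) swap("mapq1", "mapq2")
  }
  out$is_trans <- out$chrom1 != out$chrom2
  out$distance <- ifelse(out$is_trans, NA_real_, abs(out$pos2 - out$pos1))
  tibble::as_tibble(out)
}

#' Read a barcode-annotated contact-pairs file
#'
#' Tab-separated dialect with columns barcode, chrom1, pos1, chrom2, pos2,
#' mapq1, mapq2 and `#`-prefixed header lines; `#chromsize: <chrom> <len>`
#' lines carry the chromosome sizes (in canonical order). Positions are
#' 1-based, following the 4DN pairs convention. Leg order is
#' canonicalized on read.
#'
#' @param path Path to a pairs file (gzip transparent).
#' @return Tibble of contacts with attribute `chrom_sizes`.
#' @export
read_pairs <- function(path) {
  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  cs_lines <- header[startsWith(header, "#chromsize:")]
  chrom_sizes <- NULL
  if (length(cs_lines) > 0) {
    parts <- stringr::str_split_fixed(sub("^#chromsize:\\s*", "", cs_lines), "\\s+", 2)
    chrom_sizes <- stats::setNames(as.numeric(parts[, 2]), parts[, 1])
  }
  if (length(body) == 0) {
    out <- tibble::tibble(
      barcode = character(), chrom1 = character(), pos1 = double(),
      chrom2 = character(), pos2 = double(), mapq1 = integer(), mapq2 = integer(),
      is_trans = logical(), distance = double()
    )
    attr(out, "chrom_sizes") <- chrom_sizes
    return(out)
  }
  fields <- stringr::str_split(body, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 7L)
  if (length(bad) > 0) {
    line_no <- which(!is_header)[bad[1]]
    stop(sprintf("malformed pairs line %d: expected 7 columns, found %d",
                 line_no, nf[bad[1]]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 7, byrow = TRUE)
  out <- tibble::tibble(
    barcode = m[, 1], chrom1 = m[, 2], pos1 = as.numeric(m[, 3]),
    chrom2 = m[, 4], pos2 = as.numeric(m[, 5]),
    mapq1 = as.integer(m[, 6]), mapq2 = as.integer(m[, 7])
  )
  levels <- if (!is.null(chrom_sizes)) names(chrom_sizes) else {
    sort(unique(c(out$chrom1, out$chrom2)))
  }
  out <- canonicalize_contacts(out, levels)
  attr(out, "chrom_sizes") <- chrom_sizes
  out
}

#' Write contacts in the pairs dialect
#'
#' @param contacts Contact tibble (see [read_pairs()] for columns).
#' @param path Output path; `.gz` suffix writes gzip.
#' @param chrom_sizes Optional named vector written as `#chromsize:` header
#'   lines; defaults to the tibble's `chrom_sizes` attribute.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(contacts, path, chrom_sizes = attr(contacts, "chrom_sizes")) {
  header <- c(
    "## pairs-like contact file",
    "#columns: barcode chrom1 pos1 chrom2 pos2 mapq1 mapq2"
  )
  if (!is.null(chrom_sizes)) {
    header <- c(header, sprintf("#chromsize: %s %s", names(chrom_sizes),
                                format(chrom_sizes, scientific = FALSE, trim = TRUE)))
  }
  mapq1 <- if ("mapq1" %in% names(contacts)) contacts$mapq1 else rep(60L, nrow(contacts))
  mapq2 <- if ("mapq2" %in% names(contacts)) contacts$mapq2 else rep(60L, nrow(contacts))
  body <- sprintf(
    "%s\t%s\t%s\t%s\t%s\t%d\t%d",
    contacts$barcode, contacts$chrom1,
    format(contacts$pos1, scientific = FALSE, trim = TRUE),
    contacts$chrom2,
    format(contacts$pos2, scientific = FALSE, trim = TRUE),
    mapq1, mapq2
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
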