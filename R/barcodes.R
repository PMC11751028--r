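#' Read a barcode whitelist
#'
#' One barcode per line, optionally gzip-compressed (10x 737K-style). A
#' second file of equal length supplies the paired translation list used
#' by multiome assays (line i of `paired` corresponds to line i of
#' `path`).
#'
#' @param path Whitelist file.
#' @param paired Optional paired whitelist file for barcode translation.
#' @return A `whitelist` object (list with `barcodes`, optional `paired`,
#'   `width`).
#' @export
read_whitelist <- function(path, paired = NULL) {
  bcs <- readr::read_lines(path)
  bcs <- bcs[nzchar(bcs)]
  wl <- whitelist(bcs)
  if (!is.null(paired)) {
    p <- readr::read_lines(paired)
    p <- p[nzchar(p)]
    wl <- whitelist(bcs, paired = p)
  }
  wl
}

#' Construct a whitelist from barcode vectors
#'
#' @param barcodes Character vector of fixed-length ACGT barcodes.
#' @param paired Optional equal-length character vector; entry i is the
#'   translation of `barcodes[i]`.
#' @return A `whitelist` object.
#' @export
whitelist <- function(barcodes, paired = NULL) {
  if (length(barcodes) == 0) stop("empty whitelist", call. = FALSE)
  w <- unique(nchar(barcodes))
  if (length(w) != 1) stop("whitelist barcodes must share one length", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicated whitelist barcodes", call. = FALSE)
  if (!is.null(paired) && length(paired) != length(barcodes)) {
    stop("paired list must match whitelist length", call. = FALSE)
  }
  structure(list(barcodes = barcodes, paired = paired, width = w),
            class = "whitelist")
}

#' Correct one observed barcode against a whitelist
#'
#' An exact whitelist member is returned unchanged. Otherwise the unique
#' member within `max_mismatch` substitutions (Hamming distance) is
#' returned; zero or multiple candidates yield `NA` and the read is
#' discarded downstream. `N` bases count as mismatches at their position.
#'
#' @param observed Observed barcode string (whitelist width).
#' @param wl A `whitelist`.
#' @param max_mismatch Maximum substitutions allowed (default 1).
#' @return Corrected barcode, or `NA_character_`.
#' @export
match_barcode <- function(observed, wl, max_mismatch = 1) {
  if (nchar(observed) != wl$width) {
    stop("observed barcode length differs from whitelist width", call. = FALSE)
  }
  if (observed %in% wl$barcodes) return(observed)
  if (max_mismatch < 1) return(NA_character_)
  if (max_mismatch == 1) {
    hits <- unique(one_mismatch_hits(observed, wl))
  } else {
    d <- hamming_to_all(observed, wl$barcodes)
    hits <- wl$barcodes[d <= max_mismatch]
  }
  if (length(hits) == 1) hits else NA_character_
}

# all whitelist members reachable from `observed` by one substitution,
# via neighbor enumeration (3L + N-position variants) against the hash set
one_mismatch_hits <- function(observed, wl) {
  L <- wl$width
  hits <- character()
  for (i in seq_len(L)) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(observed, i, i) == b) next
      cand <- observed
      substr(cand, i, i) <- b
      if (cand %in% wl$barcodes) hits <- c(hits, cand)
    }
  }
  hits
}

hamming_to_all <- function(observed, barcodes) {
  obs <- strsplit(observed, "")[[1]]
  m <- matrix(unlist(strsplit(barcodes, "")), nrow = length(obs))
  colSums(m != obs | m == "N" | obs == "N")
}

#' Tag index reads with corrected cell barcodes
#'
#' Extracts the barcode from the first `wl$width` bases of each index read
#' (optionally reverse-complemented), corrects it against the whitelist
#' with at most one mismatch, and reports per-read assignments. Reads with
#' no or multiple whitelist hits are discarded (barcode `NA`).
#'
#' @param index_fastq Path to the index-read FASTQ, or a named character
#'   vector of read sequences (names = read ids).
#' @param wl A `whitelist`.
#' @param reverse_complement Reverse-complement reads before extraction
#'   (default `FALSE`).
#' @return Tibble `read_id`, `barcode`, `status`
#'   (exact/corrected/discarded); attribute `summary` holds the counts
#'   with `matched + corrected + discarded == total`.
#' @export
tag_reads <- function(index_fastq, wl, reverse_complement = FALSE) {
  if (is.character(index_fastq) && length(index_fastq) == 1 && file.exists(index_fastq)) {
    reads <- Biostrings::readDNAStringSet(index_fastq, format = "fastq")
    ids <- sub("\\s.*$", "", names(reads))
    seqs <- as.character(reads)
  } else {
    seqs <- as.character(index_fastq)
    ids <- names(index_fastq)
    if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  }
  if (length(seqs) == 0) {
    out <- tibble::tibble(read_id = character(), barcode = character(), status = character())
    attr(out, "summary") <- c(total = 0L, matched = 0L, corrected = 0L, discarded = 0L)
    return(out)
  }
  if (any(nchar(seqs) < wl$width)) {
    stop("index read shorter than barcode width", call. = FALSE)
  }
  if (reverse_complement) {
    seqs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  }
  obs <- substr(seqs, 1, wl$width)
  exact <- obs %in% wl$barcodes
  barcode <- ifelse(exact, obs, NA_character_)
  todo <- which(!exact)
  for (i in todo) {
    hits <- unique(one_mismatch_hits(obs[i], wl))
    if (length(hits) == 1) barcode[i] <- hits
  }
  status <- dplyr::case_when(
    exact ~ "exact",
    !is.na(barcode) ~ "corrected",
    TRUE ~ "discarded"
  )
  out <- tibble::tibble(read_id = ids, barcode = barcode, status = status)
  attr(out, "summary") <- c(
    total = length(seqs),
    matched = sum(exact),
    corrected = sum(status == "corrected"),
    discarded = sum(status == "discarded")
  )
  out
}

#' Translate multiome ATAC barcodes to their paired RNA barcodes
#'
#' Multiome whitelists pair each chromatin barcode with an RNA barcode at
#' the same line number; translation is a positional lookup. Non-members
#' return `NA`.
#'
#' @param atac_barcode Character vector of (already corrected) barcodes.
#' @param wl A `whitelist` built with a `paired` list.
#' @return Character vector of paired barcodes (`NA` for non-members).
#' @export
translate_multiome <- function(atac_barcode, wl) {
  if (is.null(wl$paired)) stop("whitelist has no paired translation list", call. = FALSE)
  wl$paired[match(atac_barcode, wl$barcodes)]
}
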