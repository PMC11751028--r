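#' Tile a genome into fixed-size bins
#'
#' Partitions every chromosome into consecutive `bin_size`-bp bins with
#' 0-based half-open coordinates. The last bin of a chromosome may be
#' shorter. Bin ordinals (`bin`, 0-based) follow chromosome order as given
#' in `chrom_sizes`, then start coordinate, and are the row/column indices
#' used by every binned object in the package.
#'
#' @param chrom_sizes Named numeric vector or two-column data frame
#'   (`chrom`, `length`) of chromosome lengths in bp. The order given here
#'   defines chromosome order throughout.
#' @param bin_size Bin width in bp (positive integer).
#'
#' @return A `genome_bins` object: a tibble with columns `chrom`, `start`,
#'   `end`, `bin`, plus attributes `chrom_sizes` (named vector) and
#'   `bin_size`.
#' @examples
#' make_bins(c(chrA = 250), 100)
#' @export
make_bins <- function(chrom_sizes, bin_size) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else {
    sizes <- chrom_sizes
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop("chrom_sizes must be named by chromosome", call. = FALSE)
  }
  if (length(bin_size) != 1 || is.na(bin_size) || bin_size <= 0) {
    stop("bin_size must be a single positive number", call. = FALSE)
  }
  if (any(sizes <= 0)) stop("all chromosome lengths must be positive", call. = FALSE)
  if (anyDuplicated(names(sizes))) stop("duplicated chromosome names", call. = FALSE)
  bin_size <- as.integer(bin_size)

  bins <- purrr::map2_dfr(names(sizes), unname(sizes), function(chrom, len) {
    starts <- seq(0L, len - 1L, by = bin_size)
    tibble::tibble(chrom = chrom, start = starts, end = pmin(starts + bin_size, len))
  })
  bins$bin <- seq_len(nrow(bins)) - 1L
  structure(bins,
    chrom_sizes = sizes, bin_size = bin_size,
    class = c("genome_bins", class(bins))
  )
}

#' Number of bins in a binning
#' @param bins A `genome_bins` object.
#' @return Integer bin count.
#' @export
n_bins <- function(bins) nrow(bins)

#' Map genomic positions to bin ordinals
#'
#' @param bins A `genome_bins` object from [make_bins()].
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 1-based positions (contact convention).
#' @return Integer vector of 0-based bin ordinals.
#' @export
bin_of <- function(bins, chrom, pos) {
  sizes <- attr(bins, "chrom_sizes")
  bin_size <- attr(bins, "bin_size")
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown) > 0) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1 | pos > sizes[chrom])) {
    stop("position outside chromosome bounds", call. = FALSE)
  }
  # first bin ordinal of each chromosome
  nb <- ceiling(sizes / bin_size)
  offset <- stats::setNames(cumsum(c(0, nb[-length(nb)])), names(sizes))
  as.integer(offset[chrom] + (pos - 1) %/% bin_size)
}

#' CpG density per bin from a genome sequence
#'
#' Counts CG dinucleotides whose first base falls inside each bin and
#' divides by bin length. A CpG straddling a bin edge is assigned to the
#' bin of its C, so it is counted exactly once. Counting is
#' case-insensitive; ambiguous bases (N etc.) never form a CpG. The track
#' calibrates scA/B compartment scores: A-compartment chromatin is
#' CpG-rich, B-compartment CpG-poor.
#'
#' @param fasta Path to a genome FASTA file, or a `Biostrings::DNAStringSet`.
#' @param bins A `genome_bins` object.
#' @return The `bins` tibble with a `value` column (CpG density, 1/bp);
#'   carries class `bin_track`.
#' @export
cpg_density <- function(fasta, bins) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(bins$chrom), names(seqs))
  if (length(missing) > 0) {
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- purrr::map_dbl(seq_len(nrow(bins)), function(i) {
    chrom <- bins$chrom[i]
    start <- bins$start[i]
    end <- bins$end[i]
    # one base of right context so an edge-straddling CpG counts here
    ctx_end <- min(end + 1L, length(seqs[[chrom]]))
    seg <- Biostrings::subseq(seqs[[chrom]], start + 1L, ctx_end)
    n <- Biostrings::countPattern("CG", Biostrings::DNAString(toupper(as.character(seg))))
    # drop a CpG whose C sits on the context base (impossible: CG needs 2 bases
    # past end); but a CpG starting at the last in-bin base is kept by design
    n / (end - start)
  })
  out <- bins
  out$value <- values
  class(out) <- unique(c("bin_track", class(out)))
  out
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with columns chromosome, length.
#' @return Named numeric vector in file order.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}
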