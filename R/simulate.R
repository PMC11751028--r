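# Seeded synthetic-data generators with ground truth for every pipeline
# stage. Each generator takes an explicit seed; stages within a generator
# draw from fixed sub-seeds so toggling one feature does not shift the
# draws of another.

substream <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 13L + 7919L * k
}

sample_powerlaw <- function(n, alpha, lo, hi) {
  u <- stats::runif(n)
  if (abs(alpha + 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a1 <- alpha + 1
    (lo^a1 + u * (hi^a1 - lo^a1))^(1 / a1)
  }
}

rand_barcodes <- function(n, width) {
  repeat {
    bcs <- unique(vapply(seq_len(ceiling(n * 1.1) + 4L), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, character(1)))
    if (length(bcs) >= n) return(bcs[seq_len(n)])
  }
}

#' Simulate a compartment-structured genome
#'
#' Builds a genome of alternating A/B compartment blocks in which each
#' bin's CpG density is drawn from its block's distribution and realized
#' in the sequence (CG dinucleotides planted in an A/T background, so
#' [cpg_density()] recovers the target within a few percent). A bins are
#' CpG-rich, B bins CpG-poor, mirroring active/inactive chromatin.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @param block_size Compartment block length; must be a multiple of
#'   `bin_size`.
#' @param cpg_high,cpg_low Mean CpG density (1/bp) of A and B bins.
#' @param rel_sd Relative s.d. of per-bin CpG density around the block
#'   mean (default 0.1).
#' @param seed Random seed.
#' @return List: `fasta` (`DNAStringSet`), `chrom_sizes`, `bins`
#'   (`genome_bins`), `truth` (tibble `bin`, `chrom`, `start`,
#'   `compartment`, `cpg_target`).
#' @export
sim_genome <- function(chrom_sizes = c(chr1 = 2e7, chr2 = 2e7), bin_size = 1e5,
                       block_size = 5e5, cpg_high = 0.02, cpg_low = 0.005,
                       rel_sd = 0.1, seed = 1) {
  if (any(chrom_sizes <= 0) || length(chrom_sizes) == 0) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (block_size %% bin_size != 0) {
    stop("block_size must be a multiple of bin_size", call. = FALSE)
  }
  set.seed(substream(seed, 1))
  bins <- make_bins(chrom_sizes, bin_size)
  block <- bins$start %/% block_size
  compartment <- ifelse(block %% 2 == 0, "A", "B")
  mu <- ifelse(compartment == "A", cpg_high, cpg_low)
  target <- pmax(mu * (1 + rel_sd * stats::rnorm(nrow(bins))), mu * 0.2)
  seqs <- purrr::map(names(chrom_sizes), function(chrom) {
    idx <- which(bins$chrom == chrom)
    parts <- purrr::map_chr(idx, function(i) {
      len <- bins$end[i] - bins$start[i]
      base <- sample(c("A", "T"), len, replace = TRUE)
      k <- round(target[i] * len)
      if (k > 0) {
        starts <- sample(seq(1L, len - 1L, by = 2L), k)
        base[starts] <- "C"
        base[starts + 1L] <- "G"
      }
      paste(base, collapse = "")
    })
    paste(parts, collapse = "")
  })
  fasta <- Biostrings::DNAStringSet(unlist(seqs))
  names(fasta) <- names(chrom_sizes)
  list(
    fasta = fasta, chrom_sizes = chrom_sizes, bins = bins,
    truth = tibble::tibble(bin = bins$bin, chrom = bins$chrom,
                           start = bins$start, compartment = compartment,
                           cpg_target = target)
  )
}

# draw cis contacts with power-law distance decay and optional
# within-compartment enrichment; comp is the per-bin compartment vector
draw_cis <- function(n, chrom_sizes, bins, comp, ps_exponent, min_cis,
                     enrichment) {
  bs <- attr(bins, "bin_size")
  out_c <- character(0); out_p1 <- numeric(0); out_p2 <- numeric(0)
  max_s <- max(chrom_sizes) - 1
  while (length(out_p1) < n) {
    m <- max(2L * (n - length(out_p1)), 1000L)
    chrom <- sample(names(chrom_sizes), m, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    L <- chrom_sizes[chrom]
    s <- round(sample_powerlaw(m, ps_exponent, min_cis + 1, max_s))
    p1 <- floor(stats::runif(m, 1, L + 1))
    p2 <- p1 + ifelse(stats::runif(m) < 0.5, 1, -1) * s
    ok <- p2 >= 1 & p2 <= L & s > min_cis
    if (enrichment > 1) {
      b1 <- rep(NA_integer_, m); b2 <- b1
      b1[ok] <- bin_of(bins, chrom[ok], p1[ok])
      b2[ok] <- bin_of(bins, chrom[ok], p2[ok])
      same <- comp[b1 + 1L] == comp[b2 + 1L]
      ok <- ok & (same | stats::runif(m) < 1 / enrichment)
    }
    out_c <- c(out_c, chrom[ok]); out_p1 <- c(out_p1, p1[ok]); out_p2 <- c(out_p2, p2[ok])
  }
  tibble::tibble(chrom1 = out_c[1:n], pos1 = out_p1[1:n],
                 chrom2 = out_c[1:n], pos2 = out_p2[1:n])
}

draw_trans <- function(n, chrom_sizes) {
  if (length(chrom_sizes) < 2) stop("trans contacts need >= 2 chromosomes", call. = FALSE)
  c1 <- sample(names(chrom_sizes), n, replace = TRUE, prob = chrom_sizes)
  c2 <- vapply(c1, function(ch) {
    rest <- chrom_sizes[names(chrom_sizes) != ch]
    sample(names(rest), 1, prob = rest)
  }, character(1))
  tibble::tibble(
    chrom1 = c1, pos1 = floor(stats::runif(n, 1, chrom_sizes[c1] + 1)),
    chrom2 = c2, pos2 = floor(stats::runif(n, 1, chrom_sizes[c2] + 1))
  )
}

mutate_barcode <- function(bc) {
  i <- sample(nchar(bc), 1)
  old <- substr(bc, i, i)
  substr(bc, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  bc
}

#' Simulate droplet single-cell Hi-C contacts with ground truth
#'
#' Generates barcode-annotated contacts for a mixture of true cells and
#' ambient droplets on a simulated genome: per-cell contact counts are
#' log-normal; cis distances follow a truncated power law with exponent
#' `ps_exponent`; contact partners are enriched within the cell's
#' compartments by `enrichment` (acceptance-rejection); trans contacts
#' occur at `trans_rate`; PCR/optical duplicates are re-emitted with leg
#' jitter uniform on `[0, dup_dist]`; barcode sequencing errors
#' substitute one base at `barcode_error_rate`. All truth tables are
#' returned alongside the data.
#'
#' @param genome Output of [sim_genome()].
#' @param n_cells Number of true cells.
#' @param contacts_meanlog,contacts_sdlog Log-normal parameters of total
#'   contacts per cell (defaults give mean ~5000).
#' @param n_ambient Number of ambient barcodes.
#' @param ambient_mean Mean (Poisson) contacts per ambient barcode.
#' @param dup_rate Probability an emitted contact is a planted duplicate.
#' @param dup_dist Duplicate jitter window in bp (default 100).
#' @param barcode_error_rate Per-contact barcode substitution rate.
#' @param ps_exponent Distance-decay exponent (default -1).
#' @param min_cis Minimum cis distance generated (default 1000 bp).
#' @param enrichment Within-compartment contact enrichment factor
#'   (default 5; 1 disables compartment structure).
#' @param trans_rate Fraction of trans contacts (default 0.1).
#' @param doublet_rate Fraction of cell barcodes hosting two cells.
#' @param cell_types Optional tibble `type`, `fraction`, and list-column
#'   `flip_bins` of bin ordinals whose compartment is flipped for cells
#'   of that type; default one type with the genome's compartments.
#' @param barcode_width Barcode length (default 12).
#' @param seed Random seed.
#' @return List: `pairs` (emitted contact tibble with observed
#'   `barcode`, legs in random order, mapq 60), `truth` (list `cells`,
#'   `contacts`, `whitelist`).
#' @export
sim_cells <- function(genome, n_cells = 20,
                      contacts_meanlog = log(5000) - 0.3^2 / 2,
                      contacts_sdlog = 0.3, n_ambient = 200, ambient_mean = 15,
                      dup_rate = 0.15, dup_dist = 100,
                      barcode_error_rate = 0.02, ps_exponent = -1,
                      min_cis = 1000, enrichment = 5, trans_rate = 0.1,
                      doublet_rate = 0, cell_types = NULL, barcode_width = 12,
                      seed = 1) {
  if (enrichment > 1 && length(unique(genome$truth$compartment)) < 2) {
    stop("compartment enrichment needs both compartments present", call. = FALSE)
  }
  if (is.null(cell_types)) {
    cell_types <- tibble::tibble(type = "base", fraction = 1,
                                 flip_bins = list(integer(0)))
  }
  base_comp <- genome$truth$compartment
  comp_of_type <- function(ty) {
    cmp <- base_comp
    fb <- cell_types$flip_bins[[match(ty, cell_types$type)]]
    if (length(fb) > 0) cmp[fb + 1L] <- ifelse(cmp[fb + 1L] == "A", "B", "A")
    cmp
  }

  set.seed(substream(seed, 2))
  wl <- rand_barcodes(n_cells + n_ambient, barcode_width)
  cell_bc <- wl[seq_len(n_cells)]
  amb_bc <- wl[n_cells + seq_len(n_ambient)]
  is_doublet <- stats::runif(n_cells) < doublet_rate
  type1 <- sample(cell_types$type, n_cells, replace = TRUE,
                  prob = cell_types$fraction)
  type2 <- ifelse(is_doublet,
                  sample(cell_types$type, n_cells, replace = TRUE,
                         prob = cell_types$fraction), NA_character_)
  n_total_cell <- pmax(2L, round(stats::rlnorm(n_cells, contacts_meanlog,
                                               contacts_sdlog)))
  n_total_amb <- stats::rpois(n_ambient, ambient_mean)

  cells <- tibble::tibble(
    barcode = c(cell_bc, amb_bc),
    status = c(ifelse(is_doublet, "doublet", "cell"), rep("ambient", n_ambient)),
    cell_type = c(type1, rep(NA_character_, n_ambient)),
    cell_type2 = c(type2, rep(NA_character_, n_ambient)),
    n_total = c(n_total_cell, n_total_amb)
  )
  cells$n_dup <- stats::rbinom(nrow(cells), cells$n_total, dup_rate)
  cells$n_unique <- cells$n_total - cells$n_dup

  set.seed(substream(seed, 3))
  # generate unique contacts grouped by effective compartment profile
  cells$profile <- ifelse(cells$status == "ambient", cell_types$type[1], cells$cell_type)
  contact_rows <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    nu <- cells$n_unique[i]
    if (nu == 0) return(NULL)
    halves <- if (cells$status[i] == "doublet") {
      nh <- stats::rbinom(1, nu, 0.5)
      list(c(cells$cell_type[i], nh), c(cells$cell_type2[i], nu - nh))
    } else {
      list(c(cells$profile[i], nu))
    }
    purrr::map_dfr(halves, function(h) {
      ty <- h[1]; nn <- as.integer(h[2])
      if (nn == 0) return(NULL)
      n_trans <- stats::rbinom(1, nn, if (length(genome$chrom_sizes) > 1) trans_rate else 0)
      cmp <- comp_of_type(ty)
      cis <- if (nn - n_trans > 0) {
        draw_cis(nn - n_trans, genome$chrom_sizes, genome$bins, cmp,
                 ps_exponent, min_cis, enrichment)
      } else NULL
      tr <- if (n_trans > 0) draw_trans(n_trans, genome$chrom_sizes) else NULL
      dplyr::bind_rows(cis, tr)
    }) |>
      dplyr::mutate(barcode_true = cells$barcode[i])
  })
  contact_rows$is_duplicate <- FALSE

  set.seed(substream(seed, 4))
  dup_rows <- purrr::map_dfr(which(cells$n_dup > 0), function(i) {
    pool <- contact_rows[contact_rows$barcode_true == cells$barcode[i], , drop = FALSE]
    if (nrow(pool) == 0) return(NULL)
    src <- pool[sample(nrow(pool), cells$n_dup[i], replace = TRUE), , drop = FALSE]
    src$pos1 <- src$pos1 + floor(stats::runif(nrow(src), 0, dup_dist + 1))
    src$pos2 <- src$pos2 + floor(stats::runif(nrow(src), 0, dup_dist + 1))
    src$pos1 <- pmin(src$pos1, genome$chrom_sizes[src$chrom1])
    src$pos2 <- pmin(src$pos2, genome$chrom_sizes[src$chrom2])
    src$is_duplicate <- TRUE
    src
  })
  all_rows <- dplyr::bind_rows(contact_rows, dup_rows)

  set.seed(substream(seed, 5))
  err <- stats::runif(nrow(all_rows)) < barcode_error_rate
  all_rows$barcode <- all_rows$barcode_true
  if (any(err)) {
    all_rows$barcode[err] <- vapply(all_rows$barcode_true[err], mutate_barcode,
                                    character(1))
  }
  # emit legs in random order to exercise canonicalization
  flip <- stats::runif(nrow(all_rows)) < 0.5
  pairs <- tibble::tibble(
    barcode = all_rows$barcode,
    chrom1 = ifelse(flip, all_rows$chrom2, all_rows$chrom1),
    pos1 = ifelse(flip, all_rows$pos2, all_rows$pos1),
    chrom2 = ifelse(flip, all_rows$chrom1, all_rows$chrom2),
    pos2 = ifelse(flip, all_rows$pos1, all_rows$pos2),
    mapq1 = 60L, mapq2 = 60L
  )
  ord <- sample(nrow(pairs))
  cells$profile <- NULL
  list(
    pairs = pairs[ord, ],
    truth = list(cells = cells, contacts = all_rows[ord, ], whitelist = wl)
  )
}

#' Simulate index reads carrying cell barcodes
#'
#' Minimal FASTQ-style index-read emitter for the barcode module: reads
#' are whitelist barcodes with a one-base substitution error at
#' `error_rate`.
#'
#' @param barcodes Whitelist barcode vector.
#' @param n_reads Number of reads.
#' @param error_rate Per-read substitution probability.
#' @param seed Random seed.
#' @return List: `reads` (named character vector, names = read ids),
#'   `truth` (tibble `read_id`, `barcode_true`, `has_error`).
#' @export
sim_index_reads <- function(barcodes, n_reads = 1000, error_rate = 0.05, seed = 1) {
  set.seed(substream(seed, 6))
  true <- sample(barcodes, n_reads, replace = TRUE)
  err <- stats::runif(n_reads) < error_rate
  obs <- true
  if (any(err)) obs[err] <- vapply(true[err], mutate_barcode, character(1))
  ids <- sprintf("read%06d", seq_len(n_reads))
  names(obs) <- ids
  list(reads = obs,
       truth = tibble::tibble(read_id = ids, barcode_true = true, has_error = err))
}

#' Write reads as FASTQ
#' @param reads Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  readr::write_lines(
    as.vector(rbind(paste0("@", names(reads)), unname(reads), "+", qual)), path)
  invisible(path)
}

#' Simulate a barcode-rank mixture at count level
#'
#' Per-barcode contact counts for a mixture of true cells (log-normal)
#' and ambient droplets (log-normal around a small mean), the input of
#' knee-point cell calling. Count-level only: no contact records are
#' materialized.
#'
#' @param n_cells Number of true cells (default 500).
#' @param cell_mean Mean contacts per true cell (default 20000).
#' @param cell_sdlog Log-sd of cell counts (default 0.5).
#' @param n_ambient Number of ambient barcodes (default 50000).
#' @param ambient_mean Mean contacts per ambient barcode (default 20).
#' @param ambient_sdlog Log-sd of ambient counts (default 0.8).
#' @param seed Random seed.
#' @return Tibble `barcode`, `n`, `is_cell`.
#' @export
sim_barcode_mixture <- function(n_cells = 500, cell_mean = 20000,
                                cell_sdlog = 0.5, n_ambient = 50000,
                                ambient_mean = 20, ambient_sdlog = 0.8,
                                seed = 1) {
  set.seed(substream(seed, 7))
  n_cell <- round(stats::rlnorm(n_cells, log(cell_mean) - cell_sdlog^2 / 2, cell_sdlog))
  n_amb <- pmax(1, round(stats::rlnorm(n_ambient, log(ambient_mean) - ambient_sdlog^2 / 2,
                                       ambient_sdlog)))
  tibble::tibble(
    barcode = sprintf("BC%06d", seq_len(n_cells + n_ambient)),
    n = c(n_cell, n_amb),
    is_cell = rep(c(TRUE, FALSE), c(n_cells, n_ambient))
  )
}

#' Simulate a barnyard (species-mixing) experiment
#'
#' Droplets hold a cell of species A, of species B, or (doublets) one of
#' each. Singlets draw a small cross-species noise fraction of reads;
#' doublets mix roughly 1:1.
#'
#' @param n_droplets Number of droplets (default 1000).
#' @param doublet_rate Doublet probability (default 0.1).
#' @param mean_reads Mean reads per droplet (default 1000, Poisson).
#' @param cross_noise Cross-species read fraction in singlets
#'   (default 0.02).
#' @param seed Random seed.
#' @return List: `counts` (tibble `barcode`, `n_genomeA`, `n_genomeB`),
#'   `truth` (tibble `barcode`, `is_doublet`, `species`).
#' @export
sim_barnyard <- function(n_droplets = 1000, doublet_rate = 0.1,
                         mean_reads = 1000, cross_noise = 0.02, seed = 1) {
  set.seed(substream(seed, 8))
  is_doublet <- stats::runif(n_droplets) < doublet_rate
  species <- ifelse(is_doublet, "AB", sample(c("A", "B"), n_droplets, replace = TRUE))
  total <- stats::rpois(n_droplets, mean_reads)
  nA <- integer(n_droplets)
  singA <- species == "A"
  singB <- species == "B"
  nA[singA] <- total[singA] - stats::rbinom(sum(singA), total[singA], cross_noise)
  nA[singB] <- stats::rbinom(sum(singB), total[singB], cross_noise)
  nA[is_doublet] <- stats::rbinom(sum(is_doublet), total[is_doublet], 0.5)
  bc <- sprintf("DROP%05d", seq_len(n_droplets))
  list(
    counts = tibble::tibble(barcode = bc, n_genomeA = nA, n_genomeB = total - nA),
    truth = tibble::tibble(barcode = bc, is_doublet = is_doublet, species = species)
  )
}

#' Simulate an aging cohort of per-cell scA/B profiles
#'
#' Three timepoints (young, middle, old) of cells organized into
#' metacells, with a planted compartment shift: `n_shifted` bins gain
#' `delta` in old cells only; young and middle are identically
#' distributed. Optionally a gene-module block of bins is elevated by
#' `module_delta` in old cells. Per-cell profiles are the bin base
#' profile (alternating compartment blocks) plus i.i.d. noise; a small
#' fraction of entries is masked at random.
#'
#' @param n_bins Bins on one synthetic chromosome (default 1000).
#' @param bin_size Bin width in bp (default 5e5).
#' @param block_bins Compartment block length in bins (default 5).
#' @param n_shifted Number of shifted bins (default 50).
#' @param delta Shift added in old cells (default 0.2).
#' @param timepoints Timepoint labels (default young/middle/old).
#' @param n_metacells Metacells per timepoint (default 15).
#' @param cells_per_metacell Cells per metacell (default 10).
#' @param noise_sd Per-cell, per-bin noise s.d. (default 0.2).
#' @param mask_rate Random masking rate (default 0.02).
#' @param module_bins Optional bin ordinals of a gene module.
#' @param module_delta Elevation of module bins in old cells (default 0).
#' @param seed Random seed.
#' @return List: `scab` (`scab_matrix`, cells x bins), `cell_meta`
#'   (tibble `barcode`, `metacell`, `timepoint`, `cell_type`), `bins`,
#'   `truth` (list `shifted_bins`, `delta`, `module_bins`,
#'   `module_delta`, `base_profile`).
#' @export
sim_aging_cohort <- function(n_bins = 1000, bin_size = 5e5, block_bins = 5,
                             n_shifted = 50, delta = 0.2,
                             timepoints = c("young", "middle", "old"),
                             n_metacells = 15, cells_per_metacell = 10,
                             noise_sd = 0.2, mask_rate = 0.02,
                             module_bins = NULL, module_delta = 0, seed = 1) {
  set.seed(substream(seed, 9))
  bins <- make_bins(stats::setNames(n_bins * bin_size, "chrS"), bin_size)
  base <- ifelse((bins$bin %/% block_bins) %% 2 == 0, 0.5, -0.5) +
    stats::rnorm(n_bins, 0, 0.05)
  shifted_bins <- sort(sample(bins$bin, n_shifted))
  n_cells_tp <- n_metacells * cells_per_metacell
  meta <- purrr::map_dfr(timepoints, function(tp) {
    tibble::tibble(
      barcode = sprintf("%s_cell%04d", tp, seq_len(n_cells_tp)),
      metacell = sprintf("%s_mc%02d", tp, rep(seq_len(n_metacells),
                                              each = cells_per_metacell)),
      timepoint = tp, cell_type = "sim"
    )
  })
  n_cells <- nrow(meta)
  m <- matrix(rep(base, each = n_cells), nrow = n_cells) +
    matrix(stats::rnorm(n_cells * n_bins, 0, noise_sd), nrow = n_cells)
  old <- meta$timepoint == "old"
  m[old, shifted_bins + 1L] <- m[old, shifted_bins + 1L] + delta
  if (!is.null(module_bins) && module_delta != 0) {
    m[old, module_bins + 1L] <- m[old, module_bins + 1L] + module_delta
  }
  if (mask_rate > 0) {
    m[matrix(stats::runif(length(m)) < mask_rate, nrow = n_cells)] <- NA_real_
  }
  rownames(m) <- meta$barcode
  scab <- structure(m, bins = bins, normalization = "raw",
                    class = c("scab_matrix", "matrix"))
  list(scab = scab, cell_meta = meta, bins = bins,
       truth = list(shifted_bins = shifted_bins, delta = delta,
                    module_bins = module_bins, module_delta = module_delta,
                    base_profile = base))
}
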