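# Independent brute-force oracles, deliberately naive and separate from
# the package's code paths.

# O(n^2) greedy duplicate clustering: scan contacts in sort order, keep a
# contact unless it matches any previously kept one under the pairwise
# duplicate predicate.
oracle_dedup <- function(contacts, dup_dist = 100) {
  n <- nrow(contacts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in which(keep)) {
      if (contacts$barcode[j] == contacts$barcode[i] &&
          contacts$chrom1[j] == contacts$chrom1[i] &&
          contacts$chrom2[j] == contacts$chrom2[i] &&
          abs(contacts$pos1[j] - contacts$pos1[i]) <= dup_dist &&
          abs(contacts$pos2[j] - contacts$pos2[i]) <= dup_dist) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  keep
}

# brute-force Hamming search over the whole whitelist; N never matches
oracle_match <- function(observed, barcodes, max_mismatch = 1) {
  o <- strsplit(observed, "")[[1]]
  dists <- vapply(barcodes, function(b) {
    bb <- strsplit(b, "")[[1]]
    sum(bb != o | bb == "N" | o == "N")
  }, numeric(1))
  if (any(dists == 0)) return(observed)
  hits <- barcodes[dists <= max_mismatch]
  if (length(hits) == 1) hits else NA_character_
}

# exact two-sided rank-sum p-value by full enumeration of arrangements
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cummin_rev <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj[o] <- pmin(1, cummin_rev)
  adj
}

# random canonical contact table on a toy genome
random_contacts <- function(n, barcodes = c("AAA", "CCC"),
                            chroms = c(chrA = 1e5, chrB = 8e4), seed = 1) {
  set.seed(seed)
  chrom1 <- sample(names(chroms), n, replace = TRUE)
  chrom2 <- sample(names(chroms), n, replace = TRUE)
  tbl <- tibble::tibble(
    barcode = sample(barcodes, n, replace = TRUE),
    chrom1 = chrom1, pos1 = sample.int(5e4, n, replace = TRUE),
    chrom2 = chrom2, pos2 = sample.int(5e4, n, replace = TRUE),
    mapq1 = 60L, mapq2 = 60L
  )
  canonicalize_contacts(tbl, names(chroms))
}

toy_bins <- function() make_bins(c(chrA = 1000, chrB = 500), 100)
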