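# Shared fixtures and independent oracles.

# Brute-force two-stage grid search for the likelihood maximum over m:
# log-spaced coarse grid, then a fine grid around the coarse argmax. Uses
# only pmf evaluations and which.max — independent of the package's
# bracketing/golden-section search path.
grid_mle <- function(counts, lo = 1e-4, hi = NULL, n = 600, cap = 10000L) {
  if (is.null(hi)) hi <- 10 * (mean(counts) + 1)
  ll <- function(m) {
    r_need <- min(max(counts), cap)
    p <- ld_pmf(m, r_need)$pmf
    capped <- pmin(counts, r_need + 1L)
    out <- 0
    inr <- capped <= r_need
    pr <- p[capped[inr] + 1L]
    if (any(pr <= 0)) return(-Inf)
    out <- sum(log(pr))
    if (any(!inr)) out <- out + sum(!inr) * log(max(1 - sum(p), 1e-300))
    out
  }
  coarse <- exp(seq(log(lo), log(hi), length.out = n))
  i <- which.max(vapply(coarse, ll, numeric(1)))
  lo2 <- coarse[max(1, i - 1)]; hi2 <- coarse[min(n, i + 1)]
  fine <- exp(seq(log(lo2), log(hi2), length.out = n))
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# Tiny frequency profile built by hand: positions 1..n, given ref string and
# a list position -> named base frequencies (rest of mass on the ref base).
toy_profile <- function(ref, alt_freq = list(), coverage = 1000) {
  refv <- strsplit(ref, "")[[1]]
  n <- length(refv)
  freq <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) freq[i, refv[i]] <- 1
  for (pos in names(alt_freq)) {
    i <- as.integer(pos)
    for (b in names(alt_freq[[pos]])) {
      f <- alt_freq[[pos]][[b]]
      freq[i, b] <- f
      freq[i, refv[i]] <- freq[i, refv[i]] - f
    }
  }
  frequency_profile(seq_len(n), refv, freq, rep(coverage, n))
}

# Directly build a well_mutation_table from per-well read sequences, skipping
# demultiplexing: reads are full-length and gaplessly aligned at offset 1.
wells_from_seqs <- function(seqs_by_well, reference) {
  df <- data.frame(
    id = unlist(lapply(names(seqs_by_well), function(w)
      paste0(w, "_", seq_along(seqs_by_well[[w]])))),
    well = rep(names(seqs_by_well), lengths(seqs_by_well)),
    seq = unlist(seqs_by_well), row.names = NULL)
  well_distributions(df, reference, offsets = rep(1L, nrow(df)))
}

# A valid driver specification for a given gene: any non-reference base.
pick_driver <- function(gene, pos, well_fraction = 0.85,
                        within_well_freq = 0.9) {
  refb <- substr(gene, pos, pos)
  list(pos = as.integer(pos),
       alt = setdiff(c("A", "C", "G", "T"), refb)[1],
       well_fraction = well_fraction, within_well_freq = within_well_freq)
}

# Place a substitution into n copies of a reference string.
mutate_seq <- function(ref, pos, alt) {
  v <- strsplit(ref, "")[[1]]; v[pos] <- alt; paste(v, collapse = "")
}
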