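# Per-position mutation-spectrum profiling from quality-filtered targeted
# sequencing: pileup construction, base frequencies, trimmed moving averages,
# windowed substitutions-per-base, fold enrichment and background subtraction.

BASES <- c("A", "C", "G", "T")

#' The twelve base-substitution types
#'
#' All ordered `ref>alt` pairs over A/C/G/T, on the reference strand (so
#' `C>T` and `G>A` are distinct classes).
#' @return Character vector of length 12, e.g. `"C>T"`.
#' @export
substitution_types <- function() {
  out <- outer(BASES, BASES, function(r, a) paste0(r, ">", a))
  out[row(out) != col(out)]
}

.parse_subst <- function(type) {
  m <- regmatches(type, regexec("^([ACGT])>([ACGT])$", type))[[1]]
  if (length(m) != 3L || m[2] == m[3])
    stop("substitution type must look like 'C>T' with distinct bases")
  c(ref = m[2], alt = m[3])
}

#' Construct a pileup matrix
#'
#' @param positions 1-based reference coordinates (strictly increasing).
#' @param ref Reference base per position (A/C/G/T).
#' @param counts Integer matrix, one row per position, columns A,C,G,T.
#' @param qmin Phred threshold that was applied when tallying.
#' @param offset Signed coordinate shift applied (recorded, not reapplied).
#' @return Object of class `pileup_matrix`.
#' @export
pileup_matrix <- function(positions, ref, counts, qmin = NA_real_,
                          offset = 0L) {
  positions <- as.integer(positions)
  ref <- toupper(as.character(ref))
  counts <- as.matrix(counts)
  colnames(counts) <- BASES
  if (length(positions) != length(ref) || nrow(counts) != length(ref))
    stop("positions, ref and counts rows must align")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!all(ref %in% BASES)) stop("ref bases must be A/C/G/T")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(positions = positions, ref = ref, counts = counts,
                 qmin = qmin, offset = as.integer(offset)),
            class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat("Pileup matrix:", length(x$positions), "positions,",
      "coverage", sum(x$counts), "base calls",
      if (!is.na(x$qmin)) paste0("(Q>=", x$qmin, ")"), "\n")
  invisible(x)
}

# Reference as character string from character / DNAString / FASTA path.
.as_ref_string <- function(reference) {
  if (inherits(reference, "DNAString"))
    return(as.character(reference))
  if (inherits(reference, "DNAStringSet"))
    return(as.character(reference[[1]]))
  if (is.character(reference) && length(reference) == 1L) {
    if (file.exists(reference) && !grepl("^[ACGTNacgtn]+$", reference)) {
      set <- Biostrings::readDNAStringSet(reference)
      return(as.character(set[[1]]))
    }
    return(toupper(reference))
  }
  stop("reference must be a DNA string, DNAString(Set) or FASTA path")
}

#' Build a quality-filtered pileup from gaplessly aligned reads
#'
#' Tallies per-position A/C/G/T counts from aligned reads, dropping every
#' base call whose Phred quality is below `qmin` (the quality filter applied
#' before any frequency is computed). Input is either a minimal SAM file
#' (only `M` CIGAR operations accepted; see [read_minimal_sam()]) or a read
#' table `data.frame(pos, seq, qual)` with 1-based leftmost positions,
#' read sequences, and Phred+33 quality strings.
#'
#' Reads overhanging the reference are trimmed with a warning; reads whose
#' alignment contains indel or clip operations are rejected (counted in a
#' single warning).
#'
#' @param reads SAM path or read table.
#' @param reference Reference sequence (string, `DNAString`, or FASTA path).
#' @param qmin Minimum Phred quality for a base call to be counted
#'   (default 35).
#' @return A [pileup_matrix()] covering every reference position.
#' @export
build_pileup <- function(reads, reference, qmin = 35) {
  refstr <- .as_ref_string(reference)
  L <- nchar(refstr)
  refv <- strsplit(refstr, "")[[1]]
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_minimal_sam(reads)
  stopifnot(is.data.frame(reads), all(c("pos", "seq", "qual") %in% names(reads)))
  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  n_trimmed <- 0L
  for (j in seq_len(nrow(reads))) {
    pos <- reads$pos[j]
    s <- toupper(reads$seq[j])
    q <- utf8ToInt(reads$qual[j]) - 33L
    n <- nchar(s)
    if (n != length(q)) stop("read ", j, ": seq and qual lengths differ")
    end <- pos + n - 1L
    if (pos < 1L || end > L) {
      n_trimmed <- n_trimmed + 1L
      keep_from <- max(1L, 2L - pos)
      keep_to <- n - max(0L, end - L)
      if (keep_from > keep_to) next
      s <- substr(s, keep_from, keep_to)
      q <- q[keep_from:keep_to]
      pos <- max(pos, 1L)
      n <- nchar(s)
    }
    bases <- strsplit(s, "")[[1]]
    ok <- q >= qmin & bases %in% BASES
    if (!any(ok)) next
    idx <- cbind(pos + which(ok) - 1L, match(bases[ok], BASES))
    for (k in seq_len(nrow(idx)))
      counts[idx[k, 1], idx[k, 2]] <- counts[idx[k, 1], idx[k, 2]] + 1L
  }
  if (n_trimmed > 0)
    warning(n_trimmed, " read(s) overhung the reference and were trimmed")
  pileup_matrix(seq_len(L), refv, counts, qmin = qmin)
}

#' Per-position base frequencies from a pileup
#'
#' For every position the frequency of each base is its count divided by the
#' total count of A+C+G+T there. Positions with zero coverage are masked
#' (`NA`), never zero-filled, so downstream window means are over observed
#' positions only.
#'
#' @param pileup A [pileup_matrix()].
#' @return Object of class `frequency_profile`: `positions`, `ref`, `freq`
#'   (matrix, columns A,C,G,T; `NA` rows where masked), `coverage`.
#' @export
position_frequencies <- function(pileup) {
  stopifnot(inherits(pileup, "pileup_matrix"))
  cov <- rowSums(pileup$counts)
  freq <- pileup$counts / ifelse(cov > 0, cov, NA_real_)
  freq[cov == 0, ] <- NA_real_
  structure(list(positions = pileup$positions, ref = pileup$ref,
                 freq = freq, coverage = cov, offset = pileup$offset),
            class = "frequency_profile")
}

#' Construct a frequency profile directly
#'
#' Mainly for synthetic and worked examples where per-position frequencies
#' are already known.
#' @inheritParams pileup_matrix
#' @param freq Matrix of per-base frequencies (rows sum to 1 where covered).
#' @param coverage Per-position total base-call counts.
#' @return A `frequency_profile`.
#' @export
frequency_profile <- function(positions, ref, freq, coverage, offset = 0L) {
  freq <- as.matrix(freq)
  colnames(freq) <- BASES
  structure(list(positions = as.integer(positions),
                 ref = toupper(as.character(ref)), freq = freq,
                 coverage = coverage, offset = as.integer(offset)),
            class = "frequency_profile")
}

#' Shift a profile's coordinates
#'
#' Adds a signed offset to every position — used to put a control strain
#' carrying an insertion/deletion relative to the target strain onto the
#' target's coordinate system before windowed comparison.
#'
#' @param profile A `frequency_profile`.
#' @param offset Signed integer shift (positions become `positions + offset`).
#' @return The shifted profile (offset recorded cumulatively).
#' @export
shift_profile <- function(profile, offset) {
  stopifnot(inherits(profile, "frequency_profile"))
  profile$positions <- profile$positions + as.integer(offset)
  profile$offset <- profile$offset + as.integer(offset)
  profile
}

#' Trimmed unweighted moving average
#'
#' Smooths a per-position numeric signal with the unweighted mean of the up
#' to `2w + 1` positions centred on each position (windows shrink at the
#' edges). Within each window, members deviating from the window mean by more
#' than `k` standard deviations are excluded (single pass) before the mean of
#' the survivors is taken — the 3-sigma rule that keeps isolated extreme
#' positions (e.g. homopolymer artefacts) from dragging the trend. Windows
#' left with fewer than 3 members are masked.
#'
#' @param values Numeric vector (may contain `NA` for masked positions), or a
#'   `frequency_profile` together with `type` naming a substitution whose
#'   per-position frequency is smoothed.
#' @param w Window half-width in positions (default 10).
#' @param k Outlier threshold in standard deviations (default 3).
#' @param type Substitution type (e.g. `"C>T"`) when `values` is a profile;
#'   positions whose reference base differs from the type's reference are
#'   masked.
#' @param scope `"window"` (default) computes the exclusion mean/SD from each
#'   window; `"global"` uses the whole profile's mean/SD.
#' @return Object of class `smoothed_profile`: `trend` (numeric, `NA` where
#'   masked), `w`, `k`, `excluded` (list of excluded indices per position).
#' @export
moving_average <- function(values, w = 10, k = 3, type = NULL,
                           scope = c("window", "global")) {
  scope <- match.arg(scope)
  if (inherits(values, "frequency_profile")) {
    stopifnot(!is.null(type))
    st <- .parse_subst(type)
    x <- ifelse(values$ref == st[["ref"]], values$freq[, st[["alt"]]],
                NA_real_)
  } else x <- as.numeric(values)
  if (w < 1) stop("w must be >= 1")
  if (k <= 0) stop("k must be positive")
  n <- length(x)
  trend <- rep(NA_real_, n)
  excluded <- vector("list", n)
  if (scope == "global") {
    gm <- mean(x, na.rm = TRUE)
    gs <- sd(x, na.rm = TRUE)
  }
  for (i in seq_len(n)) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    idx <- lo:hi
    v <- x[idx]
    ok <- !is.na(v)
    if (sum(ok) < 3L) next
    mu <- if (scope == "window") mean(v[ok]) else gm
    s <- if (scope == "window") sd(v[ok]) else gs
    keep <- ok & (is.na(s) | s == 0 | abs(v - mu) <= k * s)
    excluded[[i]] <- idx[ok & !keep]
    if (sum(keep) < 3L) next
    trend[i] <- mean(v[keep])
  }
  structure(list(trend = trend, w = w, k = k, excluded = excluded),
            class = "smoothed_profile")
}

.window_idx <- function(profile, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  which(profile$positions >= window[1] & profile$positions <= window[2])
}

#' Windowed average substitutions per base (s.p.b.)
#'
#' Mean frequency of the `alt` base over the positions in the (1-based,
#' inclusive) window whose reference base equals the substitution's reference
#' base. Positions with a different reference base, or masked positions, are
#' excluded from both numerator and denominator.
#'
#' @param profile A `frequency_profile`.
#' @param window `c(start, end)` in the profile's coordinates.
#' @param type Substitution type, e.g. `"C>T"`.
#' @return The average s.p.b., or `NA` when the window holds no usable
#'   matching-reference position.
#' @export
mean_spb <- function(profile, window, type) {
  stopifnot(inherits(profile, "frequency_profile"))
  st <- .parse_subst(type)
  idx <- .window_idx(profile, window)
  idx <- idx[profile$ref[idx] == st[["ref"]]]
  if (length(idx) == 0L) return(NA_real_)
  v <- profile$freq[idx, st[["alt"]]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Fold enrichment of substitutions relative to a control
#'
#' For each substitution type, the windowed average s.p.b. of the target
#' profile divided by that of the control profile, after shifting the control
#' onto the target's coordinates (`offset`, default 23 — the length of the
#' insertion distinguishing control from target strains). When paired
#' biological replicate profiles are supplied, the replicate standard
#' deviation of the fold is reported.
#'
#' @param target,control `frequency_profile`s (target numerator).
#' @param window `c(start, end)` in target coordinates.
#' @param offset Signed shift applied to the control (and control replicates)
#'   before windowing.
#' @param types Substitution types to report (default all 12).
#' @param replicates Optional list of `list(target =, control =)` replicate
#'   profile pairs for the SD.
#' @param pseudocount If `TRUE`, undefined ratios (control s.p.b. 0) are made
#'   finite by adding one count to every base of both pileup-backed profiles;
#'   off by default so raw ratios are reported.
#' @return `data.frame` of class `substitution_summary`: `type`,
#'   `target_spb`, `control_spb`, `fold`, `fold_sd`.
#' @export
fold_enrichment <- function(target, control, window, offset = 23L,
                            types = substitution_types(), replicates = NULL,
                            pseudocount = FALSE) {
  stopifnot(inherits(target, "frequency_profile"),
            inherits(control, "frequency_profile"))
  ctrl <- shift_profile(control, offset)
  one <- function(tg, ct, type) {
    ts <- mean_spb(tg, window, type)
    cs <- mean_spb(ct, window, type)
    if (is.na(cs) || cs == 0) {
      if (!pseudocount) return(c(ts, cs, NA_real_))
      # pseudocount path: nudge the zero control mean by one count at the
      # window's typical coverage so the ratio is finite
      cov <- mean(ct$coverage[.window_idx(ct, window)], na.rm = TRUE)
      cs <- if (is.finite(cov) && cov > 0) 1 / cov else NA_real_
      if (is.na(cs)) return(c(ts, 0, NA_real_))
    }
    c(ts, cs, ts / cs)
  }
  base <- t(vapply(types, function(ty) one(target, ctrl, ty), numeric(3)))
  fold_sd <- rep(NA_real_, length(types))
  if (!is.null(replicates) && length(replicates) >= 2) {
    rep_folds <- vapply(replicates, function(pair) {
      ctl <- shift_profile(pair$control, offset)
      vapply(types, function(ty) one(pair$target, ctl, ty)[3], numeric(1))
    }, numeric(length(types)))
    fold_sd <- apply(rep_folds, 1, sd)
  }
  out <- data.frame(type = types, target_spb = base[, 1],
                    control_spb = base[, 2], fold = base[, 3],
                    fold_sd = fold_sd, row.names = NULL)
  class(out) <- c("substitution_summary", "data.frame")
  out
}

#' Background-subtracted substitution fractions
#'
#' Subtracts the control (sequencing-error) windowed average s.p.b. from the
#' target's, per substitution type, clamping at zero, and normalises the
#' corrected values to the fraction of base substitutions attributable to
#' each type.
#'
#' @inheritParams fold_enrichment
#' @param offset Signed shift applied to the control before windowing
#'   (default 0: profiles already on common coordinates).
#' @return `data.frame`: `type`, `target_spb`, `control_spb`, `corrected`,
#'   `fraction` (all-`NA` fractions when every corrected value is zero).
#' @export
background_subtract <- function(target, control, window, offset = 0L,
                                types = substitution_types()) {
  stopifnot(inherits(target, "frequency_profile"),
            inherits(control, "frequency_profile"))
  ctrl <- shift_profile(control, offset)
  ts <- vapply(types, function(ty) mean_spb(target, window, ty), numeric(1))
  cs <- vapply(types, function(ty) mean_spb(ctrl, window, ty), numeric(1))
  corrected <- pmax(0, ifelse(is.na(ts), 0, ts) - ifelse(is.na(cs), 0, cs))
  total <- sum(corrected)
  fraction <- if (total > 0) corrected / total else rep(NA_real_, length(types))
  data.frame(type = types, target_spb = ts, control_spb = cs,
             corrected = corrected, fraction = fraction, row.names = NULL)
}

#' Estimate the mutagenesis onset position
#'
#' Locates where targeted mutagenesis switches on: the first matching-
#' reference position downstream of `tss` whose substitution frequency
#' exceeds half the downstream plateau level (plateau estimated as the mean
#' frequency over the last `plateau_frac` of matching positions). Used to
#' check that mutation initiation tracks the transcription start site.
#'
#' @param profile A `frequency_profile`.
#' @param type Substitution type driving the onset (e.g. `"C>T"`).
#' @param tss 1-based position of the transcription start site.
#' @param plateau_frac Fraction of the downstream profile used to estimate
#'   the plateau (default 0.5).
#' @return List: `onset_position` (1-based), `onset_offset` (nt downstream of
#'   `tss`), `plateau` (estimated plateau frequency); `NA`s when no position
#'   crosses threshold.
#' @export
onset_position <- function(profile, type, tss, plateau_frac = 0.5) {
  stopifnot(inherits(profile, "frequency_profile"))
  st <- .parse_subst(type)
  down <- which(profile$positions > tss & profile$ref == st[["ref"]])
  down <- down[!is.na(profile$freq[down, st[["alt"]]])]
  if (length(down) < 4L)
    return(list(onset_position = NA_integer_, onset_offset = NA_integer_,
                plateau = NA_real_))
  f <- profile$freq[down, st[["alt"]]]
  tail_n <- max(2L, ceiling(length(down) * plateau_frac))
  plateau <- mean(f[(length(f) - tail_n + 1L):length(f)])
  hit <- which(f > plateau / 2)[1]
  if (is.na(hit))
    return(list(onset_position = NA_integer_, onset_offset = NA_integer_,
                plateau = plateau))
  pos <- profile$positions[down[hit]]
  list(onset_position = pos, onset_offset = pos - tss, plateau = plateau)
}
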