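# Barcoded-amplicon enrichment analysis: demultiplexing into wells,
# per-well base distributions, two-criterion significance calling and
# codon-effect annotation.

#' Construct a barcode manifest
#'
#' Maps well labels to their front/back barcode pair. Barcodes must be unique
#' per end and of one length per end.
#'
#' @param well Character vector of well labels.
#' @param front,back Barcode sequences attached to read start/end.
#' @param max_mismatch Maximum Hamming distance tolerated per barcode
#'   (default 1).
#' @return Object of class `barcode_manifest`.
#' @export
barcode_manifest <- function(well, front, back, max_mismatch = 1L) {
  well <- as.character(well); front <- toupper(front); back <- toupper(back)
  stopifnot(length(well) == length(front), length(well) == length(back))
  if (anyDuplicated(well)) stop("well labels must be unique")
  if (anyDuplicated(front) || anyDuplicated(back))
    stop("barcodes must be unique per end")
  if (length(unique(nchar(front))) != 1L ||
      length(unique(nchar(back))) != 1L)
    stop("all barcodes must have the same length per end")
  structure(list(well = well, front = front, back = back,
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_manifest")
}

# Hamming distances between one string and a set of equal-length strings.
.hamming_to_set <- function(s, set) {
  sv <- strsplit(s, "")[[1]]
  vapply(strsplit(set, ""), function(b) sum(b != sv), integer(1))
}

#' Filter and demultiplex barcoded amplicon reads
#'
#' A read survives iff its mean Phred quality is at least `min_quality`, its
#' length lies within `length_range`, and both its front barcode (read
#' prefix) and back barcode (read suffix) match the barcodes of a single
#' well within `max_mismatch`. Reads matching two wells at the same best
#' total distance are discarded as ambiguous. Survivors are returned with
#' barcodes stripped and tagged with their well.
#'
#' @param reads `data.frame(id, seq, qual)` (see [read_fastq()]) or a FASTQ
#'   path.
#' @param manifest A [barcode_manifest()].
#' @param min_quality Minimum mean Phred quality (default 20).
#' @param length_range `c(min, max)` total read length in nt, inclusive.
#' @return `data.frame(id, well, seq, qual, mean_q)` of surviving reads
#'   (insert only, barcodes removed), with attribute `n_dropped` broken down
#'   by reason.
#' @export
filter_reads <- function(reads, manifest, min_quality = 20,
                         length_range = c(0L, .Machine$integer.max)) {
  stopifnot(inherits(manifest, "barcode_manifest"))
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  fl <- nchar(manifest$front[1]); bl <- nchar(manifest$back[1])
  mm <- manifest$max_mismatch
  n <- nrow(reads)
  drop <- c(quality = 0L, length = 0L, barcode = 0L, ambiguous = 0L)
  keep_id <- character(0); keep_well <- character(0)
  keep_seq <- character(0); keep_qual <- character(0); keep_q <- numeric(0)
  for (j in seq_len(n)) {
    s <- toupper(reads$seq[j]); qs <- reads$qual[j]
    len <- nchar(s)
    if (len < length_range[1] || len > length_range[2]) {
      drop["length"] <- drop["length"] + 1L; next
    }
    q <- utf8ToInt(qs) - 33L
    mq <- mean(q)
    if (mq < min_quality) { drop["quality"] <- drop["quality"] + 1L; next }
    if (len < fl + bl + 1L) { drop["length"] <- drop["length"] + 1L; next }
    df <- .hamming_to_set(substr(s, 1L, fl), manifest$front)
    db <- .hamming_to_set(substr(s, len - bl + 1L, len), manifest$back)
    ok <- df <= mm & db <= mm
    if (!any(ok)) { drop["barcode"] <- drop["barcode"] + 1L; next }
    tot <- df + db
    tot[!ok] <- NA
    best <- min(tot, na.rm = TRUE)
    hits <- which(!is.na(tot) & tot == best)
    if (length(hits) != 1L) { drop["ambiguous"] <- drop["ambiguous"] + 1L; next }
    keep_id <- c(keep_id, reads$id[j])
    keep_well <- c(keep_well, manifest$well[hits])
    keep_seq <- c(keep_seq, substr(s, fl + 1L, len - bl))
    keep_qual <- c(keep_qual, substr(qs, fl + 1L, len - bl))
    keep_q <- c(keep_q, mq)
  }
  out <- data.frame(id = keep_id, well = keep_well, seq = keep_seq,
                    qual = keep_qual, mean_q = keep_q, row.names = NULL)
  attr(out, "n_dropped") <- drop
  out
}

#' Trivial gapless aligner
#'
#' Finds, for each read, the 1-based offset in the reference minimising the
#' Hamming mismatch count over all offsets at which the read fits entirely
#' inside the reference. Intended for synthetic amplicons with no indels;
#' real campaigns should supply alignments from a dedicated aligner.
#'
#' @param seqs Character vector of read sequences.
#' @param reference Reference sequence (string/`DNAString`/FASTA path).
#' @return Integer vector of offsets (NA when a read is longer than the
#'   reference).
#' @export
align_gapless <- function(seqs, reference) {
  refstr <- .as_ref_string(reference)
  L <- nchar(refstr)
  refv <- strsplit(refstr, "")[[1]]
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n > L) return(NA_integer_)
    sv <- strsplit(toupper(s), "")[[1]]
    offs <- 1L:(L - n + 1L)
    mm <- vapply(offs, function(o) sum(sv != refv[o:(o + n - 1L)]),
                 integer(1))
    offs[which.min(mm)]
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-well base distributions
#'
#' Tallies, for each well, the distribution of A/C/G/T at every reference
#' position covered by that well's reads (gapless alignment at the supplied
#' per-read offsets). Positions a well never covers ("blanks") are dropped
#' from that well's table rather than zero-filled. Wells with no surviving
#' reads yield an empty entry and are flagged.
#'
#' @param assigned `data.frame(well, seq, ...)` from [filter_reads()].
#' @param reference Gene reference sequence.
#' @param offsets Per-read 1-based alignment offsets; default aligns with
#'   [align_gapless()].
#' @return Object of class `well_mutation_table`: per well a list with
#'   `n_reads`, `counts` (positions x 4), `freq`; plus `reference`,
#'   `empty_wells`.
#' @export
well_distributions <- function(assigned, reference, offsets = NULL) {
  refstr <- .as_ref_string(reference)
  L <- nchar(refstr)
  if (is.null(offsets)) offsets <- align_gapless(assigned$seq, refstr)
  stopifnot(length(offsets) == nrow(assigned))
  wells <- sort(unique(assigned$well))
  tabs <- lapply(wells, function(w) {
    sel <- which(assigned$well == w & !is.na(offsets))
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
    for (j in sel) {
      sv <- strsplit(toupper(assigned$seq[j]), "")[[1]]
      pos <- offsets[j] + seq_along(sv) - 1L
      ok <- sv %in% BASES & pos >= 1L & pos <= L
      for (k in which(ok))
        counts[pos[k], match(sv[k], BASES)] <-
          counts[pos[k], match(sv[k], BASES)] + 1L
    }
    cov <- rowSums(counts)
    keep <- cov > 0L          # blank removal: uncovered columns dropped
    list(n_reads = length(sel),
         positions = which(keep),
         counts = counts[keep, , drop = FALSE],
         freq = counts[keep, , drop = FALSE] / cov[keep])
  })
  names(tabs) <- wells
  empty <- wells[vapply(tabs, function(t) t$n_reads == 0L, logical(1))]
  structure(list(wells = tabs, reference = refstr, empty_wells = empty),
            class = "well_mutation_table")
}

#' @export
print.well_mutation_table <- function(x, ...) {
  cat("Well mutation table:", length(x$wells), "wells,",
      sum(vapply(x$wells, `[[`, integer(1), "n_reads")), "reads,",
      "reference length", nchar(x$reference), "\n")
  if (length(x$empty_wells))
    cat("  empty wells:", paste(x$empty_wells, collapse = " "), "\n")
  invisible(x)
}

#' Call significant mutations across wells
#'
#' A (position, alternative base) pair is called significant iff its global
#' frequency over all pooled filtered reads is at least `f_global`, OR it is
#' present — within-well frequency at least `presence_floor` — in at least
#' `n_wells` wells. Both thresholds are inclusive. Calls are returned sorted
#' by global frequency, descending, and annotated with codon effects when a
#' coding sequence is supplied.
#'
#' @param tables A [well_distributions()] result.
#' @param f_global Global-frequency criterion (default 0.10).
#' @param n_wells Replicate-count criterion (default 4).
#' @param presence_floor Within-well frequency defining "present" for the
#'   replicate criterion (default 0.10; not printed in the source protocol,
#'   chosen symmetric with the global criterion — adjust to taste).
#' @param cds Optional coding sequence for annotation (string/FASTA path).
#' @param frame_offset 0-based offset of the first codon within the
#'   reference.
#' @return `data.frame`: `pos`, `ref`, `alt`, `global_freq`, `n_wells`,
#'   `codon`, `aa_change` (NA columns when `cds` is absent).
#' @export
call_significant <- function(tables, f_global = 0.10, n_wells = 4L,
                             presence_floor = 0.10, cds = NULL,
                             frame_offset = 0L) {
  stopifnot(inherits(tables, "well_mutation_table"))
  L <- nchar(tables$reference)
  refv <- strsplit(tables$reference, "")[[1]]
  pooled <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  present <- array(0L, dim = c(L, 4))
  for (t in tables$wells) {
    if (t$n_reads == 0L) next
    pooled[t$positions, ] <- pooled[t$positions, ] + t$counts
    hit <- t$freq >= presence_floor
    present[t$positions, ] <- present[t$positions, ] + hit
  }
  cov <- rowSums(pooled)
  rows <- list()
  for (i in which(cov > 0)) {
    for (b in seq_len(4)) {
      if (BASES[b] == refv[i]) next
      gf <- pooled[i, b] / cov[i]
      nw <- present[i, b]
      if (gf >= f_global || nw >= n_wells) {
        rows[[length(rows) + 1L]] <-
          data.frame(pos = i, ref = refv[i], alt = BASES[b],
                     global_freq = gf, n_wells = nw)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      global_freq = numeric(), n_wells = integer(),
                      codon = integer(), aa_change = character()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$global_freq, out$pos), , drop = FALSE]
  if (!is.null(cds)) {
    ann <- lapply(seq_len(nrow(out)), function(k)
      annotate_codon(out$pos[k], out$alt[k], cds, frame_offset))
    out$codon <- vapply(ann, function(a) a$codon, integer(1))
    out$aa_change <- vapply(ann, function(a) a$label, character(1))
  } else {
    out$codon <- NA_integer_
    out$aa_change <- NA_character_
  }
  rownames(out) <- NULL
  out
}

#' Annotate the codon-level effect of a point substitution
#'
#' Translates the affected codon before and after the substitution with the
#' standard genetic code and returns a label of the form `D54N` (missense),
#' `Q237*` (nonsense), `L10L` tagged silent, or a noncoding tag for
#' positions outside the coding frame.
#'
#' @param pos 1-based position in the reference/CDS coordinates.
#' @param alt Substituted base.
#' @param cds Coding sequence (string/`DNAString`/FASTA path); length after
#'   `frame_offset` must be a multiple of 3.
#' @param frame_offset 0-based offset of the first codon within the sequence.
#' @return List: `codon` (number, NA if noncoding), `ref_aa`, `alt_aa`,
#'   `label`, `effect` (`"missense"`, `"nonsense"`, `"silent"`,
#'   `"noncoding"`).
#' @export
annotate_codon <- function(pos, alt, cds, frame_offset = 0L) {
  cdsstr <- .as_ref_string(cds)
  alt <- toupper(alt)
  cpos <- pos - frame_offset
  n_cod <- (nchar(cdsstr) - frame_offset) %/% 3L
  if (cpos < 1L || cpos > 3L * n_cod)
    return(list(codon = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, label = "noncoding",
                effect = "noncoding"))
  codon_no <- (cpos - 1L) %/% 3L + 1L
  within <- (cpos - 1L) %% 3L + 1L
  start <- frame_offset + (codon_no - 1L) * 3L + 1L
  codon <- substr(cdsstr, start, start + 2L)
  mutated <- codon
  substr(mutated, within, within) <- alt
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), no.init.codon = TRUE))
  ref_aa <- tr(codon); alt_aa <- tr(mutated)
  effect <- if (identical(ref_aa, alt_aa)) "silent"
            else if (alt_aa == "*") "nonsense" else "missense"
  label <- if (effect == "silent")
    paste0(ref_aa, codon_no, ref_aa, " (silent)")
  else paste0(ref_aa, codon_no, alt_aa)
  list(codon = codon_no, ref_aa = ref_aa, alt_aa = alt_aa, label = label,
       effect = effect)
}
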