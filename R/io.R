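# Shared plain-text format readers/writers: colony-count files, minimal SAM,
# pileup tables, FASTQ, barcode manifests, OD tables, JSON reports.

#' Read a fluctuation-assay counts file
#'
#' One integer per line (mutant colonies per culture); an optional leading
#' comment of the form `# label, N_t, plating_fraction` carries metadata.
#'
#' @param path File path.
#' @param n_final,plating_fraction Used when the header is absent.
#' @return A [fluctuation_experiment()].
#' @export
read_counts_file <- function(path, n_final = NULL, plating_fraction = 1) {
  lines <- readLines(path)
  label <- ""
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) > 0) {
    parts <- trimws(strsplit(sub("^#\\s*", "", hdr[1]), ",")[[1]])
    if (length(parts) >= 1) label <- parts[1]
    if (length(parts) >= 2) n_final <- as.numeric(parts[2])
    if (length(parts) >= 3) plating_fraction <- as.numeric(parts[3])
  }
  body <- trimws(lines[!grepl("^#", lines)])
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("counts file is empty: ", path)
  counts <- suppressWarnings(as.numeric(body))
  if (anyNA(counts)) stop("non-numeric line in counts file: ", path)
  if (is.null(n_final))
    stop("n_final not given and no header present in ", path)
  fluctuation_experiment(counts, n_final = n_final,
                         plating_fraction = plating_fraction, label = label)
}

#' Write a fluctuation-assay counts file
#' @param experiment A [fluctuation_experiment()].
#' @param path Output path.
#' @export
write_counts_file <- function(experiment, path) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  writeLines(c(sprintf("# %s, %.10g, %.10g", experiment$label,
                       experiment$n_final, experiment$plating_fraction),
               format(experiment$counts, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read a minimal SAM file
#'
#' Accepts coordinate-sorted SAM whose alignments use only `M` CIGAR
#' operations; any read with other operations (indels, clips) is rejected,
#' and the rejections reported in one warning. Header lines are skipped.
#'
#' @param path SAM file path.
#' @return `data.frame(qname, pos, seq, qual)` of accepted reads.
#' @export
read_minimal_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(qname = character(), pos = integer(),
                      seq = character(), qual = character()))
  f <- strsplit(lines, "\t")
  bad <- 0L
  rows <- lapply(f, function(x) {
    if (length(x) < 11L) { bad <<- bad + 1L; return(NULL) }
    cigar <- x[6]
    if (!grepl("^([0-9]+M)+$", cigar)) { bad <<- bad + 1L; return(NULL) }
    width <- sum(as.integer(regmatches(cigar,
                                       gregexpr("[0-9]+", cigar))[[1]]))
    if (width != nchar(x[10])) { bad <<- bad + 1L; return(NULL) }
    data.frame(qname = x[1], pos = as.integer(x[4]), seq = x[10],
               qual = x[11])
  })
  if (bad > 0)
    warning(bad, " read(s) rejected (non-M CIGAR or malformed record)")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(qname = character(), pos = integer(),
                      seq = character(), qual = character())
  out
}

#' Write gaplessly aligned reads as minimal SAM
#' @param reads `data.frame(qname, pos, seq, qual)`.
#' @param path Output path.
#' @param ref_name,ref_length Reference name/length for the `@SQ` header.
#' @export
write_minimal_sam <- function(reads, path, ref_name = "ref",
                              ref_length = NULL) {
  if (is.null(ref_length))
    ref_length <- max(reads$pos + nchar(reads$seq) - 1L, 0L)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_length)))
  body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, ref_name, as.integer(reads$pos),
                  nchar(reads$seq), reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pileup table
#'
#' Tab-separated with header `pos ref nA nC nG nT`, 1-based positions, one
#' row per covered position.
#'
#' @param path File path.
#' @param qmin,offset Metadata recorded on the result.
#' @return A [pileup_matrix()].
#' @export
read_pileup_table <- function(path, qmin = NA_real_, offset = 0L) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "integer",
                                   "integer", "integer", "integer"))
  stopifnot(identical(names(tab), c("pos", "ref", "nA", "nC", "nG", "nT")))
  pileup_matrix(tab$pos, tab$ref,
                as.matrix(tab[, c("nA", "nC", "nG", "nT")]),
                qmin = qmin, offset = offset)
}

#' Write a pileup table
#' @param pileup A [pileup_matrix()].
#' @param path Output path.
#' @export
write_pileup_table <- function(pileup, path) {
  stopifnot(inherits(pileup, "pileup_matrix"))
  tab <- data.frame(pos = pileup$positions, ref = pileup$ref,
                    nA = pileup$counts[, "A"], nC = pileup$counts[, "C"],
                    nG = pileup$counts[, "G"], nT = pileup$counts[, "T"])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTQ records (Phred+33)
#'
#' @param path FASTQ path.
#' @return `data.frame(id, seq, qual)` with quality strings.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(id = names(set), seq = as.character(set),
             qual = as.character(S4Vectors::mcols(set)$qualities),
             row.names = NULL)
}

#' Write FASTQ records (Phred+33)
#' @param reads `data.frame(id, seq, qual)`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a barcode manifest
#'
#' Tab-separated `well front back` (no header required; one is tolerated).
#' @param path File path.
#' @return A [barcode_manifest()].
#' @export
read_barcode_manifest <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("well", "front", "back"),
                    colClasses = "character")
  if (tab$well[1] == "well") tab <- tab[-1, , drop = FALSE]
  barcode_manifest(tab$well, tab$front, tab$back)
}

#' Write a barcode manifest
#' @param manifest A [barcode_manifest()].
#' @param path Output path.
#' @export
write_barcode_manifest <- function(manifest, path) {
  write.table(data.frame(manifest$well, manifest$front, manifest$back),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an OD600 time-course table
#'
#' Tab-separated with header `time_h od replicate`.
#' @param path File path.
#' @return `data.frame(time_h, od, replicate)`.
#' @export
read_od_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_h", "od", "replicate") %in% names(tab)))
  tab
}

#' Write an OD600 time-course table
#' @param od `data.frame(time_h, od, replicate)`.
#' @param path Output path.
#' @export
write_od_table <- function(od, path) {
  write.table(od[, c("time_h", "od", "replicate")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structured JSON report
#'
#' Every report embeds the payload together with the effective configuration
#' and seed, so deterministic stages can be replayed bit for bit.
#'
#' @param payload Named list of results.
#' @param path Output path.
#' @param config Named list of effective parameters (echoed verbatim).
#' @param seed Integer seed used for any randomness (or `NA`).
#' @return The path, invisibly.
#' @export
write_report <- function(payload, path, config = list(), seed = NA) {
  report <- list(config = config, seed = seed, results = payload)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
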