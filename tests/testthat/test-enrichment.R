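manifest3 <- barcode_manifest(c("w1", "w2", "w3"),
                              front = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                              back = c("TTTTTTTT", "AAAATTTT", "CCCCGGGG"))

read_of <- function(front, insert, back, q = 40L) {
  s <- paste0(front, insert, back)
  data.frame(id = "r", seq = s,
             qual = strrep(intToUtf8(q + 33L), nchar(s)))
}

test_that("demultiplexing assigns exact and near-exact barcodes, drops the rest", {
  ins <- "ACGTACGTAC"
  # exact front+back of w2
  out <- filter_reads(read_of("CCCCCCCC", ins, "AAAATTTT"), manifest3)
  expect_equal(out$well, "w2")
  expect_equal(out$seq, ins)           # barcodes stripped
  # one mismatch in the front barcode: still assigned at max_mismatch = 1
  out1 <- filter_reads(read_of("CCCCCCCA", ins, "AAAATTTT"), manifest3)
  expect_equal(out1$well, "w2")
  # two mismatches (max_mismatch + 1): discarded
  out2 <- filter_reads(read_of("CCCCCCTA", ins, "AAAATTTT"), manifest3)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_dropped")[["barcode"]], 1L)
  # ambiguous: front/back pair at equal best distance to two wells
  amb <- barcode_manifest(c("a", "b"), c("AAAA", "AATT"), c("GGGG", "GGCC"))
  outa <- filter_reads(read_of("AATA", ins, "GGGC"), amb)
  expect_equal(nrow(outa), 0L)
  expect_equal(attr(outa, "n_dropped")[["ambiguous"]], 1L)
})

test_that("quality and length filters act before demultiplexing", {
  ins <- "ACGTACGTAC"
  low_q <- filter_reads(read_of("AAAAAAAA", ins, "TTTTTTTT", q = 15L),
                        manifest3, min_quality = 20)
  expect_equal(nrow(low_q), 0L)
  expect_equal(attr(low_q, "n_dropped")[["quality"]], 1L)
  short <- filter_reads(read_of("AAAAAAAA", ins, "TTTTTTTT"),
                        manifest3, length_range = c(100, 200))
  expect_equal(attr(short, "n_dropped")[["length"]], 1L)
})

test_that("demultiplexing reproduces the generator's well labels on a campaign", {
  gene <- synthetic_cds(40, seed = 2)
  camp <- simulate_amplicon_campaign(gene, n_wells = 12, reads_per_well = 10,
                                     driver = pick_driver(gene, 60L),
                                     seed = 31)
  filt <- filter_reads(camp$reads, camp$manifest)
  expect_equal(nrow(filt), nrow(camp$reads))
  truth_well <- sub("_read.*$", "", filt$id)   # generator encodes the well
  expect_identical(filt$well, truth_well)
  # order independence
  perm <- camp$reads[rev(seq_len(nrow(camp$reads))), ]
  filt2 <- filter_reads(perm, camp$manifest)
  expect_identical(sort(filt2$id), sort(filt$id))
})

test_that("well distributions match planted within-well frequencies", {
  ref <- strrep("ACGT", 50)
  # 10 wild-type reads: distribution equals the reference everywhere
  wt <- wells_from_seqs(list(w1 = rep(ref, 10)), ref)
  expect_equal(wt$wells$w1$n_reads, 10L)
  refv <- strsplit(ref, "")[[1]]
  for (i in c(1, 77, 200))
    expect_equal(unname(wt$wells$w1$freq[i, refv[i]]), 1)
  # 6/10 reads with T>A at position 160
  mut <- mutate_seq(ref, 160, "A")
  mx <- wells_from_seqs(list(w1 = c(rep(mut, 6), rep(ref, 4))), ref)
  expect_equal(unname(mx$wells$w1$freq[160, "A"]), 0.6)
  expect_equal(unname(mx$wells$w1$freq[160, refv[160]]), 0.4)
})

test_that("significance calling applies the two-criterion rule inclusively", {
  ref <- strrep("ACGT", 25)
  mut <- mutate_seq(ref, 50, "A")   # C>A at position 50
  # 100 wells x 10 reads; mutant at within-well frequency 0.5 in k wells
  # -> global frequency k * 5 / 1000
  build <- function(k) {
    wells <- setNames(replicate(100, rep(ref, 10), simplify = FALSE),
                      sprintf("w%03d", 1:100))
    for (w in seq_len(k)) wells[[w]] <- c(rep(mut, 5), rep(ref, 5))
    wells_from_seqs(wells, ref)
  }
  # 4 wells at 2% global: called through the replicate criterion
  calls4 <- call_significant(build(4))
  expect_equal(nrow(calls4), 1L)
  expect_equal(calls4$pos, 50)
  expect_equal(calls4$n_wells, 4L)
  expect_equal(calls4$global_freq, 0.02)
  # 3 wells at 1.5% global: below both criteria
  expect_equal(nrow(call_significant(build(3))), 0L)
  # raising the thresholds never adds calls (monotonicity)
  expect_equal(nrow(call_significant(build(4), n_wells = 5L)), 0L)
})

test_that("the global-frequency criterion flips exactly at 10%", {
  ref <- strrep("ACGT", 25)
  mut <- mutate_seq(ref, 50, "A")
  build_global <- function(n_mut) {
    wells <- list(w1 = c(rep(mut, n_mut), rep(ref, 1000 - n_mut)),
                  w2 = rep(ref, 1000), w3 = rep(ref, 1000))
    wells_from_seqs(wells, ref)
  }
  # 300/3000 = 10.0%, present in 1 well only: called via global criterion
  calls <- call_significant(build_global(300))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_wells, 1L)
  # 297/3000 = 9.9%: not called
  expect_equal(nrow(call_significant(build_global(297))), 0L)
})

test_that("codon annotation translates substitutions with the standard code", {
  # CDS with codon 54 = GAT (Asp) and codon 77 = CAA (Gln)
  base <- synthetic_cds(100, seed = 8)
  cds <- base
  substr(cds, 160, 162) <- "GAT"
  substr(cds, 229, 231) <- "CAA"
  # G>A at codon-54 position 1: GAT -> AAT, Asp -> Asn
  ann <- annotate_codon(160, "A", cds)
  expect_equal(ann$label, "D54N")
  expect_equal(ann$effect, "missense")
  # C>T at codon-77 position 1: CAA -> TAA, premature stop
  ann2 <- annotate_codon(229, "T", cds)
  expect_equal(ann2$label, "Q77*")
  expect_equal(ann2$effect, "nonsense")
  # substitution reproducing the reference residue is tagged silent
  # (GAT -> GAC both encode Asp)
  ann3 <- annotate_codon(162, "C", cds)
  expect_equal(ann3$effect, "silent")
  # outside the coding frame
  expect_equal(annotate_codon(10, "A", cds, frame_offset = 297)$effect,
               "noncoding")
})

test_that("codon annotation round-trips through re-translation", {
  cds <- synthetic_cds(60, seed = 13)
  set.seed(13)
  for (k in 1:20) {
    pos <- sample(4:(nchar(cds) - 3), 1)   # avoid start/stop codons
    refb <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    ann <- annotate_codon(pos, alt, cds)
    mutated <- mutate_seq(cds, pos, alt)
    aa_new <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mutated, (ann$codon - 1) * 3 + 1,
                                   ann$codon * 3)), no.init.codon = TRUE))
    expect_equal(ann$alt_aa, aa_new)
  }
})
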