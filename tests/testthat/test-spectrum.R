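test_that("pileup tallies quality-filtered calls at the right positions", {
  # one read ACGT, all Q40 (chr 'I'): identity diagonal, coverage 1
  reads <- data.frame(pos = 1L, seq = "ACGT", qual = "IIII")
  pu <- build_pileup(reads, "ACGT", qmin = 35)
  expect_equal(unname(diag(pu$counts)), rep(1L, 4))
  expect_equal(sum(pu$counts), 4L)
  # Q = 40,30,40,40: position 2 dropped by the Q<35 filter
  reads2 <- data.frame(pos = 1L, seq = "ACGT", qual = "I?II")  # '?' = Q30
  pu2 <- build_pileup(reads2, "ACGT", qmin = 35)
  expect_equal(sum(pu2$counts[2, ]), 0L)
  expect_equal(sum(pu2$counts), 3L)
})

test_that("pileup construction is read-order invariant and trims overhangs", {
  set.seed(5)
  reads <- data.frame(pos = sample(1:5, 20, replace = TRUE),
                      seq = "ACGT", qual = "IIII")
  ref <- "ACGTACGT"
  a <- build_pileup(reads, ref, qmin = 35)
  b <- build_pileup(reads[sample(nrow(reads)), ], ref, qmin = 35)
  expect_identical(a$counts, b$counts)
  # read overhanging the reference end is trimmed with a warning
  expect_warning(pu <- build_pileup(
    data.frame(pos = 7L, seq = "ACGT", qual = "IIII"), ref, qmin = 35),
    "trimmed")
  expect_equal(sum(pu$counts), 2L)
})

test_that("per-position frequencies normalise and mask zero coverage", {
  counts <- rbind(c(90, 0, 0, 10), c(0, 0, 0, 0), c(25, 25, 25, 25))
  pu <- pileup_matrix(1:3, c("A", "C", "G"), counts)
  fp <- position_frequencies(pu)
  expect_equal(unname(fp$freq[1, ]), c(0.9, 0, 0, 0.1))
  expect_true(all(is.na(fp$freq[2, ])))       # masked, not zero-filled
  expect_equal(unname(fp$freq[3, ]), rep(0.25, 4))
  covered <- rowSums(fp$freq)
  expect_equal(covered[c(1, 3)], c(1, 1))
})

test_that("trimmed moving average keeps constants, drops outliers, tracks ramps", {
  expect_equal(moving_average(rep(0.3, 50))$trend, rep(0.3, 50))
  # one extreme outlier in an otherwise noisy-flat profile is excluded
  set.seed(1)
  x <- rnorm(80, 1e-3, 1e-5)
  x_out <- x; x_out[40] <- 0.5
  sm <- moving_average(x_out, w = 10, k = 3)
  sm_clean <- moving_average(x, w = 10, k = 3)
  expect_equal(sm$trend[-(30:50)], sm_clean$trend[-(30:50)], tolerance = 1e-9)
  expect_true(all(abs(sm$trend - 1e-3) < 1e-4))
  expect_true(40 %in% unlist(sm$excluded))
  # interior of a linear ramp equals the symmetric window mean = the ramp
  ramp <- seq(0, 1, length.out = 101)
  smr <- moving_average(ramp, w = 10, k = 10)  # large k: no exclusion
  expect_equal(smr$trend[11:91], ramp[11:91])
  # windows left with < 3 members are masked
  short <- moving_average(c(1, 2), w = 1, k = 3)
  expect_true(all(is.na(short$trend)))
})

test_that("windowed average s.p.b. uses only matching-reference positions", {
  prof <- toy_profile("CTAGC", alt_freq = list(
    `1` = list(T = 0.001), `5` = list(T = 0.003), `3` = list(T = 0.2)))
  expect_equal(mean_spb(prof, c(1, 5), "C>T"), 0.002)
  # window without any matching-ref position is undefined
  expect_true(is.na(mean_spb(prof, c(2, 2), "C>T")))
  # non-C positions do not dilute the mean
  expect_equal(mean_spb(prof, c(1, 5), "A>T"), 0.2)
})

test_that("fold enrichment is 1 against itself and divides windowed s.p.b.", {
  prof <- toy_profile(strrep("CAGT", 25), alt_freq = list(
    `1` = list(T = 2e-3), `5` = list(T = 2e-3), `9` = list(T = 2e-3)))
  fe_self <- fold_enrichment(prof, prof, c(1, 100), offset = 0)
  expect_true(all(fe_self$fold[!is.na(fe_self$fold)] == 1))
  ctrl <- toy_profile(strrep("CAGT", 25), alt_freq = list(
    `1` = list(T = 1e-5), `5` = list(T = 1e-5), `9` = list(T = 1e-5),
    `13` = list(T = 1e-5)))
  # target C>T mean over 25 C positions: 3 * 2e-3 / 25; control 4 * 1e-5 / 25
  fe <- fold_enrichment(prof, ctrl, c(1, 100), offset = 0)
  expect_equal(fe$fold[fe$type == "C>T"], (6e-3 / 25) / (4e-5 / 25))
  # control with zero C>T mass: undefined ratio unless pseudocount enabled
  ctrl0 <- toy_profile(strrep("CAGT", 25))
  fe0 <- fold_enrichment(prof, ctrl0, c(1, 100), offset = 0)
  expect_true(is.na(fe0$fold[fe0$type == "C>T"]))
  fe0p <- fold_enrichment(prof, ctrl0, c(1, 100), offset = 0,
                          pseudocount = TRUE)
  expect_true(is.finite(fe0p$fold[fe0p$type == "C>T"]))
})

test_that("the control offset shifts coordinates before windowing", {
  # control carries the same signal 23 positions earlier: after the +23
  # shift the windows line up and the fold is 1
  ref <- strrep("C", 150)
  tgt <- toy_profile(ref, alt_freq = list(`100` = list(T = 1e-3)))
  ctl <- toy_profile(ref, alt_freq = list(`77` = list(T = 1e-3)))
  fe <- fold_enrichment(tgt, ctl, c(100, 100), offset = 23)
  expect_equal(fe$fold[fe$type == "C>T"], 1)
})

test_that("background subtraction clamps at zero and renormalises", {
  ref <- strrep("ACGT", 30)
  tgt <- toy_profile(ref, alt_freq = list(
    `2` = list(T = 3e-4), `3` = list(A = 1e-4),
    `1` = list(G = 1e-4), `4` = list(C = 1e-4)))
  ctl <- toy_profile(ref)
  bs <- background_subtract(tgt, ctl, c(1, 4))
  got <- setNames(bs$fraction, bs$type)
  expect_equal(unname(got[c("C>T", "G>A", "A>G", "T>C")]),
               c(0.5, 1 / 6, 1 / 6, 1 / 6))
  # target == control: all corrected zero, fractions undefined
  bs0 <- background_subtract(tgt, tgt, c(1, 4))
  expect_true(all(bs0$corrected == 0))
  expect_true(all(is.na(bs0$fraction)))
})

test_that("replicate standard deviation is computed across profile pairs", {
  ref <- strrep("C", 20)
  mk <- function(f) toy_profile(ref, alt_freq = list(`10` = list(T = f)))
  reps <- list(list(target = mk(2e-3), control = mk(1e-3)),
               list(target = mk(4e-3), control = mk(1e-3)))
  fe <- fold_enrichment(mk(3e-3), mk(1e-3), c(1, 20), offset = 0,
                        replicates = reps)
  expect_equal(fe$fold_sd[fe$type == "C>T"], sd(c(2, 4)))
})
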