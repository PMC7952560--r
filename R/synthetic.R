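# Seeded synthetic-data generators with ground-truth bookkeeping. Every
# generator emulates the statistical structure the analysis modules assume,
# emitting exactly the inputs those modules consume plus a truth record.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a Luria-Delbrück fluctuation experiment
#'
#' Grows `n_cultures` parallel cultures from `n0` to `n_final` cells with
#' per-division mutation rate `mu`, lets each mutation found a clone, and
#' plates a fraction `plating_fraction` of each culture (binomial thinning of
#' mutant cells). The expected number of mutations per culture is
#' `m = mu * (n_final - n0)`.
#'
#' Two clone-size laws are available. The default, `"lea_coulson"`, draws
#' each clone's final size from the continuous-growth Luria-Delbrück law
#' `P(size >= j) = 1/j` (truncated at `n_final`) — the model underlying the
#' Ma-Sandri-Sarkar probability recursion, so simulated counts match
#' [ld_pmf()] arbitrarily well. `"synchronous"` uses deterministic
#' power-of-two clone sizes from synchronised doublings; its counts are
#' dyadically discretised and deviate from the MSS pmf by a total-variation
#' distance of about 0.01 at m = 2 (see the methods vignette).
#'
#' @param mu Per-division mutation rate.
#' @param n_final Final cells per culture (N_t).
#' @param n_cultures Number of parallel cultures.
#' @param n0 Initial cells per culture (default 1).
#' @param plating_fraction Fraction of each culture plated (default 1).
#' @param growth_model `"lea_coulson"` (default) or `"synchronous"`.
#' @param seed Integer seed (generators are bit-reproducible given a seed).
#' @param label Experiment label.
#' @return List: `experiment` (a [fluctuation_experiment()]) and `truth`
#'   (`mu`, `m`, the model and config).
#' @export
simulate_fluctuation <- function(mu, n_final, n_cultures, n0 = 1,
                                 plating_fraction = 1,
                                 growth_model = c("lea_coulson",
                                                  "synchronous"),
                                 seed = NULL, label = "simulated") {
  growth_model <- match.arg(growth_model)
  stopifnot(mu >= 0, mu <= 1, n_final >= n0, n0 >= 1, n_cultures >= 1,
            plating_fraction > 0, plating_fraction <= 1)
  m <- mu * (n_final - n0)
  .with_seed(seed, {
    mutants <- numeric(n_cultures)
    if (m > 0) {
      if (growth_model == "lea_coulson") {
        n_mut <- rpois(n_cultures, m)
        total <- sum(n_mut)
        if (total > 0) {
          sizes <- pmin(floor(1 / runif(total)), n_final)
          culture <- rep.int(seq_len(n_cultures), n_mut)
          agg <- rowsum(sizes, culture)
          mutants[as.integer(rownames(agg))] <- agg[, 1]
        }
      } else {
        g <- max(1L, round(log2(n_final / n0)))
        lambda <- m * 2^(seq_len(g) - 1) / (2^g - 1)  # sums to m exactly
        for (k in seq_len(g))
          mutants <- mutants + rpois(n_cultures, lambda[k]) * 2^(g - k)
      }
    }
    counts <- if (plating_fraction < 1)
      rbinom(n_cultures, size = pmin(mutants, .Machine$integer.max),
             prob = plating_fraction)
    else mutants
    list(experiment = fluctuation_experiment(counts, n_final = n_final,
                                             plating_fraction =
                                               plating_fraction,
                                             label = label),
         truth = list(mu = mu, m = m, n0 = n0, growth_model = growth_model,
                      seed = seed))
  })
}

#' Random DNA reference with guaranteed cytosines at the mutagenesis onset
#'
#' Generates a random reference of the given GC content and ensures a C at
#' the drawn onset position downstream of the transcription start site, so
#' the first mutated position is informative about the onset.
#'
#' @param length Reference length (nt).
#' @param gc GC fraction (default 0.4).
#' @param tss 1-based transcription start position (optional; when given
#'   together with `onset_offset` a C is forced at `tss + onset_offset`).
#' @param onset_offset Offset of the forced cytosine downstream of `tss`.
#' @param seed Integer seed.
#' @return Character reference sequence.
#' @export
random_reference <- function(length, gc = 0.4, tss = NULL,
                             onset_offset = NULL, seed = NULL) {
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    v <- sample(names(p), length, replace = TRUE, prob = p)
    if (!is.null(tss) && !is.null(onset_offset))
      v[tss + onset_offset] <- "C"
    paste(v, collapse = "")
  })
}

#' Configuration for the positional mutagenesis simulator
#'
#' Describes the positional substitution structure of promoter-targeted
#' deaminase mutagenesis: a C>T plateau switching on a few nucleotides
#' downstream of the transcription start site, a G>A component decaying
#' exponentially with distance from the promoter, minority A>G / T>C
#' plateaus, uniform sequencing error, and a two-point Phred quality mixture
#' around the filtering threshold.
#'
#' @param ref_length Reference length when `reference` is not supplied.
#' @param reference Optional reference sequence (string).
#' @param tss 1-based transcription start position.
#' @param onset_range Onset offset is drawn uniformly from this inclusive
#'   range of nucleotides downstream of the TSS (default 9:12).
#' @param rate_ct,rate_ag,rate_tc Plateau substitution rates (s.p.b.)
#'   downstream of the onset (defaults 1e-3, 1e-4, 1e-4).
#' @param rate_ga_init Initial G>A rate at the TSS (default 5e-4).
#' @param ga_decay_length Exponential decay length of the G>A component in nt
#'   (default 300).
#' @param error_rate Uniform per-base sequencing error rate (default 1e-4;
#'   spread evenly over the three alternative bases).
#' @param subq_fraction Fraction of base calls drawn below the quality
#'   threshold (default 0.05).
#' @param q_high,q_low The two Phred values of the quality mixture
#'   (default 40 / 30, straddling the Q35 filter).
#' @param coverage Reads (base calls) per position (default 1e5).
#' @param seed Integer seed.
#' @return A `mutagenesis_profile_config` list.
#' @export
mutagenesis_profile_config <- function(ref_length = 300L, reference = NULL,
                                       tss = 50L, onset_range = c(9L, 12L),
                                       rate_ct = 1e-3, rate_ag = 1e-4,
                                       rate_tc = 1e-4, rate_ga_init = 5e-4,
                                       ga_decay_length = 300,
                                       error_rate = 1e-4,
                                       subq_fraction = 0.05,
                                       q_high = 40L, q_low = 30L,
                                       coverage = 1e5, seed = NULL) {
  rates <- c(rate_ct, rate_ag, rate_tc, rate_ga_init, error_rate,
             subq_fraction)
  stopifnot(all(rates >= 0), all(rates <= 1), coverage > 0,
            onset_range[1] <= onset_range[2])
  len <- if (is.null(reference)) ref_length else nchar(reference)
  if (tss + onset_range[2] > len)
    stop("onset range must lie within the reference ",
         "(tss + onset exceeds its length)")
  cfg <- list(ref_length = as.integer(ref_length), reference = reference,
              tss = as.integer(tss), onset_range = as.integer(onset_range),
              rate_ct = rate_ct, rate_ag = rate_ag, rate_tc = rate_tc,
              rate_ga_init = rate_ga_init,
              ga_decay_length = ga_decay_length, error_rate = error_rate,
              subq_fraction = subq_fraction, q_high = as.integer(q_high),
              q_low = as.integer(q_low), coverage = coverage, seed = seed)
  class(cfg) <- "mutagenesis_profile_config"
  cfg
}

# Per-position true substitution rate and alt base under a config.
.positional_rates <- function(cfg, refv, onset_offset, mutagenesis = TRUE) {
  L <- length(refv)
  rate <- numeric(L)
  alt <- rep(NA_character_, L)
  if (!mutagenesis) return(list(rate = rate, alt = alt))
  onset_pos <- cfg$tss + onset_offset
  for (i in seq_len(L)) {
    b <- refv[i]
    if (b == "C" && i >= onset_pos) { rate[i] <- cfg$rate_ct; alt[i] <- "T" }
    else if (b == "G" && i > cfg$tss) {
      rate[i] <- cfg$rate_ga_init *
        exp(-(i - cfg$tss) / cfg$ga_decay_length)
      alt[i] <- "A"
    }
    else if (b == "A" && i >= onset_pos) { rate[i] <- cfg$rate_ag; alt[i] <- "G" }
    else if (b == "T" && i >= onset_pos) { rate[i] <- cfg$rate_tc; alt[i] <- "C" }
  }
  list(rate = rate, alt = alt)
}

#' Simulate a targeted deep-sequencing pileup (or reads)
#'
#' Draws, for every position and read, the true base from the positional
#' substitution profile, applies uniform sequencing error across the three
#' alternative bases, then applies the two-point quality mixture (calls that
#' land below the threshold are the ones a Q-filter would drop). The truth
#' record stores pre-error substitution counts per position.
#'
#' With `output = "counts"` (default) per-position multinomial counts are
#' drawn directly at the configured coverage and a quality-filtered
#' [pileup_matrix()] is returned (sub-threshold calls thinned out). With
#' `output = "reads"` full-length reads with per-base quality strings are
#' emitted (use modest coverage), suitable for [build_pileup()] or
#' [write_minimal_sam()].
#'
#' @param cfg A [mutagenesis_profile_config()].
#' @param mutagenesis If `FALSE`, only sequencing error is simulated (a
#'   control/background strain).
#' @param output `"counts"` or `"reads"`.
#' @return List: `pileup` (counts mode) or `reads` (`data.frame(pos, seq,
#'   qual)`, reads mode), `reference`, and `truth` (onset offset/position,
#'   per-position pre-error substitution counts, config).
#' @export
simulate_pileup <- function(cfg, mutagenesis = TRUE,
                            output = c("counts", "reads")) {
  output <- match.arg(output)
  stopifnot(inherits(cfg, "mutagenesis_profile_config"))
  .with_seed(cfg$seed, {
    onset_offset <- if (cfg$onset_range[1] == cfg$onset_range[2])
      cfg$onset_range[1]
    else sample(cfg$onset_range[1]:cfg$onset_range[2], 1L)
    refstr <- cfg$reference
    if (is.null(refstr))
      refstr <- random_reference(cfg$ref_length, tss = cfg$tss,
                                 onset_offset = onset_offset)
    refv <- strsplit(refstr, "")[[1]]
    L <- length(refv)
    pr <- .positional_rates(cfg, refv, onset_offset, mutagenesis)
    e <- cfg$error_rate
    if (output == "counts") {
      counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
      true_sub <- integer(L)
      n <- cfg$coverage
      for (i in seq_len(L)) {
        ref_i <- match(refv[i], BASES)
        # stage 1: true base (mutagenesis)
        n_mut <- rbinom(1L, n, pr$rate[i])
        true_sub[i] <- n_mut
        true_counts <- integer(4)
        true_counts[ref_i] <- n - n_mut
        if (n_mut > 0)
          true_counts[match(pr$alt[i], BASES)] <-
            true_counts[match(pr$alt[i], BASES)] + n_mut
        # stage 2: sequencing error from each true base
        obs <- integer(4)
        for (b in which(true_counts > 0L)) {
          probs <- rep(e / 3, 4); probs[b] <- 1 - e
          obs <- obs + as.integer(stats::rmultinom(1L, true_counts[b],
                                                   probs))
        }
        # stage 3: quality filter removes the sub-threshold fraction
        if (cfg$subq_fraction > 0)
          obs <- rbinom(4L, obs, 1 - cfg$subq_fraction)
        counts[i, ] <- obs
      }
      truth <- list(onset_offset = onset_offset,
                    onset_position = cfg$tss + onset_offset,
                    true_substitutions = true_sub,
                    positional_rate = pr$rate, alt = pr$alt, config = cfg)
      list(pileup = pileup_matrix(seq_len(L), refv, counts,
                                  qmin = (cfg$q_low + cfg$q_high) / 2),
           reference = refstr, truth = truth)
    } else {
      n_reads <- as.integer(cfg$coverage)
      true_sub_counts <- matrix(0L, nrow = L, ncol = 4,
                                dimnames = list(NULL, BASES))
      seqs <- character(n_reads); quals <- character(n_reads)
      q_chr <- intToUtf8(cfg$q_high + 33L)
      q_lo_chr <- intToUtf8(cfg$q_low + 33L)
      for (r in seq_len(n_reads)) {
        true <- refv
        mut <- which(runif(L) < pr$rate)
        if (length(mut)) true[mut] <- pr$alt[mut]
        for (i in seq_len(L))
          true_sub_counts[i, match(true[i], BASES)] <-
            true_sub_counts[i, match(true[i], BASES)] + 1L
        obs <- true
        err <- which(runif(L) < e)
        for (i in err)
          obs[i] <- sample(setdiff(BASES, obs[i]), 1L)
        lowq <- runif(L) < cfg$subq_fraction
        seqs[r] <- paste(obs, collapse = "")
        quals[r] <- paste(ifelse(lowq, q_lo_chr, q_chr), collapse = "")
      }
      truth <- list(onset_offset = onset_offset,
                    onset_position = cfg$tss + onset_offset,
                    true_base_counts = true_sub_counts,
                    positional_rate = pr$rate, alt = pr$alt, config = cfg)
      list(reads = data.frame(qname = paste0("read", seq_len(n_reads)),
                              pos = 1L, seq = seqs, qual = quals),
           reference = refstr, truth = truth)
    }
  })
}

#' Generate a random barcode manifest
#'
#' Draws one front and one back barcode per well, rejecting candidates
#' within Hamming distance `min_dist` of an existing barcode so that
#' single-mismatch demultiplexing is unambiguous.
#'
#' @param n_wells Number of wells.
#' @param length Barcode length (default 8).
#' @param min_dist Minimum pairwise Hamming distance per end (default 3).
#' @param seed Integer seed.
#' @return A [barcode_manifest()].
#' @export
make_barcode_manifest <- function(n_wells, length = 8L, min_dist = 3L,
                                  seed = NULL) {
  .with_seed(seed, {
    draw_set <- function(n) {
      out <- character(0)
      while (length(out) < n) {
        cand <- paste(sample(BASES, length, replace = TRUE), collapse = "")
        if (length(out) == 0 ||
            all(.hamming_to_set(cand, out) >= min_dist))
          out <- c(out, cand)
      }
      out
    }
    barcode_manifest(sprintf("well%03d", seq_len(n_wells)),
                     draw_set(n_wells), draw_set(n_wells))
  })
}

#' Generate a small synthetic coding sequence
#'
#' ATG start, random internal codons free of stop codons, one terminal stop.
#' @param n_codons Total codons including start and stop.
#' @param seed Integer seed.
#' @return Character CDS of length `3 * n_codons`.
#' @export
synthetic_cds <- function(n_codons, seed = NULL) {
  .with_seed(seed, {
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(matrix(sample(BASES, 3 * (n_codons - 2), replace = TRUE),
                           ncol = 3), 1, paste, collapse = "")
    while (any(codons %in% stops))
      codons[codons %in% stops] <-
        apply(matrix(sample(BASES, 3 * sum(codons %in% stops),
                            replace = TRUE), ncol = 3), 1, paste,
              collapse = "")
    paste(c("ATG", codons, "TAA"), collapse = "")
  })
}

#' Simulate a barcoded multi-well amplicon campaign
#'
#' Emulates a resistance-evolution endpoint: one driver substitution swept
#' into most wells at high within-well frequency, plus sporadic noise
#' substitutions each confined to a few wells at low frequency. Reads are
#' full-length gene amplicons flanked by well barcodes, with constant
#' above-threshold quality.
#'
#' @param gene Gene/CDS reference (string; e.g. [synthetic_cds()]).
#' @param n_wells Number of wells (default 177).
#' @param reads_per_well Reads per well (default 30).
#' @param driver `list(pos, alt, well_fraction, within_well_freq)`; when
#'   `NULL` (default) the driver is the transition substitution at position
#'   160 (or two-thirds into shorter genes), planted in 85% of wells at
#'   within-well frequency 0.9.
#' @param noise `list(n, max_wells, within_well_freq)`: `n` distinct noise
#'   substitutions, each planted in up to `max_wells` wells at the given
#'   within-well frequency (defaults 10, 2, 0.2).
#' @param manifest Optional [barcode_manifest()]; generated when `NULL`.
#' @param base_quality Constant Phred quality of every base (default 40).
#' @param seed Integer seed.
#' @return List: `reads` (`data.frame(id, seq, qual)` FASTQ-ready),
#'   `manifest`, `gene`, `truth` (`driver`, `driver_wells`, `noise` table of
#'   planted mutations per well).
#' @export
simulate_amplicon_campaign <- function(gene, n_wells = 177L,
                                       reads_per_well = 30L,
                                       driver = NULL,
                                       noise = list(n = 10L, max_wells = 2L,
                                                    within_well_freq = 0.2),
                                       manifest = NULL, base_quality = 40L,
                                       seed = NULL) {
  genev <- strsplit(toupper(gene), "")[[1]]
  L <- length(genev)
  if (is.null(driver)) {
    pos <- if (L >= 160L) 160L else as.integer(ceiling(2 * L / 3))
    transition <- c(A = "G", C = "T", G = "A", T = "C")
    driver <- list(pos = pos, alt = unname(transition[genev[pos]]),
                   well_fraction = 0.85, within_well_freq = 0.9)
  }
  stopifnot(driver$pos >= 1, driver$pos <= L,
            driver$well_fraction >= 0, driver$well_fraction <= 1,
            driver$within_well_freq >= 0, driver$within_well_freq <= 1)
  if (genev[driver$pos] == driver$alt)
    stop("driver alt equals the reference base at its position")
  .with_seed(seed, {
    if (is.null(manifest)) manifest <- make_barcode_manifest(n_wells)
    stopifnot(length(manifest$well) == n_wells)
    n_driver_wells <- round(driver$well_fraction * n_wells)
    driver_wells <- sort(sample.int(n_wells, n_driver_wells))
    # noise substitutions at distinct positions away from the driver
    noise_tab <- NULL
    if (noise$n > 0) {
      cand <- setdiff(seq_len(L), driver$pos)
      npos <- sample(cand, noise$n)
      noise_tab <- do.call(rbind, lapply(seq_len(noise$n), function(k) {
        ref_b <- genev[npos[k]]
        alt_b <- sample(setdiff(BASES, ref_b), 1L)
        wells <- sample.int(n_wells, sample.int(noise$max_wells, 1L))
        data.frame(pos = npos[k], ref = ref_b, alt = alt_b,
                   well = manifest$well[wells])
      }))
    }
    ids <- character(0); seqs <- character(0)
    qual_line <- strrep(intToUtf8(base_quality + 33L),
                        L + nchar(manifest$front[1]) +
                          nchar(manifest$back[1]))
    for (w in seq_len(n_wells)) {
      wl <- manifest$well[w]
      has_driver <- w %in% driver_wells
      w_noise <- if (!is.null(noise_tab))
        noise_tab[noise_tab$well == wl, , drop = FALSE] else NULL
      for (r in seq_len(reads_per_well)) {
        v <- genev
        if (has_driver && runif(1) < driver$within_well_freq)
          v[driver$pos] <- driver$alt
        if (!is.null(w_noise) && nrow(w_noise) > 0)
          for (k in seq_len(nrow(w_noise)))
            if (runif(1) < noise$within_well_freq)
              v[w_noise$pos[k]] <- w_noise$alt[k]
        ids <- c(ids, sprintf("%s_read%03d", wl, r))
        seqs <- c(seqs, paste0(manifest$front[w], paste(v, collapse = ""),
                               manifest$back[w]))
      }
    }
    truth <- list(driver = driver, driver_wells = manifest$well[driver_wells],
                  n_driver_wells = n_driver_wells, noise = noise_tab,
                  seed = seed)
    list(reads = data.frame(id = ids, seq = seqs,
                            qual = rep(qual_line, length(ids))),
         manifest = manifest, gene = gene, truth = truth)
  })
}

#' Simulate exponential OD600 growth curves
#'
#' `OD(t) = od0 * exp(rate * t)` with multiplicative log-normal noise.
#'
#' @param rate True growth rate (h^-1).
#' @param od0 OD at t = 0.
#' @param times Measurement times in hours (default `seq(4, 24, by = 4)`).
#' @param n_replicates Number of replicate curves (default 3).
#' @param noise_sd SD of the multiplicative noise on the log scale
#'   (default 0.02).
#' @param seed Integer seed.
#' @return `data.frame(time_h, od, replicate)` plus attribute `truth`.
#' @export
simulate_growth_curves <- function(rate, od0 = 0.05,
                                   times = seq(4, 24, by = 4),
                                   n_replicates = 3L, noise_sd = 0.02,
                                   seed = NULL) {
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      od <- od0 * exp(rate * times) *
        exp(rnorm(length(times), 0, noise_sd))
      data.frame(time_h = times, od = od,
                 replicate = sprintf("rep%d", r))
    }))
    attr(out, "truth") <- list(rate = rate, od0 = od0, noise_sd = noise_sd,
                               seed = seed)
    out
  })
}
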