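#!/usr/bin/env Rscript
# Fluctuation-assay mutation-rate estimation.
#
# Simulates eight-culture fluctuation assays across the dynamic range of an
# inducible targeted mutagenesis system (per-division LOF rates from
# background 1.6e-8 up to 1.1e-2), estimates each rate by MSS maximum
# likelihood with Stewart 95% CIs, and tabulates fold changes against the
# uninduced background. Writes results/fluctuation_rates.tsv.

suppressPackageStartupMessages(library(mutassay))
dir.create("results", showWarnings = FALSE)
seed <- 20260920

conditions <- data.frame(
  label = c("background", "induced_low", "induced_mid", "induced_high",
            "induced_max"),
  mu_true = c(1.6e-8, 2.5e-5, 2.5e-4, 2.7e-3, 1.1e-2),
  n_final = c(5e8, 5e6, 5e5, 5e4, 2e4)   # fewer divisions at high induction
)

rows <- lapply(seq_len(nrow(conditions)), function(i) {
  cond <- conditions[i, ]
  sim <- simulate_fluctuation(mu = cond$mu_true, n_final = cond$n_final,
                              n_cultures = 8, seed = seed + i)
  est <- estimate_rate(sim$experiment)
  data.frame(label = cond$label, mu_true = cond$mu_true,
             m_hat = est$m_hat, mu_hat = est$mu,
             ci_low = est$ci_low, ci_high = est$ci_high)
})
tab <- do.call(rbind, rows)
tab$fold_vs_background <- tab$mu_hat / tab$mu_hat[1]

write.table(format(tab, digits = 4), "results/fluctuation_rates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Estimated per-division LOF rates (8 cultures each):\n")
print(tab, digits = 3)

# Worked comparisons on the published rate table itself
cmp_max <- compare_rates(mutation_rate_estimate(1.1e-2),
                         mutation_rate_estimate(1.6e-8))
cmp_rng <- compare_rates(mutation_rate_estimate(2.7e-3),
                         mutation_rate_estimate(2.5e-5))
cat(sprintf("\nMaximal rate over background: %.0f-fold (%g at 2 s.f.)\n",
            cmp_max$fold, cmp_max$fold_2sf))
cat(sprintf("Induction dynamic range: %.0f-fold\n", cmp_rng$fold))
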