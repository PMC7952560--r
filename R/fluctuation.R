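# Luria-Delbrück fluctuation analysis: MSS maximum-likelihood estimation of the
# expected number of mutations per culture (m), the P0 estimator, Stewart 95%
# confidence intervals, and conversion to per-division mutation rates.

#' Construct a fluctuation experiment
#'
#' Bundles the per-culture mutant colony counts of one fluctuation assay with
#' the final population size and plating fraction needed to convert the
#' maximum-likelihood mutation number into a per-division mutation rate.
#'
#' @param counts Integer vector, one mutant-colony count per parallel culture.
#' @param n_final Final number of viable cells per culture (N_t, positive).
#' @param plating_fraction Fraction of each culture's volume plated on
#'   selective medium, in (0, 1]. Only used when the partial plating
#'   correction is enabled (off by default).
#' @param label Free-text experiment label.
#' @return An object of class `fluctuation_experiment`.
#' @examples
#' fluctuation_experiment(c(0, 0, 1, 0, 12, 2, 0, 1), n_final = 1e7)
#' @export
fluctuation_experiment <- function(counts, n_final, plating_fraction = 1,
                                   label = "") {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("at least one culture count is required")
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (!is.numeric(n_final) || length(n_final) != 1L || n_final <= 0)
    stop("n_final (N_t) must be a single positive number")
  if (plating_fraction <= 0 || plating_fraction > 1)
    stop("plating_fraction must lie in (0, 1]")
  structure(
    list(counts = counts, n_cultures = length(counts), n_final = n_final,
         plating_fraction = plating_fraction, label = as.character(label)[1]),
    class = "fluctuation_experiment")
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("Fluctuation experiment", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n  cultures:", x$n_cultures,
      "\n  counts:  ", paste(head(x$counts, 12), collapse = " "),
      if (x$n_cultures > 12) "...",
      "\n  N_t:     ", format(x$n_final),
      "  plating fraction:", x$plating_fraction, "\n")
  invisible(x)
}

#' Luria-Delbrück mutant-count distribution (MSS recursion)
#'
#' Computes the probability mass function of the number of mutant colonies per
#' culture under the Luria-Delbrück model with expected mutation number `m`,
#' via the Ma-Sandri-Sarkar recursion
#' \deqn{p_0 = e^{-m}, \quad p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1}.}
#'
#' The probabilities sum to less than one at any finite truncation; the
#' deficit `1 - sum(pmf)` is the upper-tail (jackpot) mass beyond `r_max`.
#'
#' @param m Expected number of mutations per culture (non-negative).
#' @param r_max Largest count for which a probability is returned
#'   (non-negative integer).
#' @return An object of class `ld_distribution` with fields `m`, `pmf`
#'   (probabilities for counts `0:r_max`) and `r_max`.
#' @examples
#' ld_pmf(1, 5)$pmf[1:2]  # exp(-1), exp(-1)/2
#' @export
ld_pmf <- function(m, r_max) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0)
    stop("m must be a single non-negative finite number")
  if (!is.numeric(r_max) || length(r_max) != 1L || r_max < 0 ||
      r_max != floor(r_max))
    stop("r_max must be a single non-negative integer")
  p <- .ld_pmf_cpp(m, as.integer(r_max))
  structure(list(m = m, pmf = p, r_max = as.integer(r_max)),
            class = "ld_distribution")
}

# Log-likelihood of counts under the MSS pmf. Counts above `cap` are lumped
# into the upper-tail mass 1 - sum(p_0..p_cap) so jackpots stay finite.
.ld_loglik <- function(m, counts, cap = 10000L) {
  capped <- pmin(counts, cap + 1L)      # cap+1 marks "beyond cap"
  r_need <- min(max(counts), cap)
  p <- .ld_pmf_cpp(m, as.integer(r_need))
  ll <- 0
  in_range <- capped <= r_need
  if (any(in_range)) {
    pr <- p[capped[in_range] + 1L]
    if (any(pr <= 0)) return(-.Machine$double.xmax)
    ll <- ll + sum(log(pr))
  }
  n_over <- sum(!in_range)
  if (n_over > 0) {
    tail_mass <- max(1 - sum(p), .Machine$double.xmin)
    ll <- ll + n_over * log(tail_mass)
  }
  ll
}

# Lea-Coulson median-based seed: solves median/m - log(m) = 1.24.
.lea_coulson_seed <- function(counts) {
  med <- stats::median(counts)
  if (med <= 0) return(NA_real_)
  f <- function(m) med / m - log(m) - 1.24
  out <- tryCatch(uniroot(f, lower = 1e-8, upper = med + 10)$root,
                  error = function(e) NA_real_)
  out
}

#' Ma-Sandri-Sarkar maximum-likelihood estimate of m
#'
#' Maximises the Luria-Delbrück log-likelihood of the observed mutant-colony
#' counts over the expected mutation number `m`. The search brackets `m`
#' between a P0/Lea-Coulson-based seed and `10 * (mean(counts) + 1)` and
#' refines on the log scale with golden-section/parabolic interpolation
#' (`stats::optimize`). All-zero counts return the boundary estimate 0.
#'
#' @param experiment A [fluctuation_experiment()], or a bare numeric vector of
#'   counts.
#' @param cap Jackpot cap: counts above `cap` contribute through the lumped
#'   upper-tail mass rather than an individual probability.
#' @param tol Relative convergence tolerance on m.
#' @return The maximum-likelihood estimate `m_hat` (non-negative scalar).
#' @examples
#' mss_mle(c(0, 0, 1, 0, 12, 2, 0, 1))
#' @export
mss_mle <- function(experiment, cap = 10000L, tol = 1e-6) {
  counts <- if (inherits(experiment, "fluctuation_experiment"))
    experiment$counts else as.numeric(experiment)
  if (length(counts) < 1L) stop("at least one culture count is required")
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (all(counts == 0)) return(0)
  lo <- 1e-6
  if (any(counts == 0)) lo <- max(lo, 0.1 * (-log(mean(counts == 0))))
  seed <- .lea_coulson_seed(counts)
  if (is.finite(seed)) lo <- max(1e-6, min(lo, seed / 10))
  hi <- 10 * (mean(counts) + 1)
  obj <- function(lm) .ld_loglik(exp(lm), counts, cap = cap)
  opt <- optimize(obj, lower = log(lo), upper = log(hi), maximum = TRUE,
                  tol = tol / 2)
  m_hat <- exp(opt$maximum)
  # guard against a maximum pinned at the bracket edge
  if (m_hat > 0.99 * hi) {
    opt <- optimize(obj, lower = log(lo), upper = log(100 * hi),
                    maximum = TRUE, tol = tol / 2)
    m_hat <- exp(opt$maximum)
  }
  m_hat
}

#' P0 estimate of m
#'
#' Estimates the expected mutation number from the fraction of cultures with
#' zero mutant colonies: `m_hat = -log(P0)`. Undefined when no culture has a
#' zero count.
#'
#' @inheritParams mss_mle
#' @return The P0 estimate of m.
#' @examples
#' p0_estimate(c(0, 0, 5, 12))  # -log(0.5)
#' @export
p0_estimate <- function(experiment) {
  counts <- if (inherits(experiment, "fluctuation_experiment"))
    experiment$counts else as.numeric(experiment)
  if (length(counts) < 1L) stop("at least one culture count is required")
  p0 <- mean(counts == 0)
  if (p0 == 0)
    stop("P0 estimator undefined: no culture has a zero mutant count")
  -log(p0)
}

#' Stewart 95% confidence interval for m
#'
#' Approximates the sampling standard deviation of `log(m_hat)` by Stewart's
#' formula \eqn{\sigma_{\ln m} = 1.225\, m^{-0.315} / \sqrt{C}} and returns
#' 95% limits on m. The default is symmetric on the log scale,
#' `exp(log(m_hat) +/- 1.96 sigma)`; `asymmetric = TRUE` applies the
#' skewness-adjusted exponents
#' `exp(log(m_hat) +/- 1.96 sigma * exp(+/-0.315 * 1.96 sigma))`, which widens
#' the upper limit to reflect the right-skewed likelihood.
#'
#' @param m_hat Maximum-likelihood estimate of m (positive).
#' @param n_cultures Number of parallel cultures C (>= 2).
#' @param asymmetric Apply the skewness correction to the limits.
#' @return Named numeric vector `c(lower, upper, sigma_ln_m)` on the m scale.
#' @examples
#' confidence_interval(1, 24)
#' @export
confidence_interval <- function(m_hat, n_cultures, asymmetric = FALSE) {
  if (!is.numeric(m_hat) || length(m_hat) != 1L || m_hat <= 0)
    stop("m_hat must be a single positive number (CI undefined at m_hat = 0)")
  if (n_cultures < 2) stop("n_cultures must be at least 2")
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(n_cultures)
  z <- 1.96
  if (asymmetric) {
    lower <- exp(log(m_hat) - z * sigma * exp(-0.315 * z * sigma))
    upper <- exp(log(m_hat) + z * sigma * exp(+0.315 * z * sigma))
  } else {
    lower <- exp(log(m_hat) - z * sigma)
    upper <- exp(log(m_hat) + z * sigma)
  }
  c(lower = lower, upper = upper, sigma_ln_m = sigma)
}

# Standard partial plating correction factor: when a fraction z of each
# culture is plated, the m estimated from plated counts underestimates the
# true m by the factor (z - 1)/(z * log(z)) (-> 1 as z -> 1).
.plating_factor <- function(z) {
  if (z >= 1) return(1)
  (z - 1) / (z * log(z))
}

#' Convert an estimate of m into a per-division mutation rate
#'
#' Divides the (optionally plating-corrected) mutation number by the final
#' population size: `mu = m_hat / N_t`, with 95% CI endpoints scaled the same
#' way. The partial plating correction is off by default — plated-count
#' estimates are then used as-is, as proxy rates for comparative analysis.
#' When enabled, `m_hat` is multiplied by `(z - 1)/(z log z)` before division.
#'
#' @param m_hat Estimate of the expected mutation number per culture.
#' @param experiment The [fluctuation_experiment()] supplying `N_t`, `C` and
#'   the plating fraction.
#' @param plating_correction Apply the partial plating correction (default
#'   `FALSE`).
#' @param method Estimator label recorded in the result (`"mss_mle"` or
#'   `"p0"`).
#' @param per_generation Report the rate per generation, `m/(N_t ln 2)`,
#'   instead of per division `m/N_t`.
#' @param asymmetric Passed to [confidence_interval()].
#' @return An object of class `mutation_rate_estimate` with fields `m_hat`,
#'   `mu`, `ci_low`, `ci_high`, `sigma_ln_m`, `n_cultures`, `method`. The CI
#'   fields are `NA` when `m_hat` is 0.
#' @examples
#' exp1 <- fluctuation_experiment(c(0, 0, 1, 0, 12, 2, 0, 1), n_final = 1e7)
#' rate_from_m(mss_mle(exp1), exp1)
#' @export
rate_from_m <- function(m_hat, experiment, plating_correction = FALSE,
                        method = "mss_mle", per_generation = FALSE,
                        asymmetric = FALSE) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  if (experiment$n_final <= 0) stop("N_t must be positive")
  m_eff <- m_hat
  if (plating_correction)
    m_eff <- m_hat * .plating_factor(experiment$plating_fraction)
  denom <- experiment$n_final * if (per_generation) log(2) else 1
  mu <- m_eff / denom
  if (m_hat > 0 && experiment$n_cultures >= 2) {
    ci <- confidence_interval(m_eff, experiment$n_cultures,
                              asymmetric = asymmetric)
    ci_low <- ci[["lower"]] / denom
    ci_high <- ci[["upper"]] / denom
    sigma <- ci[["sigma_ln_m"]]
  } else {
    ci_low <- ci_high <- sigma <- NA_real_
  }
  structure(
    list(m_hat = m_eff, mu = mu, ci_low = ci_low, ci_high = ci_high,
         sigma_ln_m = sigma, n_cultures = experiment$n_cultures,
         method = method, plating_correction = plating_correction,
         per_generation = per_generation, label = experiment$label),
    class = "mutation_rate_estimate")
}

#' Construct a mutation-rate estimate directly from a rate
#'
#' Wraps an externally obtained per-division rate (for example a published
#' value) in the container used by [compare_rates()].
#'
#' @param mu Per-division mutation rate.
#' @param label Free-text label.
#' @return A `mutation_rate_estimate`.
#' @export
mutation_rate_estimate <- function(mu, label = "") {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("mu must be a single non-negative number")
  structure(list(m_hat = NA_real_, mu = mu, ci_low = NA_real_,
                 ci_high = NA_real_, sigma_ln_m = NA_real_,
                 n_cultures = NA_integer_, method = "external",
                 plating_correction = FALSE, per_generation = FALSE,
                 label = as.character(label)[1]),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat("Mutation rate estimate",
      if (nzchar(x$label)) paste0("'", x$label, "'"), "\n",
      " method:", x$method,
      if (!is.na(x$m_hat)) paste0("  m_hat: ", signif(x$m_hat, 4)), "\n",
      " mu:", format(signif(x$mu, 4)),
      if (x$per_generation) "per generation" else "per division", "\n")
  if (!is.na(x$ci_low))
    cat("  95% CI: [", format(signif(x$ci_low, 4)), ",",
        format(signif(x$ci_high, 4)), "]\n")
  invisible(x)
}

#' Fold change between two mutation-rate estimates
#'
#' Ratio of the two per-division rates, `a$mu / b$mu`, with the ratio rounded
#' to two significant figures also reported (the convention used when quoting
#' fold increases).
#'
#' @param a,b `mutation_rate_estimate` objects (numerator, denominator).
#' @return List with `fold` and `fold_2sf`; both `NA` with a warning when the
#'   denominator rate is 0.
#' @examples
#' compare_rates(mutation_rate_estimate(1.1e-2), mutation_rate_estimate(1.6e-8))
#' @export
compare_rates <- function(a, b) {
  stopifnot(inherits(a, "mutation_rate_estimate"),
            inherits(b, "mutation_rate_estimate"))
  if (b$mu == 0) {
    warning("denominator rate is zero; fold change undefined")
    return(list(fold = NA_real_, fold_2sf = NA_real_))
  }
  fold <- a$mu / b$mu
  list(fold = fold, fold_2sf = signif(fold, 2))
}

#' Estimate a mutation rate from a fluctuation experiment in one call
#'
#' Convenience wrapper: runs the chosen estimator and converts to a rate.
#'
#' @inheritParams rate_from_m
#' @param method `"mss_mle"` (default) or `"p0"`.
#' @param ... Passed to [mss_mle()].
#' @return A `mutation_rate_estimate`.
#' @export
estimate_rate <- function(experiment, method = c("mss_mle", "p0"),
                          plating_correction = FALSE, ...) {
  method <- match.arg(method)
  m_hat <- switch(method,
                  mss_mle = mss_mle(experiment, ...),
                  p0 = p0_estimate(experiment))
  rate_from_m(m_hat, experiment, plating_correction = plating_correction,
              method = method)
}
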