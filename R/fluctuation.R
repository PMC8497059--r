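# Mutation-rate estimation from fluctuation assays under the Lea-Coulson
# model. The number of mutation events per culture, m, is estimated by
# maximum likelihood over the per-culture mutant counts; the per-division
# rate is m / Nt with Nt the final number of cells per culture.

#' Lea-Coulson probability mass function
#'
#' Computes \eqn{P(r = 0), \dots, P(r = k_{max})} for the number of resistant
#' mutants in a culture under the Lea-Coulson formulation of the
#' Luria-Delbruck distribution, using the Ma-Sandri-Sarkar recursion
#' \deqn{p_0 = e^{-m}, \quad p_n = \frac{m}{n} \sum_{i=0}^{n-1}
#'   \frac{p_i}{n - i + 1}.}
#' Equivalently, the distribution is compound Poisson: a Poisson(m) number
#' of mutational clones whose sizes are i.i.d. with
#' \eqn{P(K = k) = 1/(k(k+1))}, the clone-size law of a mutant lineage
#' growing as a birth process inside an exponentially expanding wild-type
#' population.
#'
#' @param m Expected number of mutation events per culture (>= 0).
#' @param k_max Largest mutant count to evaluate (>= 0).
#' @return Numeric vector of length `k_max + 1`, `[P(0), ..., P(k_max)]`.
#' @export
#' @examples
#' lea_coulson_pmf(1, 5)
lea_coulson_pmf <- function(m, k_max) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0) {
    stop("'m' must be a single non-negative number")
  }
  if (!is.numeric(k_max) || length(k_max) != 1 || is.na(k_max) || k_max < 0) {
    stop("'k_max' must be a single non-negative integer")
  }
  k_max <- as.integer(k_max)
  p <- numeric(k_max + 1)
  p[1] <- exp(-m)
  if (k_max >= 1) {
    for (n in seq_len(k_max)) {
      i <- 0:(n - 1)
      p[n + 1] <- (m / n) * sum(p[i + 1] / (n - i + 1))
    }
  }
  p
}

#' Construct a fluctuation experiment
#'
#' @param mutant_counts Non-negative integer vector of resistant-colony
#'   counts, one per parallel culture (at least 2 cultures).
#' @param culture_id Optional culture labels (default `c1, c2, ...`).
#' @param plated_fraction Fraction of each culture plated on selective
#'   media, in (0, 1]. Values below 1 invoke the thinned Lea-Coulson
#'   likelihood in [estimate_m()].
#' @param strain Optional strain label.
#' @return Object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(mutant_counts, culture_id = NULL,
                                   plated_fraction = 1, strain = NA_character_) {
  if (length(mutant_counts) < 2) stop("need at least 2 cultures")
  if (any(is.na(mutant_counts)) || any(mutant_counts < 0) ||
      any(mutant_counts != round(mutant_counts))) {
    stop("mutant counts must be non-negative integers")
  }
  if (!is.numeric(plated_fraction) || length(plated_fraction) != 1 ||
      plated_fraction <= 0 || plated_fraction > 1) {
    stop("plated_fraction must be in (0, 1]")
  }
  if (is.null(culture_id)) culture_id <- paste0("c", seq_along(mutant_counts))
  structure(list(culture_id = as.character(culture_id),
                 mutant_counts = as.integer(mutant_counts),
                 plated_fraction = plated_fraction,
                 strain = strain),
            class = "fluctuation_experiment")
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("Fluctuation experiment", if (!is.na(x$strain)) paste0(" [", x$strain, "]"),
      ": ", length(x$mutant_counts), " cultures, plated fraction ",
      x$plated_fraction, "\n", sep = "")
  cat("counts:", x$mutant_counts, "\n")
  invisible(x)
}

# Per-count log-probabilities under the (optionally thinned, tail-binned)
# Lea-Coulson model. Counts at or above `cap` are pooled into a right tail
# P(R >= cap) so that jackpot cultures do not destabilize the likelihood.
# With plating efficiency eps < 1, the observed count given a latent count
# k is Binomial(k, eps); the latent pmf is computed to `cap` and thinned,
# with the un-enumerated latent tail mass assigned to the observed tail bin.
lc_count_logprobs <- function(m, counts, cap = 150L, eps = 1) {
  kmax <- min(max(counts), cap)
  below <- counts[counts < cap]
  p <- lea_coulson_pmf(m, if (eps < 1) cap - 1L else kmax)
  if (eps < 1) {
    k <- 0:(cap - 1L)
    obs <- vapply(0:(cap - 1L), function(j) {
      sum(p[k >= j] * dbinom(j, k[k >= j], eps))
    }, numeric(1))
    p <- obs
  }
  ll <- 0
  if (length(below)) {
    pb <- p[below + 1]
    if (any(pb <= 0)) return(-Inf)
    ll <- ll + sum(log(pb))
  }
  n_tail <- sum(counts >= cap)
  if (n_tail > 0) {
    tail_mass <- max(1 - sum(p[seq_len(cap)]), 0)
    if (tail_mass <= 0) return(-Inf)
    ll <- ll + n_tail * log(tail_mass)
  }
  ll
}

#' Estimate the expected number of mutations per culture
#'
#' Maximum-likelihood estimate of m under the Lea-Coulson model, with a
#' profile-likelihood-ratio confidence interval (chi-squared, 1 df). When
#' all counts are zero the MLE is 0 and the interval is one-sided. When
#' `plated_fraction < 1` the likelihood is the binomially thinned
#' Lea-Coulson model; the default (1) reproduces plain Lea-Coulson fitting.
#'
#' @param exp A [fluctuation_experiment()].
#' @param cap Counts at or above this value are binned into a right tail
#'   (jackpot handling); default 150.
#' @param conf_level Confidence level for the profile interval.
#' @param tol Optimizer tolerance in m.
#' @return List of class `m_estimate` with elements `m_hat`, `ci_low`,
#'   `ci_high`, `loglik`, `n_cultures`, `plated_fraction`, `conf_level`.
#' @export
estimate_m <- function(exp, cap = 150L, conf_level = 0.95, tol = 1e-6) {
  stopifnot(inherits(exp, "fluctuation_experiment"))
  counts <- exp$mutant_counts
  eps <- exp$plated_fraction
  if (length(counts) == 0) stop("empty experiment")
  C <- length(counts)
  crit <- qchisq(conf_level, df = 1) / 2
  ll <- function(m) lc_count_logprobs(m, counts, cap = cap, eps = eps)

  if (all(counts == 0)) {
    # likelihood e^{-Cm} (thinning does not change P(0 observed | 0 latent)
    # dominance at small m); maximized at m = 0, one-sided upper bound from
    # the likelihood-ratio cutoff.
    l0 <- ll(0)
    up_hi <- 2 * crit / C + 1
    while (ll(up_hi) > l0 - crit && up_hi < 1e7) up_hi <- up_hi * 2
    up <- uniroot(function(m) ll(m) - (l0 - crit),
                  lower = 0, upper = up_hi, tol = tol)$root
    return(structure(list(m_hat = 0, ci_low = 0, ci_high = up, loglik = l0,
                          n_cultures = C, plated_fraction = eps,
                          conf_level = conf_level, cap = cap),
                     class = "m_estimate"))
  }

  # bracket: the MLE is of order mean(count)/clone-size factor; expand the
  # upper bound until the log-likelihood is decreasing.
  hi <- max(2, 2 * mean(pmin(counts, cap)))
  while (ll(hi * 2) > ll(hi) && hi < 1e6) hi <- hi * 2
  opt <- optimize(ll, interval = c(tol, hi * 2), maximum = TRUE, tol = tol)
  m_hat <- opt$maximum
  l_max <- opt$objective

  target <- l_max - crit
  lo_end <- tol * 1e-3
  ci_low <- if (ll(lo_end) >= target) 0 else
    uniroot(function(m) ll(m) - target, lower = lo_end, upper = m_hat,
            tol = tol)$root
  hi_end <- m_hat * 2 + 1
  while (ll(hi_end) > target && hi_end < 1e7) hi_end <- hi_end * 2
  ci_high <- uniroot(function(m) ll(m) - target, lower = m_hat,
                     upper = hi_end, tol = tol)$root

  structure(list(m_hat = m_hat, ci_low = ci_low, ci_high = ci_high,
                 loglik = l_max, n_cultures = C, plated_fraction = eps,
                 conf_level = conf_level, cap = cap),
            class = "m_estimate")
}

#' @export
print.m_estimate <- function(x, ...) {
  cat(sprintf("m_hat = %.4g  [%g%% CI %.4g - %.4g], %d cultures\n",
              x$m_hat, 100 * x$conf_level, x$ci_low, x$ci_high, x$n_cultures))
  invisible(x)
}

#' Estimate cells per culture from a colony-count dilution
#'
#' @param colony_count Number of colonies counted on the dilution plate.
#' @param dilution_factor Dilution factor (e.g. 10000 for a 1:10,000
#'   plating).
#' @return Object of class `nt_estimate` with `nt = colony_count *
#'   dilution_factor`. A zero colony count yields `nt = 0` with a warning
#'   (the downstream rate is then undefined).
#' @export
estimate_nt <- function(colony_count, dilution_factor) {
  if (colony_count < 0 || colony_count != round(colony_count)) {
    stop("colony_count must be a non-negative integer")
  }
  if (dilution_factor <= 0) stop("dilution_factor must be positive")
  warn <- colony_count == 0
  if (warn) warning("zero colonies counted: Nt = 0, rate undefined downstream")
  structure(list(colony_count = as.integer(colony_count),
                 dilution_factor = dilution_factor,
                 nt = colony_count * dilution_factor,
                 zero_count = warn),
            class = "nt_estimate")
}

#' Mutation rate per gene per cell division
#'
#' The per-division loss-of-function rate is m / Nt; confidence bounds on m
#' are scaled identically.
#'
#' @param m_est An [estimate_m()] result (or a bare non-negative number).
#' @param nt An [estimate_nt()] result or positive cell count.
#' @return Object of class `rate_estimate` with `rate`, `ci_low`, `ci_high`,
#'   `m_hat`, `nt`, `method`.
#' @export
mutation_rate <- function(m_est, nt) {
  if (inherits(nt, "nt_estimate")) nt <- nt$nt
  if (!is.numeric(nt) || nt <= 0) stop("nt must be positive")
  if (is.numeric(m_est)) {
    if (m_est < 0) stop("m_hat must be non-negative")
    m_est <- list(m_hat = m_est, ci_low = NA_real_, ci_high = NA_real_)
  }
  structure(list(rate = m_est$m_hat / nt,
                 ci_low = m_est$ci_low / nt,
                 ci_high = m_est$ci_high / nt,
                 m_hat = m_est$m_hat, nt = nt,
                 method = "lea_coulson_mle"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("mutation rate = %.3g per gene per division (m = %.3g, Nt = %.3g)\n",
              x$rate, x$m_hat, x$nt))
  if (!is.na(x$ci_low)) cat(sprintf("  CI: %.3g - %.3g\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Fold change between two mutation rates
#'
#' @param rate_a,rate_b [mutation_rate()] results or bare numbers;
#'   `rate_b` must be positive.
#' @return `rate_a / rate_b`.
#' @export
rate_fold_change <- function(rate_a, rate_b) {
  if (inherits(rate_a, "rate_estimate")) rate_a <- rate_a$rate
  if (inherits(rate_b, "rate_estimate")) rate_b <- rate_b$rate
  if (rate_b <= 0) stop("reference rate must be positive")
  rate_a / rate_b
}
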