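# Monte-Carlo exact comparison of two mutation spectra. The two count
# vectors form a 2 x K contingency table; under the null that both spectra
# are draws from one class distribution, the conditional law of the table
# given both margins is multivariate hypergeometric. The p-value is the
# probability of a table at most as probable as the observed one, estimated
# from seeded random tables with the same margins.

#' Arrange two spectra as a 2 x K contingency table
#'
#' @param spec_a,spec_b [spectrum_counts()] objects (or named count
#'   vectors) over identical category sets.
#' @param include_indels If FALSE, drop the `ins`/`del` categories to form a
#'   2 x 6 table; if TRUE keep them (2 x 8).
#' @return Integer matrix with 2 rows; zero columns are retained.
#' @export
build_table <- function(spec_a, spec_b, include_indels = FALSE) {
  if (!identical(names(spec_a), names(spec_b))) {
    stop("spectra have mismatched category sets")
  }
  m <- rbind(a = as.numeric(spec_a), b = as.numeric(spec_b))
  colnames(m) <- names(spec_a)
  if (!include_indels) {
    m <- m[, setdiff(colnames(m), INDEL_CLASSES), drop = FALSE]
  } else if (!all(INDEL_CLASSES %in% colnames(m))) {
    stop("include_indels = TRUE requires 'ins' and 'del' categories")
  }
  storage.mode(m) <- "integer"
  m
}

# log multivariate hypergeometric probability of a 2 x K table given its
# margins: sum_j log C(c_j, a_j) - log C(n, r1)
log_table_probability <- function(t) {
  if (any(t < 0)) stop("negative counts")
  a <- t[1, ]
  cj <- colSums(t)
  sum(lchoose(cj, a)) - lchoose(sum(t), sum(a))
}

#' Hypergeometric probability of a margin-fixed 2 x K table
#'
#' \deqn{P(T) = \frac{\prod_j \binom{c_j}{a_j}}{\binom{n}{r_1}}}
#' where `c_j` are column totals, `a_j` the first-row cells, `r_1` the first
#' row total and `n` the grand total. Computed in log space.
#'
#' @param t Non-negative integer matrix with 2 rows.
#' @return The probability of `t` conditional on both margins.
#' @export
table_probability <- function(t) exp(log_table_probability(t))

# B random 2 x K tables with the given margins, sampled by sequential
# multivariate-hypergeometric column filling; returns a B x K matrix of
# first-row cells. Vectorized over B.
sample_margin_tables <- function(B, row1_total, col_totals) {
  K <- length(col_totals)
  n <- sum(col_totals)
  A <- matrix(0L, B, K)
  rem_r1 <- rep(row1_total, B)
  rem_n <- n
  for (j in seq_len(K - 1)) {
    a <- rhyper(B, m = rem_r1, n = rem_n - rem_r1, k = col_totals[j])
    A[, j] <- a
    rem_r1 <- rem_r1 - a
    rem_n <- rem_n - col_totals[j]
  }
  A[, K] <- rem_r1
  A
}

#' Monte-Carlo exact test for spectrum differentiation
#'
#' Samples `B` random tables uniformly from the margin-conditional
#' (multivariate hypergeometric) null and reports
#' `p = (1 + #{tables with probability <= observed}) / (B + 1)`
#' (add-one smoothing, so p is never 0). Degenerate margins that make the
#' table unique give p = 1.
#'
#' @param t 2 x K contingency table from [build_table()].
#' @param B Number of random tables (>= 100; default 10000).
#' @param seed Seed; the test is deterministic given the seed.
#' @return List of class `spectrum_test` with `point_prob`, `p_value`,
#'   `B`, `seed`, `table`.
#' @export
spectrum_test <- function(t, B = 10000, seed = NULL) {
  if (B < 100) stop("B must be >= 100")
  stopifnot(is.matrix(t), nrow(t) == 2, all(t >= 0))
  log_obs <- log_table_probability(t)
  r1 <- sum(t[1, ])
  cj <- colSums(t)
  degenerate <- r1 == 0 || sum(t[2, ]) == 0 || sum(cj > 0) <= 1
  if (degenerate) {
    res <- list(point_prob = 1, p_value = 1, B = B, seed = seed, table = t)
    class(res) <- "spectrum_test"
    return(res)
  }
  p_value <- with_seed(seed, {
    A <- sample_margin_tables(B, r1, cj)
    CJ <- matrix(cj, B, length(cj), byrow = TRUE)
    logp <- rowSums(lchoose(CJ, A)) - lchoose(sum(t), r1)
    (1 + sum(logp <= log_obs + 1e-9)) / (B + 1)
  })
  structure(list(point_prob = exp(log_obs), p_value = p_value, B = B,
                 seed = seed, table = t),
            class = "spectrum_test")
}

#' @export
print.spectrum_test <- function(x, ...) {
  cat(sprintf("Monte-Carlo spectrum test: p = %.4g (point prob %.3g, B = %d)\n",
              x$p_value, x$point_prob, x$B))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value in [0, 1].
#' @param n_tests Number of tests in the family (>= 1).
#' @param alpha Family-wise error target for the cutoff (default 0.05).
#' @return List: `corrected = min(1, p_raw * n_tests)`, `cutoff =
#'   alpha / n_tests`.
#' @export
bonferroni <- function(p_raw, n_tests, alpha = 0.05) {
  if (any(p_raw < 0 | p_raw > 1)) stop("p_raw must lie in [0, 1]")
  if (n_tests < 1) stop("n_tests must be >= 1")
  list(corrected = pmin(1, p_raw * n_tests), cutoff = alpha / n_tests)
}

# bp-equivalent nonsense target of a CDS: over all positions and
# substitutions, count changes creating a premature stop, divided by 3.
# The terminal stop codon is excluded from enumeration.
nonsense_target_bp <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  code <- Biostrings::GENETIC_CODE
  n_codons <- nchar(cds) / 3
  hits <- 0L
  for (ci in seq_len(n_codons)) {
    codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    if (code[codon] == "*") next  # existing stop: no premature-stop gain
    for (off in 1:3) {
      for (b in setdiff(BASES, substr(codon, off, off))) {
        nc <- codon
        substr(nc, off, off) <- b
        if (code[nc] == "*") hits <- hits + 1L
      }
    }
  }
  hits / 3
}

#' Mutational target size from the missense/nonsense ratio
#'
#' Nonsense mutations have an exactly enumerable target: every substitution
#' in the CDS that creates a premature stop, expressed in bp-equivalents
#' (count / 3). Scaling this by the ratio of all observed point mutations to
#' observed nonsense mutations estimates the effective number of base pairs
#' at which a point mutation inactivates the reporter.
#'
#' @param counts Named vector of observed point-mutation counts by
#'   consequence (must include `nonsense`; typically also `missense` and
#'   `synonymous`).
#' @param cds CDS sequence (character or DNAString).
#' @return List of class `target_size`: `nonsense_target_bp`,
#'   `effective_target_bp`, `n_point`, `n_nonsense`.
#' @export
target_size <- function(counts, cds) {
  if (is.null(names(counts)) || !"nonsense" %in% names(counts)) {
    stop("counts must be named and include 'nonsense'")
  }
  n_nonsense <- counts[["nonsense"]]
  if (n_nonsense <= 0) stop("target size undefined without nonsense observations")
  n_point <- sum(counts)
  t_nonsense <- nonsense_target_bp(cds)
  structure(list(nonsense_target_bp = t_nonsense,
                 effective_target_bp = t_nonsense * n_point / n_nonsense,
                 n_point = n_point, n_nonsense = n_nonsense),
            class = "target_size")
}

#' @export
print.target_size <- function(x, ...) {
  cat(sprintf("nonsense target %.1f bp; effective target %.1f bp (%d point, %d nonsense)\n",
              x$nonsense_target_bp, x$effective_target_bp,
              x$n_point, x$n_nonsense))
  invisible(x)
}
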