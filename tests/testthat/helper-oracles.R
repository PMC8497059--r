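# Independent oracles used across the suite. Each one recomputes a quantity
# by a route that shares no code with the package implementation.

# Monte-Carlo simulation of the two-type branching process behind the
# Lea-Coulson distribution: a Poisson(m) number of mutational clones arise
# at exponentially-weighted random times and each grows as a stochastic
# birth process, giving clone sizes 1 + Geometric(U), U ~ Uniform(0,1).
simulate_lc_counts <- function(m, n) {
  M <- rpois(n, m)
  tot <- sum(M)
  counts <- numeric(n)
  if (tot > 0) {
    sizes <- 1 + rgeom(tot, runif(tot))
    idx <- rep.int(seq_len(n), M)
    agg <- rowsum(sizes, idx, reorder = FALSE)
    counts[as.integer(rownames(agg))] <- agg
  }
  counts
}

# total-variation distance between an empirical sample and a pmf vector,
# with everything above k_max lumped into one tail bin
tv_distance <- function(sample, pmf, k_max) {
  emp <- tabulate(pmin(sample, k_max) + 1, nbins = k_max + 1) / length(sample)
  pv <- c(pmf[seq_len(k_max)], max(1 - sum(pmf[seq_len(k_max)]), 0))
  0.5 * sum(abs(emp - pv))
}

# two-stage grid-search maximizer of the Lea-Coulson log-likelihood,
# independent of the package's optimizer
grid_search_m <- function(counts, m_max = 8, coarse = 1e-3, fine = 1e-4) {
  ll <- function(m) {
    p <- lea_coulson_pmf(m, max(counts))
    if (any(p[counts + 1] <= 0)) return(-Inf)
    sum(log(p[counts + 1]))
  }
  grid <- seq(coarse, m_max, by = coarse)
  vals <- vapply(grid, ll, numeric(1))
  m0 <- grid[which.max(vals)]
  grid2 <- seq(max(fine, m0 - 2 * coarse), m0 + 2 * coarse, by = fine)
  vals2 <- vapply(grid2, ll, numeric(1))
  grid2[which.max(vals2)]
}

# enumerate all 2 x K tables with the given margins; returns a list with
# the matrix of first-row vectors and their conditional probabilities
# (computed directly from choose(), not via the package)
enumerate_margin_tables <- function(row1_total, col_totals) {
  K <- length(col_totals)
  recurse <- function(j, remaining) {
    if (j == K) {
      if (remaining <= col_totals[K]) return(matrix(remaining, 1, 1))
      return(NULL)
    }
    out <- list()
    for (a in 0:min(col_totals[j], remaining)) {
      sub <- recurse(j + 1, remaining - a)
      if (!is.null(sub)) out[[length(out) + 1]] <- cbind(a, sub)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  A <- recurse(1, row1_total)
  n <- sum(col_totals)
  probs <- apply(A, 1, function(a) {
    prod(choose(col_totals, a)) / choose(n, row1_total)
  })
  list(tables = A, probs = probs)
}

# enumeration-exact p-value: total probability of tables no more probable
# than the observed one
exact_table_p <- function(t) {
  en <- enumerate_margin_tables(sum(t[1, ]), colSums(t))
  obs <- apply(en$tables, 1, function(a) all(a == t[1, ]))
  p_obs <- en$probs[which(obs)]
  sum(en$probs[en$probs <= p_obs + 1e-12])
}

# brute-force nonsense-target enumeration through Biostrings translation of
# whole mutated sequences (independent of the package's codon walk)
brute_nonsense_target <- function(cds) {
  bases <- c("A", "C", "G", "T")
  aa0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  hits <- 0
  for (i in seq_len(nchar(cds))) {
    for (b in setdiff(bases, substr(cds, i, i))) {
      mut <- cds
      substr(mut, i, i) <- b
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
      # premature stop: a stop strictly before the original protein end
      pos0 <- regexpr("*", aa0, fixed = TRUE)
      pos1 <- regexpr("*", aa, fixed = TRUE)
      if (pos1 > 0 && (pos0 < 0 || pos1 < pos0)) hits <- hits + 1
    }
  }
  hits / 3
}

# small random fluctuation experiment generator for property tests
random_small_experiment <- function() {
  n <- sample(4:12, 1)
  fluctuation_experiment(rpois(n, runif(1, 0.2, 1.5)))
}

# minimal call data frame builder
make_calls <- function(pos, freq, kind = "SNV", ref = "C", alt = "A") {
  n <- length(pos)
  data.frame(amplicon_pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             kind = rep_len(kind, n), frequency = freq,
             width = 1L, stringsAsFactors = FALSE)
}

# tiny hand-built polarized panel for unit tests: explicit genotypes,
# outgroup and metadata
tiny_panel <- function() {
  variants <- data.frame(
    chrom = "chrI", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("G", "A", "A", "C"),
    stringsAsFactors = FALSE)
  # strains: s1 haploid (hom), s2 het diploid, s3 het diploid
  gt <- matrix(c(2L, 0L, 0L,   # pos 100: s1 hom-alt
                 1L, 1L, 0L,   # pos 200
                 0L, 2L, 0L,   # pos 300: s2 hom-alt
                 0L, 0L, 1L),  # pos 400: s3 het (singleton)
               nrow = 4, byrow = TRUE)
  strains <- data.frame(name = c("s1", "s2", "s3"),
                        clade = c("c1", "c1", "c2"),
                        ploidy = c(1L, 2L, 2L),
                        zygosity = c("haploid", "heterozygous", "heterozygous"),
                        include = TRUE, stringsAsFactors = FALSE)
  outgroup <- data.frame(
    chrom = "chrI", pos = c(100L, 200L, 300L, 400L),
    og1 = c("A", "C", "A", "T"), og2 = c("A", "C", "A", "T"),
    og3 = c("A", "C", "A", "T"), og4 = c("A", "C", "A", "T"),
    og5 = c("A", "A", "G", "T"), stringsAsFactors = FALSE)
  list(panel = variant_panel(variants, gt, strains), outgroup = outgroup)
}
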