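# Synthetic-data generators. Every pipeline stage can be exercised against
# data with known ground truth: Luria-Delbruck-distributed fluctuation
# counts, pooled-amplicon pileups with sequencing error and planted MNMs,
# and polymorphism panels in which one clade's rare variants carry a C>A
# excess. All generators are pure functions of their configuration and
# seed.

#' Default strand-collapsed spectrum of segregating yeast polymorphisms
#'
#' Transition-rich (ts/tv roughly 2-3:1) with a C>A fraction of 0.10, the
#' reference point for mutator-clade simulations (a 3x multiplier yields an
#' expected rare-variant C>A fraction of 0.25 after renormalization).
#'
#' @return Named probability vector over the six substitution classes.
#' @export
base_polymorphism_spectrum <- function() {
  c("A>C" = 0.06, "A>G" = 0.32, "A>T" = 0.07,
    "C>A" = 0.10, "C>G" = 0.05, "C>T" = 0.40)
}

#' Default de novo mutation class probabilities for pooled-mutant pools
#'
#' Reporter-gene de novo spectra have a roughly 1:1 ts/tv ratio and a
#' substantial single-bp indel load; these probabilities emulate that.
#'
#' @return Named probability vector over six substitution classes plus
#'   `ins` and `del`.
#' @export
base_denovo_spectrum <- function() {
  c("A>C" = 0.06, "A>G" = 0.12, "A>T" = 0.10,
    "C>A" = 0.14, "C>G" = 0.09, "C>T" = 0.29,
    "ins" = 0.06, "del" = 0.14)
}

#' Simulate a fluctuation experiment
#'
#' Cultures grow from `n0` to `nt` cells by synchronous doubling; in each
#' generation the number of new mutants is Poisson with mean `rate` times
#' the number of divisions, and each mutant lineage doubles deterministically
#' thereafter. The expected number of mutation events per culture is
#' `m_true = rate * (nt - n0)`.
#'
#' @param rate Per-division mutation probability, in [0, 1).
#' @param n0 Initial cells per culture.
#' @param nt Final cells per culture (`n0 < nt`).
#' @param n_cultures Number of parallel cultures (default 96, one
#'   microplate).
#' @param seed RNG seed.
#' @param plated_fraction Plated fraction recorded on the experiment.
#' @return List with `experiment` (a [fluctuation_experiment()]) and
#'   `truth` (`m_true`, `rate`, `n0`, `nt`, `seed`).
#' @export
simulate_fluctuation <- function(rate, n0, nt, n_cultures = 96, seed = NULL,
                                 plated_fraction = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (n0 >= nt) stop("need n0 < nt")
  counts <- with_seed(seed, {
    if (rate == 0) {
      integer(n_cultures)
    } else {
      G <- max(1L, ceiling(log2(nt / n0)))
      d <- (nt - n0) * 2^(seq_len(G) - 1) / (2^G - 1)  # divisions per generation
      cnt <- numeric(n_cultures)
      for (i in seq_len(G)) {
        cnt <- cnt + rpois(n_cultures, rate * d[i]) * 2^(G - i)
      }
      cnt
    }
  })
  list(experiment = fluctuation_experiment(counts,
                                           plated_fraction = plated_fraction,
                                           strain = "sim"),
       truth = list(m_true = rate * (nt - n0), rate = rate, n0 = n0, nt = nt,
                    seed = seed))
}

# place one planted substitution: choose a strand orientation for the
# class, then a free position whose reference base matches
place_snv <- function(class, ref_seq, free) {
  from <- substr(class, 1, 1); to <- substr(class, 3, 3)
  if (runif(1) < 0.5) { from <- unname(COMPLEMENT[from]); to <- unname(COMPLEMENT[to]) }
  cand <- free[ref_seq[free] == from]
  if (!length(cand)) {  # fall back to the other strand
    from2 <- unname(COMPLEMENT[from]); to2 <- unname(COMPLEMENT[to])
    cand <- free[ref_seq[free] == from2]
    if (!length(cand)) return(NULL)
    from <- from2; to <- to2
  }
  pos <- cand[sample.int(length(cand), 1)]
  list(pos = pos, ref = from, alt = to)
}

#' Simulate a pooled-mutant amplicon pileup
#'
#' `n_mutants` mutants are pooled in equal proportions, so each planted
#' mutation has expected frequency `1/n_mutants`; per-position allele counts
#' are multinomial at the given depth with a uniform, strand-symmetric
#' per-base error rate. A fraction of mutants instead carry a two-site MNM
#' within 10 bp, with read-pair co-occurrence near 1. Read-pair
#' co-occurrence records are emitted for all planted pairs within
#' `mnm_window`.
#'
#' @param n_mutants Pool size N (<= 40 recommended).
#' @param class_probs Named probability vector over planted-event classes
#'   (six substitution classes, optionally `ins`/`del`); default
#'   [base_denovo_spectrum()].
#' @param depth Read depth per position (>= 200).
#' @param error_rate Per-base sequencing error probability; the expected
#'   mutation frequency must exceed twice this rate.
#' @param mnm_fraction Fraction of mutants carrying a 2-site MNM.
#' @param amplicon_length Amplicon length in bp.
#' @param callable_interval Callable positions (1-based inclusive); default
#'   trims 30 bp from each end.
#' @param mnm_window Maximum MNM member distance (bp).
#' @param seed RNG seed.
#' @return List with `pileup`, `cooccurrence`, `ref_seq`, `config` and
#'   `truth` (planted events: `mutant_id, pos, ref, alt, kind, class,
#'   mnm_id, freq_expected`).
#' @export
simulate_pool <- function(n_mutants = 38, class_probs = base_denovo_spectrum(),
                          depth = 2000, error_rate = 0.003,
                          mnm_fraction = 0, amplicon_length = 1800,
                          callable_interval = NULL, mnm_window = 10,
                          seed = NULL) {
  if (n_mutants < 1) stop("n_mutants must be >= 1")
  if (depth < 200) stop("depth must be >= 200")
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (1 / n_mutants <= 2 * error_rate) {
    stop("expected mutation frequency 1/N <= 2 * error rate: pool uncallable by design")
  }
  if (is.null(callable_interval)) {
    callable_interval <- c(31L, amplicon_length - 30L)
  }
  with_seed(seed, {
    ref_seq <- sample(BASES, amplicon_length, replace = TRUE)
    callable <- seq(callable_interval[1], callable_interval[2])
    f_exp <- 1 / n_mutants
    n_mnm <- round(mnm_fraction * n_mutants)
    snv_classes <- intersect(names(class_probs), MUT_CLASSES)
    snv_probs <- class_probs[snv_classes] / sum(class_probs[snv_classes])

    events <- list()
    used <- integer(0)
    mnm_counter <- 0L
    for (mid in seq_len(n_mutants)) {
      free <- setdiff(callable, used)
      if (mid <= n_mnm) {
        # two-site MNM: both substitutions, within mnm_window
        mnm_counter <- mnm_counter + 1L
        e1 <- place_snv(sample(snv_classes, 1, prob = snv_probs), ref_seq, free)
        near <- setdiff(free, e1$pos)
        near <- near[abs(near - e1$pos) <= mnm_window]
        e2 <- place_snv(sample(snv_classes, 1, prob = snv_probs), ref_seq, near)
        if (is.null(e2)) e2 <- place_snv("C>T", ref_seq, near)
        ev <- rbind(
          data.frame(mutant_id = mid, pos = e1$pos, ref = e1$ref, alt = e1$alt,
                     kind = "SNV", mnm_id = mnm_counter),
          data.frame(mutant_id = mid, pos = e2$pos, ref = e2$ref, alt = e2$alt,
                     kind = "SNV", mnm_id = mnm_counter))
      } else {
        cls <- sample(names(class_probs), 1, prob = class_probs)
        if (cls %in% MUT_CLASSES) {
          e <- place_snv(cls, ref_seq, free)
          ev <- data.frame(mutant_id = mid, pos = e$pos, ref = e$ref,
                           alt = e$alt, kind = "SNV", mnm_id = NA_integer_)
        } else {
          pos <- free[sample.int(length(free), 1)]
          ev <- data.frame(mutant_id = mid, pos = pos, ref = ref_seq[pos],
                           alt = toupper(substr(cls, 1, 1)),
                           kind = if (cls == "ins") "insertion" else "deletion",
                           mnm_id = NA_integer_)
        }
      }
      used <- c(used, ev$pos)
      events[[mid]] <- ev
    }
    truth <- do.call(rbind, events)
    truth$class <- truth$kind
    snv_rows <- truth$kind == "SNV"
    truth$class[snv_rows] <- collapse_class(truth$ref[snv_rows],
                                            truth$alt[snv_rows])
    truth$freq_expected <- f_exp

    # pileup: error-only background, then overwrite planted positions
    L <- amplicon_length
    err_counts <- matrix(rbinom(3 * L, depth, error_rate / 3), nrow = 3)
    counts <- matrix(0L, 4, L, dimnames = list(BASES, NULL))
    for (b in BASES) {
      at <- which(ref_seq == b)
      others <- setdiff(BASES, b)
      counts[others, at] <- err_counts[, at]
      counts[b, at] <- depth - colSums(err_counts[, at, drop = FALSE])
    }
    ins_c <- integer(L); del_c <- integer(L)
    snv_events <- truth[truth$kind == "SNV", ]
    for (p in unique(snv_events$pos)) {
      here <- snv_events[snv_events$pos == p, ]
      p_true <- setNames(numeric(4), BASES)
      p_true[ref_seq[p]] <- 1 - nrow(here) * f_exp
      for (r in seq_len(nrow(here))) p_true[here$alt[r]] <- p_true[here$alt[r]] + f_exp
      # uniform strand-symmetric miscall channel
      p_obs <- p_true * (1 - error_rate) + (sum(p_true) - p_true) * error_rate / 3
      counts[, p] <- rmultinom(1, depth, p_obs)
    }
    ind_events <- truth[truth$kind != "SNV", ]
    for (r in seq_len(nrow(ind_events))) {
      p <- ind_events$pos[r]
      n <- rbinom(1, depth, f_exp)
      if (ind_events$kind[r] == "insertion") ins_c[p] <- ins_c[p] + n
      else del_c[p] <- del_c[p] + n
    }
    pileup <- data.frame(pos = seq_len(L), ref = ref_seq, depth = depth,
                         A = counts["A", ], C = counts["C", ],
                         G = counts["G", ], T = counts["T", ],
                         ins = ins_c, del = del_c,
                         stringsAsFactors = FALSE)

    # co-occurrence for planted pairs within the MNM window
    cooc <- list()
    n_ev <- nrow(truth)
    alt_of <- ifelse(truth$kind == "SNV", truth$alt,
                     toupper(substr(truth$kind, 1, 1)))
    for (i in seq_len(max(n_ev - 1, 0))) {
      for (j in (i + 1):n_ev) {
        if (abs(truth$pos[j] - truth$pos[i]) > mnm_window) next
        same <- truth$mutant_id[i] == truth$mutant_id[j]
        if (same) {
          rb <- rbinom(1, depth, f_exp)
          ra <- rb + rbinom(1, depth, error_rate * f_exp)
        } else {
          rb <- rbinom(1, depth, error_rate * f_exp)
          ra <- rb + rbinom(1, depth, 2 * f_exp)
        }
        cooc[[length(cooc) + 1]] <- data.frame(
          pos_i = truth$pos[i], alt_i = alt_of[i],
          pos_j = truth$pos[j], alt_j = alt_of[j],
          reads_both = rb, reads_any = max(ra, 1))
      }
    }
    cooccurrence <- if (length(cooc)) do.call(rbind, cooc) else
      data.frame(pos_i = integer(0), alt_i = character(0),
                 pos_j = integer(0), alt_j = character(0),
                 reads_both = integer(0), reads_any = integer(0))
    cfg <- pool_config(n_mutants = n_mutants,
                       callable_interval = callable_interval)
    list(pileup = pileup, cooccurrence = cooccurrence, ref_seq = ref_seq,
         config = cfg,
         truth = truth[order(truth$pos), ],
         seed = seed)
  })
}

#' Simulate a polymorphism panel with a C>A-enriched mutator clade
#'
#' Strains are organized into clades; variants arise in an originating
#' clade, draw their derived allele count k from a decreasing law
#' (P(k) proportional to 1/k, k <= `ac_max`), and are carried het by k
#' strains of that clade (spilling over at random when k exceeds the clade
#' size), producing clade-clustered spectra. Rare variants (AC <=
#' `rare_ac_max`) originating in the mutator clade draw their class from
#' the base spectrum with its C>A probability multiplied by `ca_multiplier`
#' and renormalized. Reference/ancestral encodings and a 5-strain outgroup
#' table with occasional disagreement are emitted so the polarization and
#' filtering machinery is fully exercised.
#'
#' @param n_clades,strains_per_clade Panel layout (defaults 8 x 20).
#' @param n_variants_per_strain Expected variants carried per strain
#'   (default 2000).
#' @param base_spectrum Class probabilities for non-mutator variants.
#' @param mutator_clade Index of the mutator clade (1-based), or 0 for no
#'   mutator.
#' @param ca_multiplier C>A multiplier for mutator-clade rare variants
#'   (>= 1; default 3).
#' @param rare_ac_max Largest derived allele count shifted in the mutator
#'   clade (default 4).
#' @param ac_max Largest derived allele count generated (default 20).
#' @param missing_rate Per-genotype missingness rate.
#' @param seed RNG seed.
#' @return List with `panel` (a [variant_panel()]), `outgroup`, `mappable`,
#'   `repeats` (BED-convention data frames) and `truth`.
#' @export
simulate_panel <- function(n_clades = 8, strains_per_clade = 20,
                           n_variants_per_strain = 2000,
                           base_spectrum = base_polymorphism_spectrum(),
                           mutator_clade = 1, ca_multiplier = 3,
                           rare_ac_max = 4, ac_max = 20,
                           missing_rate = 0.01, seed = NULL) {
  if (ca_multiplier < 1) stop("ca_multiplier must be >= 1")
  if (abs(sum(base_spectrum) - 1) > 1e-8) stop("base_spectrum must sum to 1")
  if (mutator_clade > 0 && base_spectrum[["C>A"]] == 0) {
    stop("C>A multiplier applied to a class with zero base probability")
  }
  mut_spectrum <- base_spectrum
  mut_spectrum["C>A"] <- mut_spectrum["C>A"] * ca_multiplier
  mut_spectrum <- mut_spectrum / sum(mut_spectrum)

  S <- n_clades * strains_per_clade
  clades <- paste0("clade_", rep(seq_len(n_clades), each = strains_per_clade))
  strains <- data.frame(
    name = sprintf("strain_%03d", seq_len(S)),
    clade = clades, ploidy = 2L, zygosity = "heterozygous",
    include = TRUE, stringsAsFactors = FALSE)

  k_probs <- (1 / seq_len(ac_max)) / sum(1 / seq_len(ac_max))
  e_k <- sum(seq_len(ac_max) * k_probs)
  V <- round(n_variants_per_strain * S / e_k)

  with_seed(seed, {
    origin_strain <- sample.int(S, V, replace = TRUE)
    origin_clade <- (origin_strain - 1L) %/% strains_per_clade + 1L
    k <- pmin(sample.int(ac_max, V, replace = TRUE, prob = k_probs), S)

    is_mut <- origin_clade == mutator_clade & k <= rare_ac_max
    cls <- character(V)
    if (any(is_mut)) {
      cls[is_mut] <- sample(names(mut_spectrum), sum(is_mut), replace = TRUE,
                            prob = mut_spectrum)
    }
    cls[!is_mut] <- sample(names(base_spectrum), sum(!is_mut), replace = TRUE,
                           prob = base_spectrum)

    # ancestral/derived alleles with a random strand orientation
    anc <- substr(cls, 1, 1); der <- substr(cls, 3, 3)
    flip <- runif(V) < 0.5
    anc[flip] <- COMPLEMENT[anc[flip]]; der[flip] <- COMPLEMENT[der[flip]]

    # carriers: within the originating clade first, then random spillover.
    # Per clade, draw a random ranking of the members for every variant and
    # take the first k; vectorized via a two-key order() per clade.
    clade_members <- split(seq_len(S), (seq_len(S) - 1L) %/% strains_per_clade + 1L)
    gt <- matrix(0L, V, S)
    for (cl in seq_len(n_clades)) {
      rows <- which(origin_clade == cl)
      if (!length(rows)) next
      mem <- clade_members[[cl]]
      m <- length(mem)
      n_r <- length(rows)
      kk <- pmin(k[rows], m)
      u <- matrix(runif(n_r * m), n_r, m)
      colm <- matrix(((order(row(u), u) - 1L) %/% n_r) + 1L, n_r, m, byrow = TRUE)
      sel <- cbind(rep(seq_len(n_r), kk), sequence(kk))
      ii <- rows[sel[, 1]]
      jj <- mem[colm[sel]]
      gt[cbind(ii, jj)] <- 1L
      over <- rows[k[rows] > m]  # spillover beyond the clade, at random
      for (v in over) {
        extra <- sample(setdiff(seq_len(S), mem), k[v] - m)
        gt[v, extra] <- 1L
      }
    }

    # ref = ancestral for most sites; a minority encode ref = derived so
    # polarization must consult the outgroup rather than trust ref
    ref_is_anc <- runif(V) < 0.9
    ref <- ifelse(ref_is_anc, anc, der)
    alt <- ifelse(ref_is_anc, der, anc)
    flip_rows <- which(!ref_is_anc)
    if (length(flip_rows)) {
      gt[flip_rows, ] <- 2L - gt[flip_rows, , drop = FALSE]
    }
    if (missing_rate > 0) {
      nmiss <- rbinom(1, V * S, missing_rate)
      miss_idx <- sample.int(V * S, nmiss)
      gt[miss_idx] <- NA_integer_
    }

    pos <- cumsum(sample(5:15, V, replace = TRUE))
    variants <- data.frame(chrom = "chrI", pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)

    # 5-strain outgroup: ancestral everywhere, with occasional single-strain
    # disagreement (still callable) and rare 3-2 splits (uncallable)
    og <- matrix(rep(anc, 5), V, 5)
    noisy <- runif(V) < 0.03
    if (any(noisy)) {
      w <- which(noisy)
      og[cbind(w, sample.int(5, length(w), replace = TRUE))] <-
        sample(BASES, length(w), replace = TRUE)
    }
    split3 <- runif(V) < 0.02
    if (any(split3)) {
      w <- which(split3)
      og[w, 1:2] <- cbind(der[w], der[w])
      og[w, 3] <- der[w]
    }
    outgroup <- data.frame(chrom = "chrI", pos = pos,
                           og1 = og[, 1], og2 = og[, 2], og3 = og[, 3],
                           og4 = og[, 4], og5 = og[, 5],
                           stringsAsFactors = FALSE)

    mappable <- data.frame(chrom = "chrI", start = 0L,
                           end = max(pos) + 10L)
    repeats <- data.frame(chrom = "chrI", start = max(pos) + 5L,
                          end = max(pos) + 6L)

    expected_ca <- unname(mut_spectrum["C>A"])
    truth <- list(
      mutator_clade = if (mutator_clade > 0) paste0("clade_", mutator_clade) else NA,
      mutator_strains = if (mutator_clade > 0)
        strains$name[clades == paste0("clade_", mutator_clade)] else character(0),
      base_ca_fraction = unname(base_spectrum["C>A"]),
      mutator_rare_ca_fraction = expected_ca,
      classes = cls, k = k, seed = seed)
    list(panel = variant_panel(variants, gt, strains),
         outgroup = outgroup, mappable = mappable, repeats = repeats,
         truth = truth)
  })
}

#' Generate a random CDS fixture with amplicon map
#'
#' A random open reading frame (ATG start, no internal stops, terminal
#' stop), embedded in an amplicon with random flanks: a synthetic stand-in
#' for a reporter-gene amplicon.
#'
#' @param n_codons Number of codons including start and stop (>= 10).
#' @param flank Flank length on each side of the CDS.
#' @param orf_strand Strand of the ORF relative to the amplicon.
#' @param seed RNG seed.
#' @return List with `amplicon_seq`, `cds_seq` (both character) and `amap`
#'   (an [amplicon_map()]).
#' @export
make_cds_fixture <- function(n_codons = 60, flank = 30, orf_strand = "+",
                             seed = NULL) {
  if (n_codons < 10) stop("need at least 10 codons")
  with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
    insert <- if (orf_strand == "+") cds else revcomp(cds)
    amplicon <- paste0(paste(sample(BASES, flank, replace = TRUE), collapse = ""),
                       insert,
                       paste(sample(BASES, flank, replace = TRUE), collapse = ""))
    amap <- amplicon_map(chrom = "chrV", genome_start = 100000L,
                         orf_strand = orf_strand,
                         cds_start = flank + 1L,
                         cds_end = flank + nchar(cds),
                         amplicon_length = nchar(amplicon))
    list(amplicon_seq = amplicon, cds_seq = cds, amap = amap)
  })
}

# reverse complement of a character DNA string
revcomp <- function(x) {
  paste(rev(unname(COMPLEMENT[strsplit(toupper(x), "")[[1]]])), collapse = "")
}
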