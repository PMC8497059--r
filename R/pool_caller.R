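# Mutation calling from pooled-mutant amplicon pileups. A pool of N
# independent reporter-gene mutants is sequenced deeply; each true mutation
# is expected at frequency ~1/N, so calls are restricted to a frequency
# window [0.65/N, 0.95]: alleles below the window are treated as sequencing
# errors and alleles above it as fixed strain-specific SNPs. Nearby calls at
# similar frequencies supported by the same read pairs are merged into
# multinucleotide mutations (MNMs); outlying frequencies indicate that the
# same mutation arose in several pooled mutants (multiplicity).

#' Pool-calling configuration
#'
#' Holds the pool size and all calling thresholds. Defaults match the
#' published pipeline: frequency window `[0.65/N, 0.95]`, minimum depth 200,
#' pool QC failure below 40% callable amplicon coverage, MNM candidates
#' within 10 bp at frequencies within +/-0.09 confirmed by >= 70% read-pair
#' co-occurrence, adjacent indels merged when frequencies differ by < 0.10,
#' and multiplicity assigned above mean + 2 SD of the pool's call
#' frequencies.
#'
#' @param n_mutants Number of mutants pooled (N). Pools of up to ~40 keep
#'   1/N well above typical per-base error rates.
#' @param callable_interval Length-2 integer vector, 1-based inclusive
#'   amplicon positions considered callable (ends of amplicons are excluded
#'   upstream for low coverage).
#' @param lower_factor,upper_freq Frequency window: calls require
#'   `lower_factor / n_mutants <= f <= upper_freq`.
#' @param min_depth Minimum read depth per site.
#' @param min_callable_fraction Pool QC fails when fewer than this fraction
#'   of amplicon positions pass the depth filter.
#' @param mnm_window Maximum distance (bp) between MNM member candidates.
#' @param mnm_freq_tol Maximum absolute frequency difference between MNM
#'   member candidates.
#' @param mnm_cooccur_min Minimum fraction of informative read pairs
#'   carrying both alternate alleles.
#' @param indel_merge_tol Maximum absolute frequency difference for merging
#'   adjacent indels.
#' @param multiplicity_sd_k Number of SDs above the mean frequency beyond
#'   which a call is assigned multiplicity > 1.
#' @return Object of class `pool_config`.
#' @export
pool_config <- function(n_mutants, callable_interval,
                        lower_factor = 0.65, upper_freq = 0.95,
                        min_depth = 200, min_callable_fraction = 0.40,
                        mnm_window = 10, mnm_freq_tol = 0.09,
                        mnm_cooccur_min = 0.70, indel_merge_tol = 0.10,
                        multiplicity_sd_k = 2) {
  if (n_mutants < 1) stop("n_mutants must be >= 1")
  if (!(lower_factor / n_mutants < upper_freq && upper_freq < 1)) {
    stop("need 0 < lower_factor/n_mutants < upper_freq < 1")
  }
  tols <- c(mnm_freq_tol, mnm_cooccur_min, indel_merge_tol,
            min_callable_fraction)
  if (any(tols < 0 | tols > 1)) stop("tolerances must lie in [0, 1]")
  if (length(callable_interval) != 2 ||
      callable_interval[1] > callable_interval[2]) {
    stop("callable_interval must be c(start, end) with start <= end")
  }
  structure(list(n_mutants = as.integer(n_mutants),
                 callable_interval = as.integer(callable_interval),
                 lower_factor = lower_factor, upper_freq = upper_freq,
                 min_depth = min_depth,
                 min_callable_fraction = min_callable_fraction,
                 mnm_window = mnm_window, mnm_freq_tol = mnm_freq_tol,
                 mnm_cooccur_min = mnm_cooccur_min,
                 indel_merge_tol = indel_merge_tol,
                 multiplicity_sd_k = multiplicity_sd_k),
            class = "pool_config")
}

#' Depth-filter pileup sites and compute the pool QC verdict
#'
#' Removes sites outside the callable interval or with depth below
#' `min_depth`; the pool fails QC when the passing fraction of the amplicon
#' falls below `min_callable_fraction`.
#'
#' @param pileup Pileup data frame (`pos, ref, depth, A, C, G, T, ins, del`),
#'   sorted by position; see [load_pileup()].
#' @param cfg A [pool_config()].
#' @return List with `sites` (retained pileup rows) and `qc` (list:
#'   `callable_fraction`, `verdict` "PASS"/"FAIL").
#' @export
filter_sites <- function(pileup, cfg) {
  if (is.null(pileup) || nrow(pileup) == 0) stop("empty pileup")
  iv <- cfg$callable_interval
  keep <- pileup$pos >= iv[1] & pileup$pos <= iv[2] &
    pileup$depth >= cfg$min_depth
  width <- iv[2] - iv[1] + 1
  frac <- sum(keep) / width
  list(sites = pileup[keep, , drop = FALSE],
       qc = list(callable_fraction = frac,
                 verdict = if (frac < cfg$min_callable_fraction) "FAIL" else "PASS"))
}

#' Call point mutations and raw indels from filtered pileup sites
#'
#' One call per non-reference allele whose frequency f satisfies
#' `lower_factor/N <= f <= upper_freq`. Alleles below the window are
#' discarded as sequencing errors; alleles above it are routed to a
#' fixed-allele set (strain-specific SNPs, used by
#' [strain_identity_check()]), not reported as mutations.
#'
#' @param sites Filtered pileup rows from [filter_sites()].
#' @param cfg A [pool_config()].
#' @return List with `calls` and `fixed`, both data frames with columns
#'   `amplicon_pos, ref, alt, kind, frequency, width`.
#' @export
call_point_mutations <- function(sites, cfg) {
  if (cfg$n_mutants < 1) stop("n_mutants must be >= 1")
  lower <- cfg$lower_factor / cfg$n_mutants
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    alleles <- c(setdiff(BASES, s$ref), "ins", "del")
    for (al in alleles) {
      cnt <- if (al == "ins") s$ins else if (al == "del") s$del else s[[al]]
      if (is.na(cnt) || cnt == 0) next
      f <- cnt / s$depth
      if (f < lower) next
      kind <- switch(al, ins = "insertion", del = "deletion", "SNV")
      rows[[length(rows) + 1]] <- data.frame(
        amplicon_pos = s$pos, ref = s$ref,
        alt = if (kind == "SNV") al else toupper(substr(kind, 1, 1)),
        kind = kind, frequency = f, width = 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amplicon_pos = integer(0), ref = character(0),
               alt = character(0), kind = character(0),
               frequency = numeric(0), width = integer(0))
  fixed <- out$frequency > cfg$upper_freq
  list(calls = out[!fixed, , drop = FALSE],
       fixed = out[fixed, , drop = FALSE])
}

#' Merge runs of adjacent same-kind indel calls
#'
#' Indel calls at directly adjacent positions whose frequencies differ by
#' less than `indel_merge_tol` are treated as a single event: merged into
#' one call at the leftmost position with the mean frequency and a `width`
#' equal to the run length (multi-bp indels are later excluded from
#' single-bp indel spectra).
#'
#' @param calls Call data frame sorted by `amplicon_pos`.
#' @param cfg A [pool_config()].
#' @return Call data frame with merged indel runs.
#' @export
merge_adjacent_indels <- function(calls, cfg) {
  if (nrow(calls) == 0) return(calls)
  calls <- calls[order(calls$amplicon_pos), , drop = FALSE]
  is_indel <- calls$kind %in% c("insertion", "deletion")
  keep <- rep(TRUE, nrow(calls))
  i <- 1
  while (i <= nrow(calls)) {
    if (!is_indel[i] || !keep[i]) { i <- i + 1; next }
    run <- i
    j <- i
    repeat {
      nxt <- which(is_indel & keep & seq_len(nrow(calls)) > j &
                     calls$kind == calls$kind[i] &
                     calls$amplicon_pos == calls$amplicon_pos[j] + 1)
      nxt <- nxt[1]
      if (is.na(nxt) ||
          abs(calls$frequency[nxt] - calls$frequency[j]) >= cfg$indel_merge_tol) break
      run <- c(run, nxt)
      j <- nxt
    }
    if (length(run) > 1) {
      calls$frequency[i] <- mean(calls$frequency[run])
      calls$width[i] <- length(run)
      keep[run[-1]] <- FALSE
    }
    i <- j + 1
  }
  calls[keep, , drop = FALSE]
}

cooc_key <- function(pos_i, alt_i, pos_j, alt_j) {
  swap <- pos_j < pos_i
  a <- ifelse(swap, pos_j, pos_i); b <- ifelse(swap, pos_i, pos_j)
  aa <- ifelse(swap, alt_j, alt_i); ab <- ifelse(swap, alt_i, alt_j)
  paste(a, aa, b, ab, sep = ":")
}

#' Detect multinucleotide mutations from read-pair co-occurrence
#'
#' Candidate pairs are calls within `mnm_window` bp at frequencies within
#' `mnm_freq_tol` of each other; a pair becomes an MNM when both alternate
#' alleles co-occur on at least `mnm_cooccur_min` of the read pairs carrying
#' either. MNMs sharing a member are merged into complex MNMs (transitive
#' closure). Member calls are flagged `in_mnm` and excluded from
#' single-mutation spectra.
#'
#' @param calls Call data frame.
#' @param cooccurrence Data frame `pos_i, alt_i, pos_j, alt_j, reads_both,
#'   reads_any` (read pairs carrying both alts / covering both sites with at
#'   least one alt).
#' @param cfg A [pool_config()].
#' @return List with `calls` (input plus `in_mnm` flag), `mnms` (data frame
#'   `mnm_id, amplicon_pos, alt, frequency, min_support, n_members`), and
#'   `unresolved` (candidate pairs lacking a co-occurrence record).
#' @export
detect_mnms <- function(calls, cooccurrence, cfg) {
  n <- nrow(calls)
  calls <- calls[order(calls$amplicon_pos, calls$alt), , drop = FALSE]
  calls$in_mnm <- rep(FALSE, n)
  if (n < 2) {
    return(list(calls = calls,
                mnms = data.frame(mnm_id = integer(0), amplicon_pos = integer(0),
                                  alt = character(0), frequency = numeric(0),
                                  min_support = numeric(0), n_members = integer(0)),
                unresolved = data.frame(pos_i = integer(0), pos_j = integer(0))))
  }
  keys <- if (nrow(cooccurrence)) {
    setNames(cooccurrence$reads_both / pmax(cooccurrence$reads_any, 1),
             cooc_key(cooccurrence$pos_i, cooccurrence$alt_i,
                      cooccurrence$pos_j, cooccurrence$alt_j))
  } else setNames(numeric(0), character(0))

  edges <- list(); unresolved <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- abs(calls$amplicon_pos[j] - calls$amplicon_pos[i])
      if (d > cfg$mnm_window || d == 0) next
      if (abs(calls$frequency[j] - calls$frequency[i]) > cfg$mnm_freq_tol) next
      key <- cooc_key(calls$amplicon_pos[i], calls$alt[i],
                      calls$amplicon_pos[j], calls$alt[j])
      if (!key %in% names(keys)) {
        unresolved[[length(unresolved) + 1]] <-
          data.frame(pos_i = calls$amplicon_pos[i], pos_j = calls$amplicon_pos[j])
        next
      }
      if (keys[[key]] >= cfg$mnm_cooccur_min) {
        edges[[length(edges) + 1]] <- c(i, j, keys[[key]])
      }
    }
  }
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  support <- rep(Inf, n)
  for (e in edges) {
    a <- find(e[1]); b <- find(e[2])
    if (a != b) comp[max(a, b)] <- min(a, b)
    support[e[1]] <- min(support[e[1]], e[3])
    support[e[2]] <- min(support[e[2]], e[3])
  }
  root <- vapply(seq_len(n), find, numeric(1))
  sizes <- table(root)
  mnm_roots <- as.integer(names(sizes)[sizes >= 2])
  mnm_rows <- list()
  for (k in seq_along(mnm_roots)) {
    members <- which(root == mnm_roots[k])
    calls$in_mnm[members] <- TRUE
    mnm_rows[[k]] <- data.frame(mnm_id = k,
                                amplicon_pos = calls$amplicon_pos[members],
                                alt = calls$alt[members],
                                frequency = calls$frequency[members],
                                min_support = min(support[members]),
                                n_members = length(members))
  }
  list(calls = calls,
       mnms = if (length(mnm_rows)) do.call(rbind, mnm_rows) else
         data.frame(mnm_id = integer(0), amplicon_pos = integer(0),
                    alt = character(0), frequency = numeric(0),
                    min_support = numeric(0), n_members = integer(0)),
       unresolved = if (length(unresolved)) do.call(rbind, unresolved) else
         data.frame(pos_i = integer(0), pos_j = integer(0)))
}

#' Assign multiplicities from outlying call frequencies
#'
#' A mutation shared by several pooled mutants appears at a multiple of the
#' typical frequency. Let mu and sigma be the mean and population SD of all
#' call frequencies in the pool; calls with `f > mu + k sigma` (k =
#' `multiplicity_sd_k`) receive multiplicity `round(f / mu)`, all others 1.
#'
#' @param calls Call data frame for one pool.
#' @param cfg A [pool_config()].
#' @return `calls` with a `multiplicity` column.
#' @export
estimate_multiplicity <- function(calls, cfg) {
  n <- nrow(calls)
  if (n == 0) { calls$multiplicity <- integer(0); return(calls) }
  if (n == 1) {
    warning("single call in pool: multiplicity defaults to 1")
    calls$multiplicity <- 1L
    return(calls)
  }
  f <- calls$frequency
  mu <- mean(f)
  sigma <- sqrt(mean((f - mu)^2))  # population SD
  thr <- mu + cfg$multiplicity_sd_k * sigma
  mult <- rep(1L, n)
  out <- f > thr
  mult[out] <- pmax(1L, as.integer(round(f[out] / mu)))
  calls$multiplicity <- mult
  calls
}

#' Amplicon-to-genome coordinate map
#'
#' @param chrom Genome chromosome name.
#' @param genome_start Genome coordinate (1-based) of amplicon position 1;
#'   the amplicon is collinear with the genome.
#' @param orf_strand Strand of the reporter ORF relative to the amplicon
#'   ("+" or "-"); used by [annotate_consequence()].
#' @param cds_start,cds_end 1-based inclusive amplicon positions of the CDS.
#' @param amplicon_length Amplicon length in bp.
#' @return Object of class `amplicon_map`.
#' @export
amplicon_map <- function(chrom, genome_start, orf_strand, cds_start, cds_end,
                         amplicon_length) {
  if (!orf_strand %in% c("+", "-")) stop("orf_strand must be '+' or '-'")
  if ((cds_end - cds_start + 1) %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (cds_start < 1 || cds_end > amplicon_length) stop("CDS outside amplicon")
  structure(list(chrom = chrom, genome_start = as.integer(genome_start),
                 orf_strand = orf_strand, cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 amplicon_length = as.integer(amplicon_length)),
            class = "amplicon_map")
}

#' Map calls to genome coordinates and strand-collapsed classes
#'
#' @param calls Call data frame with `amplicon_pos`.
#' @param amap An [amplicon_map()].
#' @return `calls` with `genome_chrom`, `genome_pos` and (for SNVs) a
#'   strand-collapsed `class` column.
#' @export
map_to_genome <- function(calls, amap) {
  if (nrow(calls) &&
      (any(calls$amplicon_pos < 1) || any(calls$amplicon_pos > amap$amplicon_length))) {
    stop("call position outside amplicon map")
  }
  calls$genome_chrom <- rep(amap$chrom, nrow(calls))
  calls$genome_pos <- amap$genome_start + calls$amplicon_pos - 1L
  calls$class <- rep(NA_character_, nrow(calls))
  snv <- calls$kind == "SNV"
  if (any(snv)) calls$class[snv] <- collapse_class(calls$ref[snv], calls$alt[snv])
  calls
}

#' Annotate coding consequences with the standard genetic code
#'
#' SNVs inside the CDS are classified as synonymous, missense or nonsense by
#' codon translation (ORF strand-aware); indels are "indel" and calls
#' outside the CDS "noncoding".
#'
#' @param calls Call data frame (amplicon coordinates).
#' @param cds_seq CDS sequence (character or [Biostrings::DNAString]), given
#'   5'->3' on the ORF strand, length a multiple of 3.
#' @param amap An [amplicon_map()].
#' @return `calls` with a `consequence` column.
#' @export
annotate_consequence <- function(calls, cds_seq, amap) {
  cds <- toupper(as.character(cds_seq))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (nchar(cds) != amap$cds_end - amap$cds_start + 1) {
    stop("CDS length does not match amplicon map")
  }
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(codon) unname(code[codon])
  calls$consequence <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    pos <- calls$amplicon_pos[i]
    if (calls$kind[i] != "SNV") { calls$consequence[i] <- "indel"; next }
    if (pos < amap$cds_start || pos > amap$cds_end) {
      calls$consequence[i] <- "noncoding"; next
    }
    if (amap$orf_strand == "+") {
      cpos <- pos - amap$cds_start + 1L
      alt <- calls$alt[i]
    } else {
      cpos <- amap$cds_end - pos + 1L
      alt <- unname(COMPLEMENT[calls$alt[i]])
    }
    ci <- (cpos - 1L) %/% 3L
    off <- (cpos - 1L) %% 3L + 1L
    codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
    new_codon <- codon
    substr(new_codon, off, off) <- alt
    aa_old <- translate1(codon); aa_new <- translate1(new_codon)
    calls$consequence[i] <-
      if (aa_old == aa_new) "synonymous"
      else if (aa_new == "*") "nonsense"
      else "missense"
  }
  calls
}

#' Check strain identity from fixed alleles
#'
#' Fixed non-reference alleles (frequency above the calling window) should
#' match the strain's known SNPs against the reference used for mapping.
#'
#' @param fixed Fixed-allele data frame from [call_point_mutations()].
#' @param expected Data frame of the expected strain SNPs with columns
#'   `amplicon_pos, alt`.
#' @param min_match Minimum matching fraction for a PASS (default 0.9).
#' @return List: `match_fraction`, `verdict` ("PASS"/"FAIL"/"WARN").
#' @export
strain_identity_check <- function(fixed, expected, min_match = 0.9) {
  if (nrow(fixed) == 0) {
    verdict <- if (nrow(expected) > 0) "WARN" else "PASS"
    return(list(match_fraction = NA_real_, verdict = verdict))
  }
  key_f <- paste(fixed$amplicon_pos, fixed$alt)
  key_e <- paste(expected$amplicon_pos, expected$alt)
  frac <- mean(key_f %in% key_e)
  list(match_fraction = frac,
       verdict = if (frac >= min_match) "PASS" else "FAIL")
}

#' Per-strain de novo mutation spectrum from pooled calls
#'
#' Counts calls over the six strand-collapsed substitution classes plus
#' single base-pair insertions and deletions, each counted `multiplicity`
#' times. MNM members and multi-bp indels are excluded.
#'
#' @param calls Annotated call data frame (after [detect_mnms()],
#'   [estimate_multiplicity()] and [map_to_genome()]); several pools' calls
#'   for the same strain may be concatenated.
#' @param include_indels Include single-bp indel categories (default TRUE).
#' @return A [spectrum_counts()] object.
#' @export
pool_spectrum <- function(calls, include_indels = TRUE) {
  if (!nrow(calls)) {
    warning("no usable calls: empty spectrum")
    return(spectrum_counts(include_indels = include_indels))
  }
  if (is.null(calls$in_mnm)) calls$in_mnm <- FALSE
  if (is.null(calls$multiplicity)) calls$multiplicity <- 1L
  use <- !calls$in_mnm &
    (calls$kind == "SNV" | (include_indels & calls$width == 1L))
  calls <- calls[use, , drop = FALSE]
  if (!nrow(calls)) {
    warning("no usable calls: empty spectrum")
    return(spectrum_counts(include_indels = include_indels))
  }
  cls <- ifelse(calls$kind == "insertion", "ins",
                ifelse(calls$kind == "deletion", "del", NA_character_))
  snv <- calls$kind == "SNV"
  cls[snv] <- collapse_class(calls$ref[snv], calls$alt[snv])
  counts <- tapply(calls$multiplicity, cls, sum)
  spectrum_counts(setNames(as.numeric(counts), names(counts)),
                  include_indels = include_indels)
}
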