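# Mutation spectra from panel polymorphisms. Biallelic SNPs are polarized
# against an outgroup (ancestral = allele fixed in >= 4 of 5 outgroup
# strains), filtered on missingness, mappability, repeats and derived allele
# frequency, and summarized per strain as strand-collapsed spectra of
# ancestral -> derived changes. PCA over normalized spectra and a C>A
# enrichment scan over rare variants identify candidate mutator strains.

#' Construct a variant panel
#'
#' @param variants Data frame with columns `chrom, pos, ref, alt`
#'   (biallelic SNPs, 1-based positions).
#' @param gt Genotype matrix, variants x strains, coded 0 (hom-ref),
#'   1 (het), 2 (hom-alt), NA (missing).
#' @param strains Strain metadata data frame with columns `name, clade,
#'   ploidy, zygosity, include`; `zygosity` is one of "haploid",
#'   "homozygous-diploid", "heterozygous".
#' @return Object of class `variant_panel`.
#' @export
variant_panel <- function(variants, gt, strains) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(gt) == nrow(variants), ncol(gt) == nrow(strains),
            all(c("name", "clade", "zygosity") %in% names(strains)))
  if (is.null(strains$include)) strains$include <- TRUE
  if (is.null(strains$ploidy)) strains$ploidy <- 1L
  colnames(gt) <- strains$name
  structure(list(variants = variants, gt = gt, strains = strains),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("Variant panel:", nrow(x$variants), "variants x",
      nrow(x$strains), "strains\n")
  if (!is.null(x$variants$ancestral)) {
    cat("  polarized:", sum(!is.na(x$variants$ancestral)), "callable\n")
  }
  invisible(x)
}

#' Polarize variants against an outgroup allele table
#'
#' The ancestral allele is the allele fixed in at least 4 of the 5 outgroup
#' strains, provided it matches the panel's ref or alt allele; all other
#' sites (split outgroup support, or a third allele) are uncallable and are
#' excluded downstream. Adds `ancestral`, `derived`, `class` (strand
#' collapsed ancestral->derived), diploid-convention derived allele count
#' `AC` (hom-derived = 2, het = 1) and derived allele frequency `DAF`.
#'
#' @param panel A [variant_panel()].
#' @param outgroup Data frame with `chrom, pos` plus one allele column per
#'   outgroup strain (typically 5).
#' @param min_support Minimum number of identical outgroup alleles
#'   (default 4).
#' @return The panel with polarization columns added.
#' @export
polarize_variants <- function(panel, outgroup, min_support = 4) {
  v <- panel$variants
  allele_cols <- setdiff(names(outgroup), c("chrom", "pos"))
  key_v <- paste(v$chrom, v$pos)
  key_o <- paste(outgroup$chrom, outgroup$pos)
  idx <- match(key_v, key_o)
  og <- as.matrix(outgroup[idx, allele_cols, drop = FALSE])
  og[!(og %in% BASES)] <- NA
  # an allele fixed in >= min_support outgroup strains can only be ref or
  # alt if that many columns literally match ref (or alt)
  n_ref <- rowSums(og == v$ref, na.rm = TRUE)
  n_alt <- rowSums(og == v$alt, na.rm = TRUE)
  anc <- rep(NA_character_, nrow(v))
  anc[n_ref >= min_support] <- v$ref[n_ref >= min_support]
  anc[n_alt >= min_support] <- v$alt[n_alt >= min_support]
  v$ancestral <- anc
  v$derived <- ifelse(is.na(anc), NA_character_,
                      ifelse(anc == v$ref, v$alt, v$ref))
  v$class <- rep(NA_character_, nrow(v))
  ok <- !is.na(anc)
  if (any(ok)) v$class[ok] <- collapse_class(v$ancestral[ok], v$derived[ok])

  # derived allele counts under the diploid convention
  gt <- panel$gt
  alt_copies <- rowSums(gt, na.rm = TRUE)
  n_called <- rowSums(!is.na(gt))
  anc_is_ref <- !is.na(anc) & anc == v$ref
  v$AC <- ifelse(is.na(anc), NA_real_,
                 ifelse(anc_is_ref, alt_copies, 2 * n_called - alt_copies))
  v$DAF <- ifelse(n_called > 0, v$AC / (2 * n_called), NA_real_)
  panel$variants <- v
  panel
}

# masks: data.frame(chrom, start, end), BED convention (0-based half-open)
mask_granges <- function(mask) {
  if (any(mask$end <= mask$start)) stop("malformed interval: end <= start")
  GenomicRanges::GRanges(mask$chrom,
                         IRanges::IRanges(mask$start + 1L, mask$end))
}

#' Filter panel variants
#'
#' Retains biallelic SNPs with missingness below `max_missing`, inside the
#' mappable include-mask and outside the repeat exclude-mask, with a
#' callable ancestral allele and derived allele frequency strictly below
#' `max_daf` (minimizing ancestral misidentification).
#'
#' @param panel A polarized [variant_panel()].
#' @param mappable,repeats Optional BED-convention data frames
#'   (`chrom, start, end`; 0-based half-open). `mappable` is an
#'   include-list, `repeats` an exclude-list.
#' @param max_missing Missing-genotype fraction threshold (strict <).
#' @param max_daf Derived-allele-frequency threshold (strict <).
#' @return The filtered panel; exclusion counts are reported via `message()`
#'   and attached as `attr(, "attrition")`.
#' @export
filter_variants <- function(panel, mappable = NULL, repeats = NULL,
                            max_missing = 0.20, max_daf = 0.5) {
  v <- panel$variants
  if (is.null(v$ancestral)) stop("panel must be polarized first")
  n0 <- nrow(v)
  snp <- v$ref %in% BASES & v$alt %in% BASES & v$ref != v$alt
  miss <- rowMeans(is.na(panel$gt)) < max_missing
  in_map <- rep(TRUE, n0)
  out_rep <- rep(TRUE, n0)
  if (!is.null(mappable) || !is.null(repeats)) {
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    if (!is.null(mappable)) {
      in_map <- IRanges::overlapsAny(gr, mask_granges(mappable))
    }
    if (!is.null(repeats)) {
      out_rep <- !IRanges::overlapsAny(gr, mask_granges(repeats))
    }
  }
  polarized <- !is.na(v$ancestral)
  daf_ok <- !is.na(v$DAF) & v$DAF < max_daf
  keep <- snp & miss & in_map & out_rep & polarized & daf_ok
  attrition <- c(input = n0, non_snp = sum(!snp), high_missing = sum(!miss),
                 unmappable = sum(!in_map), repeat_masked = sum(!out_rep),
                 unpolarized = sum(!polarized), high_daf = sum(!daf_ok),
                 retained = sum(keep))
  message(sprintf("filter_variants: %d of %d variants retained", sum(keep), n0))
  panel$variants <- v[keep, , drop = FALSE]
  panel$gt <- panel$gt[keep, , drop = FALSE]
  attr(panel, "attrition") <- attrition
  panel
}

#' Exclude close relatives from a strain set
#'
#' Iteratively removes one member of the closest pair with pairwise genetic
#' distance below `threshold` until no such pair remains. The dropped member
#' is the one with more sub-threshold neighbors; ties are broken by dropping
#' the lexicographically later name.
#'
#' @param dist Symmetric non-negative distance matrix with strain names as
#'   dimnames.
#' @param threshold Distance below which two strains count as relatives
#'   (default 8000).
#' @return Character vector of retained strain names.
#' @export
exclude_relatives <- function(dist, threshold = 8000) {
  if (!isSymmetric(unname(as.matrix(dist)))) stop("distance matrix must be symmetric")
  d <- as.matrix(dist)
  keep <- rownames(d)
  repeat {
    dd <- d[keep, keep, drop = FALSE]
    diag(dd) <- Inf
    if (all(dd >= threshold)) break
    mn <- min(dd)
    idx <- which(dd == mn, arr.ind = TRUE)[1, ]
    pair <- c(keep[idx[1]], keep[idx[2]])
    deg <- rowSums(dd[pair, , drop = FALSE] < threshold)
    drop_name <- if (deg[1] != deg[2]) pair[which.max(deg)] else max(pair)
    keep <- setdiff(keep, drop_name)
  }
  sort(keep)
}

# derived-copy matrix: per variant x strain, number of derived allele
# copies under the diploid convention (hom-derived = 2, het = 1)
derived_copies <- function(panel) {
  v <- panel$variants
  if (is.null(v$ancestral)) stop("panel must be polarized first")
  gt <- panel$gt
  anc_is_ref <- v$ancestral == v$ref
  D <- gt
  flip <- which(!anc_is_ref)
  if (length(flip)) D[flip, ] <- 2 - gt[flip, , drop = FALSE]
  D
}

# number of strains carrying >= 1 derived copy, per variant
carrier_counts <- function(D) rowSums(D > 0, na.rm = TRUE)

#' Per-strain mutation spectra from panel variants
#'
#' Three counting modes follow the panel analysis conventions:
#' \describe{
#'   \item{all}{every derived allele the strain carries; homozygous-derived
#'     genotypes weighted 2, heterozygous 1 (diploid convention).}
#'   \item{rare}{variants with derived allele count 2-4 that are not
#'     private to a single strain; carriers weighted 1 regardless of
#'     zygosity.}
#'   \item{singleton}{variants private to the strain; required homozygous
#'     for haploid / homozygous-diploid strains, heterozygous otherwise;
#'     weight 1.}
#' }
#'
#' @param panel A polarized, filtered [variant_panel()].
#' @param mode "all", "rare" or "singleton".
#' @param rare_ac Derived-allele-count range defining rare variants.
#' @return List with `counts` (strains x 6 class matrix), `totals`, and
#'   `proportions` (rows normalized to 1).
#' @export
strain_spectra <- function(panel, mode = c("all", "rare", "singleton"),
                           rare_ac = c(2, 4)) {
  mode <- match.arg(mode)
  v <- panel$variants
  D <- derived_copies(panel)
  S <- nrow(panel$strains)
  counts <- matrix(0, S, length(MUT_CLASSES),
                   dimnames = list(panel$strains$name, MUT_CLASSES))
  carriers <- carrier_counts(D)
  sel <- switch(mode,
    all = !is.na(v$class),
    rare = !is.na(v$class) & !is.na(v$AC) &
      v$AC >= rare_ac[1] & v$AC <= rare_ac[2] & carriers > 1,
    singleton = !is.na(v$class) & carriers == 1)
  W <- D[sel, , drop = FALSE]
  if (mode == "all") {
    W[is.na(W)] <- 0L
  } else if (mode == "rare") {
    W <- (W > 0) * 1L
    W[is.na(W)] <- 0L
  } else {
    need_hom <- panel$strains$zygosity %in% c("haploid", "homozygous-diploid")
    req <- matrix(ifelse(need_hom, 2L, 1L), nrow(W), S, byrow = TRUE)
    W <- (W == req) * 1L
    W[is.na(W)] <- 0L
  }
  cs <- rowsum(W, group = factor(v$class[sel], levels = MUT_CLASSES))
  counts[, rownames(cs)] <- t(cs)
  totals <- rowSums(counts)
  props <- counts / ifelse(totals > 0, totals, 1)
  list(counts = counts, totals = totals, proportions = props, mode = mode)
}

#' Spectrum for a single strain
#'
#' @param panel A polarized, filtered [variant_panel()].
#' @param strain Strain name.
#' @inheritParams strain_spectra
#' @return A [spectrum_counts()] object.
#' @export
strain_spectrum <- function(panel, strain, mode = c("all", "rare", "singleton"),
                            rare_ac = c(2, 4)) {
  sp <- strain_spectra(panel, mode = mode, rare_ac = rare_ac)
  if (!strain %in% rownames(sp$counts)) stop("unknown strain: ", strain)
  spectrum_counts(sp$counts[strain, ])
}

#' PCA of per-strain mutation spectra
#'
#' To limit bias from uneven sampling, at most `population_cap` strains per
#' population are randomly subsampled (seeded); strains with fewer than
#' `min_variants` contributing variants are excluded. Columns (class
#' proportions) are centered, not scaled. Loadings follow a fixed sign
#' convention: the largest-magnitude entry of each component is positive.
#'
#' @param spectra A [strain_spectra()] result (normalized rows are used).
#' @param populations Named character vector (or factor) of population
#'   labels per strain (names = strain names).
#' @param population_cap Maximum strains sampled per population.
#' @param min_variants Minimum spectrum total for a strain to enter.
#' @param seed Seed for the per-population subsampling.
#' @return List of class `spectrum_pca`: `loadings`, `projections`,
#'   `explained`, `strains`.
#' @export
spectrum_pca <- function(spectra, populations, population_cap = 30,
                         min_variants = 8, seed = NULL) {
  keep <- names(spectra$totals)[spectra$totals >= min_variants]
  pops <- populations[keep]
  chosen <- with_seed(seed, {
    unlist(lapply(split(keep, pops), function(s) {
      if (length(s) <= population_cap) s else sample(s, population_cap)
    }), use.names = FALSE)
  })
  chosen <- sort(chosen)
  if (length(chosen) < 3) stop("need at least 3 strains for spectrum PCA")
  X <- spectra$proportions[chosen, , drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention for reproducibility
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  expl <- pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  structure(list(loadings = pc$rotation, projections = pc$x,
                 explained = expl, strains = chosen),
            class = "spectrum_pca")
}

#' @export
print.spectrum_pca <- function(x, ...) {
  cat("Spectrum PCA over", length(x$strains), "strains\n")
  cat("explained variance:", round(x$explained[1:min(3, length(x$explained))], 3), "\n")
  invisible(x)
}

#' Rank strains by C>A enrichment of their rare variants
#'
#' Strains in the top `top_fraction` of C>A fraction are flagged, and each
#' strain receives a bootstrap empirical p-value: its rare-variant count is
#' resampled `B` times from the panel-pooled rare-variant class
#' distribution, and `p = (1 + #{resampled C>A fraction >= observed}) /
#' (B + 1)`. Under this exchangeable null the resampled C>A count is
#' binomial with the pooled C>A probability, which is how the resampling is
#' computed.
#'
#' @param spectra A rare-mode [strain_spectra()] result.
#' @param top_fraction Fraction of strains flagged by rank (default 0.05).
#' @param B Number of bootstrap resamples (>= 100).
#' @param min_variants Minimum rare-variant total per strain.
#' @param seed Seed for the bootstrap.
#' @return Data frame: `strain, n_variants, ca_fraction, rank, percentile,
#'   top_flag, p_boot`.
#' @export
ca_enrichment <- function(spectra, top_fraction = 0.05, B = 10000,
                          min_variants = 8, seed = NULL) {
  if (B < 100) stop("B must be >= 100")
  keep <- spectra$totals >= min_variants
  counts <- spectra$counts[keep, , drop = FALSE]
  totals <- spectra$totals[keep]
  frac <- counts[, "C>A"] / totals
  pooled <- sum(counts[, "C>A"]) / sum(totals)
  p_boot <- with_seed(seed, {
    vapply(seq_along(totals), function(i) {
      x <- rbinom(B, size = totals[i], prob = pooled)
      (1 + sum(x / totals[i] >= frac[i])) / (B + 1)
    }, numeric(1))
  })
  rk <- rank(-frac, ties.method = "first")
  n_top <- max(1L, floor(top_fraction * length(frac)))
  data.frame(strain = rownames(counts), n_variants = as.integer(totals),
             ca_fraction = frac, rank = as.integer(rk),
             percentile = 1 - (rk - 1) / length(frac),
             top_flag = rk <= n_top, p_boot = p_boot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' C>A fraction by derived-allele-count bin
#'
#' For the variants carried by a given strain set, computes the C>A fraction
#' and variant total per allele-count bin (default bins AC<=2, 3-4, 5-6,
#' 7-8, >8). Under a recently activated mutator, C>A enrichment is strongest
#' in the lowest (youngest) bins.
#'
#' @param panel A polarized, filtered [variant_panel()] (AC should be
#'   computed after relative exclusion).
#' @param strains Strain names defining the variant subset (variants carried
#'   by at least one of them); default all strains.
#' @param cutoffs Upper bin edges (default `c(2, 4, 6, 8)`); a final open
#'   bin `> max(cutoffs)` is added.
#' @return Data frame: `bin, n_variants, n_ca, ca_fraction` (fraction is NA
#'   for empty bins).
#' @export
ca_by_ac_bin <- function(panel, strains = NULL, cutoffs = c(2, 4, 6, 8)) {
  v <- panel$variants
  if (is.null(v$ancestral)) stop("panel must be polarized first")
  D <- derived_copies(panel)
  if (!is.null(strains)) {
    sel <- rowSums(D[, strains, drop = FALSE] > 0, na.rm = TRUE) > 0
  } else {
    sel <- rep(TRUE, nrow(v))
  }
  sel <- sel & !is.na(v$AC) & !is.na(v$class)
  ac <- v$AC[sel]
  cls <- v$class[sel]
  breaks <- c(-Inf, cutoffs, Inf)
  labs <- c(paste0("AC<=", cutoffs[1]),
            paste(head(cutoffs, -1) + 1, cutoffs[-1], sep = "-"),
            paste0(">", cutoffs[length(cutoffs)]))
  bin <- cut(ac, breaks = breaks, labels = labs)
  n <- tapply(rep(1, length(ac)), bin, sum)
  n[is.na(n)] <- 0
  n_ca <- tapply(cls == "C>A", bin, sum)
  n_ca[is.na(n_ca)] <- 0
  data.frame(bin = labs, n_variants = as.integer(n[labs]),
             n_ca = as.integer(n_ca[labs]),
             ca_fraction = ifelse(n[labs] > 0, n_ca[labs] / n[labs], NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan candidate genes for shared rare nonsynonymous alleles
#'
#' Reports sites in candidate genes carrying a nonsynonymous (missense or
#' nonsense) allele at panel minor allele frequency below `maf` that is
#' present in every carrier strain and absent from every control strain.
#'
#' @param panel A [variant_panel()] whose `variants` carry a `consequence`
#'   column for coding variants.
#' @param genes Data frame `chrom, start, end, gene` (1-based inclusive
#'   intervals).
#' @param carriers,controls Strain name vectors; `carriers` must be
#'   non-empty.
#' @param maf Panel minor-allele-frequency threshold (strict <).
#' @return Data frame of candidate sites with gene annotation.
#' @export
candidate_mutator_scan <- function(panel, genes, carriers, controls,
                                   maf = 0.05) {
  if (length(carriers) == 0) stop("carrier set must be non-empty")
  v <- panel$variants
  if (is.null(v$consequence)) stop("variants need a 'consequence' column")
  gt <- panel$gt
  alt_copies <- rowSums(gt, na.rm = TRUE)
  n_called <- rowSums(!is.na(gt))
  af <- alt_copies / pmax(2 * n_called, 1)
  maf_v <- pmin(af, 1 - af)
  carried <- function(strain) !is.na(gt[, strain]) & gt[, strain] > 0
  in_all_carriers <- Reduce(`&`, lapply(carriers, carried))
  in_any_control <- if (length(controls)) {
    Reduce(`|`, lapply(controls, carried))
  } else rep(FALSE, nrow(v))
  gr_v <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(gr_v, gr_g)
  in_gene <- rep(NA_character_, nrow(v))
  in_gene[S4Vectors::queryHits(hit)] <- genes$gene[S4Vectors::subjectHits(hit)]
  keep <- !is.na(in_gene) &
    v$consequence %in% c("missense", "nonsense") &
    maf_v < maf & in_all_carriers & !in_any_control
  out <- v[keep, , drop = FALSE]
  out$gene <- in_gene[keep]
  out$maf <- maf_v[keep]
  rownames(out) <- NULL
  out
}
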