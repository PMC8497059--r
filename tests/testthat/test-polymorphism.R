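test_that("polarization follows the 4-of-5 outgroup fixation rule", {
  tp <- tiny_panel()
  pp <- polarize_variants(tp$panel, tp$outgroup)
  v <- pp$variants
  expect_equal(v$ancestral, c("A", "C", "A", "T"))  # pos 300: ancestral = alt
  expect_equal(v$derived, c("G", "A", "G", "C"))
  expect_equal(v$class, c("A>G", "C>A", "A>G", "A>G"))  # T>C collapses
  expect_equal(v$AC, c(2, 2, 4, 1))
  expect_equal(v$DAF, c(2, 2, 4, 1) / 6)

  # split outgroup support (3-2) is uncallable
  og <- tp$outgroup
  og[1, c("og4", "og5")] <- "G"
  expect_true(is.na(polarize_variants(tp$panel, og)$variants$ancestral[1]))
  # outgroup fixed for a third allele is uncallable
  og2 <- tp$outgroup
  og2[1, paste0("og", 1:5)] <- "T"
  expect_true(is.na(polarize_variants(tp$panel, og2)$variants$ancestral[1]))
})

test_that("variant filtering enforces missingness, masks and strict DAF < 0.5", {
  variants <- data.frame(chrom = "chrI", pos = c(10L, 20L, 30L, 40L, 50L),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  gt <- rbind(c(1L, 1L, 0L, 0L),     # DAF 0.25, kept
              c(NA, 1L, 0L, 0L),     # missingness 0.25 >= 0.2, dropped
              c(1L, 1L, 1L, 1L),     # DAF 0.5, dropped (strict <)
              c(1L, 0L, 0L, 0L),     # in repeat mask, dropped
              c(1L, 0L, 0L, 0L))     # outside mappable, dropped
  strains <- data.frame(name = paste0("s", 1:4), clade = "c1", ploidy = 2L,
                        zygosity = "heterozygous", include = TRUE)
  og <- data.frame(chrom = "chrI", pos = c(10L, 20L, 30L, 40L, 50L),
                   og1 = "A", og2 = "A", og3 = "A", og4 = "A", og5 = "A")
  panel <- polarize_variants(variant_panel(variants, gt, strains), og)
  mappable <- data.frame(chrom = "chrI", start = 0L, end = 45L)
  repeats <- data.frame(chrom = "chrI", start = 39L, end = 41L)
  f <- suppressMessages(filter_variants(panel, mappable, repeats))
  expect_equal(f$variants$pos, 10L)
  expect_error(suppressMessages(
    filter_variants(panel, data.frame(chrom = "chrI", start = 10L, end = 5L))),
    "malformed")
})

test_that("spectra after ref/alt re-encoding are identical (polarization symmetry)", {
  sim <- simulate_panel(n_clades = 2, strains_per_clade = 6,
                        n_variants_per_strain = 300, seed = 21)
  pp <- polarize_variants(sim$panel, sim$outgroup)
  fp <- suppressMessages(filter_variants(pp))
  sp1 <- strain_spectra(fp, mode = "all")

  # swap the ref/alt encoding of every record (genotypes recoded 2 - gt)
  swapped <- sim$panel
  tmp <- swapped$variants$ref
  swapped$variants$ref <- swapped$variants$alt
  swapped$variants$alt <- tmp
  swapped$gt <- 2L - swapped$gt
  pp2 <- polarize_variants(swapped, sim$outgroup)
  fp2 <- suppressMessages(filter_variants(pp2))
  sp2 <- strain_spectra(fp2, mode = "all")
  expect_equal(sp1$counts, sp2$counts)
})

test_that("relative exclusion drops the hub of a close-pair chain", {
  d <- matrix(20000, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 5000
  d["B", "C"] <- d["C", "B"] <- 5000
  expect_equal(exclude_relatives(d), c("A", "C"))  # B has two close relatives

  two <- matrix(c(0, 5000, 5000, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(exclude_relatives(two), "X")  # tie broken by name
  all_far <- matrix(9000, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  diag(all_far) <- 0
  expect_equal(exclude_relatives(all_far), c("X", "Y"))
  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_error(exclude_relatives(asym), "symmetric")
})

test_that("spectrum modes apply the documented weighting rules", {
  tp <- tiny_panel()
  pp <- polarize_variants(tp$panel, tp$outgroup)
  all <- strain_spectra(pp, mode = "all")
  # s1: hom-derived at pos 100 and 300 (weight 2 each, both A>G), het at
  # pos 200 (C>A, weight 1)
  expect_equal(unname(all$counts["s1", "A>G"]), 4)
  expect_equal(unname(all$counts["s1", "C>A"]), 1)
  expect_equal(unname(all$proportions["s1", c("A>G", "C>A")]),
               c(0.8, 0.2))

  rare <- strain_spectra(pp, mode = "rare")
  # rare variants (AC 2-4, >1 carrier): pos 200 (C>A) and pos 300 (A>G);
  # hom carriers weighted 1, same as het
  expect_equal(unname(rare$counts["s1", c("A>G", "C>A")]), c(1, 1))
  expect_equal(unname(rare$counts["s2", "C>A"]), 1)
  expect_equal(unname(rare$counts["s3", "A>G"]), 1)

  single <- strain_spectra(pp, mode = "singleton")
  # pos 100 is private-hom in haploid s1; pos 400 private-het in diploid s3
  expect_equal(unname(single$counts["s1", "A>G"]), 1)
  expect_equal(unname(single$counts["s3", "A>G"]), 1)
  expect_equal(sum(single$counts["s2", ]), 0)

  # every normalized spectrum sums to 1 (or 0 for empty)
  sim <- simulate_panel(n_clades = 2, strains_per_clade = 5,
                        n_variants_per_strain = 200, seed = 3)
  fp <- suppressMessages(filter_variants(polarize_variants(sim$panel, sim$outgroup)))
  for (mode in c("all", "rare", "singleton")) {
    sp <- strain_spectra(fp, mode = mode)
    rs <- rowSums(sp$proportions)
    expect_true(all(abs(rs[sp$totals > 0] - 1) < 1e-12))
  }
})

test_that("spectrum PCA is deterministic, sign-fixed and matches eigen oracle", {
  # two clusters differing only in C>A fraction
  set.seed(10)
  base <- c(0.06, 0.32, 0.07, 0.10, 0.05, 0.40)
  mkspec <- function(p, n) {
    counts <- t(rmultinom(n, 500, p))
    colnames(counts) <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")
    counts
  }
  shift <- base; shift[4] <- shift[4] * 3; shift <- shift / sum(shift)
  counts <- rbind(mkspec(base, 10), mkspec(shift, 10))
  rownames(counts) <- sprintf("s%02d", 1:20)
  spectra <- list(counts = counts, totals = rowSums(counts),
                  proportions = counts / rowSums(counts))
  pops <- setNames(rep(c("p1", "p2"), each = 10), rownames(counts))
  pca <- spectrum_pca(spectra, pops, seed = 1)
  # PC1 loading dominated by C>A, positive by the sign convention
  expect_equal(names(which.max(abs(pca$loadings[, 1]))), "C>A")
  expect_gt(pca$loadings["C>A", 1], 0)
  # determinism
  pca2 <- spectrum_pca(spectra, pops, seed = 1)
  expect_identical(pca, pca2)
  # eigendecomposition oracle for the explained variance of PC1
  X <- scale(spectra$proportions, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(X))$values
  expect_equal(unname(pca$explained[1]), ev[1] / sum(ev), tolerance = 1e-8)
  # identical spectra: no variance
  same <- list(counts = counts[rep(1, 5), ], totals = rep(500, 5),
               proportions = (counts / rowSums(counts))[rep(1, 5), ])
  rownames(same$proportions) <- names(same$totals) <- paste0("t", 1:5)
  pca3 <- spectrum_pca(same, setNames(rep("p", 5), paste0("t", 1:5)))
  expect_lt(sum(abs(pca3$projections)), 1e-10)
})

test_that("population subsampling respects the cap and the seed", {
  sim <- simulate_panel(n_clades = 3, strains_per_clade = 12,
                        n_variants_per_strain = 300, seed = 17)
  fp <- suppressMessages(filter_variants(polarize_variants(sim$panel, sim$outgroup)))
  sp <- strain_spectra(fp, mode = "all")
  pops <- setNames(sim$panel$strains$clade, sim$panel$strains$name)
  pca <- spectrum_pca(sp, pops, population_cap = 5, seed = 2)
  expect_equal(length(pca$strains), 15)
  expect_true(all(table(pops[pca$strains]) == 5))
  expect_identical(spectrum_pca(sp, pops, population_cap = 5, seed = 2)$strains,
                   pca$strains)
})

test_that("C>A enrichment ranking and bootstrap match an exact binomial oracle", {
  # 10 strains, n = 300 each; strain o1 has 36 C>A, the rest 30
  counts <- matrix(0, 10, 6, dimnames = list(sprintf("o%d", 1:10),
                                             c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")))
  counts[, "C>T"] <- 200
  counts[, "C>A"] <- 30
  counts["o1", "C>A"] <- 36
  counts[, "A>G"] <- 300 - rowSums(counts)
  spectra <- list(counts = counts, totals = rowSums(counts),
                  proportions = counts / rowSums(counts))
  enr <- ca_enrichment(spectra, B = 20000, seed = 6)
  expect_equal(nrow(enr), 10)
  expect_equal(sum(enr$top_flag), 1)  # floor(0.05 * 10) -> 1 strain
  expect_equal(enr$strain[enr$top_flag], "o1")
  pooled <- sum(counts[, "C>A"]) / sum(counts)
  p_exact <- 1 - pbinom(35, 300, pooled)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(enr$p_boot[enr$strain == "o1"] - p_exact), 3 * se + 1e-4)
  # a strain at the pooled fraction has p near 0.5
  expect_true(all(abs(enr$p_boot[enr$strain != "o1"] - 0.55) < 0.12))
  expect_error(ca_enrichment(spectra, B = 50), "B")
})

test_that("top-5% flag count is exact for 100 strains", {
  counts <- matrix(10, 100, 6,
                   dimnames = list(sprintf("q%03d", 1:100),
                                   c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")))
  counts[, "C>A"] <- seq(5, 104)
  spectra <- list(counts = counts, totals = rowSums(counts),
                  proportions = counts / rowSums(counts))
  enr <- ca_enrichment(spectra, B = 200, seed = 1)
  expect_equal(sum(enr$top_flag), 5)
})

test_that("C>A by allele-count bin uses the stated cutoffs and order invariance", {
  tp <- tiny_panel()
  pp <- polarize_variants(tp$panel, tp$outgroup)
  # manufacture ACs across bins
  pp$variants$AC <- c(2, 4, 9, 1)
  bins <- ca_by_ac_bin(pp)
  expect_equal(bins$bin, c("AC<=2", "3-4", "5-6", "7-8", ">8"))
  expect_equal(bins$n_variants, c(2L, 1L, 0L, 0L, 1L))
  # pos 100 (A>G, AC 2) + pos 400 (A>G, AC 1) in bin 1; pos 200 C>A AC 4
  expect_equal(bins$ca_fraction[1], 0)
  expect_equal(bins$ca_fraction[2], 1)
  expect_true(is.na(bins$ca_fraction[3]))
  # shuffling variant order changes nothing
  perm <- pp
  ord <- c(3, 1, 4, 2)
  perm$variants <- perm$variants[ord, ]
  perm$gt <- perm$gt[ord, , drop = FALSE]
  expect_equal(ca_by_ac_bin(perm), bins)
})

test_that("candidate mutator scan applies carrier, consequence and MAF rules", {
  variants <- data.frame(chrom = "chrI", pos = c(100L, 200L, 300L, 400L),
                         ref = "C", alt = "A",
                         consequence = c("missense", "missense", "synonymous",
                                         "missense"),
                         stringsAsFactors = FALSE)
  # 40 strains; carriers m1, m2 = columns 1-2 (het alleles: MAF 2/80 < 0.05)
  gt <- matrix(0L, 4, 40)
  gt[1, 1:2] <- 1L            # shared by carriers only -> reported
  gt[2, c(1, 2, 3)] <- 1L     # also in a control -> excluded
  gt[3, 1:2] <- 1L            # synonymous -> excluded
  gt[4, 1] <- 1L              # absent from one carrier -> excluded
  strains <- data.frame(name = sprintf("m%d", 1:40), clade = "c",
                        ploidy = 1L, zygosity = "haploid", include = TRUE)
  panel <- variant_panel(variants, gt, strains)
  genes <- data.frame(chrom = "chrI", start = 50L, end = 450L, gene = "GENE1")
  hits <- candidate_mutator_scan(panel, genes, carriers = c("m1", "m2"),
                                 controls = sprintf("m%d", 3:40))
  expect_equal(hits$pos, 100L)
  expect_equal(hits$gene, "GENE1")
  expect_error(candidate_mutator_scan(panel, genes, character(0), "m3"))
})
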