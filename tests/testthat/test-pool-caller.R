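cfg38 <- pool_config(n_mutants = 38, callable_interval = c(31, 970))

test_that("site filtering applies depth and interval rules with pool QC", {
  pu <- data.frame(pos = c(10, 50, 60, 70), ref = "A",
                   depth = c(5000, 150, 200, 5000),
                   A = 0, C = 0, G = 0, T = 0, ins = 0, del = 0)
  fs <- filter_sites(pu, cfg38)
  expect_equal(fs$sites$pos, c(60, 70))  # pos 10 outside interval, 150 < 200
  expect_error(filter_sites(pu[0, ], cfg38), "empty")

  # 35% of the amplicon passing fails QC; 45% passes
  cfg_small <- pool_config(38, callable_interval = c(1, 100))
  pu2 <- data.frame(pos = 1:35, ref = "A", depth = 1000,
                    A = 0, C = 0, G = 0, T = 0, ins = 0, del = 0)
  expect_equal(filter_sites(pu2, cfg_small)$qc$verdict, "FAIL")
  pu3 <- data.frame(pos = 1:45, ref = "A", depth = 1000,
                    A = 0, C = 0, G = 0, T = 0, ins = 0, del = 0)
  expect_equal(filter_sites(pu3, cfg_small)$qc$verdict, "PASS")
})

test_that("the calling window is [0.65/N, 0.95] with fixed alleles routed aside", {
  mk <- function(f) data.frame(pos = 100, ref = "C", depth = 10000,
                               A = round(f * 10000), C = 0, G = 0, T = 0,
                               ins = 0, del = 0)
  # N = 38: threshold 0.65/38 = 0.0171
  expect_equal(nrow(call_point_mutations(mk(0.02), cfg38)$calls), 1)
  expect_equal(nrow(call_point_mutations(mk(0.01), cfg38)$calls), 0)
  # lower boundary inclusive: N = 13 makes 0.65/N = 0.05 exactly
  cfg13 <- pool_config(n_mutants = 13, callable_interval = c(31, 970))
  exact <- call_point_mutations(mk(0.05), cfg13)
  expect_equal(nrow(exact$calls), 1)
  below <- call_point_mutations(mk(0.0499), cfg13)
  expect_equal(nrow(below$calls), 0)
  hi <- call_point_mutations(mk(0.97), cfg38)
  expect_equal(nrow(hi$calls), 0)
  expect_equal(nrow(hi$fixed), 1)
  at95 <- call_point_mutations(mk(0.95), cfg38)  # upper boundary inclusive
  expect_equal(nrow(at95$calls), 1)
})

test_that("calling is invariant to uniform depth rescaling", {
  sim <- simulate_pool(n_mutants = 20, depth = 4000, error_rate = 0.002,
                       amplicon_length = 600, seed = 31)
  pu <- filter_sites(sim$pileup, sim$config)$sites
  c1 <- call_point_mutations(pu, sim$config)$calls
  pu2 <- pu
  for (col in c("depth", "A", "C", "G", "T", "ins", "del")) {
    pu2[[col]] <- pu[[col]] * 3L
  }
  c2 <- call_point_mutations(pu2, sim$config)$calls
  expect_equal(c1$amplicon_pos, c2$amplicon_pos)
  expect_equal(c1$frequency, c2$frequency)
})

test_that("adjacent same-kind indels merge when frequencies are close", {
  del <- make_calls(c(101, 102), c(0.025, 0.027), kind = "deletion", alt = "D")
  m <- merge_adjacent_indels(del, cfg38)
  expect_equal(nrow(m), 1)
  expect_equal(m$amplicon_pos, 101)
  expect_equal(m$frequency, 0.026)
  expect_equal(m$width, 2L)

  apart <- make_calls(c(101, 102), c(0.025, 0.20), kind = "deletion", alt = "D")
  expect_equal(nrow(merge_adjacent_indels(apart, cfg38)), 2)

  mixed <- rbind(make_calls(101, 0.025, kind = "deletion", alt = "D"),
                 make_calls(105, 0.026, kind = "insertion", alt = "I"))
  expect_equal(nrow(merge_adjacent_indels(mixed, cfg38)), 2)
})

test_that("MNM detection follows distance, frequency and co-occurrence rules", {
  calls <- make_calls(c(50, 55), c(0.026, 0.027))
  cooc <- data.frame(pos_i = 50, alt_i = "A", pos_j = 55, alt_j = "A",
                     reads_both = 90, reads_any = 100)
  r <- detect_mnms(calls, cooc, cfg38)
  expect_equal(sum(r$calls$in_mnm), 2)
  expect_equal(nrow(r$mnms), 2)
  expect_equal(unique(r$mnms$n_members), 2)

  weak <- cooc; weak$reads_both <- 50
  r2 <- detect_mnms(calls, weak, cfg38)
  expect_equal(sum(r2$calls$in_mnm), 0)

  # frequency mismatch beyond 0.09 blocks the pair
  far <- make_calls(c(50, 55), c(0.026, 0.30))
  expect_equal(sum(detect_mnms(far, cooc, cfg38)$calls$in_mnm), 0)

  # missing co-occurrence record: unresolvable, no MNM
  r3 <- detect_mnms(calls, cooc[0, ], cfg38)
  expect_equal(sum(r3$calls$in_mnm), 0)
  expect_equal(nrow(r3$unresolved), 1)
})

test_that("MNMs sharing a member merge into a complex MNM, order-independently", {
  calls <- make_calls(c(50, 55, 60), c(0.026, 0.027, 0.025))
  cooc <- data.frame(pos_i = c(50, 55, 50), alt_i = "A",
                     pos_j = c(55, 60, 60), alt_j = "A",
                     reads_both = c(90, 88, 2), reads_any = c(100, 100, 100))
  r <- detect_mnms(calls, cooc, cfg38)
  expect_equal(max(r$mnms$n_members), 3)  # {50,55} and {55,60} share 55
  expect_equal(length(unique(r$mnms$mnm_id)), 1)

  perm <- calls[c(3, 1, 2), ]
  r2 <- detect_mnms(perm, cooc, cfg38)
  expect_equal(sort(r2$mnms$amplicon_pos), sort(r$mnms$amplicon_pos))
  expect_equal(sum(r2$calls$in_mnm), sum(r$calls$in_mnm))
})

test_that("multiplicity follows the mean + 2 SD outlier rule", {
  # 36 calls at 0.02 plus one at 0.06: mu = 0.021081, population SD =
  # 0.006486, threshold 0.034055; 0.06 -> round(0.06/0.021081) = 3
  f <- c(rep(0.02, 36), 0.06)
  calls <- make_calls(seq(100, by = 20, length.out = 37), f)
  r <- estimate_multiplicity(calls, cfg38)
  expect_equal(r$multiplicity[r$frequency == 0.06], 3L)
  expect_true(all(r$multiplicity[r$frequency == 0.02] == 1L))

  even <- estimate_multiplicity(make_calls(1:5 * 10, rep(0.025, 5)), cfg38)
  expect_true(all(even$multiplicity == 1L))  # sigma = 0, none exceed

  noise <- make_calls(1:38 * 10, 1 / 38 + seq(-1e-4, 1e-4, length.out = 38))
  expect_true(all(estimate_multiplicity(noise, cfg38)$multiplicity == 1L))

  expect_warning(one <- estimate_multiplicity(make_calls(10, 0.03), cfg38))
  expect_equal(one$multiplicity, 1L)
})

test_that("genome mapping and strand collapse are position-exact", {
  amap <- amplicon_map("chrV", 33000, "+", 31, 930, 1000)
  calls <- make_calls(c(1, 10), c(0.02, 0.03), ref = c("G", "A"),
                      alt = c("T", "G"))
  r <- map_to_genome(calls, amap)
  expect_equal(r$genome_pos, c(33000, 33009))
  expect_equal(r$class, c("C>A", "A>G"))
  bad <- make_calls(1001, 0.02)
  expect_error(map_to_genome(bad, amap), "outside")
})

test_that("consequence annotation translates codons on either strand", {
  # CDS: ATG TGG CTG GCT TAA
  cds <- "ATGTGGCTGGCTTAA"
  amap <- amplicon_map("chrV", 1000, "+", 11, 25, 40)
  calls <- make_calls(c(16, 19, 15, 5), 0.02,
                      ref = c("G", "G", "G", "A"),
                      alt = c("A", "A", "T", "C"))
  # pos 16 = codon2 pos3: TGG->TGA nonsense; pos 19 = codon3 pos3? no:
  # codon3 spans 17-19: CTG->CTA synonymous (Leu); pos 15 = codon2 pos2:
  # TGG->TTG missense (Trp->Leu); pos 5 noncoding
  r <- annotate_consequence(calls, cds, amap)
  expect_equal(r$consequence, c("nonsense", "synonymous", "missense", "noncoding"))

  # same ORF encoded on the minus strand of the amplicon
  fix <- make_cds_fixture(n_codons = 20, orf_strand = "-", seed = 4)
  amp <- strsplit(fix$amplicon_seq, "")[[1]]
  # mutate the base corresponding to CDS position 6 (codon 2, offset 3)
  cds_pos <- 6
  apos <- fix$amap$cds_end - cds_pos + 1
  ref <- amp[apos]
  codon <- substr(fix$cds_seq, 4, 6)
  # choose an alt creating a stop if possible, else any change; verify
  # agreement with direct translation
  for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
    cl <- make_calls(apos, 0.02, ref = ref, alt = alt)
    got <- annotate_consequence(cl, fix$cds_seq, fix$amap)$consequence
    new_codon <- codon
    substr(new_codon, 3, 3) <- chartr("ACGT", "TGCA", alt)
    aa_old <- Biostrings::GENETIC_CODE[codon]
    aa_new <- Biostrings::GENETIC_CODE[new_codon]
    want <- if (aa_old == aa_new) "synonymous"
            else if (aa_new == "*") "nonsense" else "missense"
    expect_equal(got, want)
  }
  expect_error(annotate_consequence(make_calls(12, .02), "ATGC", amap))
})

test_that("strain identity verdicts reflect fixed-allele overlap", {
  fixed <- data.frame(amplicon_pos = 1:10, alt = "A")
  expect_equal(strain_identity_check(fixed, fixed)$verdict, "PASS")
  disjoint <- data.frame(amplicon_pos = 11:20, alt = "A")
  r <- strain_identity_check(fixed, disjoint)
  expect_equal(r$verdict, "FAIL")
  expect_equal(r$match_fraction, 0)
  nine <- strain_identity_check(fixed, fixed[1:9, ])
  expect_equal(nine$match_fraction, 0.9)
  expect_equal(nine$verdict, "PASS")
  expect_equal(strain_identity_check(fixed[0, ], fixed)$verdict, "WARN")
})

test_that("pool spectra count multiplicities and exclude MNMs and long indels", {
  calls <- rbind(
    make_calls(c(10, 20), 0.03, ref = "C", alt = "A"),
    make_calls(30, 0.03, ref = "G", alt = "T"),       # collapses to C>A
    make_calls(40, 0.03, kind = "deletion", alt = "D"),
    make_calls(50, 0.03, kind = "insertion", alt = "I"))
  calls$multiplicity <- c(1L, 1L, 1L, 1L, 1L)
  calls$in_mnm <- FALSE
  sp <- pool_spectrum(calls)
  expect_equal(unname(sp["C>A"]), 3)
  expect_equal(unname(sp["del"]), 1)
  expect_equal(sum(sp), sum(calls$multiplicity))

  calls$multiplicity[1] <- 3L
  expect_equal(unname(pool_spectrum(calls)["C>A"]), 5)

  calls$in_mnm[2] <- TRUE                      # excluded from spectrum
  calls$width[4] <- 2L                         # 2-bp deletion excluded
  sp2 <- pool_spectrum(calls)
  expect_equal(unname(sp2["C>A"]), 4)
  expect_equal(unname(sp2["del"]), 0)
  expect_equal(sum(sp2), sum(calls$multiplicity[!calls$in_mnm &
    (calls$kind == "SNV" | calls$width == 1L)]))

  expect_warning(empty <- pool_spectrum(calls[0, ]))
  expect_equal(sum(empty), 0)
})
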