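panel5 <- tag_snp_panel(pos = c(100, 200, 300, 400, 500),
                        ref = "A", alt = "G",
                        tagged_structure = c("inversion", "inversion",
                                             "inversion", "duplication",
                                             "duplication"))

test_that("inversion calls follow the unanimity rule", {
  # all homozygous diagnostic -> H2/H2; all heterozygous -> H1/H2
  expect_equal(call_inversion_genotype(c(2, 2, 2, 0, 0), panel5)$genotype,
               "H2/H2")
  expect_equal(call_inversion_genotype(c(1, 1, 1, 0, 0), panel5)$genotype,
               "H1/H2")
  expect_equal(call_inversion_genotype(c(0, 0, 0, 0, 0), panel5)$genotype,
               "H1/H1")
  # discordant votes -> ambiguous with the tally attached
  p6 <- tag_snp_panel(pos = 1:6 * 100, ref = "A", alt = "G",
                      tagged_structure = c(rep("inversion", 5),
                                           "duplication"))
  call <- call_inversion_genotype(c(2, 2, 2, 0, 0, 0), p6)
  expect_equal(call$genotype, "ambiguous")
  expect_equal(as.integer(call$tally[c("2", "0")]), c(3L, 2L))
  # missing tags are excluded from voting
  expect_equal(call_inversion_genotype(c(NA, 1, NA, 0, 0), panel5)$genotype,
               "H1/H2")
  # all tags missing is an error distinct from ambiguous
  expect_error(call_inversion_genotype(c(NA, NA, NA, 0, 0), panel5),
               class = "invtools_no_tags")
})

test_that("vote combination matches direct enumeration over <= 5 tags", {
  # every vote pattern over k inversion tags, values in {0, 1, 2, NA}
  for (k in 1:3) {
    pk <- tag_snp_panel(pos = seq_len(k + 1) * 10, ref = "A", alt = "G",
                        tagged_structure = c(rep("inversion", k),
                                             "duplication"))
    grid <- expand.grid(rep(list(c(0L, 1L, 2L, NA)), k))
    for (r in seq_len(nrow(grid))) {
      votes <- unlist(grid[r, ])
      geno <- c(votes, 0L)
      used <- votes[!is.na(votes)]
      if (length(used) == 0) {
        expect_error(call_inversion_genotype(geno, pk),
                     class = "invtools_no_tags")
      } else {
        expected <- if (length(unique(used)) == 1)
          c("H1/H1", "H1/H2", "H2/H2")[used[1] + 1] else "ambiguous"
        expect_equal(call_inversion_genotype(geno, pk)$genotype, expected)
      }
    }
  }
})

test_that("duplication dosage respects the inversion genotype", {
  # H1/H2 with one diagnostic allele at each dup tag -> dosage 1 (H1 + H2D)
  d <- call_duplication_dosage(c(1, 1, 1, 1, 1), "H1/H2", panel5)
  expect_equal(d$dosage, 1L)
  expect_false(d$conflict)
  # H2/H2 with zero diagnostic alleles -> dosage 0 (H2prime/H2prime)
  d <- call_duplication_dosage(c(2, 2, 2, 0, 0), "H2/H2", panel5)
  expect_equal(d$dosage, 0L)
  # dosage exceeding the H2 haplotype count conflicts
  d <- call_duplication_dosage(c(1, 1, 1, 2, 2), "H1/H2", panel5)
  expect_equal(d$dosage, 2L)
  expect_true(d$conflict)
  # H1/H1 with nonzero dosage: flagged as H1-background CN, never H2D
  d <- call_duplication_dosage(c(0, 0, 0, 1, 1), "H1/H1", panel5)
  expect_true(d$h1_background)
  expect_true(d$conflict)
  # all dup tags missing -> ambiguous, not an error
  d <- call_duplication_dosage(c(1, 1, 1, NA, NA), "H1/H2", panel5)
  expect_true(is.na(d$dosage))
})

test_that("typing recovers truth perfectly with perfect tags", {
  fx <- generate_cohort(small_cohort_config(seed = 17, n = 250,
                                            h2prime = 0.2, h2d = 0.2))
  typed <- type_structures(cohort_genotypes(fx), fx$panel)
  expect_identical(typed$inv_genotype, fx$truth$inv_genotype)
  expect_identical(typed$dup_dosage, fx$truth$dup_dosage)
  expect_false(any(typed$conflict))
})

test_that("with noisy tags the typer turns errors into ambiguity, not miscalls", {
  # 5-tag panel, per-tag allele error 0.02: the unanimity rule may abstain,
  # but confidently typed samples stay right (>= 99% of calls correct)
  reg <- region_annotation()
  p5 <- tag_snp_panel(pos = c(reg$inversion[1] + c(5000, 15000, 25000),
                              reg$dup[1] + c(5000, 15000)) + 1,
                      ref = "A", alt = "G",
                      tagged_structure = c(rep("inversion", 3),
                                           rep("duplication", 2)))
  cfg <- cohort_config(groups = c(g = 1000L),
                       subtype_freqs = data.frame(group = "g",
                                                  H2prime = 0.2, H2D = 0.2),
                       n_sites = 40, panel = p5, tag_error = 0.02,
                       seed = 23)
  fx <- generate_cohort(cfg)
  typed <- type_structures(cohort_genotypes(fx), fx$panel)
  called <- typed$inv_genotype %in% c("H1/H1", "H1/H2", "H2/H2") &
    !is.na(typed$dup_dosage) & !typed$conflict
  acc <- mean(typed$inv_genotype[called] ==
                fx$truth$inv_genotype[called] &
              typed$dup_dosage[called] == fx$truth$dup_dosage[called])
  expect_gte(acc, 0.99)
  expect_gt(mean(called), 0.75)
})

test_that("heterokaryotype phasing is deterministic and never guesses", {
  # het site with diagnostic alt goes to H2; homozygous sites to both
  ph <- phase_heterokaryotype(geno = c(1L, 0L, 2L, 1L),
                              positions = c(100, 150, 250, 301),
                              inversion_genotype = "H1/H2",
                              panel = panel5)
  expect_equal(ph$h2[1], 1L); expect_equal(ph$h1[1], 0L)  # tag site
  expect_equal(ph$h1[2], 0L); expect_equal(ph$h2[2], 0L)
  expect_equal(ph$h1[3], 1L); expect_equal(ph$h2[3], 1L)
  expect_true(is.na(ph$h1[4]) && is.na(ph$h2[4]))         # uninformative het

  expect_error(phase_heterokaryotype(c(0L), c(1), "H2/H2", panel5),
               "heterokaryotype")

  # synthetic heterokaryotypes: resolved H2 haplotype equals truth at
  # non-missing sites, and no phased allele is absent from the genotype
  fx <- generate_cohort(small_cohort_config(seed = 31, n = 120))
  G <- cohort_genotypes(fx)
  hets <- which(fx$truth$inv_genotype == "H1/H2")
  pos1 <- fx$positions + 1L
  for (i in hets[1:min(20, length(hets))]) {
    ph <- phase_heterokaryotype(G[i, ], pos1, "H1/H2", fx$panel)
    rows <- c(2L * i - 1L, 2L * i)
    h2_truth_row <- rows[fx$hap_subtype[rows] != "H1"]
    truth_h2 <- fx$haplotypes[h2_truth_row, ]
    ok <- !is.na(ph$h2)
    expect_identical(ph$h2[ok], truth_h2[ok])
    for (s in which(!is.na(ph$h1))) {
      expect_true(ph$h1[s] + ph$h2[s] == G[i, s])
    }
  }
})

test_that("depth reconciliation confirms consistent calls and flags conflicts", {
  reg <- region_annotation()
  typed2 <- data.frame(sample = "x", inv_genotype = "H2/H2",
                       dup_dosage = 2L, conflict = FALSE,
                       depth_confirmed = NA)
  seg2 <- segment_read_depth(generate_read_depth(2, reg, seed = 8))
  out <- reconcile_structural(typed2, seg2, reg)
  expect_true(out$depth_confirmed)
  expect_false(out$conflict)

  # tags say dosage 1 but the track is flat: conflict, dosage retained
  typed1 <- data.frame(sample = "y", inv_genotype = "H1/H2",
                       dup_dosage = 1L, conflict = FALSE,
                       depth_confirmed = NA)
  seg0 <- segment_read_depth(generate_read_depth(0, reg, seed = 8))
  out <- reconcile_structural(typed1, seg0, reg)
  expect_false(out$depth_confirmed)
  expect_true(out$conflict)
  expect_equal(out$dup_dosage, 1L)
})

test_that("typing plus depth confirmation recovers a whole synthetic cohort", {
  reg <- region_annotation()
  fx <- generate_cohort(small_cohort_config(seed = 41, n = 100,
                                            h2prime = 0.25, h2d = 0.25))
  typed <- type_structures(cohort_genotypes(fx), fx$panel)
  confirmed <- logical(nrow(typed))
  for (i in seq_len(nrow(typed))) {
    tr <- generate_read_depth(typed$dup_dosage[i], reg, seed = 1000 + i)
    seg <- segment_read_depth(tr)
    confirmed[i] <- reconcile_structural(typed[i, ], seg,
                                         reg)$depth_confirmed
  }
  expect_true(all(confirmed))
})
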