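test_that("cohort generation is deterministic and validates its config", {
  cfg <- small_cohort_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(small_cohort_config(seed = 12))
  expect_false(identical(a$haplotypes, c2$haplotypes))

  expect_error(cohort_config(groups = c(x = 10L),
                             subtype_freqs = data.frame(group = "x",
                                                        H2prime = 0.6,
                                                        H2D = 0.6)),
               "sum to at most 1")
  expect_error(small_cohort_config(n_sites = 5), "n_sites too small")
})

test_that("every haplotype has two per individual and consistent labels", {
  fx <- generate_cohort(small_cohort_config(seed = 3, n = 80))
  expect_equal(nrow(fx$haplotypes), 2 * nrow(fx$truth))
  expect_true(all(fx$hap_subtype %in% c("H1", "H2prime", "H2D")))

  # tag alleles must match the truth subtype of every haplotype, exhaustively
  panel <- fx$panel
  tag_idx <- match(panel$pos - 1L, fx$positions)
  diag_num <- ifelse(panel$diagnostic == "alt", 1L, 0L)
  inv <- panel$tagged_structure == "inversion"
  dup <- panel$tagged_structure == "duplication"
  for (i in seq_len(nrow(fx$haplotypes))) {
    h <- fx$haplotypes[i, tag_idx]
    st <- fx$hap_subtype[i]
    expect_identical(unname(h[inv]),
                     if (st == "H1") 1L - diag_num[inv] else diag_num[inv])
    expect_identical(unname(h[dup]),
                     if (st == "H2D") diag_num[dup] else 1L - diag_num[dup])
  }
})

test_that("degenerate frequencies give an all-H1 cohort with no diagnostic alleles", {
  fx <- generate_cohort(small_cohort_config(seed = 5, h2prime = 0,
                                            h2d = 0))
  expect_true(all(fx$hap_subtype == "H1"))
  panel <- fx$panel
  tag_idx <- match(panel$pos - 1L, fx$positions)
  diag_num <- ifelse(panel$diagnostic == "alt", 1L, 0L)
  carried <- fx$haplotypes[, tag_idx, drop = FALSE]
  expect_true(all(t(carried) != diag_num))
})

test_that("subtype frequencies are calibrated", {
  # one large group: H2D haplotype count within the central 99% binomial band
  fx <- generate_cohort(small_cohort_config(seed = 21, n = 10000,
                                            h2prime = 0, h2d = 0.10))
  n_h2d <- sum(fx$hap_subtype == "H2D")
  band <- qbinom(c(0.005, 0.995), 20000, 0.10)
  expect_gte(n_h2d, band[1])
  expect_lte(n_h2d, band[2])

  # across 50 seeds, empirical frequencies within 3 binomial SE of config
  tot <- c(H1 = 0, H2prime = 0, H2D = 0)
  n_hap <- 0
  for (s in 1:50) {
    fx <- generate_cohort(small_cohort_config(seed = s, n = 40,
                                              h2prime = 0.2, h2d = 0.1))
    tot <- tot + table(factor(fx$hap_subtype,
                              levels = c("H1", "H2prime", "H2D")))
    n_hap <- n_hap + length(fx$hap_subtype)
  }
  for (st in names(tot)) {
    p <- c(H1 = 0.7, H2prime = 0.2, H2D = 0.1)[st]
    se <- sqrt(p * (1 - p) / n_hap)
    expect_lt(abs(tot[st] / n_hap - p), 3 * se)
  }
})

test_that("read-depth tracks are calibrated and carry the planted gain", {
  reg <- region_annotation()
  tr <- generate_read_depth(2, reg, baseline = 40, seed = 2)
  expect_s3_class(tr, "read_depth_track")
  span <- region_span(reg)
  expect_equal(tr$start[1], span[1])
  expect_equal(tr$end[nrow(tr)], span[2])
  expect_true(all(tr$start[-1] == tr$end[-nrow(tr)])) # windows tile

  mid <- (tr$start + tr$end) / 2
  in_dup <- mid >= reg$dup[1] & mid < reg$dup[2]
  # H2D/H2D: copy number 4 vs 2, expected ratio 2.0
  expect_equal(mean(tr$depth[in_dup]) / 40, 2.0, tolerance = 0.05)
  # outside the duplication the mean tracks the baseline within 2%
  expect_gte(sum(!in_dup), 500)
  expect_equal(mean(tr$depth[!in_dup]), 40, tolerance = 0.02 * 40)

  # H1/H1 tracks show no sustained high run at the default dispersion
  for (s in 1:25) {
    tr0 <- generate_read_depth(0, reg, baseline = 40, seed = s)
    r <- rle(tr0$depth > 1.5 * 40)
    expect_false(any(r$values & r$lengths >= 3))
  }

  expect_error(generate_read_depth(3, reg), "dup_dosage")
  expect_error(generate_read_depth(0, reg, window = 0), "window")
  expect_error(generate_read_depth(0, reg, baseline = -1), "baseline")
})

test_that("panel fixtures reproduce every configured count exactly", {
  # published composition
  fx <- generate_panel_fixture(panel_counts(), seed = 4)
  expect_equal(nrow(fx$candidates), 203)
  expect_equal(sum(fx$candidates$in_segdup), 67)
  expect_equal(nrow(fx$tags), 17)

  # independent re-count: point-in-interval scan + monomorphism scan
  for (seed in c(1, 9)) {
    cnt <- panel_counts(n_novel_candidates = 120, n_in_segdup = 30,
                        n_tag_added = 10, n_monomorphic = 41)
    fx <- generate_panel_fixture(cnt, seed = seed, n_samples = 60)
    in_seg <- vapply(fx$candidates$pos, function(p)
      any(p - 1 >= fx$segdups$start & p - 1 < fx$segdups$end), logical(1))
    expect_equal(sum(in_seg), 30)
    expect_identical(in_seg, fx$candidates$in_segdup)
    mono <- apply(fx$genotypes, 1, function(g) {
      obs <- g[!is.na(g)]
      length(obs) == 0 || (all(obs != 1) && length(unique(obs)) == 1)
    })
    expect_equal(sum(mono), 41)
    expect_setequal(rownames(fx$genotypes)[mono], fx$monomorphic_sites)
  }

  expect_error(panel_counts(n_in_segdup = 300), "exceed")
  expect_error(panel_counts(n_monomorphic = 200), "exceeds")
})
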