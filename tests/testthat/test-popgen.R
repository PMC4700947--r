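test_that("nucleotide diversity matches its definition and the oracle", {
  # identical haplotypes -> 0
  H <- matrix(0L, nrow = 4, ncol = 10)
  expect_equal(nucleotide_diversity(H, 100), 0)
  # n = 2, one mismatch, L = 100 -> 0.01
  H <- rbind(c(0L, 0L), c(0L, 1L))
  expect_equal(nucleotide_diversity(H, 100), 0.01)
  # undefined below 2 haplotypes
  expect_true(is.na(nucleotide_diversity(H[1, , drop = FALSE], 100)))

  set.seed(5)
  for (rep in 1:100) {
    H <- random_hap_matrix(sample(3:8, 1), sample(5:50, 1),
                           miss = sample(c(0, 0.1), 1))
    L <- ncol(H) + sample(0:100, 1)
    expect_equal(nucleotide_diversity(H, L), oracle_pi(H, L),
                 tolerance = 1e-12)
  }

  # invariant under haplotype and site reordering
  set.seed(6)
  H <- random_hap_matrix(8, 40)
  expect_equal(nucleotide_diversity(H, 60),
               nucleotide_diversity(H[sample(8), sample(40)], 60))
})

test_that("Tajima's D uses the canonical constants and is NA when undefined", {
  # no segregating sites -> undefined, never 0
  expect_true(is.na(tajimas_d(matrix(0L, 6, 10))))
  # all singletons -> negative D
  H <- matrix(0L, 10, 5)
  for (s in 1:5) H[s, s] <- 1L
  expect_lt(tajimas_d(H), 0)

  set.seed(9)
  for (rep in 1:100) {
    H <- random_hap_matrix(sample(4:12, 1), sample(5:40, 1),
                           miss = sample(c(0, 0.05), 1))
    expect_equal(tajimas_d(H), oracle_tajima(H), tolerance = 1e-12)
  }

  # neutral coalescent samples: D agrees with the oracle on every draw and
  # its mean is near 0 relative to its spread
  set.seed(10)
  d <- replicate(200, {
    H <- oracle_coalescent_sample(20, theta = 5)
    val <- tajimas_d(H)
    expect_equal(val, oracle_tajima(H), tolerance = 1e-12)
    val
  })
  d <- d[!is.na(d)]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.25)
})

test_that("windowed statistics tile the region and partition S", {
  set.seed(12)
  n <- 20; m <- 120
  H <- random_hap_matrix(n, m, miss = 0.02)
  positions <- sort(sample(0:99999, m))
  w <- sliding_window_stats(H, positions, 0, 100000, width = 25000)
  expect_equal(nrow(w), 4)
  expect_false(any(w$partial))
  total <- invtools:::tajima_components(H)$S
  expect_equal(sum(w$S), total)
  for (k in seq_len(nrow(w))) {
    sel <- positions >= w$start[k] & positions < w$end[k]
    expect_equal(w$pi[k], oracle_pi(H[, sel, drop = FALSE], 25000),
                 tolerance = 1e-12)
  }
  # final partial window has its true width and is flagged
  w2 <- sliding_window_stats(H, positions, 0, 90000, width = 25000)
  expect_equal(nrow(w2), 4)
  expect_true(w2$partial[4])
  expect_equal(w2$end[4] - w2$start[4], 15000)
  expect_error(sliding_window_stats(H, positions, 0, 100, width = 0),
               "positive")
})

test_that("Hudson Fst matches its fixed points and the per-site oracle", {
  set.seed(14)
  # identical sample allele frequencies in both groups -> exactly 0 with
  # the plug-in variant
  H <- random_hap_matrix(6, 30)
  Hs <- rbind(H, H)
  g <- rep(c("a", "b"), each = 6)
  expect_equal(pairwise_fst(Hs, g, estimator = "hudson_plugin")$fst["a", "b"],
               0)
  # fixed alternative alleles at every site -> 1 for both Hudson forms
  Hf <- rbind(matrix(0L, 5, 20), matrix(1L, 5, 20))
  expect_equal(pairwise_fst(Hf, rep(c("a", "b"), each = 5))$fst["a", "b"], 1)
  expect_equal(pairwise_fst(Hf, rep(c("a", "b"), each = 5),
                            estimator = "hudson_plugin")$fst["a", "b"], 1)

  for (rep in 1:100) {
    H1 <- random_hap_matrix(sample(3:8, 1), 25, miss = 0.05)
    H2 <- random_hap_matrix(sample(3:8, 1), 25, miss = 0.05)
    g2 <- rep(c("a", "b"), c(nrow(H1), nrow(H2)))
    got <- pairwise_fst(rbind(H1, H2), g2)
    expect_equal(got$fst["a", "b"], oracle_hudson_fst(H1, H2),
                 tolerance = 1e-12)
    got_p <- pairwise_fst(rbind(H1, H2), g2, estimator = "hudson_plugin")
    expect_equal(got_p$fst["a", "b"],
                 oracle_hudson_fst(H1, H2, plugin = TRUE),
                 tolerance = 1e-12)
  }

  # panmictic split: Fst indistinguishable from 0
  vals <- replicate(50, {
    p <- runif(40, 0.2, 0.8)
    H <- vapply(p, function(q) rbinom(40, 1, q), integer(40))
    pairwise_fst(H, rep(c("a", "b"), each = 20))$fst["a", "b"]
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))

  # groups below 2 haplotypes are excluded and reported
  H <- random_hap_matrix(5, 10)
  r <- pairwise_fst(H, c("a", "a", "b", "b", "c"))
  expect_equal(r$excluded_groups, "c")
  expect_true(pairwise_fst(Hf, rep(c("a", "b"), each = 5),
                           estimator = "wc")$fst["a", "b"] > 0.9)
})

test_that("Fst never exceeds 1 and matrices are symmetric with zero diagonal", {
  set.seed(15)
  for (rep in 1:30) {
    H <- random_hap_matrix(12, 20, miss = 0.05)
    g <- sample(c("a", "b", "c"), 12, replace = TRUE)
    if (min(table(g)) < 2) next
    r <- pairwise_fst(H, g)
    expect_true(all(r$fst <= 1 + 1e-12))
    expect_equal(r$fst, t(r$fst))
    expect_true(all(diag(r$fst) == 0))
  }
})

test_that("distance trees recover known topologies", {
  # 3 haplotypes: the unique unrooted topology
  H <- rbind(a = c(0L, 0L, 0L), b = c(1L, 0L, 0L), c = c(1L, 1L, 0L))
  tr <- build_distance_tree(H)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_true(all(tr$edge.length >= 0))

  # additive 4-leaf metric: ((a,b),(c,d)) with distinct internal edge
  H4 <- rbind(a = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
              b = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
              c = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L),
              d = c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L))
  tr4 <- build_distance_tree(H4)
  rooted <- ape::root(tr4, "a", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("c", "d")))

  expect_error(build_distance_tree(H[1:2, , drop = FALSE]), "3 haplotypes")
})

test_that("H1 haplotypes form a single clade on synthetic cohorts", {
  fx <- generate_cohort(small_cohort_config(seed = 51, n = 30,
                                            h2prime = 0.25, h2d = 0.25))
  labels <- paste0("h", seq_len(nrow(fx$haplotypes)), "_", fx$hap_subtype)
  tr <- build_distance_tree(fx$haplotypes, labels = labels)
  h2_tip <- labels[fx$hap_subtype != "H1"][1]
  rooted <- ape::root(tr, h2_tip, resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, labels[fx$hap_subtype == "H1"]))
})

test_that("pi orderings configured into the generator are recovered", {
  cfg <- small_cohort_config(seed = 61, n = 80, h2prime = 0.3, h2d = 0.2,
                             n_sites = 150,
                             within_family_theta = c(0.012, 0.001))
  fx <- generate_cohort(cfg)
  span <- region_span(fx$region)
  L <- span[2] - span[1]
  h1 <- fx$hap_subtype == "H1"
  pi_all <- nucleotide_diversity(fx$haplotypes, L)
  pi_h1 <- nucleotide_diversity(fx$haplotypes[h1, ], L)
  pi_h2 <- nucleotide_diversity(fx$haplotypes[!h1, ], L)
  expect_gt(pi_all, pi_h1)
  expect_gt(pi_h1, pi_h2)
})

test_that("frequency tables count truth labels exactly", {
  # arithmetic fixed point
  typed <- data.frame(sample = sprintf("s%d", 1:100),
                      inv_genotype = c(rep("H1/H1", 63),
                                       rep("H1/H2", 24),
                                       rep("H2/H2", 13)),
                      dup_dosage = c(rep(0L, 63), rep(1L, 12), rep(0L, 12),
                                     rep(2L, 8), rep(1L, 3), rep(0L, 2)),
                      stringsAsFactors = FALSE)
  groups <- setNames(rep("g", 100), typed$sample)
  ft <- haplotype_frequency_table(typed, groups)
  expect_equal(ft$H1 + ft$H2prime + ft$H2D, 200L)
  expect_equal(ft$cum_H2, (24 + 26) / 200)
  expect_equal(ft$H2D, sum(typed$dup_dosage))

  # synthetic cohort equals direct truth counting; ambiguous rows excluded
  fx <- generate_cohort(two_group_cohort_config(seed = 71))
  typed <- type_structures(cohort_genotypes(fx), fx$panel)
  typed$inv_genotype[1] <- "ambiguous"
  groups <- setNames(fx$truth$group, fx$truth$sample)
  ft <- haplotype_frequency_table(typed, groups)
  expect_equal(sum(ft$n_excluded), 1)
  for (g in c("a", "b")) {
    sel <- fx$truth$group == g & typed$inv_genotype != "ambiguous"
    truth_h2d <- sum(fx$truth$dup_dosage[sel])
    expect_equal(ft$H2D[ft$group == g], truth_h2d)
  }
  # all-H1 group has zero cumulative H2
  t0 <- data.frame(sample = "s1", inv_genotype = "H1/H1", dup_dosage = 0L)
  ft0 <- haplotype_frequency_table(t0, c(s1 = "solo"))
  expect_equal(ft0$cum_H2, 0)
})
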