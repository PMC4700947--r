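# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# per-site pi by explicit pair loop with pairwise deletion and
# renormalization of each pair's mismatch count to the span L
oracle_pi <- function(H, L) {
  n <- nrow(H)
  if (n < 2) return(NA_real_)
  acc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(H[i, ]) & !is.na(H[j, ])
      mism <- sum(H[i, ok] != H[j, ok])
      acc <- acc + mism / (L - sum(!ok))
    }
  }
  acc / choose(n, 2)
}

# Tajima (1989) D from first principles: mean pairwise difference count by
# explicit loop, S by direct count, constants written out independently
oracle_tajima <- function(H) {
  keep <- apply(H, 2, function(col) !any(is.na(col)))
  H <- H[, keep, drop = FALSE]
  n <- nrow(H)
  if (n < 2) return(NA_real_)
  cnt <- colSums(H)
  S <- sum(cnt > 0 & cnt < n)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      k <- k + sum(H[i, ] != H[j, ])
  khat <- k / (n * (n - 1) / 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (khat - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# Hudson Fst by explicit per-site loop, ratio of averages; plugin = TRUE
# uses raw sample heterozygosities, otherwise the unbiased n/(n-1) form
oracle_hudson_fst <- function(H1, H2, plugin = FALSE) {
  num <- den <- 0
  for (s in seq_len(ncol(H1))) {
    g1 <- H1[, s][!is.na(H1[, s])]
    g2 <- H2[, s][!is.na(H2[, s])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(g1); p2 <- mean(g2)
    pall <- mean(c(g1, g2))
    if (pall <= 0 || pall >= 1) next
    if (plugin) {
      num <- num + p1 * (1 - p1) + p2 * (1 - p2)
    } else {
      num <- num + p1 * (1 - p1) * n1 / (n1 - 1) +
        p2 * (1 - p2) * n2 / (n2 - 1)
    }
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) return(NA_real_)
  1 - num / den
}

# scoring function of the depth HMM, stated once here for the brute-force
# path search: initial neutral preference, NB emissions, symmetric switch
# penalty (must mirror the documented model, not the package's DP code)
hmm_path_score <- function(path, depth, ratios, penalty, dispersion,
                           baseline) {
  init <- c(-penalty, 0, -penalty)
  s <- init[path[1]] +
    dnbinom(round(depth[1]), size = dispersion,
            mu = ratios[path[1]] * baseline, log = TRUE)
  if (length(path) > 1) {
    for (t in 2:length(path)) {
      s <- s + (if (path[t] != path[t - 1]) -penalty else 0) +
        dnbinom(round(depth[t]), size = dispersion,
                mu = ratios[path[t]] * baseline, log = TRUE)
    }
  }
  s
}

# exhaustive best path over all 3^k state sequences
oracle_hmm_best <- function(depth, ratios, penalty, dispersion, baseline) {
  k <- length(depth)
  grid <- as.matrix(expand.grid(rep(list(1:3), k)))
  scores <- apply(grid, 1, hmm_path_score, depth = depth, ratios = ratios,
                  penalty = penalty, dispersion = dispersion,
                  baseline = baseline)
  list(score = max(scores), path = grid[which.max(scores), ])
}

# Hudson (no-recombination) coalescent simulator: returns a binary
# haplotype matrix for n samples under the infinite-sites model with
# population-scaled mutation rate theta (= 4*Ne*mu*L)
oracle_coalescent_sample <- function(n, theta) {
  lineages <- lapply(seq_len(n), function(i) i)
  sites <- list()
  k <- n
  while (k > 1) {
    t_k <- rexp(1, rate = choose(k, 2))
    for (l in lineages) {
      m <- rpois(1, theta / 2 * t_k)
      if (m > 0) sites <- c(sites, rep(list(l), m))
    }
    pick <- sample(k, 2)
    merged <- c(lineages[[pick[1]]], lineages[[pick[2]]])
    lineages <- c(lineages[-pick], list(merged))
    k <- k - 1
  }
  H <- matrix(0L, nrow = n, ncol = length(sites))
  for (s in seq_along(sites)) H[sites[[s]], s] <- 1L
  H
}

# random small haplotype matrix with optional missingness
random_hap_matrix <- function(n, m, miss = 0) {
  H <- matrix(rbinom(n * m, 1, runif(1, 0.1, 0.9)), nrow = n)
  if (miss > 0) H[runif(n * m) < miss] <- NA_integer_
  H
}
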