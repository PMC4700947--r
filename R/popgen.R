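#' Phased haplotype matrix with structural and group labels
#'
#' Thin container tying a binary allele matrix to site positions and
#' per-haplotype labels, the form in which phased haplotypes are sorted by
#' structural status (H1, H2prime, H2D) and geographic group.
#'
#' @param H 0/1 allele matrix (`NA` allowed), haplotypes x sites.
#' @param positions 0-based site positions, strictly increasing.
#' @param subtype per-haplotype structural subtype.
#' @param group per-haplotype group label.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(H, positions, subtype, group) {
  stopifnot(is.matrix(H), length(positions) == ncol(H),
            length(subtype) == nrow(H), length(group) == nrow(H))
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  structure(list(H = H, positions = positions,
                 subtype = subtype, group = group),
            class = "haplotype_matrix")
}

# pairwise mismatch / comparable-site counts with pairwise deletion
pairwise_counts <- function(H) {
  M1 <- (H == 1); M1[is.na(M1)] <- FALSE; storage.mode(M1) <- "numeric"
  M0 <- (H == 0); M0[is.na(M0)] <- FALSE; storage.mode(M0) <- "numeric"
  mism <- M0 %*% t(M1)
  mism <- mism + t(mism)
  ok <- M0 + M1
  comparable <- ok %*% t(ok)
  list(mism = mism, comparable = comparable)
}

#' Per-site nucleotide diversity (pi)
#'
#' Average pairwise difference per site: for each unordered haplotype pair
#' the allele mismatches are counted over mutually non-missing sites and
#' renormalized to the span length `L` (missing sites of the pair are
#' subtracted from `L`); the mean over pairs is divided by `L` implicitly
#' through that renormalization.
#'
#' @param H 0/1 allele matrix (`NA` = missing), haplotypes x sites. Sites
#'   absent from the matrix are assumed invariant across the span.
#' @param L span length in bp over which the matrix sites were observed.
#' @return per-site pi; `NA` if fewer than 2 haplotypes.
#' @export
nucleotide_diversity <- function(H, L) {
  stopifnot(is.matrix(H), L > 0)
  n <- nrow(H)
  if (n < 2) return(NA_real_)
  pc <- pairwise_counts(H)
  denom <- L - (ncol(H) - pc$comparable)
  if (any(denom[upper.tri(denom)] <= 0))
    stop("a haplotype pair has no comparable span")
  rate <- pc$mism / denom
  sum(rate[upper.tri(rate)]) / choose(n, 2)
}

# S and unnormalized mean pairwise difference count over complete-case sites
tajima_components <- function(H) {
  keep <- colSums(is.na(H)) == 0L
  Hc <- H[, keep, drop = FALSE]
  n <- nrow(Hc)
  x <- colSums(Hc)
  seg <- x > 0L & x < n
  S <- sum(seg)
  pi_sum <- if (S == 0) 0 else sum(x[seg] * (n - x[seg])) / choose(n, 2)
  list(n = n, S = S, pi_sum = pi_sum)
}

#' Tajima's D
#'
#' The standard normalized difference between the mean pairwise difference
#' count and the segregating-sites estimator of theta:
#' `D = (pi_sum - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the canonical
#' constants a1, a2, b1, b2, c1, c2, e1, e2 computed from the sample size.
#' Sites with any missing call are dropped (complete cases), so the
#' constants are exact for a single `n`. Undefined (returned as `NA`) when
#' there are no segregating sites or fewer than 2 haplotypes — never 0.
#'
#' @param H 0/1 allele matrix, haplotypes x sites.
#' @return D, or `NA` when undefined.
#' @export
tajimas_d <- function(H) {
  stopifnot(is.matrix(H))
  if (nrow(H) < 2) return(NA_real_)
  tc <- tajima_components(H)
  n <- tc$n; S <- tc$S
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (tc$pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed diversity statistics
#'
#' Tiles `[region_start, region_end)` with non-overlapping windows
#' (default 25 kb) and computes per window the number of haplotypes used,
#' segregating sites S (complete-case, matching [tajimas_d()]), per-site
#' pi over the window's true width, and Tajima's D. The final window is
#' emitted with its true (possibly shorter) width and flagged `partial`.
#'
#' @param H 0/1 allele matrix, haplotypes x sites.
#' @param positions 0-based site positions parallel to `H` columns.
#' @param region_start,region_end 0-based half-open span to tile.
#' @param width window width in bp (default 25,000).
#' @return a `data.frame` of class `window_stat` with columns `start`,
#'   `end`, `n_haplotypes`, `S`, `pi`, `tajimas_d`, `partial`.
#' @export
sliding_window_stats <- function(H, positions, region_start, region_end,
                                 width = 25000L) {
  stopifnot(is.matrix(H), length(positions) == ncol(H))
  if (width <= 0) stop("window width must be positive")
  if (region_end <= region_start) stop("empty region")
  starts <- seq(region_start, region_end - 1L, by = width)
  ends <- pmin(starts + width, region_end)
  rows <- lapply(seq_along(starts), function(k) {
    in_win <- positions >= starts[k] & positions < ends[k]
    Hw <- H[, in_win, drop = FALSE]
    tc <- tajima_components(Hw)
    w <- ends[k] - starts[k]
    data.frame(start = starts[k], end = ends[k],
               n_haplotypes = nrow(H),
               S = tc$S,
               pi = nucleotide_diversity(Hw, L = w),
               tajimas_d = tajimas_d(Hw),
               partial = w < width)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_stat", "data.frame")
  out
}

# Hudson Fst for one pair of groups, ratio of averages across sites.
# Sites monomorphic across both groups are excluded (they contribute 0/0).
# Default form uses the unbiased within-group heterozygosity
# (p*(1-p)*n/(n-1)), giving an estimator whose numerator is unbiased under
# panmixia; `plugin = TRUE` uses raw sample heterozygosities
# (1 - sum(Hw)/sum(Hb) on plug-in frequencies), which is exactly 0 when
# the two sample frequency vectors coincide.
hudson_fst_pair <- function(H1, H2, plugin = FALSE) {
  p1 <- colMeans(H1, na.rm = TRUE)
  p2 <- colMeans(H2, na.rm = TRUE)
  n1 <- colSums(!is.na(H1))
  n2 <- colSums(!is.na(H2))
  tot <- (p1 * n1 + p2 * n2) / (n1 + n2)
  keep <- !is.na(tot) & tot > 0 & tot < 1 & n1 > 1 & n2 > 1
  if (!any(keep)) return(NA_real_)
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  hw <- if (plugin)
    p1 * (1 - p1) + p2 * (1 - p2)
  else
    p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - sum(hw) / sum(hb)
}

# Weir-Cockerham theta for haploid allele data, two groups, ratio of
# averages across sites.
wc_fst_pair <- function(H1, H2) {
  p1 <- colMeans(H1, na.rm = TRUE)
  p2 <- colMeans(H2, na.rm = TRUE)
  n1 <- colSums(!is.na(H1))
  n2 <- colSums(!is.na(H2))
  tot <- (p1 * n1 + p2 * n2) / (n1 + n2)
  keep <- !is.na(tot) & tot > 0 & tot < 1 & n1 > 1 & n2 > 1
  if (!any(keep)) return(NA_real_)
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  nt <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2        # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  sum(num) / sum(den)
}

#' Pairwise Fst between groups
#'
#' Hudson-type estimator by default: ratio of averages across sites,
#' `Fst = 1 - sum(within-group heterozygosity) / sum(between-group
#' heterozygosity)`, with the unbiased within-group heterozygosity
#' (`p(1-p) n/(n-1)`), chosen for robustness to unequal sample sizes and
#' for being correctly centered at 0 under panmixia. Two variants are
#' available: `"hudson_plugin"` uses raw sample heterozygosities (exactly
#' 0 whenever the two sample frequency vectors coincide, but biased
#' upward by about `(1/n1 + 1/n2)/2`), and `"wc"` is a Weir-Cockerham
#' estimator. Negative estimates are reported as computed unless
#' `clamp = TRUE`. Groups with fewer than 2 haplotypes are excluded and
#' reported.
#'
#' @param H 0/1 allele matrix, haplotypes x sites.
#' @param groups group label per haplotype.
#' @param estimator `"hudson"`, `"hudson_plugin"` or `"wc"`.
#' @param clamp clamp negative estimates to 0.
#' @param thresholds annotation thresholds: below the first is low
#'   stratification, above the second high.
#' @return a list of class `differentiation_report`: `fst` (symmetric
#'   matrix, diagonal 0), `estimator`, `thresholds`, `excluded_groups`.
#' @export
pairwise_fst <- function(H, groups,
                         estimator = c("hudson", "hudson_plugin", "wc"),
                         clamp = FALSE, thresholds = c(low = 0.20,
                                                       high = 0.50)) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(H), length(groups) == nrow(H))
  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2]
  excluded <- setdiff(names(sizes), usable)
  if (length(usable) < 2)
    stop("need at least two groups with >= 2 haplotypes")
  fun <- switch(estimator,
                hudson = hudson_fst_pair,
                hudson_plugin = function(a, b)
                  hudson_fst_pair(a, b, plugin = TRUE),
                wc = wc_fst_pair)
  k <- length(usable)
  M <- matrix(0, k, k, dimnames = list(usable, usable))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      f <- fun(H[groups == usable[i], , drop = FALSE],
               H[groups == usable[j], , drop = FALSE])
      if (clamp && !is.na(f)) f <- max(f, 0)
      M[i, j] <- M[j, i] <- f
    }
  }
  structure(list(fst = M, estimator = estimator, thresholds = thresholds,
                 excluded_groups = excluded),
            class = "differentiation_report")
}

#' @export
print.differentiation_report <- function(x, ...) {
  cat("Pairwise Fst (", x$estimator, " estimator)\n", sep = "")
  print(round(x$fst, 4))
  if (length(x$excluded_groups))
    cat("excluded (n < 2):", paste(x$excluded_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Neighbor-joining tree of haplotypes
#'
#' Pairwise distance is the proportion of mismatching alleles over
#' mutually non-missing sites; the tree is built by neighbor joining with
#' negative branch lengths clamped to 0. This deterministic distance tree
#' stands in for a Bayesian MCMC reconstruction: the qualitative topology
#' (arrangement families as separate clades) is the supported claim, not
#' posterior support values.
#'
#' @param H 0/1 allele matrix, haplotypes x sites (>= 3 haplotypes).
#' @param labels tip labels; default `hap1 ... hapN` or rownames of `H`.
#' @return an [ape::phylo] tree.
#' @export
build_distance_tree <- function(H, labels = NULL) {
  stopifnot(is.matrix(H))
  n <- nrow(H)
  if (n < 3) stop("need at least 3 haplotypes")
  if (is.null(labels))
    labels <- if (!is.null(rownames(H))) rownames(H) else
      paste0("hap", seq_len(n))
  pc <- pairwise_counts(H)
  if (any(pc$comparable[upper.tri(pc$comparable)] == 0))
    stop("a haplotype pair has no comparable sites")
  D <- pc$mism / pc$comparable
  dimnames(D) <- list(labels, labels)
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Structural haplotype frequencies per group
#'
#' Counts H1, H2prime and H2D haplotypes per group from typed structural
#' genotypes (each diploid contributes two haplotype counts) and derives
#' frequencies and the cumulative H2 frequency. Samples with an ambiguous
#' or uncalled inversion genotype, or ambiguous duplication dosage among
#' H2 carriers, are excluded and reported.
#'
#' @param typed a [type_structures()] result (or data.frame with columns
#'   `sample`, `inv_genotype`, `dup_dosage`).
#' @param groups named character vector mapping sample id to group.
#' @return a `data.frame` of class `group_frequency_table` with counts,
#'   frequencies, `cum_H2` and `n_excluded` per group.
#' @export
haplotype_frequency_table <- function(typed, groups) {
  stopifnot(all(c("sample", "inv_genotype", "dup_dosage") %in% names(typed)))
  if (!all(typed$sample %in% names(groups)))
    stop("every sample must be mapped to a group")
  g <- groups[typed$sample]
  n_h2 <- c("H1/H1" = 0L, "H1/H2" = 1L, "H2/H2" = 2L)[typed$inv_genotype]
  usable <- !is.na(n_h2) & (n_h2 == 0L | !is.na(typed$dup_dosage)) &
    (is.na(typed$dup_dosage) | typed$dup_dosage <= n_h2)
  rows <- lapply(unique(groups), function(gr) {
    sel <- usable & g == gr
    n_ind <- sum(g == gr, na.rm = TRUE)
    n_use <- sum(sel)
    if (n_use == 0) {
      return(data.frame(group = gr, n_individuals = n_ind, n_excluded = n_ind,
                        H1 = 0L, H2prime = 0L, H2D = 0L,
                        freq_H1 = NA_real_, freq_H2prime = NA_real_,
                        freq_H2D = NA_real_, cum_H2 = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    h2d <- sum(typed$dup_dosage[sel], na.rm = TRUE)
    h2 <- sum(n_h2[sel])
    tot <- 2L * n_use
    h1 <- tot - h2
    data.frame(group = gr, n_individuals = n_ind, n_excluded = n_ind - n_use,
               H1 = h1, H2prime = h2 - h2d, H2D = h2d,
               freq_H1 = h1 / tot, freq_H2prime = (h2 - h2d) / tot,
               freq_H2D = h2d / tot, cum_H2 = h2 / tot,
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !out$undefined
  stopifnot(all(abs(out$freq_H1[ok] + out$freq_H2prime[ok] +
                      out$freq_H2D[ok] - 1) < 1e-12))
  class(out) <- c("group_frequency_table", "data.frame")
  out
}
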