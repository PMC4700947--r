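#' Configuration for a synthetic inversion cohort
#'
#' The generator emulates the population structure of the locus: two deeply
#' diverged founder haplotypes (H1 and H2) that do not recombine, a
#' duplication carried by a subset of the H2 family (the H2D subtype),
#' family-diagnostic tag SNPs, and group-specific subtype frequencies.
#'
#' @param groups named integer vector: individuals per group.
#' @param subtype_freqs data.frame with columns `group`, `H2prime`, `H2D`
#'   giving per-group haplotype frequencies of the two inverted subtypes
#'   (the remainder is H1). Per group `H2prime + H2D <= 1`.
#' @param n_sites total number of segregating sites to simulate (must be at
#'   least the number of tag SNPs).
#' @param region a [region_annotation()].
#' @param panel a [tag_snp_panel()]; defaults to [default_tag_panel()].
#' @param divergence_scale probability that a non-tag site differs between
#'   the H1 and H2 founders (deep between-family divergence).
#' @param within_family_theta per-site probability that a haplotype carries
#'   a private mutation relative to its family founder (shallow
#'   within-family diversity); either one rate for both families or a
#'   length-2 vector `c(H1, H2)` to give the families different depths
#'   (the standard arrangement is typically the more diverse one).
#' @param tag_error per-tag allele error rate (default 0: perfect tagging).
#' @param seed integer seed; every draw in the generator is governed by it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(groups,
                          subtype_freqs,
                          n_sites = 120L,
                          region = region_annotation(),
                          panel = default_tag_panel(region),
                          divergence_scale = 0.3,
                          within_family_theta = 0.002,
                          tag_error = 0,
                          seed = 1L) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named vector")
  if (any(groups < 1)) stop("group sizes must be positive")
  stopifnot(is.data.frame(subtype_freqs),
            all(c("group", "H2prime", "H2D") %in% names(subtype_freqs)))
  if (!setequal(subtype_freqs$group, names(groups)))
    stop("subtype_freqs must cover exactly the configured groups")
  f <- subtype_freqs
  if (any(f$H2prime < 0 | f$H2D < 0 | f$H2prime > 1 | f$H2D > 1))
    stop("subtype frequencies must lie in [0, 1]")
  if (any(f$H2prime + f$H2D > 1 + 1e-12))
    stop("per group, H2prime + H2D frequencies must sum to at most 1")
  if (n_sites < nrow(panel))
    stop("n_sites too small: the tag panel alone has ", nrow(panel), " sites")
  if (!length(within_family_theta) %in% 1:2)
    stop("within_family_theta must have length 1 or 2")
  if (divergence_scale < 0 || divergence_scale > 1 ||
      any(within_family_theta < 0) || any(within_family_theta > 1) ||
      tag_error < 0 || tag_error > 1)
    stop("rates must lie in [0, 1]")
  within_family_theta <- rep_len(within_family_theta, 2L)
  structure(list(groups = groups, subtype_freqs = f,
                 n_sites = as.integer(n_sites), region = region,
                 panel = panel, divergence_scale = divergence_scale,
                 within_family_theta = within_family_theta,
                 tag_error = tag_error, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort configuration mirroring the published study design
#'
#' Six continental groups with the published per-group sample sizes
#' (523, 181, 156, 549, 350 and 361 individuals; 2,120 in total) and
#' subtype frequencies chosen so that the cumulative H2 frequency per
#' group matches the published pattern (0.7% in Sub-Saharan Africa up to
#' 33.7% in South Europe, with H2D enriched over H2prime outside
#' Sub-Saharan Africa).
#'
#' @param seed integer seed.
#' @param n_sites number of sites (see [cohort_config()]).
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, n_sites = 120L) {
  groups <- c("Sub-Saharan Africa" = 523L, "North Africa" = 181L,
              "Middle East" = 156L, "South Asia" = 549L,
              "Europe" = 350L, "South Europe" = 361L)
  freqs <- data.frame(
    group = names(groups),
    H2prime = c(0.0035, 0.040, 0.050, 0.022, 0.060, 0.100),
    H2D     = c(0.0035, 0.106, 0.130, 0.060, 0.160, 0.237),
    stringsAsFactors = FALSE
  )
  cohort_config(groups = groups, subtype_freqs = freqs,
                n_sites = n_sites, seed = seed)
}

#' Generate a synthetic cohort with known structural truth
#'
#' Haplotypes are drawn on a fixed grid of `n_sites` positions inside the
#' annotated region (infinite-sites: at most one mutation per grid
#' position). An H1 founder (all ancestral) and an H2 founder (differing at
#' non-tag sites with probability `divergence_scale`) are built first; tag
#' diagnostic alleles are placed on the appropriate founder (inversion tags
#' on H2, duplication tags on H2D only). Each individual then receives two
#' haplotype subtypes sampled from its group's frequencies, and each
#' haplotype gets private within-family mutations at rate
#' `within_family_theta` per non-tag site.
#'
#' @param cfg a [cohort_config()].
#' @return an object of class `cohort_fixture`: a list with
#'   \describe{
#'     \item{haplotypes}{0/1 matrix, 2 rows per individual x `n_sites`.}
#'     \item{positions}{0-based site positions, strictly increasing.}
#'     \item{hap_subtype}{truth subtype per haplotype
#'       (`H1`, `H2prime`, `H2D`).}
#'     \item{hap_sample, hap_group}{sample / group per haplotype.}
#'     \item{truth}{per-individual truth table: sample, group, subtype1,
#'       subtype2, inv_genotype, dup_dosage.}
#'     \item{panel, region, config}{inputs used.}
#'   }
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  region <- cfg$region
  panel <- cfg$panel
  span <- region_span(region)
  tag_pos0 <- panel$pos - 1L
  n_extra <- cfg$n_sites - nrow(panel)
  grid <- setdiff(seq(span[1], span[2] - 1L), tag_pos0)
  extra <- if (n_extra > 0) sort(sample(grid, n_extra)) else integer(0)
  positions <- sort(c(tag_pos0, extra))
  is_tag <- positions %in% tag_pos0
  tag_idx <- match(tag_pos0, positions)           # panel row -> site column
  diag_num <- ifelse(panel$diagnostic == "alt", 1L, 0L)
  inv_tag <- panel$tagged_structure == "inversion"
  dup_tag <- panel$tagged_structure == "duplication"

  n_sites <- cfg$n_sites
  h1 <- integer(n_sites)
  h1[tag_idx] <- 1L - diag_num                    # H1 carries the non-diagnostic allele
  h2 <- h1
  nontag <- which(!is_tag)
  h2[nontag] <- as.integer(runif(length(nontag)) < cfg$divergence_scale)
  h2[tag_idx[inv_tag]] <- diag_num[inv_tag]
  h2d <- h2
  h2d[tag_idx[dup_tag]] <- diag_num[dup_tag]
  founders <- list(H1 = h1, H2prime = h2, H2D = h2d)

  n_ind <- sum(cfg$groups)
  group_of <- rep(names(cfg$groups), cfg$groups)
  samples <- sprintf("S%05d", seq_len(n_ind))
  f <- cfg$subtype_freqs
  rownames(f) <- f$group

  hap_subtype <- character(2L * n_ind)
  H <- matrix(0L, nrow = 2L * n_ind, ncol = n_sites)
  for (i in seq_len(n_ind)) {
    p <- f[group_of[i], ]
    probs <- c(H1 = 1 - p$H2prime - p$H2D, H2prime = p$H2prime, H2D = p$H2D)
    st <- sample(names(probs), 2L, replace = TRUE, prob = probs)
    for (k in 1:2) {
      h <- founders[[st[k]]]
      wft <- cfg$within_family_theta[if (st[k] == "H1") 1L else 2L]
      flip <- runif(length(nontag)) < wft
      h[nontag[flip]] <- 1L - h[nontag[flip]]
      if (cfg$tag_error > 0) {
        terr <- runif(length(tag_idx)) < cfg$tag_error
        h[tag_idx[terr]] <- 1L - h[tag_idx[terr]]
      }
      H[2L * (i - 1L) + k, ] <- h
      hap_subtype[2L * (i - 1L) + k] <- st[k]
    }
  }

  truth <- data.frame(
    sample = samples,
    group = group_of,
    subtype1 = hap_subtype[seq(1, 2 * n_ind, by = 2)],
    subtype2 = hap_subtype[seq(2, 2 * n_ind, by = 2)],
    stringsAsFactors = FALSE
  )
  n_h2 <- (truth$subtype1 != "H1") + (truth$subtype2 != "H1")
  truth$inv_genotype <- c("H1/H1", "H1/H2", "H2/H2")[n_h2 + 1L]
  truth$dup_dosage <- (truth$subtype1 == "H2D") + (truth$subtype2 == "H2D")

  structure(list(
    haplotypes = H,
    positions = positions,
    hap_subtype = hap_subtype,
    hap_sample = rep(samples, each = 2L),
    hap_group = rep(group_of, each = 2L),
    truth = truth,
    panel = panel,
    region = region,
    config = cfg
  ), class = "cohort_fixture")
}

#' @export
print.cohort_fixture <- function(x, ...) {
  cat("Synthetic inversion cohort:",
      nrow(x$truth), "individuals,",
      nrow(x$haplotypes), "haplotypes,",
      ncol(x$haplotypes), "sites\n")
  print(table(x$hap_group, x$hap_subtype))
  invisible(x)
}

#' Diploid ALT-dosage genotypes of a cohort fixture
#'
#' Collapses the two haplotypes of each individual into an allele-dosage
#' matrix (0/1/2), the representation the structural typer consumes.
#'
#' @param fixture a [generate_cohort()] result.
#' @return integer matrix, individuals x sites; rownames are sample ids,
#'   colnames `"<chrom>:<pos1>"` with 1-based positions.
#' @export
cohort_genotypes <- function(fixture) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  H <- fixture$haplotypes
  n <- nrow(H) / 2L
  G <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
       H[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(G) <- fixture$truth$sample
  colnames(G) <- paste0(fixture$region$chrom, ":", fixture$positions + 1L)
  G
}
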