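#' Call the inversion genotype of one individual from tag SNPs
#'
#' Each inversion tag votes with its diagnostic-allele count (0, 1 or 2
#' copies of the allele carried by the inverted H2 family). Votes are
#' combined by unanimity: all tags agreeing on 0, 1 or 2 yields H1/H1,
#' H1/H2 or H2/H2 respectively; any disagreement yields `"ambiguous"` with
#' the vote tally attached. Missing genotypes are excluded from voting.
#' No majority override is applied: discordant tags are evidence of a
#' problem (genotyping error or recombinant), not something to outvote.
#'
#' @param tag_geno integer vector of ALT-allele dosages (0/1/2, `NA` for
#'   missing) at the panel's tag sites, in panel row order.
#' @param panel a [tag_snp_panel()].
#' @param min_informative minimum number of non-missing inversion tags
#'   required to call (default 1).
#' @return a list of class `inversion_call`: `genotype` (one of `"H1/H1"`,
#'   `"H1/H2"`, `"H2/H2"`, `"ambiguous"`), `votes` (per-tag diagnostic
#'   counts, `NA` where missing), `tally` (table of non-missing votes),
#'   `n_used`.
#' @export
call_inversion_genotype <- function(tag_geno, panel, min_informative = 1L) {
  stopifnot(inherits(panel, "tag_snp_panel"),
            length(tag_geno) == nrow(panel))
  votes <- diagnostic_votes(tag_geno, panel,
                            which(panel$tagged_structure == "inversion"))
  used <- votes[!is.na(votes)]
  if (length(used) == 0)
    stop_no_tags("all inversion tags missing: cannot call")
  if (length(used) < min_informative)
    stop_no_tags("fewer informative inversion tags than min_informative")
  gt <- if (length(unique(used)) == 1L)
    c("H1/H1", "H1/H2", "H2/H2")[used[1] + 1L] else "ambiguous"
  structure(list(genotype = gt, votes = votes,
                 tally = table(used), n_used = length(used)),
            class = "inversion_call")
}

diagnostic_votes <- function(tag_geno, panel, rows) {
  g <- tag_geno[rows]
  if (any(!is.na(g) & !(g %in% 0:2)))
    stop("tag genotypes must be allele dosages in 0..2")
  ifelse(panel$diagnostic[rows] == "alt", g, 2L - g)
}

stop_no_tags <- function(msg) {
  stop(structure(class = c("invtools_no_tags", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Call the duplication dosage of one individual
#'
#' The dosage is the unanimous diagnostic-allele count over the
#' duplication tags: the number of H2D haplotypes the individual carries.
#' A dosage exceeding the number of H2 haplotypes implied by the inversion
#' genotype sets the `conflict` flag; H1/H1 individuals with nonzero
#' dosage are additionally flagged as possible H1-background copy-number
#' variants (they are never typed H2D). Missing tags are excluded; if all
#' duplication tags are missing the dosage is ambiguous (`NA`).
#'
#' @inheritParams call_inversion_genotype
#' @param inversion_genotype the individual's inversion genotype string.
#' @return a list of class `duplication_call`: `dosage` (0/1/2, `NA` if
#'   ambiguous), `conflict`, `h1_background`, `tally`.
#' @export
call_duplication_dosage <- function(tag_geno, inversion_genotype, panel,
                                    min_informative = 1L) {
  stopifnot(inherits(panel, "tag_snp_panel"),
            length(tag_geno) == nrow(panel))
  votes <- diagnostic_votes(tag_geno, panel,
                            which(panel$tagged_structure == "duplication"))
  used <- votes[!is.na(votes)]
  n_h2 <- switch(inversion_genotype,
                 "H1/H1" = 0L, "H1/H2" = 1L, "H2/H2" = 2L, NA_integer_)
  if (length(used) < max(1L, min_informative)) {
    return(structure(list(dosage = NA_integer_, conflict = FALSE,
                          h1_background = FALSE, tally = table(used)),
                     class = "duplication_call"))
  }
  dosage <- if (length(unique(used)) == 1L) used[1] else NA_integer_
  conflict <- !is.na(dosage) && !is.na(n_h2) && dosage > n_h2
  h1_background <- !is.na(dosage) && identical(inversion_genotype, "H1/H1") &&
    dosage > 0L
  structure(list(dosage = dosage, conflict = conflict,
                 h1_background = h1_background, tally = table(used)),
            class = "duplication_call")
}

#' Type inversion genotype and duplication dosage for a cohort
#'
#' Applies [call_inversion_genotype()] and [call_duplication_dosage()] to
#' every row of a genotype matrix. Samples whose inversion tags are all
#' missing are reported as `"no_call"` rather than erroring the run.
#'
#' @param G genotype matrix, individuals x sites, ALT dosages 0/1/2/`NA`;
#'   colnames `"<chrom>:<pos>"` with 1-based positions (as produced by
#'   [cohort_genotypes()] or [read_cohort_vcf()]).
#' @param panel a [tag_snp_panel()].
#' @param min_informative passed through to the per-sample callers.
#' @return a `data.frame` of class `structural_genotype` with columns
#'   `sample`, `inv_genotype`, `dup_dosage` (`NA` = ambiguous),
#'   `tag_concordant`, `conflict`, `h1_background`, `depth_confirmed`
#'   (`NA` until reconciled against read depth).
#' @export
type_structures <- function(G, panel, min_informative = 1L) {
  stopifnot(is.matrix(G), inherits(panel, "tag_snp_panel"))
  key <- paste0(panel$chrom, ":", panel$pos)
  idx <- match(key, colnames(G))
  if (anyNA(idx))
    stop("genotype matrix lacks tag sites: ",
         paste(key[is.na(idx)], collapse = ", "))
  samples <- rownames(G)
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(G)))
  res <- lapply(seq_len(nrow(G)), function(i) {
    tg <- G[i, idx]
    inv <- tryCatch(call_inversion_genotype(tg, panel, min_informative),
                    invtools_no_tags = function(e) NULL)
    if (is.null(inv)) {
      return(data.frame(sample = samples[i], inv_genotype = "no_call",
                        dup_dosage = NA_integer_, tag_concordant = FALSE,
                        conflict = FALSE, h1_background = FALSE,
                        depth_confirmed = NA, stringsAsFactors = FALSE))
    }
    dup <- call_duplication_dosage(tg, inv$genotype, panel, min_informative)
    data.frame(sample = samples[i], inv_genotype = inv$genotype,
               dup_dosage = dup$dosage,
               tag_concordant = inv$genotype != "ambiguous" &&
                 !is.na(dup$dosage),
               conflict = dup$conflict, h1_background = dup$h1_background,
               depth_confirmed = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("structural_genotype", "data.frame")
  out
}

#' Reconcile a tag-based structural call with read-depth segmentation
#'
#' Confirms the tag-based duplication dosage against copy-number segments:
#' a dosage of `d > 0` is depth-confirmed when a gain segment overlaps the
#' duplication interval with mean depth ratio within `ratio_tol` of
#' `1 + d/2`; a dosage of 0 is confirmed when no gain segment overlaps the
#' interval. Disagreement sets the `conflict` flag and keeps the tag-based
#' call (conflicts are data, not failures).
#'
#' @param typed one row of a [type_structures()] result (or any list with
#'   `inv_genotype` and `dup_dosage`).
#' @param segments a [segment_read_depth()] result.
#' @param region a [region_annotation()].
#' @param ratio_tol tolerance on the gain-segment depth ratio.
#' @return `typed` with `depth_confirmed` and `conflict` updated, plus a
#'   `depth_note` attribute describing any disagreement.
#' @export
reconcile_structural <- function(typed, segments, region, ratio_tol = 0.25) {
  stopifnot(inherits(segments, "cn_segments"),
            inherits(region, "region_annotation"))
  d <- typed$dup_dosage
  seg <- segments$segments
  gains <- seg[seg$state == "gain" &
                 seg$end > region$dup[1] & seg$start < region$dup[2], ,
               drop = FALSE]
  note <- NULL
  if (is.na(d)) {
    confirmed <- NA
  } else if (d == 0L) {
    confirmed <- nrow(gains) == 0L
    if (!confirmed) note <- "gain segment over dup interval but tag dosage 0"
  } else {
    expected <- 1 + d / 2
    confirmed <- nrow(gains) > 0L &&
      any(abs(gains$mean_ratio - expected) <= ratio_tol)
    if (!confirmed)
      note <- sprintf("no gain segment with ratio ~%.2f over dup interval",
                      expected)
  }
  typed$depth_confirmed <- confirmed
  if (isFALSE(confirmed)) typed$conflict <- TRUE
  attr(typed, "depth_note") <- note
  typed
}

#' Deterministically phase a heterokaryotype individual
#'
#' For an H1/H2 individual, homozygous sites are copied to both
#' haplotypes; heterozygous sites where one allele is a known H2-family
#' diagnostic allele assign that allele to the H2 haplotype and the other
#' to the H1 haplotype; heterozygous sites with no diagnostic information
#' are set to missing on both haplotypes — never guessed.
#'
#' @param geno ALT-dosage vector (0/1/2/`NA`) over sites.
#' @param positions 1-based positions parallel to `geno`.
#' @param inversion_genotype must be `"H1/H2"`.
#' @param panel a [tag_snp_panel()]; every panel site (inversion and
#'   duplication tags) provides diagnostic information.
#' @param h2_alleles optional extra diagnostic sites: data.frame with
#'   columns `pos` (1-based) and `allele` (0 = ref, 1 = alt), the allele
#'   carried by the H2 family.
#' @return a list with integer vectors `h1` and `h2` (0/1/`NA`).
#' @export
phase_heterokaryotype <- function(geno, positions, inversion_genotype,
                                  panel, h2_alleles = NULL) {
  if (!identical(inversion_genotype, "H1/H2"))
    stop("phase_heterokaryotype applies only to H1/H2 heterokaryotypes")
  stopifnot(length(geno) == length(positions))
  diag <- data.frame(pos = panel$pos,
                     allele = ifelse(panel$diagnostic == "alt", 1L, 0L))
  if (!is.null(h2_alleles)) diag <- rbind(diag, h2_alleles[c("pos", "allele")])
  h2_allele <- diag$allele[match(positions, diag$pos)]
  h1 <- h2 <- rep(NA_integer_, length(geno))
  hom0 <- !is.na(geno) & geno == 0L
  hom1 <- !is.na(geno) & geno == 2L
  h1[hom0] <- h2[hom0] <- 0L
  h1[hom1] <- h2[hom1] <- 1L
  het <- !is.na(geno) & geno == 1L
  inf <- het & !is.na(h2_allele)
  h2[inf] <- h2_allele[inf]
  h1[inf] <- 1L - h2_allele[inf]
  list(h1 = h1, h2 = h2)
}
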