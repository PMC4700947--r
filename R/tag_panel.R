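#' Tag-SNP panel for structural genotyping
#'
#' A tag SNP is a variant whose allele deterministically marks a structural
#' class because recombination between arrangements is suppressed:
#' inversion tags separate H1 from H2 chromosomes, duplication tags mark
#' H2D (duplication-carrying) chromosomes within the H2 family.
#'
#' @param pos 1-based positions (unique).
#' @param ref,alt reference / alternate alleles (single bases).
#' @param tagged_structure `"inversion"` or `"duplication"` per tag.
#' @param diagnostic which allele is carried by the tagged class
#'   (H2 for inversion tags, H2D for duplication tags); `"ref"` or `"alt"`.
#' @param chrom chromosome label.
#' @return a `data.frame` of class `tag_snp_panel` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `tagged_structure`, `diagnostic`.
#' @export
tag_snp_panel <- function(pos, ref, alt, tagged_structure,
                          diagnostic = "alt", chrom = "17") {
  n <- length(pos)
  tagged_structure <- match.arg(tagged_structure,
                                c("inversion", "duplication"),
                                several.ok = TRUE)
  tagged_structure <- rep_len(tagged_structure, n)
  diagnostic <- rep_len(diagnostic, n)
  if (!all(diagnostic %in% c("ref", "alt")))
    stop("diagnostic allele must be 'ref' or 'alt'")
  if (anyDuplicated(pos))
    stop("tag positions must be unique")
  if (!any(tagged_structure == "inversion") ||
      !any(tagged_structure == "duplication"))
    stop("panel needs at least one inversion tag and one duplication tag")
  out <- data.frame(chrom = rep_len(as.character(chrom), n),
                    pos = as.integer(pos),
                    ref = rep_len(as.character(ref), n),
                    alt = rep_len(as.character(alt), n),
                    tagged_structure = tagged_structure,
                    diagnostic = diagnostic,
                    stringsAsFactors = FALSE)
  class(out) <- c("tag_snp_panel", "data.frame")
  out
}

#' Default tag panel for a region
#'
#' Builds a panel of 15 inversion tags evenly spread across the inversion
#' interval and 2 duplication tags inside the duplication interval (17 tags
#' in total, the size of the published tagging assay). Diagnostic alleles
#' are the alternate allele throughout.
#'
#' @param region a [region_annotation()].
#' @param n_inversion_tags,n_duplication_tags panel composition.
#' @return a [tag_snp_panel()].
#' @export
default_tag_panel <- function(region = region_annotation(),
                              n_inversion_tags = 15L,
                              n_duplication_tags = 2L) {
  stopifnot(inherits(region, "region_annotation"),
            n_inversion_tags >= 1, n_duplication_tags >= 1)
  inv_pos <- round(seq(region$inversion[1] + 1000,
                       region$inversion[2] - 1000,
                       length.out = n_inversion_tags))
  dup_pos <- round(seq(region$dup[1] + 1000,
                       region$dup[2] - 1000,
                       length.out = n_duplication_tags))
  tag_snp_panel(pos = c(inv_pos, dup_pos) + 1L,  # to 1-based
                ref = "A", alt = "G",
                tagged_structure = rep(c("inversion", "duplication"),
                                       c(n_inversion_tags,
                                         n_duplication_tags)),
                chrom = region$chrom)
}

#' Read / write a tag panel as TSV
#'
#' The TSV has columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `tagged_structure`, `diagnostic`.
#'
#' @param path file path.
#' @param panel a [tag_snp_panel()].
#' @return `read_tag_panel()` returns a [tag_snp_panel()];
#'   `write_tag_panel()` returns `path` invisibly.
#' @export
read_tag_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  tag_snp_panel(pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
                tagged_structure = df$tagged_structure,
                diagnostic = df$diagnostic, chrom = df$chrom)
}

#' @rdname read_tag_panel
#' @export
write_tag_panel <- function(panel, path) {
  stopifnot(inherits(panel, "tag_snp_panel"))
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
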