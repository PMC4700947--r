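#' Prune variants inside segmental duplications
#'
#' Removes every variant whose (single-base) position lies strictly inside
#' any segmental-duplication interval; all other variants are retained in
#' their original order. Intervals follow the BED convention: 0-based
#' half-open.
#'
#' @param variants data.frame with columns `chrom` and `pos` (1-based).
#' @param segdups data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_segdup_bed()].
#' @return the retained rows of `variants`, with the removed rows in the
#'   `"removed"` attribute.
#' @export
prune_segdup <- function(variants, segdups) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("chrom", "start", "end") %in% names(segdups)))
  if (any(segdups$end < segdups$start))
    stop("malformed segdup interval: end < start")
  if (nrow(segdups) == 0L) {
    attr(variants, "removed") <- variants[0, , drop = FALSE]
    return(variants)
  }
  v <- GenomicRanges::GRanges(as.character(variants$chrom),
                              IRanges::IRanges(variants$pos, variants$pos))
  s <- GenomicRanges::GRanges(as.character(segdups$chrom),
                              IRanges::IRanges(segdups$start + 1,
                                               segdups$end))
  hit <- GenomicRanges::countOverlaps(v, s) > 0
  out <- variants[!hit, , drop = FALSE]
  attr(out, "removed") <- variants[hit, , drop = FALSE]
  out
}

#' Drop monomorphic sites and build the panel QC report
#'
#' A site is monomorphic iff all its non-missing genotype alleles are
#' identical: every non-missing call is homozygous for the same allele
#' (any heterozygote makes a site polymorphic). Sites with all calls
#' missing are counted monomorphic and flagged. The genotyping rate is the
#' fraction of non-missing calls over the final (retained) site list.
#'
#' @param G genotype matrix, sites x samples, ALT dosages 0/1/2/`NA`.
#' @return a list: `final_sites` (retained rownames), `G` (retained
#'   matrix), `monomorphic_sites`, `all_missing_sites`, `genotyping_rate`.
#' @export
drop_monomorphic <- function(G) {
  stopifnot(is.matrix(G))
  mono <- apply(G, 1, function(g) {
    obs <- g[!is.na(g)]
    length(obs) == 0L || (!any(obs == 1L) && length(unique(obs)) == 1L)
  })
  all_missing <- rowSums(!is.na(G)) == 0L
  keep <- !mono
  Gf <- G[keep, , drop = FALSE]
  rate <- if (nrow(Gf) == 0) NA_real_ else mean(!is.na(Gf))
  list(final_sites = rownames(G)[keep],
       G = Gf,
       monomorphic_sites = rownames(G)[mono],
       all_missing_sites = rownames(G)[all_missing],
       genotyping_rate = rate)
}

#' Run the full SNP-panel construction filter chain
#'
#' Reproduces the published panel QC chain: candidate SNPs are pruned
#' against segmental duplications, tagging SNPs are merged in, and
#' monomorphic sites are dropped; the genotyping rate is computed over the
#' final panel. Report identities
#' (`n_after_pruning = n_candidates_in - n_removed_segdup`,
#' `n_final = n_after_pruning + n_tags_added - n_removed_monomorphic`)
#' are asserted on every run.
#'
#' @param candidates data.frame with `chrom`, `pos` (1-based).
#' @param segdups data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genotypes sites x samples genotype matrix over the pruned
#'   candidates plus tags, rownames `"<chrom>:<pos>"`.
#' @param tags data.frame with `chrom`, `pos` (1-based) of tagging SNPs
#'   merged in after pruning.
#' @param verbose log a line per filter stage.
#' @return a list of class `panel_qc_report` with fields
#'   `n_candidates_in`, `n_removed_segdup`, `n_after_pruning`,
#'   `n_tags_added`, `n_removed_monomorphic`, `n_final`,
#'   `genotyping_rate`, `final_sites`.
#' @export
panel_qc <- function(candidates, segdups, genotypes, tags,
                     verbose = FALSE) {
  n_in <- nrow(candidates)
  kept <- prune_segdup(candidates, segdups)
  n_removed <- nrow(attr(kept, "removed"))
  if (verbose)
    message("segdup pruning: ", n_in, " -> ", nrow(kept),
            " (removed ", n_removed, ")")
  panel_sites <- c(paste0(kept$chrom, ":", kept$pos),
                   paste0(tags$chrom, ":", tags$pos))
  missing_sites <- setdiff(panel_sites, rownames(genotypes))
  if (length(missing_sites) > 0)
    stop("genotype matrix lacks panel sites: ",
         paste(utils::head(missing_sites, 5), collapse = ", "))
  G <- genotypes[panel_sites, , drop = FALSE]
  dm <- drop_monomorphic(G)
  if (verbose)
    message("monomorphism filter: ", nrow(G), " -> ",
            length(dm$final_sites), " (removed ",
            length(dm$monomorphic_sites), "); genotyping rate ",
            signif(dm$genotyping_rate, 4))
  rep <- structure(list(
    n_candidates_in = n_in,
    n_removed_segdup = n_removed,
    n_after_pruning = nrow(kept),
    n_tags_added = nrow(tags),
    n_removed_monomorphic = length(dm$monomorphic_sites),
    n_final = length(dm$final_sites),
    genotyping_rate = dm$genotyping_rate,
    final_sites = dm$final_sites
  ), class = "panel_qc_report")
  stopifnot(rep$n_after_pruning == rep$n_candidates_in - rep$n_removed_segdup,
            rep$n_final == rep$n_after_pruning + rep$n_tags_added -
              rep$n_removed_monomorphic)
  rep
}

#' @export
print.panel_qc_report <- function(x, ...) {
  cat("SNP-panel QC report\n")
  cat("  candidates in:        ", x$n_candidates_in, "\n")
  cat("  removed (segdup):     ", x$n_removed_segdup, "\n")
  cat("  after pruning:        ", x$n_after_pruning, "\n")
  cat("  tags added:           ", x$n_tags_added, "\n")
  cat("  removed (monomorphic):", x$n_removed_monomorphic, "\n")
  cat("  final panel:          ", x$n_final, "\n")
  cat("  genotyping rate:      ", signif(x$genotyping_rate, 4), "\n")
  invisible(x)
}

#' Write a panel QC report as TSV
#'
#' @param report a [panel_qc()] result.
#' @param path file path.
#' @export
write_panel_qc <- function(report, path) {
  stopifnot(inherits(report, "panel_qc_report"))
  df <- data.frame(
    metric = c("n_candidates_in", "n_removed_segdup", "n_after_pruning",
               "n_tags_added", "n_removed_monomorphic", "n_final",
               "genotyping_rate"),
    value = c(report$n_candidates_in, report$n_removed_segdup,
              report$n_after_pruning, report$n_tags_added,
              report$n_removed_monomorphic, report$n_final,
              report$genotyping_rate)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
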