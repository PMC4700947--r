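#' Panel composition counts
#'
#' Bookkeeping for the SNP-panel filter-chain fixture. Defaults reproduce
#' the published panel construction: 203 novel candidate SNPs, 67 of them
#' inside segmental duplications, 17 tagging SNPs merged in after pruning,
#' and 79 sites monomorphic after genotyping (leaving 74).
#'
#' @param n_novel_candidates,n_in_segdup,n_tag_added,n_monomorphic counts.
#' @return an object of class `panel_counts`.
#' @export
panel_counts <- function(n_novel_candidates = 203L, n_in_segdup = 67L,
                         n_tag_added = 17L, n_monomorphic = 79L) {
  x <- list(n_novel_candidates = as.integer(n_novel_candidates),
            n_in_segdup = as.integer(n_in_segdup),
            n_tag_added = as.integer(n_tag_added),
            n_monomorphic = as.integer(n_monomorphic))
  if (any(vapply(x, function(v) v < 0, logical(1))))
    stop("counts must be non-negative")
  if (x$n_in_segdup > x$n_novel_candidates)
    stop("n_in_segdup cannot exceed n_novel_candidates")
  if (x$n_monomorphic > x$n_novel_candidates - x$n_in_segdup + x$n_tag_added)
    stop("n_monomorphic exceeds the post-pruning + tag site count")
  structure(x, class = "panel_counts")
}

#' Generate a SNP-panel QC fixture with planted filter counts
#'
#' Emits a candidate variant list, segmental-duplication intervals and a
#' diploid genotype matrix constructed so that re-running the panel filter
#' chain reproduces every configured count exactly: exactly
#' `n_in_segdup` candidates fall inside the emitted intervals, and exactly
#' `n_monomorphic` of the post-pruning + tag sites are monomorphic across
#' all genotyped samples.
#'
#' @param counts a [panel_counts()].
#' @param seed integer seed.
#' @param n_samples number of genotyped individuals.
#' @param missing_rate per-call missingness probability (drives the
#'   genotyping rate of the QC report).
#' @param region a [region_annotation()].
#' @param tags_can_be_monomorphic if `TRUE`, planted monomorphic sites may
#'   include tag SNPs; by default only candidate sites are planted
#'   monomorphic.
#' @return a list with `candidates` (data.frame `chrom`, `pos` 1-based,
#'   `in_segdup` truth flag), `segdups` (data.frame `chrom`, `start`, `end`,
#'   0-based half-open), `tags` (data.frame `chrom`, `pos`), `genotypes`
#'   (sites x samples matrix of 0/1/2/NA over pruned candidates + tags,
#'   rownames `"<chrom>:<pos>"`), `monomorphic_sites` (planted truth), and
#'   `counts`.
#' @export
generate_panel_fixture <- function(counts = panel_counts(), seed = 1L,
                                   n_samples = 100L, missing_rate = 0.002,
                                   region = region_annotation(),
                                   tags_can_be_monomorphic = FALSE) {
  stopifnot(inherits(counts, "panel_counts"))
  n_keep <- counts$n_novel_candidates - counts$n_in_segdup
  if (!tags_can_be_monomorphic && counts$n_monomorphic > n_keep)
    stop("n_monomorphic exceeds the candidate sites available ",
         "(tags_can_be_monomorphic = FALSE)")
  withr::with_seed(seed, {
    span <- region_span(region)
    # three segdup blocks inside the region
    blk_w <- floor((span[2] - span[1]) / 12)
    seg_starts <- span[1] + c(1L, 4L, 8L) * blk_w
    segdups <- data.frame(chrom = region$chrom, start = seg_starts,
                          end = seg_starts + blk_w, stringsAsFactors = FALSE)
    inside_grid <- unlist(lapply(seq_len(3), function(i)
      seq(segdups$start[i], segdups$end[i] - 1L)))
    outside_grid <- setdiff(seq(span[1], span[2] - 1L), inside_grid)
    pos_in <- sort(sample(inside_grid, counts$n_in_segdup))
    n_out <- counts$n_novel_candidates - counts$n_in_segdup
    pos_out_all <- sort(sample(outside_grid, n_out + counts$n_tag_added))
    keep_as_tag <- sample(length(pos_out_all), counts$n_tag_added)
    pos_tag <- sort(pos_out_all[keep_as_tag])
    pos_out <- sort(pos_out_all[-keep_as_tag])
    cand_pos <- sort(c(pos_in, pos_out))
    candidates <- data.frame(chrom = region$chrom, pos = cand_pos + 1L,
                             in_segdup = cand_pos %in% pos_in,
                             stringsAsFactors = FALSE)
    tags <- data.frame(chrom = region$chrom, pos = pos_tag + 1L,
                       stringsAsFactors = FALSE)

    geno_pos <- sort(c(pos_out, pos_tag)) + 1L
    n_sites <- length(geno_pos)
    stopifnot(n_sites == n_keep + counts$n_tag_added)
    mono_pool <- if (tags_can_be_monomorphic) seq_len(n_sites) else
      which(geno_pos %in% (pos_out + 1L))
    mono_idx <- sort(sample(mono_pool, counts$n_monomorphic))
    G <- matrix(0L, nrow = n_sites, ncol = n_samples,
                dimnames = list(paste0(region$chrom, ":", geno_pos),
                                sprintf("S%04d", seq_len(n_samples))))
    poly_idx <- setdiff(seq_len(n_sites), mono_idx)
    for (i in poly_idx) {
      p <- runif(1, 0.1, 0.5)
      G[i, ] <- rbinom(n_samples, 2L, p)
    }
    if (missing_rate > 0) {
      miss <- matrix(runif(n_sites * n_samples) < missing_rate,
                     nrow = n_sites)
      G[miss] <- NA_integer_
    }
    # missingness or a bad draw must never flip a site's planted status
    for (i in poly_idx) {
      obs <- G[i, !is.na(G[i, ])]
      if (length(obs) == 0 || length(unique(obs)) < 2) {
        G[i, 1L] <- 1L
        G[i, 2L] <- 0L
      }
    }
    list(candidates = candidates, segdups = segdups, tags = tags,
         genotypes = G,
         monomorphic_sites = rownames(G)[mono_idx],
         counts = counts)
  })
}
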