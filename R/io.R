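#' Write a synthetic cohort as a phased VCF
#'
#' Emits VCF 4.2 with phased GT fields (`0|1` style), one record per site,
#' 1-based positions. Tag sites carry the panel's ref/alt alleles; other
#' sites get generic `A`/`T` alleles. The file is gzip-compressed (the
#' `.vcf.gz` convention of [vcfR::write.vcf()]).
#'
#' @param fixture a [generate_cohort()] result.
#' @param path output path (should end in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(fixture, path) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  H <- fixture$haplotypes
  n_ind <- nrow(H) / 2L
  pos1 <- fixture$positions + 1L
  n_sites <- length(pos1)
  ref <- rep("A", n_sites)
  alt <- rep("T", n_sites)
  tag_row <- match(fixture$panel$pos, pos1)
  ref[tag_row] <- fixture$panel$ref
  alt[tag_row] <- fixture$panel$alt
  fix <- cbind(CHROM = rep(fixture$region$chrom, n_sites),
               POS = as.character(pos1),
               ID = paste0("site", seq_len(n_sites)),
               REF = ref, ALT = alt,
               QUAL = rep(".", n_sites), FILTER = rep("PASS", n_sites),
               INFO = rep(".", n_sites))
  a1 <- t(H[seq(1, 2 * n_ind, by = 2), , drop = FALSE])
  a2 <- t(H[seq(2, 2 * n_ind, by = 2), , drop = FALSE])
  gt_body <- matrix(paste0(a1, "|", a2), nrow = n_sites,
                    dimnames = list(NULL, fixture$truth$sample))
  gt <- cbind(FORMAT = rep("GT", n_sites), gt_body)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", fixture$region$chrom, ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read genotypes (and phased haplotypes) from a VCF
#'
#' @param path a VCF (optionally gzipped).
#' @return a list: `G` (ALT-dosage matrix, samples x sites, colnames
#'   `"<chrom>:<pos>"`), `haplotypes` (0/1 matrix with 2 rows per sample,
#'   `NULL` if the file is not fully phased), `positions` (0-based),
#'   `chrom`, `samples`.
#' @export
read_cohort_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  chrom <- vcfR::getCHROM(vcf)
  pos1 <- vcfR::getPOS(vcf)
  samples <- colnames(gt)
  sep <- gsub("[0-9.]", "", gt[1, 1])
  phased <- all(grepl("|", gt, fixed = TRUE), na.rm = TRUE)
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  n_sites <- nrow(gt); n_ind <- ncol(gt)
  G <- matrix(a1 + a2, nrow = n_sites)
  G <- t(G)
  rownames(G) <- samples
  colnames(G) <- paste0(chrom, ":", pos1)
  haps <- NULL
  if (phased) {
    haps <- matrix(0L, nrow = 2L * n_ind, ncol = n_sites)
    haps[seq(1, 2 * n_ind, by = 2), ] <- t(matrix(a1, nrow = n_sites))
    haps[seq(2, 2 * n_ind, by = 2), ] <- t(matrix(a2, nrow = n_sites))
    rownames(haps) <- paste0(rep(samples, each = 2), c("_1", "_2"))
  }
  list(G = G, haplotypes = haps, positions = pos1 - 1L,
       chrom = chrom[1], samples = samples)
}

#' Read / write per-individual truth tables
#'
#' TSV with columns `sample`, `group`, `subtype1`, `subtype2`.
#'
#' @param fixture a [generate_cohort()] result.
#' @param path file path.
#' @export
write_truth_table <- function(fixture, path) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  write.table(fixture$truth[c("sample", "group", "subtype1", "subtype2")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read / write segmental-duplication intervals as BED
#'
#' BED is 0-based half-open; the data.frame representation used across the
#' package keeps that convention.
#'
#' @param segdups data.frame with `chrom`, `start`, `end`.
#' @param path file path.
#' @export
write_segdup_bed <- function(segdups, path) {
  gr <- GenomicRanges::GRanges(as.character(segdups$chrom),
                               IRanges::IRanges(segdups$start + 1,
                                                segdups$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_segdup_bed
#' @export
read_segdup_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read / write read-depth tracks as bedGraph
#'
#' Four-column bedGraph (`chrom`, `start`, `end`, `depth`), 0-based
#' half-open.
#'
#' @param track a `read_depth_track` data.frame.
#' @param path file path.
#' @export
write_depth_track <- function(track, path) {
  gr <- GenomicRanges::GRanges(as.character(track$chrom),
                               IRanges::IRanges(track$start + 1, track$end),
                               score = track$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_depth_track
#' @export
read_depth_track_file <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    depth = as.numeric(gr$score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  class(out) <- c("read_depth_track", "data.frame")
  out
}

#' Read / write sample-to-group mappings
#'
#' TSV with columns `sample` and `group`.
#'
#' @param groups named character vector (names are samples) or data.frame
#'   with `sample` and `group`.
#' @param path file path.
#' @export
write_group_table <- function(groups, path) {
  if (!is.data.frame(groups))
    groups <- data.frame(sample = names(groups), group = unname(groups),
                         stringsAsFactors = FALSE)
  write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_table
#' @export
read_group_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(df$group, df$sample)
}
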