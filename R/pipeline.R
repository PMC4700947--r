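#' Assign structural subtypes to phased haplotypes
#'
#' Given typed individuals and their phased haplotypes, labels each
#' haplotype H1, H2prime or H2D using the tag alleles it carries:
#' a haplotype is H2 when it carries the diagnostic allele at the majority
#' of its non-missing inversion tags, and an H2 haplotype is H2D when it
#' carries the diagnostic allele at the majority of its duplication tags.
#' Haplotypes of samples without a clean structural call get `NA`.
#'
#' @param haps 0/1 haplotype matrix, 2 rows per sample (sample order must
#'   match `typed`).
#' @param positions 1-based site positions parallel to columns.
#' @param typed a [type_structures()] result.
#' @param panel a [tag_snp_panel()].
#' @return character vector of subtypes, one per haplotype row.
#' @export
assign_haplotype_subtypes <- function(haps, positions, typed, panel) {
  stopifnot(nrow(haps) == 2L * nrow(typed))
  inv_idx <- match(panel$pos[panel$tagged_structure == "inversion"],
                   positions)
  dup_idx <- match(panel$pos[panel$tagged_structure == "duplication"],
                   positions)
  diag_inv <- ifelse(panel$diagnostic[panel$tagged_structure ==
                                        "inversion"] == "alt", 1L, 0L)
  diag_dup <- ifelse(panel$diagnostic[panel$tagged_structure ==
                                        "duplication"] == "alt", 1L, 0L)
  out <- rep(NA_character_, nrow(haps))
  for (i in seq_len(nrow(typed))) {
    if (!typed$inv_genotype[i] %in% c("H1/H1", "H1/H2", "H2/H2")) next
    for (k in 1:2) {
      h <- haps[2L * (i - 1L) + k, ]
      vi <- h[inv_idx] == diag_inv
      if (all(is.na(vi))) next
      is_h2 <- mean(vi, na.rm = TRUE) > 0.5
      if (!is_h2) {
        out[2L * (i - 1L) + k] <- "H1"
      } else {
        vd <- h[dup_idx] == diag_dup
        out[2L * (i - 1L) + k] <-
          if (!all(is.na(vd)) && mean(vd, na.rm = TRUE) > 0.5)
            "H2D" else "H2prime"
      }
    }
  }
  out
}

#' Pipeline configuration
#'
#' Bundles the file inputs and stage parameters of the end-to-end run.
#' All referenced paths are checked at validation time, before any stage
#' runs. The configuration round-trips losslessly through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param vcf path to the (phased) cohort VCF.
#' @param tag_panel path to the tag-panel TSV.
#' @param groups path to the sample-to-group TSV.
#' @param region a [region_annotation()].
#' @param segdups optional path to a segmental-duplication BED (enables
#'   the panel-QC stage together with `candidates`).
#' @param candidates optional path to a candidate-variant TSV
#'   (`chrom`, `pos`).
#' @param window_width window width for the windowed statistics.
#' @param sim a [sim_config()] for the neutrality null.
#' @param n_null_replicates replicates in the null.
#' @param seed master seed.
#' @param outdir output directory (created if needed).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, tag_panel, groups,
                            region = region_annotation(),
                            segdups = NULL, candidates = NULL,
                            window_width = 25000L,
                            sim = sim_config(),
                            n_null_replicates = 100L,
                            seed = 1L, outdir = "invtools-out") {
  for (p in c(vcf = vcf, tag_panel = tag_panel, groups = groups,
              segdups = segdups, candidates = candidates)) {
    if (!file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  }
  stopifnot(inherits(region, "region_annotation"),
            inherits(sim, "sim_config"), window_width > 0,
            n_null_replicates >= 1)
  structure(list(vcf = vcf, tag_panel = tag_panel, groups = groups,
                 region = region, segdups = segdups,
                 candidates = candidates,
                 window_width = as.integer(window_width), sim = sim,
                 n_null_replicates = as.integer(n_null_replicates),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path for the serialized configuration (plain text,
#'   R expression syntax).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  dput(unclass_recursive(config), file = path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- dget(path)
  cfg <- pipeline_config(
    vcf = x$vcf, tag_panel = x$tag_panel, groups = x$groups,
    region = do.call(region_annotation, list(
      chrom = x$region$chrom,
      inversion_interval = c(x$region$inversion[1] + 1, x$region$inversion[2]),
      dup_interval = c(x$region$dup[1] + 1, x$region$dup[2]),
      assembly = x$region$assembly)),
    segdups = x$segdups, candidates = x$candidates,
    window_width = x$window_width,
    sim = structure(x$sim, class = "sim_config"),
    n_null_replicates = x$n_null_replicates,
    seed = x$seed, outdir = x$outdir)
  cfg
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_recursive)
  x
}

#' Run the full analysis pipeline
#'
#' Stages, in order: structural typing from tag SNPs, optional SNP-panel
#' QC, per-arrangement population-genetic statistics (frequency table,
#' windowed pi / Tajima's D over the inversion interval, pairwise Fst per
#' H2 subtype, neighbor-joining tree), the simulated neutrality null, and
#' the neutrality test. Every stage writes its artifact into `outdir`; a
#' manifest records the package version, the seed and an MD5 of the
#' serialized configuration. A rerun with the same configuration and seed
#' is byte-identical for the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress.
#' @return the output directory path, invisibly; stage results are also
#'   returned in the `"results"` attribute.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[invtools] ", ...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  say("reading inputs")
  vcf <- read_cohort_vcf(config$vcf)
  panel <- read_tag_panel(config$tag_panel)
  groups <- read_group_table(config$groups)

  say("stage 1/5: structural typing")
  typed <- type_structures(vcf$G, panel)
  write.table(typed, out("structural_genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  qc <- NULL
  if (!is.null(config$segdups) && !is.null(config$candidates)) {
    say("stage 2/5: SNP-panel QC")
    cand <- read.table(config$candidates, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    segd <- read_segdup_bed(config$segdups)
    tags <- data.frame(chrom = panel$chrom, pos = panel$pos,
                       stringsAsFactors = FALSE)
    qc <- panel_qc(cand, segd, t(vcf$G), tags, verbose = verbose)
    write_panel_qc(qc, out("panel_qc.tsv"))
  } else say("stage 2/5: SNP-panel QC skipped (no candidates/segdups)")

  say("stage 3/5: population-genetic statistics")
  freq <- haplotype_frequency_table(typed, groups)
  write.table(freq, out("frequency_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (is.null(vcf$haplotypes))
    stop("popgen stage needs a fully phased VCF")
  subtype <- assign_haplotype_subtypes(vcf$haplotypes, vcf$positions + 1L,
                                       typed, panel)
  fam <- ifelse(subtype == "H1", "H1", "H2")
  inv <- config$region$inversion
  win <- list()
  for (f in c("H1", "H2")) {
    sel <- !is.na(fam) & fam == f
    if (sum(sel) >= 2) {
      w <- sliding_window_stats(vcf$haplotypes[sel, , drop = FALSE],
                                vcf$positions, inv[1], inv[2],
                                width = config$window_width)
      w$family <- f
      win[[f]] <- w
    }
  }
  win_df <- do.call(rbind, win)
  write.table(win_df, out("window_stats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hap_group <- rep(groups[vcf$samples], each = 2)
  fst <- list()
  for (st in c("H2prime", "H2D")) {
    sel <- !is.na(subtype) & subtype == st
    tb <- table(hap_group[sel])
    if (sum(tb >= 2) >= 2) {
      fr <- pairwise_fst(vcf$haplotypes[sel, , drop = FALSE],
                         hap_group[sel])
      fst[[st]] <- fr
      write.table(data.frame(group = rownames(fr$fst), fr$fst,
                             check.names = FALSE),
                  out(paste0("fst_", st, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  tree <- NULL
  usable <- !is.na(subtype)
  if (sum(usable) >= 3) {
    tree <- build_distance_tree(
      vcf$haplotypes[usable, , drop = FALSE],
      labels = paste0(rep(vcf$samples, each = 2)[usable], "_",
                      subtype[usable]))
    ape::write.tree(tree, out("haplotype_tree.nwk"))
  }

  say("stage 4/5: neutrality null (", config$n_null_replicates,
      " replicates)")
  null <- build_null(config$sim, config$n_null_replicates,
                     seed = config$seed)
  write_null_distribution(null, out("null_replicates.tsv"),
                          out("null_quantiles.tsv"))

  say("stage 5/5: neutrality test")
  observed <- list()
  if ("H1" %in% names(win)) observed$standard <- win$H1$tajimas_d
  if ("H2" %in% names(win)) observed$inverted <- win$H2$tajimas_d
  report <- NULL
  if (length(observed) > 0) {
    report <- test_neutrality(observed, null)
    write.table(report, out("neutrality_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  write_pipeline_config(config, out("config.dput"))
  manifest <- data.frame(
    key = c("package", "version", "seed", "config_md5"),
    value = c("invtools", as.character(packageVersion("invtools")),
              as.character(config$seed),
              unname(tools::md5sum(out("config.dput")))))
  write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("done: ", config$outdir)
  res <- config$outdir
  attr(res, "results") <- list(typed = typed, qc = qc, freq = freq,
                               windows = win_df, fst = fst, tree = tree,
                               null = null, report = report)
  invisible(res)
}
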