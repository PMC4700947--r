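#' Generate a read-depth track with a planted duplication signal
#'
#' Emulates the per-window depth profile of a short-read sample over the
#' locus. Windows tile the region span; the expected depth of windows
#' inside the duplication interval scales with total copy number,
#' `(2 + dup_dosage) / 2` times the baseline, where `dup_dosage` is the
#' number of duplication-carrying (H2D) haplotypes the individual carries.
#' Per-window noise is overdispersed: negative binomial with mean equal to
#' the expected depth and `size = dispersion` (variance
#' `mu + mu^2/dispersion`).
#'
#' @param dup_dosage number of duplicated haplotypes (0, 1 or 2).
#' @param region a [region_annotation()]; windows tile
#'   [region_span()] of it.
#' @param baseline mean baseline depth (diploid copy number 2).
#' @param dispersion negative-binomial size parameter.
#' @param window window width in bp.
#' @param seed integer seed.
#' @return a `data.frame` of class `read_depth_track` with columns
#'   `chrom`, `start` (0-based), `end`, `depth`.
#' @export
generate_read_depth <- function(dup_dosage, region = region_annotation(),
                                baseline = 40, dispersion = 100,
                                window = 1000L, seed = 1L) {
  stopifnot(inherits(region, "region_annotation"))
  if (!dup_dosage %in% 0:2) stop("dup_dosage must be 0, 1 or 2")
  if (window <= 0) stop("window size must be positive")
  if (baseline <= 0) stop("baseline depth must be positive")
  span <- region_span(region)
  if (span[2] <= span[1]) stop("empty region")
  starts <- seq(span[1], span[2] - 1L, by = window)
  ends <- pmin(starts + window, span[2])
  mid <- (starts + ends) / 2
  mu <- ifelse(in_interval0(mid, region$dup),
               baseline * (2 + dup_dosage) / 2, baseline)
  depth <- withr::with_seed(seed,
                            rnbinom(length(mu), size = dispersion, mu = mu))
  out <- data.frame(chrom = region$chrom, start = starts, end = ends,
                    depth = as.numeric(depth), stringsAsFactors = FALSE)
  class(out) <- c("read_depth_track", "data.frame")
  out
}
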