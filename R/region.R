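#' Region annotation for an inversion locus
#'
#' Describes the genomic region under analysis: the inversion interval and
#' the interval of the arrangement-associated duplication. Coordinates are
#' supplied 1-based inclusive (the VCF convention) and stored internally as
#' 0-based half-open; accessors below return whichever representation is
#' asked for.
#'
#' Defaults are the 17q21.31 locus on GRCh37: inversion
#' chr17:43,705,166-44,164,259 and the H2-specific duplication (CNP155)
#' chr17:44,210,855-44,294,624.
#'
#' @param chrom chromosome label.
#' @param inversion_interval length-2 integer vector, 1-based inclusive.
#' @param dup_interval length-2 integer vector, 1-based inclusive.
#' @param assembly assembly label.
#' @return an object of class `region_annotation`.
#' @export
#' @examples
#' r <- region_annotation()
#' r$inversion   # 0-based half-open
region_annotation <- function(chrom = "17",
                              inversion_interval = c(43705166L, 44164259L),
                              dup_interval = c(44210855L, 44294624L),
                              assembly = "GRCh37") {
  check_interval_1based(inversion_interval, "inversion_interval")
  check_interval_1based(dup_interval, "dup_interval")
  structure(list(
    chrom = as.character(chrom),
    # 0-based half-open
    inversion = c(inversion_interval[1] - 1, inversion_interval[2]),
    dup = c(dup_interval[1] - 1, dup_interval[2]),
    assembly = as.character(assembly)
  ), class = "region_annotation")
}

check_interval_1based <- function(x, name) {
  if (length(x) != 2 || anyNA(x) || !is.numeric(x))
    stop(name, " must be a length-2 numeric vector", call. = FALSE)
  if (x[1] > x[2])
    stop(name, ": start must be <= end", call. = FALSE)
  if (x[1] < 1)
    stop(name, ": 1-based coordinates must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("Region annotation (", x$assembly, ")\n", sep = "")
  cat("  chrom:     ", x$chrom, "\n", sep = "")
  cat(sprintf("  inversion: %s-%s (1-based)\n",
              format(x$inversion[1] + 1, big.mark = ","),
              format(x$inversion[2], big.mark = ",")))
  cat(sprintf("  duplication: %s-%s (1-based)\n",
              format(x$dup[1] + 1, big.mark = ","),
              format(x$dup[2], big.mark = ",")))
  invisible(x)
}

#' @rdname region_annotation
#' @param region a `region_annotation`.
#' @export
region_span <- function(region) {
  stopifnot(inherits(region, "region_annotation"))
  c(min(region$inversion[1], region$dup[1]),
    max(region$inversion[2], region$dup[2]))
}

# positions: 0-based; interval: 0-based half-open
in_interval0 <- function(pos, interval) {
  pos >= interval[1] & pos < interval[2]
}
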