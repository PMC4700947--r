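#' Test observed Tajima's D against a simulated neutrality null
#'
#' Summarizes the observed per-window D values of each arrangement (mean
#' across defined windows by default, median via `summary_fun`), locates
#' the summary in the arrangement's empirical null, and reports verdicts
#' against the equal-tailed 95% and 99% intervals plus a rank-based
#' empirical two-sided p-value,
#' `p = 2 * min((k_lo + 1)/(n + 1), (k_hi + 1)/(n + 1))` capped at 1,
#' where `k_lo`/`k_hi` count null values at or beyond the observed summary
#' in each tail.
#'
#' @param observed named list with (numeric) observed window D values per
#'   arrangement, e.g. `list(standard = ..., inverted = ...)`; entries may
#'   contain `NA` (undefined windows). A [sliding_window_stats()] result's
#'   `tajimas_d` column is the expected source.
#' @param null a [build_null()] result with matching arrangement names.
#' @param summary_fun summary across windows (default mean of defined
#'   values).
#' @return a `data.frame` of class `neutrality_report`: per arrangement
#'   the observed summary, window counts, null quantiles, inside/outside
#'   verdicts and the empirical p-value. Arrangements with no defined
#'   window get status `"no_verdict"`.
#' @export
test_neutrality <- function(observed, null,
                            summary_fun = function(x) mean(x, na.rm = TRUE)) {
  stopifnot(inherits(null, "null_distribution"), is.list(observed))
  arrs <- names(observed)
  if (!all(arrs %in% names(null$d)))
    stop("observed arrangements absent from the null: ",
         paste(setdiff(arrs, names(null$d)), collapse = ", "))
  rows <- lapply(arrs, function(a) {
    obs <- observed[[a]]
    nd <- null$d[[a]]
    nd <- nd[!is.na(nd)]
    if (length(nd) == 0) stop("empty null for arrangement ", a)
    n_def <- sum(!is.na(obs))
    if (n_def == 0) {
      return(data.frame(arrangement = a, observed = NA_real_,
                        n_windows = length(obs), n_undefined = length(obs),
                        q2.5 = NA_real_, q97.5 = NA_real_,
                        q0.5 = NA_real_, q99.5 = NA_real_,
                        inside_95 = NA, inside_99 = NA, p = NA_real_,
                        status = "no_verdict", stringsAsFactors = FALSE))
    }
    s <- summary_fun(obs)
    q <- quantile(nd, c(0.005, 0.025, 0.975, 0.995), type = 7,
                  names = FALSE)
    n <- length(nd)
    p <- 2 * min((sum(nd <= s) + 1) / (n + 1),
                 (sum(nd >= s) + 1) / (n + 1))
    p <- min(p, 1)
    data.frame(arrangement = a, observed = s,
               n_windows = length(obs), n_undefined = length(obs) - n_def,
               q2.5 = q[2], q97.5 = q[3], q0.5 = q[1], q99.5 = q[4],
               inside_95 = s >= q[2] & s <= q[3],
               inside_99 = s >= q[1] & s <= q[4],
               p = p, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # the 95% interval is nested in the 99% one: inside_95 implies inside_99
  ok <- out$status == "ok"
  stopifnot(all(!out$inside_95[ok] | out$inside_99[ok]))
  class(out) <- c("neutrality_report", "data.frame")
  out
}

#' @export
print.neutrality_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (r$status == "no_verdict") {
      cat(sprintf("%-9s all windows undefined: no verdict\n",
                  r$arrangement))
      next
    }
    cat(sprintf(
      "%-9s observed D = %+.3f  95%% [%+.3f, %+.3f] %s  99%% [%+.3f, %+.3f] %s  p = %.4f\n",
      r$arrangement, r$observed, r$q2.5, r$q97.5,
      if (r$inside_95) "inside" else "OUTSIDE",
      r$q0.5, r$q99.5,
      if (r$inside_99) "inside" else "OUTSIDE", r$p))
  }
  invisible(x)
}
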