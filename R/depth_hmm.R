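#' Segment a read-depth track into copy-number states
#'
#' Maximum a posteriori state path of a three-state hidden Markov chain
#' over per-window depths. States are `loss`, `neutral` and `gain` with
#' expected depths `ratio * baseline`; emissions are negative binomial
#' (`size = dispersion`) around the expected depth; transitions apply a
#' symmetric log-scale penalty for every state switch. The baseline is the
#' track median, so segmentation depends only on depth ratios and is
#' insensitive to uniform rescaling of the track. Ties are broken toward
#' the neutral state. Consecutive same-state windows are merged into
#' segments.
#'
#' @param track a `read_depth_track` (data.frame with `start`, `end`,
#'   `depth`); windows must be sorted and non-overlapping, depths positive.
#' @param ratios expected depth ratios of the three states
#'   (loss, neutral, gain).
#' @param switch_penalty log-scale cost per state switch.
#' @param dispersion negative-binomial size parameter of the emissions.
#' @param baseline baseline depth; defaults to `median(track$depth)`.
#' @return a list of class `cn_segments`: `segments` (data.frame `chrom`,
#'   `start`, `end`, `state`, `mean_ratio`, `n_windows`), `states`
#'   (per-window state), `baseline`, `low_confidence`.
#' @export
segment_read_depth <- function(track,
                               ratios = c(loss = 0.5, neutral = 1.0,
                                          gain = 1.5),
                               switch_penalty = 12,
                               dispersion = 100,
                               baseline = NULL) {
  stopifnot(is.data.frame(track),
            all(c("start", "end", "depth") %in% names(track)))
  d <- track$depth
  if (any(!is.finite(d)) || any(d <= 0))
    stop("depths must be positive and finite")
  if (is.unsorted(track$start, strictly = TRUE) ||
      any(track$end[-nrow(track)] > track$start[-1]))
    stop("windows must be sorted and non-overlapping")
  if (length(ratios) != 3 || any(ratios <= 0) || is.unsorted(ratios))
    stop("ratios must be three increasing positive values")
  if (is.null(baseline)) baseline <- median(d)
  n <- nrow(track)
  state_names <- c("loss", "neutral", "gain")
  pref <- c(2L, 1L, 3L)   # tie-break preference: neutral first

  if (n < 3) {
    obs_ratio <- mean(d) / baseline
    k <- which.min(abs(ratios - obs_ratio))
    if (abs(ratios[k] - obs_ratio) == abs(ratios[2] - obs_ratio)) k <- 2L
    states <- rep(state_names[k], n)
    return(build_segments(track, states, baseline, low_confidence = TRUE))
  }

  emis <- vapply(ratios, function(r)
    dnbinom(round(d), size = dispersion, mu = r * baseline, log = TRUE),
    numeric(n))                                  # n x 3
  score <- matrix(-Inf, n, 3)
  back <- matrix(0L, n, 3)
  init <- c(-switch_penalty, 0, -switch_penalty)
  score[1, ] <- init + emis[1, ]
  for (t in 2:n) {
    for (j in 1:3) {
      best <- -Inf; arg <- 2L
      for (i in pref) {
        s <- score[t - 1, i] + if (i == j) 0 else -switch_penalty
        if (s > best) { best <- s; arg <- i }
      }
      score[t, j] <- best + emis[t, j]
      back[t, j] <- arg
    }
  }
  path <- integer(n)
  best <- -Inf
  for (j in pref) if (score[n, j] > best) { best <- score[n, j]; path[n] <- j }
  for (t in n:2) path[t - 1] <- back[t, path[t]]
  build_segments(track, state_names[path], baseline, low_confidence = FALSE)
}

build_segments <- function(track, states, baseline, low_confidence) {
  r <- rle(states)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  segments <- data.frame(
    chrom = if ("chrom" %in% names(track)) track$chrom[idx_start] else NA,
    start = track$start[idx_start],
    end = track$end[idx_end],
    state = r$values,
    mean_ratio = vapply(seq_along(r$values), function(k)
      mean(track$depth[idx_start[k]:idx_end[k]]) / baseline, numeric(1)),
    n_windows = r$lengths,
    stringsAsFactors = FALSE
  )
  structure(list(segments = segments, states = states, baseline = baseline,
                 low_confidence = low_confidence),
            class = "cn_segments")
}

#' @export
print.cn_segments <- function(x, ...) {
  cat("Copy-number segmentation (baseline ", signif(x$baseline, 4), "x",
      if (x$low_confidence) ", LOW CONFIDENCE" else "", ")\n", sep = "")
  print(x$segments)
  invisible(x)
}
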