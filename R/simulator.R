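#' Configuration of the forward-time inversion simulator
#'
#' Wright-Fisher diploid population of constant size carrying a neutral
#' inversion, conditioned on the inversion reaching a target frequency
#' (the published framework uses a 500-kb inversion, Ne = 10,000 and
#' target frequency 0.337, the highest known frequency of the
#' polymorphism). Desk defaults scale the population and region down
#' (Ne = 500, 50 kb) while holding the population-scaled rates
#' theta = 4*Ne*mu*L and rho = 4*Ne*r*L at their full-scale values
#' (theta = 250, rho = 200, i.e. human-like mu = 1.25e-8 and r = 1e-8 per
#' bp per generation at Ne = 10,000 over 500 kb), so diversity summaries
#' are comparable across scales.
#'
#' @param Ne effective population size (diploids).
#' @param region_length simulated region length in bp.
#' @param inversion_interval interval of the inversion within the region
#'   (0-based half-open); default the central 80% of the region.
#' @param target_frequency inversion frequency at which sampling happens.
#' @param mu per-bp per-generation mutation rate; default keeps
#'   theta = 4*Ne*mu*L = 250.
#' @param r per-bp per-generation recombination rate; default keeps
#'   rho = 4*Ne*r*L = 200.
#' @param burn_in neutral generations before the inversion is introduced
#'   (builds standing variation); `"none"` (0) or a number of generations.
#'   Null-building runs conventionally use `10 * Ne`.
#' @param max_generations cap on total post-introduction generations
#'   summed across restarts; exceeded caps yield an explicit failure.
#' @param n_inverted,n_standard chromosomes sampled per arrangement at the
#'   sampling generation. Defaults mirror the published data: 64 inverted
#'   (32 homozygotes) and 300 standard (150 homozygotes) chromosomes.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(Ne = 500L, region_length = 50000L,
                       inversion_interval = NULL,
                       target_frequency = 0.337,
                       mu = NULL, r = NULL,
                       burn_in = "none",
                       max_generations = 1e6,
                       n_inverted = 64L, n_standard = 300L) {
  if (target_frequency <= 0 || target_frequency >= 1)
    stop("target_frequency must lie in (0, 1)")
  if (Ne < 2 || region_length <= 0) stop("invalid Ne or region_length")
  L <- as.numeric(region_length)
  if (is.null(mu)) mu <- 250 / (4 * Ne * L)
  if (is.null(r)) r <- 200 / (4 * Ne * L)
  if (mu < 0 || r < 0) stop("rates must be non-negative")
  if (is.null(inversion_interval))
    inversion_interval <- c(0.1 * L, 0.9 * L)
  if (inversion_interval[1] < 0 || inversion_interval[2] > L ||
      inversion_interval[1] >= inversion_interval[2])
    stop("inversion_interval must be a non-empty subinterval of the region")
  if (identical(burn_in, "none")) burn_in <- 0L
  burn_in <- as.integer(burn_in)
  if (burn_in < 0) stop("burn_in must be non-negative")
  min_inv <- floor(target_frequency * 2 * Ne)
  if (n_inverted > min_inv)
    stop("n_inverted exceeds the inverted chromosomes guaranteed at the ",
         "sampling generation (", min_inv, ")")
  if (n_standard > 2 * Ne - ceiling(target_frequency * 2 * Ne))
    warning("n_standard may exceed available standard chromosomes at high ",
            "crossing frequencies")
  structure(list(Ne = as.integer(Ne), region_length = L,
                 inversion_interval = as.numeric(inversion_interval),
                 target_frequency = target_frequency, mu = mu, r = r,
                 burn_in = burn_in, max_generations = max_generations,
                 n_inverted = as.integer(n_inverted),
                 n_standard = as.integer(n_standard)),
            class = "sim_config")
}

#' Run one conditioned simulation replicate
#'
#' One replicate: (1) optional neutral burn-in builds standing variation;
#' (2) a uniformly chosen chromosome acquires the inverted arrangement;
#' (3) each generation all `2*Ne` offspring chromosomes are gametes of
#' uniformly sampled diploid parents, with crossover count
#' Poisson(`r * L`), uniform breakpoints resampled outside the inversion
#' interval in arrangement-heterozygous parents, and Poisson(`mu * L`)
#' new infinite-sites mutations; (4) if the inversion is lost the
#' replicate restarts from step 2 (from the same standing variation, with
#' fresh randomness); (5) at the first generation where the inversion
#' frequency reaches the target, chromosomes are sampled without
#' replacement from each arrangement class.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed controlling all randomness of the replicate.
#' @return a list of class `replicate_result`: `success`, `haplotypes`
#'   (list of mutation-position vectors per sampled chromosome),
#'   `inverted` (arrangement flag per sampled chromosome), `generations`,
#'   `restarts`, `frequency` (inversion frequency at sampling). On failure
#'   (`max_generations` exceeded) only `success`, `generations` and
#'   `restarts` are set.
#' @export
run_replicate <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  res <- withr::with_seed(seed, cpp_run_replicate(
    Ne = cfg$Ne, L = cfg$region_length, mu = cfg$mu, r = cfg$r,
    inv_start = cfg$inversion_interval[1],
    inv_end = cfg$inversion_interval[2],
    target_freq = cfg$target_frequency,
    burnin_gens = cfg$burn_in,
    max_generations = cfg$max_generations,
    n_inverted = cfg$n_inverted, n_standard = cfg$n_standard))
  res$config <- cfg
  res$seed <- seed
  class(res) <- "replicate_result"
  res
}

#' Unconditioned neutral Wright-Fisher sample
#'
#' Runs the same reproduction engine without any inversion and samples
#' chromosomes after a fixed number of generations; used as a neutral
#' control and for mutation-rate scaling checks.
#'
#' @param Ne,L,mu,r population size, region length and per-bp rates.
#' @param generations generations to run from an initially monomorphic
#'   population.
#' @param n_sample chromosomes sampled (without replacement).
#' @param seed integer seed.
#' @return list of mutation-position vectors, one per sampled chromosome.
#' @export
neutral_sample <- function(Ne, L, mu, r, generations, n_sample, seed = 1L) {
  res <- withr::with_seed(seed, cpp_neutral_sample(
    Ne = as.integer(Ne), L = as.numeric(L), mu = mu, r = r,
    generations = as.integer(generations), n_sample = as.integer(n_sample)))
  res$haplotypes
}

#' Convert sparse haplotypes to a binary matrix
#'
#' @param haps list of mutation-position vectors.
#' @param interval optional `c(start, end)`: keep only mutations in the
#'   0-based half-open interval.
#' @return list with `H` (0/1 matrix, one row per haplotype) and
#'   `positions` (sorted segregating positions).
#' @export
haplotypes_to_matrix <- function(haps, interval = NULL) {
  if (!is.null(interval))
    haps <- lapply(haps, function(h) h[h >= interval[1] & h < interval[2]])
  positions <- sort(unique(unlist(haps)))
  H <- matrix(0L, nrow = length(haps), ncol = length(positions))
  for (i in seq_along(haps))
    H[i, match(haps[[i]], positions)] <- 1L
  list(H = H, positions = positions)
}

#' Build an empirical neutrality null for Tajima's D per arrangement
#'
#' Runs `n_replicates` conditioned replicates (per-replicate seeds derived
#' deterministically from the master seed), computes Tajima's D over the
#' inversion interval separately for the standard and inverted samples of
#' each replicate, and summarizes each arrangement's null with empirical
#' quantiles (type-7 interpolation) at 0.5, 2.5, 97.5 and 99.5 percent.
#' Replicates with undefined D (no segregating sites in a class) are
#' tracked separately; failed replicates (generation cap) are counted and
#' excluded.
#'
#' @param cfg a [sim_config()].
#' @param n_replicates number of replicates (the published null used
#'   1,000 runs).
#' @param seed master seed.
#' @return a list of class `null_distribution`: `d` (list with numeric
#'   vectors `standard` and `inverted`, `NA` where undefined), `quantiles`
#'   (matrix arrangement x probability), `n_replicates`, `n_failed`,
#'   `n_undefined` (per arrangement), `config`, `seed`.
#' @export
build_null <- function(cfg, n_replicates = 1000L, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L,
                                       n_replicates))
  d_std <- d_inv <- rep(NA_real_, n_replicates)
  n_failed <- 0L
  freqs <- rep(NA_real_, n_replicates)
  for (k in seq_len(n_replicates)) {
    rep_k <- run_replicate(cfg, seed = seeds[k])
    if (!rep_k$success) { n_failed <- n_failed + 1L; next }
    freqs[k] <- rep_k$frequency
    d_std[k] <- replicate_tajima(rep_k, arrangement = 0L)
    d_inv[k] <- replicate_tajima(rep_k, arrangement = 1L)
  }
  probs <- c(0.005, 0.025, 0.975, 0.995)
  qs <- rbind(
    standard = quantile(d_std, probs, na.rm = TRUE, type = 7, names = FALSE),
    inverted = quantile(d_inv, probs, na.rm = TRUE, type = 7, names = FALSE))
  colnames(qs) <- paste0("q", probs * 100)
  structure(list(d = list(standard = d_std, inverted = d_inv),
                 quantiles = qs,
                 n_replicates = n_replicates, n_failed = n_failed,
                 n_undefined = c(standard = sum(is.na(d_std)) - n_failed,
                                 inverted = sum(is.na(d_inv)) - n_failed),
                 frequencies = freqs,
                 config = cfg, seed = seed),
            class = "null_distribution")
}

replicate_tajima <- function(rep_k, arrangement) {
  sel <- rep_k$inverted == arrangement
  hm <- haplotypes_to_matrix(rep_k$haplotypes[sel],
                             interval = rep_k$config$inversion_interval)
  tajimas_d(hm$H)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Empirical Tajima's D null (", x$n_replicates, " replicates, ",
      x$n_failed, " failed)\n", sep = "")
  print(round(x$quantiles, 3))
  cat("undefined D: standard ", x$n_undefined["standard"],
      ", inverted ", x$n_undefined["inverted"], "\n", sep = "")
  invisible(x)
}

#' Write a null distribution as TSV files
#'
#' Writes a per-replicate table (replicate, arrangement, D) and a quantile
#' summary table.
#'
#' @param null a [build_null()] result.
#' @param path_replicates,path_quantiles output paths.
#' @export
write_null_distribution <- function(null, path_replicates, path_quantiles) {
  stopifnot(inherits(null, "null_distribution"))
  n <- null$n_replicates
  df <- data.frame(replicate = rep(seq_len(n), 2),
                   arrangement = rep(c("standard", "inverted"), each = n),
                   tajimas_d = c(null$d$standard, null$d$inverted))
  write.table(df, path_replicates, sep = "\t", quote = FALSE,
              row.names = FALSE)
  qdf <- data.frame(arrangement = rownames(null$quantiles),
                    null$quantiles, check.names = FALSE)
  write.table(qdf, path_quantiles, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path_replicates)
}
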