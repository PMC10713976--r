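# Synthetic cohorts and simulated RT-shift benchmarks with ground
# truth. The generator emulates extracted MS1 feature lists — peptide-
# like m/z values with a tunable fraction of near-isobaric neighbors
# (the hard negatives), bounded RT ranges, log-scale intensities and
# charge states — so every pipeline stage is testable without any
# external data.

#' Simulation specification
#'
#' @param n_features number of features in the base run.
#' @param rt_range RT range in minutes (default 80, matching the default
#'   common scaling range).
#' @param mz_range m/z range in Th (default 300-1500).
#' @param intensity_range intensity bounds; intensities are drawn
#'   log10-uniformly over this range (default 1e5-1e9).
#' @param data_type `"proteomic"` (charges 2-6) or `"metabolomic"`
#'   (charges 1-6).
#' @param near_iso_frac fraction of features given an m/z within 0.03 Th
#'   of another feature, creating the near-isobaric clusters that make
#'   negative pairs hard (default 0.1).
#' @param mu,sigma mean and standard deviation, in minutes, of the
#'   normal RT shift injected into the shifted copy (defaults 0 and
#'   0.5 — the middle of the benchmark sigma grid).
#' @param seed RNG seed; the whole cohort is a pure function of the spec.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_features = 2000L, rt_range = 80,
                     mz_range = c(300, 1500), intensity_range = c(1e5, 1e9),
                     data_type = c("proteomic", "metabolomic"),
                     near_iso_frac = 0.1, mu = 0, sigma = 0.5, seed = 42L) {
  data_type <- match.arg(data_type)
  assert_number(n_features, "n_features", 1)
  assert_number(rt_range, "rt_range", 0, strict = TRUE)
  assert_number(near_iso_frac, "near_iso_frac", 0)
  assert_number(sigma, "sigma", 0)
  structure(list(n_features = as.integer(n_features), rt_range = rt_range,
                 mz_range = mz_range, intensity_range = intensity_range,
                 data_type = data_type, near_iso_frac = near_iso_frac,
                 charge_range = if (data_type == "proteomic") 2:6 else 1:6,
                 mu = mu, sigma = sigma, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a base feature table
#'
#' m/z values are drawn uniformly over `mz_range`, then a
#' `near_iso_frac` fraction is re-seated within 0.02 Th of a randomly
#' chosen other feature so near-isobaric clusters exist; RT is uniform
#' on `[0, rt_range]`; intensities are log10-uniform; charges uniform
#' over the data type's range.
#'
#' @param spec a [sim_spec()].
#' @param sample_id sample id of the generated run (default `"S1"`).
#' @return a [feature_table()].
#' @export
generate_base_table <- function(spec = sim_spec(), sample_id = "S1") {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_features
  with_local_seed(spec$seed, {
    mz <- runif(n, spec$mz_range[1], spec$mz_range[2])
    k <- floor(spec$near_iso_frac * n)
    if (k > 0L && n > 1L) {
      idx <- sample.int(n, k)
      donor <- vapply(idx, function(i) sample(setdiff(seq_len(n), i), 1L),
                      integer(1))
      mz[idx] <- pmax(mz[donor] + runif(k, -0.02, 0.02), 1e-6)
    }
    df <- data.frame(
      feature_id = sprintf("F%06d", seq_len(n)),
      mz = mz,
      rt = runif(n, 0, spec$rt_range),
      intensity = 10^runif(n, log10(spec$intensity_range[1]),
                           log10(spec$intensity_range[2])),
      charge = sample(spec$charge_range, n, replace = TRUE))
  })
  feature_table(df, sample_id = sample_id)
}

#' Inject a normal RT shift, keeping ground truth
#'
#' Each feature independently receives `rt + N(mu, sigma)`; shifted RTs
#' are clipped at 0 (negative elution times do not exist). The returned
#' cohort records the identity correspondence between original and
#' shifted features as ground truth.
#'
#' @param table base [feature_table()].
#' @param mu,sigma shift mean / standard deviation in minutes.
#' @param seed RNG seed.
#' @param shifted_id sample id of the shifted copy (default
#'   `"<base>_shifted"`).
#' @return an object of class `simulated_cohort`: `original`, `shifted`,
#'   `truth` (columns `sample_1`, `feature_1`, `sample_2`, `feature_2`)
#'   and the shift parameters.
#' @export
inject_rt_shift <- function(table, mu = 0, sigma = 0.5, seed = 1L,
                            shifted_id = NULL) {
  stopifnot(inherits(table, "feature_table"))
  assert_number(sigma, "sigma", 0)
  shifted_id <- shifted_id %||% paste0(table$sample_id, "_shifted")
  dt <- copy(table$features)
  n <- nrow(dt)
  with_local_seed(seed, {
    shift <- rnorm(n, mu, sigma)
  })
  dt[, rt := pmax(rt + shift, 0)]
  dt[, c("rt_scaled", "rt_corrected") := NA_real_]
  shifted <- feature_table(
    dt[, .(feature_id, mz, rt, intensity, charge, rt_start, rt_end)],
    sample_id = shifted_id)
  truth <- data.table(sample_1 = table$sample_id,
                      feature_1 = table$features$feature_id,
                      sample_2 = shifted_id,
                      feature_2 = table$features$feature_id)
  structure(list(original = table, shifted = shifted, truth = truth,
                 mu = mu, sigma = sigma, seed = as.integer(seed)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d features, shift N(%.2f, %.2f^2) min\n",
              nrow(x$truth), x$mu, x$sigma))
  invisible(x)
}

#' The (mu, sigma) grid of simulated shift benchmarks
#'
#' Builds the full benchmark grid of shifted cohorts from one base
#' table: by default 3 means (0, 5, 10 min) crossed with 8 standard
#' deviations (0, 0.1, 0.3, 0.5, 0.7, 1, 3, 5 min) = 24 cohorts, all
#' sharing the same original table, each deterministically seeded from
#' `(seed, mu, sigma)`.
#'
#' @param base a base [feature_table()].
#' @param mus,sigmas grid values in minutes.
#' @param seed base RNG seed.
#' @return a list of `simulated_cohort`s with a `grid` attribute
#'   (a `data.table` of `mu`, `sigma`, `seed` per cohort).
#' @export
grid_benchmark <- function(base, mus = c(0, 5, 10),
                           sigmas = c(0, 0.1, 0.3, 0.5, 0.7, 1, 3, 5),
                           seed = 42L) {
  stopifnot(inherits(base, "feature_table"), n_features(base) > 0L)
  grid <- CJ(mu = mus, sigma = sigmas, sorted = FALSE)
  grid[, seed := as.integer((seed + 97L * seq_len(.N)) %% .Machine$integer.max)]
  cohorts <- lapply(seq_len(nrow(grid)), function(i)
    inject_rt_shift(base, grid$mu[i], grid$sigma[i], seed = grid$seed[i]))
  attr(cohorts, "grid") <- grid[]
  cohorts
}

#' Ground-truth correspondence of a simulated cohort
#'
#' Exposes the identity bijection of a cohort in the shape consumed by
#' [sample_training_pairs()].
#'
#' @param cohort a `simulated_cohort`.
#' @return a `data.table` with columns `sample_1`, `feature_1`,
#'   `sample_2`, `feature_2`.
#' @export
make_training_truth <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  copy(cohort$truth)
}

#' Labeled training pairs from the default synthetic benchmark
#'
#' Convenience wrapper reproducing the package's documented training
#' conditions: a 10,000-feature base run (large enough that thousands of
#' close-m/z negative pairs exist), near-isobaric fraction 0.1, a
#' N(0, 0.5 min) RT shift, coarse alignment, binning, then sampling of
#' `n_pos` positive and `n_neg` negative pairs.
#'
#' @param n_pos,n_neg pair counts (default 2000 each).
#' @param seed RNG seed driving the whole construction.
#' @param n_features base run size (default 10000).
#' @param mu,sigma training-shift parameters (defaults 0 and 0.5 min).
#' @return a labeled `pair_set`.
#' @export
simulate_training_pairs <- function(n_pos = 2000L, n_neg = 2000L, seed = 42L,
                                    n_features = 10000L, mu = 0, sigma = 0.5) {
  base <- generate_base_table(sim_spec(n_features = n_features, mu = mu,
                                       sigma = sigma, seed = seed))
  cohort <- inject_rt_shift(base, mu = mu, sigma = sigma, seed = seed + 1L)
  coarse <- coarse_align_cohort(list(cohort$original, cohort$shifted))
  bins <- assign_bins(coarse$tables)
  sample_training_pairs(bins, make_training_truth(cohort),
                        n_pos = n_pos, n_neg = n_neg, seed = seed + 2L)
}
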