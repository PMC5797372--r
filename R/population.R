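#' Baseline-load distributions for synthetic cohorts
#'
#' Three ways to place virtual patients on the load grid: a fixed
#' `(x, y)` point for every patient; a uniform draw over the integer
#' cells of a [region_partition()] region; or an arbitrary discrete
#' bivariate table of cell probabilities.
#'
#' @param x,y Fixed loads in `[0, 16]`.
#' @return A baseline-distribution object.
#' @export
#' @examples
#' fixed_baseline(8, 8)
#' uniform_region_baseline(region_partition(3), "neg")
fixed_baseline <- function(x, y) {
  .check_load(x, y)
  structure(list(kind = "fixed", x = x, y = y), class = "baseline_dist")
}

#' @rdname fixed_baseline
#' @param partition A [region_partition()].
#' @param region `"neg"` or `"pos"`.
#' @export
uniform_region_baseline <- function(partition, region = c("neg", "pos")) {
  stopifnot(inherits(partition, "region_partition"))
  region <- match.arg(region)
  cells <- if (region == "neg") partition$neg_cells else partition$pos_cells
  structure(list(kind = "uniform-region", cells = cells, region = region),
            class = "baseline_dist")
}

#' @rdname fixed_baseline
#' @param cells Data.frame with integer columns `x`, `y` and a
#'   probability column `p` (summing to 1).
#' @export
discrete_baseline <- function(cells) {
  stopifnot(is.data.frame(cells), all(c("x", "y", "p") %in% names(cells)))
  .check_load(cells$x, cells$y)
  if (abs(sum(cells$p) - 1) > 1e-9 || any(cells$p < 0))
    stop("cell probabilities must be non-negative and sum to 1", call. = FALSE)
  structure(list(kind = "discrete", cells = cells), class = "baseline_dist")
}

#' Synthetic cohort specification
#'
#' Defines a cohort of virtual patients: size, baseline Aβ load
#' distribution, APOE genotype frequencies and optional ADAS-Cog
#' measurement noise. The default genotype mix is 0.25 / 0.50 / 0.25
#' (APOE4-/-, +/-, +/+).
#'
#' @param n Number of patients (>= 1).
#' @param baseline A baseline distribution (see [fixed_baseline()]).
#' @param genotype_freq Named or positional probabilities for
#'   `APOE4-/-`, `APOE4+/-`, `APOE4+/+`; must sum to 1.
#' @param noise_sd ADAS-Cog measurement noise standard deviation
#'   (points, >= 0; applied by [add_measurement_noise()], never to
#'   loads).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, baseline = fixed_baseline(8, 8),
                        genotype_freq = c(0.25, 0.50, 0.25),
                        noise_sd = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  stopifnot(inherits(baseline, "baseline_dist"))
  if (length(genotype_freq) != 3 || any(genotype_freq < 0) ||
      abs(sum(genotype_freq) - 1) > 1e-9)
    stop("`genotype_freq` must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), baseline = baseline,
                 genotype_freq = stats::setNames(as.numeric(genotype_freq),
                                                 apoe_genotypes()),
                 noise_sd = noise_sd),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: n = %d, baseline %s, genotype mix %s, noise sd %.2g\n",
              x$n, x$baseline$kind,
              paste(sprintf("%s %.2f", names(x$genotype_freq), x$genotype_freq),
                    collapse = ", "),
              x$noise_sd))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` virtual patients (id, APOE genotype, baseline load) from a
#' [cohort_spec()]. Fully reproducible: the same spec and seed give an
#' identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Data.frame with columns `patient_id`, `genotype`, `x`, `y`.
#' @export
#' @examples
#' generate_cohort(cohort_spec(5, fixed_baseline(8, 8)), seed = 1)
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  genotype <- sample(apoe_genotypes(), spec$n, replace = TRUE,
                     prob = spec$genotype_freq)
  bl <- spec$baseline
  if (bl$kind == "fixed") {
    x <- rep(bl$x, spec$n); y <- rep(bl$y, spec$n)
  } else {
    cells <- bl$cells
    p <- if (bl$kind == "discrete") cells$p else rep(1 / nrow(cells), nrow(cells))
    idx <- sample.int(nrow(cells), spec$n, replace = TRUE, prob = p)
    x <- cells$x[idx]; y <- cells$y[idx]
  }
  data.frame(patient_id = sprintf("P%04d", seq_len(spec$n)),
             genotype = genotype, x = x, y = y)
}

#' Add ADAS-Cog measurement noise to trial trajectories
#'
#' Adds independent Gaussian noise to the `adas` column only (never to
#' loads), clipped to the instrument range `[0, 70]`. `noise_sd = 0` is
#' the identity.
#'
#' @param trajectories A trajectory data.frame with an `adas` column
#'   (see [simulate_trial()]).
#' @param noise_sd Noise standard deviation in ADAS-Cog points (>= 0).
#' @param seed Integer seed.
#' @return The trajectories with noisy, clipped `adas`.
#' @export
add_measurement_noise <- function(trajectories, noise_sd, seed = 1L) {
  stopifnot(is.data.frame(trajectories), "adas" %in% names(trajectories))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(trajectories)
  set.seed(as.integer(seed))
  trajectories$adas <- pmin(pmax(
    trajectories$adas + stats::rnorm(nrow(trajectories), 0, noise_sd), 0), 70)
  trajectories
}
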