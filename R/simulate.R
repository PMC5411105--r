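#' Simulate adult-female collagen values
#'
#' Independent normal draws per isotope, shaped like a collagen table so
#' synthetic and real data are interchangeable throughout the pipeline.
#' Elemental quality fields are filled with pass-through constants that
#' clear the QC screen (diagenesis is not simulated).
#'
#' @param n number of females.
#' @param mu_N,sd_N,mu_C,sd_C per-mil means and SDs of the collagen
#'   values.
#' @param seed integer seed.
#' @return Collagen-table data frame (see [read_collagen()]).
#' @export
simulate_females <- function(n, mu_N = 10.91, sd_N = 1.19,
                             mu_C = -14.48, sd_C = 1.87, seed = 1) {
  stopifnot(n >= 1, sd_N >= 0, sd_C >= 0)
  set.seed(seed)
  data.frame(sample_id = sprintf("SF-%03d", seq_len(n)),
             cemetery = "YC", cohort = "adult_female",
             age_estimate = "Young Adult",
             age_low_years = NA_real_, age_high_years = NA_real_,
             d13C = rnorm(n, mu_C, sd_C), d15N = rnorm(n, mu_N, sd_N),
             pctC = 35, pctN = 10.7, cn_ratio = 3.2, collagen_yield = 9,
             row.names = NULL)
}

#' Simulate a juvenile cohort from the weaning trajectory
#'
#' Draws ages at death, evaluates the deterministic collagen trajectory
#' ([collagen_trajectory()]) under the true weaning parameters and
#' turnover schedule, and adds normal observation noise. The default
#' age distribution is uniform over \code{age_range}; a triangular
#' weighting peaked inside the range mimics the infant-mortality peak
#' of archaeological cohorts. delta13C values are uninformative normal
#' fill (the weaning trajectory models nitrogen only) so the rows pass
#' full-pipeline validation.
#'
#' @param n cohort size.
#' @param true_params a [weaning_params()].
#' @param turnover a [turnover_model()].
#' @param obs_noise_sd per-mil SD of the observation noise on delta15N.
#' @param age_range length-2 bounds (years) of the age-at-death draws.
#' @param age_shape \code{"uniform"} or \code{"triangular"} (peak at
#'   \code{age_peak}).
#' @param age_peak mode of the triangular distribution (years).
#' @param seed integer seed.
#' @param ode_step trajectory integration step (years).
#' @return Collagen-table data frame with attribute
#'   \code{"true_params"}.
#' @export
simulate_juvenile_cohort <- function(n, true_params,
                                     turnover = turnover_model(),
                                     obs_noise_sd = 1.5,
                                     age_range = c(0, 5.5),
                                     age_shape = c("uniform", "triangular"),
                                     age_peak = 1.5, seed = 1,
                                     ode_step = 0.02) {
  stopifnot(inherits(true_params, "weaning_params"), n >= 1,
            obs_noise_sd >= 0, age_range[1] >= 0,
            age_range[1] <= age_range[2])
  age_shape <- match.arg(age_shape)
  set.seed(seed)
  u <- runif(n)
  ages <- if (age_shape == "uniform") {
    age_range[1] + u * diff(age_range)
  } else {
    .rtriangular(u, age_range[1], age_peak, age_range[2])
  }
  ages <- sort(ages)
  truth <- collagen_trajectory(true_params, turnover, ages,
                               ode_step = ode_step)
  d15N <- truth + rnorm(n, 0, obs_noise_sd)
  d13C <- rnorm(n, -19.5, 2)
  out <- data.frame(sample_id = sprintf("SJ-%03d", seq_len(n)),
                    cemetery = "YC", cohort = "juvenile",
                    age_estimate = sprintf("%.2f years", ages),
                    age_low_years = ages, age_high_years = ages,
                    d13C = d13C, d15N = d15N,
                    pctC = 35, pctN = 10.7, cn_ratio = 3.2,
                    collagen_yield = 9, row.names = NULL)
  attr(out, "true_params") <- true_params
  out
}

.rtriangular <- function(u, a, c, b) {
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Simulate mixture consumers at known source proportions
#'
#' Each consumer's isotope pair is drawn independently normal around the
#' concentration-weighted [mixture_mean()] with variance
#' [mixture_variance()] -- the mixing model's own forward model, for
#' parameter-recovery testing.
#'
#' @param p proportion vector on the simplex (one entry per source).
#' @param sources source table.
#' @param n number of consumers.
#' @param residual_sds length-2 residual SDs (N, C) added in quadrature.
#' @param seed integer seed.
#' @return Data frame with columns \code{d15N}, \code{d13C} and
#'   attribute \code{"true_p"}.
#' @export
simulate_mixture_consumers <- function(p, sources, n,
                                       residual_sds = c(0, 0), seed = 1) {
  validate_sources(sources)
  .check_simplex(p, nrow(sources))
  stopifnot(n >= 1, all(residual_sds >= 0))
  set.seed(seed)
  muN <- mixture_mean(p, sources, "N")
  muC <- mixture_mean(p, sources, "C")
  sdN <- sqrt(mixture_variance(p, sources, "N", residual_sds[1]))
  sdC <- sqrt(mixture_variance(p, sources, "C", residual_sds[2]))
  out <- data.frame(d15N = rnorm(n, muN, sdN), d13C = rnorm(n, muC, sdC))
  attr(out, "true_p") <- p
  out
}
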