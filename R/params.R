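#' Population parameters of the two-level AR(1) process
#'
#' Parameters of the person-level random-effects AR(1) model for within-day
#' affect dynamics: each person has a trait level `mu_i = gamma00 + u0i` and
#' a beep-level inertia `phi_i = gamma10 + u1i`, with `(u0i, u1i)` jointly
#' normal. Within each day the series is a stationary AR(1) around `mu_i`
#' with coefficient `phi_i` and innovation SD `sd_e`; the night interrupts
#' the process, so each day restarts independently.
#'
#' @param gamma00 population mean trait level (affect-scale units).
#' @param gamma10 population mean beep-level inertia.
#' @param sd_u0 SD of person trait deviations.
#' @param sd_u1 SD of person inertia deviations.
#' @param sd_e beep-level residual SD.
#' @param r_u0u1 correlation between trait and inertia deviations.
#' @return An `ar2_params` list.
#' @export
ar2_params <- function(gamma00, gamma10, sd_u0, sd_u1, sd_e, r_u0u1 = 0) {
  p <- list(gamma00 = gamma00, gamma10 = gamma10, sd_u0 = sd_u0,
            sd_u1 = sd_u1, sd_e = sd_e, r_u0u1 = r_u0u1)
  check_sds(c(p$sd_u0, p$sd_u1, p$sd_e))
  check_corr_matrix(corr_matrix_2l(p))
  structure(p, class = "ar2_params")
}

#' Population parameters of the three-level AR(1) process
#'
#' Parameters of the three-level model in which day means follow an AR(1)
#' across days within person (`mu_di = mu_i + beta_i (mu_{d-1,i} - mu_i) +
#' r0di`) and, conditional on the day mean, beeps follow an AR(1) within the
#' day with person-specific coefficient `zeta_i`. Person deviations of trait
#' level, day inertia and beep inertia are jointly normal with the given SDs
#' and pairwise correlations.
#'
#' @param gamma000 population mean trait level.
#' @param gamma010 population mean day-level inertia.
#' @param gamma100 population mean beep-level inertia.
#' @param sd_u00,sd_u01,sd_u10 SDs of person deviations of trait level,
#'   day inertia and beep inertia.
#' @param sd_r day-level residual SD.
#' @param sd_e beep-level residual SD.
#' @param r_u00u01,r_u00u10,r_u01u10 pairwise correlations of the person
#'   deviations.
#' @return An `ar3_params` list.
#' @export
ar3_params <- function(gamma000, gamma010, gamma100, sd_u00, sd_u01, sd_u10,
                       sd_r, sd_e, r_u00u01 = 0, r_u00u10 = 0,
                       r_u01u10 = 0) {
  p <- list(gamma000 = gamma000, gamma010 = gamma010, gamma100 = gamma100,
            sd_u00 = sd_u00, sd_u01 = sd_u01, sd_u10 = sd_u10,
            sd_r = sd_r, sd_e = sd_e, r_u00u01 = r_u00u01,
            r_u00u10 = r_u00u10, r_u01u10 = r_u01u10)
  check_sds(c(p$sd_u00, p$sd_u01, p$sd_u10, p$sd_r, p$sd_e))
  check_corr_matrix(corr_matrix_3l(p))
  structure(p, class = "ar3_params")
}

check_sds <- function(sds) {
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("standard deviations must be finite and non-negative",
         call. = FALSE)
  }
}

check_corr_matrix <- function(R) {
  if (any(abs(R[upper.tri(R)]) > 1)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
}

corr_matrix_2l <- function(p) {
  matrix(c(1, p$r_u0u1, p$r_u0u1, 1), 2, 2)
}

corr_matrix_3l <- function(p) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- p$r_u00u01
  R[1, 3] <- R[3, 1] <- p$r_u00u10
  R[2, 3] <- R[3, 2] <- p$r_u01u10
  R
}

#' Simulation-study default parameter sets
#'
#' The parameter values used by the Monte-Carlo power / Type I error study,
#' chosen to resemble multilevel AR estimates for positive affect in typical
#' student ESM samples. `sim_params_2l()` is the two-level (null) process;
#' `sim_params_3l()` the three-level process whose day level the selection
#' procedure should detect.
#'
#' @return An `ar2_params` or `ar3_params` object.
#' @export
sim_params_2l <- function() {
  ar2_params(gamma00 = 58, gamma10 = 0.37, sd_u0 = 12, sd_u1 = 0.14,
             sd_e = 15, r_u0u1 = -0.44)
}

#' @rdname sim_params_2l
#' @export
sim_params_3l <- function() {
  ar3_params(gamma000 = 58, gamma010 = 0.27, gamma100 = 0.16,
             sd_u00 = 13, sd_u01 = 0.22, sd_u10 = 0.13, sd_r = 7,
             sd_e = 15, r_u00u01 = -0.45, r_u00u10 = -0.365,
             r_u01u10 = 0.22)
}

#' Parameters of the misspecification demonstration datasets
#'
#' Five archetypal generating processes used to demonstrate how day-level
#' variance and beep-level inertia are confounded when the number of levels
#' is misspecified (all at 90 persons, 21 days, 10 beeps/day):
#' \describe{
#'   \item{A}{empty three-level process: day-level variance, no inertia.}
#'   \item{B}{A plus a fixed beep-level inertia of 0.15.}
#'   \item{C}{B with the day-level SD raised to 15 (equal to the beep SD).}
#'   \item{D}{empty three-level process with day and beep SDs both 15.}
#'   \item{E}{a genuinely two-level AR(1) process (no day level).}
#' }
#'
#' @param case one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @return An `ar2_params` (case E) or `ar3_params` object.
#' @export
artifact_params <- function(case = c("A", "B", "C", "D", "E")) {
  case <- match.arg(case)
  switch(case,
    A = ar3_params(gamma000 = 58, gamma010 = 0, gamma100 = 0,
                   sd_u00 = 12.3, sd_u01 = 0, sd_u10 = 0, sd_r = 7.9,
                   sd_e = 15),
    B = ar3_params(gamma000 = 58, gamma010 = 0, gamma100 = 0.15,
                   sd_u00 = 12.3, sd_u01 = 0, sd_u10 = 0, sd_r = 7.9,
                   sd_e = 15),
    C = ar3_params(gamma000 = 58, gamma010 = 0, gamma100 = 0.15,
                   sd_u00 = 12.3, sd_u01 = 0, sd_u10 = 0, sd_r = 15,
                   sd_e = 15),
    D = ar3_params(gamma000 = 58, gamma010 = 0, gamma100 = 0,
                   sd_u00 = 12.3, sd_u01 = 0, sd_u10 = 0, sd_r = 15,
                   sd_e = 15),
    E = ar2_params(gamma00 = 58.25, gamma10 = 0.37, sd_u0 = 12.75,
                   sd_u1 = 0.1, sd_e = 15.25, r_u0u1 = -0.44))
}

#' Design of the misspecification demonstration datasets
#' @return A `study_design` (90 persons, 21 days, 10 beeps/day).
#' @rdname artifact_params
#' @export
artifact_design <- function() study_design(90, 21, 10)
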