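#' Truncate an inertia value to the stationary region
#'
#' Sampled person-specific inertias must satisfy |inertia| < 1 for the
#' within-day (or across-day) AR(1) process to be stationary. Values of 1 or
#' larger are set to 0.99; symmetrically, values of -1 or smaller are set to
#' -0.99.
#'
#' @param value numeric vector of inertia values.
#' @return The truncated values.
#' @export
truncate_inertia <- function(value) {
  value[value >= 1] <- 0.99
  value[value <= -1] <- -0.99
  value
}

# Deterministic substream seed from a root seed and index path. Chained
# modular hash keeps everything < 2^31 and exact in double arithmetic.
derive_seed <- function(seed, ...) {
  M <- 2147483563
  h <- as.numeric(seed) %% M
  for (x in c(...)) h <- (h * 1299721 + as.numeric(x) + 1) %% M
  as.integer(h %% 2147483562) + 1L
}

# Symmetric square root of a PSD covariance built from SDs and correlations
cov_sqrt <- function(sds, R) {
  S <- diag(sds, nrow = length(sds)) %*% R %*% diag(sds, nrow = length(sds))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Draw one person's random effects inside that person's substream.
# Returns mu plus the truncated inertia value(s).
person_effects_2l <- function(params, S) {
  z <- stats::rnorm(2)
  u <- as.numeric(S %*% z)
  list(mu = params$gamma00 + u[1],
       phi = truncate_inertia(params$gamma10 + u[2]))
}

person_effects_3l <- function(params, S) {
  z <- stats::rnorm(3)
  u <- as.numeric(S %*% z)
  list(mu = params$gamma000 + u[1],
       beta = truncate_inertia(params$gamma010 + u[2]),
       zeta = truncate_inertia(params$gamma100 + u[3]))
}

#' Draw person-level random effects
#'
#' Draws each person's trait level and inertia value(s) from the joint
#' normal distribution implied by the parameter object, applying the
#' stationarity truncation to the inertias. Each person uses a dedicated
#' substream of the root seed, so the draws for person `i` do not depend on
#' how many persons are requested.
#'
#' @param params an `ar2_params` or `ar3_params` object.
#' @param n_persons number of persons to draw.
#' @param seed integer root seed.
#' @return A data.frame with one row per person: `mu` and `phi` (two-level)
#'   or `mu`, `beta`, `zeta` (three-level).
#' @export
draw_person_effects <- function(params, n_persons, seed = 1L) {
  if (inherits(params, "ar2_params")) {
    S <- cov_sqrt(c(params$sd_u0, params$sd_u1), corr_matrix_2l(params))
    rows <- lapply(seq_len(n_persons), function(i) {
      set.seed(derive_seed(seed, i))
      person_effects_2l(params, S)
    })
  } else if (inherits(params, "ar3_params")) {
    S <- cov_sqrt(c(params$sd_u00, params$sd_u01, params$sd_u10),
                  corr_matrix_3l(params))
    rows <- lapply(seq_len(n_persons), function(i) {
      set.seed(derive_seed(seed, i))
      person_effects_3l(params, S)
    })
  } else {
    stop("params must be ar2_params or ar3_params", call. = FALSE)
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# Stationary AR(1) deviations for the days of one person, as an
# (n_beeps x n_days) matrix: first beep from the stationary distribution,
# later beeps by the AR recursion; each day independent (night restart).
day_series_devs <- function(n_days, n_beeps, phi, sd_e) {
  sd_stat <- if (abs(phi) < 1) sd_e / sqrt(1 - phi^2) else sd_e
  dev <- matrix(0, n_beeps, n_days)
  dev[1, ] <- stats::rnorm(n_days, 0, sd_stat)
  if (n_beeps > 1) {
    innov <- matrix(stats::rnorm(n_days * (n_beeps - 1), 0, sd_e),
                    n_beeps - 1, n_days, byrow = TRUE)
    for (b in 2:n_beeps) dev[b, ] <- phi * dev[b - 1, ] + innov[b - 1, ]
  }
  dev
}

panel_skeleton <- function(design) {
  data.frame(
    Person = rep(seq_len(design$n_persons),
                 each = design$n_days * design$n_beeps),
    Day = rep(rep(seq_len(design$n_days), each = design$n_beeps),
              times = design$n_persons),
    Beep = rep(seq_len(design$n_beeps),
               times = design$n_persons * design$n_days))
}

apply_mcar <- function(y, design, seed, p_missing) {
  if (p_missing <= 0) return(y)
  set.seed(derive_seed(seed, 0, 777))
  y[stats::runif(length(y)) < p_missing] <- NA
  y
}

#' Simulate from the two-level AR(1) process
#'
#' Generates a complete balanced panel in which each person's days are
#' independent stationary AR(1) series around the person's trait level: the
#' first beep of a day is drawn from the within-day stationary distribution
#' and there is no carry-over across nights.
#'
#' @param params an `ar2_params` object.
#' @param design a `study_design`.
#' @param seed integer root seed; person `i` uses a substream derived from
#'   `(seed, i)`, so earlier persons are unchanged when `n_persons` grows.
#' @param outcome name for the outcome column.
#' @param p_missing optional MCAR missingness rate applied to the outcome
#'   (default 0: complete data).
#' @return An `esm_panel`.
#' @export
simulate_ar2 <- function(params, design, seed = 1L, outcome = "y",
                         p_missing = 0) {
  stopifnot(inherits(params, "ar2_params"), inherits(design, "study_design"))
  S <- cov_sqrt(c(params$sd_u0, params$sd_u1), corr_matrix_2l(params))
  y <- unlist(lapply(seq_len(design$n_persons), function(i) {
    set.seed(derive_seed(seed, i))
    eff <- person_effects_2l(params, S)
    dev <- day_series_devs(design$n_days, design$n_beeps, eff$phi,
                           params$sd_e)
    eff$mu + as.numeric(dev)
  }), use.names = FALSE)
  y <- apply_mcar(y, design, seed, p_missing)
  df <- panel_skeleton(design)
  df[[outcome]] <- y
  as_esm_panel(df, outcome = outcome)
}

#' Simulate from the three-level AR(1) process
#'
#' Day means follow a stationary AR(1) across days within each person (first
#' day from its stationary distribution); conditional on its day mean, each
#' day's beep series is an independent stationary AR(1) with the person's
#' beep-level inertia, restarting each morning. With `sd_r = 0`,
#' `gamma010 = 0` and `sd_u01 = 0` the process reduces distributionally to
#' the two-level AR(1) process with matched parameters.
#'
#' @param params an `ar3_params` object.
#' @inheritParams simulate_ar2
#' @return An `esm_panel`.
#' @export
simulate_ar3 <- function(params, design, seed = 1L, outcome = "y",
                         p_missing = 0) {
  stopifnot(inherits(params, "ar3_params"), inherits(design, "study_design"))
  S <- cov_sqrt(c(params$sd_u00, params$sd_u01, params$sd_u10),
                corr_matrix_3l(params))
  y <- unlist(lapply(seq_len(design$n_persons), function(i) {
    set.seed(derive_seed(seed, i))
    eff <- person_effects_3l(params, S)
    sd_rstat <- if (abs(eff$beta) < 1) {
      params$sd_r / sqrt(1 - eff$beta^2)
    } else params$sd_r
    m <- numeric(design$n_days)
    m[1] <- stats::rnorm(1, 0, sd_rstat)
    if (design$n_days > 1) {
      r0 <- stats::rnorm(design$n_days - 1, 0, params$sd_r)
      for (d in 2:design$n_days) m[d] <- eff$beta * m[d - 1] + r0[d - 1]
    }
    dev <- day_series_devs(design$n_days, design$n_beeps, eff$zeta,
                           params$sd_e)
    as.numeric(sweep(dev, 2, eff$mu + m, "+"))
  }), use.names = FALSE)
  y <- apply_mcar(y, design, seed, p_missing)
  df <- panel_skeleton(design)
  df[[outcome]] <- y
  as_esm_panel(df, outcome = outcome)
}

#' Simulate from the empty three-level process
#'
#' Convenience wrapper over [simulate_ar3()] with all inertias and inertia
#' variances forced to zero: person effects, i.i.d. day effects and i.i.d.
#' beep noise only.
#'
#' @param params an `ar3_params` object; its `gamma010`, `gamma100`,
#'   `sd_u01` and `sd_u10` are ignored (treated as 0).
#' @inheritParams simulate_ar2
#' @return An `esm_panel`.
#' @export
simulate_empty3 <- function(params, design, seed = 1L, outcome = "y",
                            p_missing = 0) {
  stopifnot(inherits(params, "ar3_params"))
  p0 <- ar3_params(gamma000 = params$gamma000, gamma010 = 0, gamma100 = 0,
                   sd_u00 = params$sd_u00, sd_u01 = 0, sd_u10 = 0,
                   sd_r = params$sd_r, sd_e = params$sd_e)
  simulate_ar3(p0, design, seed = seed, outcome = outcome,
               p_missing = p_missing)
}
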