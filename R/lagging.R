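#' Within-day lag of a row-aligned column
#'
#' Shifts a column down by one row inside each (person, day) block. The
#' first beep of every day receives `NA` — the night interrupts the process,
#' so a morning value is never regressed on the previous evening — and any
#' row whose predecessor is `NA` stays `NA`.
#'
#' @param x numeric vector, row-aligned with `panel`.
#' @param panel the `esm_panel` defining the person/day blocks.
#' @return The lagged column.
#' @export
within_day_lag <- function(x, panel) {
  if (length(x) != nrow(panel)) {
    stop("column length does not match panel rows", call. = FALSE)
  }
  n <- length(x)
  if (n == 0) return(x)
  out <- c(NA, x[-n])
  out[first_of_day(panel)] <- NA
  out
}

#' Empirical-Bayes beep residuals from the empty two-level fit
#'
#' Computes `e.bi = y - (gamma00_hat + u0i_hat)`: the deviation of each
#' observation from the person's empirical-Bayes (BLUP) trait level. `NA`
#' where the outcome is missing.
#'
#' @param panel an `esm_panel`.
#' @param fit an `esmar_fit` of family `empty2` on this panel.
#' @return Numeric vector of residuals, row-aligned with `panel`.
#' @export
eb_residuals_2l <- function(panel, fit) {
  stopifnot(inherits(fit, "esmar_fit"), fit$spec$family == "empty2")
  u0 <- fit$eb_person[, "(Intercept)"]
  names(u0) <- rownames(fit$eb_person)
  mu <- fit$estimates[["(Intercept)"]] + unname(u0[as.character(panel$Person)])
  panel[[outcome_name(panel)]] - mu
}

#' Empirical-Bayes day deviations from the empty three-level fit
#'
#' Extracts the BLUP day-level deviation `r0di_hat` of each (person, day)
#' and broadcasts it to every row of that day's block. Days with no
#' observed outcome at all get `NA`.
#'
#' @param panel an `esm_panel`.
#' @param fit an `esmar_fit` of family `empty3` on this panel.
#' @return Numeric vector, row-aligned with `panel`, constant within days.
#' @export
day_residuals_3l <- function(panel, fit) {
  stopifnot(inherits(fit, "esmar_fit"), fit$spec$family == "empty3")
  eb <- fit$eb_day
  key <- paste(eb$Person, eb$Day)
  val <- eb$effect
  names(val) <- key
  unname(val[paste(panel$Person, panel$Day)])
}

#' Previous-day value of a day-constant column, within persons
#'
#' Assigns to every row of day `d` the (day-constant) value of day `d - 1`
#' of the same person: `NA` on each person's first day, and `NA` whenever
#' the entire previous day is unobserved (or absent from the panel).
#' Persons are never mixed.
#'
#' @param x numeric vector, row-aligned with `panel` and constant within
#'   (person, day) blocks (e.g. the broadcast `r.0di`).
#' @param panel the `esm_panel`.
#' @return The day-lagged column, row-aligned with `panel`.
#' @export
person_day_lag <- function(x, panel) {
  if (length(x) != nrow(panel)) {
    stop("column length does not match panel rows", call. = FALSE)
  }
  if (nrow(panel) == 0) return(x)
  fd <- first_of_day(panel)
  pd_person <- panel$Person[fd]
  pd_day <- panel$Day[fd]
  pd_val <- x[fd]
  names(pd_val) <- paste(pd_person, pd_day)
  prev <- unname(pd_val[paste(panel$Person, panel$Day - 1L)])
  first_day <- stats::ave(panel$Day, panel$Person, FUN = min)
  prev[panel$Day == first_day] <- NA
  prev
}

#' Build the centered lagged predictors for the AR models
#'
#' Fits the empty two-level and empty three-level models to all observed
#' cases and derives the six working columns of the AR workflow:
#' \describe{
#'   \item{e.bi}{deviation from the EB trait level (empty two-level fit).}
#'   \item{lev1pred}{within-day lag of `e.bi` — the trait-centered lagged
#'     predictor of the two-level AR(1) model.}
#'   \item{e.bdi}{deviation from the EB day mean (empty three-level fit).}
#'   \item{lev1predfor3l}{within-day lag of `e.bdi` — the day-centered
#'     lagged predictor of the three-level AR(1) model.}
#'   \item{r.0di}{EB day deviation, broadcast to all rows of its day.}
#'   \item{lev2pred}{previous day's `r.0di` — the lagged centered day-mean
#'     predictor.}
#' }
#' The empty models are always fitted on all observed cases, even when the
#' AR models are later fitted on the smaller common subset, so that the
#' centering uses all available information. `center = "sample"` replaces
#' the EB quantities by raw person/day sample means (sensitivity option).
#'
#' If the day-level structure is inestimable (e.g. a single person-day), the
#' three-level columns are `NA` and the result carries
#' `attr(, "degenerate") = TRUE`.
#'
#' @param panel an `esm_panel` with at least two beeps on some day.
#' @param center `"eb"` (default) or `"sample"`.
#' @return An `esm_lagged` data.frame: the panel plus the six columns; the
#'   empty fits are attached as `attr(, "empty_fits")`.
#' @export
build_predictors <- function(panel, center = c("eb", "sample")) {
  stopifnot(inherits(panel, "esm_panel"))
  center <- match.arg(center)
  oc <- outcome_name(panel)
  y <- panel[[oc]]
  out <- as.data.frame(panel)
  fits <- list()
  degenerate <- FALSE
  # the day level is only identified if someone has at least two days
  multi_day <- any(tapply(panel$Day, panel$Person,
                          function(d) length(unique(d))) > 1)
  if (center == "eb") {
    fit2 <- mlm_fit(model_spec("empty2"), panel)
    fits$empty2 <- fit2
    out$e.bi <- eb_residuals_2l(panel, fit2)
    fit3 <- if (!multi_day) NULL else {
      tryCatch(mlm_fit(model_spec("empty3"), panel),
               error = function(e) NULL)
    }
    if (is.null(fit3)) {
      warning("empty three-level model inestimable; ",
              "three-level predictors set to NA", call. = FALSE)
      degenerate <- TRUE
      out$r.0di <- rep(NA_real_, nrow(out))
      out$e.bdi <- rep(NA_real_, nrow(out))
    } else {
      fits$empty3 <- fit3
      r0 <- day_residuals_3l(panel, fit3)
      u00 <- fit3$eb_person[, "(Intercept)"]
      names(u00) <- rownames(fit3$eb_person)
      mu_di <- fit3$estimates[["(Intercept)"]] +
        unname(u00[as.character(panel$Person)]) + r0
      out$r.0di <- r0
      out$e.bdi <- y - mu_di
    }
  } else {
    pmean <- stats::ave(y, panel$Person,
                        FUN = function(v) mean(v, na.rm = TRUE))
    dmean <- stats::ave(y, panel$Person, panel$Day,
                        FUN = function(v) mean(v, na.rm = TRUE))
    dmean[is.nan(dmean)] <- NA
    out$e.bi <- y - pmean
    out$r.0di <- dmean - pmean
    out$e.bdi <- y - dmean
  }
  out$lev1pred <- within_day_lag(out$e.bi, panel)
  out$lev1predfor3l <- within_day_lag(out$e.bdi, panel)
  out$lev2pred <- person_day_lag(out$r.0di, panel)
  out <- out[, c("Person", "Day", "Beep", oc, "e.bi", "lev1pred",
                 "e.bdi", "lev1predfor3l", "r.0di", "lev2pred")]
  structure(out, outcome = oc, empty_fits = fits, degenerate = degenerate,
            class = c("esm_lagged", "esm_panel", "data.frame"))
}

#' @export
print.esm_lagged <- function(x, ...) {
  cat(sprintf(
    "ESM panel with lagged predictors: %d rows, %d usable for 3-level AR\n",
    nrow(x), sum(stats::complete.cases(
      x[, c(outcome_name(x), "lev1pred", "lev1predfor3l", "lev2pred")]))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
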