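#' Common case subset for model comparison
#'
#' AIC/BIC comparisons are only valid when every model is fitted to the
#' same cases, so all AR models are fitted on the rows usable by the most
#' demanding model, the three-level AR(1): observed outcome and present
#' `lev1pred`, `lev1predfor3l` and `lev2pred`.
#'
#' @param lf an `esm_lagged` frame from [build_predictors()].
#' @return Logical row mask.
#' @export
common_subset <- function(lf) {
  stopifnot(inherits(lf, "esm_lagged"))
  mask <- !is.na(lf[[outcome_name(lf)]]) & !is.na(lf$lev1pred) &
    !is.na(lf$lev1predfor3l) & !is.na(lf$lev2pred)
  if (!any(mask)) {
    stop("common case subset is empty: the design is too small for the ",
         "three-level AR model (need >= 2 days and >= 2 beeps/day)",
         call. = FALSE)
  }
  mask
}

# The AR model set compared during level selection: the two-level AR(1)
# against the three three-level AR(1) variants, all with uncorrelated
# random effects so the complexity gap between the families stays small.
selection_model_set <- function() {
  list(ar2 = model_spec("ar2", correlated = FALSE),
       ar3_nobeta = model_spec("ar3_nobeta"),
       ar3_fixedbeta = model_spec("ar3_fixedbeta"),
       ar3_randombeta = model_spec("ar3_randombeta", correlated = FALSE))
}

is_three_level_family <- function(family) {
  family %in% c("empty3", "ar3_nobeta", "ar3_fixedbeta", "ar3_randombeta",
                "ar3_fixedonly")
}

#' Select the number of levels by information criteria
#'
#' The recommended procedure for deciding whether intensive longitudinal
#' data need a day level: build the centered lagged predictors from empty
#' models fitted to all observed cases, restrict to the common case subset,
#' fit the two-level AR(1) model and the three three-level AR(1) variants
#' (all with uncorrelated random effects), and pick the family minimizing
#' the criterion. Three levels are chosen iff a three-level family wins;
#' exact ties are broken toward fewer levels. Empty models never enter the
#' comparison — testing the day-level variance directly is unreliable in
#' the presence of autocorrelation.
#'
#' @param panel an `esm_panel` (or an `esm_lagged`, in which case the
#'   predictors are reused).
#' @param criterion `"aic"` (recommended) or `"bic"`.
#' @param model_set optional named list of `esmar_spec` objects to compare.
#' @param return_fits keep the fitted models in the result.
#' @return An `esmar_selection`: per-model table, criterion,
#'   `chosen_family`, `chosen_levels` (2 or 3).
#' @export
select_levels <- function(panel, criterion = c("aic", "bic"),
                          model_set = NULL, return_fits = TRUE) {
  criterion <- match.arg(criterion)
  lf <- if (inherits(panel, "esm_lagged")) panel else build_predictors(panel)
  mask <- common_subset(lf)
  if (is.null(model_set)) model_set <- selection_model_set()
  fm <- fit_model_set(lf, mask, model_set)
  chosen <- choose_by_criterion(fm$fits, fm$usable, criterion)
  res <- list(table = model_set_table(fm$fits),
              criterion = criterion, chosen_family = chosen,
              chosen_levels = if (is_three_level_family(chosen)) 3L else 2L,
              dropped = fm$dropped,
              fits = if (return_fits) fm$fits else NULL)
  class(res) <- "esmar_selection"
  res
}

# Fit every model of the set on the masked rows; non-converged or failed
# fits are excluded from the comparison (with a warning) but kept in the
# table when available.
fit_model_set <- function(lf, mask, model_set) {
  fits <- list()
  dropped <- character(0)
  for (nm in names(model_set)) {
    f <- tryCatch(mlm_fit(model_set[[nm]], lf, rows = mask),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      dropped <- c(dropped, nm)
      if (!is.null(f)) fits[[nm]] <- f
    } else {
      fits[[nm]] <- f
    }
  }
  usable <- setdiff(names(fits), dropped)
  if (length(usable) == 0) {
    stop("no AR model converged; cannot select the number of levels",
         call. = FALSE)
  }
  if (length(dropped) > 0) {
    warning("dropped from comparison (no convergence): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  n_obs <- unique(vapply(fits, function(f) f$n_obs, numeric(1)))
  stopifnot(length(n_obs) == 1)
  list(fits = fits, usable = usable, dropped = dropped)
}

choose_by_criterion <- function(fits, usable, criterion) {
  crit <- vapply(usable, function(nm) fits[[nm]][[criterion]], numeric(1))
  tied <- usable[crit <= min(crit)]
  two_level <- tied[!is_three_level_family(tied)]
  if (length(two_level) > 0) two_level[1] else tied[1]
}

model_set_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(family = nm, levels = if (is_three_level_family(nm)) 3L
               else 2L, n_obs = f$n_obs, loglik = f$loglik,
               k = f$k_params, aic = f$aic, bic = f$bic,
               converged = f$converged)
  }))
}

#' @export
print.esmar_selection <- function(x, ...) {
  cat(sprintf("Level selection by %s: chose '%s' (%d levels)\n",
              toupper(x$criterion), x$chosen_family, x$chosen_levels))
  tab <- x$table
  tab$loglik <- round(tab$loglik, 1)
  tab$aic <- round(tab$aic, 1)
  tab$bic <- round(tab$bic, 1)
  print(tab, row.names = FALSE)
  if (length(x$dropped) > 0) {
    cat("dropped (non-convergence):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Full level-selection workflow on a panel or CSV file
#'
#' Convenience wrapper running the recommended path end to end: read the
#' panel (if given a path), build EB-centered lagged predictors on all
#' observed cases, compare the AR model set on the common subset, and
#' return the criterion table together with the chosen model's full fit.
#'
#' @param panel an `esm_panel`, `esm_lagged`, or a path to a panel CSV.
#' @param outcome outcome column name (used when reading from file).
#' @param criterion `"aic"` or `"bic"`.
#' @return An `esmar_report`: the selection object, the chosen fit, and the
#'   usable-case counts of the panel.
#' @export
empirical_workflow <- function(panel, outcome = "y",
                               criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (is.character(panel)) panel <- read_panel(panel, outcome = outcome)
  sel <- select_levels(panel, criterion = criterion, return_fits = TRUE)
  res <- list(selection = sel, chosen_fit = sel$fits[[sel$chosen_family]],
              case_counts = usable_case_counts(
                if (inherits(panel, "esm_lagged")) {
                  as_esm_panel(as.data.frame(panel)[
                    c("Person", "Day", "Beep", outcome_name(panel))],
                    outcome_name(panel))
                } else panel))
  class(res) <- "esmar_report"
  res
}

#' @export
print.esmar_report <- function(x, ...) {
  print(x$selection)
  cat("\nUsable cases:", paste(names(x$case_counts), x$case_counts,
                               sep = " = ", collapse = ", "), "\n")
  cat("\nChosen model:\n")
  print(x$chosen_fit)
  invisible(x)
}
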