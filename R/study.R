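#' Configuration of the Monte-Carlo selection study
#'
#' @param n_persons,n_days,n_beeps vectors of sample sizes defining the
#'   design grid (defaults: the full 48-cell grid of the power study).
#' @param params_2l,params_3l generating parameters for the two-level and
#'   three-level AR(1) processes.
#' @param reps replicates per cell; presets: 1000 matches the original
#'   study, 200 is a desk-scale run.
#' @param criteria information criteria to evaluate.
#' @param seed root seed; every (cell, kind, replicate) uses a derived
#'   substream, so results do not depend on evaluation order.
#' @return An `esmar_study_config` list.
#' @export
study_config <- function(n_persons = c(30, 60, 90),
                         n_days = c(5, 7, 10, 14),
                         n_beeps = c(5, 7, 9, 11),
                         params_2l = sim_params_2l(),
                         params_3l = sim_params_3l(),
                         reps = 200, criteria = c("aic", "bic"),
                         seed = 1L) {
  stopifnot(reps >= 1)
  grid <- expand.grid(np = n_persons, nd = n_days, nb = n_beeps)
  structure(list(grid = grid, params_2l = params_2l, params_3l = params_3l,
                 reps = as.integer(reps),
                 criteria = match.arg(criteria, several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "esmar_study_config")
}

#' Run one cell of the selection study
#'
#' For each replicate: simulate a complete panel from the stated process,
#' build EB-centered lagged predictors on the full data, fit the four
#' uncorrelated AR models on the common case subset, and record whether a
#' three-level family attains the lowest criterion value. For a three-level
#' generating process the reported proportion is the power to detect the
#' day level; for a two-level process it is the Type I error rate.
#'
#' @param design a `study_design`.
#' @param dgp_params `ar2_params` or `ar3_params` matching `dgp_kind`.
#' @param dgp_kind `"two_level"` or `"three_level"`.
#' @param reps number of replicates.
#' @param criteria criteria to evaluate (`"aic"`, `"bic"`).
#' @param seed root seed for this cell.
#' @return A list with per-criterion `prop` (selecting three levels), `se`
#'   (binomial), `reps` (effective replicates) and `failures`.
#' @export
run_cell <- function(design, dgp_params, dgp_kind = c("two_level",
                                                      "three_level"),
                     reps = 200, criteria = c("aic", "bic"), seed = 1L) {
  dgp_kind <- match.arg(dgp_kind)
  criteria <- match.arg(criteria, several.ok = TRUE)
  chose3 <- matrix(NA, reps, length(criteria),
                   dimnames = list(NULL, criteria))
  failures <- 0L
  for (r in seq_len(reps)) {
    rep_seed <- derive_seed(seed, 1009, r)
    panel <- if (dgp_kind == "two_level") {
      simulate_ar2(dgp_params, design, seed = rep_seed)
    } else {
      simulate_ar3(dgp_params, design, seed = rep_seed)
    }
    res <- tryCatch(suppressWarnings({
      lf <- build_predictors(panel)
      fm <- fit_model_set(lf, common_subset(lf), selection_model_set())
      ch <- vapply(criteria, function(cr) {
        is_three_level_family(choose_by_criterion(fm$fits, fm$usable, cr))
      }, logical(1))
      list(ch = ch, dropped = length(fm$dropped) > 0)
    }), error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
    } else {
      chose3[r, ] <- res$ch
      if (res$dropped) failures <- failures + 1L
    }
  }
  eff <- colSums(!is.na(chose3))
  prop <- colMeans(chose3, na.rm = TRUE)
  list(prop = prop, se = sqrt(prop * (1 - prop) / pmax(eff, 1)),
       reps = eff, failures = failures)
}

#' Run the full study grid
#'
#' Maps [run_cell()] over every design cell for both generating processes,
#' using deterministic per-cell substreams of the root seed.
#'
#' @param config an `esmar_study_config`.
#' @return An `esmar_study` data.frame: one row per (cell, process,
#'   criterion) with the proportion selecting three levels, its binomial
#'   SE, effective replicates and failure count.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "esmar_study_config"))
  rows <- list()
  for (ci in seq_len(nrow(config$grid))) {
    g <- config$grid[ci, ]
    design <- study_design(g$np, g$nd, g$nb)
    for (kind in c("three_level", "two_level")) {
      params <- if (kind == "two_level") config$params_2l else
        config$params_3l
      cell_seed <- derive_seed(config$seed, g$np, g$nd, g$nb,
                               if (kind == "two_level") 2 else 3)
      cell <- run_cell(design, params, dgp_kind = kind,
                       reps = config$reps, criteria = config$criteria,
                       seed = cell_seed)
      for (cr in config$criteria) {
        rows[[length(rows) + 1]] <- data.frame(
          np = g$np, nd = g$nd, nb = g$nb, dgp = kind, criterion = cr,
          prop = cell$prop[[cr]], se = cell$se[[cr]],
          reps = cell$reps[[cr]], failures = cell$failures)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("esmar_study", "data.frame")
  out
}

#' @export
print.esmar_study <- function(x, ...) {
  cat("Monte-Carlo level-selection study",
      sprintf("(%d rows; power = three_level rows, Type I = two_level)\n",
              nrow(x)))
  print.data.frame(transform(as.data.frame(x), prop = round(prop, 3),
                             se = round(se, 3)), row.names = FALSE)
  invisible(x)
}

#' Demonstrate the misspecification artifacts
#'
#' Regenerates one of the demonstration datasets A-E (see
#' [artifact_params()]) and fits the cross-specified models that produce
#' the headline artifacts: the two-level AR(1) model (with correlated
#' random effects) fitted to three-level data inflates the beep-level
#' inertia; the empty three-level model fitted to two-level AR data shows
#' spurious day-level variance; the three-level AR(1) model deflates the
#' beep inertia and shows a small spurious negative day inertia.
#' The demonstrations are single stochastic realizations, so estimates are
#' reported as mean and SD over `n_realizations` independent panels.
#'
#' @param case `"A"`, `"B"`, `"C"`, `"D"` or `"E"`.
#' @param n_realizations number of independent panels (default 5).
#' @param seed root seed.
#' @param design the panel design (default 90 persons x 21 days x 10
#'   beeps).
#' @return An `esmar_demo` list: per-realization estimates, their
#'   mean/SD summary, and closed-form reference values where available.
#' @export
artifact_demo <- function(case = c("A", "B", "C", "D", "E"),
                          n_realizations = 5, seed = 1L,
                          design = artifact_design()) {
  case <- match.arg(case)
  params <- artifact_params(case)
  per_real <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    rseed <- derive_seed(seed, match(case, LETTERS), r)
    panel <- if (case == "E") {
      simulate_ar2(params, design, seed = rseed)
    } else if (case %in% c("A", "D")) {
      simulate_empty3(params, design, seed = rseed)
    } else {
      simulate_ar3(params, design, seed = rseed)
    }
    lf <- build_predictors(panel)
    est <- list()
    ar2 <- mlm_fit(model_spec("ar2", correlated = TRUE), lf)
    est$ar2_inertia <- ar2$estimates[["lev1pred"]]
    est$ar2_sd_inertia <- ar2$sd_person[["lev1pred"]]
    if (case %in% c("A", "E")) {
      e3 <- attr(lf, "empty_fits")$empty3
      est$empty3_sd_day <- e3$sd_day
      # three-level AR form used after dropping non-significant random
      # inertia effects: both dropped for three-level-null data (A),
      # only the day slope dropped for two-level AR data (E)
      spec3 <- if (case == "A") model_spec("ar3_fixedonly") else
        model_spec("ar3_fixedbeta")
      f3 <- mlm_fit(spec3, lf)
      est$ar3_beep_inertia <- f3$estimates[["lev1predfor3l"]]
      est$ar3_day_inertia <- f3$estimates[["lev2pred"]]
      est$ar3_day_inertia_p <- wald(f3, "lev2pred")$p
    }
    per_real[[r]] <- as.data.frame(est)
  }
  vals <- do.call(rbind, per_real)
  summary <- data.frame(mean = colMeans(vals),
                        sd = apply(vals, 2, stats::sd))
  # for zero-inertia day-effect-plus-noise data the pooled lag-1
  # autocorrelation around the trait level is sd_r^2 / (sd_r^2 + sd_e^2)
  reference <- switch(case,
    A = c(ar2_inertia_closed_form =
            params$sd_r^2 / (params$sd_r^2 + params$sd_e^2)),
    D = c(ar2_inertia_closed_form =
            params$sd_r^2 / (params$sd_r^2 + params$sd_e^2)),
    NULL)
  structure(list(case = case, params = params, values = vals,
                 summary = summary, reference = reference),
            class = "esmar_demo")
}

#' @export
print.esmar_demo <- function(x, ...) {
  cat(sprintf("Misspecification demo, dataset %s (%d realizations)\n",
              x$case, nrow(x$values)))
  print(round(x$summary, 4))
  if (!is.null(x$reference)) {
    cat("closed-form reference:\n")
    print(round(x$reference, 4))
  }
  invisible(x)
}
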