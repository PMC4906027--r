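#' Long-format ESM panel
#'
#' An `esm_panel` is a data.frame in long format with one row per scheduled
#' measurement occasion, columns `Person`, `Day`, `Beep` (positive integers)
#' and one numeric outcome column. Rows are kept sorted by person, then day
#' within person, then beep within day; missing outcomes are coded `NA` in
#' place, never by dropping the row (except that a wholly unobserved
#' person-day may be absent altogether, in which case it is treated as a day
#' with all beeps missing for day-level lagging).
#'
#' @param person,day,beep positive integer indices of equal length.
#' @param y numeric outcome values (`NA` allowed).
#' @param outcome name of the outcome column, default `"y"`.
#' @return An `esm_panel` data.frame sorted by (Person, Day, Beep).
#' @examples
#' p <- esm_panel(person = c(1, 1, 1), day = c(1, 1, 1), beep = 1:3,
#'                y = c(5, NA, 7))
#' usable_case_counts(p)
#' @export
esm_panel <- function(person, day, beep, y, outcome = "y") {
  df <- data.frame(Person = as.integer(person), Day = as.integer(day),
                   Beep = as.integer(beep), y = as.numeric(y))
  names(df)[4] <- outcome
  as_esm_panel(df, outcome = outcome)
}

#' Coerce a data.frame to an ESM panel
#'
#' Validates the required columns, repairs ordering by a stable sort, and
#' checks the panel invariants (unique person/day/beep triples, positive
#' integer indices).
#'
#' @param df a data.frame with columns `Person`, `Day`, `Beep` and `outcome`.
#' @param outcome name of the outcome column.
#' @return An `esm_panel`.
#' @export
as_esm_panel <- function(df, outcome = "y") {
  required <- c("Person", "Day", "Beep", outcome)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, required, drop = FALSE]
  for (col in c("Person", "Day", "Beep")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != as.integer(v)) || any(v < 1)) {
      stop("panel format error: column ", col,
           " must contain positive integers", call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  if (!is.numeric(df[[outcome]])) {
    stop("panel format error: outcome column ", outcome,
         " must be numeric", call. = FALSE)
  }
  ord <- order(df$Person, df$Day, df$Beep)  # stable repair of row order
  df <- df[ord, , drop = FALSE]
  if (anyDuplicated(df[, c("Person", "Day", "Beep")]) > 0) {
    stop("panel integrity error: duplicate (Person, Day, Beep) triples",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, outcome = outcome, class = c("esm_panel", "data.frame"))
}

#' @export
print.esm_panel <- function(x, ...) {
  oc <- outcome_name(x)
  n_obs <- sum(!is.na(x[[oc]]))
  cat(sprintf("ESM panel: %d rows (%d observed), %d persons, outcome '%s'\n",
              nrow(x), n_obs, length(unique(x$Person)), oc))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Outcome column name of a panel
#' @param panel an `esm_panel` or `esm_lagged` object.
#' @return The outcome column name.
#' @export
outcome_name <- function(panel) {
  oc <- attr(panel, "outcome")
  if (is.null(oc)) "y" else oc
}

#' Balanced study design
#'
#' A balanced simulation design: every person has `n_days` days with
#' `n_beeps` scheduled beeps each. Fitting the three-level AR model
#' meaningfully requires at least 2 days and 2 beeps per day.
#'
#' @param n_persons,n_days,n_beeps positive integer counts.
#' @return A `study_design` list.
#' @export
study_design <- function(n_persons, n_days, n_beeps) {
  for (v in c(n_persons, n_days, n_beeps)) {
    if (length(v) != 1 || is.na(v) || v < 1 || v != as.integer(v)) {
      stop("study design counts must be single positive integers",
           call. = FALSE)
    }
  }
  structure(list(n_persons = as.integer(n_persons),
                 n_days = as.integer(n_days),
                 n_beeps = as.integer(n_beeps)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study design: %d persons x %d days x %d beeps/day\n",
              x$n_persons, x$n_days, x$n_beeps))
  invisible(x)
}

#' Read an ESM panel from CSV
#'
#' Expects a comma-delimited file with a header `Person,Day,Beep,<outcome>`.
#' Missing outcomes are coded `NA` (empty cells are also accepted and treated
#' as missing). Out-of-order rows are repaired by a stable sort; duplicate
#' (Person, Day, Beep) triples are an error, as are non-numeric outcome
#' tokens other than the `NA` sentinel.
#'
#' @param path path to the CSV file.
#' @param outcome name of the outcome column to read.
#' @return An `esm_panel`.
#' @export
read_panel <- function(path, outcome = "y") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), check.names = FALSE)
  required <- c("Person", "Day", "Beep", outcome)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel format error: file lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(tok, col) {
    tok <- trimws(tok)
    out <- suppressWarnings(as.numeric(tok))
    bad <- is.na(out) & !(tok %in% c("NA", ""))
    if (any(bad)) {
      stop("panel parse error: non-numeric token '", tok[which(bad)[1]],
           "' in column ", col, call. = FALSE)
    }
    out
  }
  out <- data.frame(Person = parse_num(df$Person, "Person"),
                    Day = parse_num(df$Day, "Day"),
                    Beep = parse_num(df$Beep, "Beep"))
  out[[outcome]] <- parse_num(df[[outcome]], outcome)
  as_esm_panel(out, outcome = outcome)
}

#' Write an ESM panel to CSV
#'
#' Writes `Person,Day,Beep,<outcome>` with missing outcomes as the token
#' `NA`. Outcome values are printed with 17 significant digits so that
#' `read_panel(write_panel(p))` round-trips the panel exactly.
#'
#' @param panel an `esm_panel`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "esm_panel"))
  oc <- outcome_name(panel)
  yv <- panel[[oc]]
  ych <- ifelse(is.na(yv), "NA", sprintf("%.17g", yv))
  header <- paste(c("Person", "Day", "Beep", oc), collapse = ",")
  lines <- paste(panel$Person, panel$Day, panel$Beep, ych, sep = ",")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Usable case counts for the empty and AR models
#'
#' Counts the rows usable by each model family after listwise deletion:
#' `n_total` rows with an observed outcome (empty models), `n_ar2` rows whose
#' within-day lag-1 predecessor is also observed (two-level AR model), and
#' `n_ar3` rows of `n_ar2` that additionally lie on a day whose previous day
#' exists for that person with at least one observed beep (three-level AR
#' model, where the lagged day-mean predictor must be defined). On a complete
#' balanced panel `n_total - n_ar2 = Np * Nd` and
#' `n_ar3 = Np * (Nd - 1) * (Nb - 1)`.
#'
#' @param panel an `esm_panel`.
#' @return Named integer vector `c(n_total, n_ar2, n_ar3)`.
#' @export
usable_case_counts <- function(panel) {
  stopifnot(inherits(panel, "esm_panel"))
  y <- panel[[outcome_name(panel)]]
  obs <- !is.na(y)
  lag_ok <- obs & c(FALSE, obs[-length(obs)]) & !first_of_day(panel)
  # day-level predictor defined: previous day label d-1 present with >= 1
  # observed beep for the same person
  pd <- unique(panel[, c("Person", "Day")])
  day_obs <- tapply(obs, list(panel$Person, panel$Day),
                    any, default = FALSE)
  has_prev <- vapply(seq_len(nrow(pd)), function(i) {
    dd <- as.character(pd$Day[i] - 1L)
    pp <- as.character(pd$Person[i])
    dd %in% colnames(day_obs) && isTRUE(day_obs[pp, dd])
  }, logical(1))
  names(has_prev) <- paste(pd$Person, pd$Day)
  row_prev <- has_prev[paste(panel$Person, panel$Day)]
  c(n_total = sum(obs), n_ar2 = sum(lag_ok),
    n_ar3 = sum(lag_ok & row_prev))
}

# TRUE on the first row of each (Person, Day) block
first_of_day <- function(panel) {
  n <- nrow(panel)
  if (n == 0) return(logical(0))
  c(TRUE, panel$Person[-1] != panel$Person[-n] |
      panel$Day[-1] != panel$Day[-n])
}

# TRUE on the first row of each person block
first_of_person <- function(panel) {
  n <- nrow(panel)
  if (n == 0) return(logical(0))
  c(TRUE, panel$Person[-1] != panel$Person[-n])
}
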