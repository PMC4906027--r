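#' Specify a multilevel model family
#'
#' The model families used throughout the level-selection workflow. All are
#' Gaussian linear mixed models estimated by maximum likelihood:
#' \describe{
#'   \item{empty2}{intercept + random person intercept (k = 3).}
#'   \item{empty3}{adds a random day-within-person intercept (k = 4).}
#'   \item{ar2}{two-level AR(1): fixed + random-slope `lev1pred`
#'     (k = 5, +1 if `correlated`).}
#'   \item{ar3_nobeta}{three-level AR(1) without day inertia: fixed +
#'     random-slope `lev1predfor3l`, day intercept (k = 6).}
#'   \item{ar3_fixedbeta}{adds the fixed day-inertia term `lev2pred`
#'     (k = 7).}
#'   \item{ar3_randombeta}{adds a random person slope for `lev2pred`
#'     (k = 8, +3 if `correlated`).}
#'   \item{ar3_fixedonly}{three-level AR(1) with both fixed inertias but no
#'     random inertia slopes (k = 6); the form used in the misspecification
#'     demonstrations after dropping non-significant random inertias.}
#' }
#' Every family has exactly one person-intercept variance. `correlated`
#' controls whether the person-level random effects are allowed to
#' covary; it has no effect on the intercept-only families.
#'
#' @param family model family string.
#' @param correlated logical; correlate the person-level random effects.
#' @return An `esmar_spec` list with fields `family`, `fixed`, `ranef`,
#'   `day`, `correlated`.
#' @export
model_spec <- function(family = c("empty2", "empty3", "ar2", "ar3_nobeta",
                                  "ar3_fixedbeta", "ar3_randombeta",
                                  "ar3_fixedonly"),
                       correlated = FALSE) {
  family <- match.arg(family)
  def <- switch(family,
    empty2 = list(fixed = character(0), ranef = character(0), day = FALSE),
    empty3 = list(fixed = character(0), ranef = character(0), day = TRUE),
    ar2 = list(fixed = "lev1pred", ranef = "lev1pred", day = FALSE),
    ar3_nobeta = list(fixed = "lev1predfor3l", ranef = "lev1predfor3l",
                      day = TRUE),
    ar3_fixedbeta = list(fixed = c("lev2pred", "lev1predfor3l"),
                         ranef = "lev1predfor3l", day = TRUE),
    ar3_randombeta = list(fixed = c("lev2pred", "lev1predfor3l"),
                          ranef = c("lev2pred", "lev1predfor3l"),
                          day = TRUE),
    ar3_fixedonly = list(fixed = c("lev2pred", "lev1predfor3l"),
                         ranef = character(0), day = TRUE))
  structure(c(def, list(family = family,
                        correlated = isTRUE(correlated) &&
                          length(def$ranef) > 0)),
            class = "esmar_spec")
}

#' @export
print.esmar_spec <- function(x, ...) {
  cat(sprintf("model family '%s': fixed ~ 1%s; random person (%s)%s%s\n",
              x$family,
              if (length(x$fixed)) paste0(" + ",
                                          paste(x$fixed, collapse = " + "))
              else "",
              paste(c("1", x$ranef), collapse = ", "),
              if (x$day) " + day intercept" else "",
              if (x$correlated) ", correlated" else ""))
  invisible(x)
}

# ---- internal: data preparation -------------------------------------------

# Rows usable by a spec: observed outcome and all predictors present
spec_complete_rows <- function(spec, data) {
  oc <- outcome_name(data)
  ok <- !is.na(data[[oc]])
  for (v in union(spec$fixed, spec$ranef)) {
    if (!v %in% names(data)) {
      stop("data lacks predictor column '", v,
           "' required by family ", spec$family,
           " (run build_predictors() first)", call. = FALSE)
    }
    ok <- ok & !is.na(data[[v]])
  }
  ok
}

# Precompute per-person cross-products on the fitted rows.
prep_model_data <- function(spec, data, rows = NULL) {
  ok <- spec_complete_rows(spec, data)
  if (!is.null(rows)) ok <- ok & rows
  d <- data[ok, , drop = FALSE]
  n <- nrow(d)
  if (n == 0) stop("no usable cases for family ", spec$family,
                   call. = FALSE)
  oc <- outcome_name(data)
  X <- cbind(`(Intercept)` = rep(1, n))
  for (v in spec$fixed) X <- cbind(X, d[[v]])
  colnames(X) <- c("(Intercept)", spec$fixed)
  Z <- cbind(rep(1, n))
  for (v in spec$ranef) Z <- cbind(Z, d[[v]])
  colnames(Z) <- c("(Intercept)", spec$ranef)
  m <- cbind(X, y = d[[oc]])
  persons <- unique(d$Person)
  prep <- vector("list", length(persons))
  for (j in seq_along(persons)) {
    idx <- which(d$Person == persons[j])
    mi <- m[idx, , drop = FALSE]
    Zi <- Z[idx, , drop = FALSE]
    pp <- list(Czz = crossprod(Zi), Czm = crossprod(Zi, mi),
               Cmm = crossprod(mi))
    if (spec$day) {
      f <- factor(d$Day[idx])
      pp$ndv <- as.numeric(table(f))
      pp$Sdm <- rowsum(mi, f)
      pp$Sdz <- rowsum(Zi, f)
      pp$days <- as.integer(levels(f))
    }
    prep[[j]] <- pp
  }
  list(prep = prep, persons = persons, n = n,
       p = ncol(X), q = ncol(Z), xnames = colnames(X),
       znames = colnames(Z), rows = which(ok),
       row_key = paste(d$Person, d$Day, d$Beep))
}

# theta -> relative person Cholesky factor L (lower triangular)
theta_to_L <- function(theta, q, correlated) {
  L <- matrix(0, q, q)
  if (correlated) {
    L[lower.tri(L, diag = TRUE)] <- theta[seq_len(q * (q + 1) / 2)]
  } else {
    diag(L) <- theta[seq_len(q)]
  }
  L
}

n_theta_person <- function(q, correlated) {
  if (correlated) q * (q + 1) / 2 else q
}

# Profiled ML deviance and its ingredients at relative parameters theta
profiled_parts <- function(theta, pd, spec) {
  q <- pd$q
  ntp <- n_theta_person(q, spec$correlated)
  L <- theta_to_L(theta, q, spec$correlated)
  s <- if (spec$day) theta[ntp + 1] else 0
  parts <- esmar_lik_parts(pd$prep, L, s, spec$day)
  p <- pd$p
  midx <- p + 1
  Cxx <- parts$Cw[seq_len(p), seq_len(p), drop = FALSE]
  cxy <- parts$Cw[seq_len(p), midx]
  beta <- solve(Cxx, cxy)
  rss <- max(parts$Cw[midx, midx] - sum(cxy * beta), 1e-12)
  dev <- pd$n * log(2 * pi * rss / pd$n) + pd$n + parts$ld
  list(dev = dev, beta = as.numeric(beta), rss = rss, Cxx = Cxx,
       L = L, s = s, ld = parts$ld)
}

profiled_deviance <- function(theta, pd, spec) {
  tryCatch(profiled_parts(theta, pd, spec)$dev,
           error = function(e) 1e10)
}

# ---- fitting ---------------------------------------------------------------

#' Fit a multilevel AR model by maximum likelihood
#'
#' Maximizes the exact Gaussian marginal likelihood of the chosen family.
#' The fixed effects and residual variance are profiled out; the remaining
#' relative covariance parameters (person-level Cholesky factor and the
#' relative day-intercept SD) are optimized with bound constraints so that
#' variance estimates may sit on the zero boundary (such fits are flagged,
#' not rejected). Rows with a missing outcome or any missing predictor of
#' the family are removed listwise before fitting. Estimation is ML, not
#' REML, so log-likelihoods and information criteria are comparable across
#' families with different fixed effects.
#'
#' @param spec an `esmar_spec` from [model_spec()].
#' @param data an `esm_panel` (empty families) or `esm_lagged` (AR families).
#' @param rows optional logical mask selecting the candidate rows (e.g. the
#'   common case subset); listwise deletion is applied on top of it.
#' @param start optional numeric vector of starting values for the relative
#'   covariance parameters.
#' @return An `esmar_fit` object: fixed estimates and standard errors,
#'   variance components as SDs and correlations, `loglik`, `aic`, `bic`,
#'   `n_obs`, `k_params`, empirical-Bayes person (and day) effects,
#'   `converged` and `boundary` flags.
#' @examples
#' panel <- simulate_ar2(sim_params_2l(), study_design(10, 3, 5), seed = 1)
#' fit <- mlm_fit(model_spec("empty2"), panel)
#' fit$estimates
#' @export
mlm_fit <- function(spec, data, rows = NULL, start = NULL) {
  stopifnot(inherits(spec, "esmar_spec"))
  pd <- prep_model_data(spec, data, rows = rows)
  ntp <- n_theta_person(pd$q, spec$correlated)
  nth <- ntp + as.integer(spec$day)
  k <- pd$p + nth + 1
  if (pd$n <= k) stop("insufficient usable cases (", pd$n,
                      ") for family ", spec$family, call. = FALSE)
  lower <- rep(-Inf, nth)
  diag_pos <- if (spec$correlated) {
    cumsum(c(1, rev(seq_len(pd$q - 1) + 1)))[seq_len(pd$q)]
  } else seq_len(pd$q)
  # diagonal Cholesky entries and the day SD are scale parameters, bounded
  # at zero; off-diagonal entries are free
  bounded <- c(seq_len(ntp) %in% diag_pos, if (spec$day) TRUE)
  lower[bounded] <- 0
  if (is.null(start)) {
    start <- rep(0, nth)
    start[bounded] <- c(1, 0.1, 0.1)[pmin(seq_len(sum(bounded)), 3)]
    if (spec$day) start[nth] <- 0.4
    start[if (spec$correlated) diag_pos[1] else 1] <- 1
    if (spec$correlated && pd$q > 1) {
      # warm start from the (cheaper, better-conditioned) diagonal model
      diag_spec <- spec
      diag_spec$correlated <- FALSE
      dstart <- rep(0.1, pd$q + as.integer(spec$day))
      dstart[1] <- 1
      if (spec$day) dstart[length(dstart)] <- 0.4
      dfn <- function(th) profiled_deviance(th, pd, diag_spec)
      dob <- minqa::bobyqa(par = dstart, fn = dfn,
                           lower = rep(0, length(dstart)),
                           control = list(rhobeg = 0.25, rhoend = 1e-6,
                                          iprint = 0, maxfun = 5000))
      start[diag_pos] <- dob$par[seq_len(pd$q)]
      if (spec$day) start[nth] <- dob$par[pd$q + 1]
    }
  }
  fn <- function(th) profiled_deviance(th, pd, spec)
  if (nth == 1) {
    opt <- stats::optimize(fn, interval = c(0, 200), tol = 1e-9)
    theta <- opt$minimum
    converged <- TRUE
  } else {
    # bounded BOBYQA with deterministic restarts from the incumbent until
    # the deviance stops improving
    theta <- start
    best <- Inf
    converged <- FALSE
    rhobeg <- 0.25
    for (round in 1:4) {
      ob <- minqa::bobyqa(par = theta, fn = fn, lower = lower,
                          control = list(rhobeg = rhobeg, rhoend = 1e-8,
                                         iprint = 0, maxfun = 10000))
      improved <- best - ob$fval
      if (ob$fval <= best) {
        best <- ob$fval
        theta <- ob$par
        converged <- ob$ierr == 0
      }
      if (round > 1 && improved < 1e-6) break
      rhobeg <- rhobeg / 5
    }
  }
  at <- profiled_parts(theta, pd, spec)
  sigma2 <- at$rss / pd$n
  loglik <- -at$dev / 2
  beta <- at$beta
  names(beta) <- pd$xnames
  se <- sqrt(pmax(diag(solve(at$Cxx)) * sigma2, 0))
  names(se) <- pd$xnames
  G <- tcrossprod(at$L) * sigma2
  sds <- sqrt(diag(G))
  names(sds) <- pd$znames
  corr <- diag(1, pd$q)
  pos <- sds > 0
  if (sum(pos) > 1) {
    corr[pos, pos] <- stats::cov2cor(G[pos, pos, drop = FALSE])
  }
  dimnames(corr) <- list(pd$znames, pd$znames)
  sd_day <- if (spec$day) at$s * sqrt(sigma2) else NULL
  eb <- eb_effects(pd, spec, at)
  res <- list(spec = spec, estimates = beta, se = se,
              sd_person = sds, corr_person = corr,
              sd_day = sd_day, sigma_e = sqrt(sigma2),
              loglik = loglik, n_obs = pd$n, k_params = k,
              aic = 2 * k - 2 * loglik,
              bic = k * log(pd$n) - 2 * loglik,
              eb_person = eb$person, eb_day = eb$day,
              converged = converged,
              boundary = any(theta[bounded] < 1e-4),
              theta = theta, rows = pd$rows, row_key = pd$row_key,
              outcome = outcome_name(data))
  class(res) <- "esmar_fit"
  res
}

# Empirical Bayes (BLUP) predictions of the random effects at the optimum
eb_effects <- function(pd, spec, at) {
  q <- pd$q
  p <- pd$p
  L <- at$L
  s <- at$s
  Lam <- tcrossprod(L)
  person <- matrix(0, length(pd$persons), q,
                   dimnames = list(pd$persons, pd$znames))
  day <- NULL
  if (spec$day) day <- vector("list", length(pd$persons))
  for (j in seq_along(pd$prep)) {
    pp <- pd$prep[[j]]
    a <- pp$Czm[, p + 1] - pp$Czm[, seq_len(p), drop = FALSE] %*% at$beta
    A0 <- t(L) %*% pp$Czz %*% L
    if (spec$day) {
      g <- pp$Sdm[, p + 1] - pp$Sdm[, seq_len(p), drop = FALSE] %*% at$beta
      cd <- 1 + s^2 * pp$ndv
      B0 <- s * (t(L) %*% t(pp$Sdz))
      w2 <- (s * g) / cd
      E <- diag(1, q) + A0 - B0 %*% (t(B0) / cd)
      v1 <- solve(E, t(L) %*% a - B0 %*% w2)
      v2 <- (s * g - crossprod(B0, v1)) / cd
      ztv <- a - pp$Czz %*% (L %*% v1) - s * crossprod(pp$Sdz, v2)
      dtv <- g - pp$Sdz %*% (L %*% v1) - s * (pp$ndv * v2)
      person[j, ] <- as.numeric(Lam %*% ztv)
      day[[j]] <- data.frame(Person = pd$persons[j], Day = pp$days,
                             effect = as.numeric(s^2 * dtv))
    } else {
      M <- diag(1, q) + A0
      v1 <- solve(M, t(L) %*% a)
      person[j, ] <- as.numeric(Lam %*% (a - pp$Czz %*% (L %*% v1)))
    }
  }
  list(person = person,
       day = if (spec$day) do.call(rbind, day) else NULL)
}

#' @export
print.esmar_fit <- function(x, ...) {
  cat(sprintf("ML fit, family '%s'%s\n", x$spec$family,
              if (x$spec$correlated) " (correlated random effects)" else ""))
  cat(sprintf("  n = %d, k = %d, logLik = %.1f, AIC = %.1f, BIC = %.1f\n",
              x$n_obs, x$k_params, x$loglik, x$aic, x$bic))
  est <- cbind(Estimate = x$estimates, SE = x$se)
  print(round(est, 4))
  vc <- c(x$sd_person, if (!is.null(x$sd_day)) c(`day (Intercept)` =
                                                   x$sd_day),
          residual = x$sigma_e)
  cat("Random-effect SDs:\n")
  print(round(vc, 4))
  if (x$spec$correlated && length(x$sd_person) > 1) {
    cat("Person-level correlations:\n")
    print(round(x$corr_person, 3))
  }
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  if (x$boundary) cat("note: variance estimate(s) on the zero boundary\n")
  invisible(x)
}

#' Plain-list summary of a fit, suitable for JSON serialization
#'
#' @param fit an `esmar_fit`.
#' @return A named list with the model family, fixed estimates and SEs,
#'   variance components, log-likelihood, information criteria, case count,
#'   parameter count and status flags.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "esmar_fit"))
  list(family = fit$spec$family,
       correlated = fit$spec$correlated,
       estimates = as.list(fit$estimates),
       se = as.list(fit$se),
       sd_person = as.list(fit$sd_person),
       corr_person = if (fit$spec$correlated) fit$corr_person else NULL,
       sd_day = fit$sd_day,
       sigma_e = fit$sigma_e,
       loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
       n_obs = fit$n_obs, k_params = fit$k_params,
       converged = fit$converged, boundary = fit$boundary)
}

#' Exact marginal log-likelihood at given parameter values
#'
#' Evaluates the Gaussian marginal log-likelihood of a model family at
#' user-supplied population parameter values (no optimization). The marginal
#' covariance per person is `Z G Z' + sd_day^2 D D' + sigma_e^2 I`,
#' evaluated in closed form by block elimination.
#'
#' @param spec an `esmar_spec`.
#' @param data an `esm_panel` or `esm_lagged`.
#' @param params a list with `beta` (fixed effects, intercept first),
#'   `sigma_e`, `sd_person` (length q), optionally `corr_person` (q x q
#'   correlation matrix) and `sd_day` (required iff the family has a day
#'   level).
#' @param rows optional logical row mask, as in [mlm_fit()].
#' @return The log-likelihood (a scalar).
#' @export
marginal_loglik <- function(spec, data, params, rows = NULL) {
  stopifnot(inherits(spec, "esmar_spec"))
  pd <- prep_model_data(spec, data, rows = rows)
  q <- pd$q
  if (length(params$beta) != pd$p) {
    stop("params$beta must have length ", pd$p, call. = FALSE)
  }
  if (length(params$sd_person) != q) {
    stop("params$sd_person must have length ", q, call. = FALSE)
  }
  sigma_e <- params$sigma_e
  if (!is.numeric(sigma_e) || sigma_e <= 0) {
    stop("params$sigma_e must be positive", call. = FALSE)
  }
  R <- if (is.null(params$corr_person)) diag(1, q) else params$corr_person
  check_corr_matrix(R)
  G <- diag(params$sd_person, q) %*% R %*% diag(params$sd_person, q)
  L <- psd_chol(G) / sigma_e
  s <- if (spec$day) {
    if (is.null(params$sd_day)) stop("params$sd_day required for family ",
                                     spec$family, call. = FALSE)
    params$sd_day / sigma_e
  } else 0
  parts <- esmar_lik_parts(pd$prep, L, s, spec$day)
  cc <- c(-params$beta, 1)
  qf <- as.numeric(t(cc) %*% parts$Cw %*% cc)
  -0.5 * (pd$n * log(2 * pi * sigma_e^2) + parts$ld + qf / sigma_e^2)
}

# Lower-triangular factor of a PSD matrix (tolerates zero variances)
psd_chol <- function(G) {
  q <- nrow(G)
  ok <- tryCatch({
    L <- t(chol(G))
    TRUE
  }, error = function(e) FALSE)
  if (ok) return(t(chol(G)))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), q)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,constrained `esmar_fit` objects fitted to the same rows, with
#'   `constrained` nested in `full`.
#' @return A list with `chi2`, `df` and `p` (naive chi-squared reference,
#'   conservative when the constrained parameter is a variance on the
#'   boundary).
#' @export
lrt <- function(full, constrained) {
  stopifnot(inherits(full, "esmar_fit"), inherits(constrained, "esmar_fit"))
  if (full$n_obs != constrained$n_obs ||
      !identical(sort(full$row_key), sort(constrained$row_key))) {
    stop("fits use different case sets; refit on a common subset",
         call. = FALSE)
  }
  df <- full$k_params - constrained$k_params
  if (df < 0) stop("'full' has fewer parameters than 'constrained'",
                   call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - constrained$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Wald z-test of a fixed effect
#'
#' @param fit an `esmar_fit`.
#' @param term name of a fixed-effect term (e.g. `"lev1pred"`).
#' @return A list with `z` and the two-sided normal `p`.
#' @export
wald <- function(fit, term) {
  stopifnot(inherits(fit, "esmar_fit"))
  if (!term %in% names(fit$estimates)) {
    stop("no fixed effect '", term, "' in this fit", call. = FALSE)
  }
  se <- fit$se[[term]]
  if (!is.finite(se) || se <= 0) {
    stop("standard error unavailable or degenerate for '", term, "'",
         call. = FALSE)
  }
  z <- fit$estimates[[term]] / se
  list(z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
}
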