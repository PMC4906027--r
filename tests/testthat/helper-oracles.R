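# Independent oracles used across the test files. These deliberately use
# naive dense / brute-force computations, not the package's own code paths.

# Dense multivariate-normal log-density of the stacked outcome vector for a
# mixed model with person-level random effects (design Z, covariance G),
# optional day intercepts (variance sd_day^2) and residual variance
# sd_e^2. `d` holds Person/Day columns, X and Z are dense matrices.
dense_mvn_loglik <- function(y, X, beta, d, Z, G, sd_day, sd_e) {
  n <- length(y)
  V <- diag(sd_e^2, n)
  for (p in unique(d$Person)) {
    idx <- which(d$Person == p)
    Zi <- Z[idx, , drop = FALSE]
    V[idx, idx] <- V[idx, idx] + Zi %*% G %*% t(Zi)
    if (!is.null(sd_day)) {
      for (dd in unique(d$Day[idx])) {
        jdx <- idx[d$Day[idx] == dd]
        V[jdx, jdx] <- V[jdx, jdx] + sd_day^2
      }
    }
  }
  r <- y - as.numeric(X %*% beta)
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Brute-force pooled within-day lag-1 autocorrelation of the deviations of
# y from each person's sample mean (row scan, no vectorized shortcuts).
pooled_lag1_autocor <- function(panel) {
  oc <- outcome_name(panel)
  px <- vector("list", 0); py <- vector("list", 0)
  for (p in unique(panel$Person)) {
    rows_p <- panel[panel$Person == p, ]
    mu <- mean(rows_p[[oc]], na.rm = TRUE)
    for (d in unique(rows_p$Day)) {
      rd <- rows_p[rows_p$Day == d, ]
      v <- rd[[oc]][order(rd$Beep)] - mu
      if (length(v) < 2) next
      ok <- !is.na(v[-length(v)]) & !is.na(v[-1])
      px[[length(px) + 1]] <- v[-length(v)][ok]
      py[[length(py) + 1]] <- v[-1][ok]
    }
  }
  stats::cor(unlist(px), unlist(py))
}

# Brute-force usable-case counting by row scan with explicit rules
brute_case_counts <- function(panel) {
  oc <- outcome_name(panel)
  n_total <- 0; n_ar2 <- 0; n_ar3 <- 0
  for (i in seq_len(nrow(panel))) {
    if (is.na(panel[[oc]][i])) next
    n_total <- n_total + 1
    p <- panel$Person[i]; d <- panel$Day[i]; b <- panel$Beep[i]
    prev <- which(panel$Person == p & panel$Day == d & seq_len(nrow(panel)) < i)
    prev <- if (length(prev)) max(prev) else integer(0)
    ok2 <- length(prev) == 1 && !is.na(panel[[oc]][prev])
    if (ok2) n_ar2 <- n_ar2 + 1
    prev_day <- panel$Person == p & panel$Day == d - 1
    ok3 <- ok2 && any(prev_day) && any(!is.na(panel[[oc]][prev_day]))
    if (ok3) n_ar3 <- n_ar3 + 1
  }
  c(n_total = n_total, n_ar2 = n_ar2, n_ar3 = n_ar3)
}

# lme4 formula for each model family (independent reference implementation)
lmer_formula <- function(family, correlated = FALSE) {
  stats::as.formula(switch(family,
    empty2 = "y ~ 1 + (1 | PersonF)",
    empty3 = "y ~ 1 + (1 | PersonF) + (1 | DayF)",
    ar2 = if (correlated) "y ~ 1 + lev1pred + (1 + lev1pred | PersonF)"
          else "y ~ 1 + lev1pred + (1 | PersonF) + (0 + lev1pred | PersonF)",
    ar3_nobeta = paste("y ~ 1 + lev1predfor3l + (1 | PersonF) +",
                       "(1 | DayF) + (0 + lev1predfor3l | PersonF)"),
    ar3_fixedbeta = paste("y ~ 1 + lev2pred + lev1predfor3l +",
                          "(1 | PersonF) + (1 | DayF) +",
                          "(0 + lev1predfor3l | PersonF)"),
    ar3_randombeta = if (correlated) {
      paste("y ~ 1 + lev2pred + lev1predfor3l +",
            "(1 + lev2pred + lev1predfor3l | PersonF) + (1 | DayF)")
    } else {
      paste("y ~ 1 + lev2pred + lev1predfor3l +",
            "(1 | PersonF) + (1 | DayF) +",
            "(0 + lev2pred | PersonF) +",
            "(0 + lev1predfor3l | PersonF)")
    },
    ar3_fixedonly = paste("y ~ 1 + lev2pred + lev1predfor3l +",
                          "(1 | PersonF) + (1 | DayF)")))
}

# Fit the reference lme4 model on the rows used by an esmar fit
lmer_reference <- function(family, lf, mask = NULL, correlated = FALSE) {
  d <- as.data.frame(lf)
  if (!is.null(mask)) d <- d[mask, ]
  keep <- stats::complete.cases(d[, intersect(
    c("y", "lev1pred", "lev1predfor3l", "lev2pred"),
    switch(family,
           empty2 = "y", empty3 = "y",
           ar2 = c("y", "lev1pred"),
           ar3_nobeta = c("y", "lev1predfor3l"),
           c("y", "lev2pred", "lev1predfor3l"))), drop = FALSE])
  d <- d[keep, ]
  d$PersonF <- factor(d$Person)
  d$DayF <- factor(paste(d$Person, d$Day))
  suppressWarnings(suppressMessages(
    lme4::lmer(lmer_formula(family, correlated), data = d, REML = FALSE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.conv.grad = "ignore",
                 check.conv.hess = "ignore",
                 optimizer = "bobyqa",
                 optCtrl = list(maxfun = 50000)))))
}

# A small lagged frame with deterministic values, used as a fixture
small_lagged_fixture <- function(seed = 5, np = 4, nd = 3, nb = 4) {
  panel <- simulate_ar3(sim_params_3l(), study_design(np, nd, nb),
                        seed = seed)
  build_predictors(panel)
}
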