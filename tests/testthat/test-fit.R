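test_that("marginal log-likelihood equals a dense multivariate-normal oracle", {
  lf <- small_lagged_fixture(seed = 5, np = 3, nd = 2, nb = 3)
  mask <- common_subset(lf)
  d <- as.data.frame(lf)[mask, ]
  cases <- list(
    list(fam = "empty2", beta = c(57), sds = c(10), R = NULL,
         sd_day = NULL, Zc = character(0)),
    list(fam = "empty3", beta = c(60), sds = c(11), R = NULL,
         sd_day = 6.5, Zc = character(0)),
    list(fam = "ar2", beta = c(58, 0.3), sds = c(12, 0.2),
         R = matrix(c(1, -0.4, -0.4, 1), 2), sd_day = NULL,
         Zc = "lev1pred"),
    list(fam = "ar3_randombeta", beta = c(58, 0.25, 0.15),
         sds = c(13, 0.2, 0.1),
         R = matrix(c(1, -0.45, -0.365, -0.45, 1, 0.22,
                      -0.365, 0.22, 1), 3),
         sd_day = 7, Zc = c("lev2pred", "lev1predfor3l")))
  for (cs in cases) {
    spec <- model_spec(cs$fam, correlated = !is.null(cs$R))
    params <- list(beta = cs$beta, sigma_e = 14.5, sd_person = cs$sds,
                   corr_person = cs$R, sd_day = cs$sd_day)
    ll <- marginal_loglik(spec, lf, params, rows = mask)
    dd <- d[stats::complete.cases(d[, c("y", spec$fixed), drop = FALSE]), ]
    X <- cbind(1, as.matrix(dd[, spec$fixed, drop = FALSE]))
    Z <- cbind(1, as.matrix(dd[, cs$Zc, drop = FALSE]))
    R <- if (is.null(cs$R)) diag(length(cs$sds)) else cs$R
    G <- diag(cs$sds, length(cs$sds)) %*% R %*%
      diag(cs$sds, length(cs$sds))
    oracle <- dense_mvn_loglik(dd$y, X, cs$beta, dd, Z, G, cs$sd_day, 14.5)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("log-likelihood is equivariant under rescaling of the outcome", {
  lf <- small_lagged_fixture(seed = 6, np = 4, nd = 3, nb = 4)
  spec <- model_spec("empty3")
  params <- list(beta = 58, sigma_e = 15, sd_person = 12, sd_day = 7)
  ll <- marginal_loglik(spec, lf, params)
  cfac <- 2.5
  lf2 <- lf
  lf2$y <- lf$y * cfac
  params2 <- list(beta = 58 * cfac, sigma_e = 15 * cfac,
                  sd_person = 12 * cfac, sd_day = 7 * cfac)
  n <- sum(!is.na(lf$y))
  expect_equal(marginal_loglik(spec, lf2, params2), ll - n * log(cfac),
               tolerance = 1e-10)
})

test_that("degenerate fits behave sensibly", {
  # zero person variance reduces to an i.i.d. normal likelihood
  lf <- small_lagged_fixture(seed = 7, np = 3, nd = 2, nb = 4)
  spec <- model_spec("empty2")
  params <- list(beta = 55, sigma_e = 16, sd_person = 0)
  y <- lf$y[!is.na(lf$y)]
  expect_equal(marginal_loglik(spec, lf, params),
               sum(dnorm(y, 55, 16, log = TRUE)), tolerance = 1e-10)
  # constant outcome: intercept at the value, variances on the boundary
  pc <- esm_panel(person = rep(1:5, each = 6),
                  day = rep(rep(1:2, each = 3), 5),
                  beep = rep(1:3, 10), y = rep(7.5, 30))
  f <- mlm_fit(model_spec("empty2"), pc)
  expect_equal(unname(f$estimates[["(Intercept)"]]), 7.5, tolerance = 1e-6)
  expect_true(f$boundary)
  expect_lt(f$sd_person[["(Intercept)"]], 0.01)
})

test_that("ML estimates agree with lme4 on shared data", {
  lf <- small_lagged_fixture(seed = 8, np = 12, nd = 4, nb = 5)
  mask <- common_subset(lf)
  for (fam in c("empty3", "ar2", "ar3_fixedbeta")) {
    fit <- mlm_fit(model_spec(fam, correlated = fam == "ar2"), lf,
                   rows = mask)
    ref <- lmer_reference(fam, lf, mask, correlated = fam == "ar2")
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 2e-3)
    expect_equal(unname(fit$estimates),
                 unname(lme4::fixef(ref)), tolerance = 1e-3)
    expect_equal(fit$n_obs, stats::nobs(ref))
    expect_equal(fit$k_params, attr(stats::logLik(ref), "df"))
  }
})

test_that("empirical Bayes person effects match lme4 BLUPs", {
  panel <- simulate_ar2(sim_params_2l(), study_design(15, 4, 6), seed = 9)
  f <- mlm_fit(model_spec("empty2"), panel)
  d <- as.data.frame(panel)
  d$PersonF <- factor(d$Person)
  ref <- suppressMessages(lme4::lmer(y ~ 1 + (1 | PersonF), data = d,
                                     REML = FALSE))
  expect_equal(unname(f$eb_person[, 1]),
               lme4::ranef(ref)$PersonF[["(Intercept)"]],
               tolerance = 1e-4)
  # BLUPs shrink the person mean toward the grand mean
  pm <- tapply(d$y, d$Person, mean)
  shrunk <- f$estimates[["(Intercept)"]] + f$eb_person[, 1]
  gm <- f$estimates[["(Intercept)"]]
  expect_true(all((shrunk - gm) * (pm - gm) >= 0))
  expect_true(all(abs(shrunk - gm) <= abs(pm - gm) + 1e-10))
})

test_that("information criteria identities and likelihood nesting hold", {
  lf <- small_lagged_fixture(seed = 10, np = 8, nd = 3, nb = 5)
  mask <- common_subset(lf)
  fits <- lapply(c("ar2", "ar3_nobeta", "ar3_fixedbeta", "ar3_randombeta"),
                 function(f) mlm_fit(model_spec(f), lf, rows = mask))
  for (f in fits) {
    expect_equal(f$aic, 2 * f$k_params - 2 * f$loglik)
    expect_equal(f$bic, f$k_params * log(f$n_obs) - 2 * f$loglik)
    expect_true(all(f$sd_person >= 0))
    expect_true(all(abs(f$corr_person) <= 1 + 1e-8))
  }
  # adding parameters on identical rows can only raise the ML log-likelihood
  expect_gte(fits[[3]]$loglik, fits[[2]]$loglik - 1e-4)
  expect_gte(fits[[4]]$loglik, fits[[3]]$loglik - 1e-4)
  corr <- mlm_fit(model_spec("ar2", correlated = TRUE), lf, rows = mask)
  expect_gte(corr$loglik, fits[[1]]$loglik - 1e-4)
})

test_that("likelihood-ratio and Wald tests follow their contracts", {
  lf <- small_lagged_fixture(seed = 11, np = 10, nd = 3, nb = 5)
  mask <- common_subset(lf)
  ar2u <- mlm_fit(model_spec("ar2"), lf, rows = mask)
  ar2c <- mlm_fit(model_spec("ar2", correlated = TRUE), lf, rows = mask)
  out <- lrt(ar2c, ar2u)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)
  same <- lrt(ar2u, ar2u)
  expect_equal(same[c("chi2", "df", "p")], list(chi2 = 0, df = 0, p = 1))
  nb <- mlm_fit(model_spec("ar3_nobeta"), lf, rows = mask)
  rb <- mlm_fit(model_spec("ar3_randombeta"), lf, rows = mask)
  expect_equal(lrt(rb, nb)$df, 2)
  expect_error(lrt(nb, rb), "fewer parameters")
  # mismatched case sets are refused
  full <- mlm_fit(model_spec("ar2"), lf)
  expect_error(lrt(full, ar2u), "different case sets")

  w <- wald(ar2u, "lev1pred")
  expect_equal(w$z, ar2u$estimates[["lev1pred"]] / ar2u$se[["lev1pred"]])
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  fake <- ar2u
  fake$se[["lev1pred"]] <- 0
  expect_error(wald(fake, "lev1pred"), "degenerate")
  expect_error(wald(ar2u, "nope"), "no fixed effect")
  # z of an exactly zero estimate has p = 1
  fake2 <- ar2u
  fake2$estimates[["lev1pred"]] <- 0
  w2 <- wald(fake2, "lev1pred")
  expect_equal(w2$z, 0)
  expect_equal(w2$p, 1)
})

test_that("fits are deterministic and insufficient data is refused", {
  lf <- small_lagged_fixture(seed = 12, np = 6, nd = 3, nb = 4)
  a <- mlm_fit(model_spec("ar2"), lf)
  b <- mlm_fit(model_spec("ar2"), lf)
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$estimates, b$estimates)
  tiny <- esm_panel(person = c(1, 1, 1), day = c(1, 1, 1), beep = 1:3,
                    y = c(1, 2, 3))
  expect_error(mlm_fit(model_spec("empty2"), tiny), "insufficient")
})
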