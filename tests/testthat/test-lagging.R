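test_that("within-day lag shifts inside days and respects missingness", {
  p1 <- esm_panel(person = rep(1, 3), day = rep(1, 3), beep = 1:3,
                  y = c(10, 20, 30))
  expect_equal(within_day_lag(c(1, 2, 3), p1), c(NA, 1, 2))
  expect_equal(within_day_lag(c(1, NA, 3), p1), c(NA, 1, NA))
  # no carry-over across the night
  p2 <- esm_panel(person = rep(1, 4), day = c(1, 1, 2, 2), beep = c(1, 2, 1, 2),
                  y = 1:4)
  expect_equal(within_day_lag(c(1, 2, 3, 4), p2), c(NA, 1, NA, 3))
  # nor across persons
  p3 <- esm_panel(person = c(1, 1, 2, 2), day = rep(1, 4), beep = c(1, 2, 1, 2),
                  y = 1:4)
  expect_equal(within_day_lag(c(1, 2, 3, 4), p3), c(NA, 1, NA, 3))
  # applying the lag twice gives the lag-2 structure
  p4 <- esm_panel(person = rep(1, 5), day = rep(1, 5), beep = 1:5, y = 1:5)
  expect_equal(within_day_lag(within_day_lag(c(1, 2, 3, 4, 5), p4), p4),
               c(NA, NA, 1, 2, 3))
  expect_error(within_day_lag(1:3, p4), "length")
})

test_that("previous-day lag works within persons and skips empty days", {
  p <- esm_panel(person = rep(1:2, each = 6),
                 day = rep(rep(1:3, each = 2), 2),
                 beep = rep(1:2, 6), y = 1:12)
  r <- rep(c(101, 102, 103, 201, 202, 203), each = 2)
  expect_equal(person_day_lag(r, p),
               rep(c(NA, 101, 102, NA, 201, 202), each = 2))
  # a wholly unobserved previous day propagates NA
  r2 <- r
  r2[3:4] <- NA  # person 1, day 2 has no day residual
  expect_equal(person_day_lag(r2, p),
               rep(c(NA, 101, NA, NA, 201, 202), each = 2))
  # an absent previous day (gap in day labels) also yields NA
  pg <- esm_panel(person = rep(1, 4), day = c(1, 1, 3, 3), beep = rep(1:2, 2),
                  y = 1:4)
  expect_equal(person_day_lag(c(5, 5, 9, 9), pg), rep(NA_real_, 4))
})

test_that("EB residuals center observations on shrunken person means", {
  # a single-person constant series has zero residuals
  pc <- esm_panel(person = rep(1:4, each = 6),
                  day = rep(rep(1:2, each = 3), 4),
                  beep = rep(1:3, 8), y = rep(c(3, 3, 3, 9, 9, 9), 4))
  f <- mlm_fit(model_spec("empty2"), pc)
  e <- eb_residuals_2l(pc, f)
  expect_equal(e[pc$Person == 1], e[pc$Person == 3])
  # missing outcomes give missing residuals
  panel <- simulate_ar2(sim_params_2l(), study_design(10, 4, 6), seed = 3,
                        p_missing = 0.2)
  f2 <- mlm_fit(model_spec("empty2"), panel)
  e2 <- eb_residuals_2l(panel, f2)
  expect_identical(is.na(e2), is.na(panel$y))
  # residual means per person are near zero: the leftover is the
  # unshrunk fraction (1 - lambda) of the person deviation, a few units
  # at most at ~20 observations per person
  pm <- tapply(e2, panel$Person, mean, na.rm = TRUE)
  expect_lt(max(abs(pm)), 4)
  # shrinkage: EB person mean lies between grand mean and sample mean,
  # near the closed-form ratio  n_i sd_u0^2 / (n_i sd_u0^2 + sd_e^2)
  big <- simulate_ar2(ar2_params(50, 0, 10, 0, 15), study_design(40, 2, 5),
                      seed = 4)
  fb <- mlm_fit(model_spec("empty2"), big)
  gm <- fb$estimates[["(Intercept)"]]
  sm <- tapply(big$y, big$Person, mean)
  lambda_hat <- (fb$eb_person[, 1]) / (sm - gm)
  lambda_closed <- 10 * fb$sd_person[1]^2 /
    (10 * fb$sd_person[1]^2 + fb$sigma_e^2)
  expect_lt(max(abs(lambda_hat - lambda_closed)), 1e-6)
})

test_that("day residuals are day-constant BLUPs that track the true day effects", {
  # construct day-effect data with known truth, independently of the
  # package's simulators
  set.seed(42)
  np <- 30; nd <- 21; nb <- 10
  skel <- expand.grid(Beep = 1:nb, Day = 1:nd, Person = 1:np)
  mu <- rnorm(np, 58, 12.3)
  r_true <- matrix(rnorm(np * nd, 0, 7.9), np, nd)
  y <- mu[skel$Person] + r_true[cbind(skel$Person, skel$Day)] +
    rnorm(nrow(skel), 0, 15)
  panel <- esm_panel(skel$Person, skel$Day, skel$Beep, y)
  f3 <- mlm_fit(model_spec("empty3"), panel)
  r_hat <- day_residuals_3l(panel, f3)
  # constant within (person, day) blocks
  expect_equal(max(tapply(r_hat, paste(panel$Person, panel$Day),
                          function(v) diff(range(v)))), 0)
  # strong correlation with the generating day effects; the attainable
  # ceiling is sqrt(sd_r^2 / (sd_r^2 + sd_e^2 / nb)) ~ 0.857 here, less a
  # small person-centering factor sqrt(1 - 1/nd)
  first <- !duplicated(paste(panel$Person, panel$Day))
  expect_gt(cor(r_hat[first], r_true[cbind(panel$Person[first],
                                           panel$Day[first])]), 0.8)
  # per-person day residuals average out
  expect_lt(max(abs(tapply(r_hat[first], panel$Person[first], mean))), 3)
  # BLUP shrinkage factor close to sd_r^2 / (sd_r^2 + sd_e^2 / nb)
  lam <- coef(lm(r_hat[first] ~ 0 + r_true[cbind(panel$Person[first],
                                                 panel$Day[first])]))
  expect_lt(abs(lam - 7.9^2 / (7.9^2 + 15^2 / nb)), 0.08)
})

test_that("build_predictors assembles all six columns with the right missingness", {
  np <- 12; nd <- 4; nb <- 5
  panel <- simulate_ar3(sim_params_3l(), study_design(np, nd, nb), seed = 5)
  lf <- build_predictors(panel)
  expect_s3_class(lf, "esm_lagged")
  expect_true(all(c("e.bi", "lev1pred", "e.bdi", "lev1predfor3l", "r.0di",
                    "lev2pred") %in% names(lf)))
  # complete balanced data: lev1pred misses once per person-day, lev2pred
  # misses once per person-beep (the first day)
  expect_equal(sum(is.na(lf$lev1pred)), np * nd)
  expect_equal(sum(is.na(lf$lev2pred)), np * nb)
  expect_identical(is.na(lf$lev1pred), is.na(lf$lev1predfor3l))
  expect_equal(sum(!is.na(lf$lev2pred) & !is.na(lf$lev1predfor3l)),
               np * (nd - 1) * (nb - 1))
  expect_false(attr(lf, "degenerate"))

  # with missing outcomes the shared missingness pattern is preserved
  pm <- simulate_ar3(sim_params_3l(), study_design(10, 4, 5), seed = 6,
                     p_missing = 0.2)
  lfm <- build_predictors(pm)
  expect_identical(is.na(lfm$lev1pred), is.na(lfm$lev1predfor3l))
  # lagged predictor missing wherever previous beep's outcome was missing
  prev_na <- c(TRUE, is.na(pm$y)[-nrow(pm)])
  expect_true(all(is.na(lfm$lev1pred[prev_na])))
})

test_that("sample-mean centering option and degenerate inputs", {
  panel <- simulate_ar3(sim_params_3l(), study_design(6, 3, 4), seed = 7)
  lf <- build_predictors(panel, center = "sample")
  pm <- tapply(panel$y, panel$Person, mean)
  expect_equal(lf$e.bi,
               as.numeric(panel$y - pm[as.character(panel$Person)]))
  dm <- tapply(panel$y, paste(panel$Person, panel$Day), mean)
  expect_equal(lf$r.0di,
               as.numeric(dm[paste(panel$Person, panel$Day)] -
                            pm[as.character(panel$Person)]))
  # one person, one day: the day level is inestimable
  tiny <- esm_panel(rep(1, 6), rep(1, 6), 1:6, c(1, 4, 2, 6, 3, 5))
  expect_warning(lft <- build_predictors(tiny), "inestimable")
  expect_true(attr(lft, "degenerate"))
  expect_true(all(is.na(lft$lev2pred)))
  expect_true(all(is.na(lft$lev1predfor3l)))
})
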