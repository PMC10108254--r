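test_that("budget composition closes all accounting identities", {
  b <- make_budget()
  expect_equal(b$npp_t, 240)
  expect_equal(b$npp_u, 60)
  expect_equal(b$npp, 300)
  expect_equal(b$rh, 218)
  expect_equal(b$nep, 82)
  z <- compose_budget("s", 2016, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(z$nep, 0)
  expect_error(compose_budget("s", 2016, anpp_t = 1, l = 0, bnpp_t_cr = 0,
                              bnpp_t_fr = 0, anpp_u = NA, bnpp_u = 0,
                              rh_s = 0, rh_dw = 0), "anpp_u")
  expect_silent(check_budget_identities(rbind(b, z)))
})

test_that("class aggregation uses Student-t 95% intervals on stand means", {
  stands <- data.frame(stand_id = c("a", "b", "c", "d"),
                       age_class = c(rep("young", 3), "old"))
  mb <- do.call(rbind, lapply(1:4, function(i) {
    out <- make_budget(stand_id = c("a", "b", "c", "d")[i],
                       rh_s = 210 + c(-78, -79, -80, 0)[i])
    out$year <- NULL
    out
  }))
  # NEP values for young are 160, 161, 162 -> mean 161, hw = qt * sd/sqrt(3)
  cs <- class_aggregate(mb, stands, fluxes = "nep")
  young <- cs[cs$age_class == "young", ]
  expect_equal(young$mean, 161)
  expect_equal(young$ci95_half_width, qt(0.975, 2) * 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(young$ci95_half_width, 2.484, tolerance = 1e-3)
  old <- cs[cs$age_class == "old", ]
  expect_equal(old$n, 1)
  expect_true(is.na(old$ci95_half_width))
  # identical values give a zero-width interval
  mb2 <- mb; mb2$nep <- 100
  expect_equal(class_aggregate(mb2, stands, fluxes = "nep")$ci95_half_width[1], 0)
})

test_that("log-quadratic fit recovers exact coefficients via the log-space oracle", {
  b_true <- c(b0 = 1, b1 = 0.5, b2 = -0.05)
  ages <- c(1, exp(1), exp(2), exp(1))  # one redundant point
  y <- exp(b_true[1] + b_true[2] * log(ages) + b_true[3] * log(ages)^2)
  # independent oracle: 3x3 linear solve in log space on the unique ages
  x <- log(ages[1:3])
  oracle <- solve(cbind(1, x, x^2), log(y[1:3]))
  expect_equal(unname(oracle), unname(b_true), tolerance = 1e-12)
  fit <- fit_log_quadratic(ages, y)
  expect_equal(c(fit$b0, fit$b1, fit$b2), unname(b_true), tolerance = 1e-6)
  # constant data -> (ln c, 0, 0)
  cf <- fit_log_quadratic(c(2, 5, 20, 80), rep(7, 4))
  expect_equal(c(cf$b0, cf$b1, cf$b2), c(log(7), 0, 0), tolerance = 1e-6)
  # interior maximum at exp(-b1/(2 b2)) for b2 < 0
  peak_age <- exp(-fit$b1 / (2 * fit$b2))
  grid <- seq(1, 500, by = 0.1)
  expect_equal(grid[which.max(predict(fit, grid))], peak_age, tolerance = 0.1)
  expect_error(fit_log_quadratic(c(0.5, 2, 3, 4), 1:4), ">= 1")
})

test_that("quadratic age fit solves the exact parabola", {
  fit <- fit_poly2(c(10, 50, 90), c(5, 9, 5))
  expect_equal(c(fit$b0, fit$b1, fit$b2), c(2.75, 0.25, -0.0025),
               tolerance = 1e-10)
  # symmetric data -> vertex at the mean age
  expect_equal(-fit$b1 / (2 * fit$b2), 50)
  cf <- fit_poly2(c(10, 20, 30, 40), rep(4, 4))
  expect_equal(c(cf$b0, cf$b1, cf$b2), c(4, 0, 0), tolerance = 1e-10)
  # flux predictions clamp at zero
  low <- fit_poly2(c(1, 2, 3), c(2, 1, 0))
  expect_gte(min(predict(low, seq(1, 10, 0.5))), 0)
})

test_that("the NEP trend is the lazy difference of the NPP and RH curves", {
  npp <- fit_poly2(c(10, 50, 90), rep(391, 3))
  rh <- fit_poly2(c(10, 50, 90), rep(217, 3))
  nep <- nep_trend(npp, rh)
  expect_equal(nep(c(20, 70)), c(174, 174), tolerance = 1e-9)
  same <- nep_trend(npp, npp)
  expect_equal(same(seq(10, 90, 10)), rep(0, 9), tolerance = 1e-9)
})

test_that("old-stand imputation uses fixed ratios and BA regressions", {
  mb <- rbind(make_budget("r1", rh_s = 200), make_budget("r2", rh_s = 240))
  mb$year <- NULL
  refs <- build_old_stand_references(mb, ba = c(20, 40),
                                     rh_dw_downed = c(4, 4))
  # RH_s regression through (20, 200) and (40, 240) -> 220 at BA = 30
  b <- impute_old_stand_budget("old1", 0L, 30, anpp_t = 150, bnpp_t_cr = 30,
                               refs, rh_dw_standing = 2)
  expect_equal(b$rh_s, 220)
  expect_equal(b$rh_dw, 6)
  expect_equal(b$bnpp_t_fr, refs$r_bnpp_t_fr * 150)
  expect_silent(check_budget_identities(b))
  # single reference stand degenerates to that stand's proportions
  refs1 <- build_old_stand_references(mb[1, ], ba = 25, rh_dw_downed = 4)
  expect_warning(
    b1 <- impute_old_stand_budget("old2", 0L, 30, anpp_t = 150,
                                  bnpp_t_cr = 30, refs1, 4), "outside")
  expect_equal(b1$anpp_u / b1$anpp_t, mb$anpp_u[1] / mb$anpp_t[1])
  expect_equal(b1$rh_s, mb$rh_s[1])
  # zero ratios reduce the budget to the measured components minus modelled RH
  refs0 <- refs
  refs0$r_bnpp_t_fr <- refs0$r_l <- refs0$r_anpp_u <- refs0$r_bnpp_u <- 0
  b0 <- impute_old_stand_budget("old3", 0L, 30, anpp_t = 150, bnpp_t_cr = 30,
                                refs0, 0)
  expect_equal(b0$npp, 180)
})
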