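test_that("chamber flux implements the ideal-gas slope conversion", {
  t <- seq(0, 120, 10)
  expect_equal(chamber_flux(t, rep(400, length(t)), ta_c = 20), 0)
  f <- chamber_flux(t, 400 + 1 * t, ta_c = 20, pressure_kpa = 101.325,
                    height_m = 0.2)
  expect_equal(f, 0.2 * 101325 / (8.314 * 293.15), tolerance = 1e-6)
  expect_equal(f, 8.314, tolerance = 1e-3)
  # doubling chamber height doubles flux for the same slope
  expect_equal(chamber_flux(t, 400 + t, ta_c = 20, height_m = 0.4), 2 * f)
  # deadband leaves too few points
  expect_error(chamber_flux(c(0, 5, 12, 20, 30), 400 + c(0, 5, 12, 20, 30),
                            ta_c = 20), "usable points")
  expect_warning(f0 <- chamber_flux(t, 400 - 1 * t, ta_c = 20), "clamped")
  expect_equal(f0, 0)
})

test_that("Lloyd-Taylor model has the reference-temperature identity", {
  expect_equal(lloyd_taylor(10, r_ref = 2, e0 = 308.56), 2)
  expect_equal(lloyd_taylor(20, r_ref = 2, e0 = 308.56), 4.607, tolerance = 1e-3)
  expect_error(lloyd_taylor(-60, 1, 300), "undefined")
})

test_that("Lloyd-Taylor fitting recovers parameters and degenerates gracefully", {
  ts <- c(5, 10, 15, 20)
  flux <- lloyd_taylor(ts, r_ref = 2, e0 = 308.56)
  fit <- fit_lloyd_taylor(ts, flux)
  expect_equal(fit$r_ref, 2, tolerance = 1e-4)
  expect_equal(fit$e0, 308.56, tolerance = 1e-4)
  expect_equal(predict(fit, ts_c = 10), fit$r_ref, tolerance = 1e-9)
  # temperature-insensitive data -> constant model
  flat <- fit_lloyd_taylor(ts, rep(3, 4))
  expect_equal(flat$r_ref, 3, tolerance = 1e-6)
  expect_equal(flat$e0, 0, tolerance = 1e-3)
  expect_error(fit_lloyd_taylor(c(5, 6, 7, 8), 1:4), "span")
  expect_error(fit_lloyd_taylor(c(5, 15, 25), 1:3), ">= 4")
})

test_that("fit matches a brute-force grid-search oracle on noise-free draws", {
  set.seed(11)
  grid_r <- seq(0.2, 8, by = 0.05)
  grid_e <- seq(0, 600, by = 5)
  ts <- seq(4, 20, length.out = 8)
  for (k in 1:20) {
    r_true <- runif(1, 0.5, 5)
    e_true <- runif(1, 100, 500)
    flux <- lloyd_taylor(ts, r_true, e_true)
    fit <- fit_lloyd_taylor(ts, flux)
    sse_fit <- sum((flux - lloyd_taylor(ts, fit$r_ref, fit$e0))^2)
    oracle <- Inf
    for (e in grid_e) {
      g <- lloyd_taylor(ts, 1, e)
      r <- sum(flux * g) / sum(g * g)
      oracle <- min(oracle, sum((flux - r * g)^2))
    }
    expect_lte(sse_fit, oracle + 1e-10)
    expect_equal(fit$r_ref, r_true, tolerance = 1e-4)
    expect_equal(fit$e0, e_true, tolerance = 1e-4)
  }
})

test_that("annual soil respiration integrates the half-hourly series", {
  const_fit <- structure(list(r_ref = 1, e0 = 0, t0_k = 227.13, tref_k = 283.15),
                         class = "lloyd_taylor_fit")
  n <- 365 * 48
  expect_equal(annual_rhs(const_fit, rep(10, n)), 31536000 * 12.011e-6,
               tolerance = 1e-9)
  expect_equal(annual_rhs(const_fit, rep(10, n)), 378.78, tolerance = 1e-4)
  warm <- structure(list(r_ref = 1, e0 = 308.56, t0_k = 227.13, tref_k = 283.15),
                    class = "lloyd_taylor_fit")
  expect_equal(annual_rhs(warm, rep(20, n)), 2.3034 * 378.78, tolerance = 1e-3)
  zero <- structure(list(r_ref = 0, e0 = 300, t0_k = 227.13, tref_k = 283.15),
                    class = "lloyd_taylor_fit")
  expect_equal(annual_rhs(zero, rep(10, n)), 0)
  # monotone in R_ref and in pointwise temperature increase
  ts <- rep(c(0, 5, 10, 15), n / 4)
  r1 <- annual_rhs(warm, ts)
  expect_gt(annual_rhs(warm, ts + 1), r1)
  warm2 <- warm; warm2$r_ref <- 2
  expect_gt(annual_rhs(warm2, ts), r1)
  # gap handling
  gappy <- rep(10, n); gappy[1:100] <- NA
  expect_equal(annual_rhs(const_fit, gappy), 378.78, tolerance = 1e-4)
  gappy[1:(0.2 * n)] <- NA
  expect_error(annual_rhs(const_fit, gappy), "coverage")
})

test_that("dead-wood respiration applies decay constants per pool", {
  k_tab <- list(pine = list(downed = list("2" = 0.04, "3" = 0)))
  pools <- data.frame(species = "pine", position = "downed",
                      decay_class = 2L, carbon_g_m2 = 500)
  expect_equal(annual_rhdw(pools, k_tab), 500 * (1 - exp(-0.04)))
  expect_equal(annual_rhdw(pools, k_tab), 19.61, tolerance = 1e-3)
  expect_equal(annual_rhdw(pools, k_tab, mode = "linear"), 20)
  pools$decay_class <- 3L
  expect_equal(annual_rhdw(pools, k_tab), 0)
  expect_equal(annual_rhdw(pools[0, ], k_tab), 0)
  pools$decay_class <- 5L
  expect_error(annual_rhdw(pools, k_tab), "class 5")
  expect_equal(total_rh(210, 8), 218)
  expect_equal(total_rh(0, 0), 0)
  expect_error(total_rh(-1, 0), ">= 0")
})

test_that("annual RH_s is recovered within 5% from noisy campaigns in most seeds", {
  # plot-specific fit as in the field design: 8 campaigns per year pooled
  # over the three study years, 10% multiplicative flux noise
  ok <- 0
  n_seeds <- 100
  doy <- rep(1:365, each = 48)
  year_off <- c(-0.3, 0, 0.3)
  ts_years <- lapply(year_off, function(o)
    o + 2.4 + 9 * sin(2 * pi * (doy - 120) / 365))
  camp_idx <- (round(seq(125, 298, length.out = 8)) - 1) * 48 + 25
  camp_ts <- unlist(lapply(ts_years, function(s) s[camp_idx]))
  truth_fit <- structure(list(r_ref = 1.8, e0 = 308.56, t0_k = 227.13,
                              tref_k = 283.15), class = "lloyd_taylor_fit")
  rhs_true <- annual_rhs(truth_fit, ts_years[[2]])
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    flux <- predict(truth_fit, ts_c = camp_ts) *
      (1 + rnorm(length(camp_ts), 0, 0.1))
    fit <- try(fit_lloyd_taylor(camp_ts, pmax(flux, 0.01)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rhs_hat <- annual_rhs(fit, ts_years[[2]])
    if (abs(rhs_hat - rhs_true) / rhs_true <= 0.05) ok <- ok + 1
  }
  expect_gte(ok, 0.9 * n_seeds)
})
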