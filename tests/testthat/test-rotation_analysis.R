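test_that("cumulative NEP matches symbolic integration", {
  nep <- function(a) a * (60 - a) / 100
  tr <- cumulative_nep(nep, horizon = 60, step = 0.1)
  # closed form: int_0^45 (60a - a^2)/100 da = 303.75 g C m-2
  at45 <- tr$cumulative_gc_m2[abs(tr$age - 45) < 1e-9]
  expect_equal(at45, 303.75, tolerance = 1e-3)
  expect_equal(tr$cumulative_t_c_ha[abs(tr$age - 45) < 1e-9], 3.0375,
               tolerance = 1e-4)
  # zero curve -> zero trajectory; trajectory starts at 0
  tr0 <- cumulative_nep(function(a) 0 * a, horizon = 10, step = 1)
  expect_true(all(tr0$cumulative_gc_m2 == 0))
  expect_equal(tr$cumulative_gc_m2[1], 0)
  # constant 100 integrated from age 1 -> 900 g C m-2 at age 10
  trc <- cumulative_nep(function(a) rep(100, length(a)), horizon = 10,
                        step = 0.5, from = 1)
  expect_equal(trc$cumulative_gc_m2[trc$age == 10], 900)
  # convergence: halving the step changes the value by <= 0.1%
  fine <- cumulative_nep(nep, horizon = 60, step = 0.05)
  expect_lt(abs(fine$cumulative_gc_m2[abs(fine$age - 45) < 1e-9] - at45) /
              at45, 0.001)
  expect_error(cumulative_nep(nep, horizon = 60, step = 0), "step")
})

test_that("optimum rotation equals the calculus solution and flags flat curves", {
  opt <- optimum_rotation(function(a) a * (60 - a) / 100, horizon = 60)
  expect_equal(opt$optimum_age, 45, tolerance = 0.02)
  expect_false(opt$no_interior_optimum)
  flat <- optimum_rotation(function(a) rep(50, length(a)), horizon = 100,
                           from = 1)
  expect_true(flat$no_interior_optimum)
  expect_equal(flat$optimum_age, 100)
})

test_that("compensation point finds the zero crossing of cumulative NEP", {
  tr <- cumulative_nep(function(a) a - 6, horizon = 20, step = 0.1)
  cp <- compensation_point(tr)
  expect_equal(cp$ccp, 12, tolerance = 0.01)
  expect_true(cp$recovered)
  # never-negative trajectory -> 0
  pos <- cumulative_nep(function(a) rep(5, length(a)), horizon = 20, step = 1)
  expect_equal(compensation_point(pos)$ccp, 0)
  # never-recovering trajectory -> horizon with flag
  sink <- cumulative_nep(function(a) rep(-5, length(a)), horizon = 20, step = 1)
  cp2 <- compensation_point(sink)
  expect_false(cp2$recovered)
  expect_equal(cp2$ccp, 20)
})

test_that("long-term sequestration rate halves the rotation total", {
  lt <- long_term_rate(173, 138)
  expect_equal(lt$lcsr, 86.5)
  expect_equal(lt$harvest_rate, 100 / 138)
  expect_equal(long_term_rate(0, 50)$lcsr, 0)
  expect_equal(long_term_rate(3.0375, 45)$lcsr, 1.51875)
  # sawtooth mode averages the actual trajectory
  tr <- cumulative_nep(function(a) rep(100, length(a)), horizon = 10, step = 0.1)
  st <- long_term_rate(10, 10, mode = "sawtooth", trajectory = tr)
  expect_equal(st$lcsr, 5, tolerance = 0.01)
})

test_that("the MAI-culmination identity holds on random hump-shaped curves", {
  set.seed(3)
  grid <- seq(1, 300, by = 0.01)
  n_ok <- 0; n_curves <- 25
  for (k in seq_len(n_curves)) {
    a_peak <- runif(1, 40, 120)
    peak <- runif(1, 250, 400)
    rh <- runif(1, 120, 200)
    b2 <- runif(1, -0.6, -0.15)
    b1 <- -2 * b2 * log(a_peak)
    b0 <- log(peak) - b1 * log(a_peak) - b2 * log(a_peak)^2
    nep <- function(a) exp(b0 + b1 * log(pmax(a, 1)) +
                             b2 * log(pmax(a, 1))^2) - rh
    opt <- optimum_rotation(nep, horizon = 300, min_age = 1)
    if (opt$no_interior_optimum) next
    # dense-grid oracle: argmax of C(a)/a
    tr <- cumulative_nep(nep, horizon = 300, step = 0.01, min_age = 1)
    mai <- tr$cumulative_gc_m2[-1] / tr$age[-1]
    a_oracle <- tr$age[-1][which.max(mai)]
    expect_lte(abs(opt$optimum_age - a_oracle), 0.5)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 15)  # most draws must yield an interior optimum
})

test_that("rotation summary composes all steps consistently", {
  nep <- function(a) a * (60 - a) / 100
  rs <- rotation_summary(nep, horizon = 60, step = 0.1, from = 0,
                         min_age = NULL)
  expect_equal(rs$optimum_age, 45, tolerance = 0.02)
  expect_equal(rs$cumulative_at_optimum, 3.0375, tolerance = 1e-3)
  expect_equal(rs$lcsr, rs$cumulative_at_optimum / 2)
  expect_equal(rs$ccp, 0)
  expect_output(print(rs), "optimum rotation age")
})
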