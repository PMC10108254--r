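cfg <- sf_config()

test_that("allometric biomass evaluates the ln-linear d/(d+c) family", {
  co <- list(pine = list(stem = list(a = 0, b = 0, c = 12)))
  expect_equal(tree_biomass(7, "pine", "stem", co), 1.0)
  co$pine$stem <- list(a = -2, b = 10, c = 12)
  expect_equal(tree_biomass(12, "pine", "stem", co), exp(3), tolerance = 1e-12)
  expect_equal(tree_biomass(0, "pine", "stem", co), exp(-2), tolerance = 1e-12)
  # strictly increasing in dbh for b > 0
  d <- seq(0, 50, 5)
  expect_true(all(diff(tree_biomass(d, "pine", "stem", co)) > 0))
  expect_error(tree_biomass(10, "pine", "branches", co), "coefficients")
})

test_that("stand pools scale by plot area and are linear in tree count", {
  # two live trees with 20.086 kg aboveground on an r = 10 m plot
  co <- cfg
  co$allometry$pine$stem <- list(a = -2, b = 10, c = 12)      # exp(3) at dbh 12
  co$allometry$pine$branches <- list(a = -40, b = 0, c = 1)   # ~0
  co$allometry$pine$foliage <- list(a = -40, b = 0, c = 1)
  tr <- data.frame(stand_id = "a", tree_id = c("1", "2"), year = 2017L,
                   dbh = 12, species = "pine", status = "live",
                   decay_class = NA_integer_)
  pools <- stand_biomass_pools(tr, 10, co)
  expect_equal(pools$above_live_mg_ha, 2 * exp(3) / (pi * 100) * 10,
               tolerance = 1e-6)
  expect_equal(pools$above_live_mg_ha, 1.2787, tolerance = 1e-4)
  # carbon pool = 50% of dry mass
  expect_equal(pools$above_live_gc_m2, 2 * exp(3) * 0.5 * 1000 / (pi * 100),
               tolerance = 1e-9)
  # doubling identical trees doubles pools
  p2 <- stand_biomass_pools(rbind(tr, transform(tr, tree_id = c("3", "4"))),
                            10, co)
  expect_equal(p2$above_live_mg_ha, 2 * pools$above_live_mg_ha)
  # no trees -> all pools zero
  p0 <- stand_biomass_pools(tr[0, ], 10, co)
  expect_true(all(unlist(p0) == 0))
  # dead tree with density ratio 0.5 -> half the live-equivalent dry pool
  co$dead_wood$density_ratio[["1"]] <- 0.5
  co$dead_wood$c_fraction[["1"]] <- 0.5
  dtr <- transform(tr[1, ], status = "dead_standing", decay_class = 1L)
  pd <- stand_biomass_pools(dtr, 10, co)
  expect_equal(pd$above_dead_mg_ha, pools$above_live_mg_ha / 2 / 2)
  dtr$decay_class <- 99L
  expect_error(stand_biomass_pools(dtr, 10, co), "decay class")
})

test_that("annual increments from inventories and ring widths agree with bookkeeping", {
  inv <- data.frame(stand_id = "a", tree_id = "t1", year = c(2016L, 2018L),
                    dbh = c(10.0, 10.6), species = "pine", status = "live",
                    decay_class = NA_integer_)
  inc <- annual_increment(inv)
  expect_equal(inc$d_dbh_cm_yr, c(0.3, 0.3))
  expect_equal(inc$year, c(2017L, 2018L))
  # constant DBH -> zero
  inv$dbh <- 10
  expect_true(all(annual_increment(inv)$d_dbh_cm_yr == 0))
  # shrinkage beyond tolerance warns and clamps
  inv$dbh <- c(10, 9.5)
  expect_warning(inc <- annual_increment(inv), "shrank")
  expect_true(all(inc$d_dbh_cm_yr == 0))
  # ring width 1.5 mm -> 0.3 cm yr-1 diameter increment, filling extra years
  cores <- data.frame(tree_id = "t1", year = c(2014L, 2015L),
                      ring_width_mm = 1.5)
  inv$dbh <- c(10, 10.6)
  both <- annual_increment(inv, cores)
  expect_equal(both$d_dbh_cm_yr[both$year %in% 2014:2015], c(0.3, 0.3))
})

test_that("tree production arithmetic sums pools, mortality and litterfall", {
  expect_equal(anpp_trees(0, 0, 0), 0)
  expect_equal(anpp_trees(100, 0, 50), 150)
  expect_equal(anpp_trees(80, 20, 40), 140)
  expect_error(anpp_trees(10, -1, 0), ">= 0")
  expect_equal(bnpp_coarse_roots(0, 0), 0)
  expect_equal(bnpp_coarse_roots(30, 5), 35)
  expect_warning(x <- bnpp_coarse_roots(-10, 5), "negative")
  expect_equal(x, -5)  # post-thinning sign pass-through
})

test_that("litterfall scales trap mass to ground area and carbon", {
  expect_equal(litterfall_annual(c(0, 0, 0), 0.25), 0)
  expect_equal(litterfall_annual(c(50, 50, 50), 0.25, c_fraction = 0.5), 100)
  expect_equal(litterfall_annual(0.75, 0.75, 1, c_fraction = 1), 1)
  expect_error(litterfall_annual(numeric(0), 0.25), "n_traps")
})

test_that("clear-cut imputation interpolates initiation-class age relations", {
  ref <- data.frame(age = c(10, 20), l = c(20, 40))
  expect_equal(unname(impute_clearcut_tree_components(15, ref)["l"]), 30)
  expect_equal(unname(impute_clearcut_tree_components(20, ref)["l"]), 40)
  # extrapolation below zero clamps
  ref2 <- data.frame(age = c(10, 20), l = c(5, 40))
  expect_equal(unname(impute_clearcut_tree_components(2, ref2)["l"]), 0)
  expect_error(impute_clearcut_tree_components(5, ref[1, ]), ">= 2")
})
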