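# a reduced landscape design for fast generator-level tests
small_config <- function() {
  sf_config(overrides = list(design = list(
    class_counts = list(initiation = 4, young = 2, middle_aged = 2,
                        mature = 2, old = 2),
    n_pine = 7, n_spruce = 5, n_till = 8, n_sediment = 4,
    n_clearcuts = 1, n_additional_old = 2
  )))
}

test_that("the default design reproduces the 50-stand campaign layout", {
  nf <- noisefree_run()
  st <- nf$gen$bundle$stands
  expect_equal(nrow(st), 50)
  counts <- table(st$age_class)
  expect_equal(unname(counts[c("initiation", "young", "middle_aged",
                               "mature", "old")]), c(8, 9, 13, 14, 6),
               ignore_attr = TRUE)
  expect_equal(sum(st$species_group == "pine"), 28)
  expect_equal(sum(st$species_group == "spruce"), 22)
  expect_equal(sum(st$soil_type == "till"), 35)
  expect_equal(sum(st$soil_type == "sediment"), 15)
  expect_true(all(st$age >= 5 & st$age <= 211))
  # clear-cuts carry no inventoried trees
  expect_length(setdiff(st$stand_id, unique(nf$gen$bundle$trees$stand_id)), 3)
  # truth budgets satisfy the accounting identities exactly
  expect_silent(check_budget_identities(nf$gen$truth$budgets))
})

test_that("the generator is deterministic and supports the empty design", {
  cfg <- small_config()
  g1 <- generate_landscape(cfg, seed = 7)
  g2 <- generate_landscape(cfg, seed = 7)
  expect_identical(g1$bundle, g2$bundle)
  expect_identical(g1$truth$budgets, g2$truth$budgets)
  g3 <- generate_landscape(cfg, seed = 8)
  expect_false(identical(g1$bundle$chambers, g3$bundle$chambers))
  empty_cfg <- sf_config(overrides = list(design = list(
    class_counts = list(initiation = 0, young = 0, middle_aged = 0,
                        mature = 0, old = 0))))
  expect_length(generate_landscape(empty_cfg, seed = 1)$bundle, 0)
  neg_cfg <- sf_config(overrides = list(design = list(
    class_counts = list(initiation = -1, young = 0, middle_aged = 0,
                        mature = 0, old = 0))))
  expect_error(generate_landscape(neg_cfg, seed = 1), "counts")
})

test_that("simulated inventories grow, persist and die as configured", {
  t0 <- data.frame(stand_id = "s", tree_id = c("a", "b"), dbh = c(10, 12),
                   species = "pine")
  # zero growth, zero mortality: identical tables across years
  inv <- simulate_inventories(t0, 2016:2018, growth_cm_yr = 0)
  expect_equal(inv$dbh, rep(c(10, 12), 3))
  expect_true(all(inv$status == "live"))
  # +0.5 cm/yr over 3 years -> d, d + 0.5, d + 1.0
  inv <- simulate_inventories(t0[1, ], 2016:2018, growth_cm_yr = 0.5)
  expect_equal(inv$dbh, c(10, 10.5, 11))
  # DBH non-decreasing for live trees
  expect_true(all(diff(inv$dbh) >= 0))
  # certain mortality: all live trees standing dead with decay class 1
  inv <- simulate_inventories(t0, 2016:2017, growth_cm_yr = 0.2,
                              mortality_prob = 1)
  y2 <- inv[inv$year == 2017, ]
  expect_true(all(y2$status == "dead_standing"))
  expect_true(all(y2$decay_class == 1L))
  expect_error(simulate_inventories(t0, 2016:2018, growth_cm_yr = -1), ">= 0")
})

test_that("simulated chamber campaigns invert to the Lloyd-Taylor fluxes", {
  cfg <- sf_config()
  series <- data.frame(stand_id = "s",
                       timestamp = sprintf("2017-06-01 %02d:00", 0:23),
                       ts_c = 10)
  ch <- simulate_chamber_campaigns("s", r_ref = 2, e0 = 308.56, series,
                                   campaign_idx = c(3, 9, 15), noise_sd = 0,
                                   config = cfg)
  expect_equal(length(unique(ch$campaign_id)), 3)
  for (cid in unique(ch$campaign_id)) {
    cm <- ch[ch$campaign_id == cid, ]
    flux <- chamber_flux(cm$elapsed_s, cm$co2_ppm, cm$ta_bc_c[1],
                         cm$pressure_kpa[1], cfg$chamber$height_m)
    expect_equal(flux, 2, tolerance = 1e-9)  # Ts = T_ref -> R_ref
  }
  series$ts_c <- 20
  ch <- simulate_chamber_campaigns("s", 2, 308.56, series, 5, 0, cfg)
  flux <- chamber_flux(ch$elapsed_s, ch$co2_ppm, ch$ta_bc_c[1],
                       ch$pressure_kpa[1], cfg$chamber$height_m)
  expect_equal(flux, 4.607, tolerance = 1e-3)
  expect_error(simulate_chamber_campaigns("s", 2, 300, series, 99, 0, cfg),
               "coverage")
})

test_that("campaign schedule yields the configured rows per plot-year", {
  nf <- noisefree_run()
  ch <- nf$gen$bundle$chambers
  one <- ch[ch$stand_id == "S10", ]
  expect_equal(length(unique(one$campaign_id)), 8 * 3)  # 8 campaigns x 3 years
})
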