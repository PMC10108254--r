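# End-to-end pipeline: measurement bundle -> per-stand budgets -> class
# summaries, age trends, rotation calculus and driver analysis.

#' Run the full carbon-budget pipeline on a measurement bundle
#'
#' Processes every measurement channel of a bundle (as generated by
#' [generate_landscape()] or read from CSV with [read_bundle()]):
#'
#' 1. tree components per measured stand from repeated inventories and
#'    litter traps; clear-cut stands (no inventoried trees) are imputed
#'    from the age relationships of the measured initiation-class stands;
#' 2. understory production from the reference-year clip harvests, carried
#'    across years with the shrub-increment index;
#' 3. fine-root production from ingrowth cores, scaled across years with
#'    the fixed root-to-shoot ratio and partitioned into understory and
#'    tree shares via the clear-cut-derived ratio `r_u`;
#' 4. plot-specific Lloyd-Taylor fits to the chamber campaigns,
#'    extrapolated to annual soil heterotrophic respiration over the
#'    half-hourly soil-temperature series, plus dead-wood respiration from
#'    pools and decay constants;
#' 5. budget composition, multi-year stand means, age-class summaries,
#'    age-trend fits, the NEP trend curve, rotation analysis, optional
#'    basal-area imputation of additional old stands, and the driver
#'    PCA/correlation analysis.
#'
#' @param bundle Named list of measurement tables ([sf_schemas()] names;
#'   optionally `additional_old`).
#' @param config Configuration list.
#' @param verbose Log per-stage timing to stderr.
#' @return List of class `sf_pipeline`: `budgets`, `mean_budgets`,
#'   `class_summary`, `trend_fits`, `nep_trend`, `rotation`, `r_u`,
#'   `fr_ratio`, `lt_fits`, `old_refs`, `additional_budgets`,
#'   `old_class_augmented`, `pca_primary`, `pca_secondary`, `correlations`.
#' @export
run_pipeline <- function(bundle, config = sf_config(), verbose = FALSE) {
  t0 <- Sys.time()
  log_stage <- function(msg) {
    if (verbose) {
      message(sprintf("[standflux +%5.1fs] %s",
                      as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
    }
  }
  stands <- bundle$stands
  years <- sort(unique(bundle$shrub_index$year))
  cfrac <- config$carbon$live_c_fraction

  # --- tree components ----------------------------------------------------
  log_stage("tree production")
  measured <- intersect(stands$stand_id, unique(bundle$trees$stand_id))
  clearcuts <- setdiff(stands$stand_id, measured)
  tree_comp <- list()
  for (sid in measured) {
    tr <- bundle$trees[bundle$trees$stand_id == sid, ]
    lt <- bundle$litter[bundle$litter$stand_id == sid, ]
    radius <- stands$plot_radius[stands$stand_id == sid]
    res <- tree_npp_for_stand(tr, lt, radius, config)
    res$stand_id <- sid
    tree_comp[[sid]] <- res[res$year %in% years, ]
  }
  tree_comp <- do.call(rbind, tree_comp)

  # clear-cut imputation from measured initiation stands, per year
  init_ids <- stands$stand_id[stands$age_class == "initiation" &
                                stands$stand_id %in% measured]
  for (sid in clearcuts) {
    age <- stands$age[stands$stand_id == sid]
    for (y in years) {
      ref <- tree_comp[tree_comp$stand_id %in% init_ids & tree_comp$year == y, ]
      imp <- impute_clearcut_tree_components(
        age, data.frame(age = stands$age[match(ref$stand_id, stands$stand_id)],
                        anpp_t = ref$anpp_t, l = ref$l,
                        bnpp_t_cr = ref$bnpp_t_cr))
      tree_comp <- rbind(tree_comp, data.frame(
        year = y, delta_b_above = NA_real_, mort_above = NA_real_,
        l = imp[["l"]], delta_b_cr = NA_real_, mort_cr = NA_real_,
        anpp_t = imp[["anpp_t"]], bnpp_t_cr = imp[["bnpp_t_cr"]],
        stand_id = sid, stringsAsFactors = FALSE
      ))
    }
  }

  # --- understory production ----------------------------------------------
  log_stage("understory production")
  ref_year <- sort(unique(bundle$understory$year))[1]
  und <- list()
  for (sid in stands$stand_id) {
    h <- bundle$understory[bundle$understory$stand_id == sid &
                             bundle$understory$year == ref_year, ]
    a_ref <- anpp_understory(h, cfrac)
    si <- bundle$shrub_index[bundle$shrub_index$stand_id == sid, ]
    idx_ref <- si$index[si$year == ref_year]
    for (y in years) {
      und[[length(und) + 1]] <- data.frame(
        stand_id = sid, year = y,
        anpp_u = interannual_understory_scaling(a_ref, si$index[si$year == y],
                                                idx_ref),
        stringsAsFactors = FALSE
      )
    }
  }
  und <- do.call(rbind, und)

  # --- fine-root production and partitioning ------------------------------
  log_stage("fine roots")
  core_year <- max(years)
  comp <- merge(tree_comp[c("stand_id", "year", "anpp_t", "l", "bnpp_t_cr")],
                und, by = c("stand_id", "year"))
  comp$anpp <- comp$anpp_t + comp$anpp_u
  fr <- vapply(stands$stand_id, function(sid) {
    bnpp_fineroot_from_ingrowth(
      bundle$ingrowth[bundle$ingrowth$stand_id == sid, ], cfrac)
  }, numeric(1))
  ratio <- fr / comp$anpp[match(paste(stands$stand_id, core_year),
                                paste(comp$stand_id, comp$year))]
  names(ratio) <- stands$stand_id
  comp$bnpp_fr <- apply_root_to_shoot_scaling(comp$anpp, ratio[comp$stand_id])
  cc18 <- match(paste(clearcuts, core_year), paste(comp$stand_id, comp$year))
  r_u <- derive_clearcut_root_ratio(data.frame(
    bnpp_fr = comp$bnpp_fr[cc18], anpp_u = comp$anpp_u[cc18]))
  part <- partition_bnpp(comp$bnpp_fr, comp$anpp_u, r_u)
  comp$bnpp_u <- part$bnpp_u
  comp$bnpp_t_fr <- part$bnpp_t_fr

  # --- heterotrophic respiration ------------------------------------------
  log_stage("chamber fluxes and Lloyd-Taylor fits")
  ch_cfg <- config$chamber
  lt_cfg <- config$lloyd_taylor
  st_year <- substr(bundle$soiltemp$timestamp, 1, 4)
  lt_fits <- list()
  rh_rows <- list()
  for (sid in stands$stand_id) {
    ch <- bundle$chambers[bundle$chambers$stand_id == sid, ]
    pts <- do.call(rbind, lapply(split(ch, ch$campaign_id), function(cm) {
      data.frame(ts_c = cm$ts_c[1], flux = chamber_flux(
        cm$elapsed_s, cm$co2_ppm, cm$ta_bc_c[1], cm$pressure_kpa[1],
        ch_cfg$height_m, ch_cfg$deadband_s, ch_cfg$min_points))
    }))
    fit <- fit_lloyd_taylor(pts$ts_c, pts$flux, lt_cfg$t0_k, lt_cfg$tref_k,
                            unlist(lt_cfg$e0_grid))
    lt_fits[[sid]] <- fit
    dw <- bundle$deadwood[bundle$deadwood$stand_id == sid, ]
    rh_dw <- annual_rhdw(dw, config$decay_constants, config$rh_dw_mode)
    sel_stand <- bundle$soiltemp$stand_id == sid
    for (y in years) {
      ts_y <- bundle$soiltemp$ts_c[sel_stand & st_year == as.character(y)]
      rh_rows[[length(rh_rows) + 1]] <- data.frame(
        stand_id = sid, year = y,
        rh_s = annual_rhs(fit, ts_y,
                          max_gap_fraction = config$soil_temp$max_gap_fraction),
        rh_dw = rh_dw, stringsAsFactors = FALSE
      )
    }
  }
  rh_tab <- do.call(rbind, rh_rows)

  # --- budgets -------------------------------------------------------------
  log_stage("budget composition")
  comp <- merge(comp, rh_tab, by = c("stand_id", "year"))
  budgets <- do.call(rbind, lapply(seq_len(nrow(comp)), function(j) {
    compose_budget(comp$stand_id[j], comp$year[j],
                   anpp_t = comp$anpp_t[j], l = comp$l[j],
                   bnpp_t_cr = comp$bnpp_t_cr[j],
                   bnpp_t_fr = comp$bnpp_t_fr[j], anpp_u = comp$anpp_u[j],
                   bnpp_u = comp$bnpp_u[j], rh_s = comp$rh_s[j],
                   rh_dw = comp$rh_dw[j])
  }))
  budgets <- budgets[order(budgets$stand_id, budgets$year), ]
  mean_budgets <- stand_mean_budgets(budgets)
  class_summary <- class_aggregate(mean_budgets, stands)

  # --- age trends and rotation --------------------------------------------
  log_stage("age trends and rotation")
  age <- stands$age[match(mean_budgets$stand_id, stands$stand_id)]
  if (!isTRUE(config$trend$include_thinned)) {
    thin <- attr(bundle, "thinned_id")
    keep <- !mean_budgets$stand_id %in% thin
  } else keep <- rep(TRUE, nrow(mean_budgets))
  fit_set <- mean_budgets[keep, ]
  fit_age <- pmax(age[keep], 1)
  trend_fits <- list(
    npp = fit_log_quadratic(fit_age, fit_set$npp),
    npp_t = fit_log_quadratic(fit_age, fit_set$npp_t),
    npp_u = fit_log_quadratic(fit_age, fit_set$npp_u),
    rh_dw = fit_log_quadratic(fit_age, fit_set$rh_dw),
    rh = fit_poly2(fit_age, fit_set$rh, config$trend$rh_poly_in_log_age),
    rh_s = fit_poly2(fit_age, fit_set$rh_s, config$trend$rh_poly_in_log_age)
  )
  nep_fn <- nep_trend(trend_fits$npp, trend_fits$rh)
  rotation <- rotation_summary(
    nep_fn, horizon = config$rotation$horizon_yr,
    step = config$rotation$step_yr, from = 0,
    min_age = config$rotation$min_age_yr,
    lcsr_mode = if (config$rotation$lcsr_mode == "half") "half" else "sawtooth"
  )

  # --- additional old stands via basal-area references --------------------
  old_refs <- additional_budgets <- old_class_augmented <- NULL
  if (!is.null(bundle$additional_old) && nrow(bundle$additional_old)) {
    log_stage("old-stand imputation")
    ba_main <- bundle$drivers$ba[match(mean_budgets$stand_id,
                                       bundle$drivers$stand_id)]
    old_refs <- build_old_stand_references(mean_budgets, ba_main)
    ao <- bundle$additional_old
    additional_budgets <- do.call(rbind, lapply(seq_len(nrow(ao)), function(j) {
      suppressWarnings(impute_old_stand_budget(
        ao$stand_id[j], 0L, ao$ba[j], ao$anpp_t[j], ao$bnpp_t_cr[j],
        old_refs, ao$rh_dw_standing[j]))
    }))
    old_ids <- stands$stand_id[stands$age_class == "old"]
    nep_old <- c(mean_budgets$nep[mean_budgets$stand_id %in% old_ids],
                 additional_budgets$nep)
    n_old <- length(nep_old)
    old_class_augmented <- data.frame(
      age_class = "old", flux = "nep", n = n_old, mean = mean(nep_old),
      ci95_half_width = if (n_old >= 2)
        stats::qt(0.975, n_old - 1) * stats::sd(nep_old) / sqrt(n_old)
      else NA_real_
    )
  }

  # --- driver analysis -----------------------------------------------------
  log_stage("driver PCA and correlations")
  drv <- merge(bundle$drivers, mean_budgets, by = "stand_id")
  drv$age_class <- stands$age_class[match(drv$stand_id, stands$stand_id)]
  driver_vars <- c("slope", "ns_aspect", "ew_aspect", "b_t", "lai_max",
                   "o_depth", "cn_ratio", "bd")
  pca_primary <- pca_varimax(drv[c(driver_vars, "npp", "npp_t", "npp_u",
                                   "rh", "rh_s", "rh_dw", "nep")])
  pca_secondary <- pca_varimax(drv[c(driver_vars, "npp_t")])
  correlations <- pearson_by_class(drv, c("nep", "npp_t"),
                                   c(driver_vars, "swc", "ts", "soc", "ba"),
                                   group = "age_class")
  log_stage("done")
  structure(list(
    budgets = budgets, mean_budgets = mean_budgets,
    class_summary = class_summary, trend_fits = trend_fits,
    nep_trend = nep_fn, rotation = rotation,
    r_u = r_u, fr_ratio = ratio, lt_fits = lt_fits,
    old_refs = old_refs, additional_budgets = additional_budgets,
    old_class_augmented = old_class_augmented,
    pca_primary = pca_primary, pca_secondary = pca_secondary,
    correlations = correlations
  ), class = "sf_pipeline")
}

#' @export
print.sf_pipeline <- function(x, ...) {
  cat("standflux pipeline result:", nrow(x$mean_budgets), "stands,",
      nrow(x$budgets), "stand-years\n")
  nep <- x$class_summary[x$class_summary$flux == "nep", ]
  cat("class-mean NEP (g C m-2 yr-1):\n")
  for (i in seq_len(nrow(nep))) {
    cat(sprintf("  %-12s %6.1f +/- %5.1f (n = %d)\n", nep$age_class[i],
                nep$mean[i], nep$ci95_half_width[i], nep$n[i]))
  }
  print(x$rotation)
  invisible(x)
}
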