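# Tree NPP components: allometric biomass, increments, mortality transfers,
# litterfall, and age-based imputation for recent clear-cuts.

#' Allometric single-tree biomass
#'
#' Evaluates the DBH-driven allometric family
#' `ln(B_kg) = a + b * d / (d + c)` for one biomass component of one species,
#' the standard form of Fennoscandian single-tree biomass equations.
#' Coefficients are configuration, not results: ship your regional values in
#' the `allometry` block of the config file.
#'
#' @param dbh Diameter at breast height, cm (vectorised).
#' @param species One of `pine`, `spruce`, `birch`, `other_deciduous`.
#' @param component One of `stem`, `branches`, `foliage`, `coarse_roots`.
#' @param coeffs Allometry table, `sf_config()$allometry`.
#' @return Dry mass in kg (same length as `dbh`).
#' @export
#' @examples
#' cfg <- sf_config()
#' tree_biomass(20, "pine", "stem", cfg$allometry)
tree_biomass <- function(dbh, species, component, coeffs) {
  if (any(dbh < 0)) stop("dbh must be >= 0")
  co <- coeffs[[species]][[component]]
  if (is.null(co)) {
    stop("no allometric coefficients for (", species, ", ", component, ")")
  }
  if (co$c <= 0) stop("allometry shape parameter c must be > 0")
  exp(co$a + co$b * dbh / (dbh + co$c))
}

ABOVE_COMPONENTS <- c("stem", "branches", "foliage")

tree_biomass_above <- function(dbh, species, coeffs) {
  Reduce(`+`, lapply(ABOVE_COMPONENTS, function(cp) tree_biomass(dbh, species, cp, coeffs)))
}

tree_biomass_below <- function(dbh, species, coeffs) {
  tree_biomass(dbh, species, "coarse_roots", coeffs)
}

#' Stand-level biomass pools from a single inventory
#'
#' Sums allometric per-tree masses over all trees recorded in one stand-year
#' and scales to ground area (circular plot, area `pi * r^2`). Live biomass is
#' converted to carbon with the live C fraction (default 50%); dead trees are
#' first scaled by the decay-class density ratio and then by the decay-class
#' C fraction.
#'
#' @param trees Tree observations for a single stand and year (columns
#'   `dbh`, `species`, `status`, `decay_class`).
#' @param plot_radius Plot radius in m.
#' @param config Configuration list.
#' @return One-row data frame with dry-mass pools in Mg ha-1
#'   (`*_mg_ha`) and carbon pools in g C m-2 (`*_gc_m2`) for
#'   above/below x live/dead.
#' @export
stand_biomass_pools <- function(trees, plot_radius, config = sf_config()) {
  area_m2 <- pi * plot_radius^2
  coeffs <- config$allometry
  zero <- list(above_live = 0, below_live = 0, above_dead = 0, below_dead = 0)
  dry_kg <- zero  # dry mass on the plot, kg
  c_kg <- zero    # carbon on the plot, kg
  if (nrow(trees)) {
    if (length(unique(trees$stand_id)) > 1 || length(unique(trees$year)) > 1) {
      stop("stand_biomass_pools expects trees from a single stand-year")
    }
    for (i in seq_len(nrow(trees))) {
      ab <- tree_biomass_above(trees$dbh[i], trees$species[i], coeffs)
      be <- tree_biomass_below(trees$dbh[i], trees$species[i], coeffs)
      if (trees$status[i] == "live") {
        dry_kg$above_live <- dry_kg$above_live + ab
        dry_kg$below_live <- dry_kg$below_live + be
        c_kg$above_live <- c_kg$above_live + ab * config$carbon$live_c_fraction
        c_kg$below_live <- c_kg$below_live + be * config$carbon$live_c_fraction
      } else {
        cls <- as.character(trees$decay_class[i])
        dens <- config$dead_wood$density_ratio[[cls]]
        cfr <- config$dead_wood$c_fraction[[cls]]
        if (is.null(dens) || is.null(cfr)) stop("unknown decay class: ", cls)
        dry_kg$above_dead <- dry_kg$above_dead + ab * dens
        dry_kg$below_dead <- dry_kg$below_dead + be * dens
        c_kg$above_dead <- c_kg$above_dead + ab * dens * cfr
        c_kg$below_dead <- c_kg$below_dead + be * dens * cfr
      }
    }
  }
  out <- list()
  for (nm in names(zero)) {
    out[[paste0(nm, "_mg_ha")]] <- dry_kg[[nm]] / area_m2 * 10  # kg m-2 -> Mg ha-1
    out[[paste0(nm, "_gc_m2")]] <- c_kg[[nm]] / area_m2 * 1000  # kg m-2 -> g m-2
  }
  as.data.frame(out)
}

#' Per-tree annual DBH increments
#'
#' Derives annual diameter increments from repeated inventories (linear
#' interpolation between consecutive inventory years) and, where supplied,
#' from increment-core ring widths (one ring per year; diameter increment is
#' twice the ring width). Core-based increments fill years that the
#' inventories do not cover. Live-tree increments are non-negative; apparent
#' shrinkage beyond the tolerance triggers a warning and is clamped to zero
#' (small negative readings are measurement jitter).
#'
#' @param inventories Tree observations across >= 2 years for one stand.
#' @param cores Optional data frame (`tree_id`, `year`, `ring_width_mm`).
#' @param tolerance_cm Allowed apparent shrinkage before warning (default 0.1).
#' @return Data frame (`tree_id`, `year`, `d_dbh_cm_yr`) where `year` is the
#'   year the increment accrued.
#' @export
annual_increment <- function(inventories, cores = NULL, tolerance_cm = 0.1) {
  out <- list()
  for (id in unique(inventories$tree_id)) {
    tr <- inventories[inventories$tree_id == id, ]
    tr <- tr[order(tr$year), ]
    if (nrow(tr) >= 2) {
      for (k in seq_len(nrow(tr) - 1)) {
        span <- tr$year[k + 1] - tr$year[k]
        inc <- (tr$dbh[k + 1] - tr$dbh[k]) / span
        if (inc < 0) {
          if (-inc * span > tolerance_cm) {
            warning("tree ", id, ": DBH shrank ", round(-inc * span, 2),
                    " cm between ", tr$year[k], " and ", tr$year[k + 1],
                    "; increment clamped to 0")
          }
          inc <- 0
        }
        out[[length(out) + 1]] <- data.frame(
          tree_id = id, year = (tr$year[k] + 1):tr$year[k + 1],
          d_dbh_cm_yr = inc
        )
      }
    }
  }
  inv_inc <- if (length(out)) do.call(rbind, out) else
    data.frame(tree_id = character(), year = integer(), d_dbh_cm_yr = numeric())
  if (!is.null(cores) && nrow(cores)) {
    core_inc <- data.frame(
      tree_id = cores$tree_id, year = cores$year,
      d_dbh_cm_yr = 2 * cores$ring_width_mm / 10  # mm radius -> cm diameter
    )
    have <- paste(inv_inc$tree_id, inv_inc$year)
    core_inc <- core_inc[!paste(core_inc$tree_id, core_inc$year) %in% have, ]
    inv_inc <- rbind(inv_inc, core_inc)
  }
  if (nrow(inv_inc) == 0 && is.null(cores)) {
    stop("annual_increment needs >= 2 inventory years or a core series")
  }
  inv_inc[order(inv_inc$tree_id, inv_inc$year), , drop = FALSE]
}

#' Aboveground tree NPP from pools, mortality and litterfall
#'
#' `ANPP_t = dB_live_above + mortality_above + L`: the annual change in the
#' live aboveground biomass pool, plus the biomass of trees that died during
#' the year (their growth happened, and the same mass simultaneously enters
#' the dead-wood pool), plus annual litterfall.
#'
#' Negative live-pool changes (e.g. after thinning) are passed through with a
#' warning rather than clamped; harvest removals should be accounted
#' explicitly where known.
#'
#' @param delta_b_live_above Annual change in live aboveground biomass,
#'   g C m-2 yr-1 (may be negative after harvest).
#' @param mortality_above Aboveground biomass of trees dying in the year,
#'   g C m-2 yr-1 (>= 0).
#' @param l Litterfall, g C m-2 yr-1 (>= 0).
#' @return ANPP_t in g C m-2 yr-1.
#' @export
anpp_trees <- function(delta_b_live_above, mortality_above, l) {
  if (any(mortality_above < 0) || any(l < 0)) {
    stop("mortality_above and l must be >= 0")
  }
  if (any(delta_b_live_above < 0)) {
    warning("negative live aboveground pool change passed through ",
            "(thinning/harvest?)")
  }
  delta_b_live_above + mortality_above + l
}

#' Coarse-root tree NPP
#'
#' As [anpp_trees()] without the litterfall term:
#' `BNPP_t-cr = dB_cr_live + mortality_cr`.
#'
#' @param delta_b_cr_live Annual change in live coarse-root biomass,
#'   g C m-2 yr-1.
#' @param mortality_cr Coarse-root biomass of trees dying in the year (>= 0).
#' @return BNPP_t-cr in g C m-2 yr-1.
#' @export
bnpp_coarse_roots <- function(delta_b_cr_live, mortality_cr) {
  if (any(mortality_cr < 0)) stop("mortality_cr must be >= 0")
  if (any(delta_b_cr_live < 0)) {
    warning("negative live coarse-root pool change passed through")
  }
  delta_b_cr_live + mortality_cr
}

#' Annual litterfall from trap collections
#'
#' Scales the total annual dry mass caught in the stand's funnel traps to
#' ground area and converts to carbon:
#' `L = C_fraction * total_mass / (n_traps * trap_area)`.
#'
#' @param trap_masses_g Vector of per-trap annual dry masses, g.
#' @param trap_area_m2 Area of one trap, m2 (> 0).
#' @param n_traps Number of traps (>= 1); defaults to `length(trap_masses_g)`.
#' @param c_fraction Carbon fraction of litter dry mass.
#' @return L in g C m-2 yr-1.
#' @export
#' @examples
#' litterfall_annual(c(40, 50, 60), 0.25)  # 100 g C m-2 yr-1
litterfall_annual <- function(trap_masses_g, trap_area_m2 = 0.25,
                              n_traps = length(trap_masses_g),
                              c_fraction = 0.5) {
  if (n_traps < 1 || trap_area_m2 <= 0) {
    stop("need n_traps >= 1 and trap_area_m2 > 0")
  }
  if (any(trap_masses_g < 0)) stop("trap masses must be >= 0")
  c_fraction * sum(trap_masses_g) / (n_traps * trap_area_m2)
}

#' Impute tree components for recent clear-cuts from the initiation class
#'
#' Recent clear-cuts carry no inventoried trees (all DBH < 3 cm), so their
#' annual tree biomass production and litterfall are predicted from the
#' age-relationships of those components across the measured stands of the
#' initiation age class: a straight-line fit in age per component, clamped at
#' zero (production cannot be negative).
#'
#' @param age Clear-cut stand age, years.
#' @param reference Data frame of initiation-class stands: column `age` plus
#'   one numeric column per component to impute.
#' @return Named numeric vector of imputed component values (g C m-2 yr-1).
#' @export
#' @examples
#' ref <- data.frame(age = c(10, 20), l = c(20, 40))
#' impute_clearcut_tree_components(15, ref)  # l = 30
impute_clearcut_tree_components <- function(age, reference) {
  if (nrow(reference) < 2) {
    stop("need >= 2 initiation-class reference stands for clear-cut imputation")
  }
  comps <- setdiff(names(reference), "age")
  out <- vapply(comps, function(cp) {
    fit <- stats::lm(reference[[cp]] ~ reference$age)
    pred <- sum(stats::coef(fit) * c(1, age))
    max(pred, 0)
  }, numeric(1))
  stats::setNames(out, comps)
}

# Per-stand tree NPP components from inventories + litter traps, by cohort
# accounting over consecutive inventory pairs:
#   survivors  (live -> live)    : growth B(d1) - B(d0) enters the live pool
#                                  change;
#   deaths     (live -> dead)    : biomass at death counts toward NPP (the
#                                  growth happened) and simultaneously enters
#                                  the dead-wood pool;
#   removals   (live -> absent)  : harvested; excluded from production (their
#                                  removal-year growth is unknown);
#   recruits   (absent -> live)  : full biomass at first inventory counted as
#                                  ingrowth production.
# Returns one row per budget year with live-pool changes, mortality
# transfers, litterfall, ANPP_t and BNPP_t-cr (all g C m-2 yr-1).
tree_npp_for_stand <- function(trees, litter, plot_radius,
                               config = sf_config(),
                               mortality_in_npp = TRUE) {
  years <- sort(unique(trees$year))
  if (length(years) < 2) stop("need >= 2 inventory years")
  area_m2 <- pi * plot_radius^2
  coeffs <- config$allometry
  cfrac <- config$carbon$live_c_fraction
  mass_c <- function(tr, fun) {
    if (!nrow(tr)) return(0)
    sum(mapply(function(d, s) fun(d, s, coeffs), tr$dbh, tr$species)) *
      cfrac * 1000 / area_m2
  }
  out <- list()
  for (k in seq_len(length(years) - 1)) {
    y0 <- years[k]; y1 <- years[k + 1]
    prev <- trees[trees$year == y0 & trees$status == "live", ]
    cur <- trees[trees$year == y1, ]
    surv <- intersect(prev$tree_id, cur$tree_id[cur$status == "live"])
    died <- intersect(prev$tree_id, cur$tree_id[cur$status != "live"])
    recruits <- setdiff(cur$tree_id[cur$status == "live"], prev$tree_id)
    d_above <- mass_c(cur[cur$tree_id %in% surv, ], tree_biomass_above) -
      mass_c(prev[prev$tree_id %in% surv, ], tree_biomass_above) +
      mass_c(cur[cur$tree_id %in% recruits, ], tree_biomass_above)
    d_below <- mass_c(cur[cur$tree_id %in% surv, ], tree_biomass_below) -
      mass_c(prev[prev$tree_id %in% surv, ], tree_biomass_below) +
      mass_c(cur[cur$tree_id %in% recruits, ], tree_biomass_below)
    mort_above <- mort_below <- 0
    if (length(died) && mortality_in_npp) {
      dtr <- cur[cur$tree_id %in% died, ]
      mort_above <- mass_c(dtr, tree_biomass_above)
      mort_below <- mass_c(dtr, tree_biomass_below)
    }
    lt <- litter[litter$year == y1, ]
    l_flux <- if (nrow(lt)) {
      litterfall_annual(lt$dry_mass_g, config$litter$trap_area_m2,
                        nrow(lt), cfrac)
    } else 0
    span <- y1 - y0
    out[[k]] <- data.frame(
      year = y1,
      delta_b_above = d_above / span,
      mort_above = mort_above / span,
      l = l_flux,
      delta_b_cr = d_below / span,
      mort_cr = mort_below / span
    )
  }
  res <- do.call(rbind, out)
  res$anpp_t <- suppressWarnings(anpp_trees(res$delta_b_above, res$mort_above, res$l))
  res$bnpp_t_cr <- suppressWarnings(bnpp_coarse_roots(res$delta_b_cr, res$mort_cr))
  res
}
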