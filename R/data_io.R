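#' @keywords internal
"_PACKAGE"

# Canonical column order for budget tables; ANPP_t includes litterfall (L is
# reported alongside as an informational sub-component).
BUDGET_COLS <- c(
  "stand_id", "year",
  "anpp_t", "l", "bnpp_t_cr", "bnpp_t_fr", "npp_t",
  "anpp_u", "bnpp_u", "npp_u", "bnpp_fr",
  "npp", "rh_s", "rh_dw", "rh", "nep"
)

AGE_CLASSES <- c("initiation", "young", "middle_aged", "mature", "old")
SPECIES_GROUPS <- c("pine", "spruce")
TREE_SPECIES <- c("pine", "spruce", "birch", "other_deciduous")
SOIL_TYPES <- c("till", "sediment")
TREE_STATUS <- c("live", "dead_standing", "dead_downed")
PFTS <- c("herbs", "shrubs", "mosses", "lichens")

#' Load the pipeline configuration
#'
#' Reads the package's default YAML configuration and optionally merges a
#' user file and/or an override list on top of it. The configuration holds
#' every constant that the carbon-budget pipeline takes from cited
#' literature (allometric coefficients, decay-class wood density and carbon
#' fractions, dead-wood decomposition rate constants) together with
#' measurement-protocol constants (plot radius, litter-trap geometry,
#' chamber dimensions, Lloyd-Taylor reference temperatures) and the
#' synthetic-landscape design.
#'
#' @param path Optional path to a YAML file; its entries replace the
#'   defaults key-by-key (nested lists are merged recursively).
#' @param overrides Optional named list merged last, highest precedence.
#' @return A nested list of configuration values.
#' @export
#' @examples
#' cfg <- sf_config()
#' cfg$litter$trap_area_m2
sf_config <- function(path = NULL, overrides = list()) {
  default_path <- system.file("extdata", "config.yaml", package = "standflux")
  cfg <- yaml::read_yaml(default_path)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) cfg <- modify_list_deep(cfg, overrides)
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) && !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Table schemas for all pipeline inputs and outputs
#'
#' Returns the column names and types of every CSV table the pipeline reads
#' or writes. Units are fixed per column (cm for DBH, g dry mass for trap and
#' core collections, g C m-2 yr-1 for fluxes, Mg ha-1 for stocks); no unit
#' autodetection is performed.
#'
#' @return Named list; each element has `cols` (named character vector of
#'   types: character/integer/numeric) and optionally a row validator.
#' @export
sf_schemas <- function() {
  list(
    stands = list(cols = c(
      stand_id = "character", age = "integer", age_class = "character",
      species_group = "character", soil_type = "character",
      plot_radius = "numeric"
    )),
    trees = list(cols = c(
      stand_id = "character", tree_id = "character", year = "integer",
      dbh = "numeric", species = "character", status = "character",
      decay_class = "integer"
    )),
    litter = list(cols = c(
      stand_id = "character", year = "integer", trap_id = "character",
      dry_mass_g = "numeric"
    )),
    understory = list(cols = c(
      stand_id = "character", year = "integer", month = "character",
      pft = "character", dry_mass_g_m2 = "numeric"
    )),
    shrub_index = list(cols = c(
      stand_id = "character", year = "integer", index = "numeric"
    )),
    ingrowth = list(cols = c(
      stand_id = "character", core_id = "character", diameter_cm = "numeric",
      depth_cm = "numeric", span_yr = "numeric", ingrowth_dry_mass_g = "numeric"
    )),
    deadwood = list(cols = c(
      stand_id = "character", position = "character", species = "character",
      decay_class = "integer", carbon_g_m2 = "numeric"
    )),
    chambers = list(cols = c(
      stand_id = "character", campaign_id = "character", timestamp = "character",
      elapsed_s = "numeric", co2_ppm = "numeric", ts_c = "numeric",
      swc_pct = "numeric", ta_bc_c = "numeric", pressure_kpa = "numeric"
    )),
    soiltemp = list(cols = c(
      stand_id = "character", timestamp = "character", ts_c = "numeric"
    )),
    drivers = list(cols = c(
      stand_id = "character", slope = "numeric", ns_aspect = "numeric",
      ew_aspect = "numeric", b_t = "numeric", lai_max = "numeric",
      o_depth = "numeric", cn_ratio = "numeric", bd = "numeric",
      swc = "numeric", ts = "numeric", soc = "numeric", ba = "numeric"
    )),
    budgets = list(cols = stats::setNames(
      c("character", "integer", rep("numeric", length(BUDGET_COLS) - 2L)),
      BUDGET_COLS
    ))
  )
}

#' Read a typed pipeline table from CSV
#'
#' Reads one of the pipeline's CSV tables, checks the header against the
#' schema, coerces column types, and validates field invariants row by row.
#' Row order is preserved.
#'
#' @param path CSV file path.
#' @param table Schema name, one of `names(sf_schemas())`.
#' @param config Configuration list from [sf_config()] (used for bounds such
#'   as age-class limits).
#' @return A `data.frame` with one validated row per input record.
#' @export
read_table <- function(path, table, config = sf_config()) {
  schemas <- sf_schemas()
  if (!table %in% names(schemas)) stop("unknown table schema: ", table)
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- schemas[[table]]$cols
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    raw <- df[[col]]
    if (type == "character") next
    suppressWarnings(val <- as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      stop("unparseable value in ", basename(path), " column '", col,
           "' line ", bad[1] + 1L, ": '", raw[bad[1]], "'")
    }
    df[[col]] <- if (type == "integer") as.integer(round(val)) else val
  }
  validate_table(df, table, config)
  df
}

#' Write a typed pipeline table to CSV
#'
#' @param df Data frame matching the schema.
#' @param path Output path.
#' @param table Schema name.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, table) {
  schema <- sf_schemas()[[table]]$cols
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("cannot write ", table, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  utils::write.csv(df[names(schema)], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_table <- function(df, table, config = sf_config()) {
  ctx <- function(i) {
    id <- if ("stand_id" %in% names(df)) df$stand_id[i] else "?"
    paste0(" (stand_id=", id, ", row ", i, ")")
  }
  fail <- function(i, msg) stop(table, " validation: ", msg, ctx(i))
  nonneg <- function(col) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) fail(bad[1], paste0(col, " must be >= 0, got ", df[[col]][bad[1]]))
  }
  switch(table,
    stands = {
      nonneg("age")
      bad <- which(!df$age_class %in% AGE_CLASSES)
      if (length(bad)) fail(bad[1], paste0("unknown age_class '", df$age_class[bad[1]], "'"))
      bad <- which(!df$species_group %in% SPECIES_GROUPS)
      if (length(bad)) fail(bad[1], paste0("unknown species_group '", df$species_group[bad[1]], "'"))
      bad <- which(!df$soil_type %in% SOIL_TYPES)
      if (length(bad)) fail(bad[1], paste0("unknown soil_type '", df$soil_type[bad[1]], "'"))
      bad <- which(df$plot_radius <= 0)
      if (length(bad)) fail(bad[1], "plot_radius must be > 0")
      expected <- classify_age(df$age, config)
      bad <- which(df$age_class != expected)
      if (length(bad)) {
        fail(bad[1], paste0("age ", df$age[bad[1]], " inconsistent with class '",
                            df$age_class[bad[1]], "' (expected '", expected[bad[1]], "')"))
      }
    },
    trees = {
      bad <- which(!df$species %in% TREE_SPECIES)
      if (length(bad)) fail(bad[1], paste0("unknown species '", df$species[bad[1]], "'"))
      bad <- which(!df$status %in% TREE_STATUS)
      if (length(bad)) fail(bad[1], paste0("unknown status '", df$status[bad[1]], "'"))
      min_dbh <- config$inventory$min_dbh_cm
      bad <- which(df$dbh < min_dbh)
      if (length(bad)) fail(bad[1], paste0("dbh ", df$dbh[bad[1]], " below inventory threshold ", min_dbh))
      bad <- which(df$status == "live" & !is.na(df$decay_class))
      if (length(bad)) fail(bad[1], "live tree must not carry a decay_class")
      bad <- which(df$status != "live" & is.na(df$decay_class))
      if (length(bad)) fail(bad[1], "dead tree must carry a decay_class")
    },
    litter = nonneg("dry_mass_g"),
    understory = {
      nonneg("dry_mass_g_m2")
      bad <- which(!df$pft %in% PFTS)
      if (length(bad)) fail(bad[1], paste0("unknown pft '", df$pft[bad[1]], "'"))
      bad <- which(!df$month %in% c("june", "august"))
      if (length(bad)) fail(bad[1], paste0("month must be june/august, got '", df$month[bad[1]], "'"))
    },
    shrub_index = {
      bad <- which(df$index <= 0)
      if (length(bad)) fail(bad[1], "shrub index must be > 0")
    },
    ingrowth = {
      nonneg("ingrowth_dry_mass_g")
      for (col in c("diameter_cm", "depth_cm", "span_yr")) {
        bad <- which(df[[col]] <= 0)
        if (length(bad)) fail(bad[1], paste0(col, " must be > 0"))
      }
    },
    deadwood = {
      nonneg("carbon_g_m2")
      bad <- which(!df$position %in% c("standing", "downed"))
      if (length(bad)) fail(bad[1], paste0("position must be standing/downed, got '", df$position[bad[1]], "'"))
    },
    chambers = NULL,
    soiltemp = NULL,
    drivers = {
      bad <- which(abs(df$ns_aspect) > 1 | abs(df$ew_aspect) > 1)
      if (length(bad)) fail(bad[1], "aspect components must lie in [-1, 1]")
      for (col in c("slope", "b_t", "lai_max", "o_depth", "cn_ratio", "bd",
                    "swc", "soc", "ba")) nonneg(col)
    },
    budgets = check_budget_identities(df)
  )
  invisible(df)
}

#' Check the carbon-budget accounting identities
#'
#' Verifies, for every row of a budget table, that the component sums close:
#' NPP_t = ANPP_t + BNPP_t-cr + BNPP_t-fr, NPP_u = ANPP_u + BNPP_u,
#' NPP = NPP_t + NPP_u, RH = RH_s + RH_dw and NEP = NPP - RH, and that all
#' NPP and RH components are non-negative (NEP may take either sign: positive
#' NEP is net ecosystem C uptake, negative is net emission).
#'
#' @param budgets Budget data frame with the columns of `sf_schemas()$budgets`.
#' @param tol Relative tolerance for the identities.
#' @return Invisibly, `budgets`; stops with the offending `stand_id` otherwise.
#' @export
check_budget_identities <- function(budgets, tol = 1e-9) {
  req <- setdiff(BUDGET_COLS, names(budgets))
  if (length(req)) stop("budget table missing column(s): ", paste(req, collapse = ", "))
  scale <- pmax(abs(budgets$npp) + abs(budgets$rh), 1)
  bad_id <- function(i, what) {
    stop("budget identity violated (", what, ") for stand_id=",
         budgets$stand_id[i], ", year=", budgets$year[i])
  }
  chk <- function(lhs, rhs, what) {
    bad <- which(abs(lhs - rhs) > tol * scale)
    if (length(bad)) bad_id(bad[1], what)
  }
  with(budgets, {
    chk(npp_t, anpp_t + bnpp_t_cr + bnpp_t_fr, "NPP_t components")
    chk(npp_u, anpp_u + bnpp_u, "NPP_u components")
    chk(npp, npp_t + npp_u, "NPP = NPP_t + NPP_u")
    chk(rh, rh_s + rh_dw, "RH = RH_s + RH_dw")
    chk(nep, npp - rh, "NEP = NPP - RH")
    chk(bnpp_fr, bnpp_t_fr + bnpp_u, "BNPP_fr partition")
  })
  comp <- setdiff(BUDGET_COLS, c("stand_id", "year", "nep"))
  for (col in comp) {
    bad <- which(budgets[[col]] < -tol * scale)
    if (length(bad)) bad_id(bad[1], paste0(col, " negative"))
  }
  invisible(budgets)
}

#' Write a validated budget table
#'
#' Refuses to write if any accounting identity fails, naming the offending
#' stand. A round-trip through [read_table()] returns values equal to within
#' 1e-9 relative tolerance.
#'
#' @inheritParams check_budget_identities
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_budget_table <- function(budgets, path, tol = 1e-9) {
  check_budget_identities(budgets, tol)
  df <- budgets[BUDGET_COLS]
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "year"
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign stand age classes
#'
#' Maps stand age (years since establishment) to the five-class succession
#' scheme (initiation, young, middle-aged, mature, old). Class breaks are the
#' midpoints between the configured observed age ranges, so ages falling in
#' the gaps between ranges are attributed to the nearest class.
#'
#' @param age Integer vector of stand ages (years, >= 0).
#' @param config Configuration list.
#' @return Character vector of age-class labels.
#' @export
#' @examples
#' classify_age(c(7, 95))
classify_age <- function(age, config = sf_config()) {
  if (any(age < 0)) stop("age must be >= 0")
  rng <- config$age_classes$ranges
  lo <- vapply(AGE_CLASSES, function(cl) rng[[cl]][1], numeric(1))
  hi <- vapply(AGE_CLASSES, function(cl) rng[[cl]][2], numeric(1))
  breaks <- (hi[-length(hi)] + lo[-1]) / 2
  AGE_CLASSES[findInterval(age, breaks) + 1L]
}

#' Write a measurement bundle to a directory of CSV files
#'
#' @param bundle Named list of tables as produced by [generate_landscape()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in intersect(names(sf_schemas()), names(bundle))) {
    if (is.null(bundle[[nm]]) || !nrow(bundle[[nm]])) next
    write_table(bundle[[nm]], file.path(dir, paste0(nm, ".csv")), nm)
  }
  invisible(dir)
}

#' Read a measurement bundle from a directory of CSV files
#'
#' @param dir Directory holding `<table>.csv` files.
#' @param config Configuration list.
#' @return Named list of validated tables.
#' @export
read_bundle <- function(dir, config = sf_config()) {
  out <- list()
  for (nm in names(sf_schemas())) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) out[[nm]] <- read_table(p, nm, config)
  }
  out
}
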