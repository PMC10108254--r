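# Per-stand budget composition, age-class aggregation, age-trend curve
# fitting, the NEP trend as a curve difference, and basal-area-based budget
# imputation for additional old stands.

#' Compose a stand-year carbon budget from its components
#'
#' Builds the full budget row and closes all accounting identities:
#' `NPP_t = ANPP_t + BNPP_t-cr + BNPP_t-fr`, `NPP_u = ANPP_u + BNPP_u`,
#' `NPP = NPP_t + NPP_u`, `RH = RH_s + RH_dw`, `NEP = NPP - RH`. `ANPP_t`
#' includes litterfall; `l` is carried as an informational sub-component.
#'
#' @param stand_id,year Identifiers.
#' @param anpp_t,l,bnpp_t_cr,bnpp_t_fr,anpp_u,bnpp_u,rh_s,rh_dw Component
#'   fluxes in g C m-2 yr-1, all >= 0 (NEP alone may be negative).
#' @return One-row budget data frame in canonical column order.
#' @export
#' @examples
#' compose_budget("s1", 2017, anpp_t = 150, l = 40, bnpp_t_cr = 30,
#'                bnpp_t_fr = 60, anpp_u = 40, bnpp_u = 20,
#'                rh_s = 210, rh_dw = 8)   # NPP 300, RH 218, NEP 82
compose_budget <- function(stand_id, year, anpp_t, l, bnpp_t_cr, bnpp_t_fr,
                           anpp_u, bnpp_u, rh_s, rh_dw) {
  args <- list(anpp_t = anpp_t, l = l, bnpp_t_cr = bnpp_t_cr,
               bnpp_t_fr = bnpp_t_fr, anpp_u = anpp_u, bnpp_u = bnpp_u,
               rh_s = rh_s, rh_dw = rh_dw)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || length(args[[nm]]) != 1 || is.na(args[[nm]])) {
      stop("missing budget component: ", nm)
    }
  }
  npp_t <- anpp_t + bnpp_t_cr + bnpp_t_fr
  npp_u <- anpp_u + bnpp_u
  npp <- npp_t + npp_u
  rh <- rh_s + rh_dw
  data.frame(
    stand_id = stand_id, year = as.integer(year),
    anpp_t = anpp_t, l = l, bnpp_t_cr = bnpp_t_cr, bnpp_t_fr = bnpp_t_fr,
    npp_t = npp_t, anpp_u = anpp_u, bnpp_u = bnpp_u, npp_u = npp_u,
    bnpp_fr = bnpp_t_fr + bnpp_u, npp = npp, rh_s = rh_s, rh_dw = rh_dw,
    rh = rh, nep = npp - rh, stringsAsFactors = FALSE
  )
}

#' Multi-year mean budgets per stand
#'
#' Averages each budget column over the study years per stand; all
#' accounting identities are linear, so they keep holding exactly for the
#' means.
#'
#' @param budgets Per-stand-year budget table.
#' @return One row per stand with the same columns (`year` dropped).
#' @export
stand_mean_budgets <- function(budgets) {
  cols <- setdiff(BUDGET_COLS, c("stand_id", "year"))
  out <- stats::aggregate(budgets[cols], by = list(stand_id = budgets$stand_id),
                          FUN = mean)
  out[order(out$stand_id), , drop = FALSE]
}

#' Age-class flux summaries
#'
#' Mean and two-sided 95% Student-t confidence half-width per age class per
#' flux, computed on multi-year stand means. Classes with a single stand get
#' an undefined (NA) half-width.
#'
#' @param mean_budgets Per-stand mean budgets ([stand_mean_budgets()]).
#' @param stands Stand table providing `age_class` per `stand_id`.
#' @param fluxes Budget columns to summarise.
#' @return Data frame: `age_class`, `flux`, `n`, `mean`, `ci95_half_width`.
#' @export
class_aggregate <- function(mean_budgets, stands,
                            fluxes = c("npp_t", "npp_u", "npp", "rh_s",
                                       "rh_dw", "rh", "nep")) {
  cls <- stands$age_class[match(mean_budgets$stand_id, stands$stand_id)]
  if (anyNA(cls)) stop("stand(s) missing from the stands table: ",
                       paste(mean_budgets$stand_id[is.na(cls)], collapse = ", "))
  rows <- list()
  for (cl in intersect(AGE_CLASSES, unique(cls))) {
    sel <- mean_budgets[cls == cl, , drop = FALSE]
    for (fx in fluxes) {
      x <- sel[[fx]]
      n <- length(x)
      hw <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        age_class = cl, flux = fx, n = n, mean = mean(x),
        ci95_half_width = hw, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Log-quadratic age-trend fit
#'
#' Fits `y = exp(b0 + b1 ln(age) + b2 ln(age)^2)` to stand-level flux data by
#' Levenberg-Marquardt least squares on the natural scale, the standard form
#' for hump-shaped (b2 < 0) or monotone NPP/RH_dw age trends. The fit is
#' deterministic: it is initialised from the closed-form ordinary
#' least-squares solution in log space and refined by Marquardt iteration;
#' on non-convergence the log-space solution is returned with a warning.
#'
#' @param age Stand ages, years (>= 1; the log form is undefined at 0).
#' @param y Flux values, g C m-2 yr-1 (> 0 for the log-space initialisation).
#' @return Object of class `age_trend_fit` with `form = "log_quadratic"`,
#'   coefficients `b0`, `b1`, `b2`, and diagnostics `rmse`, `r2`, `n`.
#' @export
fit_log_quadratic <- function(age, y) {
  if (length(age) < 4) stop("need >= 4 stands for the log-quadratic fit")
  if (any(age < 1)) stop("age must be >= 1 for the log-quadratic form")
  x <- log(age)
  ylog <- log(pmax(y, 1e-9))
  init <- stats::coef(stats::lm(ylog ~ x + I(x^2)))
  names(init) <- c("b0", "b1", "b2")
  fit <- tryCatch({
    df <- data.frame(x = x, y = y)
    m <- minpack.lm::nlsLM(y ~ exp(b0 + b1 * x + b2 * x^2), data = df,
                           start = as.list(init),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
    stats::coef(m)
  }, error = function(e) {
    warning("Marquardt refinement failed; using log-space solution")
    init
  })
  pred <- exp(fit[["b0"]] + fit[["b1"]] * x + fit[["b2"]] * x^2)
  new_age_trend_fit("log_quadratic", fit[["b0"]], fit[["b1"]], fit[["b2"]],
                    y, pred)
}

#' Quadratic age-trend fit
#'
#' Second-degree polynomial regression `y = b0 + b1 t + b2 t^2`, used for
#' the RH and RH_s age trends, which lack the strong curvature of NPP.
#' By default `t` is age in years; `in_log_age = TRUE` uses `t = ln(age)`.
#' Predictions for fluxes are floored at zero.
#'
#' @param age Stand ages, years.
#' @param y Flux values.
#' @param in_log_age Regress on ln(age) instead of age.
#' @return Object of class `age_trend_fit` with `form = "poly2"`.
#' @export
fit_poly2 <- function(age, y, in_log_age = FALSE) {
  if (length(age) < 3) stop("need >= 3 stands for the quadratic fit")
  t <- if (in_log_age) log(age) else age
  co <- stats::coef(stats::lm(y ~ t + I(t^2)))
  pred <- co[[1]] + co[[2]] * t + co[[3]] * t^2
  out <- new_age_trend_fit("poly2", co[[1]], co[[2]], co[[3]], y, pred)
  out$in_log_age <- in_log_age
  out
}

new_age_trend_fit <- function(form, b0, b1, b2, y, pred) {
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    form = form, b0 = b0, b1 = b1, b2 = b2,
    rmse = sqrt(rss / length(y)),
    r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    n = length(y)
  ), class = "age_trend_fit")
}

#' @export
predict.age_trend_fit <- function(object, age, ...) {
  if (object$form == "log_quadratic") {
    if (any(age < 1)) stop("log-quadratic trend defined for age >= 1")
    x <- log(age)
    exp(object$b0 + object$b1 * x + object$b2 * x^2)
  } else {
    t <- if (isTRUE(object$in_log_age)) log(age) else age
    pmax(object$b0 + object$b1 * t + object$b2 * t^2, 0)
  }
}

#' @export
print.age_trend_fit <- function(x, ...) {
  cat(sprintf("%s age trend: b0 = %.4g, b1 = %.4g, b2 = %.4g (n = %d, R2 = %.3f)\n",
              x$form, x$b0, x$b1, x$b2, x$n, x$r2))
  invisible(x)
}

#' NEP age trend as the difference of the NPP and RH trend curves
#'
#' The NEP trend is not fitted directly; it is the lazily evaluated
#' difference `NEP(age) = NPP_fit(age) - RH_fit(age)` of the two component
#' trends.
#'
#' @param npp_fit,rh_fit `age_trend_fit` objects (or any objects with a
#'   `predict(object, age)` method).
#' @return A function of `age` returning NEP in g C m-2 yr-1.
#' @export
nep_trend <- function(npp_fit, rh_fit) {
  force(npp_fit); force(rh_fit)
  function(age) stats::predict(npp_fit, age = age) - stats::predict(rh_fit, age = age)
}

#' Reference ratios and basal-area regressions for old-stand imputation
#'
#' From the fully measured stands, derives (i) fixed mean ratios of the
#' unmeasured NPP components (`BNPP_t-fr`, `L`, `ANPP_u`, `BNPP_u`) to
#' measured `ANPP_t`, and (ii) linear-in-basal-area regressions for `RH_s`
#' and for downed-dead-wood respiration. With a single reference stand (or
#' zero basal-area variance) the regressions degenerate to constants.
#'
#' @param mean_budgets Per-stand mean budgets of the reference stands.
#' @param ba Basal area (m2 ha-1) per reference stand, aligned with
#'   `mean_budgets` rows.
#' @param rh_dw_downed Downed-wood share of `rh_dw` per reference stand;
#'   defaults to half of `rh_dw`.
#' @return List of class `old_stand_references`.
#' @export
build_old_stand_references <- function(mean_budgets, ba,
                                       rh_dw_downed = mean_budgets$rh_dw / 2) {
  stopifnot(nrow(mean_budgets) == length(ba))
  ratio <- function(col) mean(mean_budgets[[col]] / mean_budgets$anpp_t)
  lin <- function(y) {
    if (length(ba) >= 2 && stats::var(ba) > 0) {
      stats::coef(stats::lm(y ~ ba))
    } else c(mean(y), 0)
  }
  structure(list(
    r_bnpp_t_fr = ratio("bnpp_t_fr"), r_l = ratio("l"),
    r_anpp_u = ratio("anpp_u"), r_bnpp_u = ratio("bnpp_u"),
    rh_s_vs_ba = lin(mean_budgets$rh_s),
    rh_dw_downed_vs_ba = lin(rh_dw_downed),
    ba_range = range(ba), n = nrow(mean_budgets)
  ), class = "old_stand_references")
}

#' Impute a full budget for an additional old stand
#'
#' Old stands outside the main sample have measured `ANPP_t` and
#' `BNPP_t-cr` (from inventories and coring) plus standing-dead-wood
#' respiration; the remaining NPP components come from the fixed reference
#' ratios, and `RH_s` and downed-wood respiration from the basal-area
#' regressions. The composed budget satisfies all accounting identities by
#' construction.
#'
#' @param stand_id,year Identifiers for the output row.
#' @param ba Stand basal area, m2 ha-1.
#' @param anpp_t Measured aboveground tree NPP (incl. litterfall),
#'   g C m-2 yr-1.
#' @param bnpp_t_cr Measured coarse-root NPP, g C m-2 yr-1.
#' @param references [build_old_stand_references()] output.
#' @param rh_dw_standing Standing-dead-wood respiration measured via decay
#'   constants, g C m-2 yr-1.
#' @return One-row budget data frame.
#' @export
impute_old_stand_budget <- function(stand_id, year, ba, anpp_t, bnpp_t_cr,
                                    references, rh_dw_standing = 0) {
  if (ba < references$ba_range[1] || ba > references$ba_range[2]) {
    warning("basal area ", ba, " outside reference range [",
            references$ba_range[1], ", ", references$ba_range[2],
            "]; extrapolating")
  }
  lin <- function(co) max(co[[1]] + co[[2]] * ba, 0)
  compose_budget(
    stand_id, year,
    anpp_t = anpp_t,
    l = references$r_l * anpp_t,
    bnpp_t_cr = bnpp_t_cr,
    bnpp_t_fr = references$r_bnpp_t_fr * anpp_t,
    anpp_u = references$r_anpp_u * anpp_t,
    bnpp_u = references$r_bnpp_u * anpp_t,
    rh_s = lin(references$rh_s_vs_ba),
    rh_dw = rh_dw_standing + lin(references$rh_dw_downed_vs_ba)
  )
}
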