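# Understory NPP: clip-harvest aboveground production, ingrowth-core
# fine-root production, and the clear-cut-derived partitioning of fine-root
# production between understory and trees.

#' Aboveground understory NPP from seasonal clip harvests
#'
#' Herb production is taken as the August peak biomass; shrub, moss and
#' lichen production as the June-to-August biomass pool increase, floored at
#' zero per functional type (a seasonal pool decrease is not negative
#' production). Dry mass is converted to carbon with the live C fraction.
#'
#' @param harvests Clip-harvest rows for one stand-year: columns `month`
#'   (june/august), `pft` (herbs/shrubs/mosses/lichens), `dry_mass_g_m2`.
#' @param c_fraction Carbon fraction of dry mass.
#' @return `ANPP_u` in g C m-2 yr-1.
#' @export
#' @examples
#' h <- data.frame(month = c("june", "august", "august"),
#'                 pft = c("shrubs", "shrubs", "herbs"),
#'                 dry_mass_g_m2 = c(50, 70, 10))
#' anpp_understory(h)  # 0.5 * (20 + 10) = 15
anpp_understory <- function(harvests, c_fraction = 0.5) {
  total <- 0
  for (p in unique(harvests$pft)) {
    h <- harvests[harvests$pft == p, ]
    aug <- h$dry_mass_g_m2[h$month == "august"]
    if (p == "herbs") {
      if (!length(aug)) stop("missing august harvest for pft 'herbs'")
      total <- total + sum(aug) / length(aug)
    } else {
      jun <- h$dry_mass_g_m2[h$month == "june"]
      if (!length(aug) || !length(jun)) {
        stop("missing june or august harvest for pft '", p, "'")
      }
      total <- total + max(0, sum(aug) / length(aug) - sum(jun) / length(jun))
    }
  }
  c_fraction * total
}

#' Fine-root production from ingrowth cores
#'
#' Each root-free core's ingrown root dry mass is scaled by the core's
#' surface area (`pi * (d/2)^2`) and installation span, averaged over the
#' stand's cores, and converted to carbon. Fine roots (<= 2 mm) of trees and
#' understory are not separable here; see [partition_bnpp()].
#'
#' @param cores Ingrowth-core rows for one stand: columns `diameter_cm`,
#'   `span_yr`, `ingrowth_dry_mass_g`.
#' @param c_fraction Carbon fraction of root dry mass.
#' @return `BNPP_fr` in g C m-2 yr-1.
#' @export
#' @examples
#' cores <- data.frame(diameter_cm = 10, span_yr = 1.25,
#'                     ingrowth_dry_mass_g = 1.2)
#' bnpp_fineroot_from_ingrowth(cores)  # 61.12
bnpp_fineroot_from_ingrowth <- function(cores, c_fraction = 0.5) {
  if (!nrow(cores)) stop("need >= 1 ingrowth core")
  area_m2 <- pi * (cores$diameter_cm / 100 / 2)^2
  per_core <- cores$ingrowth_dry_mass_g / area_m2 / cores$span_yr
  c_fraction * mean(per_core)
}

#' Understory root-to-shoot production ratio from clear-cut stands
#'
#' In recent clear-cuts tree fine roots are assumed negligible, so all
#' fine-root ingrowth there is understory production. The ratio
#' `r_u = BNPP_fr / ANPP_u`, averaged over the clear-cut reference stands, is
#' then held constant across the landscape to split fine-root production
#' elsewhere.
#'
#' @param clearcuts Data frame with one row per clear-cut reference stand:
#'   columns `bnpp_fr` and `anpp_u` (g C m-2 yr-1).
#' @return `r_u`, dimensionless.
#' @export
derive_clearcut_root_ratio <- function(clearcuts) {
  ok <- clearcuts$anpp_u > 0
  if (any(!ok)) {
    warning(sum(!ok), " clear-cut reference stand(s) with ANPP_u = 0 skipped")
  }
  cc <- clearcuts[ok, , drop = FALSE]
  if (!nrow(cc)) stop("no clear-cut reference stand with ANPP_u > 0")
  mean(cc$bnpp_fr / cc$anpp_u)
}

#' Partition fine-root production into understory and tree components
#'
#' `BNPP_u = min(r_u * ANPP_u, BNPP_fr)`; the remainder
#' `BNPP_t-fr = BNPP_fr - BNPP_u` is attributed to trees. The cap guarantees
#' a non-negative tree component, and mass is conserved exactly:
#' `BNPP_u + BNPP_t-fr = BNPP_fr`.
#'
#' @param bnpp_fr Total fine-root production, g C m-2 yr-1 (>= 0).
#' @param anpp_u Aboveground understory production, g C m-2 yr-1 (>= 0).
#' @param r_u Understory root-to-shoot production ratio (>= 0).
#' @return List with `bnpp_u` and `bnpp_t_fr`.
#' @export
#' @examples
#' partition_bnpp(100, 40, 0.8)  # bnpp_u 32, bnpp_t_fr 68
partition_bnpp <- function(bnpp_fr, anpp_u, r_u) {
  if (any(c(bnpp_fr, anpp_u, r_u) < 0)) stop("all inputs must be >= 0")
  bnpp_u <- pmin(r_u * anpp_u, bnpp_fr)
  list(bnpp_u = bnpp_u, bnpp_t_fr = bnpp_fr - bnpp_u)
}

#' Scale fine-root production across years with a fixed root-to-shoot ratio
#'
#' Ingrowth cores integrate a single installation span; the ratio of
#' fine-root production to total aboveground production (`ANPP_t + ANPP_u`)
#' in the core year is assumed constant, so other years' `BNPP_fr` follows
#' their aboveground production.
#'
#' @param anpp Vector of annual total aboveground production, g C m-2 yr-1.
#' @param ratio `BNPP_fr / ANPP` in the reference (core) year (>= 0); scalar
#'   or one value per element of `anpp`.
#' @return `BNPP_fr` per year.
#' @export
apply_root_to_shoot_scaling <- function(anpp, ratio) {
  if (any(ratio < 0)) stop("ratio must be >= 0")
  ratio * anpp
}

#' Carry understory production across years with a shrub-increment index
#'
#' Clip harvests were taken in a single reference year; other years' dwarf
#' shrub production follows the measured annual shoot-increment index, and
#' the other functional types are assumed to keep a constant production
#' ratio to shrubs, so the whole per-PFT vector scales by
#' `index_year / index_ref`.
#'
#' @param anpp_u_ref Named numeric vector of per-PFT production in the
#'   reference year (g C m-2 yr-1), or a single total.
#' @param index_year Shrub increment index in the target year.
#' @param index_ref Shrub increment index in the reference year (> 0).
#' @return Scaled per-PFT production vector for the target year.
#' @export
interannual_understory_scaling <- function(anpp_u_ref, index_year, index_ref) {
  if (index_ref <= 0) stop("reference-year shrub index must be > 0")
  anpp_u_ref * (index_year / index_ref)
}
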