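# Raw-value calculators for the ecological benefit leaves. These are optional
# front-ends: the evaluation pipeline accepts leaf values from any source
# (field data, statistics yearbooks, expert grades); these functions cover the
# indicators with an explicit closed-form definition. Symbols that collide
# between formulas (prices, rates) are disambiguated by argument name, scoped
# to one indicator each.

#' Simpson diversity index
#'
#' `D2 = N (N - 1) / sum_i n_i (n_i - 1)` over species abundances, where `N`
#' is the total number of individuals. Equals 1 for a single-species stand
#' (minimum diversity) and grows with evenness and richness.
#'
#' @param counts Non-negative integer vector of per-species individual counts.
#' @return The index value, `>= 1`.
#' @examples
#' simpson_diversity(c(2, 2))  # 3
#' simpson_diversity(10)       # 1
#' @export
simpson_diversity <- function(counts) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (N < 2) fahp_error("need at least two individuals", "fahp_validation")
  denom <- sum(counts * (counts - 1))
  if (denom == 0) {
    fahp_error("all species are singletons: Simpson index undefined", "fahp_degenerate")
  }
  N * (N - 1) / denom
}

#' Shannon stability index
#'
#' `D5 = -sum_i r_i ln r_i` with relative abundances `r_i = n_i / N`.
#' Zero-count species are skipped. Bounded by `ln(s)` for `s` species, with
#' the bound attained by a perfectly even community.
#'
#' @param counts Non-negative vector of per-species individual counts.
#' @return The entropy value in nats.
#' @examples
#' shannon_stability(c(5, 5))  # log(2)
#' @export
shannon_stability <- function(counts) {
  counts <- check_counts(counts)
  counts <- counts[counts > 0]
  r <- counts / sum(counts)
  -sum(r * log(r))
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    fahp_error("species counts must be non-negative integers", "fahp_validation")
  }
  if (sum(counts) < 1) fahp_error("at least one individual is required", "fahp_validation")
  counts
}

#' Integrity of the forest landscape (D1)
#'
#' Product `V * O * R` of system vitality (primary productivity standard),
#' the organization index and the restoring-force index, the latter two
#' expressed as relative degrees on \[0, 1\].
#'
#' @param vitality System vitality `V` (non-negative).
#' @param organization Organization index `O` in \[0, 1\].
#' @param restoring Restoring-force index in \[0, 1\].
#' @export
landscape_integrity <- function(vitality, organization, restoring) {
  check_nonneg(vitality = vitality)
  if (organization < 0 || organization > 1 || restoring < 0 || restoring > 1) {
    fahp_error("organization and restoring indexes must lie in [0, 1]", "fahp_validation")
  }
  vitality * organization * restoring
}

#' Plantation productivity (D3)
#'
#' Sum of seven annual production terms: net growth of trunks, branches,
#' leaves and roots, litter fall, understory net growth, and animal intake.
#'
#' @param trunks,branches,leaves,roots Annual net growth rates by component.
#' @param litter Annual litter amount.
#' @param understory Annual net growth of understory plants.
#' @param intake Annual intake of animals.
#' @export
plantation_productivity <- function(trunks, branches, leaves, roots,
                                    litter, understory, intake) {
  check_nonneg(trunks = trunks, branches = branches, leaves = leaves,
               roots = roots, litter = litter, understory = understory,
               intake = intake)
  trunks + branches + leaves + roots + litter + understory + intake
}

#' Forest restoration force / fertility index (D4)
#'
#' Ratio `M_s / F_t` of the time needed to return from the stress state to
#' the steady state over the maximum cutting intensity the forest can bear.
#'
#' @param recovery_time Time from stress state back to steady state (`M_s`).
#' @param max_intensity Maximum bearable cutting intensity (`F_t`, > 0).
#' @export
restoration_force <- function(recovery_time, max_intensity) {
  check_nonneg(recovery_time = recovery_time)
  if (max_intensity <= 0) {
    fahp_error("max bearable cutting intensity must be > 0", "fahp_degenerate")
  }
  recovery_time / max_intensity
}

#' Water source conservation value (D6)
#'
#' Monetary value of the forest's water benefit, decomposed as
#' `D6 = D6a + D6b` with
#' `D6a = sum_i m_i (H_i - H_0) * b * beta` (flood-control value over forest
#' types) and `D6b = T (P1 a + P2 eta)` (water-supply utilization value).
#'
#' @param area Vector `m_i` of areas per forest type.
#' @param flood_storage Vector `H_i` of flood storage capacities per type.
#' @param flood_storage_nonforest Flood storage capacity `H_0` of non-forest
#'   land (same unit).
#' @param cost_per_m3 Construction fee `b` of reservoir/dam per m^3 retained.
#' @param benefit_ratio Benefit/input ratio `beta`.
#' @param water_increment Incremental water resource amount `T` the forest
#'   provides.
#' @param price_irrigation,price_industrial Water prices `P1`, `P2`.
#' @param coef_irrigation,coef_industrial Utilization coefficients `a`, `eta`.
#' @return Total value, with the two components attached as attribute
#'   `"components"` (`flood_control`, `water_supply`).
#' @export
water_conservation <- function(area, flood_storage, flood_storage_nonforest,
                               cost_per_m3, benefit_ratio,
                               water_increment, price_irrigation, price_industrial,
                               coef_irrigation, coef_industrial) {
  if (length(area) != length(flood_storage)) {
    fahp_error("`area` and `flood_storage` must align per forest type", "fahp_validation")
  }
  check_nonneg(cost_per_m3 = cost_per_m3, benefit_ratio = benefit_ratio,
               water_increment = water_increment,
               price_irrigation = price_irrigation,
               price_industrial = price_industrial)
  d6a <- sum(area * (flood_storage - flood_storage_nonforest)) * cost_per_m3 * benefit_ratio
  d6b <- water_increment * (price_irrigation * coef_irrigation +
                            price_industrial * coef_industrial)
  structure(d6a + d6b,
            components = c(flood_control = d6a, water_supply = d6b))
}

#' Soil and water conservation value (D7)
#'
#' `D7 = K * P_r / 2`: half the product of the soil mass the forest saves
#' relative to bare land and the average cost of dredging one tonne of
#' sediment.
#'
#' @param soil_saved Soil loss avoided `K` (t).
#' @param dredge_cost Average dredging cost `P_r` per tonne.
#' @export
soil_water_conservation <- function(soil_saved, dredge_cost) {
  check_nonneg(soil_saved = soil_saved, dredge_cost = dredge_cost)
  soil_saved * dredge_cost / 2
}

#' Air purification (oxygen release) value (D8)
#'
#' `D8 = M * L * d * P_y * (1 + Z) * K_l`: stocking volume times net growth
#' rate times dry mass, priced at the industrial oxygen price, inflated by
#' the root-and-shoot share of annual growth and the oxygen yield per tonne
#' of dry matter.
#'
#' @param stock Stocking volume `M` of the existing forest.
#' @param growth_rate Net growth rate `L`.
#' @param dry_mass Mass of dry wood `d`.
#' @param oxygen_price Price of industrial oxygen `P_y` per m^3.
#' @param root_shoot Percentage `Z` (as a fraction) of root and shoot annual
#'   growth in timber annual growth, by dry mass.
#' @param oxygen_per_t Oxygen emission `K_l` per tonne of dry matter.
#' @export
air_purification <- function(stock, growth_rate, dry_mass, oxygen_price,
                             root_shoot, oxygen_per_t) {
  check_nonneg(stock = stock, growth_rate = growth_rate, dry_mass = dry_mass,
               oxygen_price = oxygen_price, root_shoot = root_shoot,
               oxygen_per_t = oxygen_per_t)
  stock * growth_rate * dry_mass * oxygen_price * (1 + root_shoot) * oxygen_per_t
}

#' Soil improvement value (D9)
#'
#' `D9 = G * S_1 * sum_{i=1}^{3} P1_i * P2_i * P3_i`: annual litter per unit
#' area times forest area times a three-component nutrient valuation. The
#' three per-component factor triples (`P1`, `P2`, `P3`) are nutrient
#' content, fertilizer-equivalent conversion and fertilizer price in the
#' usual application, but any consistent factorization works.
#'
#' @param litter_rate Litter amount `G` per unit area and year (t/(hm^2 a)).
#' @param area Forest area `S_1`.
#' @param p1,p2,p3 Numeric vectors of length 3: the per-component factors.
#' @export
soil_improvement <- function(litter_rate, area, p1, p2, p3) {
  if (length(p1) != 3L || length(p2) != 3L || length(p3) != 3L) {
    fahp_error("p1, p2, p3 must each have three components", "fahp_validation")
  }
  check_nonneg(litter_rate = litter_rate, area = area)
  litter_rate * area * sum(p1 * p2 * p3)
}

#' Value of benefits for future generations (D30)
#'
#' Willingness-to-pay valuation over `m` payment grades:
#' `D30 = sum_i N * (n_i / n) * x_i`, with `x_i` the average voluntary
#' payment of grade i (currency/person), `n_i` the number of respondents in
#' grade i, `N` the total number surveyed and `n = N` (the total), so the
#' grade shares sum to at most 1.
#'
#' @param payments Vector `x_i` of average voluntary payments per grade (the
#'   first grade's payment is conventionally 0).
#' @param counts Vector `n_i` of respondents per grade.
#' @param n_total Total respondents `N`; defaults to `sum(counts)`, and
#'   `sum(counts)` may not exceed it.
#' @export
future_generations_value <- function(payments, counts, n_total = sum(counts)) {
  if (length(payments) != length(counts)) {
    fahp_error("`payments` and `counts` must align per grade", "fahp_validation")
  }
  check_nonneg(n_total = n_total)
  counts <- check_counts(counts)
  if (sum(counts) > n_total) {
    fahp_error("grade counts exceed the total number surveyed", "fahp_validation")
  }
  sum(n_total * (counts / n_total) * payments)
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || anyNA(args[[nm]]) || any(args[[nm]] < 0)) {
      fahp_error(sprintf("parameter '%s' must be non-negative", nm), "fahp_validation")
    }
  }
  invisible(TRUE)
}
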