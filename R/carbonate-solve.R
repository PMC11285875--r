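#' Solve the seawater CO2 system from any two carbonate parameters
#'
#' Full speciation of the seawater inorganic carbon system at a given
#' temperature and salinity from exactly two of pH, total alkalinity,
#' DIC and pCO2. The alkalinity balance includes the carbonate, borate and
#' water terms (minus free hydrogen); nutrient terms and pressure
#' corrections are out of scope (surface incubations).
#'
#' Pairs involving pH are solved in closed form. The remaining pairs are
#' solved by a bracketed root search for pH on \[2, 12\] (deterministic, no
#' randomness) converged to machine precision in pH; the alkalinity
#' residual at the returned root is checked against 1e-12 mol/kg.
#'
#' @param temperature Degrees C.
#' @param salinity Practical salinity.
#' @param ph pH on `ph_scale` (optional).
#' @param total_alkalinity Total alkalinity, umol/kg (optional).
#' @param dic Dissolved inorganic carbon, umol/kg (optional).
#' @param pco2 CO2 partial pressure, uatm (optional).
#' @param constants A [carb_constants()] object; computed from
#'   `temperature`/`salinity` with defaults when `NULL`.
#' @param ph_scale Scale of the supplied `ph`: `"total"` (default),
#'   `"NBS"`, `"sws"` or `"free"`. Internally everything is on the total
#'   scale; the NBS boundary goes through the Takahashi activity factor.
#'
#' @return An object of class `seawater_state`: a list with temperature,
#'   salinity, `ph` (total scale), `ah` (total-scale \[H+\], mol/kg),
#'   `ta`, `dic`, `carb_alk`, `co2`, `hco3`, `co3` (all mol/kg), `pco2`
#'   (atm) and the `constants` used. `tidy()` returns a one-row tibble in
#'   reporting units (umol/kg, uatm).
#'
#' @examples
#' st <- solve_carb(15, 35, ph = 8.1, total_alkalinity = 2300)
#' tidy(st)
#' @export
solve_carb <- function(temperature, salinity, ph = NULL,
                       total_alkalinity = NULL, dic = NULL, pco2 = NULL,
                       constants = NULL, ph_scale = "total") {
  if (is.null(constants)) constants <- carb_constants(temperature, salinity)
  supplied <- c(ph = !is.null(ph), total_alkalinity = !is.null(total_alkalinity),
                dic = !is.null(dic), pco2 = !is.null(pco2))
  if (sum(supplied) != 2) {
    stop_domain(sprintf(
      "exactly two of {ph, total_alkalinity, dic, pco2} must be supplied (got %d)",
      sum(supplied)))
  }
  k <- constants
  ta <- if (!is.null(total_alkalinity)) {
    check_scalar_number(total_alkalinity, "total_alkalinity", 0, Inf)
    total_alkalinity * 1e-6
  }
  dic_m <- if (!is.null(dic)) {
    check_scalar_number(dic, "dic", 0, Inf)
    dic * 1e-6
  }
  pco2_atm <- if (!is.null(pco2)) {
    check_scalar_number(pco2, "pco2", 0, Inf)
    pco2 * 1e-6
  }
  if (!is.null(dic_m) && dic_m == 0 && !is.null(ta) && ta > 0) {
    stop_domain("dic = 0 with total_alkalinity > 0 is not solvable")
  }

  h <- if (!is.null(ph)) {
    check_scalar_number(ph, "ph", 0, 14)
    ph_to_h_total(ph, ph_scale, k)
  } else if (!is.null(ta) && !is.null(dic_m)) {
    solve_h(function(h) ta_from_h_dic(h, dic_m, k) - ta, k)
  } else if (!is.null(ta) && !is.null(pco2_atm)) {
    solve_h(function(h) ta_from_h_co2(h, k$K0 * pco2_atm, k) - ta, k)
  } else {
    # dic + pco2
    co2 <- k$K0 * pco2_atm
    if (co2 >= dic_m) stop_domain("pco2 implies [CO2] >= DIC; pair not solvable")
    solve_h(function(h) dic_m * h^2 / (h^2 + k$K1 * h + k$K1 * k$K2) - co2, k,
            increasing = TRUE)
  }

  if (!is.null(dic_m)) {
    den <- h^2 + k$K1 * h + k$K1 * k$K2
    co2 <- dic_m * h^2 / den
    hco3 <- dic_m * k$K1 * h / den
    co3 <- dic_m * k$K1 * k$K2 / den
  } else if (!is.null(pco2_atm)) {
    co2 <- k$K0 * pco2_atm
    hco3 <- k$K1 * co2 / h
    co3 <- k$K2 * hco3 / h
  } else {
    # ph + ta: carbonate alkalinity by subtracting borate/water/H terms
    a <- ta - borate_water_alk(h, k)
    if (a <= 0) stop_domain("carbonate alkalinity <= 0 at the supplied pH/TA")
    hco3 <- a * h / (h + 2 * k$K2)
    co3 <- a * k$K2 / (h + 2 * k$K2)
    co2 <- h * hco3 / k$K1
  }

  state <- structure(
    list(temperature = temperature, salinity = salinity,
         ph = -log10(h), ah = h,
         ta = hco3 + 2 * co3 + borate_water_alk(h, k),
         dic = co2 + hco3 + co3,
         carb_alk = hco3 + 2 * co3,
         co2 = co2, hco3 = hco3, co3 = co3,
         pco2 = co2 / k$K0,
         constants = k),
    class = "seawater_state"
  )
  if (!is.null(ta) && abs(state$ta - ta) > 1e-12) {
    stop_numeric(sprintf(
      "alkalinity residual %.3e mol/kg exceeds 1e-12 after root search",
      state$ta - ta))
  }
  state
}

# Borate + water - free-hydrogen contribution to total alkalinity at
# total-scale [H+] = h.
borate_water_alk <- function(h, k) {
  k$KB * k$TB / (k$KB + h) + k$Kw / h - h * k$free_per_tot
}

ta_from_h_dic <- function(h, dic, k) {
  den <- h^2 + k$K1 * h + k$K1 * k$K2
  dic * (k$K1 * h + 2 * k$K1 * k$K2) / den + borate_water_alk(h, k)
}

ta_from_h_co2 <- function(h, co2, k) {
  hco3 <- k$K1 * co2 / h
  hco3 + 2 * k$K2 * hco3 / h + borate_water_alk(h, k)
}

# Bracketed root search for total-scale [H+] on pH in [2, 12]. `f` must be
# monotone in pH over the bracket (decreasing for alkalinity-type
# residuals, increasing for the DIC/CO2 ratio residual).
solve_h <- function(f, k, increasing = FALSE) {
  g <- function(ph) f(10^-ph)
  lo <- g(2); hi <- g(12)
  if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi)) {
    stop_numeric(sprintf(
      "no root bracketed on pH in [2, 12] (f(2) = %.3e, f(12) = %.3e)", lo, hi))
  }
  r <- uniroot(g, c(2, 12), tol = 1e-15, maxiter = 200)
  10^-r$root
}

#' @export
print.seawater_state <- function(x, ...) {
  cat(sprintf("<seawater_state> %.2f degC, S %.2f, pH(total) %.4f\n",
              x$temperature, x$salinity, x$ph))
  cat(sprintf("  TA %.1f  DIC %.1f  [CO2] %.2f  [HCO3] %.1f  [CO3] %.1f umol/kg  pCO2 %.1f uatm\n",
              x$ta * 1e6, x$dic * 1e6, x$co2 * 1e6, x$hco3 * 1e6,
              x$co3 * 1e6, x$pco2 * 1e6))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.seawater_state <- function(x, ...) {
  tibble(
    temperature = x$temperature, salinity = x$salinity,
    ph_total = x$ph,
    ph_nbs = h_total_to_ph(x$ah, "NBS", x$constants),
    total_alkalinity = x$ta * 1e6, dic = x$dic * 1e6,
    carb_alk = x$carb_alk * 1e6,
    co2 = x$co2 * 1e6, hco3 = x$hco3 * 1e6, co3 = x$co3 * 1e6,
    pco2 = x$pco2 * 1e6
  )
}
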