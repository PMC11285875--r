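#' Buffered CO2 release per mole of carbonate precipitated (psi)
#'
#' `psi_analytic()` evaluates the Frankignoulle-type analytical model of
#' the ratio psi between CO2 released to the environment and carbonate
#' precipitated, for a seawater parcel that stays in gas-exchange
#' equilibrium with an unchanged ambient pCO2. Precipitating one mole of
#' CaCO3 removes one mole of DIC and two of alkalinity; because the
#' re-equilibrated water then holds less DIC at the same pCO2, part of the
#' parcel's carbon is evaded as CO2 gas: psi is that evaded amount per
#' mole precipitated, about 0.6-0.8 in surface seawater.
#'
#' With carbonate alkalinity `A`, total-scale hydrogen-ion concentration
#' `aH` and the intermediates
#' \deqn{P = K_B T_B/(a_H+K_B)^2 + K_w/a_H^2 + 1}
#' \deqn{Q = a_H + 2K_2}
#' \deqn{R = AQ + 2K_2A + PQa_H}
#' the model reduces to the closed form
#' \deqn{\psi = 2AQ/R - 1,}
#' obtained by implicit differentiation of the constant-pCO2 carbonate
#' system (equivalently \eqn{\psi = 2\,(\partial DIC/\partial TA)_{pCO2} - 1}).
#' The derivation and its validation against the finite-difference
#' perturbation oracle are laid out in the methods vignette; tests assert
#' agreement within 1e-3 across a temperature x pH x alkalinity grid. A
#' further diagnostic intermediate `CS` is reported alongside but plays no
#' role in psi.
#'
#' `psi_finite_difference()` is the model-free oracle: it simulates
#' precipitation of `delta` mol/kg (TA - 2 delta, DIC - delta), lets the
#' parcel re-equilibrate to the original pCO2, and measures the evaded CO2
#' per mole precipitated as a central difference (precipitation vs
#' dissolution), second-order accurate in `delta`.
#'
#' @param state A solved [solve_carb()] state.
#' @param constants Optional [carb_constants()]; defaults to those stored
#'   in `state`.
#' @param delta Perturbation size, mol/kg, in (0, 1e-6].
#'
#' @return An object of class `psi_result`: list with `psi`, intermediates
#'   `P`, `Q`, `R`, `CS`, and `method` (`"analytic"` or
#'   `"finite_difference"`). `tidy()` gives a one-row tibble.
#'
#' @examples
#' st <- solve_carb(15, 35, ph = 8.1, total_alkalinity = 2300, ph_scale = "NBS")
#' psi_analytic(st)$psi
#' psi_finite_difference(st)$psi
#' @export
psi_analytic <- function(state, constants = NULL) {
  stopifnot(inherits(state, "seawater_state"))
  k <- constants %||% state$constants
  h <- state$ah
  A <- state$carb_alk
  P <- k$KB * k$TB / (h + k$KB)^2 + k$Kw / h^2 + k$free_per_tot
  Q <- h + 2 * k$K2
  R <- A * Q + 2 * k$K2 * A + P * Q * h
  if (R == 0) stop_numeric("division by zero in intermediate R")
  if (h == 0 || k$K1 == 0) stop_numeric("division by zero in intermediate CS")
  # diagnostic only: the most literal reading of the printed buffer-sum
  # intermediate; not used in psi (see vignette)
  CS <- (k$K2 * A + P * Q * (h + k$K2) + R * h / k$K1 -
           Q * (1 + 2 * h / k$K1)) / h
  new_psi_result(2 * A * Q / R - 1, P, Q, R, CS, "analytic")
}

#' @rdname psi_analytic
#' @export
psi_finite_difference <- function(state, constants = NULL, delta = 1e-9) {
  stopifnot(inherits(state, "seawater_state"))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1e-6) {
    stop_domain("`delta` must be in (0, 1e-6] mol/kg")
  }
  k <- constants %||% state$constants
  evaded <- function(d) {
    # precipitate d mol/kg, then re-equilibrate at the original pCO2:
    # evaded CO2 = DIC - d - DIC'(TA - 2d, pCO2)
    st2 <- solve_carb(state$temperature, state$salinity,
                      total_alkalinity = (state$ta - 2 * d) * 1e6,
                      pco2 = state$pco2 * 1e6, constants = k)
    state$dic - d - st2$dic
  }
  psi <- (evaded(delta) - evaded(-delta)) / (2 * delta)
  ref <- psi_analytic(state, k)
  new_psi_result(psi, ref$P, ref$Q, ref$R, ref$CS, "finite_difference")
}

new_psi_result <- function(psi, P, Q, R, CS, method) {
  structure(list(psi = psi, P = P, Q = Q, R = R, CS = CS, method = method),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("<psi_result> psi = %.4f (%s)\n", x$psi, x$method))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.psi_result <- function(x, ...) {
  tibble(psi = x$psi, P = x$P, Q = x$Q, R = x$R, CS = x$CS,
         method = x$method)
}

#' Evaluate psi over a grid of seawater conditions
#'
#' Data-frame-first wrapper: takes one row per seawater condition, solves
#' the CO2 system and evaluates the buffered CO2-release ratio psi by both
#' the analytical model and the finite-difference oracle.
#'
#' @param grid A data frame with columns `temperature`, `salinity`, `ph`
#'   and `total_alkalinity` (umol/kg). An optional `ph_scale` column (or
#'   the `ph_scale` argument) declares the pH scale per row.
#' @param ph_scale Default pH scale for rows without a `ph_scale` column.
#' @param formulation K1/K2 formulation passed to [carb_constants()].
#' @param delta Perturbation size for the oracle (mol/kg).
#'
#' @return The input grid with columns `psi` (analytic), `psi_fd`
#'   (oracle), the intermediates `P`, `Q`, `R`, `CS`, and the solved
#'   `ph_total`, `dic`, `pco2`.
#'
#' @examples
#' grid <- tidyr::expand_grid(temperature = c(5, 15, 25), salinity = 35,
#'                            ph = 8.1, total_alkalinity = 2300)
#' psi_grid(grid)
#' @export
psi_grid <- function(grid, ph_scale = "total", formulation = "lueker2000",
                     delta = 1e-9) {
  grid <- as_tibble(grid)
  needed <- c("temperature", "salinity", "ph", "total_alkalinity")
  missing_cols <- setdiff(needed, names(grid))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("`grid` is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (!"ph_scale" %in% names(grid)) grid$ph_scale <- ph_scale
  res <- purrr::pmap(
    grid[c(needed, "ph_scale")],
    function(temperature, salinity, ph, total_alkalinity, ph_scale) {
      k <- carb_constants(temperature, salinity, formulation)
      st <- solve_carb(temperature, salinity, ph = ph,
                       total_alkalinity = total_alkalinity,
                       constants = k, ph_scale = ph_scale)
      an <- psi_analytic(st, k)
      fd <- psi_finite_difference(st, k, delta)
      tibble(psi = an$psi, psi_fd = fd$psi, P = an$P, Q = an$Q, R = an$R,
             CS = an$CS, ph_total = st$ph, dic = st$dic * 1e6,
             pco2 = st$pco2 * 1e6)
    })
  dplyr::bind_cols(grid, bind_rows(res))
}
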