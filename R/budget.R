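#' Partition the organismal carbon budget among terminal sinks
#'
#' Splits the total bicarbonate uptake of a calcifying alga among its
#' three terminal sinks -- skeletal carbonate, organic matter, and net CO2
#' released -- and derives the calcification-side quantities. Under the
#' bicarbonate-use stoichiometry 2 HCO3- -> CO3^2- + CO2 + H2O, each mole
#' of precipitated carbonate produces one mole of CO2, so:
#' \itemize{
#'   \item CO2 produced = skeleton `P`; calcification demand `D = 2 P`;
#'   \item total uptake `U = O + P + net_release` (terminal sinks only --
#'     recycled CO2 re-enters organic fixation and is not double counted);
#'   \item recycled fraction of produced CO2 = `(P - net_release)/P`;
#'     released fraction = `net_release/P`.
#' }
#' All inputs must share one unit (nmol/g, rates, or percentages).
#'
#' @param organic Organic fixation `O`.
#' @param skeleton Skeletal deposition `P` (carbon units, i.e. Mg-adjusted
#'   Ca+Mg incorporation under the 1:1 C : Ca+Mg assumption).
#' @param net_release Net CO2 release to the medium.
#'
#' @return A one-row tibble: `total_uptake`, `frac_skeleton`,
#'   `frac_organic`, `frac_net_release`, `frac_co2_produced`,
#'   `frac_calc_demand`, `frac_total_fixed`, `recycled_of_produced`,
#'   `released_of_produced`.
#'
#' @examples
#' budget_partition(organic = 39, skeleton = 38, net_release = 23)
#' @export
budget_partition <- function(organic, skeleton, net_release) {
  check_scalar_number(organic, "organic", lower = 0)
  check_scalar_number(skeleton, "skeleton", lower = 0)
  check_scalar_number(net_release, "net_release", lower = 0)
  if (skeleton == 0 && net_release > 0) {
    stop_domain("net_release > 0 with skeleton = 0: release without precipitation")
  }
  u <- organic + skeleton + net_release
  if (u == 0) stop_domain("all budget inputs are zero")
  tibble(
    total_uptake = u,
    frac_skeleton = skeleton / u,
    frac_organic = organic / u,
    frac_net_release = net_release / u,
    frac_co2_produced = skeleton / u,
    frac_calc_demand = 2 * skeleton / u,
    frac_total_fixed = (organic + skeleton) / u,
    recycled_of_produced = if (skeleton > 0) (skeleton - net_release) / skeleton else NA_real_,
    released_of_produced = if (skeleton > 0) net_release / skeleton else NA_real_
  )
}

#' Monte-Carlo uncertainty propagation through the budget partition
#'
#' Propagates measurement uncertainty into the budget fractions by drawing
#' each input from a normal distribution truncated at zero, centred on the
#' group mean with the standard error of the mean (sd/sqrt(n)) as spread,
#' running [budget_partition()] per draw, and summarising each output.
#'
#' @param input A data frame with columns `component` (`"organic"`,
#'   `"skeleton"`, `"net_release"`), `mean`, `sd`, `n`.
#' @param n_draws Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed (mandatory; draws are reproducible).
#'
#' @return A tibble with one row per budget output: `quantity`, `mean`,
#'   `sd`, plus attributes `n_draws` and `seed`.
#'
#' @examples
#' input <- tibble::tribble(
#'   ~component, ~mean, ~sd, ~n,
#'   "organic", 39, 14, 8,
#'   "skeleton", 38, 22, 8,
#'   "net_release", 23, 3, 8
#' )
#' budget_propagate(input, n_draws = 2000, seed = 1)
#' @export
budget_propagate <- function(input, n_draws = 10000, seed) {
  input <- validate_budget_input(input)
  if (missing(seed)) stop_domain("`seed` is mandatory for budget_propagate()")
  check_scalar_number(n_draws, "n_draws", lower = 1000)
  se <- input$sd / sqrt(input$n)
  names(se) <- input$component
  mu <- set_names(input$mean, input$component)
  draws <- withr::with_seed(seed, {
    tibble(
      organic = rtruncnorm0(n_draws, mu[["organic"]], se[["organic"]]),
      skeleton = rtruncnorm0(n_draws, mu[["skeleton"]], se[["skeleton"]]),
      net_release = rtruncnorm0(n_draws, mu[["net_release"]], se[["net_release"]])
    )
  })
  res <- partition_vec(draws$organic, draws$skeleton, draws$net_release)
  out <- res |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "quantity") |>
    group_by(.data$quantity) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value)) |>
    arrange(match(.data$quantity, names(res)))
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  class(out) <- c("coralcarb_budget", class(out))
  out
}

#' First-order (delta-method) propagation cross-check
#'
#' Analytic counterpart of [budget_propagate()]: linearises each budget
#' output around the input means and combines the input standard errors in
#' quadrature. Used to cross-check the Monte-Carlo propagation; agrees
#' with it to first order when the standard errors are small relative to
#' the means.
#'
#' @inheritParams budget_propagate
#' @return A tibble `quantity`, `mean` (at the input means), `sd`
#'   (first-order propagated).
#' @export
budget_propagate_delta <- function(input) {
  input <- validate_budget_input(input)
  mu <- set_names(input$mean, input$component)
  se <- set_names(input$sd / sqrt(input$n), input$component)
  f <- function(x) unlist(partition_vec(x[["organic"]], x[["skeleton"]],
                                        x[["net_release"]]))
  base <- f(mu)
  grads <- purrr::map(names(mu), function(nm) {
    hstep <- max(1e-6, abs(mu[[nm]]) * 1e-6)
    up <- mu; up[[nm]] <- up[[nm]] + hstep
    dn <- mu; dn[[nm]] <- dn[[nm]] - hstep
    (f(up) - f(dn)) / (2 * hstep)
  })
  var_out <- purrr::reduce(
    purrr::map2(grads, se[names(mu)], function(g, s) (g * s)^2), `+`)
  out <- tibble(quantity = names(base), mean = unname(base),
                sd = sqrt(unname(var_out)))
  class(out) <- c("coralcarb_budget", class(out))
  out
}

# vectorised partition core used by the Monte-Carlo loop
partition_vec <- function(organic, skeleton, net_release) {
  u <- organic + skeleton + net_release
  tibble(
    total_uptake = u,
    frac_skeleton = skeleton / u,
    frac_organic = organic / u,
    frac_net_release = net_release / u,
    frac_co2_produced = skeleton / u,
    frac_calc_demand = 2 * skeleton / u,
    frac_total_fixed = (organic + skeleton) / u,
    recycled_of_produced = (skeleton - net_release) / skeleton,
    released_of_produced = net_release / skeleton
  )
}

validate_budget_input <- function(input) {
  if (!is.data.frame(input)) stop_domain("`input` must be a data frame")
  need <- c("component", "mean", "sd", "n")
  missing_cols <- setdiff(need, names(input))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("budget input is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  comp <- c("organic", "skeleton", "net_release")
  if (!setequal(input$component, comp)) {
    stop_domain("budget input must have components organic, skeleton, net_release")
  }
  if (any(input$mean < 0)) stop_domain("budget means must be >= 0")
  if (any(input$sd < 0)) stop_domain("budget sds must be >= 0")
  if (any(input$n < 1)) stop_domain("budget n must be >= 1")
  as_tibble(input)
}

#' Signed percent change between two group means
#'
#' 100 * (treatment - reference) / reference; negative values are
#' reductions.
#'
#' @param reference Reference (e.g. control) mean; must be > 0.
#' @param treatment Treatment mean.
#' @return Signed percent change.
#' @examples
#' percent_change(1.47, 0.19)  # -87.07: an 87% reduction
#' @export
percent_change <- function(reference, treatment) {
  if (any(reference <= 0)) stop_domain("reference mean must be > 0")
  100 * (treatment - reference) / reference
}

#' Metabolic share of the calcification carbon source
#'
#' Given per-timepoint ratios of skeletal 14C-bicarbonate incorporation to
#' Mg-adjusted 45Ca incorporation (the externally sourced share of
#' calcification carbon), returns the complementary metabolic-DIC share as
#' a percentage: 100 * (1 - mean(ratios)).
#'
#' @param external_ratios Ratios in \[0, 1\].
#' @return Percent of calcification carbon sourced from metabolic DIC.
#' @examples
#' metabolic_dic_share(c(0.647, 0.645))  # 35.4
#' @export
metabolic_dic_share <- function(external_ratios) {
  if (any(external_ratios < 0 | external_ratios > 1)) {
    stop_domain("external ratios must lie in [0, 1]")
  }
  100 * (1 - mean(external_ratios))
}
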