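#' Run the full incubation analysis pipeline
#'
#' One-call orchestration: simulate (or accept) a vial table, convert
#' activities to incorporation, apply the Mg adjustment and optional
#' direct-deposition blanks, summarise groups, estimate the organismal
#' release ratio psi_I from the inhibited treatment, partition the carbon
#' budget at the final timepoint with Monte-Carlo uncertainty, run the
#' group statistics, and evaluate the seawater-buffered psi as the
#' no-recycling expectation. A manifest (config snapshot, seed, package
#' version, and checksums of any files written) makes runs reproducible:
#' identical manifest in, identical checksums out.
#'
#' @param config A [sim_config()]; ignored when `vials` is supplied except
#'   for the label and adjustment parameters.
#' @param seed Integer seed for simulation and Monte-Carlo propagation.
#' @param vials Optional measured vial table (see [read_vials()]); when
#'   `NULL` one is simulated from `config`.
#' @param blank_rate Direct-deposition blank passed to
#'   [correct_direct_deposition()]; 0 disables the correction.
#' @param budget_timepoint_h Timepoint whose group statistics feed the
#'   budget (default: the last).
#' @param n_draws Monte-Carlo draws for [budget_propagate()].
#' @param seawater Named list of conditions for the buffered-psi
#'   reference: `temperature`, `salinity`, `ph`, `ph_scale`,
#'   `total_alkalinity` (umol/kg).
#' @param out_dir Optional directory; when given, the vial table,
#'   incorporation results, group summary and budget are written as CSV,
#'   a JSON report is emitted, and their md5 checksums are recorded in
#'   the manifest.
#'
#' @return A list of class `coralcarb_run`: `vials`, `incorporation`,
#'   `summary`, `psi_i_records`, `psi_i_summary`, `budget_input`,
#'   `budget`, `budget_mc`, `stats` (list of kw/dunn/pearson tables),
#'   `psi_seawater`, and `manifest`.
#'
#' @examples
#' run <- run_pipeline(sim_config(), seed = 1, n_draws = 1000)
#' run$budget
#' @export
run_pipeline <- function(config = sim_config(), seed, vials = NULL,
                         blank_rate = 0, budget_timepoint_h = NULL,
                         n_draws = 10000,
                         seawater = list(temperature = 15, salinity = 35,
                                         ph = 8.1, ph_scale = "NBS",
                                         total_alkalinity = 2300),
                         out_dir = NULL) {
  if (missing(seed)) stop_domain("`seed` is mandatory for run_pipeline()")
  if (is.null(vials)) vials <- sim_vials(config, seed = seed)
  vials <- validate_vials(vials)
  labels <- label_specs(config$label_activity_kbq, config$vial_volume_l,
                        config$ca_mol_kg, config$dic_mol_kg)

  incorp <- incorporation(vials, labels) |>
    mg_adjust(config$mg_over_ca)
  if (!identical(blank_rate, 0)) {
    incorp <- correct_direct_deposition(incorp, blank_rate)
  }
  summary_tbl <- summarise_incorporation(incorp)
  psi_records <- psi_i_records(incorp, treatment = config$treatments[2])
  psi_summary <- summarise_psi_i(psi_records)

  tp <- budget_timepoint_h %||% max(vials$timepoint_h)
  budget_input <- budget_input_from_summary(summary_tbl,
                                            treatment = config$treatments[1],
                                            timepoint_h = tp)
  budget <- budget_partition(
    organic = budget_input$mean[budget_input$component == "organic"],
    skeleton = budget_input$mean[budget_input$component == "skeleton"],
    net_release = budget_input$mean[budget_input$component == "net_release"])
  budget_mc <- budget_propagate(budget_input, n_draws = n_draws,
                                seed = seed + 1L)

  cells <- vials |>
    mutate(cell = paste(.data$treatment, .data$timepoint_h, sep = "_"))
  camg <- incorp |> filter(.data$channel == "ca45") |>
    mutate(cell = paste(.data$treatment, .data$timepoint_h, sep = "_"))
  wide <- incorp |>
    filter(.data$channel %in% c("ca45", "c14_inorganic")) |>
    select("vial_id", "treatment", "channel", "absolute_nmol_g") |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = "absolute_nmol_g")
  stats_out <- list(
    kw_calcification = kw_test(camg, .data$rate_nmol_h_g, .data$cell),
    dunn_calcification = dunn_sidak(camg, .data$rate_nmol_h_g, .data$cell),
    kw_o2 = if (!all(is.na(vials$o2_rate_umol_h_g)))
      kw_test(cells, .data$o2_rate_umol_h_g, .data$cell),
    pearson_c14_vs_camg = purrr::map(
      set_names(config$treatments),
      function(tr) pearson_cor(filter(wide, .data$treatment == tr),
                               .data$c14_inorganic, .data$ca45)) |>
      bind_rows(.id = "treatment")
  )

  sw_const <- carb_constants(seawater$temperature, seawater$salinity)
  sw_state <- solve_carb(seawater$temperature, seawater$salinity,
                         ph = seawater$ph,
                         total_alkalinity = seawater$total_alkalinity,
                         constants = sw_const,
                         ph_scale = seawater$ph_scale %||% "total")
  psi_sw <- psi_analytic(sw_state, sw_const)

  manifest <- list(
    package_version = as.character(packageVersion("coralcarb")),
    seed = seed,
    config = unclass(config),
    seawater = seawater,
    blank_rate = blank_rate,
    budget_timepoint_h = tp,
    n_draws = n_draws,
    files = list()
  )

  run <- structure(
    list(vials = vials, incorporation = incorp, summary = summary_tbl,
         psi_i_records = psi_records, psi_i_summary = psi_summary,
         budget_input = budget_input, budget = budget,
         budget_mc = budget_mc, stats = stats_out,
         psi_seawater = psi_sw, manifest = manifest),
    class = "coralcarb_run")

  if (!is.null(out_dir)) run <- write_run(run, out_dir)
  run
}

# Build the budget input (mean, sd, n per component) from the group
# summary of absolute incorporation at one treatment x timepoint.
budget_input_from_summary <- function(summary_tbl, treatment, timepoint_h) {
  sel <- summary_tbl |>
    filter(.data$treatment == !!treatment,
           .data$timepoint_h == !!timepoint_h)
  comp_map <- c(ca45 = "skeleton", c14_organic = "organic",
                c14_co2 = "net_release")
  need <- names(comp_map)
  if (!all(need %in% sel$channel)) {
    stop_domain("summary lacks the channels needed for the budget at this timepoint")
  }
  sel |>
    filter(.data$channel %in% need) |>
    mutate(component = unname(comp_map[.data$channel])) |>
    select("component", mean = "mean_absolute", sd = "sd_absolute", "n")
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vials = file.path(out_dir, "vials.csv"),
    incorporation = file.path(out_dir, "incorporation.csv"),
    summary = file.path(out_dir, "group_summary.csv"),
    budget = file.path(out_dir, "budget.csv"),
    report = file.path(out_dir, "report.json"))
  readr::write_csv(run$vials, paths[["vials"]])
  readr::write_csv(run$incorporation, paths[["incorporation"]])
  readr::write_csv(run$summary, paths[["summary"]])
  readr::write_csv(run$budget_mc, paths[["budget"]])
  report <- list(
    budget = run$budget, budget_mc = run$budget_mc,
    psi_i = run$psi_i_summary,
    psi_seawater = tidy(run$psi_seawater),
    kw_calcification = run$stats$kw_calcification,
    manifest = run$manifest[c("package_version", "seed", "blank_rate",
                              "budget_timepoint_h", "n_draws")])
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  run$manifest$files <- as.list(unname(tools::md5sum(paths)))
  names(run$manifest$files) <- basename(paths)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run
}

#' @export
print.coralcarb_run <- function(x, ...) {
  cat("<coralcarb_run>\n")
  cat(sprintf("  %d vials; seed %d; package %s\n", nrow(x$vials),
              x$manifest$seed, x$manifest$package_version))
  b <- x$budget
  cat(sprintf("  terminal sinks: skeleton %.0f%% / organic %.0f%% / net release %.0f%%\n",
              100 * b$frac_skeleton, 100 * b$frac_organic,
              100 * b$frac_net_release))
  cat(sprintf("  calcification demand %.0f%% of uptake; recycled %.0f%% of produced CO2\n",
              100 * b$frac_calc_demand, 100 * b$recycled_of_produced))
  cat(sprintf("  psi_I (+EZ, pooled, last timepoint) %.3f; seawater psi %.3f\n",
              x$psi_i_summary$psi_i_pooled[which.max(x$psi_i_summary$timepoint_h)],
              x$psi_seawater$psi))
  invisible(x)
}

#' Glance at a pipeline run
#'
#' One-row summary of the headline quantities of a [run_pipeline()]
#' result.
#'
#' @param x A `coralcarb_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.coralcarb_run <- function(x, ...) {
  tibble(
    n_vials = nrow(x$vials),
    seed = x$manifest$seed,
    frac_skeleton = x$budget$frac_skeleton,
    frac_organic = x$budget$frac_organic,
    frac_net_release = x$budget$frac_net_release,
    frac_calc_demand = x$budget$frac_calc_demand,
    recycled_of_produced = x$budget$recycled_of_produced,
    psi_i_pooled = x$psi_i_summary$psi_i_pooled[
      which.max(x$psi_i_summary$timepoint_h)],
    psi_seawater = x$psi_seawater$psi,
    kw_calcification_h = x$stats$kw_calcification$statistic,
    kw_calcification_p = x$stats$kw_calcification$p_value
  )
}

#' Recompute the study's headline numbers from printed inputs
#'
#' Reproduces, from printed group statistics alone (no raw data), the
#' quantities a reader would check first: the budget partition from the
#' 39/38/23 organic/skeleton/net-release split, the calcification-demand
#' and recycling percentages, the percent reduction of calcification under
#' carbonic-anhydrase inhibition (1.47 -> 0.19 nmol Ca+Mg/h/g), the
#' metabolic share of the calcification carbon source from the
#' external-ratio pair (0.647, 0.645), and the seawater-buffered psi at
#' the incubation temperature.
#'
#' @param sweep Data frame of seawater conditions for the psi sweep;
#'   defaults to [loch_sween_sweep()].
#' @return A tibble with `quantity`, `value`, `units`.
#' @examples
#' reproduce_headline()
#' @export
reproduce_headline <- function(sweep = loch_sween_sweep()) {
  b <- budget_partition(organic = 39, skeleton = 38, net_release = 23)
  psi <- psi_reference(sweep)
  tibble(
    quantity = c("frac_skeleton_pct", "frac_organic_pct",
                 "frac_net_release_pct", "calc_demand_pct",
                 "total_fixed_pct", "recycled_of_produced_pct",
                 "released_of_produced_pct", "ca_inhibition_pct_change",
                 "metabolic_dic_share_pct", "psi_seawater"),
    value = c(100 * b$frac_skeleton, 100 * b$frac_organic,
              100 * b$frac_net_release, 100 * b$frac_calc_demand,
              100 * b$frac_total_fixed, 100 * b$recycled_of_produced,
              100 * b$released_of_produced,
              percent_change(1.47, 0.19),
              metabolic_dic_share(c(0.647, 0.645)),
              psi$psi_one_decimal),
    units = c(rep("% of total uptake", 5), rep("% of produced CO2", 2),
              "%", "% of calcification carbon", "mol CO2 / mol CO3")
  )
}

#' Plausible west-Scotland summer surface-seawater conditions
#'
#' The default sweep used to evaluate the buffered CO2-release ratio at
#' the 15 degC incubation temperature: salinity 34-35, total alkalinity
#' 2300 umol/kg, pH 8.05-8.10 on the NBS scale.
#'
#' @return A tibble of conditions for [psi_grid()].
#' @export
loch_sween_sweep <- function() {
  tidyr::expand_grid(
    temperature = 15,
    salinity = c(34, 34.5, 35),
    ph = c(8.05, 8.075, 8.10),
    total_alkalinity = 2300,
    ph_scale = "NBS")
}

#' Buffered-release ratio over a condition sweep, reported to one decimal
#'
#' Evaluates psi over a sweep of seawater conditions and reports a single
#' reference value. The exact pH of the incubation water is not an
#' observable of the vial experiment, so the sweep is anchored at the
#' condition whose solved pCO2 lies closest to atmospheric: mesocosm
#' seawater is aerated for weeks before incubation and therefore sits
#' near air equilibrium. The anchored psi is reported to one decimal
#' alongside the full sweep, so the sensitivity across the band is always
#' visible. Used by [reproduce_headline()] and the acceptance script.
#'
#' @param sweep Conditions for [psi_grid()].
#' @param reference_pco2_uatm Atmospheric anchor (default 420 uatm,
#'   present-day air).
#' @param formulation K1/K2 formulation passed down to [psi_grid()].
#' @return A list: `grid` (full sweep with psi), `anchor` (the anchored
#'   row), `psi` (anchored value) and `psi_one_decimal`.
#' @export
psi_reference <- function(sweep = loch_sween_sweep(),
                          reference_pco2_uatm = 420,
                          formulation = "lueker2000") {
  grid <- psi_grid(sweep, formulation = formulation)
  anchor <- grid[which.min(abs(grid$pco2 - reference_pco2_uatm)), ]
  list(grid = grid, anchor = anchor, psi = anchor$psi,
       psi_one_decimal = round(anchor$psi, 1))
}
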