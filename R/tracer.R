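#' Specific-concentration label specifications for the two isotopes
#'
#' Converts the amount of radiolabel added to a vial into the specific
#' concentration `Con` (nmol of carrier per kBq of label) that turns a
#' counted activity into moles of the traced species. For 45Ca the carrier
#' pool is seawater calcium in the vial; for 14C it is the vial's DIC.
#'
#' @param activity_kbq Label activity added per vial (kBq).
#' @param vial_volume_l Vial volume (litres); the carrier pool assumes
#'   1 kg of seawater per litre.
#' @param ca_mol_kg Seawater calcium concentration (mol/kg; default
#'   10.28 mmol/kg, the S = 35 value).
#' @param dic_mol_kg Seawater DIC (mol/kg; default 2.1 mmol/kg).
#'
#' @return A list of class `label_specs` with elements `ca45` and `c14`,
#'   each holding `activity_kbq`, `carrier_pool_mol` and `con_nmol_kbq`.
#'
#' @examples
#' label_specs()$ca45$con_nmol_kbq  # ~343 nmol/kBq
#' @export
label_specs <- function(activity_kbq = 600, vial_volume_l = 0.02,
                        ca_mol_kg = 0.01028, dic_mol_kg = 0.0021) {
  check_scalar_number(activity_kbq, "activity_kbq", lower = 1e-12)
  check_scalar_number(vial_volume_l, "vial_volume_l", lower = 1e-12)
  check_scalar_number(ca_mol_kg, "ca_mol_kg", lower = 0)
  check_scalar_number(dic_mol_kg, "dic_mol_kg", lower = 0)
  one <- function(pool_mol) {
    list(activity_kbq = activity_kbq, carrier_pool_mol = pool_mol,
         con_nmol_kbq = pool_mol * 1e9 / activity_kbq)
  }
  structure(list(ca45 = one(ca_mol_kg * vial_volume_l),
                 c14 = one(dic_mol_kg * vial_volume_l)),
            class = "label_specs")
}

# channel -> (activity column, isotope label) map; single source of truth
tracer_channels <- function() {
  tibble(
    channel = c("ca45", "c14_inorganic", "c14_organic", "c14_co2"),
    column = c("act_ca45_skel_kbq", "act_c14_skel_kbq",
               "act_c14_org_kbq", "act_c14_co2_kbq"),
    isotope = c("ca45", "c14", "c14", "c14")
  )
}

#' Radioisotope incorporation from counted activities
#'
#' Converts per-vial scintillation activities into absolute incorporation
#' (nmol per g dry mass) and incorporation rates (nmol per hour per g):
#' rate = activity x Con / (M x T), absolute = rate x T, where `Con` is
#' the label's specific concentration, `M` the dry skeletal mass and `T`
#' the incubation time. The result is one row per vial x channel.
#'
#' @param vials A vial table as produced by [sim_vials()] or read with
#'   [read_vials()]: columns `vial_id`, `treatment`, `timepoint_h`,
#'   `dry_mass_g` and the activity columns
#'   `act_ca45_skel_kbq`, `act_c14_skel_kbq`, `act_c14_org_kbq`,
#'   `act_c14_co2_kbq` (missing activity columns are skipped).
#' @param labels A [label_specs()] object.
#' @param channels Channels to compute; any of `"ca45"`,
#'   `"c14_inorganic"`, `"c14_organic"`, `"c14_co2"`.
#'
#' @return A tibble with columns `vial_id`, `treatment`, `timepoint_h`,
#'   `dry_mass_g`, `channel`, `activity_kbq`, `rate_nmol_h_g`,
#'   `absolute_nmol_g`, `mg_adjusted`, `corrected`.
#'
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' incorporation(vials) |> head()
#' @export
incorporation <- function(vials, labels = label_specs(),
                          channels = tracer_channels()$channel) {
  vials <- validate_vials(vials)
  map <- tracer_channels() |> filter(.data$channel %in% channels)
  missing_cols <- setdiff(map$column, names(vials))
  map <- map |> filter(!.data$column %in% missing_cols)
  if (nrow(map) == 0) stop_domain("no requested activity column present in `vials`")
  purrr::pmap(map, function(channel, column, isotope) {
    con <- labels[[isotope]]$con_nmol_kbq
    vials |>
      mutate(channel = channel,
             activity_kbq = .data[[column]],
             rate_nmol_h_g = .data$activity_kbq * con /
               (.data$dry_mass_g * .data$timepoint_h),
             absolute_nmol_g = .data$rate_nmol_h_g * .data$timepoint_h,
             mg_adjusted = FALSE, corrected = FALSE) |>
      select("vial_id", "treatment", "timepoint_h", "dry_mass_g", "channel",
             "activity_kbq", "rate_nmol_h_g", "absolute_nmol_g",
             "mg_adjusted", "corrected")
  }) |> bind_rows()
}

#' Adjust 45Ca incorporation for parallel magnesium incorporation
#'
#' Coralline algae deposit high-Mg calcite, so carbonate deposition
#' exceeds what 45Ca alone traces. The calcium-based incorporation is
#' scaled by (1 + Mg/Ca) to give total Ca+Mg deposition. Only rows of the
#' `ca45` channel are adjusted; applying the adjustment twice errors.
#'
#' @param incorp An [incorporation()] result.
#' @param mg_over_ca Molar Mg/Ca ratio of the deposited calcite
#'   (default 0.15, typical of high-Mg calcite).
#' @return `incorp` with `ca45` rates and absolutes multiplied by
#'   `1 + mg_over_ca` and `mg_adjusted` set.
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' incorporation(vials) |> mg_adjust() |> head()
#' @export
mg_adjust <- function(incorp, mg_over_ca = 0.15) {
  check_scalar_number(mg_over_ca, "mg_over_ca", lower = 0)
  validate_incorp(incorp)
  is_ca <- incorp$channel == "ca45"
  if (any(incorp$mg_adjusted[is_ca])) {
    stop_usage("Mg adjustment already applied to these ca45 rows")
  }
  incorp |>
    mutate(
      rate_nmol_h_g = ifelse(is_ca, .data$rate_nmol_h_g * (1 + mg_over_ca),
                             .data$rate_nmol_h_g),
      absolute_nmol_g = ifelse(is_ca, .data$absolute_nmol_g * (1 + mg_over_ca),
                               .data$absolute_nmol_g),
      mg_adjusted = ifelse(is_ca, TRUE, .data$mg_adjusted)
    )
}

#' Correct incorporation for direct deposition on bare skeleton
#'
#' Branches snapped from parent thalli expose bare skeleton on which
#' labelled bicarbonate can deposit abiotically, overestimating
#' incorporation. The correction subtracts a blank rate (from dedicated
#' blank vials or configuration), flooring at zero; clamped rows are
#' reported via a message so the event is logged, never silent.
#'
#' @param incorp An [incorporation()] result.
#' @param blank_rate Either a single rate (nmol/h/g) applied everywhere,
#'   or a data frame with columns `timepoint_h` and `blank_rate_nmol_h_g`
#'   (optionally `channel`) for per-timepoint blanks.
#' @param channels Channels to correct (default `"ca45"` and
#'   `"c14_inorganic"`, the skeletal channels).
#' @return `incorp` with corrected rates/absolutes and `corrected` set on
#'   the targeted channels.
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' incorporation(vials) |> correct_direct_deposition(0.02) |> head()
#' @export
correct_direct_deposition <- function(incorp, blank_rate,
                                      channels = c("ca45", "c14_inorganic")) {
  validate_incorp(incorp)
  if (is.data.frame(blank_rate)) {
    if (!all(c("timepoint_h", "blank_rate_nmol_h_g") %in% names(blank_rate))) {
      stop_domain("`blank_rate` data frame needs columns timepoint_h and blank_rate_nmol_h_g")
    }
    by <- intersect(c("timepoint_h", "channel"), names(blank_rate))
    incorp2 <- incorp |> left_join(as_tibble(blank_rate), by = by) |>
      mutate(.blank = dplyr::coalesce(.data$blank_rate_nmol_h_g, 0)) |>
      select(-"blank_rate_nmol_h_g")
  } else {
    check_scalar_number(blank_rate, "blank_rate", lower = 0)
    incorp2 <- incorp |> mutate(.blank = blank_rate)
  }
  if (any(incorp2$.blank < 0)) stop_domain("blank rates must be >= 0")
  target <- incorp2$channel %in% channels
  clamped <- target & (incorp2$rate_nmol_h_g < incorp2$.blank)
  if (any(clamped)) {
    inform(sprintf(
      "direct-deposition correction clamped %d of %d rates at zero",
      sum(clamped), sum(target)))
  }
  incorp2 |>
    mutate(
      rate_nmol_h_g = ifelse(target,
                             pmax(0, .data$rate_nmol_h_g - .data$.blank),
                             .data$rate_nmol_h_g),
      absolute_nmol_g = ifelse(target,
                               .data$rate_nmol_h_g * .data$timepoint_h,
                               .data$absolute_nmol_g),
      corrected = ifelse(target, TRUE, .data$corrected)
    ) |>
    select(-".blank")
}

#' Organismal ratio of calcification-released CO2 to precipitated carbon
#'
#' `psi_i()` is the elementary estimator: (CO2 production - organic
#' fixation) / Mg-adjusted Ca incorporation, all three in the same units.
#' It may legitimately be negative in noisy early timepoints; negative
#' values are reported with a warning, never clamped.
#'
#' `psi_i_records()` computes the per-vial estimate from an
#' [incorporation()] table (channels `c14_co2`, `c14_organic` and
#' Mg-adjusted `ca45`), restricted by default to the carbonic-anhydrase
#' inhibited (+EZ) treatment, in which CO2 uptake through the cell's
#' carbon-concentrating machinery is suppressed so the medium 14CO2 signal
#' isolates calcification-derived CO2. `summarise_psi_i()` gives the
#' per-timepoint mean, sd and n, and additionally the cohort-level
#' ratio-of-group-means estimate `psi_i_pooled`, which is first-order
#' unbiased under multiplicative measurement noise (see vignette).
#'
#' @param co2_production CO2 production (e.g. nmol/h/g).
#' @param organic_fixation Organic fixation, same units.
#' @param ca_mg_incorporation Mg-adjusted Ca incorporation, same units;
#'   must be > 0.
#' @return `psi_i()`: numeric vector. `psi_i_records()`: tibble with one
#'   row per vial (`vial_id`, `treatment`, `timepoint_h`, the three input
#'   rates and `psi_i`). `summarise_psi_i()`: one row per timepoint.
#' @examples
#' psi_i(5, 1.2, 10)  # 0.38
#' @export
psi_i <- function(co2_production, organic_fixation, ca_mg_incorporation) {
  if (any(ca_mg_incorporation <= 0)) {
    stop_domain("ca_mg_incorporation must be > 0 (zero denominator)")
  }
  out <- (co2_production - organic_fixation) / ca_mg_incorporation
  if (any(out < 0)) {
    warn(sprintf("%d negative psi_I value(s) reported (noise-dominated records)",
                 sum(out < 0)))
  }
  out
}

#' @rdname psi_i
#' @param incorp An [incorporation()] table with Mg adjustment applied.
#' @param treatment Treatment whose records enter the estimator
#'   (default `"EZ"`).
#' @export
psi_i_records <- function(incorp, treatment = "EZ") {
  validate_incorp(incorp)
  need <- c("ca45", "c14_organic", "c14_co2")
  if (!all(need %in% incorp$channel)) {
    stop_domain("`incorp` must contain channels ca45, c14_organic and c14_co2")
  }
  if (!any(incorp$mg_adjusted[incorp$channel == "ca45"])) {
    stop_usage("apply mg_adjust() before psi_i_records()")
  }
  wide <- incorp |>
    filter(.data$treatment == !!treatment, .data$channel %in% need) |>
    select("vial_id", "treatment", "timepoint_h", "channel",
           "rate_nmol_h_g") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "rate_nmol_h_g")
  wide |>
    mutate(psi_i = psi_i(.data$c14_co2, .data$c14_organic, .data$ca45))
}

#' @rdname psi_i
#' @param records A [psi_i_records()] result.
#' @export
summarise_psi_i <- function(records) {
  records |>
    group_by(.data$treatment, .data$timepoint_h) |>
    summarise(
      mean_psi_i = mean(.data$psi_i),
      sd_psi_i = sd(.data$psi_i),
      n = dplyr::n(),
      psi_i_pooled = (mean(.data$c14_co2) - mean(.data$c14_organic)) /
        mean(.data$ca45),
      .groups = "drop"
    )
}

#' Per-group incorporation summary
#'
#' Mean, standard deviation and n of rates and absolute incorporation by
#' treatment, timepoint and channel -- the shape consumed by the budget
#' module and written by the pipeline.
#'
#' @param incorp An [incorporation()] result.
#' @return A tibble with one row per treatment x timepoint x channel.
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' incorporation(vials) |> summarise_incorporation()
#' @export
summarise_incorporation <- function(incorp) {
  validate_incorp(incorp)
  incorp |>
    group_by(.data$treatment, .data$timepoint_h, .data$channel) |>
    summarise(
      mean_rate = mean(.data$rate_nmol_h_g),
      sd_rate = sd(.data$rate_nmol_h_g),
      mean_absolute = mean(.data$absolute_nmol_g),
      sd_absolute = sd(.data$absolute_nmol_g),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-interval incorporation rates between consecutive timepoints
#'
#' Cumulative rates divide the absolute incorporation by the full
#' incubation time. This alternative computes, from group-mean absolute
#' incorporation, the rate within each interval between consecutive
#' timepoints: (mean_abs(t2) - mean_abs(t1)) / (t2 - t1).
#'
#' @param incorp An [incorporation()] result.
#' @return A tibble with one row per treatment x channel x interval.
#' @export
interval_rates <- function(incorp) {
  summarise_incorporation(incorp) |>
    group_by(.data$treatment, .data$channel) |>
    arrange(.data$timepoint_h, .by_group = TRUE) |>
    mutate(
      interval_start_h = dplyr::lag(.data$timepoint_h, default = 0),
      interval_rate = (.data$mean_absolute -
                         dplyr::lag(.data$mean_absolute, default = 0)) /
        (.data$timepoint_h - .data$interval_start_h)
    ) |>
    ungroup() |>
    select("treatment", "channel", "interval_start_h",
           interval_end_h = "timepoint_h", "interval_rate")
}

#' Skeletal mass gain implied by a calcification rate
#'
#' Convenience conversion from a Ca+Mg deposition rate (nmol/h/g) to a
#' percent-per-day skeletal mass gain, assuming the deposit is
#' (Ca,Mg)CO3 with a configurable mean molar mass. Note: measured
#' nmol-scale deposition rates translate to mass gains around 2e-4 %/day,
#' three orders of magnitude below percent-level daily gains reported by
#' buoyant-weight methods; the two observables are not interchangeable and
#' this helper is provided for transparency only.
#'
#' @param rate_nmol_h_g Ca+Mg deposition rate, nmol/h/g dry mass.
#' @param molar_mass_g_mol Mean molar mass of the deposited carbonate
#'   (default 97.6 g/mol: 0.85 CaCO3 + 0.15 MgCO3).
#' @return Percent mass gain per day.
#' @export
mass_gain_percent_per_day <- function(rate_nmol_h_g, molar_mass_g_mol = 97.6) {
  rate_nmol_h_g * 1e-9 * molar_mass_g_mol * 24 * 100
}

validate_vials <- function(vials) {
  if (!is.data.frame(vials)) stop_domain("`vials` must be a data frame")
  vials <- as_tibble(vials)
  need <- c("vial_id", "treatment", "timepoint_h", "dry_mass_g")
  missing_cols <- setdiff(need, names(vials))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("`vials` is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(vials$dry_mass_g <= 0)) stop_domain("dry_mass_g must be > 0")
  if (any(vials$timepoint_h <= 0)) stop_domain("timepoint_h must be > 0")
  act_cols <- intersect(tracer_channels()$column, names(vials))
  for (cc in act_cols) {
    if (any(vials[[cc]] < 0, na.rm = TRUE)) {
      stop_domain(sprintf("%s contains negative activities", cc))
    }
  }
  vials
}

validate_incorp <- function(incorp) {
  need <- c("vial_id", "treatment", "timepoint_h", "channel",
            "rate_nmol_h_g", "absolute_nmol_g", "mg_adjusted", "corrected")
  missing_cols <- setdiff(need, names(incorp))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("incorporation table is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  invisible(incorp)
}

#' Read and write vial tables
#'
#' The on-disk interchange format is a UTF-8 CSV with one row per vial and
#' the header `vial_id, treatment, timepoint_h, dry_mass_g,
#' act_ca45_skel_kbq, act_c14_skel_kbq, act_c14_org_kbq, act_c14_co2_kbq,
#' o2_rate_umol_h_g` (the oxygen column may be empty). [sim_vials()]
#' writes the same schema, so simulated and measured tables are
#' interchangeable.
#'
#' @param path CSV file path.
#' @return `read_vials()` returns a validated tibble; `write_vials()`
#'   returns `path` invisibly.
#' @export
read_vials <- function(path) {
  vials <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             vial_id = readr::col_character(),
                             treatment = readr::col_character(),
                             .default = readr::col_double()))
  validate_vials(vials)
}

#' @rdname read_vials
#' @param vials A vial table.
#' @export
write_vials <- function(vials, path) {
  readr::write_csv(validate_vials(vials), path)
  invisible(path)
}
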