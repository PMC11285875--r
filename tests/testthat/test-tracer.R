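# Radioisotope bookkeeping: incorporation, adjustments, psi_I.

test_that("label specific concentrations follow from carrier pool and activity", {
  ls <- label_specs()
  expect_equal(ls$ca45$con_nmol_kbq, 0.01028 * 0.02 * 1e9 / 600)
  expect_equal(ls$c14$con_nmol_kbq, 0.0021 * 0.02 * 1e9 / 600)
  expect_equal(ls$ca45$carrier_pool_mol * 1e9 / ls$ca45$activity_kbq,
               ls$ca45$con_nmol_kbq, tolerance = 1e-12)
  expect_error(label_specs(activity_kbq = 0), class = "coralcarb_domain_error")
})

test_that("incorporation implements rate = activity * Con / (M * T)", {
  inc <- incorporation(tiny_vials(), unit_labels())
  row <- inc[inc$vial_id == "T01" & inc$channel == "ca45", ]
  expect_equal(row$rate_nmol_h_g, 2 * 1.5 / (0.5 * 5))  # = 1.2
  expect_equal(row$absolute_nmol_g, row$rate_nmol_h_g * 5)
  org_ez <- inc[inc$vial_id == "T03" & inc$channel == "c14_organic", ]
  expect_equal(org_ez$rate_nmol_h_g, 0)
  expect_equal(org_ez$absolute_nmol_g, 0)
  expect_false(any(inc$mg_adjusted) || any(inc$corrected))
})

test_that("incorporation is homogeneous in activity, Con, mass and time", {
  base <- tiny_vials()
  inc0 <- incorporation(base, unit_labels())
  heavier <- dplyr::mutate(base, dry_mass_g = dry_mass_g * 2)
  expect_equal(incorporation(heavier, unit_labels())$rate_nmol_h_g,
               inc0$rate_nmol_h_g / 2)
  longer <- dplyr::mutate(base, timepoint_h = timepoint_h * 4)
  expect_equal(incorporation(longer, unit_labels())$rate_nmol_h_g,
               inc0$rate_nmol_h_g / 4)
  hotter <- dplyr::mutate(base, dplyr::across(dplyr::starts_with("act_"),
                                              ~ .x * 3))
  expect_equal(incorporation(hotter, unit_labels())$rate_nmol_h_g,
               inc0$rate_nmol_h_g * 3)
  expect_equal(incorporation(base, unit_labels(3))$rate_nmol_h_g,
               inc0$rate_nmol_h_g * 2)
})

test_that("invalid vial tables raise domain errors", {
  bad_mass <- dplyr::mutate(tiny_vials(), dry_mass_g = 0)
  expect_error(incorporation(bad_mass, unit_labels()),
               class = "coralcarb_domain_error")
  bad_act <- dplyr::mutate(tiny_vials(), act_ca45_skel_kbq = -1)
  expect_error(incorporation(bad_act, unit_labels()),
               class = "coralcarb_domain_error")
  expect_error(incorporation(tiny_vials()[, 1:3], unit_labels()),
               "missing column", class = "coralcarb_domain_error")
})

test_that("mg_adjust scales only the calcium channel and refuses double application", {
  inc <- incorporation(tiny_vials(), unit_labels())
  adj0 <- mg_adjust(inc, mg_over_ca = 0)
  expect_equal(adj0$rate_nmol_h_g, inc$rate_nmol_h_g)
  adj <- mg_adjust(inc, mg_over_ca = 0.15)
  is_ca <- adj$channel == "ca45"
  expect_equal(adj$rate_nmol_h_g[is_ca], inc$rate_nmol_h_g[is_ca] * 1.15)
  expect_equal(adj$rate_nmol_h_g[!is_ca], inc$rate_nmol_h_g[!is_ca])
  expect_true(all(adj$mg_adjusted[is_ca]))
  expect_error(mg_adjust(adj), class = "coralcarb_usage_error")
})

test_that("direct-deposition correction subtracts, clamps at zero and logs the clamp", {
  inc <- incorporation(tiny_vials(), unit_labels())
  same <- correct_direct_deposition(inc, 0)
  expect_equal(same$rate_nmol_h_g, inc$rate_nmol_h_g)
  expect_true(all(same$corrected[same$channel == "ca45"]))
  corr <- correct_direct_deposition(inc, 0.2, channels = "ca45")
  ctrl <- corr[corr$vial_id == "T01" & corr$channel == "ca45", ]
  expect_equal(ctrl$rate_nmol_h_g, 1.2 - 0.2)
  expect_equal(ctrl$absolute_nmol_g, 1.0 * 5)
  # EZ ca45 rate is 0.3; a 0.4 blank must clamp to zero, with a message
  expect_message(
    clamped <- correct_direct_deposition(inc, 0.4, channels = "ca45"),
    "clamped")
  expect_equal(
    clamped$rate_nmol_h_g[clamped$vial_id == "T03" & clamped$channel == "ca45"],
    0)
  # per-timepoint blank table
  blanks <- tibble::tibble(timepoint_h = 5, blank_rate_nmol_h_g = 0.1)
  bt <- correct_direct_deposition(inc, blanks, channels = "ca45")
  expect_equal(bt$rate_nmol_h_g[bt$vial_id == "T01" & bt$channel == "ca45"],
               1.1)
})

test_that("psi_i computes the release ratio and reports negatives with a warning", {
  expect_equal(psi_i(5, 1.2, 10), 0.38)
  expect_equal(psi_i(3, 3, 7), 0)
  # invariant to common rescaling
  expect_equal(psi_i(5 * 12, 1.2 * 12, 10 * 12), psi_i(5, 1.2, 10))
  expect_warning(neg <- psi_i(1, 2, 4), "negative")
  expect_equal(neg, -0.25)
  expect_error(psi_i(5, 1.2, 0), class = "coralcarb_domain_error")
})

test_that("psi_i_records restricts to the inhibited treatment and needs the Mg adjustment", {
  inc <- incorporation(tiny_vials(), unit_labels())
  expect_error(psi_i_records(inc), class = "coralcarb_usage_error")
  adj <- mg_adjust(inc, 0.15)
  rec <- psi_i_records(adj)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$treatment == "EZ"))
  # activities 0.2 (co2), 0 (organic), 0.5 * 1.15 (Ca+Mg), Con common
  expect_equal(rec$psi_i, rep((0.2 - 0) / (0.5 * 1.15), 2))
  s <- summarise_psi_i(rec)
  expect_equal(s$n, 2)
  expect_equal(s$psi_i_pooled, s$mean_psi_i)  # identical replicates
})

test_that("group summaries and interval rates are consistent with the records", {
  inc <- incorporation(tiny_vials(), unit_labels())
  s <- summarise_incorporation(inc)
  expect_equal(nrow(s), 2 * 4)  # 2 treatments x 4 channels, one timepoint
  ca <- s[s$treatment == "control" & s$channel == "ca45", ]
  expect_equal(ca$mean_rate, 1.2)
  expect_equal(ca$sd_rate, 0)
  expect_equal(ca$n, 2)
  ir <- interval_rates(inc)
  # single timepoint: interval rate equals the cumulative rate
  expect_equal(ir$interval_rate[ir$treatment == "control" &
                                  ir$channel == "ca45"], 1.2)
})

test_that("vial tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  vials <- sim_vials(sim_config(), seed = 7)
  write_vials(vials, path)
  back <- read_vials(path)
  expect_equal(as.data.frame(back), as.data.frame(vials), tolerance = 1e-12)
})

test_that("the mass-gain convenience conversion has the documented scale", {
  # nmol-scale deposition translates to ~2e-4 %/day, not percent-level
  expect_lt(mass_gain_percent_per_day(1.47), 1e-2)
  expect_equal(mass_gain_percent_per_day(1.47),
               1.47e-9 * 97.6 * 24 * 100)
})
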