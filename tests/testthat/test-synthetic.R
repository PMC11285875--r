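# The forward simulator of the incubation design.

test_that("the default design yields 2 x 4 x 8 = 64 vials in the CSV schema", {
  vials <- sim_vials(sim_config(), seed = 2)
  expect_equal(nrow(vials), 64)
  expect_named(vials, c("vial_id", "treatment", "timepoint_h", "dry_mass_g",
                        "act_ca45_skel_kbq", "act_c14_skel_kbq",
                        "act_c14_org_kbq", "act_c14_co2_kbq",
                        "o2_rate_umol_h_g"))
  counts <- dplyr::count(vials, treatment, timepoint_h)
  expect_equal(nrow(counts), 8)
  expect_true(all(counts$n == 8))
  expect_true(all(vials$timepoint_h %in% c(0.5, 1.5, 3, 5)))
  expect_true(all(vials$dry_mass_g > 0))
  expect_true(all(dplyr::select(vials, dplyr::starts_with("act_")) >= 0))
})

test_that("identical seed and config give byte-identical tables", {
  cfg <- sim_config()
  expect_identical(sim_vials(cfg, seed = 123), sim_vials(cfg, seed = 123))
  expect_false(identical(sim_vials(cfg, seed = 123),
                         sim_vials(cfg, seed = 124)))
  expect_error(sim_vials(cfg), class = "coralcarb_domain_error")
})

test_that("noise-free simulation inverts exactly through the tracer pipeline", {
  cfg <- noise_free_config()
  vials <- sim_vials(cfg, seed = 1)
  labels <- label_specs(cfg$label_activity_kbq, cfg$vial_volume_l,
                        cfg$ca_mol_kg, cfg$dic_mol_kg)
  inc <- mg_adjust(incorporation(vials, labels), cfg$mg_over_ca)
  camg <- inc[inc$channel == "ca45", ]
  expect_equal(camg$rate_nmol_h_g,
               unname(cfg$calc_rate_camg[camg$treatment]),
               tolerance = 1e-12)
  org <- inc[inc$channel == "c14_organic", ]
  expect_equal(org$rate_nmol_h_g, unname(cfg$organic_rate[org$treatment]),
               tolerance = 1e-12)
  co2 <- inc[inc$channel == "c14_co2", ]
  expect_equal(co2$rate_nmol_h_g,
               unname(cfg$co2_release_rate[co2$treatment]),
               tolerance = 1e-12)
  # the psi_I estimator then recovers the configured truth exactly
  s <- summarise_psi_i(psi_i_records(inc))
  expect_equal(s$psi_i_pooled, rep(cfg$psi_i_true, 4), tolerance = 1e-12)
  # and the control budget closes on the configured sink fractions
  b <- budget_partition(
    organic = cfg$organic_rate[["control"]],
    skeleton = cfg$calc_rate_camg[["control"]],
    net_release = cfg$co2_release_rate[["control"]])
  expect_equal(b$frac_skeleton, cfg$frac_skeleton)
  expect_equal(b$frac_organic, cfg$frac_organic)
  expect_equal(b$frac_net_release, cfg$frac_net_release)
})

test_that("derived truth rates follow from the sink fractions", {
  cfg <- sim_config()
  expect_equal(cfg$organic_rate[["control"]], 1.47 * 0.39 / 0.38)
  expect_equal(cfg$co2_release_rate[["control"]], 1.47 * 0.23 / 0.38)
  expect_equal(cfg$co2_release_rate[["EZ"]], 0.38 * 0.19)
})

test_that("oxygen rates encode the inhibition effect except at the first timepoint", {
  cfg <- noise_free_config()
  vials <- sim_vials(cfg, seed = 1)
  m <- vials |>
    dplyr::summarise(o2 = mean(o2_rate_umol_h_g),
                     .by = c(treatment, timepoint_h)) |>
    tidyr::pivot_wider(names_from = treatment, values_from = o2)
  expect_equal(m$control, rep(cfg$o2_rate_control, 4))
  expect_equal(m$control[m$timepoint_h == 0.5],
               m$EZ[m$timepoint_h == 0.5])
  expect_equal(percent_change(m$EZ[m$timepoint_h == 5],
                              m$control[m$timepoint_h == 5]), 86)
  # unit factors disable the effect entirely
  flat <- noise_free_config(o2_ez_factor = c(`0.5` = 1, `1.5` = 1,
                                             `3` = 1, `5` = 1))
  fv <- sim_vials(flat, seed = 1)
  expect_equal(mean(fv$o2_rate_umol_h_g[fv$treatment == "EZ"]),
               mean(fv$o2_rate_umol_h_g[fv$treatment == "control"]))
})

test_that("pipeline estimates are unbiased over repeated cohorts", {
  cfg <- sim_config()
  labels <- label_specs(cfg$label_activity_kbq, cfg$vial_volume_l,
                        cfg$ca_mol_kg, cfg$dic_mol_kg)
  ests <- purrr::map(1:60, function(s) {
    vials <- sim_vials(cfg, seed = 4000 + s) |>
      dplyr::filter(timepoint_h == 5)
    inc <- mg_adjust(incorporation(vials, labels), cfg$mg_over_ca)
    tibble::tibble(
      camg = mean(inc$rate_nmol_h_g[inc$channel == "ca45" &
                                      inc$treatment == "control"]),
      organic = mean(inc$rate_nmol_h_g[inc$channel == "c14_organic" &
                                         inc$treatment == "control"]),
      psi_i = summarise_psi_i(psi_i_records(inc))$psi_i_pooled)
  }) |> dplyr::bind_rows()
  for (col in c("camg", "organic", "psi_i")) {
    truth <- c(camg = cfg$calc_rate_camg[["control"]],
               organic = cfg$organic_rate[["control"]],
               psi_i = cfg$psi_i_true)[[col]]
    bias <- mean(ests[[col]]) - truth
    expect_lt(abs(bias), 0.5 * sd(ests[[col]]))
  }
})

test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(frac_skeleton = 0.5), "sum to 1",
               class = "coralcarb_domain_error")
  expect_error(sim_config(calc_rate_camg = c(a = 1, b = 2)),
               class = "coralcarb_domain_error")
  expect_error(sim_config(noise_cv = -0.1), class = "coralcarb_domain_error")
  expect_error(sim_config(timepoints_h = c(0.5, 2)),
               class = "coralcarb_domain_error")
})
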