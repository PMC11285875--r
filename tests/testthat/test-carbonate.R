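# Equilibrium constants and CO2-system speciation.

test_that("constants at 25 degC / S 35 match the published formulations", {
  k <- carb_constants(25, 35)
  # frozen from direct evaluation of the closed-form expressions
  expect_equal(-log10(k$K1), 5.8472, tolerance = 1e-4)
  expect_equal(-log10(k$K2), 8.9660, tolerance = 1e-4)
  expect_equal(-log10(k$KB), 8.5975, tolerance = 1e-4)
  expect_equal(k$K0, 0.02839, tolerance = 1e-3)
  expect_equal(k$TB, 0.000416)  # Uppstrom at S = 35
  expect_equal(carb_constants(12, 35)$TB, 0.000416)  # T-independent
  expect_equal(carb_constants(25, 17.5)$TB, 0.000416 / 2)
})

test_that("constants are positive, ordered and deterministic", {
  for (f in c("lueker2000", "dickson_millero1987", "roy1993")) {
    for (tc in c(5, 15, 25)) {
      k <- carb_constants(tc, 35, formulation = f)
      expect_true(all(unlist(k[c("K0", "K1", "K2", "KB", "Kw", "TB")]) > 0))
      expect_gt(k$K1, k$K2)
      expect_true(k$K1 < 1e-5 && k$K1 > 1e-11)
      expect_true(k$K2 < 1e-5 && k$K2 > 1e-11)
    }
  }
  expect_identical(carb_constants(15, 35), carb_constants(15, 35))
  # the two Mehrbach refits agree closely once on a common scale
  a <- carb_constants(15, 35, "lueker2000")
  b <- carb_constants(15, 35, "dickson_millero1987")
  expect_equal(log10(a$K1), log10(b$K1), tolerance = 0.01)
  expect_equal(log10(a$K2), log10(b$K2), tolerance = 0.01)
})

test_that("CO2 is more soluble in cold water", {
  expect_gt(carb_constants(5, 35)$K0, carb_constants(25, 35)$K0)
})

test_that("out-of-range temperature or salinity raises a domain error naming the field", {
  expect_error(carb_constants(50, 35), "temperature",
               class = "coralcarb_domain_error")
  expect_error(carb_constants(15, 60), "salinity",
               class = "coralcarb_domain_error")
})

test_that("solved states close their mass and alkalinity balances", {
  grid <- expand.grid(tc = c(5, 15, 25), ph = c(7.8, 8.1),
                      ta = c(2200, 2400))
  for (i in seq_len(nrow(grid))) {
    st <- solve_carb(grid$tc[i], 35, ph = grid$ph[i],
                     total_alkalinity = grid$ta[i])
    expect_equal(st$co2 + st$hco3 + st$co3, st$dic, tolerance = 1e-10)
    expect_equal(st$hco3 + 2 * st$co3, st$carb_alk, tolerance = 1e-10)
    # equilibrium identity linking aH, K1, [CO2] and [HCO3-]
    expect_equal(st$ah * st$hco3 / (st$constants$K1 * st$co2), 1,
                 tolerance = 1e-8)
    expect_true(all(c(st$co2, st$hco3, st$co3) >= 0))
  }
})

test_that("speciation at 25 degC / pH 8.1 / TA 2300 lands in the expected DIC band", {
  st <- solve_carb(25, 35, ph = 8.1, total_alkalinity = 2300)
  expect_gt(st$dic * 1e6, 1900)
  expect_lt(st$dic * 1e6, 2100)
})

test_that("solving from any output pair round-trips the input pair", {
  st <- solve_carb(15, 35, ph = 8.05, total_alkalinity = 2300)
  # ta + dic
  rt <- solve_carb(15, 35, total_alkalinity = st$ta * 1e6,
                   dic = st$dic * 1e6, constants = st$constants)
  expect_equal(rt$ph, st$ph, tolerance = 1e-9)
  expect_equal(rt$pco2, st$pco2, tolerance = 1e-9)
  # ta + pco2
  rt2 <- solve_carb(15, 35, total_alkalinity = st$ta * 1e6,
                    pco2 = st$pco2 * 1e6, constants = st$constants)
  expect_equal(rt2$dic, st$dic, tolerance = 1e-9)
  expect_equal(rt2$ph, st$ph, tolerance = 1e-9)
  # dic + pco2
  rt3 <- solve_carb(15, 35, dic = st$dic * 1e6, pco2 = st$pco2 * 1e6,
                    constants = st$constants)
  expect_equal(rt3$ta, st$ta, tolerance = 1e-9)
  # ph + dic and ph + pco2
  rt4 <- solve_carb(15, 35, ph = st$ph, dic = st$dic * 1e6,
                    constants = st$constants)
  expect_equal(rt4$ta, st$ta, tolerance = 1e-9)
  rt5 <- solve_carb(15, 35, ph = st$ph, pco2 = st$pco2 * 1e6,
                    constants = st$constants)
  expect_equal(rt5$dic, st$dic, tolerance = 1e-9)
})

test_that("NBS-scale pH input is converted and reported back consistently", {
  st <- solve_carb(15, 35, ph = 8.1, total_alkalinity = 2300,
                   ph_scale = "NBS")
  expect_lt(st$ph, 8.1)  # total-scale pH sits below NBS pH
  expect_equal(tidy(st)$ph_nbs, 8.1, tolerance = 1e-10)
})

test_that("invalid parameter pairs raise domain errors", {
  expect_error(solve_carb(15, 35, ph = 8.1), "exactly two",
               class = "coralcarb_domain_error")
  expect_error(solve_carb(15, 35, ph = 8.1, total_alkalinity = 2300,
                          dic = 2000), "exactly two",
               class = "coralcarb_domain_error")
  expect_error(solve_carb(15, 35, dic = 0, total_alkalinity = 2300),
               class = "coralcarb_domain_error")
  expect_error(solve_carb(15, 35, dic = 100, pco2 = 100000),
               class = "coralcarb_domain_error")
})
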