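test_that("van't Hoff correction behaves at reference, zero enthalpy and by hand", {
  expect_identical(vant_hoff_logk(4, 0, 280), 4)
  expect_identical(vant_hoff_logk(-11.2, 0, 305), -11.2)
  expect_equal(vant_hoff_logk(7.3, 62000, 298.15), 7.3)
  # hand evaluation of the van't Hoff expression
  expect_equal(vant_hoff_logk(4, 50000, 278.15), 3.370, tolerance = 1e-3)
  expect_error(vant_hoff_logk(4, 0, 260), "outside")
  expect_error(vant_hoff_logk(4, 0, 320), "outside")
})

test_that("van't Hoff correction is monotone in 1/T and zero at T_ref", {
  tk <- seq(272, 312, by = 2)
  lk <- vant_hoff_logk(5, 40000, tk)
  expect_true(all(diff(lk) > 0)) # endothermic: K grows with T
  lk2 <- vant_hoff_logk(5, -40000, tk)
  expect_true(all(diff(lk2) < 0))
  expect_equal(vant_hoff_logk(5, 40000, 298.15), 5)
})

test_that("Davies activity coefficients: uncharged, infinite dilution, hand value", {
  expect_identical(davies_gamma(0, 0.7), 1)
  expect_identical(davies_gamma(1, 0), 1)
  expect_equal(davies_gamma(1, 0.7, A = 0.5115), 0.749, tolerance = 2e-3)
  expect_error(davies_gamma(1, -0.1), "non-negative")
})

test_that("seawater recipe scales linearly and has the right ionic strength", {
  sw0 <- seawater_composition(0)
  expect_true(all(sw0$conc == 0))
  expect_identical(sw0$ionic_strength, 0)
  sw35 <- seawater_composition(35)
  expect_gt(sw35$ionic_strength, 0.68)
  expect_lt(sw35$ionic_strength, 0.74)
  sw17 <- seawater_composition(17.5)
  expect_equal(sw17$conc, sw35$conc / 2)
  expect_error(seawater_composition(50), "0, 42")
})

test_that("inorganic speciation: no side reactions collapse to free ion", {
  sp <- inorganic_speciation(1e-9, 8, 10, 35, thermo = toy_thermo_empty())
  expect_equal(attr(sp, "fe_prime"), 1e-9)
})

test_that("single hydrolysis step with unit ratio doubles Fe'", {
  # mass action by hand: [FeOH]/[Fe3+] = 10^(-8) / 10^(-8) = 1 at pH 8
  sp <- inorganic_speciation(2e-10, 8, 25, 35, thermo = toy_thermo_one())
  expect_equal(attr(sp, "fe_prime"), 4e-10, tolerance = 1e-12)
})

test_that("Fe' is strictly linear in free Fe3+ over six decades", {
  th <- fe_thermo()
  alpha <- fe_prime_alpha(7.9, 8, 35, th)
  for (lf in seq(-21, -15)) {
    sp <- inorganic_speciation(10^lf, 7.9, 8, 35, th)
    expect_equal(attr(sp, "fe_prime") / (alpha * 10^lf), 1, tolerance = 1e-12)
  }
})

test_that("solved species satisfy mass action to 1e-10 in log units", {
  th <- fe_thermo()
  fe3 <- 3e-19
  ph <- 7.8
  tc <- 6
  S <- 34.8
  sw <- seawater_composition(S, tc)
  gam <- davies_gamma(0:4, sw$ionic_strength, tc)
  sp <- inorganic_speciation(fe3, ph, tc, S, th)
  for (i in seq_len(nrow(th$reactions))) {
    rx <- th$reactions[i, ]
    conc <- sp$conc[sp$species == rx$product]
    act_sp <- conc * gam[abs(rx$charge) + 1]
    st <- rx$stoich[[1]]
    lhs <- log10(act_sp) - st[["fe3"]] * log10(fe3 * gam[4]) -
      st[["h"]] * (-ph)
    expect_equal(lhs, vant_hoff_logk(rx$logk_ref, rx$delta_h, tc + 273.15),
                 tolerance = 1e-10)
  }
})

test_that("species referencing undefined components are rejected", {
  expect_error(
    thermo_dataset(
      toy_components(),
      tibble::tibble(product = "x", charge = 0, logk_ref = 1, delta_h = 0,
                     stoich = list(c(unobtainium = 1)))
    ),
    "undefined component"
  )
  expect_error(
    thermo_dataset(
      toy_components(),
      tibble::tibble(product = "x", charge = 0, logk_ref = 1, delta_h = 0,
                     stoich = list(numeric(0)))
    ),
    "empty stoichiometry"
  )
})

test_that("Fe' solubility increases as pH and temperature decrease", {
  th <- fe_thermo()
  for (ph in c(7.5, 7.7, 7.9)) {
    expect_gte(fe_prime_solubility(ph, 5, 34.7, th),
               fe_prime_solubility(ph + 0.2, 5, 34.7, th))
  }
  for (tc in c(2, 6, 10)) {
    expect_gte(fe_prime_solubility(7.8, tc, 34.7, th),
               fe_prime_solubility(7.8, tc + 5, 34.7, th))
  }
})

test_that("solubility chains the cap through the hydrolysis ladder", {
  # with one reaction giving Fe'/[Fe3+] = 2 and a toy Ks, the solubility is
  # exactly 2 * Ks * {H+}^3 in conditional mode
  th <- toy_thermo_one(logk = -8, logks = 4)
  expect_equal(fe_prime_solubility(8, 25, 35, th), 2 * 10^(4 - 24),
               tolerance = 1e-12)
  expect_error(fe_prime_solubility(8, 25, 35, toy_thermo_empty()),
               "no mineral")
})

test_that("pH scale conversions: identity, round trip, sulfate sign", {
  expect_identical(convert_ph(7.9, "total", "total", 35, 10), 7.9)
  rt <- convert_ph(convert_ph(7.9, "total", "free", 35, 10),
                   "free", "total", 35, 10)
  expect_equal(rt, 7.9, tolerance = 1e-12)
  rt2 <- convert_ph(convert_ph(7.9, "NBS", "free", 35, 10),
                    "free", "NBS", 35, 10)
  expect_equal(rt2, 7.9, tolerance = 1e-12)
  # HSO4- association makes the free-scale value the larger one at S = 35,
  # by about 0.1 units
  offset <- convert_ph(8, "total", "free", 35, 25) - 8
  expect_gt(offset, 0.05)
  expect_lt(offset, 0.2)
  expect_error(convert_ph(8, "total", "seawater", 35, 25), "scales")
})
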