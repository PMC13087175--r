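test_that("NICA isotherm reduces to Langmuir at half saturation", {
  g <- nica_group(qmax = 2, logk_h = 4, n_h = 1, p = 1)
  ph <- nica_phase("toy", list(g, g), donnan_b = 0.5, mass = 1)
  b <- nica_binding(ph, c(h = 1e-4)) # K c = 1
  expect_equal(b$theta, rep(0.5, 2), tolerance = 1e-14)
  expect_equal(b$bound, rep(1, 2), tolerance = 1e-14)
})

test_that("ions with identical parameters bind identically", {
  g <- nica_group(qmax = 1, logk_h = 5, n_h = 0.7, p = 0.6,
                  logk = c(fe = 5), n = c(fe = 0.7))
  ph <- nica_phase("toy", list(g, g), donnan_b = 0.5, mass = 1)
  b <- nica_binding(ph, c(h = 3e-6, fe = 3e-6))
  expect_equal(b$bound[b$ion == "h"], b$bound[b$ion == "fe"])
})

test_that("non-ideality flattens the isotherm: n = 0.5, Kc = 100 gives 10/11", {
  g <- nica_group(qmax = 1, logk_h = 2, n_h = 0.5, p = 1)
  ph <- nica_phase("toy", list(g, g), donnan_b = 0.5, mass = 1)
  b <- nica_binding(ph, c(h = 1)) # K c = 100, (Kc)^0.5 = 10
  expect_equal(b$theta, rep(10 / 11, 2), tolerance = 1e-12)
})

test_that("all-zero concentrations give zero binding, negatives error", {
  g <- nica_group(qmax = 1, logk_h = 4, n_h = 1, p = 1)
  ph <- nica_phase("toy", list(g, g), donnan_b = 0.5, mass = 1)
  expect_true(all(nica_binding(ph, c(h = 0))$bound == 0))
  expect_error(nica_binding(ph, c(h = -1)), ">= 0")
})

test_that("site occupancy never exceeds unity over random compositions", {
  set.seed(42)
  phases <- default_phases()
  for (i in 1:2000) {
    ph <- if (i %% 2) phases$dom else phases$pom
    g <- ph$groups[[sample(2, 1)]]
    local <- c(h = 10^runif(1, -10, -2), mg = 10^runif(1, -4, 0),
               ca = 10^runif(1, -5, -1), fe = 10^runif(1, -24, -10))
    b <- nica_binding(nica_phase("x", ph$groups, ph$donnan_b, 1), local)
    for (gi in 1:2) {
      expect_lte(sum(b$theta[b$group == gi]), 1 + 1e-12)
    }
  }
})

test_that("bound Fe rises with free Fe and falls with protons", {
  ph <- dom_phase(1e-6)
  fe_grid <- 10^seq(-22, -16, by = 1)
  b_fe <- vapply(fe_grid, function(fe) {
    sum(nica_binding(ph, c(h = 1e-8, mg = 0.05, ca = 0.01, fe = fe))$bound[
      nica_binding(ph, c(h = 1e-8, mg = 0.05, ca = 0.01, fe = fe))$ion == "fe"])
  }, numeric(1))
  expect_true(all(diff(b_fe) > 0))
  h_grid <- 10^seq(-9, -5, by = 1)
  b_h <- vapply(h_grid, function(h) {
    bb <- nica_binding(ph, c(h = h, mg = 0.05, ca = 0.01, fe = 1e-19))
    sum(bb$bound[bb$ion == "fe"])
  }, numeric(1))
  expect_true(all(diff(b_h) < 0))
})

test_that("Donnan volume follows the empirical law and clips", {
  expect_equal(donnan_volume(0.3, 10), 0.1)
  expect_equal(donnan_volume(0.9, 10), 0.1)
  expect_equal(donnan_volume(0.7, 1), 10^(-0.3), tolerance = 1e-12)
  expect_equal(donnan_volume(0.7, 0.7), 0.6434, tolerance = 1e-3)
  expect_equal(donnan_volume(0.7, 1e6), 5e-4) # clipped
  expect_error(donnan_volume(0.5, 0), "> 0")
})

test_that("a vanishing-charge phase has chi = 1; a net-negative phase has chi > 1", {
  sw <- seawater_composition(35, 10)
  tiny <- anionic_phase(qmax = 1e-12)
  d <- solve_donnan(tiny, sw, ph_free = 8)
  expect_equal(d$chi, 1, tolerance = 1e-9)
  neg <- anionic_phase(qmax = 1)
  d2 <- solve_donnan(neg, sw, ph_free = 8)
  expect_gt(d2$chi, 1)
  expect_lt(abs(d2$residual), 1e-10)
})

test_that("Donnan solve matches a plain bisection oracle on random draws", {
  set.seed(7)
  sw <- seawater_composition(34.7, 8)
  phases <- default_phases()
  for (i in 1:20) {
    tpl <- if (i %% 2) phases$dom else phases$pom
    ph <- nica_phase("x", tpl$groups, tpl$donnan_b, 1e-6)
    pf <- runif(1, 7.2, 8.2)
    d <- solve_donnan(ph, sw, ph_free = pf)
    # independent bracketing bisection on the same charge-balance residual
    vd <- donnan_volume(ph$donnan_b, sw$ionic_strength)
    gam1 <- davies_gamma(1, sw$ionic_strength, sw$temp_c)
    bind_conc <- c(h = 10^(-pf) / gam1, mg = unname(sw$conc["mg"]),
                   ca = unname(sw$conc["ca"]), fe = 0)
    f <- function(chi) fespec:::donnan_residual(chi, ph, vd, sw$conc,
                                                sw$charge, bind_conc)
    lo <- 1e-4
    hi <- 1e4
    for (k in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    expect_equal(d$chi, sqrt(lo * hi), tolerance = 1e-8)
  }
})

test_that("siderophore binding saturates at the ligand total", {
  sw <- seawater_composition(34.7, 5)
  lig0 <- siderophore_ligand(0)
  expect_equal(siderophore_binding(lig0, 1e-18, sw, 7.9)$fe_sid, 0)
  lig <- siderophore_ligand(100e-12)
  expect_equal(siderophore_binding(lig, 0, sw, 7.9)$fe_sid, 0)
  # high-affinity proxy binds near-stoichiometrically when Fe is ample
  b <- siderophore_binding(lig, 1e-15, sw, 7.9)
  expect_gt(b$fe_sid / lig$total, 0.99)
  expect_lte(b$fe_sid, lig$total)
  # monotone approach to the total
  vals <- vapply(10^seq(-22, -14), function(fe)
    siderophore_binding(lig, fe, sw, 7.9)$fe_sid, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(siderophore_ligand(-1), ">= 0")
})

test_that("phase and group constructors validate their invariants", {
  expect_error(nica_group(qmax = -1, logk_h = 1, n_h = 1, p = 1), "positive")
  expect_error(nica_group(qmax = 1, logk_h = 1, n_h = 1, p = 1.2), "\\(0, 1\\]")
  expect_error(nica_group(qmax = 1, logk_h = 1, n_h = 1.5, p = 1), "\\(0, 1\\]")
  g <- nica_group(qmax = 1, logk_h = 1, n_h = 1, p = 1)
  expect_error(nica_phase("x", list(g), 0.5, 1), "two site groups")
  expect_error(nica_phase("x", list(g, g), 0.5, -1), "non-negative")
  # default POM parameterisation: 1 mol sites per kg split 3:1
  pom <- pom_phase(1e-8)
  q <- vapply(pom$groups, `[[`, numeric(1), "qmax")
  expect_equal(sum(q), 1)
  expect_equal(q[1] / q[2], 3)
})
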