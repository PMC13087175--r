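test_that("empty system returns zero pools with finite Boltzmann factors", {
  pr <- speciation_problem(0, 7.8, 5, 34.7, dom = dom_phase(2e-6),
                           pom = pom_phase(2e-8),
                           siderophore = siderophore_ligand(1e-10),
                           allow_mineral = TRUE)
  res <- solve_equilibrium(pr)
  expect_true(res$converged)
  expect_true(all(pool_vector(res) == 0))
  expect_true(is.finite(res$chi_dom) && res$chi_dom > 0)
  expect_true(is.finite(res$chi_pom) && res$chi_pom > 0)
})

test_that("with no phases and no mineral, all Fe is inorganic", {
  pr <- speciation_problem(3e-9, 7.8, 5, 34.7)
  res <- solve_equilibrium(pr)
  expect_equal(res$fe_prime, 3e-9, tolerance = 1e-10)
  expect_equal(res$fe_dom + res$fe_sid + res$fe_pom + res$auth_feoh, 0)
})

test_that("far above solubility the cap fixes Fe' and the remainder precipitates", {
  tot <- 5e-8
  pr <- speciation_problem(tot, 7.8, 5, 34.7, dom = dom_phase(1e-8),
                           allow_mineral = TRUE)
  res <- solve_equilibrium(pr)
  expect_true(res$capped)
  sol <- fe_prime_solubility(res$ph_free, 5, 34.7)
  expect_equal(res$fe_prime / sol, 1, tolerance = 1e-9)
  expect_equal(res$auth_feoh, tot - res$fe_prime - res$fe_dom - res$fe_sid -
                 res$fe_pom)
  expect_gt(res$auth_feoh / tot, 0.8)
  expect_equal(res$saturation_index, 0, tolerance = 1e-6)
})

test_that("pools conserve total Fe over random problems", {
  set.seed(11)
  for (i in 1:300) {
    pr <- random_problem()
    res <- solve_equilibrium(pr)
    expect_true(res$converged)
    expect_lt(abs(sum(pool_vector(res)) / pr$total_fe - 1), 1e-8)
    expect_true(all(pool_vector(res) >= 0))
  }
})

test_that("Newton and nested-bisection solvers agree on random problems", {
  set.seed(5)
  for (i in 1:30) {
    pr <- random_problem()
    expect_pools_close(solve_equilibrium(pr), bisect_equilibrium(pr),
                       rel = 1e-6)
  }
})

test_that("precipitation complementarity: authFeOH positive iff at saturation", {
  set.seed(23)
  n_capped <- 0
  for (i in 1:60) {
    pr <- random_problem()
    res <- solve_equilibrium(pr)
    if (res$auth_feoh > 0) {
      n_capped <- n_capped + 1
      expect_lt(abs(res$saturation_index), 1e-6)
    } else {
      expect_lte(res$saturation_index, 1e-6)
    }
    sol <- fe_prime_solubility(res$ph_free, pr$temp_c, pr$salinity)
    expect_lte(res$fe_prime, sol + 1e-12)
  }
  expect_gt(n_capped, 0) # the draw must actually exercise the capped branch
})

test_that("pools vary continuously across the saturation boundary", {
  base <- function(tot) {
    solve_equilibrium(speciation_problem(
      tot, 7.8, 4, 34.7, dom = dom_phase(1.5e-6), pom = pom_phase(1.5e-8),
      allow_mineral = TRUE))
  }
  # locate the precipitation onset by bisection on the capped flag
  lo <- 1e-10
  hi <- 1e-7
  for (k in 1:40) {
    mid <- sqrt(lo * hi)
    if (base(mid)$capped) hi <- mid else lo <- mid
  }
  below <- base(lo)
  above <- base(hi)
  expect_false(below$capped)
  expect_true(above$capped)
  pa <- pool_vector(below)
  pb <- pool_vector(above)
  expect_lt(max(abs(pa - pb)) / lo, 1e-6)
})

test_that("Fe' grows with total Fe and FeDOM with DOM mass", {
  tots <- 10^seq(-11, -8, by = 0.5)
  fp <- vapply(tots, function(tot) {
    solve_equilibrium(speciation_problem(tot, 7.8, 5, 34.7,
                                         dom = dom_phase(1.6e-6),
                                         allow_mineral = TRUE))$fe_prime
  }, numeric(1))
  expect_true(all(diff(fp) >= -1e-18))
  masses <- c(5e-7, 1e-6, 2e-6, 4e-6)
  fd <- vapply(masses, function(m) {
    solve_equilibrium(speciation_problem(7e-10, 7.8, 5, 34.7,
                                         dom = dom_phase(m)))$fe_dom
  }, numeric(1))
  expect_true(all(diff(fd) > 0))
})

test_that("saturation index follows logarithm arithmetic", {
  # uncapped inorganic-only solves: fe3 is linear in total, so doubling the
  # total raises SI by log10(2)
  pr1 <- speciation_problem(1e-11, 7.8, 5, 34.7, allow_mineral = TRUE)
  pr2 <- speciation_problem(2e-11, 7.8, 5, 34.7, allow_mineral = TRUE)
  r1 <- solve_equilibrium(pr1)
  r2 <- solve_equilibrium(pr2)
  expect_lt(r1$saturation_index, 0)
  expect_equal(r2$saturation_index - r1$saturation_index, log10(2),
               tolerance = 1e-9)
})

test_that("tidy and glance views carry the pool partition", {
  res <- solve_equilibrium(speciation_problem(7e-10, 7.75, 4, 34.6,
                                              dom = dom_phase(1.6e-6),
                                              allow_mineral = TRUE))
  td <- tidy(res)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$conc), res$total_fe, tolerance = 1e-9)
  expect_equal(sum(td$fraction), 1, tolerance = 1e-8)
  gl <- glance(res)
  expect_true(gl$converged)
  expect_identical(gl$method, "newton")
})
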