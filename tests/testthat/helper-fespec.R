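# shared fixtures: toy thermodynamic datasets, toy phases and a random
# speciation-problem generator spanning the study's condition ranges

toy_components <- function() {
  tibble::tibble(name = c("fe3", "h"), charge = c(3, 1))
}

# no side reactions: Fe' collapses to [Fe3+]
toy_thermo_empty <- function() {
  thermo_dataset(
    toy_components(),
    tibble::tibble(product = character(), charge = numeric(),
                   logk_ref = numeric(), delta_h = numeric(),
                   stoich = list()),
    activity_model = "conditional"
  )
}

# single hydrolysis step with [FeOH2+]/[Fe3+] = 1 at pH 8 (conditional mode)
toy_thermo_one <- function(logk = -8, logks = NULL) {
  mineral <- if (!is.null(logks)) {
    list(name = "authFeOH", logks_ref = logks, delta_h = 0, medium = "toy")
  }
  thermo_dataset(
    toy_components(),
    tibble::tibble(product = "feoh", charge = 2, logk_ref = logk,
                   delta_h = 0, stoich = list(c(fe3 = 1, h = -1))),
    mineral = mineral,
    activity_model = "conditional"
  )
}

# homogeneous (Langmuir-limit) site group bound to one ion
langmuir_group <- function(logk_fe, qmax = 1) {
  nica_group(qmax = qmax, logk_h = -20, n_h = 1, p = 1,
             logk = c(fe = logk_fe), n = c(fe = 1))
}

# a phase with negligible cation binding: net charge -Qmax in seawater
anionic_phase <- function(qmax = 1) {
  g <- nica_group(qmax = qmax, logk_h = -20, n_h = 1, p = 1)
  nica_phase("anionic", list(g, g), donnan_b = 0.5, mass = 1e-6)
}

random_problem <- function(allow_mineral = TRUE) {
  speciation_problem(
    total_fe = 10^runif(1, -12, -7),
    ph_total = runif(1, 7.2, 8.2),
    temp_c = runif(1, 1.6, 16),
    salinity = runif(1, 34, 35.5),
    dom = dom_phase(runif(1, 0, 5e-6)),
    pom = pom_phase(runif(1, 0, 5e-8)),
    siderophore = siderophore_ligand(runif(1, 0, 425e-12)),
    allow_mineral = allow_mineral
  )
}

pool_vector <- function(res) {
  c(fe_prime = res$fe_prime, fe_dom = res$fe_dom, fe_sid = res$fe_sid,
    fe_pom = res$fe_pom, auth_feoh = res$auth_feoh)
}

expect_pools_close <- function(a, b, rel = 1e-6) {
  pa <- pool_vector(a)
  pb <- pool_vector(b)
  floor_abs <- 1e-15 * max(a$total_fe, 1e-30)
  denom <- pmax(abs(pa), abs(pb), floor_abs)
  expect_lt(max(abs(pa - pb) / denom), rel)
}
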