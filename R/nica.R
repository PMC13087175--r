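# NICA-Donnan heterogeneous binding phases (DOM and POM) and the discrete
# siderophore ligand. The NICA isotherm distributes each ion over two binding
# site groups with ion-specific non-ideality; the Donnan gel phase accumulates
# counter-ions according to a Boltzmann factor solved from charge balance.

#' Define a NICA binding site group
#'
#' @param qmax Site density, mol sites kg-1 (> 0).
#' @param logk_h Median proton affinity, log10.
#' @param n_h Proton non-ideality, in (0, 1].
#' @param p Generic (intrinsic) heterogeneity of the group, in (0, 1].
#' @param logk,n Named numeric vectors of per-ion median affinities (log10)
#'   and non-idealities; names are ion identifiers such as `mg`, `ca`, `fe`.
#' @return A list describing the group, consumed by [nica_phase()].
#' @export
nica_group <- function(qmax, logk_h, n_h, p, logk = numeric(), n = numeric()) {
  if (qmax <= 0) abort("nica_group: `qmax` must be positive.")
  if (p <= 0 || p > 1) abort("nica_group: `p` must lie in (0, 1].")
  nn <- c(h = n_h, n)
  if (any(nn <= 0 | nn > 1)) abort("nica_group: non-ideality `n` must lie in (0, 1].")
  list(qmax = qmax, p = p,
       logk = c(h = logk_h, logk),
       n = nn)
}

#' Assemble a NICA-Donnan phase
#'
#' @param name Phase identifier (`"dom"` or `"pom"` in the pipeline).
#' @param groups List of exactly two [nica_group()] definitions.
#' @param donnan_b Dimensionless Donnan-volume parameter.
#' @param mass Phase mass concentration, kg L-1 (>= 0).
#' @return An object of class `fe_nica_phase`.
#' @export
nica_phase <- function(name, groups, donnan_b, mass) {
  if (length(groups) != 2) abort("nica_phase: exactly two site groups required.")
  if (mass < 0) abort("nica_phase: `mass` must be non-negative.")
  structure(list(name = name, groups = groups, donnan_b = donnan_b,
                 mass = mass),
            class = "fe_nica_phase")
}

#' @export
print.fe_nica_phase <- function(x, ...) {
  cat("<fe_nica_phase> ", x$name, ": Qmax = ",
      paste(vapply(x$groups, `[[`, numeric(1), "qmax"), collapse = " + "),
      " mol/kg, b = ", x$donnan_b, ", mass = ", format(x$mass), " kg/L\n",
      sep = "")
  invisible(x)
}

#' Default dissolved organic matter phase
#'
#' Marine-DOM NICA-Donnan phase built from the bundled synthetic placeholder
#' parameter set (fulvic-acid-shaped groups with Fe affinities tuned to
#' open-ocean iron partitioning; see the package vignette).
#'
#' @param mass DOM mass concentration, kg L-1 (e.g. from [dom_from_doc()]).
#' @param params Optional phase template from [load_phases()].
#' @return An `fe_nica_phase`.
#' @export
dom_phase <- function(mass, params = NULL) {
  p <- params %||% default_phases()$dom
  nica_phase("dom", p$groups, p$donnan_b, mass)
}

#' Default particulate organic matter phase
#'
#' POM NICA-Donnan phase: generic-humic-shaped groups with total site density
#' 1 mol kg-1 split 3:1 between the low- and high-affinity groups
#' (Qmax 0.75 and 0.25 mol kg-1), as estimated for marine particulate
#' material. All other parameters are hypothetical placeholders.
#'
#' @param mass POM mass concentration, kg L-1 (e.g. from [pom_from_tpp()]).
#' @param params Optional phase template from [load_phases()].
#' @return An `fe_nica_phase`.
#' @export
pom_phase <- function(mass, params = NULL) {
  p <- params %||% default_phases()$pom
  nica_phase("pom", p$groups, p$donnan_b, mass)
}

# NICA isotherm for one group: local (Donnan-phase) free concentrations in,
# bound amounts (mol/kg) out. `local` is a named vector including "h".
nica_bound_group <- function(group, local) {
  ions <- names(group$logk)
  ci <- local[ions]
  ci[is.na(ci)] <- 0
  s_terms <- (10^group$logk * ci)^group$n
  S <- sum(s_terms)
  if (S <= 0) return(setNames(rep(0, length(ions)), ions))
  theta <- s_terms / S * S^group$p / (1 + S^group$p)
  setNames(group$n / group$n["h"] * group$qmax * theta, ions)
}

#' NICA bound amounts for a phase
#'
#' Evaluates the bimodal NICA isotherm at given Donnan-phase free
#' concentrations. For group \eqn{g} and ion \eqn{i},
#' \deqn{\theta_{i,g} = \frac{(K_{i,g} c_i)^{n_{i,g}}}{S_g}
#'       \cdot \frac{S_g^{p_g}}{1 + S_g^{p_g}}, \qquad
#'       S_g = \sum_j (K_{j,g} c_j)^{n_{j,g}},}
#' and the bound amount is \eqn{(n_{i,g}/n_{H,g}) Q_{max,g} \theta_{i,g}}.
#'
#' @param phase An `fe_nica_phase`.
#' @param local Named numeric vector of free ion concentrations inside the
#'   Donnan phase (mol L-1), including `h`.
#' @return Tibble with columns `ion`, `group`, `theta`, `bound` (mol kg-1).
#' @examples
#' g <- nica_group(qmax = 1, logk_h = 4, n_h = 1, p = 1)
#' ph <- nica_phase("toy", list(g, g), donnan_b = 0.5, mass = 1e-6)
#' nica_binding(ph, c(h = 1e-4))
#' @export
nica_binding <- function(phase, local) {
  if (any(local < 0, na.rm = TRUE)) abort("nica_binding: concentrations must be >= 0.")
  rows <- lapply(seq_along(phase$groups), function(gi) {
    g <- phase$groups[[gi]]
    b <- nica_bound_group(g, local)
    tibble(ion = names(b), group = gi,
           theta = unname(b / (g$n[names(b)] / g$n["h"] * g$qmax)),
           bound = unname(b))
  })
  bind_rows(rows)
}

#' Donnan gel volume
#'
#' Empirical Donnan-volume law \eqn{\log_{10} V_D = b (1 - \log_{10} I) - 1},
#' clipped below at `vmin` for numerical safety far outside the seawater
#' regime.
#'
#' @param b Donnan-volume parameter of the phase.
#' @param ionic_strength Bulk ionic strength, mol L-1 (> 0).
#' @param vmin Lower clip, L kg-1.
#' @return Donnan volume, L kg-1.
#' @export
donnan_volume <- function(b, ionic_strength, vmin = 5e-4) {
  if (any(ionic_strength <= 0)) abort("donnan_volume: `ionic_strength` must be > 0.")
  pmax(10^(b * (1 - log10(ionic_strength)) - 1), vmin)
}

# charge-balance residual (mol charge per kg phase) at Boltzmann factor chi.
# bulk: named conc vector; bulk_z: charges; binding ions h/mg/ca/fe taken
# from `bind_conc` (bulk free concentrations) scaled into the gel by chi^z.
.BIND_Z <- c(h = 1, mg = 2, ca = 2, fe = 3)
donnan_residual <- function(chi, phase, vd, bulk, bulk_z, bind_conc) {
  local <- bind_conc * chi^.BIND_Z[names(bind_conc)]
  qtot <- 0
  zb <- 0
  for (g in phase$groups) {
    b <- nica_bound_group(g, local)
    qtot <- qtot + g$qmax
    zb <- zb + sum(.BIND_Z[names(b)] * b)
  }
  q <- -qtot + zb
  q + vd * sum(bulk_z * bulk * (chi^bulk_z - 1))
}

#' Solve the Donnan potential of a phase
#'
#' Finds the Boltzmann factor \eqn{\chi = \exp(-F\psi_D/RT)} at which the
#' phase charge (deprotonated sites plus bound cations) is neutralised by the
#' Donnan-phase ion excess. The residual is strictly increasing in
#' \eqn{\chi}, so a bracketing root solve is used. A net-negative phase in
#' seawater returns \eqn{\chi > 1} (cation enrichment).
#'
#' @param phase An `fe_nica_phase`.
#' @param composition An `fe_seawater` from [seawater_composition()].
#' @param ph_free pH on the free scale.
#' @param fe3_free Bulk free Fe3+ concentration, mol L-1.
#' @param temp_c Temperature (Celsius) for the proton activity coefficient.
#' @return A list with `chi`, `psi_d` (V), `v_d` (L kg-1) and the residual.
#' @export
solve_donnan <- function(phase, composition, ph_free, fe3_free = 0,
                         temp_c = composition$temp_c) {
  I <- composition$ionic_strength
  vd <- donnan_volume(phase$donnan_b, I)
  gam1 <- davies_gamma(1, I, temp_c)
  bind_conc <- c(h = 10^(-ph_free) / gam1,
                 mg = unname(composition$conc["mg"]),
                 ca = unname(composition$conc["ca"]),
                 fe = fe3_free)
  f <- function(lchi) donnan_residual(10^lchi, phase, vd, composition$conc,
                                      composition$charge, bind_conc)
  root <- uniroot(f, c(-6, 6), tol = 1e-14)
  chi <- 10^root$root
  tk <- temp_c + 273.15
  list(chi = chi, psi_d = -log(chi) * .R_GAS * tk / 96485.33212, v_d = vd,
       residual = root$f.root)
}

# ---- discrete siderophore ligand -------------------------------------------

#' Define a discrete siderophore ligand
#'
#' @param total Total ligand concentration, mol L-1 (>= 0).
#' @param constants Stability constants, see [sid_constants()].
#' @return A list of class `fe_ligand`.
#' @export
siderophore_ligand <- function(total, constants = sid_constants()) {
  if (total < 0) abort("siderophore_ligand: `total` must be >= 0.")
  structure(list(name = "ferrioxamine B proxy", total = total,
                 constants = constants),
            class = "fe_ligand")
}

# side-reaction coefficient of the free ligand over protonated/Mg/Ca species
sid_alpha <- function(constants, ph_free, composition) {
  aH <- 10^(-ph_free)
  1 + sum(10^constants$logb_h * aH^seq_along(constants$logb_h)) +
    10^constants$logb_mg * unname(composition$conc["mg"]) +
    10^constants$logb_ca * unname(composition$conc["ca"])
}

#' Iron binding by the siderophore ligand
#'
#' Closes the ligand mass balance over protonated, Mg, Ca and Fe species.
#' The ferric complex saturates at the ligand total as free Fe3+ grows; at
#' the high affinity of the ferrioxamine proxy, binding is near
#' stoichiometric whenever iron is available in excess.
#'
#' @param ligand An `fe_ligand`.
#' @param fe3_free Free Fe3+ concentration, mol L-1.
#' @param composition An `fe_seawater`.
#' @param ph_free pH on the free scale.
#' @return A list with `fe_sid` (mol L-1), `alpha` (ligand side-reaction
#'   coefficient) and `logk_cond` (conditional Fe affinity of the free
#'   ligand pool).
#' @export
siderophore_binding <- function(ligand, fe3_free, composition, ph_free) {
  if (ligand$total == 0 || fe3_free <= 0) {
    al <- sid_alpha(ligand$constants, ph_free, composition)
    return(list(fe_sid = 0, alpha = al,
                logk_cond = ligand$constants$logb_fe - log10(al)))
  }
  al <- sid_alpha(ligand$constants, ph_free, composition)
  bfe <- 10^ligand$constants$logb_fe
  fe_sid <- bfe * fe3_free * ligand$total / (al + bfe * fe3_free)
  list(fe_sid = fe_sid, alpha = al,
       logk_cond = ligand$constants$logb_fe - log10(al))
}
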