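# Thermodynamic database, temperature / ionic-strength corrections, inorganic
# Fe(III) speciation and ferrihydrite saturation chemistry.
#
# Constants are stored at the 298.15 K reference temperature and corrected at
# run time via the van't Hoff relation. Activities follow the Davies equation
# so that constants conditioned to a simple electrolyte can be applied at
# seawater ionic strength; setting `activity_model = "conditional"` on a
# dataset disables activity corrections for constants already conditioned to
# seawater.

#' Van't Hoff temperature correction of an equilibrium constant
#'
#' Corrects a log10 equilibrium constant from the 298.15 K reference
#' temperature to `temp_k` using the reaction enthalpy:
#' \deqn{\log_{10}K(T) = \log_{10}K_{ref} - \frac{\Delta H}{R \ln 10}
#'   \left(\frac{1}{T} - \frac{1}{T_{ref}}\right)}
#' Reactions with unknown enthalpy (`delta_h = 0`) are returned unchanged.
#'
#' @param logk_ref log10 K at 298.15 K (dimensionless).
#' @param delta_h Reaction enthalpy, J mol-1 (0 if unknown).
#' @param temp_k Absolute temperature, K. Must lie in \[271, 313\]; the
#'   parameterisation is not validated outside that oceanographic range and
#'   extrapolation is refused.
#' @return log10 K at `temp_k`.
#' @examples
#' vant_hoff_logk(4, 50000, 278.15)
#' @export
vant_hoff_logk <- function(logk_ref, delta_h, temp_k) {
  if (any(temp_k < 271 | temp_k > 313)) {
    abort("`temp_k` outside the supported range [271, 313] K; extrapolation unsupported.")
  }
  logk_ref - delta_h / (.R_GAS * log(10)) * (1 / temp_k - 1 / .T_REF)
}

# Debye-Huckel limiting-law coefficient, quadratic fit in Celsius to the
# standard values 0.4918 (0 C), 0.5092 (25 C), 0.5319 (50 C)
debye_a <- function(temp_c) {
  0.4918 + 5.66e-4 * temp_c + 4.18e-6 * temp_c^2
}

#' Davies activity coefficient
#'
#' Single-ion activity coefficient from the Davies equation,
#' \eqn{\log_{10}\gamma = -A z^2 (\sqrt{I}/(1+\sqrt{I}) - 0.3 I)}.
#' Uncharged species and infinite dilution return 1.
#'
#' @param z Integer charge of the ion.
#' @param ionic_strength Ionic strength, mol L-1 (>= 0).
#' @param temp_c Temperature in Celsius, used for the Debye-Huckel `A`
#'   coefficient when `A` is not given.
#' @param A Optional explicit Debye-Huckel coefficient.
#' @return Dimensionless activity coefficient.
#' @examples
#' davies_gamma(1, 0.7, A = 0.5115)
#' @export
davies_gamma <- function(z, ionic_strength, temp_c = 25, A = NULL) {
  if (any(ionic_strength < 0)) abort("`ionic_strength` must be non-negative.")
  A <- A %||% debye_a(temp_c)
  sq <- sqrt(ionic_strength)
  10^(-A * z^2 * (sq / (1 + sq) - 0.3 * ionic_strength))
}

# reference seawater major-ion composition at S = 35, mol L-1
.SW_REF <- c(na = 0.46860, mg = 0.05282, ca = 0.01028, k = 0.01021,
             cl = 0.54590, so4 = 0.02823)
.SW_Z <- c(na = 1, mg = 2, ca = 2, k = 1, cl = -1, so4 = -2)

#' Major-ion composition of seawater
#'
#' Scales a reference S = 35 major-ion recipe (Na, Mg, Ca, K, Cl, SO4)
#' linearly with practical salinity and computes the ionic strength as the
#' standard half-sum \eqn{I = \tfrac12 \sum c_i z_i^2}.
#'
#' @param salinity Practical salinity, in \[0, 42\].
#' @param temp_c Temperature, Celsius (carried along for downstream
#'   corrections).
#' @return A list of class `fe_seawater` with elements `conc` (named mol L-1
#'   vector), `charge` (named), `salinity`, `temp_c`, `ionic_strength`.
#' @examples
#' sw <- seawater_composition(35, 15)
#' sw$ionic_strength
#' @export
seawater_composition <- function(salinity, temp_c = 15) {
  if (salinity < 0 || salinity > 42) abort("`salinity` must lie in [0, 42].")
  conc <- .SW_REF * salinity / 35
  structure(
    list(conc = conc, charge = .SW_Z, salinity = salinity, temp_c = temp_c,
         ionic_strength = 0.5 * sum(conc * .SW_Z^2)),
    class = "fe_seawater"
  )
}

# ---- pH scale conversions ---------------------------------------------------

# HSO4- dissociation constant (Dickson 1990), free scale, mol/kg-solution
ks_hso4 <- function(salinity, temp_c) {
  T <- temp_c + 273.15
  I <- 19.924 * salinity / (1000 - 1.005 * salinity)
  lnK <- -4276.1 / T + 141.328 - 23.093 * log(T) +
    (-13856 / T + 324.57 - 47.986 * log(T)) * sqrt(I) +
    (35474 / T - 771.54 + 114.723 * log(T)) * I -
    2698 / T * I^1.5 + 1776 / T * I^2 +
    log(1 - 0.001005 * salinity)
  exp(lnK)
}

total_sulfate <- function(salinity) 0.14 / 96.062 * salinity / 1.80655

#' Convert pH between total, free and NBS scales
#'
#' Total and free scales are related through sulfate association,
#' \eqn{[H^+]_T = [H^+]_F (1 + S_T/K_S)} with the Dickson (1990) HSO4-
#' constant; the NBS scale is related to the free scale through the Davies
#' activity coefficient of the proton. At seawater salinity the free-scale
#' value exceeds the total-scale value.
#'
#' @param ph Input pH value(s).
#' @param from,to One of `"total"`, `"free"`, `"NBS"`.
#' @param salinity Practical salinity.
#' @param temp_c Temperature, Celsius.
#' @return Converted pH.
#' @examples
#' convert_ph(7.8, "total", "free", salinity = 35, temp_c = 10)
#' @export
convert_ph <- function(ph, from, to, salinity, temp_c) {
  scales <- c("total", "free", "NBS")
  if (!(from %in% scales) || !(to %in% scales)) {
    abort("pH scales must be one of 'total', 'free', 'NBS'.")
  }
  if (from == to) return(ph)
  dtf <- log10(1 + total_sulfate(salinity) / ks_hso4(salinity, temp_c))
  I <- seawater_composition(salinity, temp_c)$ionic_strength
  dnbs <- -log10(davies_gamma(1, I, temp_c))
  ph_free <- switch(from,
    total = ph + dtf,
    free = ph,
    NBS = ph - dnbs
  )
  switch(to,
    total = ph_free - dtf,
    free = ph_free,
    NBS = ph_free + dnbs
  )
}

# ---- thermodynamic dataset --------------------------------------------------

#' Assemble a thermodynamic dataset
#'
#' Bundles a component basis, formation reactions (stoichiometry expressed as
#' signed counts over components; water implicit) and an optional mineral
#' phase into a validated dataset used by the speciation engine.
#'
#' @param components Tibble with columns `name`, `charge`.
#' @param reactions Tibble with columns `product`, `charge`, `logk_ref`,
#'   `delta_h` and a list-column `stoich` of named numeric vectors over
#'   component names.
#' @param mineral `NULL` or a list with `name`, `logks_ref` (log10 of the
#'   Fe(OH)3(s) + 3H+ = Fe3+ + 3H2O solubility constant at 298.15 K),
#'   `delta_h` (J mol-1) and `medium` (free-text provenance note).
#' @param activity_model `"davies"` or `"conditional"` (unit activity
#'   coefficients, for constants already conditioned to seawater).
#' @return An object of class `fe_thermo`.
#' @seealso [fe_thermo()] for the bundled default set, [load_thermo()] to read
#'   a dataset from a YAML configuration.
#' @export
thermo_dataset <- function(components, reactions, mineral = NULL,
                           activity_model = c("davies", "conditional")) {
  activity_model <- match.arg(activity_model)
  components <- as_tibble(components)
  reactions <- as_tibble(reactions)
  if (anyDuplicated(components$name)) {
    abort("thermo config: duplicate component names.")
  }
  zmap <- setNames(components$charge, components$name)
  for (i in seq_len(nrow(reactions))) {
    st <- reactions$stoich[[i]]
    if (length(st) == 0) {
      abort(sprintf("thermo config: reaction '%s' has empty stoichiometry.",
                    reactions$product[i]))
    }
    unknown <- setdiff(names(st), components$name)
    if (length(unknown)) {
      abort(sprintf("thermo config: reaction '%s' references undefined component(s): %s",
                    reactions$product[i], paste(unknown, collapse = ", ")))
    }
    zsum <- sum(st * zmap[names(st)])
    if (abs(zsum - reactions$charge[i]) > 1e-9) {
      abort(sprintf("thermo config: reaction '%s' is not charge balanced (%g vs %g).",
                    reactions$product[i], zsum, reactions$charge[i]))
    }
  }
  if (!is.null(mineral) && !is.finite(mineral$logks_ref)) {
    abort("thermo config: mineral logks_ref must be finite.")
  }
  structure(
    list(components = components, reactions = reactions, mineral = mineral,
         activity_model = activity_model),
    class = "fe_thermo"
  )
}

#' @export
print.fe_thermo <- function(x, ...) {
  cat("<fe_thermo> ", nrow(x$components), " components, ",
      nrow(x$reactions), " reactions, mineral: ",
      if (is.null(x$mineral)) "none" else x$mineral$name,
      ", activity model: ", x$activity_model, "\n", sep = "")
  invisible(x)
}

#' Default iron thermodynamic dataset
#'
#' Loads the bundled Fe(III) hydrolysis and ferrihydrite dataset. The numeric
#' values are a synthetic placeholder set: plausible hydrolysis constants and
#' enthalpies for the four mononuclear hydroxo complexes and a ferrihydrite
#' solubility product chosen to reproduce field-scale inorganic iron
#' solubilities (order 1 nmol L-1 at deep-ocean pH), not a critically
#' reviewed compilation. Replace via [load_thermo()] when a calibrated
#' dataset is available.
#'
#' @return An `fe_thermo` dataset.
#' @export
fe_thermo <- function() {
  if (is.null(.fespec_cache$thermo)) {
    .fespec_cache$thermo <- load_thermo(
      system.file("extdata", "fe_thermo_synthetic.yaml",
                  package = "fespec", mustWork = TRUE))
  }
  .fespec_cache$thermo
}

# activities of the component basis at given conditions
component_activities <- function(fe3_free, ph_free, sw, gamma) {
  a <- c(fe3 = unname(fe3_free * gamma["3"]),
         h = 10^(-ph_free))
  bulk <- sw$conc * gamma[as.character(abs(sw$charge))]
  c(a, setNames(unname(bulk), names(bulk)))
}

gamma_table <- function(I, temp_c, activity_model) {
  if (activity_model == "conditional") {
    setNames(rep(1, 5), as.character(0:4))
  } else {
    setNames(davies_gamma(0:4, I, temp_c), as.character(0:4))
  }
}

#' Inorganic Fe(III) speciation
#'
#' Distributes free Fe3+ over its hydroxo complexes by mass action with
#' temperature- and activity-corrected constants, and returns the inorganic
#' iron sum Fe' = \[Fe3+\] + hydrolysis species. Fe' is strictly linear in
#' the free Fe3+ concentration at fixed pH, temperature and salinity.
#'
#' @param fe3_free Free Fe3+ concentration, mol L-1.
#' @param ph_free pH on the free scale (fixed proton activity).
#' @param temp_c Temperature, Celsius.
#' @param salinity Practical salinity.
#' @param thermo An `fe_thermo` dataset.
#' @return A tibble with one row per species (`species`, `conc`) carrying the
#'   scalar `fe_prime` (mol L-1) as an attribute; see also [fe_prime_alpha()].
#' @export
inorganic_speciation <- function(fe3_free, ph_free, temp_c, salinity,
                                 thermo = fe_thermo()) {
  if (fe3_free < 0) abort("`fe3_free` must be non-negative.")
  sw <- seawater_composition(salinity, temp_c)
  gam <- gamma_table(sw$ionic_strength, temp_c, thermo$activity_model)
  act <- component_activities(fe3_free, ph_free, sw, gam)
  tk <- temp_c + 273.15
  rx <- thermo$reactions
  conc <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    st <- rx$stoich[[i]]
    miss <- setdiff(names(st), names(act))
    if (length(miss)) {
      abort(sprintf("species '%s' references undefined component(s): %s",
                    rx$product[i], paste(miss, collapse = ", ")))
    }
    logk <- vant_hoff_logk(rx$logk_ref[i], rx$delta_h[i], tk)
    log_a <- logk + sum(st * log10(pmax(act[names(st)], 1e-300)))
    conc[i] <- 10^log_a / gam[as.character(abs(rx$charge[i]))]
  }
  if (fe3_free == 0) conc[] <- 0
  out <- tibble(species = c("fe3", rx$product), conc = c(fe3_free, conc))
  attr(out, "fe_prime") <- sum(out$conc)
  out
}

# Fe'/[Fe3+] side-reaction coefficient at fixed conditions (scalar, >= 1)
fe_prime_alpha <- function(ph_free, temp_c, salinity, thermo = fe_thermo()) {
  sp <- inorganic_speciation(1e-15, ph_free, temp_c, salinity, thermo)
  attr(sp, "fe_prime") / 1e-15
}

# temperature-corrected mineral solubility product (log10, activity basis)
mineral_logks <- function(thermo, temp_k) {
  if (is.null(thermo$mineral)) {
    abort("thermo config: no mineral phase defined; cannot evaluate solubility.")
  }
  vant_hoff_logk(thermo$mineral$logks_ref, thermo$mineral$delta_h, temp_k)
}

#' Inorganic iron solubility at ferrihydrite saturation
#'
#' The Fe' concentration in equilibrium with authigenic ferric oxyhydroxide:
#' the Fe3+ activity at saturation is \eqn{\{Fe^{3+}\}_{sat} = K_s(T)
#' \{H^+\}^3} (dissolution convention), converted to concentration and
#' propagated through the hydrolysis ladder. With the bundled exothermic
#' dissolution enthalpy, solubility increases as both temperature and pH
#' decrease.
#'
#' @inheritParams inorganic_speciation
#' @return Fe' at saturation, mol L-1.
#' @export
fe_prime_solubility <- function(ph_free, temp_c, salinity,
                                thermo = fe_thermo()) {
  sw <- seawater_composition(salinity, temp_c)
  gam <- gamma_table(sw$ionic_strength, temp_c, thermo$activity_model)
  tk <- temp_c + 273.15
  a_fe_sat <- 10^(mineral_logks(thermo, tk) - 3 * ph_free)
  fe3_sat <- a_fe_sat / gam["3"]
  unname(fe3_sat * fe_prime_alpha(ph_free, temp_c, salinity, thermo))
}
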