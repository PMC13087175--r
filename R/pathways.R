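# Pathway configuration and per-sample partition predictions. The four
# equilibrium pathways are: p1 reversible Fe binding to DOM, p2 binding to a
# discrete siderophore, p3 authigenic Fe oxyhydroxide precipitation, p4
# reversible binding to POM. Pathway sets without p4 partition the observed
# dissolved Fe; including p4 partitions the total labile pool
# (TLFe = DFe + LPFe) with no prior assumption on the dissolved/particulate
# split.

validate_pathways <- function(pathways) {
  known <- c("p1", "p2", "p3", "p4")
  bad <- setdiff(pathways, known)
  if (length(bad)) {
    abort(sprintf("unknown pathway id(s): %s", paste(bad, collapse = ", ")))
  }
  pathways
}

required_columns <- function(pathways, has_pom_col) {
  req <- c("dfe_obs", "ph_total", "temp_c", "salinity")
  if ("p1" %in% pathways) req <- c(req, "doc")
  if ("p2" %in% pathways) req <- c(req, "siderophore")
  if ("p4" %in% pathways) req <- c(req, "lpfe_obs", if (!has_pom_col) "tpp")
  unique(req)
}

#' Run pathway combinations over a sample table
#'
#' Builds and solves one [speciation_problem()] per row. Input concentrations
#' follow the field's reporting units: `dfe_obs`/`lpfe_obs` in nmol L-1,
#' `doc` in umol L-1, `tpp` in nmol L-1, `siderophore` in pmol L-1
#' (`NA` treated as below detection, i.e. 0). Predicted dissolved iron is
#' Fe' + FeDOM + FeSid; predicted labile particulate iron is
#' authFeOH + FePOM. Rows with missing required fields yield an explicit
#' per-row error record (`error` column) and the run continues.
#'
#' @param data Data frame of samples; required columns depend on `pathways`.
#' @param pathways Character subset of `c("p1", "p2", "p3", "p4")`.
#' @param thermo An `fe_thermo` dataset.
#' @param phases Phase templates from [load_phases()].
#' @param constants Siderophore constants, see [sid_constants()].
#' @param affinity Also compute occupied effective affinities (slower).
#' @return The input tibble with prediction columns appended: pool
#'   concentrations in nmol L-1 (`fe_prime`, `fe_dom`, `fe_sid`, `fe_pom`,
#'   `auth_feoh`), `dfe_pred`, `lpfe_pred`, `total_fe` (the boundary
#'   condition used), `saturation_index`, Fe:C ratios (umol mol-1),
#'   convergence flags and the `error` column.
#' @examples
#' samples <- tibble::tibble(
#'   dfe_obs = c(0.6, 1.2), lpfe_obs = c(0.03, 0.1), ph_total = 7.75,
#'   temp_c = 4, salinity = 34.6, doc = 40, tpp = 1.2, siderophore = c(0, 150)
#' )
#' run_pathways(samples, c("p1", "p2", "p3", "p4"))
#' @export
run_pathways <- function(data, pathways = c("p1", "p2", "p3", "p4"),
                         thermo = fe_thermo(), phases = default_phases(),
                         constants = sid_constants(), affinity = FALSE) {
  pathways <- validate_pathways(pathways)
  data <- as_tibble(data)
  has_pom_col <- "pom_kg" %in% names(data)
  req <- required_columns(pathways, has_pom_col)
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing required column(s) for pathways %s: %s",
                  paste(pathways, collapse = "+"),
                  paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  out <- tibble(
    fe_prime = rep(NA_real_, n), fe_dom = NA_real_, fe_sid = NA_real_,
    fe_pom = NA_real_, auth_feoh = NA_real_, dfe_pred = NA_real_,
    lpfe_pred = NA_real_, total_fe = NA_real_, fe3_free = NA_real_,
    saturation_index = NA_real_, fe_c_dom = NA_real_, fe_c_pom = NA_real_,
    logkp_fedom = NA_real_, logkp_fepom = NA_real_,
    capped = NA, converged = NA, method = NA_character_,
    error = NA_character_
  )
  warm <- NULL
  use_p4 <- "p4" %in% pathways
  for (i in seq_len(n)) {
    row <- data[i, ]
    res <- tryCatch({
      total_nmol <- if (use_p4) row$dfe_obs + row$lpfe_obs else row$dfe_obs
      if (is.na(total_nmol)) abort("missing Fe boundary condition")
      for (col in setdiff(req, c("siderophore"))) {
        if (is.na(row[[col]])) abort(sprintf("missing required field '%s'", col))
      }
      dom <- if ("p1" %in% pathways) {
        dom_phase(dom_from_doc(row$doc), params = phases$dom)
      } else NULL
      pom <- if (use_p4) {
        mass <- if (has_pom_col) row$pom_kg else pom_from_tpp(row$tpp)$pom_kg
        pom_phase(mass, params = phases$pom)
      } else NULL
      sid <- if ("p2" %in% pathways) {
        tot <- row$siderophore
        siderophore_ligand(ifelse(is.na(tot), 0, tot) * 1e-12, constants)
      } else NULL
      pr <- speciation_problem(
        total_fe = total_nmol * 1e-9, ph_total = row$ph_total,
        temp_c = row$temp_c, salinity = row$salinity,
        dom = dom, pom = pom, siderophore = sid,
        allow_mineral = "p3" %in% pathways, thermo = thermo
      )
      solve_equilibrium(pr, warm = warm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
      next
    }
    warm <- res
    out$fe_prime[i] <- res$fe_prime * 1e9
    out$fe_dom[i] <- res$fe_dom * 1e9
    out$fe_sid[i] <- res$fe_sid * 1e9
    out$fe_pom[i] <- res$fe_pom * 1e9
    out$auth_feoh[i] <- res$auth_feoh * 1e9
    out$dfe_pred[i] <- (res$fe_prime + res$fe_dom + res$fe_sid) * 1e9
    out$lpfe_pred[i] <- (res$auth_feoh + res$fe_pom) * 1e9
    out$total_fe[i] <- res$total_fe * 1e9
    out$fe3_free[i] <- res$fe3_free
    out$saturation_index[i] <- res$saturation_index
    out$capped[i] <- res$capped
    out$converged[i] <- res$converged
    out$method[i] <- res$method
    if ("p1" %in% pathways && !is.na(row$doc)) {
      out$fe_c_dom[i] <- fe_c_ratio(res$fe_dom, row$doc * 1e-6)
    }
    if (use_p4) {
      mass <- if (has_pom_col) row$pom_kg else pom_from_tpp(row$tpp)$pom_kg
      poc_mol <- 0.5 * mass * 1000 / 12.011
      out$fe_c_pom[i] <- fe_c_ratio(res$fe_pom, poc_mol)
    }
    if (affinity) {
      aff <- occupied_affinity(res)
      if (nrow(aff)) {
        kd <- aff$logk_prime[aff$phase == "dom"]
        kp <- aff$logk_prime[aff$phase == "pom"]
        if (length(kd)) out$logkp_fedom[i] <- kd
        if (length(kp)) out$logkp_fepom[i] <- kp
      }
    }
  }
  bind_cols(data, out)
}

#' Iron to organic carbon ratio
#'
#' @param bound_fe Bound iron, mol L-1.
#' @param organic_c Organic carbon, mol L-1 (> 0; zero yields `NA`).
#' @return Ratio in umol Fe (mol C)-1.
#' @examples
#' fe_c_ratio(1e-9, 50e-6) # 20 umol/mol
#' @export
fe_c_ratio <- function(bound_fe, organic_c) {
  ifelse(organic_c > 0, 1e6 * bound_fe / organic_c, NA_real_)
}

#' Scavenging residence time ratio
#'
#' At equilibrium the residence time of labile particulate iron relates to
#' that of the particles via
#' \eqn{\tau_{LPFe}/\tau_{Part} = 1 + c_{DFe}/c_{LPFe}}.
#'
#' @param c_dfe Dissolved iron concentration (any unit).
#' @param c_lpfe Labile particulate iron concentration (same unit; zero
#'   yields `Inf`).
#' @return Dimensionless ratio.
#' @examples
#' residence_time_ratio(0.70, 0.021)
#' @export
residence_time_ratio <- function(c_dfe, c_lpfe) {
  ifelse(c_lpfe > 0, 1 + c_dfe / c_lpfe, Inf)
}
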