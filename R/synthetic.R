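# Seedable synthetic zonal-transect generator. Produces sample tables with
# the spatial and statistical structure the analysis assumes — smooth
# background hydrography, a mesopelagic siderophore patch, and planted iron
# sources — plus forward-model "observations" with known truth so the
# pipeline can be tested end to end. No claim of dynamical realism beyond
# the documented field ranges.

default_depths <- function() {
  c(250, 300, 400, 500, 650, 800, 1000, 1250, 1500, 2000, 2500,
    3000, 3500, 4000, 4500)
}

#' Generate a synthetic zonal transect
#'
#' Builds a station/depth grid spanning roughly 72 deg W to 179 deg E at
#' 250-5000 m, fills in background fields (temperature 1.6-16 C, salinity,
#' total-scale pH, oxygen, DOC, particulate phosphorus), a mesopelagic
#' siderophore patch (up to 425 pmol L-1 between 400 and 1500 m near
#' 117 deg W), and three planted iron sources (hydrothermal ridge at
#' 117 deg W, volcano at 177 deg E, continental shelf at the eastern edge).
#' Equilibrium observations are constructed by running the forward pathway
#' model on the generated conditions and emitting the predicted
#' dissolved/labile-particulate partition with multiplicative lognormal
#' observational noise; anomaly samples are then perturbed away from
#' equilibrium by configured offsets (defaults: twice the enhanced-residual
#' thresholds, planted at saturated plume cores and at deep eastern
#' ferromanganese-like samples).
#'
#' @param seed Integer seed; fixes all randomness.
#' @param n_stations Number of stations along the track.
#' @param depths Sample depths, m.
#' @param noise_fe Lognormal sigma of Fe observational noise (0 disables).
#' @param noise_fields Lognormal sigma for DOC/TPP field noise.
#' @param anomalies Plant non-equilibrium anomalies.
#' @param anomaly_scale Offset size in multiples of the enhanced-residual
#'   thresholds (default 2).
#' @param pathways Pathway set used for the forward model.
#' @param ... Passed to [run_pathways()] (thermo/phase configuration).
#' @return A list with `samples` (the observation table consumed by
#'   [run_transect()]) and `truth` (per-sample true pools in nmol L-1, true
#'   class, and generator metadata).
#' @examples
#' tr <- synth_transect(seed = 7, n_stations = 6, depths = c(300, 800, 2500))
#' head(tr$samples)
#' @export
synth_transect <- function(seed = 1, n_stations = 34,
                           depths = default_depths(),
                           noise_fe = 0.05, noise_fields = 0.02,
                           anomalies = TRUE, anomaly_scale = 2,
                           pathways = c("p1", "p2", "p3", "p4"), ...) {
  with_seed(seed, {
    t_frac <- seq(0, 1, length.out = n_stations)
    lon_u <- -72 - 109 * t_frac            # unwrapped track longitude
    lon <- ifelse(lon_u < -180, lon_u + 360, lon_u)
    lat <- -32.5 + 1.5 * sin(pi * t_frac)
    station <- sprintf("%02d", seq_len(n_stations))

    g <- expand_grid_samples(station, lon, lon_u, lat, t_frac, depths)
    z <- g$depth
    east <- 1 - g$t_frac                   # 1 at the South American end

    g$temp_c <- pmin(16, pmax(1.6,
      1.6 + 14.4 * exp(-(z - 250) / 650) * (1 - 0.05 * sin(pi * g$t_frac)) +
        rnorm(nrow(g), 0, 0.05)))
    g$salinity <- 34.70 - 0.42 * exp(-((z - 800) / 500)^2) +
      rnorm(nrow(g), 0, 0.005)
    g$ph_total <- 7.87 - 0.28 * east * exp(-((z - 600) / 500)^2) -
      0.03 * exp(-(z - 250) / 2000) + rnorm(nrow(g), 0, 0.005)
    g$o2 <- pmax(15, 210 - 185 * east * exp(-((z - 500) / 400)^2) +
                   20 * z / 5000 + rnorm(nrow(g), 0, 2))
    o2_sat <- 356 - 7.7 * g$temp_c + 0.12 * g$temp_c^2
    g$aou <- pmax(0, o2_sat - g$o2)
    g$doc <- (38.5 + 15.5 * exp(-(z - 250) / 450)) *
      exp(rnorm(nrow(g), 0, noise_fields))
    g$tpp <- (0.25 + 2.1 * exp(-(z - 250) / 500)) *
      exp(rnorm(nrow(g), 0, noise_fields))
    sid <- 425 * exp(-((g$lon_u + 117) / 14)^2 - ((z - 950) / 320)^2)
    sid[z < 400 | z > 1500 | sid < 5] <- 0
    g$siderophore <- sid
    g$lpmn <- 22 * exp(rnorm(nrow(g), 0, 0.1))

    # total labile Fe: smooth background plus three planted source plumes
    plume_ridge <- 10.5 * exp(-((g$lon_u + 117) / 5)^2 - ((z - 2500) / 450)^2)
    plume_volc <- 3.2 * exp(-((g$lon_u + 183) / 4)^2 - ((z - 1200) / 500)^2)
    plume_shelf <- 5.0 * exp(-((g$lon_u + 73.5) / 2.5)^2 - ((4800 - z) / 900)^2)
    tlfe <- (0.35 + 0.75 * (1 - exp(-(z - 250) / 900))) * (1 + 0.45 * east) +
      plume_ridge + plume_volc + plume_shelf

    fw <- g
    fw$dfe_obs <- tlfe
    fw$lpfe_obs <- 0
    pred <- run_pathways(fw, pathways = pathways, ...)
    if (any(!is.na(pred$error))) {
      abort("synth_transect: forward model failed on generated conditions.")
    }

    n <- nrow(g)
    g$dfe_obs <- pred$dfe_pred * exp(rnorm(n, 0, noise_fe))
    g$lpfe_obs <- pred$lpfe_pred * exp(rnorm(n, 0, noise_fe))
    g$tpfe_obs <- g$lpfe_obs * 2.5 + 0.05

    truth <- tibble(
      sample_id = g$sample_id,
      fe_prime = pred$fe_prime, fe_dom = pred$fe_dom, fe_sid = pred$fe_sid,
      fe_pom = pred$fe_pom, auth_feoh = pred$auth_feoh,
      tlfe_true = tlfe, capped = pred$capped,
      plume = plume_ridge + plume_volc + plume_shelf,
      class = "equilibrium"
    )

    if (anomalies) {
      thr <- .ENHANCED
      pick_top <- function(score, k, eligible) {
        ord <- order(ifelse(eligible, score, -Inf), decreasing = TRUE)
        ord[seq_len(min(k, sum(eligible)))]
      }
      # labile/reduced Fe inputs at saturated plume cores: observed DFe
      # exceeds what equilibrium can hold in solution
      for (src in list(list(p = plume_ridge, lab = "anomaly_hydrothermal"),
                       list(p = plume_volc, lab = "anomaly_volcano"),
                       list(p = plume_shelf, lab = "anomaly_shelf"))) {
        idx <- pick_top(src$p, 4, pred$capped & src$p > 0.5)
        g$dfe_obs[idx] <- g$dfe_obs[idx] + anomaly_scale * abs(thr$dfe_neg)
        truth$class[idx] <- src$lab
      }
      # benthic ferromanganese particles: inert LPFe excess at depth, with
      # labile Fe:Mn near the ferromanganese ratio; placed in clearly
      # undersaturated bottom waters (where such aged oxides persist without
      # re-equilibrating through the authigenic phase)
      fmn <- pick_top(east * (z > 3000), 6,
                      z > 3000 & east > 0.3 & !pred$capped &
                        pred$saturation_index < -0.5 &
                        truth$class == "equilibrium")
      g$lpfe_obs[fmn] <- g$lpfe_obs[fmn] + anomaly_scale * abs(thr$lpfe_neg)
      g$lpmn[fmn] <- g$lpfe_obs[fmn] * 1000 / 1.1
      truth$class[fmn] <- "anomaly_ferromanganese"
      # apparent dissolved deficit (e.g. fresh colloid aggregation): observed
      # DFe below the equilibrium prediction at high-Fe samples
      posi <- pick_top(pred$dfe_pred, 4,
                       pred$capped & pred$dfe_pred > 2 &
                         truth$class == "equilibrium")
      g$dfe_obs[posi] <- pmax(0.05,
        g$dfe_obs[posi] - anomaly_scale * thr$dfe_pos)
      truth$class[posi] <- "anomaly_positive"
    }
    g$dfe_obs <- pmin(pmax(g$dfe_obs, 0.014), 12.6)
    list(samples = select(g, -"t_frac", -"lon_u"), truth = truth)
  })
}

expand_grid_samples <- function(station, lon, lon_u, lat, t_frac, depths) {
  idx <- rep(seq_along(station), each = length(depths))
  z <- rep(depths, length(station))
  tibble(
    sample_id = sprintf("S%s-%04d", station[idx], z),
    station = station[idx], lon = lon[idx], lon_u = lon_u[idx],
    lat = lat[idx], t_frac = t_frac[idx], depth = z
  )
}

#' Generate synthetic water-mass mixtures for eOMPA tests
#'
#' Forward-constructs observations `E x + r dP + noise` from known
#' fractions.
#'
#' @param fractions Numeric vector of non-negative fractions summing to 1
#'   (length = number of endmembers).
#' @param delta_p Remineralisation extent, umol kg-1 phosphate.
#' @param noise Additive Gaussian noise standard deviation per parameter.
#' @param seed Integer seed.
#' @param endmembers Endmember table, see [wm_endmembers()].
#' @param redfield Redfield vector.
#' @return One-row tibble with the six eOMPA parameter columns.
#' @export
synth_mixture <- function(fractions, delta_p = 0, noise = 0, seed = 1,
                          endmembers = wm_endmembers(),
                          redfield = redfield_vector()) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-10) {
    abort("synth_mixture: fractions must be non-negative and sum to 1.")
  }
  if (length(fractions) != nrow(endmembers)) {
    abort("synth_mixture: one fraction per endmember required.")
  }
  with_seed(seed, {
    E <- t(as.matrix(endmembers[, .EOMPA_PARAMS]))
    obs <- as.numeric(E %*% fractions) + redfield[.EOMPA_PARAMS] * delta_p +
      rnorm(length(.EOMPA_PARAMS), 0, noise)
    as_tibble(as.list(setNames(obs, .EOMPA_PARAMS)))
  })
}
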