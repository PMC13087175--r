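# Extended optimum multiparameter analysis: decompose each sample into
# non-negative water-mass endmember fractions summing to one, plus a
# remineralisation extent acting through a fixed Redfield vector.

.EOMPA_PARAMS <- c("temperature", "salinity", "oxygen", "phosphate",
                   "nitrate", "silicate")

#' Default Redfield remineralisation vector
#'
#' Changes per umol kg-1 of phosphate remineralised:
#' 0 (temperature), 0 (salinity), -170 (oxygen), 1 (phosphate),
#' 16 (nitrate + nitrite), 40 (silicate).
#'
#' @return Named numeric vector over the six eOMPA parameters.
#' @export
redfield_vector <- function() {
  c(temperature = 0, salinity = 0, oxygen = -170, phosphate = 1,
    nitrate = 16, silicate = 40)
}

#' Water-mass endmember table
#'
#' Loads the bundled endmember properties for six South Pacific water
#' masses (STW, ESSW, AAIW, UCDW, PDW, LCDW). The values are a synthetic
#' placeholder table at hydrographically plausible magnitudes, not the
#' study-specific calibration; supply your own table with the same columns
#' to override.
#'
#' @param path Optional path to a CSV with columns `water_mass`,
#'   `temperature`, `salinity`, `oxygen`, `phosphate`, `nitrate`,
#'   `silicate`.
#' @return A tibble, one row per water mass.
#' @export
wm_endmembers <- function(path = NULL) {
  path <- path %||% system.file("extdata", "endmembers_synthetic.csv",
                                package = "fespec", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Solve water-mass mixing fractions (eOMPA)
#'
#' Weighted constrained least squares: for each sample, minimises
#' \eqn{\|W(E x + r \Delta P - b)\|} over non-negative fractions `x`
#' (summing to one through a heavily weighted mass-conservation row) and a
#' free remineralisation extent \eqn{\Delta P} acting through the Redfield
#' vector `r`. Parameter rows are standardised by the spread of the
#' endmember matrix before weighting. The non-negative core is solved with
#' `pracma::lsqnonneg`; the sign-free \eqn{\Delta P} is split into positive
#' and negative parts.
#'
#' @param data Data frame with the six parameter columns
#'   (`temperature`, `salinity`, `oxygen`, `phosphate`, `nitrate`,
#'   `silicate`).
#' @param endmembers Endmember table, see [wm_endmembers()].
#' @param redfield Redfield vector, see [redfield_vector()].
#' @param weights Optional named per-parameter weights (default 1).
#' @param mass_weight Weight of the mass-conservation row relative to
#'   tracer rows (default 100).
#' @return A tibble of class `fe_mixing`: one row per sample with fraction
#'   columns `f_<water_mass>`, `delta_p` (umol kg-1), `residual_norm` and
#'   `fraction_sum`.
#' @examples
#' em <- wm_endmembers()
#' solve_mixing(em[2, ], em) # pure ESSW sample recovers fraction 1
#' @export
solve_mixing <- function(data, endmembers = wm_endmembers(),
                         redfield = redfield_vector(), weights = NULL,
                         mass_weight = 100) {
  data <- as_tibble(data)
  endmembers <- as_tibble(endmembers)
  if (nrow(endmembers) < 2) abort("solve_mixing: need at least 2 endmembers.")
  pars <- .EOMPA_PARAMS
  missing_cols <- setdiff(pars, names(data))
  if (length(missing_cols)) {
    abort(sprintf("solve_mixing: missing parameter column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  E <- t(as.matrix(endmembers[, pars])) # params x masses
  k <- ncol(E)
  spread <- apply(E, 1, sd)
  spread[spread == 0 | !is.finite(spread)] <- 1
  w <- rep(1, length(pars))
  names(w) <- pars
  if (!is.null(weights)) w[names(weights)] <- weights
  W <- w / spread
  r <- redfield[pars]
  A <- cbind(E * W, r * W, -r * W)
  A <- rbind(A, c(rep(mass_weight, k), 0, 0))
  # rank check on the un-split system (the +/- split of delta P is
  # deliberately rank-deficient; lsqnonneg handles it)
  A0 <- rbind(cbind(E * W, r * W), c(rep(mass_weight, k), 0))
  rc <- rcond(crossprod(A0))
  if (rc < 1e-14) {
    abort(sprintf("solve_mixing: degenerate endmember system (rcond = %.2e); check endmember table.",
                  rc))
  }
  out <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    b <- as.numeric(data[i, pars])
    if (anyNA(b)) {
      row <- as.list(rep(NA_real_, k + 3))
      names(row) <- c(paste0("f_", endmembers$water_mass), "delta_p",
                      "residual_norm", "fraction_sum")
      out[[i]] <- as_tibble(row)
      next
    }
    bb <- c(b * W, mass_weight)
    fit <- pracma::lsqnonneg(A, bb)
    x <- fit$x[seq_len(k)]
    dp <- fit$x[k + 1] - fit$x[k + 2]
    resid <- as.numeric(E %*% x + r * dp - b) * W
    row <- as.list(c(x, dp, sqrt(sum(resid^2)), sum(x)))
    names(row) <- c(paste0("f_", endmembers$water_mass), "delta_p",
                    "residual_norm", "fraction_sum")
    out[[i]] <- as_tibble(row)
  }
  res <- bind_cols(data, bind_rows(out))
  class(res) <- c("fe_mixing", class(res))
  attr(res, "water_masses") <- endmembers$water_mass
  res
}

#' Correlate a tracer with water-mass fractions
#'
#' Pearson correlation (with two-sided p value) between a tracer and each
#' solved water-mass fraction. Constant fraction vectors yield `NA` with a
#' flag.
#'
#' @param solutions An `fe_mixing` tibble from [solve_mixing()].
#' @param tracer Numeric vector, same length as `nrow(solutions)`.
#' @return Tibble with `water_mass`, `r`, `p_value`, `n`, `degenerate`.
#' @export
correlate_fractions <- function(solutions, tracer) {
  wms <- attr(solutions, "water_masses")
  rows <- map(wms, function(wm) {
    f <- solutions[[paste0("f_", wm)]]
    ok <- is.finite(f) & is.finite(tracer)
    if (sum(ok) < 3) {
      return(tibble(water_mass = wm, r = NA_real_, p_value = NA_real_,
                    n = sum(ok), degenerate = TRUE))
    }
    if (sd(f[ok]) == 0 || sd(tracer[ok]) == 0) {
      return(tibble(water_mass = wm, r = NA_real_, p_value = NA_real_,
                    n = sum(ok), degenerate = TRUE))
    }
    ct <- cor.test(f[ok], tracer[ok])
    tibble(water_mass = wm, r = unname(ct$estimate), p_value = ct$p.value,
           n = sum(ok), degenerate = FALSE)
  })
  bind_rows(rows)
}

#' Long view of mixing fractions
#' @method tidy fe_mixing
#' @param x An `fe_mixing`.
#' @param ... Unused.
#' @export
tidy.fe_mixing <- function(x, ...) {
  wms <- attr(x, "water_masses")
  tibble::as_tibble(x)[, c(paste0("f_", wms), "delta_p", "residual_norm")] |>
    mutate(sample = row_number()) |>
    pivot_longer(cols = paste0("f_", wms), names_to = "water_mass",
                 names_prefix = "f_", values_to = "fraction") |>
    select("sample", "water_mass", "fraction", "delta_p", "residual_norm")
}

#' One-row summary of a mixing solve
#' @method glance fe_mixing
#' @param x An `fe_mixing`.
#' @param ... Unused.
#' @export
glance.fe_mixing <- function(x, ...) {
  tibble(
    n = nrow(x),
    max_residual_norm = max(x$residual_norm, na.rm = TRUE),
    max_fraction_sum_error = max(abs(x$fraction_sum - 1), na.rm = TRUE),
    median_delta_p = median(x$delta_p, na.rm = TRUE)
  )
}
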