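# Delimited-text readers/writers with column mapping and unit normalisation.
# Canonical internal convention: concentrations per litre, with Fe in
# nmol L-1, Mn and siderophores in pmol L-1, DOC in umol L-1, TPP in
# nmol L-1; depth in m.

.CANONICAL_UNITS <- c(
  dfe_obs = "nmol/L", lpfe_obs = "nmol/L", tpfe_obs = "nmol/L",
  lpmn = "pmol/L", siderophore = "pmol/L", doc = "umol/L", tpp = "nmol/L"
)

#' Seawater density at atmospheric pressure
#'
#' International one-atmosphere equation of state of seawater (EOS-80
#' surface polynomial), used to convert per-kilogram concentrations to
#' per-litre.
#'
#' @param salinity Practical salinity.
#' @param temp_c Temperature, Celsius.
#' @return Density, kg m-3.
#' @examples
#' sw_density(35, 5) # 1027.675 kg/m3
#' @export
sw_density <- function(salinity, temp_c) {
  t <- temp_c
  rw <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rw + A * salinity + B * salinity^1.5 + C * salinity^2
}

#' Read a sample table
#'
#' Reads a comma-separated observation table, optionally renaming columns
#' through a mapping from canonical field names to file headers, converting
#' per-kilogram units to per-litre using the in-situ (surface-pressure)
#' density, applying the below-detection policy (siderophore `NA` becomes
#' 0; other fields keep `NA`), and the analysis-domain depth filter.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector `canonical = "file
#'   header"`.
#' @param units Optional named character vector giving the file's units for
#'   concentration columns, e.g. `c(dfe_obs = "nmol/kg")`; defaults assume
#'   canonical per-litre units.
#' @param depth_min Depth filter, m; `NULL` disables.
#' @return A tibble of unit-normalised samples.
#' @export
read_samples <- function(path, mapping = NULL, units = NULL,
                         depth_min = 250) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    abort(sprintf("cannot parse '%s': %s", path,
                                  conditionMessage(e)))
                  })
  if (nrow(raw) == 0) abort(sprintf("'%s' contains no data rows.", path))
  data <- as_tibble(raw)
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(data))
    if (length(missing_src)) {
      abort(sprintf("mapped column(s) absent from file: %s (canonical names: %s)",
                    paste(missing_src, collapse = ", "),
                    paste(names(mapping)[mapping %in% missing_src], collapse = ", ")))
    }
    for (canon in names(mapping)) {
      names(data)[names(data) == mapping[[canon]]] <- canon
    }
  }
  if (!is.null(units)) {
    unknown <- setdiff(names(units), names(.CANONICAL_UNITS))
    if (length(unknown)) {
      abort(sprintf("unit declarations for unknown column(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    for (col in names(units)) {
      u <- units[[col]]
      target <- .CANONICAL_UNITS[[col]]
      if (u == target) next
      per_kg <- sub("/L$", "/kg", target)
      if (u == per_kg) {
        if (!all(c("salinity", "temp_c") %in% names(data))) {
          abort("per-kg unit conversion requires `salinity` and `temp_c` columns.")
        }
        rho <- sw_density(data$salinity, data$temp_c) / 1000 # kg/L
        data[[col]] <- data[[col]] * rho
      } else {
        abort(sprintf("cannot convert column '%s' from '%s' to '%s'.",
                      col, u, target))
      }
    }
  }
  if ("siderophore" %in% names(data)) {
    data$siderophore[is.na(data$siderophore)] <- 0
  }
  if (!is.null(depth_min) && "depth" %in% names(data)) {
    data <- data[data$depth > depth_min, ]
  }
  data
}

#' Write a sample or result table
#'
#' Plain UTF-8 comma-separated output with `.` decimal; round-trips through
#' [read_samples()] bit-exactly for finite values.
#'
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path) {
  df <- as.data.frame(data)
  keep <- vapply(df, function(col) is.atomic(col), logical(1))
  df <- df[, keep, drop = FALSE]
  # full binary precision so finite values survive the round trip
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
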