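# Structured-configuration readers. Thermodynamic constants and NICA-Donnan
# phase parameters live in YAML files with explicit blocks; loaders validate
# the schema and raise errors naming the offending block.

#' Load a thermodynamic dataset from a YAML configuration
#'
#' Expected blocks: `components` (list of `{name, charge}`), `reactions`
#' (list of `{product, charge, logk_ref, delta_h, stoich}` where `stoich` is
#' a map of component name to signed count), optional `mineral`
#' (`{name, logks_ref, delta_h, medium}`) and optional `activity_model`.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "fe_thermo_synthetic.yaml", package = "fespec")`
#'   for the bundled layout.
#' @return An `fe_thermo` dataset.
#' @export
load_thermo <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (block in c("components", "reactions")) {
    if (is.null(cfg[[block]])) {
      abort(sprintf("thermo config '%s': missing block '%s'.", path, block))
    }
  }
  comps <- tibble(
    name = map_chr_checked(cfg$components, "name", "components"),
    charge = map_num_checked(cfg$components, "charge", "components")
  )
  rx <- tibble(
    product = map_chr_checked(cfg$reactions, "product", "reactions"),
    charge = map_num_checked(cfg$reactions, "charge", "reactions"),
    logk_ref = map_num_checked(cfg$reactions, "logk_ref", "reactions"),
    delta_h = map_num_checked(cfg$reactions, "delta_h", "reactions"),
    stoich = lapply(cfg$reactions, function(r) {
      if (is.null(r$stoich) || !length(r$stoich)) {
        abort(sprintf("thermo config: block 'reactions' entry '%s' has no stoich map.",
                      r$product %||% "<unnamed>"))
      }
      unlist(r$stoich)
    })
  )
  mineral <- NULL
  if (!is.null(cfg$mineral)) {
    for (f in c("name", "logks_ref", "delta_h")) {
      if (is.null(cfg$mineral[[f]])) {
        abort(sprintf("thermo config: block 'mineral' missing field '%s'.", f))
      }
    }
    mineral <- cfg$mineral
  }
  thermo_dataset(comps, rx, mineral,
                 activity_model = cfg$activity_model %||% "davies")
}

map_chr_checked <- function(lst, field, block) {
  vapply(lst, function(x) {
    if (is.null(x[[field]])) {
      abort(sprintf("config: block '%s' entry missing field '%s'.", block, field))
    }
    as.character(x[[field]])
  }, character(1))
}

map_num_checked <- function(lst, field, block) {
  vapply(lst, function(x) {
    if (is.null(x[[field]])) {
      abort(sprintf("config: block '%s' entry missing field '%s'.", block, field))
    }
    as.numeric(x[[field]])
  }, numeric(1))
}

#' Load NICA-Donnan phase definitions from a YAML configuration
#'
#' Each top-level block defines one phase: `donnan_b` plus exactly two
#' `groups`, each with `qmax`, `logk_h`, `n_h`, `p` and an `ions` map of
#' per-ion `{logk, n}` entries.
#'
#' @param path Path to a YAML file; the bundled
#'   `nica_phases_synthetic.yaml` mirrors the layout of typical speciation
#'   program input decks.
#' @return Named list of phase templates consumed by [nica_phase()].
#' @export
load_phases <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  for (nm in names(cfg)) {
    ph <- cfg[[nm]]
    if (is.null(ph$groups) || length(ph$groups) != 2) {
      abort(sprintf("phase config: block '%s' must define exactly two groups.", nm))
    }
    groups <- lapply(ph$groups, function(g) {
      for (f in c("qmax", "logk_h", "n_h", "p")) {
        if (is.null(g[[f]])) {
          abort(sprintf("phase config: block '%s' group missing field '%s'.", nm, f))
        }
      }
      ions <- g$ions %||% list()
      nica_group(
        qmax = g$qmax, logk_h = g$logk_h, n_h = g$n_h, p = g$p,
        logk = vapply(ions, function(x) as.numeric(x$logk), numeric(1)),
        n = vapply(ions, function(x) as.numeric(x$n), numeric(1))
      )
    })
    if (is.null(ph$donnan_b)) {
      abort(sprintf("phase config: block '%s' missing field 'donnan_b'.", nm))
    }
    out[[nm]] <- list(groups = groups, donnan_b = ph$donnan_b)
  }
  out
}

.fespec_cache <- new.env(parent = emptyenv())

default_phases <- function() {
  if (is.null(.fespec_cache$phases)) {
    .fespec_cache$phases <- load_phases(
      system.file("extdata", "nica_phases_synthetic.yaml",
                  package = "fespec", mustWork = TRUE))
  }
  .fespec_cache$phases
}

#' Default siderophore (ferrioxamine B proxy) stability constants
#'
#' Cumulative protonation constants for the trihydroxamate ligand and
#' formation constants for its Mg, Ca and Fe(III) complexes. The values are
#' a synthetic placeholder set at the literature order of magnitude for
#' desferrioxamine B (logK of the ferric complex near 30.6); conditional to
#' seawater, temperature-independent by default.
#'
#' @return Named list of log10 constants used by [siderophore_binding()].
#' @export
sid_constants <- function() {
  list(logb_h = c(9.46, 18.46, 26.76), logb_mg = 4.30, logb_ca = 2.64,
       logb_fe = 30.60)
}
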