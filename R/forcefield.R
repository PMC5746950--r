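#' Load force-field parameter tables
#'
#' Reads a structured YAML parameter file into the symmetric Lennard-Jones
#' and bonded parameter tables used by the engine. The package ships a
#' documented default table (`system.file("extdata", "martini_cg.yaml",
#' package = "lnpsim")`) with Martini-2.0-like magnitudes; all values are
#' configurable, none are hard-coded.
#'
#' Validation enforces: every pair of the five bead types (C1, Na, P3, P4,
#' AF) present; a symmetric table with positive sigma and epsilon; and the
#' hydrophobic ordering `eps(C1,P4) < eps(C1,C1)` and
#' `eps(C1,P4) < eps(P4,P4)` that hydrophobic collapse requires.
#'
#' @param path Path to a YAML parameter file; defaults to the shipped table.
#' @return An object of class `cg_forcefield`: a list with `types`,
#'   `sigma` and `eps` (symmetric type-by-type matrices), `ring_sigma`,
#'   `ring_eps_scale`, `bonded` (chain bond/angle and ring defaults),
#'   `water` (antifreeze ratio, real-water mapping) and `mass`.
#' @examples
#' ff <- load_forcefield()
#' ff$eps["C1", "P4"] < ff$eps["C1", "C1"]
#' @export
load_forcefield <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "martini_cg.yaml", package = "lnpsim")
  }
  if (!file.exists(path)) stop("force-field configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  forcefield_from_config(cfg)
}

#' @rdname load_forcefield
#' @export
default_forcefield <- function() load_forcefield()

# Build validated tables from a parsed configuration list.
forcefield_from_config <- function(cfg) {
  types <- .bead_types
  missing_types <- setdiff(types, unlist(cfg$bead_types))
  if (length(missing_types) > 0) {
    stop("configuration error: bead types missing from config: ",
         paste(missing_types, collapse = ", "))
  }
  nt <- length(types)
  eps <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  for (a in names(cfg$lj$epsilon)) {
    for (b in names(cfg$lj$epsilon[[a]])) {
      val <- cfg$lj$epsilon[[a]][[b]]
      if (!is.na(eps[a, b]) && eps[a, b] != val) {
        stop("configuration error: asymmetric epsilon entry for pair ",
             a, "-", b)
      }
      eps[a, b] <- val
      if (!is.na(eps[b, a]) && eps[b, a] != val) {
        stop("configuration error: asymmetric epsilon entry for pair ",
             b, "-", a)
      }
      eps[b, a] <- val
    }
  }
  if (any(is.na(eps))) {
    idx <- which(is.na(eps) & upper.tri(eps, diag = TRUE), arr.ind = TRUE)
    stop("configuration error: missing epsilon entry for pair ",
         paste(types[idx[1, 1]], types[idx[1, 2]], sep = "-"))
  }
  sigma <- matrix(cfg$lj$default_sigma, nt, nt, dimnames = list(types, types))
  for (a in names(cfg$lj$sigma_overrides)) {
    for (b in names(cfg$lj$sigma_overrides[[a]])) {
      sigma[a, b] <- sigma[b, a] <- cfg$lj$sigma_overrides[[a]][[b]]
    }
  }
  ff <- structure(list(
    types = types,
    sigma = sigma,
    eps = eps,
    ring_sigma = cfg$lj$ring_sigma,
    ring_eps_scale = cfg$lj$ring_eps_scale,
    bonded = cfg$bonded,
    water = cfg$water,
    mass = cfg$mass,
    version = cfg$version
  ), class = "cg_forcefield")
  validate_forcefield(ff)
  ff
}

#' Validate force-field tables
#'
#' Checks symmetry, positivity and the hydrophobic interaction ordering.
#' Called automatically by [load_forcefield()]; exported so user-assembled
#' tables can be checked too.
#'
#' @param ff A `cg_forcefield` object.
#' @return `ff`, invisibly, when valid; otherwise an error is raised.
#' @export
validate_forcefield <- function(ff) {
  if (!isTRUE(all.equal(ff$sigma, t(ff$sigma))) ||
      !isTRUE(all.equal(ff$eps, t(ff$eps)))) {
    stop("configuration error: LJ table is not symmetric")
  }
  if (any(ff$sigma <= 0) || any(ff$eps <= 0)) {
    stop("configuration error: LJ sigma and epsilon must be positive")
  }
  if (!(ff$eps["C1", "P4"] < ff$eps["C1", "C1"] &&
        ff$eps["C1", "P4"] < ff$eps["P4", "P4"])) {
    stop("ordering violation: hydrophobic collapse requires ",
         "eps(C1,P4) < eps(C1,C1) and eps(C1,P4) < eps(P4,P4)")
  }
  if (ff$ring_sigma <= 0 || ff$ring_eps_scale <= 0) {
    stop("configuration error: ring parameters must be positive")
  }
  for (fld in c("bond", "angle", "ring_bond", "ring_diagonal")) {
    if (is.null(ff$bonded[[fld]])) {
      stop("configuration error: missing bonded defaults for '", fld, "'")
    }
  }
  invisible(ff)
}

#' Write force-field tables back to a YAML file
#'
#' @param ff A `cg_forcefield` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  types <- ff$types
  eps_list <- list()
  sig_over <- list()
  for (i in seq_along(types)) {
    row <- list()
    for (j in i:length(types)) row[[types[j]]] <- ff$eps[i, j]
    eps_list[[types[i]]] <- row
    for (j in i:length(types)) {
      # record sigma entries that differ from the modal (default) value
      if (ff$sigma[i, j] != stats::median(ff$sigma)) {
        sig_over[[types[i]]][[types[j]]] <- ff$sigma[i, j]
      }
    }
  }
  cfg <- list(
    version = ff$version,
    units = list(length = "nm", energy = "kJ/mol", mass = "amu"),
    bead_types = types,
    mass = ff$mass,
    lj = list(default_sigma = stats::median(ff$sigma),
              ring_sigma = ff$ring_sigma,
              ring_eps_scale = ff$ring_eps_scale,
              epsilon = eps_list,
              sigma_overrides = sig_over),
    bonded = ff$bonded,
    water = ff$water
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("CG force field (version", x$version, ")\n")
  cat("bead types:", paste(x$types, collapse = ", "),
      "- mass", x$mass, "amu each\n")
  cat("LJ sigma range:", min(x$sigma), "-", max(x$sigma), "nm;",
      "epsilon range:", min(x$eps), "-", max(x$eps), "kJ/mol\n")
  cat("chain bond r0", x$bonded$bond$r0, "nm, k", x$bonded$bond$k,
      "; angle theta0", x$bonded$angle$theta0, "deg, k", x$bonded$angle$k, "\n")
  invisible(x)
}
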