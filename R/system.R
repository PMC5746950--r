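#' System composition specifications and presets
#'
#' A `cg_sysspec` fixes the composition of one simulation: lipid and
#' surfactant molecule counts, P4/AF water bead counts, the initial cubic
#' box side, thermodynamic targets and the RNG seed. The named presets
#' `s1`-`s5` reproduce the compositions of the five reference study
#' systems (the benchmark systems this package models); `desk` is a reduced system (24 lipids in a thin water shell)
#' sized to self-assemble on a single CPU core.
#'
#' @param name One of `"s1"`, `"s2"`, `"s3"`, `"s4"`, `"s5"`, `"desk"`.
#' @param scale Fraction in (0, 1] multiplying all molecule counts
#'   (rounded); the box side scales with its cube root.
#' @param seed Integer seed controlling placement jitter, antifreeze
#'   assignment and initial velocities.
#' @return A `cg_sysspec` list.
#' @examples
#' preset_spec("s1")$n_lipid  # 64 tripalmitin molecules
#' @export
preset_spec <- function(name, scale = 1, seed = 1) {
  tab <- list(
    #        lipid surf  p4     af    box_nm
    s1   = c(64,   0,    4176,  462,  9.2),
    s2   = c(216,  0,    28003, 3143, 16.9),
    s3   = c(392,  0,    60210, 6627, 21.5),
    s4   = c(216,  3,    22268, 2420, 15.6),
    s5   = c(216,  221,  31826, 3518, 17.9),
    desk = c(24,   0,    1500,  150,  6.35)
  )
  name <- tolower(name)
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  v <- tab[[name]]
  system_spec(n_lipid = v[1], n_surfactant = v[2], n_p4 = v[3], n_af = v[4],
              box_side = v[5], seed = seed, scale = scale, name = name)
}

#' @param n_lipid,n_surfactant,n_p4,n_af Molecule/bead counts (>= 0).
#' @param box_side Initial cubic box side in nm (relaxed by the barostat).
#' @param temperature Target temperature in K.
#' @param pressure Target pressure in atm.
#' @rdname preset_spec
#' @export
system_spec <- function(n_lipid, n_surfactant = 0, n_p4 = 0, n_af = NULL,
                        box_side, temperature = 310, pressure = 1,
                        seed = 1, scale = 1, name = "custom") {
  if (is.null(n_af)) n_af <- water_composition(n_p4)$n_af
  counts <- c(n_lipid, n_surfactant, n_p4, n_af)
  if (any(counts < 0)) stop("all composition counts must be >= 0")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  if (scale < 1) {
    counts <- round(counts * scale)
    box_side <- box_side * scale^(1 / 3)
  }
  structure(list(
    name = name,
    n_lipid = as.integer(counts[1]),
    n_surfactant = as.integer(counts[2]),
    n_p4 = as.integer(counts[3]),
    n_af = as.integer(counts[4]),
    box_side = box_side,
    temperature = temperature,
    pressure = pressure,
    seed = as.integer(seed),
    scale = scale
  ), class = "cg_sysspec")
}

#' @export
print.cg_sysspec <- function(x, ...) {
  cat("CG system spec '", x$name, "' (scale ", x$scale, "): ",
      x$n_lipid, " lipids, ", x$n_surfactant, " surfactants, ",
      x$n_p4, " P4 + ", x$n_af, " AF water beads, box ",
      round(x$box_side, 2), " nm, ", x$temperature, " K, ",
      x$pressure, " atm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# centre and radius of a conformer
conformer_radius <- function(xyz) {
  ctr <- colMeans(xyz)
  max(sqrt(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Build a solvated starting configuration
#'
#' Places the solute molecules (tripalmitin, then Tween 20) on a cubic
#' lattice centred in the box, choosing the smallest lattice spacing for
#' which no intermolecular bead pair comes within 0.3 nm (minimum image),
#' then fills the remaining volume with a jittered lattice of water beads at
#' a liquid-like density, randomly interspersing antifreeze beads among the
#' P4 beads at the configured ratio. Initial velocities are drawn from the
#' Maxwell-Boltzmann distribution at the spec temperature (net momentum
#' removed, then rescaled to the exact target). The construction is fully
#' deterministic given `spec$seed`.
#'
#' If the solute array cannot fit in the spec box with one LJ cutoff of
#' clearance to its periodic image, the initial box is enlarged to the
#' smallest side that fits (the barostat subsequently relaxes the density).
#'
#' @param spec A `cg_sysspec` from [preset_spec()] or [system_spec()].
#' @param ff Force-field tables.
#' @return A `cg_system` state: positions (nm), velocities (nm/ps), cubic
#'   box side, per-bead species/type/ring/molecule indices and the global
#'   bonded-term and exclusion tables used by the engine.
#' @export
build_system <- function(spec, ff = load_forcefield()) {
  stopifnot(inherits(spec, "cg_sysspec"))
  set.seed(spec$seed)
  lip <- build_tripalmitin(ff)
  twn <- build_tween20(ff)
  n_mol_solute <- spec$n_lipid + spec$n_surfactant
  tops <- c(rep(list(lip), spec$n_lipid), rep(list(twn), spec$n_surfactant))

  box <- spec$box_side
  cutoff <- 1.4

  pos <- NULL
  mol_of_bead <- integer(0)
  if (n_mol_solute > 0) {
    rmax <- max(vapply(tops, function(t) conformer_radius(t$xyz), 0))
    k <- ceiling(n_mol_solute^(1 / 3))
    # seeded random orientations let neighbouring molecules interleave;
    # search for the smallest overlap-free lattice spacing, redrawing
    # orientations a few times before giving up
    spacing <- NA
    placed <- NULL
    last_cp <- NULL
    for (grow in 1:4) {
      for (draw in 1:5) {
        rots <- lapply(seq_len(n_mol_solute), function(i) random_rotation())
        for (s in seq(0.9, min(4, box / k), by = 0.05)) {
          trial <- place_on_lattice(tops, k, s, box, rots)
          cp <- cg_contact_pairs_cpp(trial$pos, box, 0.3, trial$mol)
          last_cp <- cp
          if (nrow(cp) == 0) { spacing <- s; placed <- trial; break }
        }
        if (!is.na(spacing)) break
      }
      if (!is.na(spacing)) break
      # dense compositions: random sequential insertion with overlap
      # rejection packs tighter than a rigid lattice
      placed <- try_random_insertion(tops, box, n_attempts = 400)
      if (!is.null(placed)) { spacing <- 0; break }
      box <- box * 1.1
      message("initial box enlarged to ", round(box, 2),
              " nm to accommodate the solute array")
    }
    if (is.na(spacing)) {
      stop("placement error: could not place molecule ",
           if (NROW(last_cp) > 0) last_cp[1, 2] else 1,
           " without bead overlaps below 0.3 nm")
    }
    # prefer a spacing that leaves one LJ cutoff of clearance between the
    # array and its periodic image when the box allows it; otherwise the
    # array is dispersed through the periodic box (overlap-checked above)
    pos <- placed$pos
    mol_of_bead <- placed$mol
  }

  # --- solvation -----------------------------------------------------------
  n_w <- spec$n_p4 + spec$n_af
  wpos <- NULL
  if (n_w > 0) {
    target_density <- 8.3   # water beads per nm^3, liquid-like at 1 atm
    m <- max(3, ceiling(box / (1 / target_density)^(1 / 3)))
    sites <- NULL
    for (attempt in 1:8) {
      ws <- box / m
      jit <- max(0, min(0.08, (ws - 0.31) / 2))
      g <- (seq_len(m) - 0.5) * ws
      sites <- as.matrix(expand.grid(x = g, y = g, z = g))
      sites <- sites + matrix(stats::runif(3 * nrow(sites), -jit, jit),
                              ncol = 3)
      if (!is.null(pos)) {
        blocked <- sites_near_beads(sites, pos, box, 0.5)
        sites <- sites[!blocked, , drop = FALSE]
      }
      if (nrow(sites) >= n_w) break
      m <- m + 1
    }
    if (nrow(sites) < n_w) {
      stop("placement error: water molecule ", nrow(sites) + 1,
           " cannot be placed; box too small for the requested composition")
    }
    keep <- sample(nrow(sites), n_w)
    wpos <- sites[keep, , drop = FALSE]
  }
  af_pick <- if (n_w > 0 && spec$n_af > 0) sample(n_w, spec$n_af) else integer(0)

  # --- assemble global arrays ---------------------------------------------
  species <- c(rep("TP", spec$n_lipid * nrow(lip$beads)),
               rep("TW", spec$n_surfactant * nrow(twn$beads)))
  type_chr <- unlist(lapply(tops, function(t) t$beads$bead_type))
  ring <- unlist(lapply(tops, function(t) t$beads$is_ring))
  bead_name <- unlist(lapply(tops, function(t) t$beads$name))
  if (n_w > 0) {
    wtype <- rep("P4", n_w)
    wtype[af_pick] <- "AF"
    wspecies <- ifelse(wtype == "AF", "AF", "P4")
    species <- c(species, wspecies)
    type_chr <- c(type_chr, wtype)
    ring <- c(ring, rep(FALSE, n_w))
    bead_name <- c(bead_name, ifelse(wtype == "AF", "WF", "W"))
    mol_of_bead <- c(mol_of_bead, n_mol_solute + seq_len(n_w))
    pos <- rbind(pos, wpos)
  }
  n <- nrow(pos)
  pos <- pos - box * floor(pos / box)   # wrap into [0, box)

  # global bonded terms from per-topology tables with bead offsets
  bonds <- angles <- NULL
  offset <- 0L
  for (t in tops) {
    nb <- nrow(t$beads)
    if (nrow(t$bonds) > 0) {
      b <- t$bonds
      b$i <- b$i + offset; b$j <- b$j + offset
      bonds <- rbind(bonds, b)
    }
    if (nrow(t$angles) > 0) {
      a <- t$angles
      a$i <- a$i + offset; a$j <- a$j + offset; a$k <- a$k + offset
      angles <- rbind(angles, a)
    }
    offset <- offset + nb
  }
  if (is.null(bonds)) bonds <- bond_df(integer(0), integer(0), numeric(0), numeric(0))
  if (is.null(angles)) {
    angles <- angle_df(integer(0), integer(0), integer(0), numeric(0), numeric(0))
  }
  excl <- build_exclusions(n, bonds)

  # Maxwell-Boltzmann velocities at the target temperature
  mass <- rep(.bead_mass, n)
  vel <- matrix(rnorm(3 * n), ncol = 3) * sqrt(.kB * spec$temperature / mass)
  vel <- sweep(vel, 2, colMeans(vel))           # remove net momentum
  ke <- 0.5 * sum(mass * rowSums(vel^2))
  vel <- vel * sqrt(1.5 * n * .kB * spec$temperature / ke)

  structure(list(
    pos = unname(pos), vel = unname(vel), box = box,
    species = species,
    type = match(type_chr, .bead_types),
    ring = as.integer(ring),
    mass = mass,
    mol = as.integer(mol_of_bead),
    bead_name = bead_name,
    n_mol = n_mol_solute + n_w,
    bonds = bonds, angles = angles,
    excl = excl,
    spec = spec, ff = ff
  ), class = "cg_system")
}

place_on_lattice <- function(tops, k, spacing, box, rots) {
  n_mol <- length(tops)
  grid <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k)))
  grid <- (grid[seq_len(n_mol), , drop = FALSE] - (k + 1) / 2) * spacing +
    box / 2
  pos <- NULL
  mol <- integer(0)
  for (i in seq_len(n_mol)) {
    xyz <- tops[[i]]$xyz
    xyz <- sweep(xyz, 2, colMeans(xyz))
    xyz <- xyz %*% t(rots[[i]])
    xyz <- sweep(xyz, 2, grid[i, ], "+")
    pos <- rbind(pos, xyz)
    mol <- c(mol, rep(i, nrow(xyz)))
  }
  out <- list(pos = pos - box * floor(pos / box), mol = mol)
  attr(out, "rots") <- rots
  out
}

# seeded random sequential insertion with overlap rejection; NULL when a
# molecule cannot be placed within the attempt budget
try_random_insertion <- function(tops, box, n_attempts = 400) {
  pos <- NULL
  mol <- integer(0)
  for (i in seq_along(tops)) {
    xyz0 <- sweep(tops[[i]]$xyz, 2, colMeans(tops[[i]]$xyz))
    done <- FALSE
    for (a in seq_len(n_attempts)) {
      xyz <- xyz0 %*% t(random_rotation())
      xyz <- sweep(xyz, 2, stats::runif(3, 0, box), "+")
      xyz <- xyz - box * floor(xyz / box)
      if (is.null(pos)) { pos <- xyz; mol <- rep(1L, nrow(xyz)); done <- TRUE; break }
      trial <- rbind(pos, xyz)
      tm <- c(mol, rep(i, nrow(xyz)))
      cp <- cg_contact_pairs_cpp(trial, box, 0.3, tm)
      if (nrow(cp) == 0) {
        pos <- trial; mol <- tm; done <- TRUE; break
      }
    }
    if (!done) return(NULL)
  }
  list(pos = pos, mol = mol)
}

# uniform random rotation matrix from a quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# TRUE for candidate sites with any bead of `pos` within `cutoff` (min image)
sites_near_beads <- function(sites, pos, box, cutoff) {
  nm <- nrow(pos)
  all_pos <- rbind(pos, sites)
  mol <- c(rep(1L, nm), 1L + seq_len(nrow(sites)))
  cp <- cg_contact_pairs_cpp(all_pos, box, cutoff, mol)
  blocked <- logical(nrow(sites))
  cp <- cp[cp[, 1] == 1L, , drop = FALSE]   # site-site pairs don't block
  if (nrow(cp) > 0) blocked[cp[, 2] - 1L] <- TRUE
  blocked
}

# 1-2 and 1-3 exclusion pairs in CSR form (0-based) for the C++ kernels
build_exclusions <- function(n, bonds) {
  if (nrow(bonds) == 0) {
    return(list(ptr = integer(n + 1), idx = integer(0)))
  }
  adj <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
  nb12_i <- c(bonds$i, bonds$j)
  nb12_j <- c(bonds$j, bonds$i)
  # 1-3: neighbours of neighbours
  nb13_i <- integer(0); nb13_j <- integer(0)
  for (key in names(adj)) {
    i <- as.integer(key)
    nn <- unique(unlist(adj[as.character(adj[[key]])], use.names = FALSE))
    nn <- setdiff(nn, i)
    if (length(nn) > 0) {
      nb13_i <- c(nb13_i, rep(i, length(nn)))
      nb13_j <- c(nb13_j, nn)
    }
  }
  ei <- c(nb12_i, nb13_i)
  ej <- c(nb12_j, nb13_j)
  keep <- !duplicated(paste(ei, ej))
  ei <- ei[keep]; ej <- ej[keep]
  o <- order(ei, ej)
  ei <- ei[o]; ej <- ej[o]
  cnt <- tabulate(ei, nbins = n)
  list(ptr = c(0L, cumsum(cnt)), idx = as.integer(ej - 1L))
}

#' @export
print.cg_system <- function(x, ...) {
  cat("CG system:", nrow(x$pos), "beads in a", round(x$box, 3),
      "nm cubic box\n")
  tt <- table(.bead_types[x$type])
  cat("types:", paste(names(tt), tt, collapse = ", "), "\n")
  cat(nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      x$n_mol, "molecules\n")
  invisible(x)
}
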