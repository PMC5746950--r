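#' Molecule topologies for the coarse-grained model
#'
#' A `cg_topology` holds the beads, bonded terms and reference coordinates of
#' one molecule species. Beads are rows of a data frame with `name`,
#' `bead_type` (one of C1, Na, P3, P4, AF), `mass` (always 72 amu) and
#' `is_ring` (fine-mapped ring bead). Bonds and angles carry their own
#' parameters so ring restraints and chain terms coexist in one table.
#'
#' @name cg_topology
#' @keywords internal
NULL

new_topology <- function(species_name, beads, bonds, angles, xyz) {
  top <- structure(list(
    species_name = species_name,
    beads = beads,
    bonds = bonds,
    angles = angles,
    xyz = xyz
  ), class = "cg_topology")
  check_topology(top)
  top
}

# Structural sanity: index ranges, connectivity, the fixed bead mass, and a
# self-overlap check on the reference conformer.
check_topology <- function(top) {
  n <- nrow(top$beads)
  stopifnot(all(top$beads$mass == .bead_mass),
            all(top$beads$bead_type %in% .bead_types))
  if (nrow(top$bonds) > 0) {
    idx <- c(top$bonds$i, top$bonds$j)
    if (any(idx < 1 | idx > n)) stop("bond index out of range")
  }
  if (nrow(top$angles) > 0) {
    idx <- c(top$angles$i, top$angles$j, top$angles$k)
    if (any(idx < 1 | idx > n)) stop("angle index out of range")
  }
  if (n > 1) {
    # connectivity over the bond graph
    adj <- vector("list", n)
    for (b in seq_len(nrow(top$bonds))) {
      i <- top$bonds$i[b]; j <- top$bonds$j[b]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    seen <- logical(n); queue <- 1L; seen[1] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen)) stop("bond graph of ", top$species_name, " is not connected")
    # nonbonded self-distances in the reference conformer
    d <- as.matrix(stats::dist(top$xyz))
    bonded <- matrix(FALSE, n, n)
    bonded[cbind(top$bonds$i, top$bonds$j)] <- TRUE
    bonded <- bonded | t(bonded)
    diag(d) <- Inf
    d[bonded] <- Inf
    if (min(d) < 0.3) {
      stop("reference conformer of ", top$species_name,
           " has a nonbonded self-distance below 0.3 nm (", round(min(d), 3), ")")
    }
  }
  invisible(top)
}

bead_df <- function(name, bead_type, is_ring = FALSE) {
  data.frame(name = name, bead_type = bead_type, mass = .bead_mass,
             is_ring = is_ring, stringsAsFactors = FALSE)
}

bond_df <- function(i, j, r0, k) {
  data.frame(i = as.integer(i), j = as.integer(j), r0 = r0, k = k)
}

angle_df <- function(i, j, k, theta0, ktheta) {
  data.frame(i = as.integer(i), j = as.integer(j), k = as.integer(k),
             theta0 = theta0, ktheta = ktheta)
}

# chain angles along an ordered bead path
chain_angles <- function(path, theta0, ktheta) {
  if (length(path) < 3) {
    return(angle_df(integer(0), integer(0), integer(0), numeric(0), numeric(0)))
  }
  n <- length(path)
  angle_df(path[1:(n - 2)], path[2:(n - 1)], path[3:n], theta0, ktheta)
}

normalize <- function(v) v / sqrt(sum(v^2))

#' Build the tripalmitin CG topology
#'
#' Tripalmitin (glycerol tripalmitate) maps to 19 beads: the three C16 alkyl
#' tails and the glycerol/headgroup linker become 16 apolar C1 beads and each
#' of the three ester groups becomes one intermediate-polarity Na bead. The
#' connectivity used here is three tails of four C1 beads, each joined
#' through an Na ester bead to a four-bead C1 linker region. The reference
#' conformer is deliberately compact (tails folded into squares) so that
#' molecules can be placed densely on a lattice; minimisation and dynamics
#' relax it.
#'
#' @param ff Force-field tables from [load_forcefield()] supplying bonded
#'   defaults.
#' @return A `cg_topology` with 19 beads (16 C1, 3 Na), each of mass 72 amu.
#' @examples
#' top <- build_tripalmitin(load_forcefield())
#' table(top$beads$bead_type)
#' @export
build_tripalmitin <- function(ff = load_forcefield()) {
  b0 <- ff$bonded$bond$r0; bk <- ff$bonded$bond$k
  a0 <- ff$bonded$angle$theta0; ak <- ff$bonded$angle$k

  beads <- rbind(
    bead_df(paste0("GL", 1:4), "C1"),
    bead_df(paste0("ES", 1:3), "Na"),
    bead_df(paste0("T", rep(1:3, each = 4), rep(c("A", "B", "C", "D"), 3)), "C1")
  )
  # indices: GL 1-4, ES 5-7, tails 8-11, 12-15, 16-19
  gl <- 1:4; es <- 5:7
  tails <- list(8:11, 12:15, 16:19)

  xyz <- matrix(0, 19, 3)
  xyz[gl, ] <- rbind(c(0, 0, 0), c(b0, 0, 0), c(b0, b0, 0), c(0, b0, 0))
  dirs <- list(normalize(c(-1, -1, -1)), normalize(c(1, -1, -1)),
               normalize(c(1, 1, -1)))
  bonds <- rbind(bond_df(1, 2, b0, bk), bond_df(2, 3, b0, bk),
                 bond_df(3, 4, b0, bk))
  angles <- rbind(chain_angles(c(1, 2, 3), a0, ak), chain_angles(c(2, 3, 4), a0, ak))
  for (t in 1:3) {
    d <- dirs[[t]]
    p <- normalize(c(d[2], -d[1], 0))      # tangential, perpendicular to d
    q <- c(d[2] * p[3] - d[3] * p[2],      # d x p, completes the frame
           d[3] * p[1] - d[1] * p[3],
           d[1] * p[2] - d[2] * p[1])
    xyz[es[t], ] <- xyz[gl[t], ] + b0 * d
    tb <- tails[[t]]
    # compactly folded tail: out, sideways, back, then out of plane
    xyz[tb[1], ] <- xyz[es[t], ] + b0 * d
    xyz[tb[2], ] <- xyz[tb[1], ] + b0 * p
    xyz[tb[3], ] <- xyz[tb[2], ] - b0 * d
    xyz[tb[4], ] <- xyz[tb[3], ] + b0 * q
    bonds <- rbind(bonds,
                   bond_df(gl[t], es[t], b0, bk),
                   bond_df(es[t], tb[1], b0, bk),
                   bond_df(tb[1], tb[2], b0, bk),
                   bond_df(tb[2], tb[3], b0, bk),
                   bond_df(tb[3], tb[4], b0, bk))
    angles <- rbind(angles,
                    chain_angles(c(gl[t], es[t], tb), a0, ak))
  }
  new_topology("tripalmitin", beads, bonds, angles, xyz)
}

#' Build the Tween 20 CG topology
#'
#' Tween 20 (polysorbate 20) maps to 30 beads: a sorbitan ring modelled at
#' higher resolution (one heavy atom plus hydrogens per bead, flagged
#' `is_ring` and held near-rigid by stiff bonds plus cross-ring distance
#' restraints), four polyoxyethylene arms of polar P3 beads, and one arm
#' terminated by an Na ester bead and a three-bead C1 lauryl tail.
#'
#' @inheritParams build_tripalmitin
#' @return A `cg_topology` with 30 beads using types P3, Na and C1 only;
#'   the five ring beads are flagged `is_ring`.
#' @examples
#' top <- build_tween20(load_forcefield())
#' sum(top$beads$is_ring)
#' @export
build_tween20 <- function(ff = load_forcefield()) {
  b0 <- ff$bonded$bond$r0; bk <- ff$bonded$bond$k
  a0 <- ff$bonded$angle$theta0; ak <- ff$bonded$angle$k
  r0_ring <- ff$bonded$ring_bond$r0; k_ring <- ff$bonded$ring_bond$k
  k_diag <- ff$bonded$ring_diagonal$k

  beads <- rbind(
    bead_df(paste0("R", 1:5), c("Na", "Na", "Na", "Na", "C1"), is_ring = TRUE),
    bead_df(paste0("B", 1:5), "P3"),
    bead_df(paste0("C", 1:5), "P3"),
    bead_df(paste0("D", 1:5), "P3"),
    bead_df(paste0("A", 1:6), "P3"),
    bead_df("AE", "Na"),
    bead_df(paste0("AT", 1:3), "C1")
  )
  ring <- 1:5
  arms <- list(6:10, 11:15, 16:20, 21:30)  # attached to R1..R4
  rp <- r0_ring / (2 * sin(pi / 5))        # circumradius of the pentagon
  diag_len <- 2 * rp * sin(2 * pi / 5)

  xyz <- matrix(0, 30, 3)
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  xyz[ring, ] <- cbind(rp * cos(ang), rp * sin(ang), 0)

  bonds <- NULL
  for (i in 1:5) {
    j <- if (i == 5) 1L else i + 1L
    bonds <- rbind(bonds, bond_df(i, j, r0_ring, k_ring))
  }
  # cross-ring restraints: the five pentagon diagonals
  for (i in 1:5) {
    j <- if (i >= 4) i - 3L else i + 2L
    if (i < j) bonds <- rbind(bonds, bond_df(i, j, diag_len, k_diag))
  }
  bonds <- rbind(bonds, bond_df(4, 1, diag_len, k_diag),
                 bond_df(5, 2, diag_len, k_diag))
  # keep each diagonal once
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  bonds <- bonds[!duplicated(key), ]

  angles <- angle_df(integer(0), integer(0), integer(0), numeric(0), numeric(0))
  for (a in 1:4) {
    u <- normalize(xyz[a, ])                 # radially outward in the ring plane
    tg <- normalize(c(-u[2], u[1], 0))       # tangent
    zh <- c(0, 0, 1)
    arm <- arms[[a]]
    # snake walk through a 2 x 2 x L grid: compact, bond lengths all b0,
    # nonbonded grid distances >= b0
    sq_even <- list(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    sq_odd <- rev(sq_even)
    for (s in seq_along(arm)) {
      lvl <- (s - 1) %/% 4
      w <- (s - 1) %% 4
      lat <- if (lvl %% 2 == 0) sq_even[[w + 1]] else sq_odd[[w + 1]]
      xyz[arm[s], ] <- xyz[a, ] + b0 * (lvl + 1) * u +
        b0 * lat[1] * tg + b0 * lat[2] * zh
    }
    path <- c(a, arm)
    for (s in 1:(length(path) - 1)) {
      bonds <- rbind(bonds, bond_df(path[s], path[s + 1], b0, bk))
    }
    angles <- rbind(angles, chain_angles(path, a0, ak))
  }
  new_topology("tween20", beads, bonds, angles, xyz)
}

#' Single-bead CG water topologies
#'
#' The CG water model is a two-component mixture: polar P4 beads, each
#' standing for four real water molecules, and antifreeze (AF) beads that
#' frustrate artificial crystallisation of the P4 lattice, at a default
#' ratio of one AF per ten P4.
#'
#' @inheritParams build_tripalmitin
#' @return A list with single-bead topologies `p4` and `af`.
#' @export
build_water <- function(ff = load_forcefield()) {
  empty_b <- bond_df(integer(0), integer(0), numeric(0), numeric(0))
  empty_a <- angle_df(integer(0), integer(0), integer(0), numeric(0), numeric(0))
  list(
    p4 = new_topology("water_p4", bead_df("W", "P4"), empty_b, empty_a,
                      matrix(0, 1, 3)),
    af = new_topology("water_af", bead_df("WF", "AF"), empty_b, empty_a,
                      matrix(0, 1, 3))
  )
}

#' CG water composition from a P4 bead count
#'
#' One P4 bead corresponds to four real water molecules and one antifreeze
#' bead is added for each ten P4 beads.
#'
#' @param n_p4 Number of P4 water beads (non-negative).
#' @return A list with `n_p4`, `n_af` and `n_real_waters`.
#' @examples
#' water_composition(100)  # 100 P4, 10 AF, 400 real waters
#' @export
water_composition <- function(n_p4) {
  if (length(n_p4) != 1 || is.na(n_p4) || n_p4 < 0) {
    stop("n_p4 must be a single non-negative count")
  }
  list(n_p4 = as.integer(n_p4),
       n_af = as.integer(round(n_p4 / 10)),
       n_real_waters = as.integer(4 * n_p4))
}

#' Total molecular mass of a topology
#' @param top A `cg_topology`.
#' @return Mass in amu.
#' @export
molecule_mass <- function(top) sum(top$beads$mass)

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology:", x$species_name, "-", nrow(x$beads), "beads (",
      paste(names(table(x$beads$bead_type)), table(x$beads$bead_type),
            collapse = ", "), ")\n")
  cat(nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      sum(x$beads$is_ring), "ring beads; mass", molecule_mass(x), "amu\n")
  invisible(x)
}

#' Export a topology as a GROMACS-dialect ITP file
#'
#' Writes `[moleculetype]`, `[atoms]`, `[bonds]` and `[angles]` sections.
#' Ring restraints are written as stiff bonds (the integrator treats them
#' the same way).
#'
#' @param top A `cg_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_itp <- function(top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("; ", top$species_name, " coarse-grain topology (lnpsim)")
  w("[ moleculetype ]")
  w("; name  nrexcl")
  w(top$species_name, "  2")
  w("")
  w("[ atoms ]")
  w(";  nr  type  resnr  residue  atom  cgnr  charge  mass")
  for (i in seq_len(nrow(top$beads))) {
    w(sprintf("%5d %5s %6d %8s %5s %5d %7.1f %7.1f",
              i, top$beads$bead_type[i], 1, toupper(substr(top$species_name, 1, 4)),
              top$beads$name[i], i, 0, top$beads$mass[i]))
  }
  w("")
  w("[ bonds ]")
  w(";   i    j  funct  length  force.c.")
  for (b in seq_len(nrow(top$bonds))) {
    w(sprintf("%5d %5d %6d %8.3f %9.1f",
              top$bonds$i[b], top$bonds$j[b], 1L, top$bonds$r0[b], top$bonds$k[b]))
  }
  if (nrow(top$angles) > 0) {
    w("")
    w("[ angles ]")
    w(";   i    j    k  funct  angle  force.c.")
    for (a in seq_len(nrow(top$angles))) {
      w(sprintf("%5d %5d %5d %6d %7.1f %9.1f",
                top$angles$i[a], top$angles$j[a], top$angles$k[a], 2L,
                top$angles$theta0[a], top$angles$ktheta[a]))
    }
  }
  invisible(path)
}
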