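#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of beads from their centre of
#' mass: `Rg^2 = sum_i m_i |r_i - r_cm|^2 / sum_i m_i`. The selection is
#' assumed unwrapped (made whole across periodic boundaries) - see
#' [make_whole()].
#'
#' @param pos N x 3 coordinate matrix (nm).
#' @param masses Optional bead masses (amu); equal masses by default.
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # dimer: d/2 = 0.5
#' @export
radius_of_gyration <- function(pos, masses = NULL) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 1) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(pos))
  com <- colSums(pos * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(pos, 2, com)^2)) / sum(masses))
}

#' Gyration-tensor shape analysis (asphericity)
#'
#' Diagonalises the mass-weighted gyration tensor; the principal radii
#' `R1 >= R2 >= R3` are the square roots of its eigenvalues and satisfy
#' `Rg^2 = R1^2 + R2^2 + R3^2`. The asphericity is
#' `Delta = (3/2) * sum_i (R_i - Rm)^2 / (R1 + R2 + R3)^2` with
#' `Rm = (R1 + R2 + R3)/3`; it lies in [0, 1], equalling 0 for a perfect
#' sphere (isotropic tensor) and 1 for a rod (collinear beads). Degenerate
#' (collinear or planar) inputs simply yield zero eigenvalues.
#'
#' @inheritParams radius_of_gyration
#' @return A `cg_shape` list: `rg`, `principal_radii` (descending),
#'   `delta`.
#' @examples
#' oct <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
#' asphericity(oct)$delta  # 0: isotropic
#' @export
asphericity <- function(pos, masses = NULL) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 1) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(pos))
  com <- colSums(pos * masses) / sum(masses)
  d <- sweep(pos, 2, com)
  gyr <- crossprod(d * masses, d) / sum(masses)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0  # numerical guard for degenerate configurations
  r <- sqrt(ev)
  rm_ <- mean(r)
  delta <- if (sum(r) > 0) 1.5 * sum((r - rm_)^2) / sum(r)^2 else 0
  structure(list(rg = sqrt(sum(ev)), principal_radii = r, delta = delta),
            class = "cg_shape")
}

#' @export
print.cg_shape <- function(x, ...) {
  cat(sprintf("Rg = %.4f nm; R1,R2,R3 = %.4f, %.4f, %.4f nm; Delta = %.3g\n",
              x$rg, x$principal_radii[1], x$principal_radii[2],
              x$principal_radii[3], x$delta))
  invisible(x)
}

#' Lipid number density of an aggregate
#'
#' `3 N / (4 pi Rg^3)`: the number of lipid molecules per unit volume of a
#' sphere whose radius is taken as the radius of gyration. Reported to two
#' decimals when `display = TRUE` (full precision otherwise).
#'
#' @param n_lipids Number of lipid molecules (>= 1).
#' @param rg Radius of gyration in nm (> 0).
#' @param display Round to two decimals for reporting.
#' @return Density in nm^-3.
#' @examples
#' lipid_number_density(64, 2.5)  # 0.98
#' @export
lipid_number_density <- function(n_lipids, rg, display = TRUE) {
  if (any(rg <= 0)) stop("rg must be positive")
  if (any(n_lipids < 1)) stop("n_lipids must be >= 1")
  dens <- 3 * n_lipids / (4 * pi * rg^3)
  if (display) round(dens, 2) else dens
}

#' Detect molecular aggregates by contact clustering
#'
#' Two molecules are connected when any intermolecular bead pair lies
#' within `contact_cutoff` under the minimum-image convention; aggregates
#' are the connected components of that contact graph.
#'
#' @param state A `cg_system`.
#' @param contact_cutoff Contact distance in nm (default 0.6, just above
#'   the regular bead sigma).
#' @param species Species codes included in the clustering (default: the
#'   solute species TP and TW).
#' @return A list: `membership` (cluster id per included molecule, named by
#'   molecule id), `sizes`, `largest_size`, `n_clusters` and
#'   `all_lipids_in_largest`.
#' @export
detect_aggregates <- function(state, contact_cutoff = 0.6,
                              species = c("TP", "TW")) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  sel <- state$species %in% species
  mols <- sort(unique(state$mol[sel]))
  if (length(mols) == 0) {
    return(list(membership = integer(0), sizes = integer(0),
                largest_size = 0L, n_clusters = 0L,
                all_lipids_in_largest = NA))
  }
  cp <- cg_contact_pairs_cpp(state$pos[sel, , drop = FALSE], state$box,
                             contact_cutoff, state$mol[sel])
  g <- igraph::make_empty_graph(n = length(mols), directed = FALSE)
  if (nrow(cp) > 0) {
    e <- rbind(match(cp[, 1], mols), match(cp[, 2], mols))
    g <- igraph::add_edges(g, as.vector(e))
  }
  comp <- igraph::components(g)
  membership <- setNames(comp$membership, mols)
  lipid_mols <- unique(state$mol[state$species == "TP"])
  largest <- which.max(comp$csize)
  list(membership = membership,
       sizes = as.integer(comp$csize),
       largest_size = as.integer(max(comp$csize)),
       n_clusters = comp$no,
       all_lipids_in_largest =
         if (length(lipid_mols) > 0) {
           all(membership[as.character(lipid_mols)] == largest)
         } else NA)
}

#' Unwrap molecules and aggregates across periodic boundaries
#'
#' Makes each selected molecule whole by walking its bond graph from a
#' reference bead and applying minimum-image displacements, then makes the
#' aggregate whole by walking the molecule contact graph and shifting
#' molecules by whole box lengths so contacting pairs are adjacent. Shape
#' observables assume such unwrapped coordinates.
#'
#' @param state A `cg_system`.
#' @param species Species codes to unwrap (solutes by default).
#' @param contact_cutoff Contact distance (nm) for the aggregate graph.
#' @return A copy of `state` whose `pos` holds unwrapped coordinates for
#'   the selected beads.
#' @export
make_whole <- function(state, species = c("TP", "TW"), contact_cutoff = 0.6) {
  pos <- state$pos
  box <- state$box
  sel <- state$species %in% species
  if (!any(sel)) return(state)
  mols <- sort(unique(state$mol[sel]))
  # molecule-internal unwrap over the bond graph
  badj <- split(c(state$bonds$j, state$bonds$i), c(state$bonds$i, state$bonds$j))
  for (m in mols) {
    beads <- which(state$mol == m)
    seen <- setNames(logical(length(beads)), beads)
    queue <- beads[1]; seen[as.character(beads[1])] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in badj[[as.character(v)]]) {
        if (!isTRUE(seen[as.character(w)])) {
          seen[as.character(w)] <- TRUE
          d <- pos[w, ] - pos[v, ]
          pos[w, ] <- pos[v, ] + (d - box * round(d / box))
          queue <- c(queue, w)
        }
      }
    }
  }
  # aggregate-level unwrap: walk the molecule contact graph breadth-first
  # and shift each molecule by whole box lengths so its centre of mass sits
  # at the minimum image of the running aggregate centre of mass. Anchoring
  # to the aggregate COM (rather than chaining pairwise shifts) keeps the
  # reconstruction compact even when the aggregate transiently touches its
  # own periodic image.
  cp <- cg_contact_pairs_cpp(state$pos[sel, , drop = FALSE], box,
                             contact_cutoff, state$mol[sel])
  if (nrow(cp) > 0) {
    adj <- vector("list", length(mols))
    names(adj) <- mols
    for (r in seq_len(nrow(cp))) {
      a <- as.character(cp[r, 1]); b <- as.character(cp[r, 2])
      adj[[a]] <- c(adj[[a]], cp[r, 2])
      adj[[b]] <- c(adj[[b]], cp[r, 1])
    }
    beads_of <- split(seq_along(state$mol), state$mol)
    mol_com <- function(m) colMeans(pos[beads_of[[as.character(m)]], ,
                                        drop = FALSE])
    placed <- setNames(logical(length(mols)), mols)
    for (root in as.character(mols)) {
      if (placed[root]) next
      placed[root] <- TRUE
      acc_com <- mol_com(root)
      n_placed <- 1
      queue <- root
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        for (w in as.character(adj[[v]])) {
          if (placed[w]) next
          placed[w] <- TRUE
          shift <- -box * round((mol_com(w) - acc_com) / box)
          wb <- beads_of[[w]]
          pos[wb, ] <- sweep(pos[wb, , drop = FALSE], 2, shift, "+")
          acc_com <- (acc_com * n_placed + mol_com(w)) / (n_placed + 1)
          n_placed <- n_placed + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  state$pos <- pos
  state
}

#' Classify interior water beads
#'
#' Voxelises the periodic box, blocks voxels within one bead radius of any
#' lipid bead, and flood-fills the unblocked space (periodic
#' 6-connectivity) to mark the exterior, seeding from the unblocked voxel
#' farthest from the aggregate's centre of mass so the classification is
#' invariant under translation of the whole system; water beads in
#' unreached voxels are interior. Deterministic given the voxel size.
#'
#' @param state A `cg_system`.
#' @param voxel Voxel edge in nm (must be positive and at most box/4).
#' @param r_block Blocking radius around lipid beads in nm (default: the
#'   regular bead sigma, 0.47).
#' @return A `cg_waterpartition` list: `inside` (logical per water bead),
#'   `water_index` (bead indices), `n_inside`, `n_outside`,
#'   `n_p4_inside`, `n_af_inside`.
#' @export
classify_interior_water <- function(state, voxel = 0.35, r_block = 0.47) {
  if (voxel <= 0 || voxel > state$box / 4) {
    stop("voxel size must be positive and at most box/4")
  }
  lipid <- state$species == "TP"
  water <- state$species %in% c("P4", "AF")
  r <- cg_interior_cpp(state$pos[lipid, , drop = FALSE],
                       state$pos[water, , drop = FALSE],
                       state$box, voxel, r_block)
  inside <- as.logical(r$inside)
  wtypes <- .bead_types[state$type[water]]
  structure(list(
    inside = inside,
    water_index = which(water),
    n_inside = sum(inside),
    n_outside = sum(!inside),
    n_p4_inside = sum(inside & wtypes == "P4"),
    n_af_inside = sum(inside & wtypes == "AF"),
    voxel = r$voxel_actual
  ), class = "cg_waterpartition")
}

#' Track interior/exterior water exchange events
#'
#' Scans per-frame interior labels and emits one event per persistent
#' inside/outside flip: a label change only counts when the new label
#' persists for at least `debounce` frames; shorter excursions are
#' suppressed.
#'
#' @param labels Logical matrix, frames x beads, TRUE = inside. (Build it
#'   by applying [classify_interior_water()] per frame.)
#' @param debounce Minimum persistence in frames (>= 1).
#' @return A data frame of events with columns `bead` (column index),
#'   `frame` (first frame of the new persistent state) and `direction`
#'   (`"in"` or `"out"`).
#' @export
track_exchange_events <- function(labels, debounce = 2) {
  if (debounce < 1) stop("debounce must be >= 1")
  labels <- as.matrix(labels)
  out <- NULL
  for (b in seq_len(ncol(labels))) {
    r <- rle(labels[, b])
    frame <- cumsum(c(1, head(r$lengths, -1)))
    persistent <- r$lengths >= debounce
    if (!any(persistent)) next
    runs <- which(persistent)
    cur <- r$values[runs[1]]
    for (k in runs[-1]) {
      if (r$values[k] != cur) {
        out <- rbind(out, data.frame(
          bead = b, frame = frame[k],
          direction = if (r$values[k]) "in" else "out"))
        cur <- r$values[k]
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(bead = integer(0), frame = integer(0),
                      direction = character(0))
  }
  out
}

# latitude-band partition of the sphere into n equal-area patches;
# returns patch index for unit direction vectors
equal_area_patch <- function(dirs, n_patches) {
  n_bands <- max(1, round(sqrt(n_patches)))
  base <- n_patches %/% n_bands
  m <- rep(base, n_bands)
  extra <- n_patches - sum(m)
  if (extra > 0) {
    mid <- order(abs(seq_len(n_bands) - (n_bands + 1) / 2))
    m[mid[seq_len(extra)]] <- m[mid[seq_len(extra)]] + 1
  }
  zb <- 1 - 2 * cumsum(c(0, m)) / n_patches   # z boundaries, 1 .. -1
  z <- pmin(pmax(dirs[, 3], -1), 1)
  band <- findInterval(-z, -zb, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1), n_bands)
  phi <- atan2(dirs[, 2], dirs[, 1]) + pi      # [0, 2pi)
  sector <- pmin(floor(phi / (2 * pi) * m[band]), m[band] - 1)
  offset <- cumsum(c(0, m))[band]
  as.integer(offset + sector + 1)
}

#' Surfactant surface-coverage map
#'
#' Bins surfactant beads within a radial shell around the aggregate's
#' centre of mass into equal-area angular patches (latitude-band
#' partition). Summarises coverage as the fraction of patches holding at
#' least one bead and the coefficient of variation of patch counts (the
#' inhomogeneity measure).
#'
#' @param state A `cg_system` (unwrap first with [make_whole()] for
#'   assembled aggregates).
#' @param n_patches Number of equal-area patches.
#' @param shell Radial tolerance in nm: surfactant beads within
#'   `surface radius + shell` of the centre of mass are counted. The
#'   surface radius is the 95th percentile of lipid-bead radial distances;
#'   with no lipids present all surfactant beads are used.
#' @return A `cg_coverage` list: `counts` per patch, `covered_fraction`,
#'   `cv`, `n_in_shell`.
#' @export
surface_coverage <- function(state, n_patches = 32, shell = 1.0) {
  surf <- state$species == "TW"
  if (!any(surf)) {
    return(structure(list(counts = rep(0L, n_patches), covered_fraction = 0,
                          cv = NA_real_, n_in_shell = 0L, empty = TRUE),
                     class = "cg_coverage"))
  }
  lipid <- state$species == "TP"
  ref <- if (any(lipid)) state$pos[lipid, , drop = FALSE] else
    state$pos[surf, , drop = FALSE]
  com <- colMeans(ref)
  spos <- sweep(state$pos[surf, , drop = FALSE], 2, com)
  rad <- sqrt(rowSums(spos^2))
  if (any(lipid)) {
    lrad <- sqrt(rowSums(sweep(state$pos[lipid, , drop = FALSE], 2, com)^2))
    rsurf <- stats::quantile(lrad, 0.95, names = FALSE)
    keep <- rad <= rsurf + shell
  } else {
    keep <- rep(TRUE, length(rad))
  }
  spos <- spos[keep & rad > 0, , drop = FALSE]
  counts <- rep(0L, n_patches)
  if (nrow(spos) > 0) {
    dirs <- spos / sqrt(rowSums(spos^2))
    p <- equal_area_patch(dirs, n_patches)
    tab <- tabulate(p, nbins = n_patches)
    counts <- as.integer(tab)
  }
  structure(list(
    counts = counts,
    covered_fraction = mean(counts > 0),
    cv = if (mean(counts) > 0) sd(counts) / mean(counts) else NA_real_,
    n_in_shell = sum(counts),
    empty = FALSE
  ), class = "cg_coverage")
}

#' Core versus total radius of gyration
#'
#' Rg over lipid beads only (`rg_core`) and over lipid plus surfactant
#' beads (`rg_total`). With surfactant adsorbed peripherally the total
#' exceeds the core; with no surfactant the two are identical.
#'
#' @param state A `cg_system` (unwrapped; see [make_whole()]).
#' @return A list with `rg_core` and `rg_total` (nm).
#' @export
core_vs_total_rg <- function(state) {
  lipid <- state$species == "TP"
  both <- state$species %in% c("TP", "TW")
  list(
    rg_core = radius_of_gyration(state$pos[lipid, , drop = FALSE],
                                 state$mass[lipid]),
    rg_total = radius_of_gyration(state$pos[both, , drop = FALSE],
                                  state$mass[both])
  )
}
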