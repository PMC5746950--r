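# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's computational paths: the LJ oracle
# is a plain-R all-pairs evaluation, clustering uses a hand-rolled
# union-find, and shape fixtures are constructed analytically.

# all-pairs switched-LJ energy/forces oracle (no neighbour list)
brute_lj <- function(st, ff, ron = 1.0, rc = 1.4) {
  n <- nrow(st$pos)
  f <- matrix(0, n, 3)
  E <- 0
  swf <- function(r2) {
    A <- rc^2 - r2
    B <- rc^2 + 2 * r2 - 3 * ron^2
    A^2 * B / (rc^2 - ron^2)^3
  }
  dswdr <- function(r2) {
    12 * sqrt(r2) * (rc^2 - r2) * (ron^2 - r2) / (rc^2 - ron^2)^3
  }
  excl <- matrix(FALSE, n, n)
  if (nrow(st$bonds) > 0) {
    adj <- vector("list", n)
    for (b in seq_len(nrow(st$bonds))) {
      i <- st$bonds$i[b]; j <- st$bonds$j[b]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    for (i in 1:n) {
      nb <- adj[[i]]
      nn <- unique(unlist(adj[nb]))
      for (j in setdiff(c(nb, nn), i)) excl[i, j] <- TRUE
    }
  }
  types <- c("C1", "Na", "P3", "P4", "AF")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (excl[i, j]) next
      d <- st$pos[i, ] - st$pos[j, ]
      d <- d - st$box * round(d / st$box)
      r2 <- sum(d^2)
      if (r2 >= rc^2) next
      ti <- types[st$type[i]]; tj <- types[st$type[j]]
      if (st$ring[i] && st$ring[j]) {
        s <- ff$ring_sigma; e <- ff$eps[ti, tj] * ff$ring_eps_scale
      } else {
        s <- ff$sigma[ti, tj]; e <- ff$eps[ti, tj]
      }
      r <- sqrt(r2)
      sr6 <- (s / r)^6
      V <- 4 * e * (sr6^2 - sr6)
      dV <- 4 * e * (-12 * sr6^2 + 6 * sr6) / r
      if (r2 > ron^2) {
        Ft <- -(dV * swf(r2) + V * dswdr(r2))
        E <- E + V * swf(r2)
      } else {
        Ft <- -dV
        E <- E + V
      }
      fv <- Ft * d / r
      f[i, ] <- f[i, ] + fv
      f[j, ] <- f[j, ] - fv
    }
  }
  list(E = E, f = f)
}

# brute-force union-find over molecule contacts (min image)
brute_clusters <- function(pos, mol, box, cutoff) {
  mols <- sort(unique(mol))
  parent <- seq_along(mols)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mol[i] == mol[j]) next
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) < cutoff^2) {
        a <- find(match(mol[i], mols)); b <- find(match(mol[j], mols))
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_along(mols), find, 0L)
  match(roots, unique(roots))
}

# a small water-only state whose type/ring fields tests can overwrite
random_bead_state <- function(n, box, seed, ff = load_forcefield()) {
  st <- build_system(system_spec(0, 0, n_p4 = n, n_af = 0, box_side = box,
                                 seed = seed), ff)
  st
}

# hollow lipid shell of radius r_shell (dense Fibonacci covering) with
# k interior and m exterior water beads at known radii
hollow_sphere_state <- function(r_shell = 2, k_inside = 7, n_outside = 30,
                                box = 8, bead_spacing = 0.2,
                                ff = load_forcefield()) {
  n_shell <- ceiling(4 * pi * r_shell^2 / bead_spacing^2 * 1.3)
  i <- seq_len(n_shell)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / n_shell
  r <- sqrt(1 - z^2)
  shell <- cbind(r * cos(golden * i), r * sin(golden * i), z) * r_shell
  set.seed(99)
  inside <- matrix(stats::runif(3 * k_inside, -0.5, 0.5), ncol = 3)
  u <- matrix(stats::rnorm(3 * n_outside), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  outside <- u * stats::runif(n_outside, r_shell + 1.3, box / 2 - 0.3)
  ctr <- box / 2
  pos <- rbind(shell, inside, outside) + ctr
  n <- nrow(pos)
  st <- structure(list(
    pos = pos, vel = matrix(0, n, 3), box = box,
    species = c(rep("TP", n_shell), rep("P4", k_inside + n_outside)),
    type = c(rep(1L, n_shell), rep(4L, k_inside + n_outside)),
    ring = rep(0L, n), mass = rep(72, n),
    mol = seq_len(n), bead_name = rep("X", n), n_mol = n,
    bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                       k = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), ktheta = numeric(0)),
    excl = list(ptr = integer(n + 1), idx = integer(0)),
    spec = system_spec(0, 0, 0, 0, box_side = box), ff = ff
  ), class = "cg_system")
  attr(st, "k_inside") <- k_inside
  st
}

# minimal bare state from raw positions (no bonded terms)
bare_state <- function(pos, box, species = NULL, type = NULL,
                       mol = NULL, ff = load_forcefield()) {
  n <- nrow(pos)
  if (is.null(species)) species <- rep("TP", n)
  if (is.null(type)) type <- rep(1L, n)
  if (is.null(mol)) mol <- seq_len(n)
  structure(list(
    pos = pos, vel = matrix(0, n, 3), box = box,
    species = species, type = type, ring = rep(0L, n),
    mass = rep(72, n), mol = as.integer(mol),
    bead_name = rep("X", n), n_mol = length(unique(mol)),
    bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                       k = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), ktheta = numeric(0)),
    excl = list(ptr = integer(n + 1), idx = integer(0)),
    spec = system_spec(0, 0, 0, 0, box_side = box), ff = ff
  ), class = "cg_system")
}

# uniform points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(1 - z^2)
  cbind(r * cos(golden * i), r * sin(golden * i), z) * radius
}
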