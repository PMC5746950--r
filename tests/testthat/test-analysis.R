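ff <- load_forcefield()

test_that("radius of gyration matches analytic values", {
  expect_equal(radius_of_gyration(matrix(c(3, 1, 2), 1)), 0)
  # symmetric dimer: half the separation
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0.8, 0, 0))), 0.4)
  # mass weighting: an infinitely heavy partner pulls Rg towards it
  expect_lt(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)),
                               masses = c(1000, 1)), 0.1)
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("asphericity hits its analytic limits", {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(asphericity(oct)$delta, 0, tolerance = 1e-12)
  for (n in c(3, 5, 12)) {
    rod <- cbind(seq_len(n), 0, 0)
    expect_equal(asphericity(rod)$delta, 1, tolerance = 1e-12)
  }
  # planar square: R3 = 0, delta = 1/4 analytically
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(asphericity(sq)$delta, 0.25, tolerance = 1e-12)
})

test_that("Rg^2 equals the sum of squared principal radii and delta is invariant", {
  set.seed(53)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    pos <- matrix(stats::rnorm(3 * n), ncol = 3)
    m <- stats::runif(n, 0.5, 2)
    shp <- asphericity(pos, m)
    expect_equal(shp$rg^2, sum(shp$principal_radii^2), tolerance = 1e-9)
    expect_equal(shp$rg, radius_of_gyration(pos, m), tolerance = 1e-9)
    expect_gte(shp$delta, 0)
    expect_lte(shp$delta, 1)
    # independent oracle: dense outer-product tensor construction
    com <- colSums(pos * m) / sum(m)
    gyr <- matrix(0, 3, 3)
    for (i in 1:n) {
      d <- pos[i, ] - com
      gyr <- gyr + m[i] * outer(d, d)
    }
    gyr <- gyr / sum(m)
    r <- sqrt(pmax(sort(eigen(gyr)$values, decreasing = TRUE), 0))
    d_oracle <- 1.5 * sum((r - mean(r))^2) / sum(r)^2
    expect_equal(shp$delta, d_oracle, tolerance = 1e-9)
    # invariance under rotation, translation, uniform scaling
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    pos2 <- 2.5 * pos %*% q + matrix(stats::rnorm(3), n, 3, byrow = TRUE)
    expect_equal(asphericity(pos2, m)$delta, shp$delta, tolerance = 1e-8)
  }
})

test_that("lipid number density follows its closed form", {
  expect_equal(lipid_number_density(1, 1, display = FALSE), 3 / (4 * pi),
               tolerance = 1e-12)
  expect_equal(lipid_number_density(1, 1), 0.24)
  expect_error(lipid_number_density(10, 0), "positive")
  expect_error(lipid_number_density(0, 1), ">= 1")
})

test_that("aggregate detection matches brute-force union-find", {
  set.seed(61)
  for (rep in 1:12) {
    n_mol <- 20
    box <- 6
    centers <- matrix(stats::runif(3 * n_mol, 0, box), ncol = 3)
    pos <- NULL; mol <- integer(0)
    for (m in 1:n_mol) {
      nb <- sample(2:4, 1)
      pos <- rbind(pos, sweep(matrix(stats::rnorm(3 * nb, sd = 0.2), ncol = 3),
                              2, centers[m, ], "+") %% box)
      mol <- c(mol, rep(m, nb))
    }
    st <- bare_state(pos, box, mol = mol)
    got <- detect_aggregates(st, contact_cutoff = 0.6)
    want <- brute_clusters(pos, mol, box, 0.6)
    # same partition up to label permutation
    expect_equal(length(unique(want)), got$n_clusters)
    relabel <- function(x) match(x, unique(x))
    expect_equal(relabel(unname(got$membership)), relabel(want))
  }
})

test_that("isolated molecules each form their own cluster", {
  pos <- rbind(c(1, 1, 1), c(4, 1, 1), c(1, 4, 1), c(4, 4, 4))
  st <- bare_state(pos, box = 9, mol = 1:4)
  got <- detect_aggregates(st, contact_cutoff = 0.6)
  expect_equal(got$n_clusters, 4L)
  expect_equal(got$largest_size, 1L)
})

test_that("interior-water flood fill recovers exact counts on hollow spheres", {
  for (k in c(4, 7, 12)) {
    st <- hollow_sphere_state(r_shell = 2, k_inside = k, n_outside = 25)
    for (vox in c(0.2, 0.3, 0.35, 0.5)) {
      wp <- classify_interior_water(st, voxel = vox)
      expect_equal(wp$n_inside, k, info = paste("voxel", vox))
      expect_equal(wp$n_inside + wp$n_outside, k + 25)
      expect_equal(wp$n_p4_inside, k)
    }
  }
  st <- hollow_sphere_state()
  expect_error(classify_interior_water(st, voxel = 0), "voxel")
  expect_error(classify_interior_water(st, voxel = 3), "voxel")
})

test_that("interior counts are invariant under whole-system translation", {
  st <- hollow_sphere_state(k_inside = 9)
  wp0 <- classify_interior_water(st)
  for (shift in list(c(1.7, 0, 0), c(2.3, 3.1, 0.9))) {
    st2 <- st
    st2$pos <- sweep(st$pos, 2, shift, "+") %% st$box
    wp <- classify_interior_water(st2)
    expect_equal(wp$n_inside, wp0$n_inside)
  }
})

test_that("exchange events respect the debounce window", {
  # constant labels: no events
  lab <- matrix(TRUE, nrow = 10, ncol = 3)
  expect_equal(nrow(track_exchange_events(lab, 2)), 0)
  # in,in,out,out,out with debounce 2: one outbound event at frame 3
  lab <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE), ncol = 1)
  ev <- track_exchange_events(lab, 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 3)
  expect_equal(ev$direction, "out")
  # a 1-frame excursion is suppressed at debounce 2 but counted at 1
  lab <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), ncol = 1)
  expect_equal(nrow(track_exchange_events(lab, 2)), 0)
  expect_equal(nrow(track_exchange_events(lab, 1)), 2)
  expect_error(track_exchange_events(lab, 0), "debounce")
})

test_that("coverage maps distinguish uniform from hemispherical surfactant", {
  set.seed(71)
  full <- fibonacci_sphere(640, radius = 3) + 5
  st <- bare_state(full, box = 10, species = rep("TW", 640))
  cov <- surface_coverage(st, n_patches = 32, shell = 1)
  expect_equal(cov$covered_fraction, 1)
  expect_lt(cov$cv, 0.5)
  expect_equal(sum(cov$counts), 640)
  # hemisphere over a lipid core (the core anchors the aggregate COM at
  # the sphere centre): at most half the patches plus discretisation slack
  core <- fibonacci_sphere(200, radius = 2.6) + 5
  hemi <- fibonacci_sphere(800, radius = 3)
  hemi <- hemi[hemi[, 3] > 0.05, ] + 5
  st2 <- bare_state(rbind(core, hemi), box = 10,
                    species = c(rep("TP", 200), rep("TW", nrow(hemi))))
  cov2 <- surface_coverage(st2, n_patches = 32, shell = 1)
  expect_lte(cov2$covered_fraction, 0.5 + 0.2)
  expect_gt(cov2$cv, cov$cv)
  # no surfactant: flagged empty result, not an error
  st3 <- bare_state(matrix(stats::runif(9, 0, 5), 3), box = 5,
                    species = rep("TP", 3))
  cov3 <- surface_coverage(st3)
  expect_true(cov3$empty)
  expect_equal(cov3$covered_fraction, 0)
})

test_that("core and total Rg separate a shelled construction", {
  core <- fibonacci_sphere(200, radius = 2) + 6
  shell <- fibonacci_sphere(100, radius = 3.5) + 6
  st <- bare_state(rbind(core, shell), box = 12,
                   species = c(rep("TP", 200), rep("TW", 100)))
  ct <- core_vs_total_rg(st)
  expect_gt(ct$rg_total, ct$rg_core)
  # identical selections coincide when no surfactant is present
  st2 <- bare_state(core, box = 12, species = rep("TP", 200))
  ct2 <- core_vs_total_rg(st2)
  expect_equal(ct2$rg_core, ct2$rg_total)
})

test_that("make_whole reassembles a cluster split across the boundary", {
  # two touching molecules straddling the periodic wall
  box <- 5
  m1 <- rbind(c(4.8, 2, 2), c(4.95, 2, 2))
  m2 <- rbind(c(0.15, 2, 2), c(0.4, 2, 2))
  st <- bare_state(rbind(m1, m2), box = box, mol = c(1, 1, 2, 2))
  whole <- make_whole(st)
  rg <- radius_of_gyration(whole$pos)
  expect_lt(rg, 0.5)   # wrapped coordinates would give ~2.3
})
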