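ff <- load_forcefield()

test_that("presets reproduce the study compositions exactly", {
  tab <- list(
    s1 = c(64, 0, 4176, 462),
    s2 = c(216, 0, 28003, 3143),
    s3 = c(392, 0, 60210, 6627),
    s4 = c(216, 3, 22268, 2420),
    s5 = c(216, 221, 31826, 3518)
  )
  box <- c(s1 = 9.2, s2 = 16.9, s3 = 21.5, s4 = 15.6, s5 = 17.9)
  for (nm in names(tab)) {
    sp <- preset_spec(nm)
    expect_equal(c(sp$n_lipid, sp$n_surfactant, sp$n_p4, sp$n_af),
                 as.integer(tab[[nm]]), info = nm)
    expect_equal(sp$box_side, box[[nm]], info = nm)
  }
  expect_error(preset_spec("s9"), "unknown preset")
  expect_error(system_spec(-1, 0, 0, 0, box_side = 5), ">= 0")
})

test_that("scaling multiplies counts and shrinks the box by the cube root", {
  sp <- preset_spec("s1", scale = 0.25)
  expect_equal(sp$n_lipid, 16L)
  expect_equal(sp$n_p4, round(4176 * 0.25))
  expect_equal(sp$box_side, 9.2 * 0.25^(1 / 3))
})

test_that("built systems have no bead pair closer than 0.3 nm (min image)", {
  for (seed in c(1, 7)) {
    st <- build_system(preset_spec("s1", scale = 0.1, seed = seed), ff)
    # brute-force minimum-image check over all bead pairs
    n <- nrow(st$pos)
    dmin <- Inf
    for (ax in 1:3) {
      d <- abs(outer(st$pos[, ax], st$pos[, ax], "-"))
      d <- pmin(d, st$box - d)
      dmin2 <- if (ax == 1) d^2 else dmin2 + d^2
    }
    diag(dmin2) <- Inf
    # bonded pairs may sit closer than nonbonded ones but never below 0.3
    expect_gte(sqrt(min(dmin2)), 0.3)
  }
})

test_that("composition, bead counts and types match the spec", {
  sp <- preset_spec("s4", scale = 0.1, seed = 3)
  st <- build_system(sp, ff)
  expect_equal(nrow(st$pos), sp$n_lipid * 19 + sp$n_surfactant * 30 +
                 sp$n_p4 + sp$n_af)
  expect_equal(sum(st$species == "AF"), sp$n_af)
  expect_equal(sum(st$species == "P4"), sp$n_p4)
  expect_true(all(st$mass == 72))
  expect_true(all(st$pos >= 0 & st$pos < st$box))
  expect_true(all(is.finite(st$vel)))
})

test_that("identical spec and seed give a bit-identical initial state", {
  a <- build_system(preset_spec("desk", seed = 5), ff)
  b <- build_system(preset_spec("desk", seed = 5), ff)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  expect_identical(a$type, b$type)
  c <- build_system(preset_spec("desk", seed = 6), ff)
  expect_false(identical(a$pos, c$pos))
})

test_that("solvent density is isotropic across octants", {
  st <- build_system(preset_spec("s1", scale = 0.25, seed = 2), ff)
  w <- st$species %in% c("P4", "AF")
  oct <- 1 + (st$pos[w, 1] > st$box / 2) + 2 * (st$pos[w, 2] > st$box / 2) +
    4 * (st$pos[w, 3] > st$box / 2)
  counts <- tabulate(oct, nbins = 8)
  expect_true(all(abs(counts / mean(counts) - 1) < 0.05 + 3 / sqrt(mean(counts))))
})

test_that("initial velocities sample Maxwell-Boltzmann at the target temperature", {
  st <- build_system(preset_spec("s1", scale = 0.25, seed = 4), ff)
  ke <- 0.5 * sum(st$mass * rowSums(st$vel^2))
  temp <- 2 * ke / (3 * nrow(st$pos) * 0.0083144621)
  expect_equal(temp, 310, tolerance = 1e-6)
})
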