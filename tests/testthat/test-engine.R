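ff <- load_forcefield()

test_that("pair energies follow the switched 12-6 form at landmark distances", {
  mk <- function(r) bare_state(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box = 5)
  # zero crossing at r = sigma
  expect_equal(compute_energy_forces(mk(0.47))$report$lj, 0, tolerance = 1e-12)
  # minimum depth -eps at 2^(1/6) sigma (inside the unswitched region)
  expect_equal(compute_energy_forces(mk(2^(1 / 6) * 0.47))$report$lj,
               -ff$eps["C1", "C1"], tolerance = 1e-9)
  # exactly zero energy and force beyond the cutoff
  r15 <- compute_energy_forces(mk(1.5))
  expect_identical(r15$report$lj, 0)
  expect_identical(max(abs(r15$forces)), 0)
  # continuous at the switch onset
  eps_r <- 1e-9
  e_lo <- compute_energy_forces(mk(1.0 - eps_r))$report$lj
  e_hi <- compute_energy_forces(mk(1.0 + eps_r))$report$lj
  expect_equal(e_lo, e_hi, tolerance = 1e-6)
})

test_that("neighbour-list forces match the all-pairs oracle on random systems", {
  set.seed(31)
  worst_f <- 0
  worst_e <- 0
  for (rep in 1:100) {
    n <- sample(20:50, 1)
    box <- stats::runif(1, 3.2, 6)
    st <- random_bead_state(n, box, seed = 1000 + rep, ff)
    st$type <- sample(1:5, n, replace = TRUE)
    st$ring <- as.integer(stats::runif(n) < 0.2)
    got <- compute_energy_forces(st)
    want <- brute_lj(st, ff)
    scale <- max(1, max(abs(want$f)))
    worst_f <- max(worst_f, max(abs(got$forces - want$f)) / scale)
    worst_e <- max(worst_e, abs(got$report$lj - want$E) / max(1, abs(want$E)))
  }
  expect_lt(worst_f, 1e-9)
  expect_lt(worst_e, 1e-9)
})

test_that("forces are the exact negative gradient of the potential", {
  # finite-difference check including bonds, angles and ring terms
  st <- build_system(system_spec(1, 1, n_p4 = 20, n_af = 2, box_side = 6,
                                 seed = 13), ff)
  r <- compute_energy_forces(st)
  h <- 1e-6
  idx <- c(1, 5, 20, 25, 40, 60)  # beads across lipid, tween ring, water
  for (i in idx) {
    for (k in 1:3) {
      sp <- st; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- st; sm$pos[i, k] <- sm$pos[i, k] - h
      ep <- lnpsim:::potential_energy(sp, run_config())$energy
      em <- lnpsim:::potential_energy(sm, run_config())$energy
      expect_equal(-(ep - em) / (2 * h), r$forces[i, k], tolerance = 1e-4)
    }
  }
})

test_that("energy terms are translation invariant and forces sum to zero", {
  st <- build_system(system_spec(2, 0, n_p4 = 60, n_af = 6, box_side = 5,
                                 seed = 17), ff)
  r <- compute_energy_forces(st)
  expect_lt(max(abs(colSums(r$forces))), 1e-9 * max(1, max(abs(r$forces))))
  e1 <- r$report
  st2 <- st
  st2$pos <- (st2$pos + 1.7319) %% st2$box
  e2 <- compute_energy_forces(st2)$report
  for (term in c("bond", "angle", "lj")) {
    expect_equal(e1[[term]], e2[[term]], tolerance = 1e-9)
  }
  # report total is the sum of its parts
  expect_equal(e1$total, e1$bond + e1$angle + e1$lj + e1$kinetic,
               tolerance = 1e-12)
  expect_gte(e1$instantaneous_temperature, 0)
})

test_that("an isolated pair at the LJ minimum is a fixed point of NVE stepping", {
  st <- bare_state(rbind(c(2, 2, 2), c(2 + 2^(1 / 6) * 0.47, 2, 2)), box = 6)
  cfg <- run_config(n_steps = 1, thermostat_gamma = 0, barostat = FALSE,
                    output_stride = 0, energy_stride = 0)
  out <- step_langevin(st, cfg)
  expect_equal(out$pos, st$pos, tolerance = 1e-12)
})

test_that("NVE total energy drifts less than 0.5% of mean kinetic energy over 1e4 steps", {
  spec <- system_spec(3, 0, n_p4 = 209, n_af = 21, box_side = 3.4, seed = 23)
  st <- build_system(spec, ff)
  st <- minimize_energy(st, max_steps = 300, tol = 50)
  warm <- run_simulation(st, run_config(n_steps = 1000, seed = 23,
                                        barostat = FALSE, output_stride = 0,
                                        energy_stride = 0))
  tr <- run_simulation(warm$state,
                       run_config(n_steps = 10000, thermostat_gamma = 0,
                                  barostat = FALSE, output_stride = 0,
                                  energy_stride = 100))
  s <- tr$series
  drift <- abs(s$total[nrow(s)] - s$total[1])
  expect_lt(drift, 0.005 * mean(s$kinetic))
})

test_that("the Langevin thermostat holds bulk water at 310 K within 2%", {
  spec <- system_spec(0, 0, n_p4 = 480, n_af = 48, box_side = 4.0, seed = 29)
  st <- build_system(spec, ff)
  st <- minimize_energy(st, max_steps = 250, tol = 100)
  tr <- run_simulation(st, run_config(n_steps = 20000, thermostat_gamma = 1,
                                      barostat = FALSE, seed = 29,
                                      output_stride = 0, energy_stride = 50))
  temps <- tr$series$temperature
  tbar <- mean(temps[-(1:80)])  # discard the equilibration transient
  expect_lt(abs(tbar - 310) / 310, 0.02)
})

test_that("the barostat keeps a bulk water box stable with no monotonic drift", {
  spec <- system_spec(0, 0, n_p4 = 480, n_af = 48, box_side = 4.0, seed = 37)
  st <- build_system(spec, ff)
  st <- minimize_energy(st, max_steps = 250, tol = 100)
  warm <- run_simulation(st, run_config(n_steps = 5000, seed = 37,
                                        output_stride = 0, energy_stride = 0))
  tr <- run_simulation(warm$state,
                       run_config(n_steps = 25000, seed = 38,
                                  output_stride = 0, energy_stride = 100))
  b <- tr$series$box
  half <- b[(length(b) %/% 2):length(b)]
  # final-half box series is flat: no monotonic trend
  fit <- coef(lm(half ~ seq_along(half)))[2]
  expect_lt(abs(fit * length(half)), 0.05 * mean(half))
  # density settles near liquid-like values
  dens <- (480 + 48) / tail(b, 1)^3
  expect_gt(dens, 7)
  expect_lt(dens, 10)
})

test_that("two-body minimisation lands on the analytic LJ minimum", {
  st <- bare_state(rbind(c(2, 2, 2), c(2.2, 2, 2)), box = 6)
  out <- minimize_energy(st, max_steps = 5000, tol = 0.5)
  sep <- sqrt(sum((out$pos[1, ] - out$pos[2, ])^2))
  expect_equal(sep, 2^(1 / 6) * 0.47, tolerance = 0.02 * 2^(1 / 6) * 0.47)
})

test_that("minimisation is a fixed point on an already-minimised state and conserves beads", {
  spec <- system_spec(2, 0, n_p4 = 100, n_af = 10, box_side = 4, seed = 41)
  st <- build_system(spec, ff)
  n0 <- nrow(st$pos)
  m1 <- minimize_energy(st, max_steps = 3000, tol = 40)
  expect_true(attr(m1, "converged"))
  e1 <- lnpsim:::potential_energy(m1, run_config())$energy
  m2 <- minimize_energy(m1, max_steps = 300, tol = 40)
  e2 <- lnpsim:::potential_energy(m2, run_config())$energy
  expect_lte(e2, e1 + 1e-9)
  expect_equal(e2, e1, tolerance = 1e-3)
  expect_equal(nrow(m2$pos), n0)
})

test_that("identical state, config and seed reproduce a bit-identical trajectory", {
  spec <- system_spec(1, 0, n_p4 = 60, n_af = 6, box_side = 4, seed = 43)
  st <- build_system(spec, ff)
  st <- minimize_energy(st, max_steps = 300, tol = 100)
  cfg <- run_config(n_steps = 500, seed = 99, output_stride = 100,
                    energy_stride = 100)
  a <- run_simulation(st, cfg)
  b <- run_simulation(st, cfg)
  expect_identical(a$state$pos, b$state$pos)
  expect_identical(a$series, b$series)
})

test_that("an empty run returns exactly the initial frame", {
  st <- bare_state(rbind(c(1, 1, 1), c(2, 2, 2)), box = 5)
  tr <- run_simulation(st, run_config(n_steps = 0, output_stride = 10))
  expect_length(tr$frames, 1)
  expect_equal(tr$frames[[1]], st$pos)
  expect_equal(tr$frame_time, 0)
})

test_that("coincident beads raise an integration-hazard error naming the pair", {
  st <- bare_state(rbind(c(1, 1, 1), c(1, 1, 1)), box = 5)
  expect_error(compute_energy_forces(st), "non-finite force.*1-2")
  expect_error(minimize_energy(st), "minimization failure")
})
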