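ff <- load_forcefield()

# a deliberately tiny, short experiment: exercises the full pipeline
# (build, minimise, dynamics, equilibrium window, observables, report)
tiny_preset <- function(seed) {
  experiment_preset("s1", scale = 0.05, seed = seed, n_steps = 4000,
                    output_stride = 500)
}

test_that("the experiment pipeline emits a complete report at small scale", {
  rep <- run_experiment(tiny_preset(11), ff = ff)
  expect_s3_class(rep, "cg_report")
  expect_true(is.logical(rep$assembled))
  expect_true(is.finite(rep$rg$mean))
  expect_true(is.finite(rep$delta$mean))
  expect_true(is.finite(rep$density$mean))
  expect_gte(rep$delta$mean, 0)
  expect_lte(rep$delta$mean, 1)
  expect_true(rep$n_frames_analyzed >= 2)
  # every reported average names its frame window
  expect_length(rep$frame_window, 2)
  expect_equal(rep$n_frames_analyzed,
               rep$frame_window[2] - rep$frame_window[1] + 1)
  expect_true(is.finite(rep$water$n_p4_inside))
})

test_that("experiments are reproducible: same seed, identical report", {
  a <- run_experiment(tiny_preset(19), ff = ff)
  b <- run_experiment(tiny_preset(19), ff = ff)
  expect_identical(a$rg, b$rg)
  expect_identical(a$delta, b$delta)
  expect_identical(a$box, b$box)
  expect_identical(a$water, b$water)
})

test_that("report averages recompute identically from the stored trajectory", {
  preset <- tiny_preset(23)
  state <- build_system(preset$spec, ff)
  state <- minimize_energy(state, max_steps = 400, tol = 50,
                           config = preset$config)
  traj <- run_simulation(state, preset$config)
  r1 <- analyze_trajectory(traj, preset)
  r2 <- analyze_trajectory(traj, preset)
  expect_identical(r1$rg, r2$rg)
  expect_identical(r1$density, r2$density)
})

test_that("run_experiment writes a JSON report and trajectory artifacts", {
  out <- tempfile("exp")
  rep <- run_experiment(tiny_preset(27), out_dir = out, ff = ff)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "energy.tsv")))
  expect_true(file.exists(file.path(out, "final.gro")))
  j <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(j$rg$mean, rep$rg$mean, tolerance = 1e-9)
  # XYZ trajectory round-trips
  xyz <- read_xyz(file.path(out, "trajectory.xyz"))
  expect_equal(length(xyz$frames), 9)  # initial + 4000/500
  expect_true(all(is.finite(xyz$frames[[1]])))
})
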