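#' MD run configuration
#'
#' Collects the integrator and interaction settings. Defaults follow the
#' study conditions: a 20 fs time step, Langevin thermostat at 310 K with
#' friction 1 ps^-1, pressure coupling to 1 atm, and Lennard-Jones
#' interactions truncated at 1.4 nm with a C1-continuous switching function
#' starting at 1.0 nm.
#'
#' @param dt Time step in fs.
#' @param n_steps Number of integration steps.
#' @param thermostat_gamma Langevin friction in ps^-1 (0 gives NVE velocity
#'   Verlet exactly).
#' @param target_T Thermostat target in K.
#' @param target_P Barostat target in atm.
#' @param barostat Logical; isotropic weak-coupling pressure control.
#' @param lj_cutoff LJ truncation radius in nm.
#' @param lj_switch_start Switching-function onset in nm (< `lj_cutoff`).
#' @param neighbor_skin Verlet-list skin in nm.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   before integration so runs are reproducible.
#' @param output_stride Steps between stored trajectory frames (0 = only
#'   the initial frame).
#' @param energy_stride Steps between energy/box log rows.
#' @param tau_p Barostat coupling time in ps.
#' @param compressibility Barostat compressibility parameter in atm^-1.
#' @return A `cg_runconfig` list.
#' @export
run_config <- function(dt = 20, n_steps = 1000, thermostat_gamma = 1,
                       target_T = 310, target_P = 1, barostat = TRUE,
                       lj_cutoff = 1.4, lj_switch_start = 1.0,
                       neighbor_skin = 0.15, seed = NULL,
                       output_stride = 5000, energy_stride = 500,
                       tau_p = 2, compressibility = 4.5e-5) {
  if (dt <= 0) stop("dt must be positive")
  if (lj_switch_start >= lj_cutoff) {
    stop("lj_switch_start must be smaller than lj_cutoff")
  }
  if (neighbor_skin <= 0) stop("neighbor_skin must be positive")
  structure(list(
    dt = dt, n_steps = as.integer(n_steps),
    thermostat_gamma = thermostat_gamma,
    target_T = target_T, target_P = target_P, barostat = barostat,
    lj_cutoff = lj_cutoff, lj_switch_start = lj_switch_start,
    neighbor_skin = neighbor_skin, seed = seed,
    output_stride = as.integer(output_stride),
    energy_stride = as.integer(energy_stride),
    tau_p = tau_p, compressibility = compressibility
  ), class = "cg_runconfig")
}

# arguments shared by every C++ entry point
engine_args <- function(state, config) {
  list(
    type = state$type - 1L, ring = state$ring, mass = state$mass,
    sigma = state$ff$sigma, eps = state$ff$eps,
    ring_sigma = state$ff$ring_sigma, ring_eps_scale = state$ff$ring_eps_scale,
    r_on = config$lj_switch_start, r_cut = config$lj_cutoff,
    bonds = cbind(state$bonds$i - 1L, state$bonds$j - 1L),
    bond_r0 = state$bonds$r0, bond_k = state$bonds$k,
    angles = cbind(state$angles$i - 1L, state$angles$j - 1L,
                   state$angles$k - 1L),
    angle_cos0 = cos(state$angles$theta0 * pi / 180),
    angle_k = state$angles$ktheta,
    excl_ptr = state$excl$ptr, excl_idx = state$excl$idx
  )
}

#' Energies and forces for a configuration
#'
#' Evaluates the full CG potential (switched 12-6 Lennard-Jones with
#' minimum-image convention and 1-2/1-3 bonded exclusions, harmonic bonds,
#' cosine-harmonic angles) and returns the forces together with an energy
#' report. Forces are the exact negative gradient of the implemented
#' potential.
#'
#' @param state A `cg_system`.
#' @param config A `cg_runconfig` (supplies cutoff/switch radii).
#' @return A list with `forces` (N x 3, kJ mol^-1 nm^-1) and `report`:
#'   `bond`, `angle`, `lj`, `kinetic`, `total` energies (kJ/mol),
#'   `instantaneous_temperature` (K) and `instantaneous_pressure` (atm).
#' @export
compute_energy_forces <- function(state, config = run_config()) {
  a <- engine_args(state, config)
  r <- cg_forces_cpp(state$pos, state$box, a$type, a$ring, a$sigma, a$eps,
                     a$ring_sigma, a$ring_eps_scale, a$r_on, a$r_cut,
                     a$bonds, a$bond_r0, a$bond_k,
                     a$angles, a$angle_cos0, a$angle_k,
                     a$excl_ptr, a$excl_idx)
  n <- nrow(state$pos)
  ke <- 0.5 * sum(state$mass * rowSums(state$vel^2))
  vol <- state$box^3
  report <- list(
    bond = r$bond, angle = r$angle, lj = r$lj, kinetic = ke,
    total = r$bond + r$angle + r$lj + ke,
    instantaneous_temperature = 2 * ke / (3 * n * .kB),
    instantaneous_pressure = (2 * ke + r$virial) / (3 * vol) * .press_atm,
    virial = r$virial
  )
  list(forces = r$forces, report = report)
}

potential_energy <- function(state, config) {
  a <- engine_args(state, config)
  r <- cg_forces_cpp(state$pos, state$box, a$type, a$ring, a$sigma, a$eps,
                     a$ring_sigma, a$ring_eps_scale, a$r_on, a$r_cut,
                     a$bonds, a$bond_r0, a$bond_k,
                     a$angles, a$angle_cos0, a$angle_k,
                     a$excl_ptr, a$excl_idx)
  list(energy = r$bond + r$angle + r$lj, forces = r$forces)
}

#' Steepest-descent energy minimisation
#'
#' Normalised steepest descent with step-size backtracking: the move is the
#' force direction scaled so the largest per-component displacement equals
#' the current trust step, which grows on accepted moves and halves on
#' rejected ones. Robust on hard-overlap starting configurations, for which
#' gradient magnitudes span many orders. Deterministic given its inputs.
#'
#' @param state A `cg_system`.
#' @param max_steps Iteration cap.
#' @param tol Convergence threshold on the largest force component
#'   (kJ mol^-1 nm^-1).
#' @param config Run configuration (cutoff/switch radii).
#' @return The minimised `cg_system` (velocities untouched), with
#'   attributes `converged`, `f_max` and `n_iter`.
#' @export
minimize_energy <- function(state, max_steps = 1000, tol = 10,
                            config = run_config()) {
  cur <- tryCatch(potential_energy(state, config),
                  error = function(e) list(energy = NaN))
  if (!is.finite(cur$energy)) {
    stop("minimization failure: non-finite energy at input ",
         "(overlapping beads beyond recovery)")
  }
  pos <- state$pos
  box <- state$box
  alpha <- 0.02   # nm, max per-component displacement
  iter <- 0L
  fmax <- max(abs(cur$forces))
  while (iter < max_steps && fmax >= tol) {
    iter <- iter + 1L
    step <- cur$forces * (alpha / fmax)
    trial <- state
    trial$pos <- pos + step
    trial$pos <- trial$pos - box * floor(trial$pos / box)
    nxt <- tryCatch(potential_energy(trial, config),
                    error = function(e) list(energy = Inf))
    if (is.finite(nxt$energy) && nxt$energy < cur$energy) {
      pos <- trial$pos
      cur <- nxt
      fmax <- max(abs(cur$forces))
      alpha <- min(alpha * 1.2, 0.05)
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
  }
  state$pos <- pos
  attr(state, "converged") <- fmax < tol
  attr(state, "f_max") <- fmax
  attr(state, "n_iter") <- iter
  state
}

#' Advance one Langevin velocity-Verlet step
#'
#' A single BAOAB step: half kick, half drift, Ornstein-Uhlenbeck velocity
#' refresh satisfying fluctuation-dissipation at `target_T`, half drift,
#' half kick. With `thermostat_gamma = 0` this is exactly one NVE
#' velocity-Verlet step.
#'
#' @param state A `cg_system`.
#' @param config A `cg_runconfig`.
#' @return The advanced `cg_system`.
#' @export
step_langevin <- function(state, config = run_config()) {
  cfg <- config
  cfg$n_steps <- 1L
  cfg$barostat <- FALSE
  cfg$output_stride <- 0L
  cfg$energy_stride <- 0L
  traj <- run_simulation(state, cfg)
  traj$state
}

#' Run a CG molecular dynamics simulation
#'
#' Integrates `config$n_steps` steps of Langevin dynamics under periodic
#' boundary conditions, with optional isotropic weak-coupling pressure
#' control, storing trajectory frames every `output_stride` steps (nominal
#' time = step x dt) and an energy/temperature/pressure/box series every
#' `energy_stride` steps.
#'
#' @param state A `cg_system`.
#' @param config A `cg_runconfig`.
#' @param out_dir Optional directory: writes `energy.tsv`, a final `.gro`
#'   configuration and an XYZ trajectory.
#' @return A `cg_trajectory`: `frames` (list of N x 3 matrices),
#'   `frame_time` (ps), `frame_box` (nm), `series` (data frame), and
#'   `state`, the final `cg_system`.
#' @export
run_simulation <- function(state, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(state, "cg_system"), inherits(config, "cg_runconfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  a <- engine_args(state, config)
  dt_ps <- config$dt / 1000
  res <- cg_run_cpp(state$pos, state$vel, state$box,
                    a$type, a$ring, a$mass, a$sigma, a$eps,
                    a$ring_sigma, a$ring_eps_scale,
                    a$r_on, a$r_cut, config$neighbor_skin,
                    a$bonds, a$bond_r0, a$bond_k,
                    a$angles, a$angle_cos0, a$angle_k,
                    a$excl_ptr, a$excl_idx,
                    dt_ps, config$n_steps, config$thermostat_gamma,
                    config$target_T, config$barostat, config$target_P,
                    config$tau_p, config$compressibility,
                    config$output_stride, config$energy_stride)
  final <- state
  final$pos <- res$pos
  final$vel <- res$vel
  final$box <- res$box
  traj <- structure(list(
    frames = res$frames,
    frame_time = res$frame_time,
    frame_box = res$frame_box,
    series = res$series,
    state = final,
    config = config
  ), class = "cg_trajectory")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(traj$series, file.path(out_dir, "energy.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_gro(final, file.path(out_dir, "final.gro"))
    write_xyz(traj, file.path(out_dir, "trajectory.xyz"))
  }
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nt <- length(x$frames)
  cat("CG trajectory:", nt, "frames over",
      round(max(x$frame_time) / 1000, 3), "ns nominal time,",
      nrow(x$state$pos), "beads\n")
  if (nrow(x$series) > 1) {
    last <- tail(x$series, 1)
    cat(sprintf("final: T = %.1f K, P = %.0f atm, box = %.3f nm, E = %.1f kJ/mol\n",
                last$temperature, last$pressure, last$box, last$total))
  }
  invisible(x)
}
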