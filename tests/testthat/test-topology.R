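ff <- load_forcefield()

test_that("tripalmitin maps to 19 beads: 16 C1, 3 Na, all 72 amu", {
  top <- build_tripalmitin(ff)
  expect_equal(nrow(top$beads), 19)
  expect_equal(sum(top$beads$bead_type == "C1"), 16)
  expect_equal(sum(top$beads$bead_type == "Na"), 3)
  expect_true(all(top$beads$mass == 72))
  expect_equal(molecule_mass(top), 19 * 72)
  expect_false(any(top$beads$is_ring))
})

test_that("Tween 20 maps to 30 beads of types P3/Na/C1 with a flagged ring", {
  top <- build_tween20(ff)
  expect_equal(nrow(top$beads), 30)
  expect_true(all(top$beads$bead_type %in% c("P3", "Na", "C1")))
  expect_true(all(top$beads$mass == 72))
  expect_equal(sum(top$beads$is_ring), 5)
  # ring held by stiff bonds plus cross-ring restraints
  ring_idx <- which(top$beads$is_ring)
  ring_bonds <- top$bonds$i %in% ring_idx & top$bonds$j %in% ring_idx
  expect_gte(sum(ring_bonds), 10)  # 5 edges + 5 diagonals
})

test_that("topology constructors are deterministic and graphs acyclic outside the ring", {
  a <- build_tripalmitin(ff)
  b <- build_tripalmitin(ff)
  expect_identical(a, b)
  expect_identical(build_tween20(ff), build_tween20(ff))
  # tripalmitin bond graph is a tree: n-1 edges, connected (checked on build)
  expect_equal(nrow(a$bonds), nrow(a$beads) - 1)
  # tween non-ring subgraph is a forest hanging off the ring
  tw <- build_tween20(ff)
  ring_idx <- which(tw$beads$is_ring)
  outside <- !(tw$bonds$i %in% ring_idx & tw$bonds$j %in% ring_idx)
  expect_equal(sum(outside), nrow(tw$beads) - length(ring_idx))
})

test_that("water composition follows the 4:1 and 10:1 mapping rules", {
  expect_equal(water_composition(100), list(n_p4 = 100L, n_af = 10L,
                                            n_real_waters = 400L))
  expect_equal(water_composition(0), list(n_p4 = 0L, n_af = 0L,
                                          n_real_waters = 0L))
  expect_equal(water_composition(4176)$n_af, 418L)
  expect_equal(water_composition(4176)$n_real_waters, 16704L)
  expect_error(water_composition(-1), "non-negative")
})

test_that("topologies export to ITP and molecules to GRO/PDB", {
  top <- build_tripalmitin(ff)
  itp <- tempfile(fileext = ".itp")
  write_itp(top, itp)
  txt <- readLines(itp)
  expect_true(any(grepl("moleculetype", txt)))
  expect_equal(sum(grepl("^\\s*\\d+\\s+(C1|Na|P3|P4|AF)", txt)), 19)

  st <- build_system(system_spec(1, 0, 0, 0, box_side = 6, seed = 1), ff)
  gro <- tempfile(fileext = ".gro")
  write_gro(st, gro)
  back <- read_gro(gro)
  expect_equal(back$pos, unname(st$pos), tolerance = 1e-3)
  expect_equal(back$box, st$box, tolerance = 1e-4)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(st, pdb)
  expect_true(file.exists(pdb))
  rb <- bio3d::read.pdb(pdb)
  expect_equal(nrow(rb$atom), 19)
})

test_that("tween ring geometry survives solvated dynamics at 310 K", {
  spec <- system_spec(0, 1, n_p4 = 290, n_af = 29, box_side = 3.6, seed = 21)
  st <- build_system(spec, ff)
  st <- minimize_energy(st, max_steps = 200, tol = 100)
  cfg <- run_config(n_steps = 10000, seed = 21, barostat = FALSE,
                    output_stride = 0, energy_stride = 0)
  out <- run_simulation(st, cfg)$state
  tw <- build_tween20(ff)
  ring_idx <- which(tw$beads$is_ring)
  rb <- tw$bonds[tw$bonds$i %in% ring_idx & tw$bonds$j %in% ring_idx, ]
  d <- sqrt(rowSums((out$pos[rb$i, ] - out$pos[rb$j, ])^2))
  rel_dev <- abs(d - rb$r0) / rb$r0
  expect_lt(mean(rel_dev), 0.05)
})
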