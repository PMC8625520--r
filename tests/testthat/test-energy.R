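test_that("the binding-energy combination reproduces hand substitution", {
  zero <- c(E_pot1 = 0, E_pot2 = 0, E_sol1 = 0, E_sol2 = 0,
            E_pot_comp = 0, E_sol_comp = 0)
  expect_equal(binding_energy(zero), 0)
  expect_equal(binding_energy(c(E_pot1 = -100, E_pot2 = -50, E_sol1 = -20,
                                E_sol2 = -10, E_pot_comp = -180,
                                E_sol_comp = -40)), 40)
  ## non-interacting limit: complex terms equal the sums of the parts
  expect_equal(binding_energy(c(E_pot1 = -7, E_pot2 = 3, E_sol1 = 11,
                                E_sol2 = 2, E_pot_comp = -4,
                                E_sol_comp = 13)), 0)
  expect_error(binding_energy(c(E_pot1 = 1)), class = "mf_domain_error")
  expect_error(binding_energy(c(E_pot1 = Inf, E_pot2 = 0, E_sol1 = 0,
                                E_sol2 = 0, E_pot_comp = 0, E_sol_comp = 0)),
               class = "mf_domain_error")
})

test_that("null backend gives identically zero components and binding energy", {
  pc <- make_planted_complex(seed = 3)
  comp <- compute_components(pc$system, backend = null_backend())
  expect_true(all(comp == 0))
  expect_equal(binding_energy(comp), 0)
})

test_that("reference backend matches closed forms for a pair at the minimum", {
  ## two carbons in different residues exactly at the pair minimum distance
  sys <- tiny_system(c("CB", "CB"), c("ALA", "ALA"), c("C", "C"),
                     c("receptor", "ligand"), c(1, 1),
                     rbind(c(0, 0, 0), c(3.82, 0, 0)))
  sys <- assign_charges(sys)
  be <- reference_backend()
  e <- be$potential_energy(sys, 1:2, 1)
  expect_equal(e, -0.36, tolerance = 1e-12)
})

test_that("reference backend Coulomb term matches hand arithmetic", {
  ## +1 sodium and -1 chloride at 10 Angstrom, dielectric 4r:
  ## coulomb = 1389.35 * (+1)(-1) / (4 * 10^2); LJ added in closed form
  sys <- tiny_system(c("NA", "CL"), c("NA", "CL"), c("NA", "CL"),
                     c("ion", "ion"), c(1, 2),
                     rbind(c(0, 0, 0), c(10, 0, 0)))
  sys <- assign_charges(sys)
  be <- reference_backend()
  coul <- 1389.35 * (1 * -1) / (4 * 10^2)
  rmin <- 1.37 + 2.27
  lj <- sqrt(0.36 * 0.42) * ((rmin / 10)^12 - 2 * (rmin / 10)^6)
  expect_equal(be$potential_energy(sys, 1:2, 1), coul + lj,
               tolerance = 1e-12)
})

test_that("solvation of isolated atoms is proportional to their sphere area", {
  be <- reference_backend(gamma = 0.025)
  one <- function(el, r) {
    sys <- tiny_system("X", "ALA", el, "receptor", 1,
                       rbind(c(1, 2, 3)))
    got <- be$solvation_energy(sys, 1, 1)
    expect_equal(got, 0.025 * 4 * pi * (r + 1.4)^2, tolerance = 1e-9)
  }
  one("C", 1.70)
  one("O", 1.52)
  one("N", 1.55)
})

test_that("far-separated neutral species bind with energy zero", {
  sys <- tiny_system(c("CB", "C8"), c("ALA", "NAG"), c("C", "C"),
                     c("receptor", "ligand"), c(1, 1),
                     rbind(c(0, 0, 0), c(1e6, 0, 0)))
  sys <- assign_charges(sys)
  comp <- compute_components(sys, backend = reference_backend())
  expect_lt(abs(binding_energy(comp)), 1e-9)
})

test_that("a planted salt bridge has positive binding energy", {
  sys <- assign_charges(plant_ionic_system())
  comp <- compute_components(sys, backend = reference_backend())
  expect_gt(binding_energy(comp), 0)
})

test_that("components are invariant under rigid motion of the whole complex", {
  sys <- assign_charges(plant_ionic_system())
  be <- reference_backend()
  c0 <- compute_components(sys, backend = be)
  ## translation: exact (pair distances and surface points shift together)
  shifted <- sys
  shifted$xyz[, , 1] <- sweep(sys$xyz[, , 1], 2, c(5, -3, 11), `+`)
  expect_equal(compute_components(shifted, backend = be), c0,
               tolerance = 1e-9)
  ## rotation: potential exact; solvation to surface-sampling resolution
  R <- mdfinger:::random_rotation(c(0.21, 0.73, 0.4))
  rotated <- sys
  rotated$xyz[, , 1] <- sys$xyz[, , 1] %*% t(R)
  c1 <- compute_components(rotated, backend = be)
  expect_equal(c1[c("E_pot1", "E_pot2", "E_pot_comp")],
               c0[c("E_pot1", "E_pot2", "E_pot_comp")], tolerance = 1e-9)
  expect_equal(c1[c("E_sol1", "E_sol2", "E_sol_comp")],
               c0[c("E_sol1", "E_sol2", "E_sol_comp")], tolerance = 0.01)
})

test_that("windowed statistics drop the leading 40% and use population SD", {
  tr <- structure(data.frame(frame = 1:5, time = 0:4,
                             E_bind = c(0, 0, 0, 10, 20)),
                  class = c("bind_trace", "data.frame"))
  st <- trace_statistics(tr)
  ## window: t >= 0 + 0.4*4 = 1.6, i.e. values {0, 10, 20}
  expect_equal(unname(st["mean"]), 10)
  expect_equal(unname(st["sd"]), sqrt(200 / 3))
  expect_equal(unname(st["n"]), 3)
  ## constant series
  tc <- tr; tc$E_bind <- rep(7, 5)
  expect_equal(unname(trace_statistics(tc)["mean"]), 7)
  expect_equal(unname(trace_statistics(tc)["sd"]), 0)
  ## single-frame window
  expect_equal(unname(trace_statistics(tr, bounds = c(4, 4))["sd"]), 0)
  ## empty window
  expect_error(trace_statistics(tr, bounds = c(90, 99)),
               class = "mf_statistics_error")
  ## closed left boundary: a frame exactly at the cut is included
  tb <- structure(data.frame(frame = 1:5, time = c(0, 1, 2, 3, 5),
                             E_bind = 1:5),
                  class = c("bind_trace", "data.frame"))
  expect_equal(unname(trace_statistics(tb)["n"]), 3)  # t >= 2
})

test_that("a rigid trajectory yields a constant binding-energy trace", {
  pc <- plant_ionic_system()
  traj <- make_trajectory(pc, n_frames = 3, jitter_sd = 0, seed = 1)
  traj <- assign_charges(traj)
  tr <- binding_energy_trace(traj, backend = reference_backend())
  expect_equal(nrow(tr), 3)
  expect_equal(unname(trace_statistics(tr)["sd"]), 0)
  expect_equal(length(unique(round(tr$E_bind, 9))), 1L)
})
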