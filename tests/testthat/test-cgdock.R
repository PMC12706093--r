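# minimal bare system for toy-model checks
mk_bare <- function() list(
  pos = matrix(0, 1, 3), comp = 1L, body = 1L,
  bonds = matrix(0, 0, 5), quads = matrix(0L, 0, 4),
  lambda = numeric(0), theta0 = numeric(0),
  faces = matrix(0L, 0, 3), V0 = 1, kV = 0, rep_k = 0, rep_cut = 0,
  snare_pairs = matrix(0L, 0, 2), snare_eps = 0, snare_rc = 1,
  tethers = matrix(0L, 0, 2), tether_kang = 0, tether_active = FALSE,
  box = c(1e4, 1e4), periodic = FALSE)

run_bare <- function(sys, nsteps, dt, kT, mob = 1, seed = 1,
                     mc_sweeps = 0L, masks_on = FALSE,
                     protein_quads = list(), theta0_active = numeric(0),
                     mask_state = logical(0)) {
  set.seed(seed)
  svfusion:::cpp_cg_run(sys, as.integer(nsteps), dt,
                        rep(mob, nrow(sys$pos)), kT, 0L, 0L,
                        protein_quads, theta0_active, mask_state,
                        masks_on, 1e6, as.integer(mc_sweeps))
}

test_that("configuration carries the study constants and the reduced preset", {
  cfg <- sim_config()
  expect_equal(cfg$sv_outer_diameter_nm, 42.5)
  expect_equal(cfg$patch_side_nm, 180)
  expect_equal(cfg$timestep_ns, 0.1)
  expect_equal(cfg$viscosity_cP, 2.21)
  expect_equal(cfg$bending_rigidity_J, 0.8e-19)
  expect_equal(cfg$curvature_trigger_gap_nm, 6)
  r <- sim_config(reduced_preset = TRUE)
  expect_equal(r$sv_outer_diameter_nm, 20)
  expect_equal(r$patch_side_nm, 60)
  expect_error(sim_config(viscosity_cP = -1), "positive")
  expect_error(sim_config(curvature_protein_copies = -3), ">= 0")
})

test_that("system building is deterministic and validates density", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 4,
                    curvature_protein_copies = 10)
  a <- build_system(cfg)
  b <- build_system(cfg)
  expect_identical(a$pos, b$pos)
  expect_identical(a$bonds, b$bonds)
  expect_gt(a$V0, 0)
  expect_error(build_system(sim_config(reduced_preset = TRUE,
                                       curvature_protein_copies = 5000)),
               "dense")
})

test_that("rest-state energies sit at their minima and scale correctly", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 1)
  sys <- build_system(cfg)
  e <- total_energy(sys)
  expect_equal(e[["stretching"]], 0, tolerance = 1e-6)
  expect_equal(e[["volume"]], 0, tolerance = 1e-6)
  expect_equal(e[["snare"]], 0, tolerance = 1e-6)
  # bending of the sphere plus flat patch is ~ 8 pi kappa (pN nm)
  expect_lt(abs(e[["bending"]] - 8 * pi * 80) / (8 * pi * 80), 0.15)

  # doubling a pairwise overlap quadruples the harmonic repulsion
  two <- mk_bare()
  two$pos <- rbind(c(0, 0, 0), c(0, 0, 1.5))
  two$comp <- c(1L, 3L); two$body <- c(1L, 2L)
  two$rep_k <- 50; two$rep_cut <- 2
  e1 <- svfusion:::cpp_cg_energy(two)[["repulsion"]]
  two$pos[2, 3] <- 1.0
  e2 <- svfusion:::cpp_cg_energy(two)[["repulsion"]]
  expect_equal(e2 / e1, 4, tolerance = 1e-9)
})

test_that("discrete sphere bending energy approaches the Helfrich value", {
  kappa <- 80
  ico <- icosphere(10, 1)                 # edge <= R/10
  topo <- svfusion:::mesh_topology(ico$faces)
  sys <- mk_bare()
  sys$pos <- ico$vertices
  sys$comp <- rep(1L, nrow(ico$vertices))
  sys$body <- rep(1L, nrow(ico$vertices))
  sys$quads <- matrix(as.integer(topo$quads - 1L), ncol = 4)
  sys$lambda <- rep(2 * sqrt(3) * kappa, nrow(topo$quads))
  sys$theta0 <- rep(0, nrow(topo$quads))
  e <- svfusion:::cpp_cg_energy(sys)
  expect_lt(abs(e[["bending"]] - 8 * pi * kappa) / (8 * pi * kappa), 0.15)
})

test_that("zero temperature and zero force leave particles stationary", {
  two <- mk_bare()
  two$pos <- rbind(c(0, 0, 0), c(0, 0, 2))
  two$comp <- c(1L, 1L); two$body <- c(1L, 1L)
  two$bonds <- matrix(c(0, 1, 2, 25, 1), 1)
  res <- run_bare(two, 500, 0.01, kT = 0)
  expect_equal(res$pos, two$pos, tolerance = 1e-12)
})

test_that("free-particle MSD follows Stokes-Einstein within 3 SE", {
  eta <- 2.21; kT <- 4.282
  D <- kT / (6 * pi * eta * 1)
  nstep <- 1e5; dt <- 0.1
  mob <- 1 / (6 * pi * eta)
  set.seed(5)
  sq <- replicate(200, {
    r <- svfusion:::cpp_cg_run(mk_bare(), as.integer(nstep), dt, mob, kT,
                               0L, 0L, list(), numeric(0), logical(0),
                               FALSE, 1e6, 0L)
    sum(r$pos^2)
  })
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 6 * D * nstep * dt), 3 * se)
})

test_that("energy is non-increasing during zero-temperature relaxation", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 1)
  sys <- build_system(cfg)
  s <- sys
  Es <- total_energy(s)[["total"]]
  for (k in 1:6) {
    s <- step_bd(s, n_steps = 200, temperature_K = 0)
    Es <- c(Es, total_energy(s)[["total"]])
  }
  expect_true(all(diff(Es) <= 1e-6))
})

test_that("energy is invariant under rigid translation (periodic patch)", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 2,
                    curvature_protein_copies = 5)
  sys <- build_system(cfg)
  e0 <- total_energy(sys)[["total"]]
  s2 <- sys
  s2$pos <- sweep(s2$pos, 2, c(17.3, -9.1, 4.2), "+")
  e1 <- total_energy(s2)[["total"]]
  expect_lt(abs(e1 - e0) / abs(e0), 1e-6)
})

test_that("SV volume is conserved by the volume potential (1%) and drifts without it", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 1)
  sys <- build_system(cfg)
  mob <- rep(1 / (6 * pi * 2.21), nrow(sys$pos))
  set.seed(3)
  res <- svfusion:::cpp_cg_run(sys, 10000L, 0.01, mob, 4.282, 500L, 0L,
                               sys$protein_quads, sys$theta0_active,
                               sys$mask_state, FALSE, 1, 0L)
  dev <- abs(res$volume_series / sys$V0 - 1)
  expect_lt(max(dev), 0.01)
  s0 <- sys; s0$kV <- 0
  set.seed(3)
  res0 <- svfusion:::cpp_cg_run(s0, 10000L, 0.01, mob, 4.282, 500L, 0L,
                                sys$protein_quads, sys$theta0_active,
                                sys$mask_state, FALSE, 1, 0L)
  dev0 <- abs(res0$volume_series / sys$V0 - 1)
  expect_gt(max(dev0), max(dev))
})

test_that("Metropolis mask updates obey the Boltzmann acceptance law", {
  th_a <- 0.4; lam <- 50; kT <- 4.282
  toy <- mk_bare()
  toy$pos <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(1, 0, 0))
  toy$comp <- rep(1L, 4); toy$body <- rep(1L, 4)
  toy$quads <- matrix(c(0L, 1L, 2L, 3L), 1)
  toy$lambda <- lam; toy$theta0 <- 0
  dE <- lam * (1 - cos(th_a))
  res <- run_bare(toy, 0, 0.1, kT, seed = 9, mc_sweeps = 1e5,
                  masks_on = TRUE, protein_quads = list(0L),
                  theta0_active = th_a, mask_state = FALSE)
  mc <- res$mc
  p_emp <- mc[["acc_on"]] / mc[["prop_on"]]
  p_theo <- exp(-dE / kT)
  se <- sqrt(p_theo * (1 - p_theo) / mc[["prop_on"]])
  expect_lt(abs(p_emp - p_theo), 3 * se)
  expect_equal(mc[["acc_off"]], mc[["prop_off"]])  # downhill toggles

  # infinite-temperature limit accepts everything
  res2 <- run_bare(toy, 0, 0.1, 1e12, seed = 9, mc_sweeps = 1e4,
                   masks_on = TRUE, protein_quads = list(0L),
                   theta0_active = th_a, mask_state = FALSE)
  expect_equal(sum(res2$mc[c("acc_on", "acc_off")]),
               sum(res2$mc[c("prop_on", "prop_off")]))

  # no proteins: the update is a no-op
  cfg <- sim_config(reduced_preset = TRUE, seed = 1)
  sys <- build_system(cfg)
  sys2 <- mc_curvature_update(sys, cfg)
  expect_identical(sys2$theta0, sys$theta0)
})

test_that("an oversized timestep aborts with an instability diagnostic", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 1)
  sys <- build_system(cfg)
  cfg_bad <- cfg
  cfg_bad$timestep_ns <- 1
  set.seed(1)
  expect_error(step_bd(sys, cfg_bad, n_steps = 400), "timestep")
})

test_that("without tether torque the gap stays at its initial level", {
  cfg <- sim_config(reduced_preset = TRUE, seed = 6,
                    tether_kang = 1e-9, relax_time_us = 0.05,
                    run_time_us = 0.1)
  tr <- run_docking(cfg)
  expect_false(tr$triggered)
  expect_lt(abs(mean(tr$gap_series$gap_nm) - cfg$initial_gap_nm), 1.5)
})

test_that("tether activation recruits the SV toward the membrane", {
  runs0 <- docking_runs()[["0"]]
  final_gaps <- vapply(runs0, function(tr) tail(tr$gap_series$gap_nm, 1), 0)
  expect_lt(median(final_gaps), 12)
  expect_true(all(vapply(runs0, function(tr) tr$triggered, TRUE)))
  # gap series times strictly increase
  for (tr in runs0)
    expect_true(all(diff(tr$gap_series$time_us) > 0))
})

test_that("curvature-protein crowding does not accelerate recruitment", {
  runs <- docking_runs()
  t0 <- vapply(runs[["0"]], function(tr) tr$time_to_trigger_us, 0)
  t30 <- vapply(runs[["30"]], function(tr) tr$time_to_trigger_us, 0)
  expect_true(all(is.finite(t0)))
  expect_true(all(is.finite(t30)))
  expect_lte(median(t0), median(t30))
})
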