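make_lj_box <- function(n = 8, L = 24, epsilon = 0.3) {
  lj <- lj_topology(epsilon = epsilon)
  pts <- expand.grid(x = seq(3, L - 3, length.out = 3),
                     y = seq(3, L - 3, length.out = 3),
                     z = seq(3, L - 3, length.out = 3))
  poses <- lapply(seq_len(n), function(k)
    molecule_pose("lj", as.numeric(pts[k, ])))
  configuration(rep(L, 3), poses, list(lj = lj))
}

test_that("downhill displacement moves are always accepted", {
  # two LJ molecules just inside the repulsive wall: almost any move of
  # molecule 2 away from 1 lowers the energy; all downhill records accepted
  lj <- lj_topology(epsilon = 0.5)
  cfg <- configuration(c(30, 30, 30),
                       list(molecule_pose("lj", c(15, 15, 15)),
                            molecule_pose("lj", c(17.8, 15, 15))),
                       list(lj = lj))
  spec <- simulation_spec(cutoff = 10, volume_move_frequency = 0,
                          max_translation = 0.2)
  set.seed(4)
  for (k in 1:200) {
    out <- metropolis_step(cfg, spec)
    if (out$record$delta_energy <= 0)
      expect_true(out$record$accepted)
    cfg <- out$configuration
  }
})

test_that("frame-count arithmetic is exact for stride/step combinations", {
  expect_equal(expected_frame_count(
    simulation_spec(n_production = 154000, snapshot_stride = 500,
                    n_parallel_runs = 2)), 616L)
  expect_equal(expected_frame_count(
    simulation_spec(n_production = 499, snapshot_stride = 500,
                    n_parallel_runs = 1)), 0L)
  expect_equal(expected_frame_count(
    simulation_spec(n_production = 1000, snapshot_stride = 3,
                    n_parallel_runs = 3)), 999L)
  # run_simulation records exactly that many frames
  cfg <- make_lj_box()
  spec <- simulation_spec(cutoff = 8, n_thermalization = 10,
                          n_production = 230, snapshot_stride = 50,
                          n_parallel_runs = 2, rng_seed = 3)
  sim <- run_simulation(cfg, spec)
  expect_length(sim$frames, expected_frame_count(spec))
  expect_length(sim$frames, 8L)
})

test_that("identical spec and seed reproduce the trajectory bitwise", {
  cfg <- make_lj_box()
  spec <- simulation_spec(cutoff = 8, n_thermalization = 50,
                          n_production = 300, snapshot_stride = 100,
                          n_parallel_runs = 2, rng_seed = 42)
  s1 <- run_simulation(cfg, spec)
  s2 <- run_simulation(cfg, spec)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$moves, s2$moves)
  s3 <- run_simulation(cfg, simulation_spec(
    cutoff = 8, n_thermalization = 50, n_production = 300,
    snapshot_stride = 100, n_parallel_runs = 2, rng_seed = 43))
  expect_false(identical(s1$frames, s3$frames))
})

test_that("incremental energy bookkeeping matches full recomputation", {
  cfg <- make_lj_box(n = 10)
  spec <- simulation_spec(cutoff = 9, volume_move_frequency = 0.05,
                          max_translation = 0.4)
  sys <- emip:::compile_system(cfg, spec$cutoff)
  sys <- emip:::add_pair_tables(sys)
  U <- emip:::total_energy_fast(sys)
  set.seed(8)
  for (s in 1:20000) {
    out <- emip:::step_sys(sys, spec, U)
    sys <- out$sys; U <- out$U
  }
  expect_lt(abs(U - emip:::total_energy_fast(sys)), 1e-8)
})

test_that("volume moves that would break the cutoff invariant auto-reject", {
  cfg <- make_lj_box(L = 21)
  # cutoff 10 barely below half-edge 10.5: shrinking moves soon violate it
  spec <- simulation_spec(cutoff = 10.4, volume_move_frequency = 1 - 1e-12,
                          max_ln_volume_step = 0.2)
  sys <- emip:::compile_system(cfg, spec$cutoff)
  sys <- emip:::add_pair_tables(sys)
  U <- emip:::total_energy_fast(sys)
  set.seed(9)
  rejected_na <- 0L
  for (s in 1:50) {
    out <- emip:::step_sys(sys, spec, U)
    if (!out$record$accepted && is.na(out$record$delta_energy))
      rejected_na <- rejected_na + 1L
    sys <- out$sys; U <- out$U
  }
  expect_gt(rejected_na, 0L)
  expect_true(spec$cutoff < min(sys$box) / 2)
})

test_that("layered builder places molecules with guaranteed clearances", {
  sys <- make_toy_system()
  # template alone: centred on the midplane of the box
  set.seed(1)
  solo <- build_layered_initial(sys$template, sys$monomer, sys$solvent, 0, 0)
  expect_length(solo$poses, 1L)
  expect_equal(solo$poses[[1]]$position, rep(solo$box[1] / 2, 3))
  # desk-scale default: no two sites of different molecules within
  # 0.85 sigma_ij (brute-force check over all site pairs)
  set.seed(2)
  cfg <- build_layered_initial(sys$template, sys$monomer, sys$solvent,
                               60, 500)
  sites <- config_sites(cfg)
  n <- length(sites)
  X <- t(vapply(sites, function(s) s$xyz, numeric(3)))
  mol <- vapply(sites, function(s) s$mol, 0L)
  sig <- vapply(sites, function(s) s$sigma, 0)
  min_ratio <- Inf
  for (ax in 1:3) {
    D <- outer(X[, ax], X[, ax], "-")
    D <- D - cfg$box[ax] * round(D / cfg$box[ax])
    assign(paste0("D", ax), D)
  }
  R <- sqrt(D1^2 + D2^2 + D3^2)
  lim <- 0.85 * sqrt(outer(sig, sig))
  different <- outer(mol, mol, "!=")
  expect_true(all(R[different] >= lim[different]))
  # roles land in the right half-spaces
  roles <- vapply(cfg$poses, function(p)
    cfg$topologies[[p$topology_ref]]$role, "")
  z <- vapply(cfg$poses, function(p) p$position[3], 0)
  expect_true(all(z[roles == "monomer"] < cfg$box[3] / 2))
  expect_true(all(z[roles == "solvent"] > cfg$box[3] / 2))
})

test_that("the full-scale layered box (1 + 601 + 5000) constructs", {
  sys <- make_toy_system()
  set.seed(3)
  cfg <- build_layered_initial(sys$template, sys$monomer, sys$solvent,
                               601, 5000)
  expect_length(cfg$poses, 5602L)
})

test_that("impossible packing requests fail with actionable errors", {
  sys <- make_toy_system()
  expect_error(
    build_layered_initial(sys$template, sys$monomer, sys$solvent,
                          601, 5000, target_density = 3),
    "lower target_density")
})
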