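test_that("shell extraction matches the brute-force neighbour search", {
  set.seed(21)
  sys <- make_toy_system()
  topos <- stats::setNames(list(sys$template, sys$monomer, sys$solvent),
                           c(sys$template$name, sys$monomer$name,
                             sys$solvent$name))
  for (rep in 1:30) {
    L <- 26
    poses <- c(list(molecule_pose(sys$template$name, runif(3, 0, L),
                                  emip:::quat_random())),
               lapply(1:10, function(k)
                 molecule_pose(sys$monomer$name, runif(3, 0, L),
                               emip:::quat_random())),
               lapply(1:4, function(k)
                 molecule_pose(sys$solvent$name, runif(3, 0, L))))
    frame <- trajectory_frame(1L, rep * 10L,
                              configuration(rep(L, 3), poses, topos), 0)
    cav <- extract_first_shell(frame, shell_cutoff = 5)
    expect_equal(cav$n_monomers,
                 length(oracle_shell_members(frame, 5)))
  }
})

test_that("empty shells and missing templates are handled", {
  sys <- make_toy_system()
  topos <- stats::setNames(list(sys$template, sys$monomer),
                           c(sys$template$name, sys$monomer$name))
  poses <- list(molecule_pose(sys$template$name, c(40, 40, 40)),
                molecule_pose(sys$monomer$name, c(5, 5, 5)))
  frame <- trajectory_frame(1L, 0L,
                            configuration(rep(80, 3), poses, topos), 0)
  cav <- extract_first_shell(frame, 4)
  expect_equal(cav$n_monomers, 0L)
  expect_equal(binding_energy(cav), 0)
  no_t <- trajectory_frame(1L, 0L, configuration(
    rep(80, 3), list(molecule_pose(sys$monomer$name, c(5, 5, 5))),
    topos), 0)
  expect_error(extract_first_shell(no_t, 4), "exactly one template")
})

test_that("shell cutoff is recovered from a bimodal distance distribution", {
  set.seed(5)
  # first shell at ~3, second at ~6, trough at 4.5
  d <- c(rnorm(4000, 3.0, 0.45), rnorm(6000, 6.2, 0.6))
  d <- d[d > 0.5]
  cut <- shell_cutoff_from_rdf(d, bin_width = 0.15)
  expect_lt(abs(cut - 4.5), 0.3)
  # monotone histogram: no interior minimum
  expect_error(shell_cutoff_from_rdf(sqrt(runif(5000)) * 5),
               "supply the shell cutoff manually|no interior minimum")
  # uniform distances: structureless
  set.seed(6)
  expect_error(shell_cutoff_from_rdf(runif(5000, 1, 8)),
               "no interior minimum")
})

test_that("relaxation finds the LJ dimer minimum and never raises energy", {
  sig <- 3.2
  lj1 <- lj_topology("t", sigma = sig, epsilon = 0.4, role = "template")
  lj2 <- lj_topology("m", sigma = sig, epsilon = 0.4, role = "monomer")
  topos <- list(t = lj1, m = lj2)
  cav <- cavity(molecule_pose("t", c(0, 0, 0)),
                list(molecule_pose("m", c(1.5 * sig, 0, 0))),
                topos, run_id = 1L, step = 0L)
  e0 <- binding_energy(cav)
  rel <- relax_cavity(cav, "stage1")
  expect_lte(rel$binding_energy, e0)
  rel2 <- relax_cavity(rel, "stage2")
  expect_lte(rel2$binding_energy, rel$binding_energy)
  r <- sqrt(sum((rel2$monomer_poses[[1]]$position -
                   rel2$template_pose$position)^2))
  expect_lt(abs(r - 2^(1 / 6) * sig), 1e-3 * sig)
  expect_equal(rel2$binding_energy, -0.4, tolerance = 1e-4)
  # already-at-minimum dimer stays put
  cav_min <- cavity(molecule_pose("t", c(0, 0, 0)),
                    list(molecule_pose("m", c(2^(1 / 6) * sig, 0, 0))),
                    topos)
  rel3 <- relax_cavity(cav_min, "stage1")
  expect_equal(rel3$binding_energy, -0.4, tolerance = 1e-3)
  # stage order is enforced
  expect_error(relax_cavity(cav, "stage2"), "stage1")
})

test_that("binding energy equals the sum of intermolecular pair terms", {
  set.seed(31)
  sys <- make_toy_system()
  topos <- stats::setNames(list(sys$template, sys$monomer),
                           c(sys$template$name, sys$monomer$name))
  tp <- molecule_pose(sys$template$name, c(10, 10, 10))
  m1 <- molecule_pose(sys$monomer$name, c(14.5, 10, 10),
                      emip:::quat_random())
  m2 <- molecule_pose(sys$monomer$name, c(10, 14.5, 10),
                      emip:::quat_random())
  cav <- cavity(tp, list(m1, m2), topos)
  big <- configuration(rep(200, 3), list(tp, m1, m2), topos)
  expect_equal(binding_energy(cav),
               pair_energy(big, 1, 2) + pair_energy(big, 1, 3) +
                 pair_energy(big, 2, 3),
               tolerance = 1e-10)
  # and matches the brute-force oracle
  expect_equal(binding_energy(cav), oracle_total_energy(big),
               tolerance = 1e-10)
})

test_that("funnel thresholds are inclusive and per-group at stage 1", {
  expect_equal(funnel_survivors(c(0, 9.9, 10.1), 10),
               c(TRUE, TRUE, FALSE))
  expect_equal(funnel_survivors(c(0, 10, 10.0000001), 10),
               c(TRUE, TRUE, FALSE))
  # per-group: each group's minimum survives its own cut
  e <- c(0, 12, 100, 103, 115)
  g <- c(1, 1, 2, 2, 2)
  expect_equal(funnel_survivors(e, 10, group = g),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("funnel survivor counts are monotone across stages", {
  # engineered energy sets over groups 18-23 whose stage-1 survivors
  # total 46 of 60 cavities
  set.seed(41)
  groups <- rep(18:23, each = 10)
  energies <- numeric(60)
  per_group_survivors <- c(9, 7, 8, 8, 7, 7)  # sums to 46
  for (k in seq_along(18:23)) {
    idx <- which(groups == (18:23)[k])
    ns <- per_group_survivors[k]
    energies[idx] <- c(runif(ns, 0, 9.5), runif(10 - ns, 10.5, 30))
  }
  s1 <- funnel_survivors(energies, 10, group = groups)
  expect_equal(sum(s1), 46L)
  s2 <- funnel_survivors(energies[s1], 5)
  expect_lte(sum(s2), sum(s1))
  for (g in 18:23) {
    idx <- groups == g
    expect_true(s1[idx][which.min(energies[idx])])
  }
})

test_that("funnel_select runs the full relax-and-cut pipeline", {
  sig <- 3.0
  tmpl <- lj_topology("t", sigma = sig, epsilon = 0.4, role = "template")
  mono <- lj_topology("m", sigma = sig, epsilon = 0.4, role = "monomer")
  topos <- list(t = tmpl, m = mono)
  set.seed(51)
  mk_cav <- function(n, step) {
    dirs <- matrix(rnorm(3 * n), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cavity(molecule_pose("t", c(0, 0, 0)),
           lapply(seq_len(n), function(k)
             molecule_pose("m", dirs[k, ] * runif(1, 3.4, 4.2))),
           topos, run_id = 1L, step = step)
  }
  cavs <- c(lapply(1:4, function(k) mk_cav(2, k * 10L)),
            lapply(1:4, function(k) mk_cav(3, k * 10L)))
  rep <- funnel_select(cavs, funnel_spec(10, 5, c(2, 3)),
                       max_iterations = 60)
  expect_s3_class(rep, "funnel_report")
  expect_true(all(rep$groups$n_stage1 <= rep$groups$n_extracted))
  expect_true(all(rep$groups$n_stage2 <= rep$groups$n_stage1))
  expect_true(all(vapply(rep$selected, function(cv)
    cv$stage == "final_scored", TRUE)))
  # group_range filtering and empty input
  expect_warning(funnel_select(cavs, funnel_spec(10, 5, c(30, 40))),
                 "excludes all")
  expect_warning(funnel_select(list(), funnel_spec()), "no cavities")
})

test_that("population statistics reproduce a hand-computed oracle", {
  # single cavity: one group at 100 %
  one <- population_report(c(7L))
  expect_equal(one$fraction, 1)
  set.seed(61)
  sizes <- sample(16:25, 500, replace = TRUE,
                  prob = c(1, 2, 6, 9, 10, 8, 4, 3, 1, 1))
  rep <- population_report(sizes)
  expect_equal(sum(rep$fraction), 1, tolerance = 1e-9)
  for (k in seq_len(nrow(rep))) {
    expect_equal(rep$count[k], sum(sizes == rep$n_monomers[k]))
    expect_equal(rep$fraction[k], mean(sizes == rep$n_monomers[k]))
  }
  # interval share equals the sum of member fractions
  expect_equal(population_share(rep, c(19, 21)),
               mean(sizes >= 19 & sizes <= 21), tolerance = 1e-12)
})
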