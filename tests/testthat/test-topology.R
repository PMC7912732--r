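test_that("site and topology invariants are enforced", {
  expect_error(site_params("A", "O", -1, 0.1, 0), "sigma")
  expect_error(site_params("A", "O", 3, -0.1, 0), "epsilon")
  expect_error(site_params("A", "O", 3, 0.1, 0, c(1, NA, 0)),
               "local_position")
  expect_error(molecule_topology("m", "monomer", list()), "at least 1 site")
  # header net charge must match the site-charge sum
  expect_error(
    molecule_topology("m", "monomer",
                      list(site_params("A", "O", 3, 0.1, 1)),
                      net_charge = 0),
    "net_charge")
  single <- molecule_topology("m", "monomer",
                              list(site_params("A", "O", 3.0, 0.1, 0)))
  expect_equal(single$net_charge, 0)
  expect_equal(single$n_sites, 1L)
})

test_that("topology files round-trip through write/read", {
  topo <- molecule_topology("tst", "template", list(
    site_params("C1", "C", 4.2, 0.3, 0.55, c(0, 0, 0)),
    site_params("O1", "O", 2.9123456789, 0.17, -0.25, c(-1.5, 1, 0.25)),
    site_params("N1", "N", 3.3, 0.17, 0.7, c(1.25, 0, 0))
  ), net_charge = 1)
  path <- withr::local_tempfile(fileext = ".topology")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_equal(back, topo)
  # writing the re-read topology reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".topology")
  write_topology(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the shipped toy monomer file parses and round-trips exactly", {
  path <- system.file("extdata", "opd_toy.topology", package = "emip")
  topo <- read_topology(path)
  expect_equal(topo$n_sites, 3L)
  expect_equal(topo$role, "monomer")
  expect_equal(topo$net_charge, 0)
  path2 <- withr::local_tempfile()
  write_topology(topo, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed topology files fail with line/field diagnostics", {
  path <- withr::local_tempfile()
  writeLines(c("name x", "role monomer", "net_charge 0", "sites 1",
               "label element sigma epsilon charge x y z",
               "A O bad 0.1 0 0 0 0"), path)
  expect_error(read_topology(path), "non-numeric value in field 'sigma'")
  writeLines(c("name x", "role monomer", "sites 1",
               "label element sigma epsilon charge x y z",
               "A O 3 0.1 0 0 0 0"), path)
  expect_error(read_topology(path), "net_charge")
  # file whose site charges sum to +1 while the header claims 0
  writeLines(c("name x", "role monomer", "net_charge 0", "sites 1",
               "label element sigma epsilon charge x y z",
               "A O 3 0.1 1 0 0 0"), path)
  expect_error(read_topology(path), "net_charge")
})

test_that("configurations wrap poses and wrapping is idempotent", {
  lj <- lj_topology()
  cfg <- configuration(c(10, 10, 10),
                       list(molecule_pose("lj", c(12, -3, 5))),
                       list(lj = lj))
  expect_true(all(cfg$poses[[1]]$position >= 0 &
                    cfg$poses[[1]]$position < 10))
  expect_equal(cfg$poses[[1]]$position, c(2, 7, 5))
  expect_equal(wrap_configuration(cfg), cfg)
})

test_that("configuration validation catches bad boxes, poses and templates", {
  lj <- lj_topology()
  expect_error(configuration(c(-1, 10, 10),
                             list(molecule_pose("lj", c(1, 1, 1))),
                             list(lj = lj)), "box")
  expect_error(configuration(c(10, 10, 10),
                             list(molecule_pose("nope", c(1, 1, 1))),
                             list(lj = lj)), "undefined topologies")
  expect_error(molecule_pose("lj", c(1, 1, 1), c(1, 1, 0, 0)),
               "unit quaternion")
  tmpl <- lj_topology("t", role = "template")
  expect_error(
    configuration(c(10, 10, 10),
                  list(molecule_pose("t", c(1, 1, 1)),
                       molecule_pose("t", c(5, 5, 5))),
                  list(t = tmpl)),
    "at most one template")
})

test_that("trajectories round-trip exactly through the XYZ dialect", {
  set.seed(11)
  topos <- list(t = random_topology("t", 4, role = "template"),
                m = random_topology("m", 3, role = "monomer"))
  frames <- lapply(c(0L, 500L, 1000L), function(s) {
    poses <- list(molecule_pose("t", runif(3, 0, 15), emip:::quat_random()),
                  molecule_pose("m", runif(3, 0, 15), emip:::quat_random()),
                  molecule_pose("m", runif(3, 0, 15), emip:::quat_random()))
    trajectory_frame(1L, s, configuration(c(15, 16, 17), poses, topos),
                     potential_energy = rnorm(1))
  })
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(frames, path)
  back <- read_trajectory(path, topos)
  expect_equal(length(back), 3L)
  for (k in 1:3) {
    expect_equal(back[[k]]$step, frames[[k]]$step)
    expect_equal(back[[k]]$potential_energy, frames[[k]]$potential_energy)
    expect_equal(back[[k]]$volume, frames[[k]]$volume)
    for (i in 1:3) {
      expect_equal(back[[k]]$configuration$poses[[i]]$position,
                   frames[[k]]$configuration$poses[[i]]$position,
                   tolerance = 1e-12)
      expect_equal(back[[k]]$configuration$poses[[i]]$orientation,
                   frames[[k]]$configuration$poses[[i]]$orientation,
                   tolerance = 1e-12)
    }
  }
})

test_that("trajectory writing enforces preconditions", {
  expect_error(write_trajectory(list(), withr::local_tempfile()),
               "non-empty")
  lj <- lj_topology()
  cfg <- configuration(c(10, 10, 10), list(molecule_pose("lj", c(1, 1, 1))),
                       list(lj = lj))
  f1 <- trajectory_frame(1L, 100L, cfg, 0)
  f2 <- trajectory_frame(1L, 50L, cfg, 0)
  expect_error(write_trajectory(list(f1, f2), withr::local_tempfile()),
               "non-monotone")
})

test_that("a 616-frame trajectory writes and re-reads completely", {
  lj <- lj_topology()
  topos <- list(lj = lj)
  frames <- lapply(seq_len(616), function(k)
    trajectory_frame(1L, k * 500L,
                     configuration(c(10, 10, 10),
                                   list(molecule_pose("lj", c(k %% 10, 1, 1))),
                                   topos),
                     potential_energy = k))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(frames, path)
  back <- read_trajectory(path, topos)
  expect_length(back, 616L)
  expect_equal(back[[616]]$step, 308000L)
})
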