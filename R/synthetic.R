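# Fixture generators. Every generator is deterministic given its seed and
# returns its ground truth as the "truth" attribute; when written to disk a
# sidecar CSV carries the same truth so tests never re-derive it.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# quaternion rotating unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a * a)); b <- b / sqrt(sum(b * b))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(quat_identity())
  if (d < -1 + 1e-12) {
    # opposite: rotate pi about any perpendicular axis
    perp <- cross3(a, c(1, 0, 0))
    if (sum(perp^2) < 1e-12) perp <- cross3(a, c(0, 1, 0))
    return(quat_from_axis_angle(perp, pi))
  }
  quat_from_axis_angle(cross3(a, b), acos(d))
}

write_truth_sidecar <- function(truth, path) {
  df <- data.frame(key = names(truth),
                   value = vapply(truth, function(v)
                     paste(format(v, digits = 17), collapse = ";"), ""))
  utils::write.csv(df, paste0(path, ".truth.csv"), row.names = FALSE)
}

#' Toy imprinting system: template, monomer and solvent topologies
#'
#' A coarse-grained stand-in for the MDPV / o-PD / water system. The
#' template is a protonated (net charge +1) analyte-like molecule with
#' three hydrogen-bond acceptor sites (two ether-like oxygens and one
#' carbonyl-like oxygen) and a cationic amine shielded behind a bulky
#' core, so the amine is sterically hindered, as for the tertiary amine
#' of the real analyte. The monomer carries two donor sites on an
#' aromatic-like core (net charge 0), and the solvent is a neutral
#' Lennard-Jones sphere. Charges and LJ parameters are chosen so that a
#' donor--acceptor contact is favorable with its energy minimum at
#' 2.8--3.2 angstrom separation (see [donor_acceptor_scan()]).
#'
#' @return Named list with elements `template`, `monomer`, `solvent`.
#' @export
make_toy_system <- function() {
  template <- molecule_topology(
    "mdpv_toy", "template",
    list(
      site_params("C1", "C", 4.50, 0.30, 0.80, c(0.0, 0.0, 0.0)),
      site_params("N1", "N", 3.30, 0.17, 0.80, c(1.30, 0.0, 0.0)),
      site_params("O1", "O", 2.60, 1.50, -0.20, c(-1.50, 1.00, 0.0)),
      site_params("O2", "O", 2.60, 1.50, -0.20, c(-1.50, -1.00, 0.0)),
      site_params("O3", "O", 2.65, 1.70, -0.20, c(0.30, 1.80, 0.60))
    ),
    net_charge = 1
  )
  monomer <- molecule_topology(
    "opd_toy", "monomer",
    list(
      site_params("R1", "C", 3.55, 0.07, -0.30, c(0.0, 0.0, 0.0)),
      site_params("D1", "N", 2.80, 1.50, 0.15, c(1.20, 0.70, 0.0)),
      site_params("D2", "N", 2.80, 1.50, 0.15, c(1.20, -0.70, 0.0))
    ),
    net_charge = 0
  )
  solvent <- molecule_topology(
    "water_toy", "solvent",
    list(site_params("OW", "O", 3.16, 0.155, 0.0)),
    net_charge = 0
  )
  list(template = template, monomer = monomer, solvent = solvent)
}

#' Scan a donor--acceptor approach of the toy monomer to the template
#'
#' Places the monomer so that its donor site approaches the chosen
#' template acceptor head-on (ring pointing away) and scans the
#' molecule--molecule interaction energy as a function of the
#' donor--acceptor site separation. No periodicity or cutoff.
#'
#' @param template,monomer Topologies from [make_toy_system()].
#' @param distances Donor--acceptor separations to scan, angstrom.
#' @param acceptor Template acceptor site label.
#' @param donor Monomer donor site label.
#' @return Data frame (`distance`, `energy`) with attributes
#'   `min_distance` and `min_energy`.
#' @export
donor_acceptor_scan <- function(template, monomer,
                                distances = seq(2.0, 8.0, by = 0.01),
                                acceptor = "O1", donor = "D1") {
  alab <- vapply(template$sites, function(s) s$label, "")
  dlab <- vapply(monomer$sites, function(s) s$label, "")
  ai <- match(acceptor, alab); di <- match(donor, dlab)
  if (is.na(ai)) stop("unknown acceptor site '", acceptor, "'")
  if (is.na(di)) stop("unknown donor site '", donor, "'")
  apos <- template$sites[[ai]]$local_position
  dpos <- monomer$sites[[di]]$local_position
  u <- apos / sqrt(sum(apos^2))     # outward approach axis
  q <- rotation_between(dpos, -u)   # donor axis points back at the template
  r <- quat_to_matrix(q)
  topos <- list(template, monomer)
  names(topos) <- c(template$name, monomer$name)
  energy <- vapply(distances, function(d) {
    mpos <- apos + d * u - as.numeric(r %*% dpos)
    poses <- list(molecule_pose(template$name, c(0, 0, 0)),
                  molecule_pose(monomer$name, mpos, q))
    total_energy_sys(compile_poses(poses, topos, box = NULL, cutoff = Inf),
                     overlap = "inf")
  }, 0)
  out <- data.frame(distance = distances, energy = energy)
  k <- which.min(energy)
  attr(out, "min_distance") <- distances[k]
  attr(out, "min_energy") <- energy[k]
  out
}

#' Authored cavity-count preset reproducing the printed population
#'
#' Per-size cavity counts over 616 frames whose fractions reproduce the
#' reported population statistics of the full-scale study (20 monomers:
#' 22.7 %, 19: 20.5 %, 21: 18.5 %). These counts are authored to match
#' the printed statistics; they are a worked-example fixture, not a
#' re-simulation.
#'
#' @return Named integer vector (names = monomer counts) summing to 616.
#' @export
mdpv_population_counts <- function() {
  c(`18` = 80L, `19` = 126L, `20` = 140L, `21` = 114L, `22` = 88L,
    `23` = 68L)
}

#' Generate a trajectory with prescribed first-shell monomer counts
#'
#' Emits one frame per requested cavity: the template sits at the box
#' centre and exactly `n` monomers are placed with at least one site
#' within the shell cutoff of a template site (well clear of the
#' boundary), while `n_outside` decoy monomers are placed far outside the
#' shell. Running [extract_first_shell()] at the same cutoff therefore
#' reproduces the requested counts exactly, which the generator verifies
#' before returning.
#'
#' @param counts_by_size Named integer vector: `counts_by_size[["20"]]`
#'   frames with 20 shell monomers, etc.
#' @param seed Integer seed (mandatory; the generator is deterministic
#'   given it).
#' @param shell_cutoff Shell cutoff the fixture is built for, angstrom.
#' @param n_outside Decoy monomers per frame outside the shell.
#' @param box_edge Cubic box edge, angstrom.
#' @param system Topologies from [make_toy_system()].
#' @param path Optional trajectory file path; a `.truth.csv` sidecar with
#'   the per-frame shell counts is written next to it.
#' @return List of [trajectory_frame()]s with attribute `truth` (integer
#'   vector of per-frame shell counts, in frame order).
#' @export
gen_cavity_count_fixture <- function(counts_by_size, seed,
                                     shell_cutoff = 4.0, n_outside = 5L,
                                     box_edge = 90, system = make_toy_system(),
                                     path = NULL) {
  stopifnot(!is.null(names(counts_by_size)), all(counts_by_size >= 0))
  sizes <- rep(as.integer(names(counts_by_size)),
               times = as.integer(counts_by_size))
  if (!length(sizes)) stop("no frames requested")
  set.seed(seed)
  sizes <- sample(sizes)
  topos <- list(system$template, system$monomer)
  names(topos) <- vapply(topos, function(t) t$name, "")
  center <- rep(box_edge / 2, 3)
  tpose <- molecule_pose(system$template$name, center)
  txyz <- pose_site_coords(tpose, system$template)
  mono_local <- topology_local_coords(system$monomer)
  n_tsites <- nrow(txyz)
  min_site_dist <- function(mxyz) {
    dx <- outer(txyz[, 1], mxyz[, 1], "-")
    dy <- outer(txyz[, 2], mxyz[, 2], "-")
    dz <- outer(txyz[, 3], mxyz[, 3], "-")
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }
  frames <- vector("list", length(sizes))
  for (fi in seq_along(sizes)) {
    poses <- list(tpose)
    n_in <- sizes[fi]
    for (k in seq_len(n_in)) {
      ts <- ((k - 1L) %% n_tsites) + 1L
      u <- stats::rnorm(3); u <- u / sqrt(sum(u * u))
      q <- quat_random()
      r <- quat_to_matrix(q)
      ctr <- txyz[ts, ] + 3.0 * u
      for (adjust in 1:60) {
        mxyz <- sweep(mono_local %*% t(r), 2, ctr, "+")
        d <- min_site_dist(mxyz)
        if (d > shell_cutoff - 0.4) ctr <- ctr - 0.2 * u
        else if (d < 1.3) ctr <- ctr + 0.2 * u
        else break
      }
      poses[[length(poses) + 1L]] <-
        molecule_pose(system$monomer$name, ctr, q)
    }
    for (k in seq_len(n_outside)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u * u))
      ctr <- center + (0.28 * box_edge + 3 * k) * u
      poses[[length(poses) + 1L]] <-
        molecule_pose(system$monomer$name, ctr, quat_random())
    }
    cfg <- configuration(rep(box_edge, 3), poses, topos)
    frames[[fi]] <- trajectory_frame(1L, fi * 500L, cfg, 0)
    got <- extract_first_shell(frames[[fi]], shell_cutoff)$n_monomers
    if (got != n_in)
      stop("geometrically unsatisfiable request: frame ", fi,
           " yields ", got, " shell monomers instead of ", n_in)
  }
  attr(frames, "truth") <- sizes
  if (!is.null(path)) {
    write_trajectory(frames, path)
    write_truth_sidecar(list(shell_counts = sizes,
                             shell_cutoff = shell_cutoff), path)
  }
  frames
}

#' Generate a linear calibration series with additive blank noise
#'
#' `current = slope * concentration + intercept + N(0, s_blank)`. The
#' default slope and intercept are the calibration-line presets of the
#' AgNP-enhanced imprinted sensor (slope 567e-4 A L/mol).
#'
#' @param slope Sensitivity, A per mol/L.
#' @param intercept Blank current, A.
#' @param s_blank Additive noise standard deviation, A (0 = noiseless).
#' @param levels Concentration levels, mol/L.
#' @param replicates Replicates per level.
#' @param seed Integer seed.
#' @param path Optional CSV path (`concentration,current`); truth sidecar
#'   written alongside.
#' @return Data frame (`concentration`, `current`) with attribute `truth`.
#' @export
gen_calibration <- function(slope = 567e-4, intercept = 1e-8,
                            s_blank = 0, levels = c(5, 10, 25, 50, 100) * 1e-6,
                            replicates = 1L, seed = 1L, path = NULL) {
  set.seed(seed)
  conc <- rep(levels, each = replicates)
  cur <- slope * conc + intercept +
    if (s_blank > 0) stats::rnorm(length(conc), 0, s_blank) else 0
  out <- data.frame(concentration = conc, current = cur)
  truth <- list(slope = slope, intercept = intercept, s_blank = s_blank)
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    write_truth_sidecar(truth, path)
  }
  out
}

#' Generate a Randles-circuit impedance spectrum with noise
#'
#' Simulates the equivalent circuit over a logarithmic frequency grid and
#' adds proportional complex Gaussian noise:
#' `Z + noise_fraction * |Z| * (e1 + i e2)`, `e ~ N(0, 1)`. The default
#' model mirrors the imprinted-film charge-transfer resistance preset
#' (2820 ohm).
#'
#' @param model A [randles_model()].
#' @param f_range Frequency range `c(min, max)`, Hz.
#' @param points_per_decade Sampling density.
#' @param noise_fraction Proportional noise level (0 = exact model).
#' @param seed Integer seed.
#' @param path Optional CSV path (`frequency,z_real,z_imag`).
#' @return An [eis_spectrum()] with attribute `truth` (the model).
#' @export
gen_eis <- function(model = randles_model(100, 2820, 2e-6, 0.9),
                    f_range = c(0.1, 1e5), points_per_decade = 10L,
                    noise_fraction = 0, seed = 1L, path = NULL) {
  set.seed(seed)
  n <- ceiling(log10(f_range[2] / f_range[1]) * points_per_decade) + 1L
  f <- 10^seq(log10(f_range[2]), log10(f_range[1]), length.out = n)
  z <- randles_impedance(model, f)
  if (noise_fraction > 0) {
    z <- z + noise_fraction * Mod(z) *
      complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  }
  out <- eis_spectrum(f, Re(z), Im(z))
  attr(out, "truth") <- model
  if (!is.null(path)) {
    utils::write.csv(data.frame(frequency = out$frequency,
                                z_real = out$z_real, z_imag = out$z_imag),
                     path, row.names = FALSE)
    write_truth_sidecar(model, path)
  }
  out
}

#' Generate a labelled bond-critical-point table
#'
#' Non-covalent rows follow the closed-shell signature (positive
#' Laplacian, `|H|` below 0.004 a.u., weakly negative `V`); covalent rows
#' have negative Laplacian and substantially negative `H`. Row labels are
#' recorded as ground truth.
#'
#' @param n_noncovalent,n_covalent Row counts.
#' @param seed Integer seed.
#' @param n_cavities Number of cavity ids to spread rows over.
#' @param path Optional CSV path; truth sidecar written alongside.
#' @return A `bcp_table` with attribute `truth` (character label vector).
#' @export
gen_bcp_table <- function(n_noncovalent = 15L, n_covalent = 5L, seed = 1L,
                          n_cavities = 3L, path = NULL) {
  set.seed(seed)
  n <- n_noncovalent + n_covalent
  if (n < 1L) stop("empty table requested")
  lab <- c(rep("non_covalent", n_noncovalent), rep("covalent", n_covalent))
  lap <- c(stats::runif(n_noncovalent, 0.02, 0.15),
           stats::runif(n_covalent, -0.8, -0.1))
  V <- c(stats::runif(n_noncovalent, -0.03, -0.002),
         stats::runif(n_covalent, -0.3, -0.05))
  H <- c(stats::runif(n_noncovalent, -0.004, 0.004),
         stats::runif(n_covalent, -0.1, -0.02))
  df <- data.frame(
    cavity_id = paste0("CAV", ((seq_len(n) - 1L) %% n_cavities) + 1L),
    atom_a = paste0("O", seq_len(n)),
    atom_b = paste0("N", seq_len(n)),
    rho = stats::runif(n, 0.005, 0.05),
    laplacian = lap, V = V, G = H - V, H = H
  )
  ord <- sample.int(n)
  df <- df[ord, , drop = FALSE]
  lab <- lab[ord]
  rownames(df) <- NULL
  df <- validate_bcp_table(df)
  attr(df, "truth") <- lab
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    write_truth_sidecar(list(label = lab), path)
  }
  df
}
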