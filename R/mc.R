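#' Specification of a Monte Carlo sampling run
#'
#' Collects every knob of the constant-NPT Metropolis sampler. Defaults
#' target 30--50 % acceptance for dense desk-scale boxes; the structural
#' defaults (two parallel chains, a snapshot every 500 production steps)
#' mirror the sampling protocol the cavity statistics are built on.
#'
#' @param temperature Temperature, K.
#' @param pressure Pressure, atm.
#' @param cutoff Molecule-based interaction cutoff, angstrom. Must stay
#'   below half the smallest box edge at all times.
#' @param max_translation Half-width of the uniform translation cube,
#'   angstrom.
#' @param max_rotation Maximum rotation angle, radians.
#' @param max_ln_volume_step Half-width of the uniform step in
#'   \eqn{\ln V}.
#' @param n_thermalization Unrecorded equilibration steps per chain.
#' @param n_production Recorded production steps per chain.
#' @param snapshot_stride Record one frame every this many production
#'   steps.
#' @param n_parallel_runs Number of independent chains.
#' @param rng_seed Integer master seed; per-chain seeds are derived from
#'   it deterministically.
#' @param volume_move_frequency Probability that a step proposes a volume
#'   move, in [0, 1); 0 disables volume moves (fixed-box sampling).
#' @return A `simulation_spec` object.
#' @seealso [run_simulation()], [metropolis_step()]
#' @export
simulation_spec <- function(temperature = 298, pressure = 1, cutoff = 10,
                            max_translation = 0.5, max_rotation = 0.35,
                            max_ln_volume_step = 0.02,
                            n_thermalization = 1000, n_production = 5000,
                            snapshot_stride = 500, n_parallel_runs = 2,
                            rng_seed = 1, volume_move_frequency = 0.02) {
  stopifnot(n_thermalization >= 0, n_production >= 0, snapshot_stride >= 1,
            n_parallel_runs >= 1, cutoff > 0,
            volume_move_frequency >= 0, volume_move_frequency < 1,
            max_translation > 0, max_rotation > 0, max_ln_volume_step > 0)
  structure(
    list(temperature = temperature, pressure = pressure, cutoff = cutoff,
         max_translation = max_translation, max_rotation = max_rotation,
         max_ln_volume_step = max_ln_volume_step,
         n_thermalization = as.integer(n_thermalization),
         n_production = as.integer(n_production),
         snapshot_stride = as.integer(snapshot_stride),
         n_parallel_runs = as.integer(n_parallel_runs),
         rng_seed = as.integer(rng_seed),
         volume_move_frequency = volume_move_frequency),
    class = "simulation_spec"
  )
}

#' Number of frames a sampling run records
#'
#' Each chain records one frame every `snapshot_stride` production steps,
#' so a run yields
#' `n_parallel_runs * floor(n_production / snapshot_stride)` frames.
#'
#' @param spec A [simulation_spec()].
#' @return Integer frame count.
#' @examples
#' expected_frame_count(simulation_spec(n_production = 154000,
#'   snapshot_stride = 500, n_parallel_runs = 2))  # 616
#' @export
expected_frame_count <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  spec$n_parallel_runs * (spec$n_production %/% spec$snapshot_stride)
}

# ---- internal move machinery ----------------------------------------------

# add site-pair parameter matrices for the vectorized total-energy path
add_pair_tables <- function(sys, max_sites = 1200L) {
  ns <- vapply(seq_along(sys$mol_topo), function(i)
    sys$topo[[sys$mol_topo[i]]]$ns, 0L)
  sys$site_mol <- rep(seq_along(ns), ns)
  S <- length(sys$site_mol)
  if (S <= max_sites) {
    sig <- unlist(lapply(sys$mol_topo, function(nm) sys$topo[[nm]]$sigma))
    eps <- unlist(lapply(sys$mol_topo, function(nm) sys$topo[[nm]]$epsilon))
    q <- unlist(lapply(sys$mol_topo, function(nm) sys$topo[[nm]]$charge))
    sys$SIG <- sqrt(outer(sig, sig))
    sys$EPS <- sqrt(outer(eps, eps))
    sys$QQ <- outer(q, q)
  }
  sys
}

total_energy_fast <- function(sys, overlap = "inf") {
  if (is.null(sys$SIG)) return(total_energy_sys(sys, overlap))
  n <- nrow(sys$cog)
  if (n < 2L) return(0)
  mol <- sys$site_mol
  X <- do.call(rbind, sys$xyz)
  Dx <- matrix(sys$cog[, 1], n, n, byrow = TRUE) - sys$cog[, 1]
  Dy <- matrix(sys$cog[, 2], n, n, byrow = TRUE) - sys$cog[, 2]
  Dz <- matrix(sys$cog[, 3], n, n, byrow = TRUE) - sys$cog[, 3]
  if (!is.null(sys$box)) {
    SHx <- -sys$box[1] * round(Dx / sys$box[1])
    SHy <- -sys$box[2] * round(Dy / sys$box[2])
    SHz <- -sys$box[3] * round(Dz / sys$box[3])
    W <- (Dx + SHx)^2 + (Dy + SHy)^2 + (Dz + SHz)^2 <= sys$cutoff^2
  } else {
    SHx <- SHy <- SHz <- matrix(0, n, n)
    W <- matrix(TRUE, n, n)
  }
  A1 <- X[, 1]; A2 <- X[, 2]; A3 <- X[, 3]
  dx <- outer(A1, A1, "-") - SHx[mol, mol]
  dy <- outer(A2, A2, "-") - SHy[mol, mol]
  dz <- outer(A3, A3, "-") - SHz[mol, mol]
  sel <- W[mol, mol] & outer(mol, mol, "<")
  r2 <- dx[sel]^2 + dy[sel]^2 + dz[sel]^2
  if (!length(r2)) return(0)
  r <- sqrt(r2)
  if (any(r < 1e-6)) {
    if (overlap == "inf") return(Inf)
    stop("overlapping sites (r < 1e-6 A)")
  }
  sij <- sys$SIG[sel]; eij <- sys$EPS[sel]; qq <- sys$QQ[sel]
  sr6 <- (sij / r)^6
  e <- sum(4 * eij * (sr6 * sr6 - sr6)) + .COULOMB * sum(qq / r)
  if (is.finite(sys$cutoff)) {
    sc6 <- (sij / sys$cutoff)^6
    e <- e - sum(4 * eij * (sc6 * sc6 - sc6))
  }
  e
}

# translate/rotate molecule i in place; returns updated sys
apply_translation <- function(sys, i, delta) {
  m <- sys$xyz[[i]]
  m[, 1] <- m[, 1] + delta[1]
  m[, 2] <- m[, 2] + delta[2]
  m[, 3] <- m[, 3] + delta[3]
  sys$xyz[[i]] <- m
  sys$pos[i, ] <- sys$pos[i, ] + delta
  sys$cog[i, ] <- sys$cog[i, ] + delta
  sys
}

apply_rotation <- function(sys, i, q) {
  r <- quat_to_matrix(q)
  cog <- sys$cog[i, ]
  m <- sys$xyz[[i]]
  m[, 1] <- m[, 1] - cog[1]
  m[, 2] <- m[, 2] - cog[2]
  m[, 3] <- m[, 3] - cog[3]
  m <- m %*% t(r)
  m[, 1] <- m[, 1] + cog[1]
  m[, 2] <- m[, 2] + cog[2]
  m[, 3] <- m[, 3] + cog[3]
  sys$xyz[[i]] <- m
  sys$pos[i, ] <- cog + as.numeric(r %*% (sys$pos[i, ] - cog))
  sys$quat[i, ] <- quat_normalize(quat_multiply(q, sys$quat[i, ]))
  sys
}

wrap_molecule <- function(sys, i) {
  shift <- -sys$box * floor(sys$cog[i, ] / sys$box)
  if (any(shift != 0)) {
    m <- sys$xyz[[i]]
    m[, 1] <- m[, 1] + shift[1]
    m[, 2] <- m[, 2] + shift[2]
    m[, 3] <- m[, 3] + shift[3]
    sys$xyz[[i]] <- m
    sys$pos[i, ] <- sys$pos[i, ] + shift
    sys$cog[i, ] <- sys$cog[i, ] + shift
  }
  sys
}

# one Metropolis step on a compiled system; U is the cached total energy
step_sys <- function(sys, spec, U) {
  n <- nrow(sys$pos)
  beta <- 1 / (.KB * spec$temperature)
  if (spec$volume_move_frequency > 0 &&
      stats::runif(1) < spec$volume_move_frequency) {
    delta <- stats::runif(1, -spec$max_ln_volume_step, spec$max_ln_volume_step)
    lam <- exp(delta / 3)
    newbox <- sys$box * lam
    if (spec$cutoff >= min(newbox) / 2) {
      return(list(sys = sys, U = U,
                  record = list(move_kind = "volume", accepted = FALSE,
                                delta_energy = NA_real_)))
    }
    old <- sys[c("xyz", "pos", "cog", "box")]
    shift <- sys$cog * (lam - 1)
    for (i in seq_len(n)) {
      m <- sys$xyz[[i]]
      m[, 1] <- m[, 1] + shift[i, 1]
      m[, 2] <- m[, 2] + shift[i, 2]
      m[, 3] <- m[, 3] + shift[i, 3]
      sys$xyz[[i]] <- m
    }
    sys$pos <- sys$pos + shift
    sys$cog <- sys$cog * lam
    sys$box <- newbox
    Unew <- total_energy_fast(sys)
    dU <- Unew - U
    Vold <- prod(old$box); Vnew <- prod(newbox)
    arg <- -beta * (dU + spec$pressure * .ATM_A3 * (Vnew - Vold)) +
      (n + 1) * delta
    if (is.finite(Unew) && (arg >= 0 || stats::runif(1) < exp(arg))) {
      return(list(sys = sys, U = Unew,
                  record = list(move_kind = "volume", accepted = TRUE,
                                delta_energy = dU)))
    }
    sys[c("xyz", "pos", "cog", "box")] <- old
    return(list(sys = sys, U = U,
                record = list(move_kind = "volume", accepted = FALSE,
                              delta_energy = dU)))
  }
  i <- sample.int(n, 1L)
  rotate <- stats::runif(1) < 0.5
  Eold <- mol_energy_sys(sys, i, overlap = "inf")
  old <- list(xyz = sys$xyz[[i]], pos = sys$pos[i, ], cog = sys$cog[i, ],
              quat = sys$quat[i, ])
  if (rotate) {
    axis <- stats::rnorm(3)
    angle <- stats::runif(1, -spec$max_rotation, spec$max_rotation)
    sys <- apply_rotation(sys, i, quat_from_axis_angle(axis, angle))
    kind <- "rotate"
  } else {
    delta <- stats::runif(3, -spec$max_translation, spec$max_translation)
    sys <- apply_translation(sys, i, delta)
    if (!is.null(sys$box)) sys <- wrap_molecule(sys, i)
    kind <- "translate"
  }
  Enew <- mol_energy_sys(sys, i, overlap = "inf")
  dU <- Enew - Eold
  acc <- is.finite(Enew) && (dU <= 0 || stats::runif(1) < exp(-beta * dU))
  if (!acc) {
    sys$xyz[[i]] <- old$xyz
    sys$pos[i, ] <- old$pos
    sys$cog[i, ] <- old$cog
    sys$quat[i, ] <- old$quat
    return(list(sys = sys, U = U,
                record = list(move_kind = kind, accepted = FALSE,
                              delta_energy = dU)))
  }
  list(sys = sys, U = U + dU,
       record = list(move_kind = kind, accepted = TRUE, delta_energy = dU))
}

#' Perform a single Metropolis Monte Carlo step
#'
#' With probability `volume_move_frequency` the step proposes a volume move
#' uniform in \eqn{\ln V} (coordinates scaled through molecule centres,
#' acceptance
#' \eqn{\min\{1, \exp(-\beta[\Delta U + P\Delta V] + (N+1)\ln(V'/V))\}});
#' otherwise a uniformly chosen molecule receives either a random
#' translation (uniform in a cube of half-width `max_translation`) or a
#' random rotation (uniform axis, angle uniform in `+-max_rotation`),
#' accepted with \eqn{\min\{1, \exp(-\beta\Delta U)\}}. A rejected move
#' returns the input configuration unchanged. A volume move that would
#' violate the cutoff invariant (`cutoff < min(box)/2`) is auto-rejected.
#'
#' Uses R's global random number stream; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param config A [configuration()].
#' @param spec A [simulation_spec()].
#' @return List with elements `configuration` (the new configuration) and
#'   `record` (a move record: `move_kind`, `accepted`, `delta_energy`).
#' @export
metropolis_step <- function(config, spec) {
  stopifnot(inherits(config, "configuration"), inherits(spec, "simulation_spec"))
  sys <- compile_system(config, spec$cutoff)
  sys$temperature <- spec$temperature
  sys$pressure <- spec$pressure
  sys <- add_pair_tables(sys)
  U <- total_energy_fast(sys)
  out <- step_sys(sys, spec, U)
  list(configuration = decompile_system(out$sys), record = out$record)
}

#' Run a constant-NPT Metropolis Monte Carlo simulation
#'
#' Runs `n_parallel_runs` logically independent chains whose seeds are
#' derived deterministically from `rng_seed` and the run index. Each chain
#' performs `n_thermalization` unrecorded steps followed by `n_production`
#' steps, recording a frame every `snapshot_stride` production steps.
#' Identical inputs and seed reproduce the trajectory bitwise.
#'
#' @param initial A [configuration()]; every chain starts from it.
#' @param spec A [simulation_spec()].
#' @return A `simulation_result` list: `frames` (list of
#'   [trajectory_frame()]; `n_parallel_runs * floor(n_production /
#'   snapshot_stride)` of them), `moves` (data frame of move records with
#'   run and step), and `spec`.
#' @export
run_simulation <- function(initial, spec) {
  stopifnot(inherits(initial, "configuration"), inherits(spec, "simulation_spec"))
  if (spec$cutoff >= min(initial$box) / 2)
    stop("cutoff must be smaller than half the smallest box edge")
  set.seed(spec$rng_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_parallel_runs)
  frames <- list()
  total_steps <- spec$n_thermalization + spec$n_production
  logs <- vector("list", spec$n_parallel_runs)
  for (run in seq_len(spec$n_parallel_runs)) {
    set.seed(run_seeds[run])
    sys <- compile_system(initial, spec$cutoff)
    sys$temperature <- spec$temperature
    sys$pressure <- spec$pressure
    sys <- add_pair_tables(sys)
    U <- total_energy_fast(sys)
    if (!is.finite(U))
      stop("initial configuration has overlapping sites")
    kind <- character(total_steps)
    acc <- logical(total_steps)
    dE <- numeric(total_steps)
    for (s in seq_len(total_steps)) {
      out <- step_sys(sys, spec, U)
      sys <- out$sys; U <- out$U
      kind[s] <- out$record$move_kind
      acc[s] <- out$record$accepted
      dE[s] <- out$record$delta_energy
      prod_step <- s - spec$n_thermalization
      if (prod_step >= 1L && prod_step %% spec$snapshot_stride == 0L) {
        frames[[length(frames) + 1L]] <-
          trajectory_frame(run, prod_step, decompile_system(sys), U)
      }
    }
    logs[[run]] <- data.frame(run_id = run, step = seq_len(total_steps),
                              move_kind = kind, accepted = acc,
                              delta_energy = dE)
  }
  structure(list(frames = frames, moves = do.call(rbind, logs), spec = spec),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  acc <- tapply(x$moves$accepted, x$moves$move_kind, mean)
  cat("<simulation_result> ", length(x$frames), " frame(s), ",
      nrow(x$moves), " moves; acceptance: ",
      paste(sprintf("%s %.1f%%", names(acc), 100 * acc), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Build a layered template/monomer/solvent starting configuration
#'
#' Places the monomers on a jittered lattice in the lower half of the box,
#' the solvent in the upper half, and the single template molecule at the
#' centre of the dividing plane -- the layered arrangement from which the
#' pre-polymerization sampling starts. The box edge is sized from the
#' total molar mass and `target_density`. Lattice spacing and jitter are
#' chosen so that no two sites of different molecules are closer than
#' `0.85 * sigma_ij` by construction.
#'
#' Uses R's global random stream (lattice-point shuffling, jitter,
#' orientations); seed with [set.seed()] for reproducibility.
#'
#' @param template,monomer,solvent [molecule_topology()] objects with the
#'   matching roles.
#' @param n_monomer,n_solvent Molecule counts (`>= 0`).
#' @param target_density Packing density for the initial box, g/cm^3.
#'   The default 0.35 lets the coarse-grained toy molecules pack without
#'   overlap; NPT sampling then relaxes the volume.
#' @param temperature,pressure State point stored in the configuration.
#' @param interface_gap Extra clearance between the monomer and solvent
#'   layers, angstrom.
#' @return A [configuration()].
#' @export
build_layered_initial <- function(template, monomer, solvent,
                                  n_monomer, n_solvent,
                                  target_density = 0.35,
                                  temperature = 298, pressure = 1,
                                  interface_gap = 1.0) {
  stopifnot(inherits(template, "molecule_topology"),
            template$role == "template",
            n_monomer >= 0, n_solvent >= 0, target_density > 0)
  if (n_monomer > 0) stopifnot(inherits(monomer, "molecule_topology"),
                               monomer$role == "monomer")
  if (n_solvent > 0) stopifnot(inherits(solvent, "molecule_topology"),
                               solvent$role == "solvent")
  mass <- topology_mass(template) +
    (if (n_monomer > 0) n_monomer * topology_mass(monomer) else 0) +
    (if (n_solvent > 0) n_solvent * topology_mass(solvent) else 0)
  vol <- mass * 1.66053906892 / target_density  # g/mol -> A^3 at density
  L <- vol^(1 / 3)
  topos <- list(template)
  if (n_monomer > 0) topos <- c(topos, list(monomer))
  if (n_solvent > 0) topos <- c(topos, list(solvent))
  names(topos) <- vapply(topos, function(t) t$name, "")
  sig_max <- max(unlist(lapply(topos, function(t)
    vapply(t$sites, function(s) s$sigma, 0))))
  rad_t <- topology_radius(template)
  center <- c(L / 2, L / 2, L / 2)
  poses <- list(molecule_pose(template$name, center))
  place_layer <- function(topo, count, z_lo, z_hi) {
    if (count == 0L) return(list())
    rad <- topology_radius(topo)
    sig_l <- max(vapply(topo$sites, function(s) s$sigma, 0))
    # clearance between two molecules of this layer, before jitter;
    # cross-layer contacts are covered by interface_gap and the template
    # by its exclusion sphere below
    clear <- 0.85 * sig_l + 2 * rad
    kxy <- floor(L / clear)
    kz <- floor((z_hi - z_lo) / clear)
    if (kxy < 1L || kz < 1L || kxy * kxy * kz < count)
      stop("cannot place ", count, " '", topo$name,
           "' molecules without overlap; lower target_density")
    sx <- L / kxy; sz <- (z_hi - z_lo) / kz
    jit <- max(0, min(0.3, 0.45 * (min(sx, sz) - clear)))
    grid <- expand.grid(x = (seq_len(kxy) - 0.5) * sx,
                        y = (seq_len(kxy) - 0.5) * sx,
                        z = z_lo + (seq_len(kz) - 0.5) * sz)
    excl <- rad_t + rad + 0.85 * sig_max
    d2 <- (grid$x - center[1])^2 + (grid$y - center[2])^2 +
      (grid$z - center[3])^2
    grid <- grid[d2 > excl^2, , drop = FALSE]
    if (nrow(grid) < count)
      stop("cannot place ", count, " '", topo$name,
           "' molecules after template exclusion; lower target_density")
    pick <- grid[sample.int(nrow(grid), count), , drop = FALSE]
    lapply(seq_len(count), function(k) {
      p <- as.numeric(pick[k, ]) + stats::runif(3, -jit, jit)
      q <- if (topo$n_sites > 1L) quat_random() else quat_identity()
      molecule_pose(topo$name, p, q)
    })
  }
  poses <- c(poses,
             place_layer(monomer, n_monomer, 0, L / 2 - interface_gap / 2),
             place_layer(solvent, n_solvent, L / 2 + interface_gap / 2, L))
  configuration(c(L, L, L), poses, topos,
                temperature = temperature, pressure = pressure)
}
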