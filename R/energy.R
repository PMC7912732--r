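# Internal compiled system representation and the nonbonded energy kernel.
#
# The pair potential is OPLS-style: 12-6 Lennard-Jones plus Coulomb over all
# site pairs of a molecule pair, with geometric-mean combining rules for
# both sigma and epsilon. Molecule pairs interact only when the
# minimum-image distance between their centres of geometry is within the
# cutoff (molecule-based cutoff: whole-molecule interactions switch
# together), and the LJ term is shifted by its value at the cutoff so the
# molecular interaction is truncated-and-shifted. Coulomb uses a straight
# cutoff at the same molecular distance.

compile_system <- function(config, cutoff = Inf) {
  compile_poses(config$poses, config$topologies, config$box, cutoff,
                config$temperature, config$pressure)
}

# box = NULL builds an isolated (non-periodic) system, as used for cavities
compile_poses <- function(poses, topologies, box = NULL, cutoff = Inf,
                          temperature = 298, pressure = 1) {
  config <- list(poses = poses, topologies = topologies, box = box,
                 temperature = temperature, pressure = pressure)
  topo <- lapply(config$topologies, function(t) {
    sv <- topology_site_vectors(t)
    list(local = topology_local_coords(t), sigma = sv$sigma,
         epsilon = sv$epsilon, charge = sv$charge, element = sv$element,
         ns = t$n_sites, role = t$role, name = t$name)
  })
  nmol <- length(config$poses)
  mol_topo <- vapply(config$poses, function(p) p$topology_ref, "")
  pos <- do.call(rbind, lapply(config$poses, function(p) p$position))
  quat <- do.call(rbind, lapply(config$poses, function(p) p$orientation))
  xyz <- vector("list", nmol)
  cog <- matrix(0, nmol, 3)
  for (i in seq_len(nmol)) {
    tc <- topo[[mol_topo[i]]]
    r <- quat_to_matrix(quat[i, ])
    m <- tc$local %*% t(r)
    m[, 1] <- m[, 1] + pos[i, 1]
    m[, 2] <- m[, 2] + pos[i, 2]
    m[, 3] <- m[, 3] + pos[i, 3]
    xyz[[i]] <- m
    cog[i, ] <- colMeans(m)
  }
  sys <- list(box = config$box, cutoff = cutoff,
              temperature = config$temperature, pressure = config$pressure,
              topo = topo, mol_topo = mol_topo, pos = pos, quat = quat,
              xyz = xyz, cog = cog, topologies = config$topologies)
  sys
}

decompile_system <- function(sys) {
  poses <- lapply(seq_along(sys$mol_topo), function(i)
    molecule_pose(sys$mol_topo[i], sys$pos[i, ],
                  quat_normalize(sys$quat[i, ])))
  configuration(sys$box, poses, sys$topologies,
                temperature = sys$temperature, pressure = sys$pressure)
}

# site-site LJ + Coulomb sum between two site sets; B already shifted to
# the minimum image of A's molecule. Returns Inf for overlapping sites
# when overlap = "inf", otherwise errors.
site_set_energy <- function(A, B, ta, tb, cutoff, overlap = "error",
                            pair_id = NULL) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(r < 1e-6)) {
    if (overlap == "inf") return(Inf)
    stop("overlapping sites (r < 1e-6 A)",
         if (!is.null(pair_id)) paste0(" between molecules ", pair_id) else "")
  }
  sij <- sqrt(outer(ta$sigma, tb$sigma))
  eij <- sqrt(outer(ta$epsilon, tb$epsilon))
  sr6 <- (sij / r)^6
  e <- sum(4 * eij * (sr6 * sr6 - sr6)) +
    .COULOMB * sum(outer(ta$charge, tb$charge) / r)
  if (is.finite(cutoff)) {
    sc6 <- (sij / cutoff)^6
    e <- e - sum(4 * eij * (sc6 * sc6 - sc6))
  }
  e
}

mol_pair_energy_sys <- function(sys, i, j, overlap = "error") {
  d <- sys$cog[j, ] - sys$cog[i, ]
  shift <- c(0, 0, 0)
  if (!is.null(sys$box)) {
    shift <- -sys$box * round(d / sys$box)
    d <- d + shift
  }
  if (sqrt(sum(d * d)) > sys$cutoff) return(0)
  B <- sys$xyz[[j]]
  if (any(shift != 0)) {
    B[, 1] <- B[, 1] + shift[1]
    B[, 2] <- B[, 2] + shift[2]
    B[, 3] <- B[, 3] + shift[3]
  }
  site_set_energy(sys$xyz[[i]], B, sys$topo[[sys$mol_topo[i]]],
                  sys$topo[[sys$mol_topo[j]]], sys$cutoff, overlap,
                  pair_id = paste(i, "and", j))
}

# energy of molecule i against all others (or a subset)
mol_energy_sys <- function(sys, i, overlap = "error") {
  n <- nrow(sys$pos)
  if (n < 2L) return(0)
  others <- setdiff(seq_len(n), i)
  if (!is.null(sys$box) && is.finite(sys$cutoff)) {
    d1 <- sys$cog[others, 1] - sys$cog[i, 1]
    d2 <- sys$cog[others, 2] - sys$cog[i, 2]
    d3 <- sys$cog[others, 3] - sys$cog[i, 3]
    d1 <- d1 - sys$box[1] * round(d1 / sys$box[1])
    d2 <- d2 - sys$box[2] * round(d2 / sys$box[2])
    d3 <- d3 - sys$box[3] * round(d3 / sys$box[3])
    others <- others[d1 * d1 + d2 * d2 + d3 * d3 <= sys$cutoff^2]
  }
  e <- 0
  for (j in others) {
    ej <- mol_pair_energy_sys(sys, i, j, overlap)
    if (!is.finite(ej)) return(ej)
    e <- e + ej
  }
  e
}

total_energy_sys <- function(sys, overlap = "error") {
  n <- nrow(sys$pos)
  e <- 0
  if (n < 2L) return(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    eij <- mol_pair_energy_sys(sys, i, j, overlap)
    if (!is.finite(eij)) return(eij)
    e <- e + eij
  }
  e
}

#' Intermolecular pair energy between two molecules
#'
#' Sum over all site pairs of the 12-6 Lennard-Jones term
#' \eqn{4\epsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]} (shifted by
#' its value at the cutoff when the cutoff is finite) plus the Coulomb term
#' \eqn{C q_i q_j / r}, with geometric-mean combining rules for both
#' \eqn{\sigma} and \eqn{\epsilon} and minimum-image distances. The pair is
#' skipped entirely (energy 0) when the minimum-image distance between the
#' two molecules' centres of geometry exceeds `cutoff`.
#'
#' @param config A [configuration()].
#' @param a,b Pose indices (1-based), `a != b`.
#' @param cutoff Molecule-based interaction cutoff, angstrom. `Inf` disables
#'   truncation and shifting.
#' @return Energy in kcal/mol. Errors if any site pair is closer than
#'   1e-6 angstrom.
#' @examples
#' lj <- molecule_topology("lj", "solvent",
#'   list(site_params("A", "O", 3.0, 0.5, 0)))
#' cfg <- configuration(c(20, 20, 20),
#'   list(molecule_pose("lj", c(5, 5, 5)), molecule_pose("lj", c(8, 5, 5))),
#'   list(lj = lj))
#' pair_energy(cfg, 1, 2)  # r = sigma: LJ term is zero
#' @export
pair_energy <- function(config, a, b, cutoff = Inf) {
  stopifnot(inherits(config, "configuration"))
  n <- length(config$poses)
  if (a == b) stop("pair_energy requires a != b")
  if (a < 1 || a > n || b < 1 || b > n) stop("pose index out of range")
  sys <- compile_system(config, cutoff)
  mol_pair_energy_sys(sys, a, b)
}

#' Total intermolecular energy of a configuration
#'
#' Sum of [pair_energy()] over all unordered molecule pairs.
#'
#' @inheritParams pair_energy
#' @return Energy in kcal/mol; 0 for a single molecule.
#' @export
total_energy <- function(config, cutoff = Inf) {
  stopifnot(inherits(config, "configuration"))
  total_energy_sys(compile_system(config, cutoff))
}
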