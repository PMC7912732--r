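# Independent brute-force oracles and small toy builders shared by tests.
# The oracles deliberately re-derive everything from first principles
# (plain double loops, no package internals).

COULOMB_K <- 332.06371

lj_topology <- function(name = "lj", sigma = 3, epsilon = 0.5, charge = 0,
                        role = "solvent") {
  molecule_topology(name, role,
                    list(site_params("A", "O", sigma, epsilon, charge)))
}

# random multi-site topology for oracle comparisons
random_topology <- function(name, n_sites, role = "monomer") {
  sites <- lapply(seq_len(n_sites), function(k)
    site_params(paste0("S", k), sample(c("C", "N", "O"), 1),
                runif(1, 2.5, 3.8), runif(1, 0.05, 0.4),
                runif(1, -0.3, 0.3),
                if (k == 1) c(0, 0, 0) else runif(3, -1.2, 1.2)))
  molecule_topology(name, role, sites)
}

random_configuration <- function(n_mol = 5, box = c(18, 20, 22),
                                 n_sites = 3) {
  topos <- list()
  poses <- list()
  for (i in seq_len(n_mol)) {
    nm <- paste0("mol", i)
    topos[[nm]] <- random_topology(nm, n_sites)
    poses[[i]] <- molecule_pose(nm, runif(3, 0, min(box)),
                                emip:::quat_random())
  }
  configuration(box, poses, topos)
}

# all site coordinates + parameters of a configuration, for brute force
config_sites <- function(config) {
  out <- list()
  for (i in seq_along(config$poses)) {
    p <- config$poses[[i]]
    topo <- config$topologies[[p$topology_ref]]
    xyz <- pose_site_coords(p, topo)
    for (k in seq_len(topo$n_sites)) {
      s <- topo$sites[[k]]
      out[[length(out) + 1L]] <- list(mol = i, xyz = xyz[k, ],
                                      sigma = s$sigma, epsilon = s$epsilon,
                                      charge = s$charge)
    }
  }
  out
}

# brute-force pair energy: explicit double loop over sites, molecule-based
# minimum image through centres of geometry, truncated-shifted LJ
oracle_pair_energy <- function(config, a, b, cutoff = Inf) {
  pa <- config$poses[[a]]; pb <- config$poses[[b]]
  ta <- config$topologies[[pa$topology_ref]]
  tb <- config$topologies[[pb$topology_ref]]
  A <- pose_site_coords(pa, ta); B <- pose_site_coords(pb, tb)
  box <- config$box
  d <- colMeans(B) - colMeans(A)
  shift <- -box * round(d / box)
  if (sqrt(sum((d + shift)^2)) > cutoff) return(0)
  e <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    r <- sqrt(sum((A[i, ] - (B[j, ] + shift))^2))
    sij <- sqrt(ta$sites[[i]]$sigma * tb$sites[[j]]$sigma)
    eij <- sqrt(ta$sites[[i]]$epsilon * tb$sites[[j]]$epsilon)
    lj <- 4 * eij * ((sij / r)^12 - (sij / r)^6)
    if (is.finite(cutoff))
      lj <- lj - 4 * eij * ((sij / cutoff)^12 - (sij / cutoff)^6)
    e <- e + lj +
      COULOMB_K * ta$sites[[i]]$charge * tb$sites[[j]]$charge / r
  }
  e
}

oracle_total_energy <- function(config, cutoff = Inf) {
  n <- length(config$poses)
  e <- 0
  if (n < 2) return(0)
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    e <- e + oracle_pair_energy(config, a, b, cutoff)
  e
}

# brute-force first-shell membership: per-site minimum image, double loop
oracle_shell_members <- function(frame, shell_cutoff) {
  cfg <- frame$configuration
  roles <- vapply(cfg$poses, function(p)
    cfg$topologies[[p$topology_ref]]$role, "")
  ti <- which(roles == "template")
  txyz <- pose_site_coords(cfg$poses[[ti]],
                           cfg$topologies[[cfg$poses[[ti]]$topology_ref]])
  members <- integer()
  for (mi in which(roles == "monomer")) {
    mxyz <- pose_site_coords(cfg$poses[[mi]],
                             cfg$topologies[[cfg$poses[[mi]]$topology_ref]])
    found <- FALSE
    for (i in seq_len(nrow(txyz))) for (j in seq_len(nrow(mxyz))) {
      dv <- txyz[i, ] - mxyz[j, ]
      dv <- dv - cfg$box * round(dv / cfg$box)
      if (sqrt(sum(dv^2)) <= shell_cutoff) found <- TRUE
    }
    if (found) members <- c(members, mi)
  }
  members
}
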