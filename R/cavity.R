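#' Pre-polymerization cavity: a template plus its first monomer shell
#'
#' A cavity is the template molecule together with the functional monomers
#' of its first solvation shell, extracted from one trajectory frame. Its
#' binding energy (negative = stabilizing) is the total intermolecular
#' interaction energy of the isolated complex; with rigid molecules the
#' isolated-molecule reference energies are zero, so no subtraction is
#' needed.
#'
#' @param template_pose [molecule_pose()] of the template.
#' @param monomer_poses List of [molecule_pose()]s of the shell monomers
#'   (possibly empty).
#' @param topologies Named list of the referenced [molecule_topology()]s.
#' @param run_id,step Provenance: chain and production step of the source
#'   frame.
#' @param stage Pipeline stage tag.
#' @param binding_energy Energy in kcal/mol, `NA` until scored.
#' @return A `cavity` object with element `n_monomers`.
#' @export
cavity <- function(template_pose, monomer_poses, topologies,
                   run_id = NA_integer_, step = NA_integer_,
                   stage = c("extracted", "relaxed_stage1",
                             "relaxed_stage2", "final_scored"),
                   binding_energy = NA_real_) {
  stage <- match.arg(stage)
  stopifnot(inherits(template_pose, "molecule_pose"))
  for (p in monomer_poses)
    if (!inherits(p, "molecule_pose")) stop("monomer_poses must be poses")
  if (stage != "extracted" && !is.finite(binding_energy))
    stop("binding_energy must be finite once a cavity is relaxed")
  structure(
    list(template_pose = template_pose, monomer_poses = monomer_poses,
         n_monomers = length(monomer_poses), topologies = topologies,
         run_id = run_id, step = step, stage = stage,
         binding_energy = binding_energy),
    class = "cavity"
  )
}

#' @export
print.cavity <- function(x, ...) {
  cat("<cavity> ", x$n_monomers, " monomer(s), stage ", x$stage,
      if (is.finite(x$binding_energy))
        sprintf(", E = %.4f kcal/mol (|E| = %.4f)", x$binding_energy,
                abs(x$binding_energy)) else "",
      ", from run ", x$run_id, " step ", x$step, "\n", sep = "")
  invisible(x)
}

cavity_system <- function(cav) {
  compile_poses(c(list(cav$template_pose), cav$monomer_poses),
                cav$topologies, box = NULL, cutoff = Inf)
}

#' Extract the first monomer solvation shell around the template
#'
#' A monomer belongs to the first shell when the minimum over all
#' site--site pairs of the minimum-image distance to any template site is
#' at most `shell_cutoff`. Solvent molecules are ignored. Shell members
#' are stored unwrapped relative to the template (shifted by whole box
#' vectors) so the cavity is a connected, isolated complex.
#'
#' @param frame A [trajectory_frame()] whose configuration contains
#'   exactly one template molecule.
#' @param shell_cutoff Shell distance cutoff, angstrom. The default 4.0 is
#'   a typical first-minimum position of a template--monomer contact
#'   distance distribution; see [shell_cutoff_from_rdf()] to derive it
#'   from the trajectory itself.
#' @return A [cavity()] at stage `"extracted"`; `n_monomers` may be 0.
#' @export
extract_first_shell <- function(frame, shell_cutoff = 4.0) {
  stopifnot(inherits(frame, "trajectory_frame"), shell_cutoff > 0)
  cfg <- frame$configuration
  roles <- vapply(cfg$poses, function(p)
    cfg$topologies[[p$topology_ref]]$role, "")
  ti <- which(roles == "template")
  if (length(ti) != 1L)
    stop("frame must contain exactly one template molecule, found ",
         length(ti))
  box <- cfg$box
  tpose <- cfg$poses[[ti]]
  txyz <- pose_site_coords(tpose, cfg$topologies[[tpose$topology_ref]])
  tcog <- colMeans(txyz)
  monomers <- list()
  for (mi in which(roles == "monomer")) {
    p <- cfg$poses[[mi]]
    mxyz <- pose_site_coords(p, cfg$topologies[[p$topology_ref]])
    dx <- outer(txyz[, 1], mxyz[, 1], "-")
    dy <- outer(txyz[, 2], mxyz[, 2], "-")
    dz <- outer(txyz[, 3], mxyz[, 3], "-")
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
    if (min(dx * dx + dy * dy + dz * dz) <= shell_cutoff^2) {
      # unwrap the member next to the template (molecule-based image)
      shift <- -box * round((colMeans(mxyz) - tcog) / box)
      p$position <- p$position + shift
      monomers[[length(monomers) + 1L]] <- p
    }
  }
  cavity(tpose, monomers, cfg$topologies,
         run_id = frame$run_id, step = frame$step)
}

#' Derive the first-shell cutoff from the contact-distance distribution
#'
#' Histograms the per-monomer minimum template--monomer site distances
#' over a trajectory, smooths the histogram with a centred moving average,
#' and returns the location of the first local minimum after the first
#' peak, refined by a 3-point parabolic fit. This is the conventional
#' operational definition of the first solvation shell boundary (first
#' minimum of the radial distribution of contact distances).
#'
#' @param x Either a list of at least 10 [trajectory_frame()]s, or a
#'   numeric vector of contact distances (angstrom).
#' @param bin_width Histogram bin width, angstrom.
#' @param smooth Moving-average window (odd integer, bins).
#' @return Cutoff distance in angstrom. Errors when the histogram has no
#'   interior minimum (monotone or structureless distribution), in which
#'   case a manual cutoff must be supplied.
#' @export
shell_cutoff_from_rdf <- function(x, bin_width = 0.15, smooth = 5) {
  if (is.numeric(x)) {
    d <- x
  } else {
    if (length(x) < 10L)
      stop("need at least 10 frames to estimate the shell cutoff")
    d <- unlist(lapply(x, function(frame) {
      cfg <- frame$configuration
      roles <- vapply(cfg$poses, function(p)
        cfg$topologies[[p$topology_ref]]$role, "")
      ti <- which(roles == "template")
      if (length(ti) != 1L) stop("frame must contain exactly one template")
      txyz <- pose_site_coords(cfg$poses[[ti]],
                               cfg$topologies[[cfg$poses[[ti]]$topology_ref]])
      vapply(which(roles == "monomer"), function(mi) {
        p <- cfg$poses[[mi]]
        mxyz <- pose_site_coords(p, cfg$topologies[[p$topology_ref]])
        dx <- outer(txyz[, 1], mxyz[, 1], "-")
        dy <- outer(txyz[, 2], mxyz[, 2], "-")
        dz <- outer(txyz[, 3], mxyz[, 3], "-")
        dx <- dx - cfg$box[1] * round(dx / cfg$box[1])
        dy <- dy - cfg$box[2] * round(dy / cfg$box[2])
        dz <- dz - cfg$box[3] * round(dz / cfg$box[3])
        sqrt(min(dx * dx + dy * dy + dz * dz))
      }, 0)
    }))
  }
  if (length(d) < 20L) stop("too few distances to build a histogram")
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  s <- as.numeric(stats::filter(h$counts, rep(1 / smooth, smooth),
                                sides = 2))
  s[is.na(s)] <- 0
  mids <- h$mids
  n <- length(s)
  peak <- NA_integer_
  for (i in 2:(n - 1)) {
    if (s[i] >= s[i - 1] && s[i] > s[i + 1] && s[i] >= 0.1 * max(s)) {
      peak <- i; break
    }
  }
  if (is.na(peak))
    stop("no interior minimum found (no leading peak); ",
         "supply the shell cutoff manually")
  trough <- NA_integer_
  for (i in (peak + 1L):(n - 1L)) {
    if (s[i] <= s[i - 1] && s[i] < s[i + 1] && s[i] <= 0.8 * s[peak] &&
        any(s[(i + 1L):n] >= 1.2 * max(s[i], 1e-12))) {
      trough <- i; break
    }
  }
  if (is.na(trough))
    stop("no interior minimum found after the first peak; ",
         "supply the shell cutoff manually")
  # parabolic refinement over the smoothed histogram
  y <- s[(trough - 1L):(trough + 1L)]
  denom <- y[1] - 2 * y[2] + y[3]
  offset <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
  mids[trough] + offset * bin_width
}

#' Relax a cavity by greedy rigid-body coordinate descent
#'
#' Minimizes the intermolecular energy of the isolated cavity (no
#' periodicity) by cycling over per-molecule rigid translations and
#' rotations along each axis, keeping only energy-lowering moves, with
#' step sizes halved whenever a full cycle improves the energy by less
#' than the stage tolerance. The two stages form a coarse-to-fine
#' hierarchy: `"stage1"` converges to 1e-2 kcal/mol per cycle, `"stage2"`
#' to 1e-4. Energy is monotone non-increasing by construction.
#'
#' @param cav A [cavity()]; stage order is enforced (`stage2` requires a
#'   `stage1`-relaxed input).
#' @param scorer `"stage1"` or `"stage2"`.
#' @param max_iterations Maximum descent cycles.
#' @return The relaxed cavity with updated poses, advanced `stage` and
#'   `binding_energy` set.
#' @export
relax_cavity <- function(cav, scorer = c("stage1", "stage2"),
                         max_iterations = 200) {
  scorer <- match.arg(scorer)
  stopifnot(inherits(cav, "cavity"))
  if (scorer == "stage2" &&
      !cav$stage %in% c("relaxed_stage1", "relaxed_stage2"))
    stop("stage2 relaxation requires a stage1-relaxed cavity")
  tol <- if (scorer == "stage1") 1e-2 else 1e-4
  sys <- cavity_system(cav)
  n <- nrow(sys$pos)
  U <- total_energy_sys(sys)  # errors on overlapping sites, naming the pair
  if (!is.finite(U)) stop("non-finite cavity energy")
  t_step <- 0.25
  r_step <- 0.15
  axes <- diag(3)
  for (iter in seq_len(max_iterations)) {
    U0 <- U
    for (i in seq_len(n)) {
      Ei <- mol_energy_sys(sys, i)
      for (ax in 1:3) for (sgn in c(1, -1)) {
        trial <- apply_translation(sys, i, sgn * t_step * axes[ax, ])
        Et <- mol_energy_sys(trial, i, overlap = "inf")
        if (Et < Ei) { sys <- trial; U <- U + (Et - Ei); Ei <- Et }
      }
      if (sys$topo[[sys$mol_topo[i]]]$ns > 1L) {
        for (ax in 1:3) for (sgn in c(1, -1)) {
          trial <- apply_rotation(sys, i,
                                  quat_from_axis_angle(axes[ax, ],
                                                       sgn * r_step))
          Et <- mol_energy_sys(trial, i, overlap = "inf")
          if (Et < Ei) { sys <- trial; U <- U + (Et - Ei); Ei <- Et }
        }
      }
    }
    if (U0 - U < tol) {
      if (t_step < 1e-4) break
      t_step <- t_step / 2
      r_step <- r_step / 2
    }
  }
  poses <- lapply(seq_len(n), function(i)
    molecule_pose(sys$mol_topo[i], sys$pos[i, ],
                  quat_normalize(sys$quat[i, ])))
  cavity(poses[[1]], poses[-1], cav$topologies,
         run_id = cav$run_id, step = cav$step,
         stage = if (scorer == "stage1") "relaxed_stage1" else
           "relaxed_stage2",
         binding_energy = U)
}

#' Binding energy of a cavity
#'
#' `E(complex) - E(template) - sum E(monomer)`. With rigid molecules the
#' isolated-molecule terms vanish, so the binding energy equals the total
#' intermolecular interaction energy of the isolated cavity (no cutoff,
#' no periodicity). Negative values are stabilizing; reports also quote
#' the magnitude `|E|`.
#'
#' @param cav A [cavity()].
#' @return Energy in kcal/mol; 0 for an empty shell.
#' @export
binding_energy <- function(cav) {
  stopifnot(inherits(cav, "cavity"))
  if (cav$n_monomers == 0L) return(0)
  total_energy_sys(cavity_system(cav))
}

#' Two-stage energy-cutoff funnel specification
#'
#' Stage 1 keeps, within each monomer-count group, the cavities within
#' `stage1_cutoff` of that group's minimum (default 10 kcal/mol); stage 2
#' keeps the survivors within `stage2_cutoff` of the overall minimum
#' (default 5 kcal/mol). Both cuts are inclusive (`<=`). `group_range`
#' restricts the analysis to the representative monomer counts.
#'
#' @param stage1_cutoff,stage2_cutoff Energy windows, kcal/mol (> 0).
#' @param group_range Inclusive monomer-count interval `c(lo, hi)`.
#' @return A `funnel_spec` object.
#' @export
funnel_spec <- function(stage1_cutoff = 10, stage2_cutoff = 5,
                        group_range = c(18, 23)) {
  stopifnot(stage1_cutoff > 0, stage2_cutoff > 0,
            length(group_range) == 2L, group_range[1] <= group_range[2])
  structure(list(stage1_cutoff = stage1_cutoff,
                 stage2_cutoff = stage2_cutoff,
                 group_range = as.integer(group_range)),
            class = "funnel_spec")
}

#' Energy-window survivors of a funnel stage
#'
#' Pure threshold rule of the funnel: an entry survives when its energy
#' lies within `cutoff` of the reference minimum, inclusively. With
#' `group` given, the minimum is taken per group (stage-1 semantics, so
#' each group's minimum always survives its own cut); without it, the
#' minimum is global (stage-2 semantics).
#'
#' @param energy Numeric energies, kcal/mol (lower = more stable).
#' @param cutoff Energy window, kcal/mol.
#' @param group Optional grouping vector (e.g. monomer counts).
#' @return Logical vector of survivors.
#' @examples
#' funnel_survivors(c(0, 9.9, 10.1), 10)  # TRUE TRUE FALSE
#' @export
funnel_survivors <- function(energy, cutoff, group = NULL) {
  stopifnot(is.numeric(energy), cutoff > 0)
  if (is.null(group)) return(energy <= min(energy) + cutoff)
  ref <- stats::ave(energy, group, FUN = min)
  energy <= ref + cutoff
}

#' Run the two-stage relax-and-cut funnel over extracted cavities
#'
#' Implements the selection pipeline: (1) group cavities by monomer
#' count; (2) restrict to `group_range`; (3) relax every member with the
#' coarse stage-1 scorer and keep those within `stage1_cutoff` of their
#' group minimum; (4) relax the survivors with the fine stage-2 scorer
#' and keep those within `stage2_cutoff` of the overall minimum; (5)
#' rescore the final survivors with a single-point energy; (6) report,
#' per group, the most stable cavity and the counts surviving each stage.
#' Ties for "most stable" break towards fewer monomers, then the earlier
#' provenance step.
#'
#' @param cavities List of [cavity()] objects (stage `"extracted"`, or
#'   pre-scored when `relax = FALSE`).
#' @param spec A [funnel_spec()].
#' @param relax When `FALSE`, skip geometry relaxation and use each
#'   cavity's stored `binding_energy` for both cuts (useful for funnel
#'   logic on externally scored sets).
#' @param max_iterations Descent cycles per relaxation.
#' @return A `funnel_report`: `groups` data frame (`n_monomers`,
#'   `n_extracted`, `n_stage1`, `n_stage2`, `best_energy`, `best_step`),
#'   `selected` (final cavities, stage `"final_scored"`), and
#'   `n_stage1_total`.
#' @export
funnel_select <- function(cavities, spec = funnel_spec(), relax = TRUE,
                          max_iterations = 200) {
  stopifnot(inherits(spec, "funnel_spec"))
  if (!length(cavities)) {
    warning("no cavities supplied; empty funnel report")
    return(empty_funnel_report())
  }
  sizes <- vapply(cavities, function(cv) cv$n_monomers, 0L)
  keep <- sizes >= spec$group_range[1] & sizes <= spec$group_range[2]
  if (!any(keep)) {
    warning("group_range excludes all cavities; empty funnel report")
    return(empty_funnel_report())
  }
  cavities <- cavities[keep]
  sizes <- sizes[keep]
  if (relax) {
    cavities <- lapply(cavities, relax_cavity, scorer = "stage1",
                       max_iterations = max_iterations)
  } else {
    for (cv in cavities)
      if (!is.finite(cv$binding_energy))
        stop("relax = FALSE requires finite binding_energy on every cavity")
  }
  e1 <- vapply(cavities, function(cv) cv$binding_energy, 0)
  s1 <- funnel_survivors(e1, spec$stage1_cutoff, group = sizes)
  surv1 <- cavities[s1]
  sizes1 <- sizes[s1]
  if (relax)
    surv1 <- lapply(surv1, relax_cavity, scorer = "stage2",
                    max_iterations = max_iterations)
  e2 <- vapply(surv1, function(cv) cv$binding_energy, 0)
  s2 <- funnel_survivors(e2, spec$stage2_cutoff)
  final <- surv1[s2]
  sizes2 <- sizes1[s2]
  final <- lapply(final, function(cv) {
    cv$binding_energy <- if (relax) binding_energy(cv) else cv$binding_energy
    cv$stage <- "final_scored"
    cv
  })
  ef <- vapply(final, function(cv) cv$binding_energy, 0)
  groups <- sort(unique(sizes))
  gdf <- data.frame(
    n_monomers = groups,
    n_extracted = vapply(groups, function(g) sum(sizes == g), 0L),
    n_stage1 = vapply(groups, function(g) sum(sizes1 == g), 0L),
    n_stage2 = vapply(groups, function(g) sum(sizes2 == g), 0L),
    best_energy = NA_real_, best_step = NA_integer_
  )
  for (k in seq_along(groups)) {
    idx <- which(sizes2 == groups[k])
    if (length(idx)) {
      steps <- vapply(final[idx], function(cv) as.integer(cv$step), 0L)
      ord <- order(ef[idx], steps)
      gdf$best_energy[k] <- ef[idx][ord[1]]
      gdf$best_step[k] <- steps[ord[1]]
    }
  }
  structure(list(groups = gdf, selected = final,
                 n_stage1_total = sum(s1)),
            class = "funnel_report")
}

empty_funnel_report <- function() {
  structure(list(groups = data.frame(n_monomers = integer(),
                                     n_extracted = integer(),
                                     n_stage1 = integer(),
                                     n_stage2 = integer(),
                                     best_energy = numeric(),
                                     best_step = integer()),
                 selected = list(), n_stage1_total = 0L),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> ", x$n_stage1_total, " stage-1 survivor(s), ",
      length(x$selected), " final cavity(ies)\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Population statistics of cavities by monomer count
#'
#' Counts cavities per monomer-count group and reports each group's
#' fraction of all extracted cavities. Fractions sum to 1.
#'
#' @param x List of [cavity()] objects, or an integer vector of monomer
#'   counts.
#' @return A `cavity_population` data frame with columns `n_monomers`,
#'   `count`, `fraction`, and attribute `total`.
#' @seealso [population_share()]
#' @export
population_report <- function(x) {
  sizes <- if (is.numeric(x)) as.integer(x)
  else vapply(x, function(cv) {
    stopifnot(inherits(cv, "cavity")); cv$n_monomers
  }, 0L)
  if (!length(sizes)) stop("no cavities to report on")
  tab <- table(sizes)
  out <- data.frame(n_monomers = as.integer(names(tab)),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / length(sizes))
  attr(out, "total") <- length(sizes)
  class(out) <- c("cavity_population", "data.frame")
  out
}

#' Combined population share of a monomer-count interval
#'
#' @param report A [population_report()] result.
#' @param range Inclusive monomer-count interval `c(lo, hi)`.
#' @return The summed fraction of the groups inside the interval, in
#'   `[0, 1]`.
#' @examples
#' rep <- population_report(c(19L, 19L, 20L, 21L, 25L))
#' population_share(rep, c(19, 21))  # 0.8
#' @export
population_share <- function(report, range) {
  stopifnot(inherits(report, "cavity_population"), length(range) == 2L)
  sel <- report$n_monomers >= range[1] & report$n_monomers <= range[2]
  sum(report$fraction[sel])
}
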