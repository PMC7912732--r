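#' Pose of one rigid molecule instance
#'
#' @param topology_ref Name of the topology this pose instantiates.
#' @param position Numeric length-3 body-frame origin in box coordinates,
#'   angstrom.
#' @param orientation Unit quaternion `(w, x, y, z)`; defaults to identity.
#' @return A `molecule_pose` object.
#' @export
molecule_pose <- function(topology_ref, position, orientation = c(1, 0, 0, 0)) {
  position <- as.numeric(position); orientation <- as.numeric(orientation)
  stopifnot(is.character(topology_ref), length(position) == 3L,
            length(orientation) == 4L)
  if (!all(is.finite(position))) stop("pose position must be finite")
  nrm <- sqrt(sum(orientation^2))
  if (abs(nrm - 1) > 1e-9)
    stop("pose orientation must be a unit quaternion (|q| - 1| = ",
         format(abs(nrm - 1)), ")")
  structure(list(topology_ref = topology_ref, position = position,
                 orientation = orientation),
            class = "molecule_pose")
}

#' Periodic simulation box configuration
#'
#' An orthorhombic periodic box holding rigid-molecule poses at a state
#' point. Pose positions are wrapped into `[0, box)` on construction
#' (molecule-based wrapping: a molecule's sites move with its origin and
#' are never split across the boundary).
#'
#' @param box Positive length-3 edge lengths, angstrom.
#' @param poses List of [molecule_pose()] objects.
#' @param topologies Named list of [molecule_topology()] objects covering
#'   every `topology_ref` used by `poses`.
#' @param temperature Temperature, K.
#' @param pressure Pressure, atm.
#' @return A `configuration` object.
#' @seealso [wrap_configuration()], [total_energy()]
#' @export
configuration <- function(box, poses, topologies, temperature = 298,
                          pressure = 1) {
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive edge lengths")
  if (!is.list(poses)) stop("poses must be a list of molecule_pose objects")
  for (p in poses)
    if (!inherits(p, "molecule_pose"))
      stop("poses must be molecule_pose objects")
  if (is.null(names(topologies)))
    names(topologies) <- vapply(topologies, function(t) t$name, "")
  refs <- vapply(poses, function(p) p$topology_ref, "")
  missing <- setdiff(unique(refs), names(topologies))
  if (length(missing))
    stop("poses reference undefined topologies: ",
         paste(missing, collapse = ", "))
  roles <- vapply(topologies, function(t) t$role, "")
  n_templ <- sum(refs %in% names(topologies)[roles == "template"])
  if (n_templ > 1L)
    stop("a configuration may contain at most one template molecule, got ",
         n_templ)
  obj <- structure(
    list(box = box, poses = poses, topologies = topologies,
         temperature = as.numeric(temperature),
         pressure = as.numeric(pressure)),
    class = "configuration"
  )
  wrap_configuration(obj)
}

#' Wrap molecule positions into the primary box image
#'
#' Molecule-based wrapping: each pose position is translated by whole box
#' vectors into `[0, box)`. Re-wrapping an already wrapped configuration
#' is the identity.
#'
#' @param config A [configuration()].
#' @return The wrapped configuration.
#' @export
wrap_configuration <- function(config) {
  stopifnot(inherits(config, "configuration"))
  box <- config$box
  config$poses <- lapply(config$poses, function(p) {
    p$position <- p$position - box * floor(p$position / box)
    p
  })
  config
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration> box ", paste(sprintf("%.3f", x$box), collapse = " x "),
      " A, ", length(x$poses), " molecule(s), T = ", x$temperature,
      " K, P = ", x$pressure, " atm\n", sep = "")
  invisible(x)
}

#' One recorded frame of a trajectory
#'
#' @param run_id Integer id of the Markov chain that produced the frame.
#' @param step Production step index at which the frame was recorded
#'   (`>= 0`).
#' @param config The [configuration()] at that step.
#' @param potential_energy Total intermolecular potential energy, kcal/mol.
#' @return A `trajectory_frame` object; its `volume` element is the box
#'   volume in cubic angstrom.
#' @export
trajectory_frame <- function(run_id, step, config, potential_energy) {
  stopifnot(inherits(config, "configuration"))
  step <- as.integer(step)
  if (is.na(step) || step < 0L) stop("step must be an integer >= 0")
  structure(
    list(run_id = as.integer(run_id), step = step, configuration = config,
         potential_energy = as.numeric(potential_energy),
         volume = prod(config$box)),
    class = "trajectory_frame"
  )
}
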