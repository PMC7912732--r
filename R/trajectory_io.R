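#' Write and read trajectories in the package's extended-XYZ dialect
#'
#' One XYZ block per frame. The first line is the number of site rows, the
#' comment line carries `run_id`, `step`, the box edges, the potential
#' energy (kcal/mol), temperature and pressure as `key=value` pairs, and
#' each site row holds `element x y z mol topology`, with seven extra
#' fields (`px py pz qw qx qy qz`) appended on a molecule's first site
#' carrying the exact pose. Numbers are printed with full double
#' precision, so `read_trajectory(write_trajectory(x))` reproduces poses,
#' coordinates and energies exactly (well inside 1e-9).
#'
#' @param frames Non-empty list of [trajectory_frame()] objects with
#'   monotone increasing `step` within each `run_id`.
#' @param path File path.
#' @param topologies Named list of [molecule_topology()] objects; needed on
#'   read because XYZ blocks reference topologies by name.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a list of `trajectory_frame`s.
#' @export
write_trajectory <- function(frames, path) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of trajectory_frame objects")
  for (f in frames)
    if (!inherits(f, "trajectory_frame"))
      stop("frames must be trajectory_frame objects")
  runs <- vapply(frames, function(f) f$run_id, 0L)
  steps <- vapply(frames, function(f) f$step, 0L)
  for (r in unique(runs)) {
    s <- steps[runs == r]
    if (any(diff(s) <= 0))
      stop("non-monotone step indices within run_id ", r)
  }
  con <- file(path, "w")
  on.exit(close(con))
  g <- function(x) sprintf("%.17g", x)
  for (f in frames) {
    cfg <- f$configuration
    nsite <- sum(vapply(cfg$poses, function(p)
      cfg$topologies[[p$topology_ref]]$n_sites, 0L))
    writeLines(as.character(nsite), con)
    writeLines(paste0(
      "run_id=", f$run_id, " step=", f$step,
      " box=", g(cfg$box[1]), ",", g(cfg$box[2]), ",", g(cfg$box[3]),
      " energy=", g(f$potential_energy),
      " temp=", g(cfg$temperature), " press=", g(cfg$pressure)), con)
    for (i in seq_along(cfg$poses)) {
      p <- cfg$poses[[i]]
      topo <- cfg$topologies[[p$topology_ref]]
      xyz <- pose_site_coords(p, topo)
      sv <- topology_site_vectors(topo)
      for (k in seq_len(topo$n_sites)) {
        extra <- if (k == 1L)
          paste("", g(p$position[1]), g(p$position[2]), g(p$position[3]),
                g(p$orientation[1]), g(p$orientation[2]),
                g(p$orientation[3]), g(p$orientation[4]))
        else ""
        writeLines(paste0(sv$element[k], " ", g(xyz[k, 1]), " ",
                          g(xyz[k, 2]), " ", g(xyz[k, 3]), " ", i, " ",
                          topo$name, extra), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, topologies) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (is.null(names(topologies)))
    names(topologies) <- vapply(topologies, function(t) t$name, "")
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nsite <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nsite) || nsite < 1L)
      stop("line ", i, ": expected site count, got '", lines[i], "'")
    if (i + 1L + nsite > length(lines) + 1L)
      stop("line ", i, ": frame block truncated")
    meta <- parse_frame_comment(lines[i + 1L], i + 1L)
    rows <- lines[(i + 2L):(i + 1L + nsite)]
    poses <- list()
    cur_mol <- -1L
    for (ri in seq_along(rows)) {
      fields <- strsplit(trimws(rows[ri]), "\\s+")[[1]]
      if (!length(fields) %in% c(6L, 13L))
        stop("line ", i + 1L + ri, ": malformed site row")
      mol <- as.integer(fields[5])
      if (mol != cur_mol) {
        if (length(fields) != 13L)
          stop("line ", i + 1L + ri,
               ": first site of molecule ", mol, " must carry pose fields")
        topo_name <- fields[6]
        if (is.null(topologies[[topo_name]]))
          stop("line ", i + 1L + ri, ": unknown topology '", topo_name, "'")
        num <- as.numeric(fields[7:13])
        poses[[mol]] <- molecule_pose(topo_name, num[1:3],
                                      quat_normalize(num[4:7]))
        cur_mol <- mol
      }
    }
    cfg <- configuration(meta$box, poses, topologies,
                         temperature = meta$temp, pressure = meta$press)
    frames[[length(frames) + 1L]] <-
      trajectory_frame(meta$run_id, meta$step, cfg, meta$energy)
    i <- i + 2L + nsite
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

parse_frame_comment <- function(line, lineno) {
  kv <- strsplit(trimws(line), "\\s+")[[1]]
  out <- list()
  for (tok in kv) {
    parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", lineno, ": malformed comment token '", tok, "'")
    out[[parts[1]]] <- parts[2]
  }
  for (f in c("run_id", "step", "box", "energy"))
    if (is.null(out[[f]]))
      stop("line ", lineno, ": comment line missing '", f, "'")
  box <- as.numeric(strsplit(out$box, ",", fixed = TRUE)[[1]])
  if (length(box) != 3L || anyNA(box))
    stop("line ", lineno, ": malformed box edges")
  list(run_id = as.integer(out$run_id), step = as.integer(out$step),
       box = box, energy = as.numeric(out$energy),
       temp = if (is.null(out$temp)) 298 else as.numeric(out$temp),
       press = if (is.null(out$press)) 1 else as.numeric(out$press))
}

#' Site coordinates of a pose in box coordinates
#'
#' @param pose A [molecule_pose()].
#' @param topology The [molecule_topology()] it references.
#' @return `n_sites x 3` numeric matrix, angstrom.
#' @export
pose_site_coords <- function(pose, topology) {
  local <- topology_local_coords(topology)
  r <- quat_to_matrix(pose$orientation)
  sweep(local %*% t(r), 2, pose$position, "+")
}
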