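#' Interaction-site parameters for a rigid molecule
#'
#' One row of a molecule's site table: an OPLS-style nonbonded site with a
#' Lennard-Jones diameter and well depth, a fixed partial charge, and a
#' position in the molecule's body frame.
#'
#' @param label Short site label (e.g. `"N1"`).
#' @param element Chemical element symbol; used for molar mass lookups and
#'   trajectory output.
#' @param sigma Lennard-Jones diameter, angstrom. Must be positive.
#' @param epsilon Lennard-Jones well depth, kcal/mol. Must be non-negative.
#' @param charge Partial charge, elementary charge units.
#' @param local_position Numeric length-3 position in the body frame, angstrom.
#' @return A `site_params` object (named list).
#' @seealso [molecule_topology()]
#' @export
site_params <- function(label, element, sigma, epsilon, charge,
                        local_position = c(0, 0, 0)) {
  stopifnot(is.character(label), length(label) == 1L,
            is.character(element), length(element) == 1L)
  sigma <- as.numeric(sigma); epsilon <- as.numeric(epsilon)
  charge <- as.numeric(charge)
  local_position <- as.numeric(local_position)
  if (!is.finite(sigma) || sigma <= 0)
    stop("site '", label, "': sigma must be > 0")
  if (!is.finite(epsilon) || epsilon < 0)
    stop("site '", label, "': epsilon must be >= 0")
  if (length(local_position) != 3L || !all(is.finite(local_position)))
    stop("site '", label, "': local_position must be a finite 3-vector")
  structure(
    list(label = label, element = element, sigma = sigma, epsilon = epsilon,
         charge = charge, local_position = local_position),
    class = "site_params"
  )
}

#' Rigid molecular topology
#'
#' A molecule is rigid: its interaction sites have fixed body-frame
#' coordinates and only the molecule's position and orientation change
#' during sampling. Each topology has a role in the imprinting system:
#' the `template` (the analyte being imprinted), a functional `monomer`,
#' or `solvent`.
#'
#' @param name Topology name; referenced by poses and trajectory files.
#' @param role One of `"template"`, `"monomer"`, `"solvent"`.
#' @param sites List of [site_params()] objects (at least one).
#' @param net_charge Total molecular charge, elementary charges. Must match
#'   the sum of site charges to within 1e-6.
#' @return A `molecule_topology` object.
#' @examples
#' m <- molecule_topology("lj", "solvent",
#'   list(site_params("A", "O", 3.0, 0.1, 0)), net_charge = 0)
#' m$n_sites
#' @export
molecule_topology <- function(name, role, sites, net_charge = NULL) {
  role <- match.arg(role, c("template", "monomer", "solvent"))
  if (!is.list(sites) || length(sites) < 1L)
    stop("topology '", name, "': needs at least 1 site")
  sites <- lapply(sites, function(s) {
    if (!inherits(s, "site_params"))
      stop("topology '", name, "': sites must be site_params objects")
    s
  })
  qsum <- sum(vapply(sites, function(s) s$charge, 0))
  if (is.null(net_charge)) net_charge <- qsum
  if (abs(net_charge - qsum) > 1e-6)
    stop("topology '", name, "': net_charge (", net_charge,
         ") does not equal the sum of site charges (", qsum, ")")
  obj <- structure(
    list(name = name, role = role, sites = sites,
         net_charge = net_charge, n_sites = length(sites)),
    class = "molecule_topology"
  )
  obj
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat("<molecule_topology> ", x$name, " (", x$role, "), ",
      x$n_sites, " site(s), net charge ", format(x$net_charge), " e\n",
      sep = "")
  invisible(x)
}

# body-frame site coordinate matrix (n_sites x 3)
topology_local_coords <- function(topo) {
  do.call(rbind, lapply(topo$sites, function(s) s$local_position))
}

topology_site_vectors <- function(topo) {
  list(
    sigma   = vapply(topo$sites, function(s) s$sigma, 0),
    epsilon = vapply(topo$sites, function(s) s$epsilon, 0),
    charge  = vapply(topo$sites, function(s) s$charge, 0),
    element = vapply(topo$sites, function(s) s$element, ""),
    label   = vapply(topo$sites, function(s) s$label, "")
  )
}

# largest body-frame site radius; used for packing clearances
topology_radius <- function(topo) {
  max(sqrt(rowSums(topology_local_coords(topo)^2)))
}

topology_mass <- function(topo) {
  sum(element_mass(vapply(topo$sites, function(s) s$element, "")))
}

.num10 <- function(x) sprintf("%.10g", x)

#' Write / read a molecular topology file
#'
#' Topologies are stored in a small documented text dialect: a header of
#' `key value` lines (`name`, `role`, `net_charge`, `sites`), a column
#' header line, and one whitespace-separated row per site with columns
#' `label element sigma epsilon charge x y z` (angstrom, kcal/mol,
#' elementary charges). Numbers are printed with `%.10g`, so
#' `write_topology()` followed by [read_topology()] round-trips exactly.
#'
#' @param topology A [molecule_topology()] object.
#' @param path File path.
#' @return `write_topology()` returns `path` invisibly; `read_topology()`
#'   returns a validated `molecule_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "molecule_topology"))
  lines <- c(
    "# emip topology v1",
    paste("name", topology$name),
    paste("role", topology$role),
    paste("net_charge", .num10(topology$net_charge)),
    paste("sites", topology$n_sites),
    "label element sigma epsilon charge x y z",
    vapply(topology$sites, function(s) {
      paste(s$label, s$element, .num10(s$sigma), .num10(s$epsilon),
            .num10(s$charge), .num10(s$local_position[1]),
            .num10(s$local_position[2]), .num10(s$local_position[3]))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lnum <- which(keep)
  lines <- lines[keep]
  header <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^(name|role|net_charge|sites) ", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2L)
      stop("line ", lnum[i], ": malformed header field '", lines[i], "'")
    header[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  for (f in c("name", "role", "net_charge", "sites"))
    if (is.null(header[[f]]))
      stop("missing header field '", f, "'")
  n_sites <- suppressWarnings(as.integer(header$sites))
  if (is.na(n_sites) || n_sites < 1L)
    stop("header field 'sites' must be a positive integer")
  if (i > length(lines) ||
      !identical(strsplit(trimws(lines[i]), "\\s+")[[1]],
                 c("label", "element", "sigma", "epsilon", "charge",
                   "x", "y", "z")))
    stop("line ", if (i <= length(lines)) lnum[i] else NA,
         ": expected site table header ",
         "'label element sigma epsilon charge x y z'")
  i <- i + 1L
  if (length(lines) - i + 1L < n_sites)
    stop("site table truncated: expected ", n_sites, " rows")
  sites <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    fields <- strsplit(trimws(lines[i + k - 1L]), "\\s+")[[1]]
    if (length(fields) != 8L)
      stop("line ", lnum[i + k - 1L], ": site row needs 8 fields, got ",
           length(fields))
    num <- suppressWarnings(as.numeric(fields[3:8]))
    if (anyNA(num))
      stop("line ", lnum[i + k - 1L], ": non-numeric value in field '",
           c("sigma", "epsilon", "charge", "x", "y", "z")[which(is.na(num))[1]],
           "'")
    sites[[k]] <- site_params(fields[1], fields[2], num[1], num[2], num[3],
                              num[4:6])
  }
  nq <- suppressWarnings(as.numeric(header$net_charge))
  if (is.na(nq)) stop("header field 'net_charge' is not numeric")
  molecule_topology(header$name, header$role, sites, net_charge = nq)
}
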