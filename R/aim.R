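#' Read a bond-critical-point property table
#'
#' The CSV schema (all properties in atomic units) has mandatory columns
#' `cavity_id`, `atom_a` (template atom), `atom_b` (monomer atom), `rho`
#' (electron density at the BCP), `laplacian` (\eqn{\nabla^2\rho}), `V`
#' (potential-energy density), and optional `G` (kinetic-energy density)
#' and `H` (total-energy density). `H` is computed as `V + G` when absent;
#' when both `G` and `H` are present the identity `H = V + G` is checked
#' to 1e-6 a.u.
#'
#' @param path CSV file path.
#' @return A validated `bcp_table` data frame.
#' @seealso [classify_interaction()], [espinosa_be()]
#' @export
read_bcp_table <- function(path) {
  if (!file.exists(path)) stop("BCP table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_bcp_table(df)
}

validate_bcp_table <- function(df) {
  mandatory <- c("cavity_id", "atom_a", "atom_b", "rho", "laplacian", "V")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("BCP table missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in intersect(c("rho", "laplacian", "V", "G", "H"), names(df))) {
    if (!is.numeric(df[[col]]))
      stop("BCP column '", col, "' contains non-numeric cells")
    if (anyNA(df[[col]]))
      stop("BCP column '", col, "' contains missing values")
  }
  if (any(df$rho <= 0))
    stop("rho must be positive at every bond critical point (row ",
         which(df$rho <= 0)[1], ")")
  has_g <- "G" %in% names(df)
  has_h <- "H" %in% names(df)
  if (!has_h && !has_g)
    stop("BCP table needs at least one of columns 'G' or 'H'")
  if (!has_h) df$H <- df$V + df$G
  if (!has_g) df$G <- df$H - df$V
  bad <- abs(df$H - (df$V + df$G)) > 1e-6
  if (any(bad))
    stop("inconsistent energy densities |H - (V + G)| > 1e-6 a.u. (row ",
         which(bad)[1], ")")
  class(df) <- c("bcp_table", "data.frame")
  df
}

#' Classify a bond-critical-point interaction
#'
#' Closed-shell (non-covalent) contacts have a positive Laplacian of the
#' electron density and a total-energy density close to zero; shared
#' (covalent) interactions have a negative Laplacian. The "close to zero"
#' tolerance `h_tol` defaults to 0.005 a.u., a typical QTAIM practice
#' threshold. Anything else (positive Laplacian but substantial `|H|`) is
#' flagged ambiguous.
#'
#' @param x A `bcp_table` (or any data frame with `laplacian` and `H`
#'   columns), or a single record as a list.
#' @param h_tol Tolerance on `|H|` for the non-covalent call, a.u.
#' @return Character vector with levels `"non_covalent"`, `"covalent"`,
#'   `"ambiguous"`.
#' @export
classify_interaction <- function(x, h_tol = 0.005) {
  if (is.list(x) && !is.data.frame(x)) x <- as.data.frame(x)
  stopifnot(all(c("laplacian", "H") %in% names(x)), h_tol > 0)
  ifelse(x$laplacian < 0, "covalent",
         ifelse(x$laplacian > 0 & abs(x$H) <= h_tol, "non_covalent",
                "ambiguous"))
}

#' Espinosa binding energy from the potential-energy density
#'
#' \deqn{BE = V(r)/2,} converted from hartree to kcal/mol (factor
#' 627.5095). The sign is preserved: `V < 0` gives a negative (attractive,
#' stabilizing) binding energy.
#'
#' @param x A `bcp_table`, a data frame with a `V` column, or a numeric
#'   vector of potential-energy densities in a.u.
#' @return Binding energies in kcal/mol.
#' @examples
#' espinosa_be(-0.02)  # -6.275095
#' @export
espinosa_be <- function(x) {
  v <- if (is.numeric(x)) x else {
    if (is.list(x) && !is.data.frame(x)) x <- as.data.frame(x)
    stopifnot("V" %in% names(x))
    x$V
  }
  v / 2 * .HARTREE
}

#' Per-cavity summary of non-covalent interactions
#'
#' Classifies every record, computes Espinosa binding energies, and
#' aggregates per cavity: the number of non-covalent contacts, the summed
#' binding energy and the mean magnitude `|BE|` (individual closed-shell
#' contacts are weak; it is their number that stabilizes the template in
#' the cavity). A `TOTAL` row aggregates over all cavities.
#'
#' @param df A `bcp_table` (see [read_bcp_table()]).
#' @param h_tol Passed to [classify_interaction()].
#' @return Data frame with columns `cavity_id`, `n_noncovalent`,
#'   `sum_be_kcal`, `mean_abs_be_kcal`.
#' @export
cavity_interaction_summary <- function(df, h_tol = 0.005) {
  df <- validate_bcp_table(as.data.frame(df))
  if (!nrow(df)) stop("empty BCP table")
  cls <- classify_interaction(df, h_tol)
  be <- espinosa_be(df)
  ids <- unique(df$cavity_id)
  rows <- lapply(ids, function(id) {
    sel <- df$cavity_id == id & cls == "non_covalent"
    data.frame(cavity_id = id,
               n_noncovalent = sum(sel),
               sum_be_kcal = sum(be[sel]),
               mean_abs_be_kcal = if (any(sel)) mean(abs(be[sel])) else NA_real_)
  })
  out <- do.call(rbind, rows)
  total_sel <- cls == "non_covalent"
  rbind(out, data.frame(
    cavity_id = "TOTAL",
    n_noncovalent = sum(total_sel),
    sum_be_kcal = sum(be[total_sel]),
    mean_abs_be_kcal = if (any(total_sel)) mean(abs(be[total_sel]))
    else NA_real_))
}

#' Annotate a BCP table with classification and binding energies
#'
#' @inheritParams cavity_interaction_summary
#' @return The table with added `classification` and `BE` (kcal/mol)
#'   columns.
#' @export
annotate_bcp_table <- function(df, h_tol = 0.005) {
  df <- validate_bcp_table(as.data.frame(df))
  df$classification <- classify_interaction(df, h_tol)
  df$BE <- espinosa_be(df)
  df
}
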