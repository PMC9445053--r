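#' Chromophore objects
#'
#' A \code{chromophore} carries an ordered set of atoms (element symbols and
#' Cartesian coordinates in Å), per-atom masses (Da), and optionally one
#' transition charge per atom in units of the elementary charge e. The
#' transition charges are the atomic representation of the molecule's
#' electronic transition density: their first moment about any origin is the
#' transition dipole, provided they sum to zero.
#'
#' Invariants enforced at construction: at least one atom; coordinates,
#' masses and charges finite; one charge per atom; and, when charges are
#' set, \eqn{|\sum_i q_i| \le} \code{charge_sum_tol} (a non-zero net
#' transition charge would make the transition dipole origin-dependent).
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param xyz Numeric matrix with one row per atom and 3 columns (Å).
#' @param charges Optional numeric vector of transition charges (e).
#' @param name Identifier used in reports.
#' @param masses Optional numeric vector of masses (Da); defaults to
#'   standard atomic masses looked up from \code{elements}.
#' @param charge_sum_tol Tolerance on \eqn{|\sum q_i|} (e), default 1e-4.
#' @return An object of class \code{"chromophore"}: a list with components
#'   \code{name}, \code{elements}, \code{xyz}, \code{charges}, \code{masses}.
#' @examples
#' chm <- chromophore(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)),
#'                    charges = c(0.1, -0.1))
#' transition_dipole(chm)
#' @export
chromophore <- function(elements, xyz, charges = NULL, name = "chromophore",
                        masses = NULL, charge_sum_tol = 1e-4) {
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3)
    stop("'xyz' must be an n x 3 matrix of coordinates", call. = FALSE)
  n <- nrow(xyz)
  if (n < 1) stop("empty structure: a chromophore needs at least one atom",
                  call. = FALSE)
  if (length(elements) != n)
    stop("length(elements) must equal nrow(xyz)", call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates", call. = FALSE)
  if (is.null(masses)) masses <- atomic_mass(elements)
  if (length(masses) != n || !all(is.finite(masses)) || any(masses <= 0))
    stop("'masses' must be ", n, " finite positive values", call. = FALSE)
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n)
      stop("need one transition charge per atom: got ", length(charges),
           " charges for ", n, " atoms", call. = FALSE)
    if (!all(is.finite(charges)))
      stop("non-finite transition charges", call. = FALSE)
    if (abs(sum(charges)) > charge_sum_tol)
      stop(sprintf(
        "net transition charge %.3e e exceeds tolerance %.1e e", sum(charges),
        charge_sum_tol), call. = FALSE)
  }
  structure(
    list(name = name, elements = as.character(elements), xyz = unname(xyz),
         charges = charges, masses = as.numeric(masses)),
    class = "chromophore"
  )
}

#' @export
print.chromophore <- function(x, ...) {
  cat("chromophore '", x$name, "': ", nrow(x$xyz), " atoms, charges ",
      if (is.null(x$charges)) "unset" else
        sprintf("set (sum %.2e e)", sum(x$charges)),
      "\n", sep = "")
  invisible(x)
}

#' Environment (protein) atom model for clash testing
#'
#' Holds the Cartesian positions (Å) of all environment atoms considered in
#' steric clash tests. May be empty, in which case nothing can clash.
#'
#' @param positions Numeric matrix with one row per atom and 3 columns (Å);
#'   a 0-row matrix is a valid empty environment.
#' @param source Free-text provenance tag.
#' @return An object of class \code{"environment_model"}.
#' @examples
#' env <- environment_model(matrix(numeric(0), 0, 3))
#' clash_test(make_point_dipole(), env, cutoff = 1)
#' @export
environment_model <- function(positions, source = "user") {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  if (ncol(positions) != 3)
    stop("'positions' must have 3 columns", call. = FALSE)
  if (nrow(positions) > 0 && !all(is.finite(positions)))
    stop("non-finite environment coordinates", call. = FALSE)
  structure(list(positions = unname(positions), source = source),
            class = "environment_model")
}

#' @export
print.environment_model <- function(x, ...) {
  cat("environment_model: ", nrow(x$positions), " atoms (", x$source, ")\n",
      sep = "")
  invisible(x)
}

#' Mass-weighted centre of mass
#'
#' @param chrom A \code{\link{chromophore}}.
#' @param selection Optional integer vector of 1-based atom indices defining
#'   the subset to average over (e.g. the atoms of a pi-conjugated plane);
#'   default is all atoms.
#' @return Numeric length-3 vector (Å).
#' @examples
#' chm <- chromophore(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
#' center_of_mass(chm)           # c(1, 0, 0)
#' center_of_mass(chm, 1L)       # position of atom 1
#' @export
center_of_mass <- function(chrom, selection = NULL) {
  stopifnot(inherits(chrom, "chromophore"))
  if (is.null(selection)) selection <- seq_len(nrow(chrom$xyz))
  if (length(selection) == 0)
    stop("empty atom selection", call. = FALSE)
  if (any(selection < 1) || any(selection > nrow(chrom$xyz)))
    stop("selection indices out of range 1..", nrow(chrom$xyz), call. = FALSE)
  m <- chrom$masses[selection]
  drop(crossprod(chrom$xyz[selection, , drop = FALSE], m)) / sum(m)
}

# vector helpers -------------------------------------------------------------

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Evaluate expr with a deterministic, locally scoped RNG state: the global
# .Random.seed is restored afterwards so generators never leak into, or
# depend on, ambient random state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
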