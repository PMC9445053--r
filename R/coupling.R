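#' Transition dipole moment from atomic transition charges
#'
#' Computes \eqn{\mu = \sum_i q_i r_i} in e·Å. The result is independent of
#' the coordinate origin only when the charges sum to zero, so a net charge
#' beyond \code{charge_sum_tol} is an error rather than a silent
#' origin-dependent answer.
#'
#' @param chrom A \code{\link{chromophore}} with charges set.
#' @param charge_sum_tol Maximum tolerated \eqn{|\sum q_i|} (e).
#' @return Numeric length-3 vector, the transition dipole in e·Å.
#' @examples
#' chm <- make_point_dipole(q = 0.1, delta = 2, direction = c(0, 0, 1))
#' transition_dipole(chm)  # c(0, 0, 0.2)
#' @export
transition_dipole <- function(chrom, charge_sum_tol = 1e-4) {
  stopifnot(inherits(chrom, "chromophore"))
  if (is.null(chrom$charges))
    stop("transition charges are unset on '", chrom$name, "'", call. = FALSE)
  if (abs(sum(chrom$charges)) > charge_sum_tol)
    stop(sprintf(
      "net transition charge %.3e e makes the dipole origin-dependent",
      sum(chrom$charges)), call. = FALSE)
  drop(crossprod(chrom$xyz, chrom$charges))
}

.check_unit <- function(e_hat, tol = 1e-9) {
  if (length(e_hat) != 3 || abs(.vnorm(e_hat) - 1) > tol)
    stop("'e_hat' must be a unit 3-vector (|e| = 1 within ", tol, ")",
         call. = FALSE)
  e_hat
}

#' Signed orientation factor kappa of the dipole-dipole interaction
#'
#' \deqn{\kappa = \hat\mu_D\cdot\hat\mu_A -
#'   3(\hat\mu_D\cdot\hat e)(\hat\mu_A\cdot\hat e),}
#' where \eqn{\hat e} is the unit vector joining the donor and acceptor
#' reference points. \eqn{\kappa^2 \in [0, 4]}: 4 for collinear
#' head-to-tail dipoles, 1 for parallel dipoles perpendicular to the
#' separation axis, 0 for mutually orthogonal arrangements.
#'
#' @param mu_D,mu_A Donor and acceptor transition dipoles (3-vectors, any
#'   consistent unit; only directions matter).
#' @param e_hat Unit vector from donor to acceptor reference point.
#' @return The signed scalar \eqn{\kappa}; square it for the orientation
#'   factor.
#' @examples
#' kappa_factor(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))  # -2 (head-to-tail)
#' kappa_factor(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1))  # +1
#' @export
kappa_factor <- function(mu_D, mu_A, e_hat) {
  if (.vnorm(mu_D) == 0 || .vnorm(mu_A) == 0)
    stop("zero-norm transition dipole", call. = FALSE)
  .check_unit(e_hat)
  d <- .unit(mu_D)
  a <- .unit(mu_A)
  sum(d * a) - 3 * sum(d * e_hat) * sum(a * e_hat)
}

#' Angles between the transition dipoles and the separation axis
#'
#' Returns the three angles that parameterize the orientation factor:
#' \eqn{\theta_{DA}} between the two dipoles, \eqn{\theta_D} between the
#' donor dipole and the separation unit vector, and \eqn{\theta_A} between
#' the acceptor dipole and the separation unit vector. In terms of these,
#' \eqn{\kappa^2 = (\cos\theta_{DA} - 3\cos\theta_D\cos\theta_A)^2}.
#' Arc-cosine arguments are clamped to [-1, 1] to absorb rounding.
#'
#' @inheritParams kappa_factor
#' @return Named numeric vector \code{c(theta_DA, theta_D, theta_A)} in
#'   degrees, each in [0, 180].
#' @export
dipole_angles <- function(mu_D, mu_A, e_hat) {
  if (.vnorm(mu_D) == 0 || .vnorm(mu_A) == 0)
    stop("zero-norm transition dipole", call. = FALSE)
  .check_unit(e_hat)
  d <- .unit(mu_D)
  a <- .unit(mu_A)
  ang <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi
  c(theta_DA = ang(sum(d * a)),
    theta_D = ang(sum(d * e_hat)),
    theta_A = ang(sum(a * e_hat)))
}

.coupling_result <- function(value, method, n_screen, donor_id, acceptor_id) {
  structure(list(value = value, method = method, n_screen = n_screen,
                 donor_id = donor_id, acceptor_id = acceptor_id),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("%s coupling %s -> %s: %.4f cm^-1 (n = %.3g)\n",
              x$method, x$donor_id, x$acceptor_id, x$value, x$n_screen))
  invisible(x)
}

#' Dipole-dipole (point-dipole) electronic coupling
#'
#' Leading multipole term of the Coulomb coupling between two transition
#' densities, treated as point dipoles at their reference points:
#' \deqn{V^{DD} = \frac{|\mu_D||\mu_A|\,\kappa}{4\pi\varepsilon_0 n^2
#'   R_{DA}^3},}
#' evaluated in cm\eqn{^{-1}} with dipoles in e·Å and distances in Å via
#' the pinned Coulomb constant (see \code{\link{fret_constants}}). The
#' optional \eqn{1/n^2} factor is the refractive-index screening of the
#' medium.
#'
#' @param mu_D,mu_A Transition dipoles in e·Å.
#' @param r_D,r_A Reference points (Å) at which the dipoles sit.
#' @param n_screen Refractive index in the \eqn{1/n^2} prefactor
#'   (default 1, i.e. unscreened).
#' @param donor_id,acceptor_id Labels carried into the result.
#' @return A \code{coupling_result} with \code{method = "DD"}; the value is
#'   signed (the sign is \eqn{\kappa}'s).
#' @export
dd_coupling <- function(mu_D, mu_A, r_D, r_A, n_screen = 1,
                        donor_id = "D", acceptor_id = "A") {
  if (n_screen <= 0) stop("n_screen must be positive", call. = FALSE)
  sep <- r_A - r_D
  R <- .vnorm(sep)
  if (R == 0) stop("zero donor-acceptor separation", call. = FALSE)
  k <- kappa_factor(mu_D, mu_A, sep / R)
  cc <- fret_constants()
  v <- cc$coulomb_cm1_angstrom * .vnorm(mu_D) * .vnorm(mu_A) * k /
    (n_screen^2 * R^3)
  .coupling_result(v, "DD", n_screen, donor_id, acceptor_id)
}

# Defining brute-force double sum of q_i q_j / r_ij over all donor-acceptor
# atom pairs (e^2/Angstrom, no prefactor). Errors on near-coincident atoms.
.tresp_sum <- function(donor, acceptor, min_dist = 1e-6) {
  A <- donor$xyz
  B <- acceptor$xyz
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  if (any(d2 < min_dist^2))
    stop("singular distance: donor and acceptor atoms closer than ",
         min_dist, " Angstrom", call. = FALSE)
  sum(outer(donor$charges, acceptor$charges) / sqrt(d2))
}

#' TrESP electronic coupling from atomic transition charges
#'
#' Classical Coulomb interaction between the two sets of transition
#' charges:
#' \deqn{V^{TrESP} = \frac{1}{4\pi\varepsilon_0 n^2}
#'   \sum_{i\in D}\sum_{j\in A} \frac{q_i q_j}{r_{ij}},}
#' in cm\eqn{^{-1}} with charges in e and distances in Å. Unlike the
#' point-dipole approximation this multi-centre sum retains all higher
#' multipole orders of the two densities, and remains accurate when the
#' separation is comparable to the molecular size. The brute-force double
#' sum over all atom pairs is the defining semantics.
#'
#' @param donor,acceptor \code{\link{chromophore}} objects with charges set.
#' @param n_screen Refractive index in the \eqn{1/n^2} prefactor.
#' @return A \code{coupling_result} with \code{method = "TrESP"}; exactly
#'   symmetric under swapping donor and acceptor.
#' @export
tresp_coupling <- function(donor, acceptor, n_screen = 1) {
  stopifnot(inherits(donor, "chromophore"), inherits(acceptor, "chromophore"))
  if (is.null(donor$charges) || is.null(acceptor$charges))
    stop("both chromophores need transition charges", call. = FALSE)
  if (n_screen <= 0) stop("n_screen must be positive", call. = FALSE)
  cc <- fret_constants()
  v <- cc$coulomb_cm1_angstrom * .tresp_sum(donor, acceptor) / n_screen^2
  .coupling_result(v, "TrESP", n_screen, donor$name, acceptor$name)
}

#' Effective orientation factor from the TrESP coupling
#'
#' The orientation factor \eqn{\kappa^2} belongs to the point-dipole
#' picture; the TrESP coupling is formally \eqn{\kappa^2}-free. The
#' effective orientation factor is the \eqn{\kappa^2} a single
#' point-dipole interaction would need in order to reproduce the TrESP
#' coupling exactly:
#' \deqn{\kappa_{eff}^2 = \left(\frac{R_{DA}^3}{|\mu_D||\mu_A|}
#'   \sum_{i\in D}\sum_{j\in A}\frac{q_i q_j}{r_{ij}}\right)^2,}
#' with all lengths in Å and charges in e. The \eqn{4\pi\varepsilon_0 n^2}
#' prefactor cancels in the ratio, so the quantity is screening-free and
#' dimensionless. It is invariant under any rigid rotation or translation
#' applied to the whole assembly, and reduces to \eqn{\kappa^2} in the
#' point-dipole limit.
#'
#' @param donor,acceptor \code{\link{chromophore}} objects with charges set.
#' @param R_DA Donor-acceptor reference distance (Å) used in the
#'   back-conversion.
#' @return Non-negative scalar \eqn{\kappa_{eff}^2}.
#' @export
effective_kappa_sq <- function(donor, acceptor, R_DA) {
  stopifnot(inherits(donor, "chromophore"), inherits(acceptor, "chromophore"))
  if (!is.numeric(R_DA) || R_DA <= 0)
    stop("R_DA must be a positive distance in Angstrom", call. = FALSE)
  mu_D <- transition_dipole(donor)
  mu_A <- transition_dipole(acceptor)
  nD <- .vnorm(mu_D)
  nA <- .vnorm(mu_A)
  if (nD == 0 || nA == 0)
    stop("zero transition dipole on '",
         if (nD == 0) donor$name else acceptor$name, "'", call. = FALSE)
  (R_DA^3 / (nD * nA) * .tresp_sum(donor, acceptor))^2
}

#' Couplings as a function of donor-acceptor distance
#'
#' Rigidly translates the acceptor along \code{direction} so that the
#' reference-point separation equals each requested distance, keeping both
#' internal geometries (and hence both transition dipoles) fixed, and
#' reports the TrESP and point-dipole couplings at every distance. Also
#' locates the convergence distance of the two methods: the smallest
#' scanned R from which \eqn{|V^{TrESP} - V^{DD}|} stays within
#' \code{threshold} for all larger scanned R.
#'
#' @param donor,acceptor \code{\link{chromophore}} objects with charges set.
#' @param direction Unit 3-vector along which the acceptor is placed,
#'   pointing from donor to acceptor.
#' @param R_values Positive, sorted distances (Å) between the reference
#'   points.
#' @param n_screen Refractive index for both couplings.
#' @param threshold Agreement threshold (cm\eqn{^{-1}}) defining the
#'   convergence distance (default 5).
#' @param donor_sel,acceptor_sel Optional atom selections defining the
#'   reference points (centres of mass of the selections; default all
#'   atoms).
#' @return Data frame with columns \code{R}, \code{V_tresp}, \code{V_dd},
#'   \code{clash} (TRUE where atoms would overlap and the couplings are
#'   NA), with the convergence distance in
#'   \code{attr(, "convergence_R")} (NA if never reached).
#' @export
coupling_distance_scan <- function(donor, acceptor, direction, R_values,
                                   n_screen = 1, threshold = 5,
                                   donor_sel = NULL, acceptor_sel = NULL) {
  if (any(R_values <= 0)) stop("R_values must be positive", call. = FALSE)
  if (is.unsorted(R_values, strictly = TRUE))
    stop("R_values must be sorted increasing", call. = FALSE)
  u <- .unit(direction)
  ref_D <- center_of_mass(donor, donor_sel)
  ref_A <- center_of_mass(acceptor, acceptor_sel)
  mu_D <- transition_dipole(donor)
  mu_A <- transition_dipole(acceptor)
  out <- data.frame(R = R_values, V_tresp = NA_real_, V_dd = NA_real_,
                    clash = FALSE)
  for (i in seq_along(R_values)) {
    shift <- ref_D + R_values[i] * u - ref_A
    acc_i <- acceptor
    acc_i$xyz <- sweep(acceptor$xyz, 2, shift, "+")
    vt <- tryCatch(tresp_coupling(donor, acc_i, n_screen)$value,
                   error = function(e) NA_real_)
    if (is.na(vt)) {
      out$clash[i] <- TRUE
      next
    }
    out$V_tresp[i] <- vt
    out$V_dd[i] <- dd_coupling(mu_D, mu_A, ref_D, ref_D + R_values[i] * u,
                               n_screen)$value
  }
  ok <- !out$clash
  dev <- abs(out$V_tresp - out$V_dd)
  conv <- NA_real_
  within <- ok & dev <= threshold
  # smallest R from which agreement holds for every larger scanned R
  for (i in seq_along(R_values)) {
    if (all(within[i:length(R_values)])) {
      conv <- R_values[i]
      break
    }
  }
  attr(out, "convergence_R") <- conv
  attr(out, "threshold") <- threshold
  out
}

#' Rank acceptors by absolute TrESP coupling to a donor
#'
#' Mirrors the screening step of a multi-pigment analysis: compute the
#' TrESP coupling of one donor to each candidate acceptor and rank by
#' coupling magnitude (ties keep the input order).
#'
#' @param donor A \code{\link{chromophore}} with charges set.
#' @param acceptors Non-empty list of \code{\link{chromophore}} objects
#'   with charges set.
#' @param n_screen Refractive index for the couplings.
#' @return Data frame with columns \code{acceptor_id}, \code{V_abs}
#'   (cm\eqn{^{-1}}), \code{R_DA} (Å, centre-of-mass separation), sorted by
#'   decreasing \code{V_abs}.
#' @export
multi_acceptor_couplings <- function(donor, acceptors, n_screen = 1) {
  if (length(acceptors) == 0) stop("empty acceptor list", call. = FALSE)
  ref_D <- center_of_mass(donor)
  v <- vapply(acceptors, function(a)
    abs(tresp_coupling(donor, a, n_screen)$value), 0)
  r <- vapply(acceptors, function(a) .vnorm(center_of_mass(a) - ref_D), 0)
  ids <- vapply(seq_along(acceptors), function(i) {
    nm <- acceptors[[i]]$name
    if (is.null(nm) || nm == "chromophore") sprintf("acceptor_%d", i) else nm
  }, "")
  ord <- order(-v)  # stable: ties keep input order
  data.frame(acceptor_id = ids[ord], V_abs = v[ord], R_DA = r[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

# n x 3 matrix of independent uniform random unit vectors (normalized
# trivariate standard normals)
.random_units <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Monte Carlo isotropic averages of the orientation factor
#'
#' Draws independent, uniformly random unit vectors for the donor and
#' acceptor dipole directions (the separation axis is held fixed; by
#' symmetry this does not change the distribution of \eqn{\kappa}) and
#' estimates two conventions of the isotropic orientation factor: the
#' dynamic mean \eqn{E[\kappa^2]} (analytically 2/3) and the squared mean
#' absolute value \eqn{(E[|\kappa|])^2} (the "static" value, approximately
#' 0.476).
#'
#' @param n_samples Number of orientation pairs (at least 1000).
#' @param seed Integer seed; the draw is fully reproducible and does not
#'   disturb the global RNG state.
#' @param chunk_size Samples per internal block (memory control; does not
#'   affect the values for a fixed seed and chunk size).
#' @return List with \code{mean_kappa_sq}, \code{se_kappa_sq},
#'   \code{mean_abs_kappa_squared} (\eqn{(E[|\kappa|])^2}),
#'   \code{se_abs_kappa_squared} (delta-method standard error), and
#'   \code{n}.
#' @examples
#' isotropic_kappa_mc(1e4, seed = 1)$mean_kappa_sq  # about 2/3
#' @export
isotropic_kappa_mc <- function(n_samples, seed, chunk_size = 1e6) {
  if (n_samples < 1000) stop("n_samples must be at least 1000", call. = FALSE)
  n_samples <- as.numeric(n_samples)
  with_seed(seed, {
    s_abs <- s_abs2 <- s_k2 <- s_k4 <- 0
    done <- 0
    while (done < n_samples) {
      m <- min(chunk_size, n_samples - done)
      d <- .random_units(m)
      a <- .random_units(m)
      # e_hat fixed at +z
      k <- rowSums(d * a) - 3 * d[, 3] * a[, 3]
      s_abs <- s_abs + sum(abs(k))
      s_abs2 <- s_abs2 + sum(k^2)
      s_k2 <- s_k2 + sum(k^2)
      s_k4 <- s_k4 + sum(k^4)
      done <- done + m
    }
    n <- n_samples
    mean_abs <- s_abs / n
    var_abs <- s_abs2 / n - mean_abs^2
    mean_k2 <- s_k2 / n
    var_k2 <- s_k4 / n - mean_k2^2
    se_abs <- sqrt(var_abs / n)
    list(mean_kappa_sq = mean_k2,
         se_kappa_sq = sqrt(var_k2 / n),
         mean_abs_kappa = mean_abs,
         se_abs_kappa = se_abs,
         mean_abs_kappa_squared = mean_abs^2,
         se_abs_kappa_squared = 2 * mean_abs * se_abs,
         n = n)
  })
}
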