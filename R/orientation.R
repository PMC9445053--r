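#' z-y-z Euler rotation matrix
#'
#' Composes \eqn{R = R_z(\gamma) R_y(\beta) R_z(\alpha)}: the body is
#' rotated by \eqn{\alpha} about z, then \eqn{\beta} about the (new) y,
#' then \eqn{\gamma} about the (new) z. Angles are in degrees, taken
#' modulo 360.
#'
#' @param alpha,beta,gamma Euler angles in degrees.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' euler_matrix(0, 0, 0)            # identity
#' det(euler_matrix(100, 320, 100)) # 1
#' @export
euler_matrix <- function(alpha, beta, gamma) {
  rz <- function(t) {
    c <- cos(t); s <- sin(t)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    c <- cos(t); s <- sin(t)
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
  }
  d2r <- pi / 180
  rz(gamma * d2r) %*% ry(beta * d2r) %*% rz(alpha * d2r)
}

#' Rotate a chromophore rigidly about its centre of mass
#'
#' Applies the z-y-z Euler rotation with the all-atom centre of mass as
#' origin: \eqn{r_i' = M (r_i - COM) + COM}. Charges are untouched, so the
#' dipole magnitude and the centre of mass are preserved and the
#' transition dipole transforms as \eqn{\mu' = M \mu} (when the charges
#' sum to zero).
#'
#' @param chrom A \code{\link{chromophore}}.
#' @inheritParams euler_matrix
#' @return The rotated chromophore.
#' @export
rotate_about_com <- function(chrom, alpha, beta, gamma) {
  stopifnot(inherits(chrom, "chromophore"))
  M <- euler_matrix(alpha, beta, gamma)
  com <- center_of_mass(chrom)
  chrom$xyz <- sweep(tcrossprod(sweep(chrom$xyz, 2, com), M), 2, com, "+")
  chrom
}

#' Full z-y-z Euler-angle grid
#'
#' All triples \eqn{(\alpha, \beta, \gamma)} with each angle in
#' \{0, step, 2 step, ...\} over [0, 360). The full 360-degree range is
#' used on all three axes even though \eqn{\beta \in [0, 180)} would cover
#' orientation space without duplication; the redundancy is intentional so
#' grid counts match the full-range convention (step 20 gives
#' \eqn{18^3 = 5832} triples).
#'
#' @param step Grid step in degrees; must be positive and divide 360.
#' @return Data frame of class \code{"euler_grid"} with columns
#'   \code{alpha}, \code{beta}, \code{gamma} in lexicographic order
#'   (\code{(0,0,0)} first) and attribute \code{step}.
#' @export
euler_grid <- function(step) {
  if (!is.numeric(step) || step <= 0)
    stop("step must be a positive number of degrees", call. = FALSE)
  k <- 360 / step
  if (abs(k - round(k)) > 1e-9)
    stop("step must divide 360 degrees", call. = FALSE)
  ang <- seq(0, 360 - step, by = step)
  g <- expand.grid(gamma = ang, beta = ang, alpha = ang,
                   KEEP.OUT.ATTRS = FALSE)[, c("alpha", "beta", "gamma")]
  rownames(g) <- NULL
  structure(g, class = c("euler_grid", "data.frame"), step = step)
}

# squared minimum distance between two coordinate sets (brute force)
.min_dist_sq <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  min(pmax(d2, 0))
}

#' Steric clash test against the environment
#'
#' TRUE iff any chromophore atom lies strictly closer than \code{cutoff}
#' to any environment atom. The brute-force minimum over all atom pairs is
#' the defining semantics; a pair at exactly the cutoff is not a clash. An
#' empty environment never clashes.
#'
#' @param chrom A \code{\link{chromophore}}.
#' @param env An \code{\link{environment_model}}.
#' @param cutoff Clash distance in Å, non-negative.
#' @return Logical scalar.
#' @export
clash_test <- function(chrom, env, cutoff) {
  stopifnot(inherits(chrom, "chromophore"),
            inherits(env, "environment_model"))
  if (!is.numeric(cutoff) || cutoff < 0)
    stop("cutoff must be non-negative", call. = FALSE)
  if (nrow(env$positions) == 0) return(FALSE)
  .min_dist_sq(chrom$xyz, env$positions) < cutoff^2
}

#' Euler-angle orientation scan with clash filtering
#'
#' Enumerates donor orientations on an Euler grid: for each triple the
#' donor is rigidly rotated about its centre of mass (the acceptor, the
#' environment and the donor-acceptor distance are never touched), rotated
#' structures clashing with the environment are excluded, and the
#' effective orientation factor is computed for every surviving
#' orientation. The identity orientation (0, 0, 0) is always evaluated and
#' reported separately as the reference.
#'
#' @param donor,acceptor \code{\link{chromophore}} objects with charges
#'   set; the donor is the molecule being reoriented.
#' @param env An \code{\link{environment_model}} of surrounding (protein)
#'   atoms.
#' @param grid An \code{\link{euler_grid}} (or data frame with columns
#'   \code{alpha}, \code{beta}, \code{gamma}).
#' @param cutoff Clash cutoff in Å (default 1).
#' @param R_DA Fixed donor-acceptor reference distance (Å) used in the
#'   effective-orientation-factor back-conversion.
#' @return List with components:
#'   \item{candidates}{Data frame, one row per grid triple in grid order:
#'     \code{alpha}, \code{beta}, \code{gamma}, \code{clash},
#'     \code{kappa_sq_eff} (NA where clashing).}
#'   \item{kept}{The clash-free rows ranked by decreasing
#'     \code{kappa_sq_eff}, ties broken lexicographically by
#'     (\code{alpha}, \code{beta}, \code{gamma}).}
#'   \item{reference}{The (0, 0, 0) row (evaluated even when absent from
#'     the grid).}
#'   \item{summary}{List with \code{n_generated}, \code{n_removed},
#'     \code{n_kept}, \code{removed_fraction}.}
#' @export
orientation_scan <- function(donor, acceptor, env, grid, cutoff = 1, R_DA) {
  stopifnot(inherits(donor, "chromophore"),
            inherits(acceptor, "chromophore"),
            inherits(env, "environment_model"))
  if (!all(c("alpha", "beta", "gamma") %in% names(grid)))
    stop("'grid' needs columns alpha, beta, gamma", call. = FALSE)
  if (!is.numeric(R_DA) || R_DA <= 0)
    stop("R_DA must be positive", call. = FALSE)
  com <- center_of_mass(donor)
  centered <- sweep(donor$xyz, 2, com)
  mu_A <- transition_dipole(acceptor)
  mu_D0 <- transition_dipole(donor)
  nDnA <- .vnorm(mu_D0) * .vnorm(mu_A)
  if (nDnA == 0) stop("zero transition dipole", call. = FALSE)
  env_pos <- env$positions
  acc_pos <- acceptor$xyz
  q_D <- donor$charges
  q_A <- acceptor$charges
  qq <- outer(q_D, q_A)
  eval_one <- function(a, b, g) {
    M <- euler_matrix(a, b, g)
    xyz <- sweep(tcrossprod(centered, M), 2, com, "+")
    cl <- if (nrow(env_pos) > 0)
      .min_dist_sq(xyz, env_pos) < cutoff^2 else FALSE
    k2 <- NA_real_
    if (!cl) {
      d2 <- outer(rowSums(xyz^2), rowSums(acc_pos^2), "+") -
        2 * tcrossprod(xyz, acc_pos)
      s <- sum(qq / sqrt(pmax(d2, 0)))
      k2 <- (R_DA^3 / nDnA * s)^2
    }
    c(cl, k2)
  }
  res <- mapply(eval_one, grid$alpha, grid$beta, grid$gamma)
  candidates <- data.frame(alpha = grid$alpha, beta = grid$beta,
                           gamma = grid$gamma,
                           clash = as.logical(res[1, ]),
                           kappa_sq_eff = res[2, ])
  ref_row <- which(grid$alpha == 0 & grid$beta == 0 & grid$gamma == 0)
  if (length(ref_row) > 0) {
    reference <- candidates[ref_row[1], , drop = FALSE]
  } else {
    r <- eval_one(0, 0, 0)
    reference <- data.frame(alpha = 0, beta = 0, gamma = 0,
                            clash = as.logical(r[1]), kappa_sq_eff = r[2])
  }
  rownames(reference) <- NULL
  kept <- candidates[!candidates$clash, , drop = FALSE]
  kept <- kept[order(-kept$kappa_sq_eff, kept$alpha, kept$beta, kept$gamma),
               , drop = FALSE]
  rownames(kept) <- NULL
  n_gen <- nrow(candidates)
  n_kept <- nrow(kept)
  list(candidates = candidates, kept = kept, reference = reference,
       summary = list(n_generated = n_gen, n_removed = n_gen - n_kept,
                      n_kept = n_kept,
                      removed_fraction = (n_gen - n_kept) / n_gen))
}

#' Angle table for the top-ranked scan orientations
#'
#' Builds the report that accompanies an orientation scan: for the top-k
#' clash-free orientations plus the (0, 0, 0) reference, the effective
#' orientation factor together with the angles \eqn{\theta_{DA}},
#' \eqn{\theta_D}, \eqn{\theta_A} of the rotated donor dipole, the fixed
#' acceptor dipole and the separation axis. With a fixed acceptor,
#' \eqn{\theta_A} is constant across rows by construction. The angle
#' columns describe geometry; the tabulated orientation factor is the
#' transition-charge (effective) value, which the point-dipole angle
#' formula reproduces only approximately.
#'
#' @param scan Result of \code{\link{orientation_scan}}.
#' @param donor,acceptor The chromophores used in the scan.
#' @param top_k Number of top-ranked orientations to report (at least 1).
#' @return Data frame with columns \code{alpha}, \code{beta}, \code{gamma},
#'   \code{kappa_sq_eff}, \code{theta_DA}, \code{theta_D}, \code{theta_A};
#'   the reference orientation is the first row.
#' @export
report_angles <- function(scan, donor, acceptor, top_k = 5) {
  if (!is.numeric(top_k) || top_k < 1)
    stop("top_k must be at least 1", call. = FALSE)
  rows <- scan$kept[seq_len(min(top_k, nrow(scan$kept))), , drop = FALSE]
  is_ref <- rows$alpha == 0 & rows$beta == 0 & rows$gamma == 0
  rows <- rbind(scan$reference, rows[!is_ref, , drop = FALSE])
  mu_A <- transition_dipole(acceptor)
  e_hat <- .unit(center_of_mass(acceptor) - center_of_mass(donor))
  mu_D0 <- transition_dipole(donor)
  ang <- t(mapply(function(a, b, g) {
    mu_D <- drop(euler_matrix(a, b, g) %*% mu_D0)
    dipole_angles(mu_D, mu_A, e_hat)
  }, rows$alpha, rows$beta, rows$gamma))
  out <- data.frame(alpha = rows$alpha, beta = rows$beta,
                    gamma = rows$gamma, kappa_sq_eff = rows$kappa_sq_eff,
                    theta_DA = ang[, "theta_DA"], theta_D = ang[, "theta_D"],
                    theta_A = ang[, "theta_A"])
  rownames(out) <- NULL
  out
}
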