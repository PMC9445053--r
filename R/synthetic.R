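#' Two-atom point-dipole realization
#'
#' The ideal-dipole toy used to probe the point-dipole limits of the
#' coupling formulas: charges \eqn{\pm q} separated by \code{delta} along
#' \code{direction}, giving a transition dipole of magnitude exactly
#' \eqn{q\,\delta} and zero net charge. Both atoms are carbons, so the
#' centre of mass is the midpoint \code{center}.
#'
#' @param q Charge magnitude (e).
#' @param delta Internal separation (Å); small \code{delta} relative to
#'   the intermolecular distance approaches the ideal dipole.
#' @param center Midpoint position (Å).
#' @param direction Dipole direction (need not be normalized).
#' @param name Chromophore name.
#' @return A \code{\link{chromophore}} with 2 atoms.
#' @examples
#' d <- make_point_dipole(q = 0.5, delta = 0.02)
#' sqrt(sum(transition_dipole(d)^2))  # 0.01 e Angstrom
#' @export
make_point_dipole <- function(q = 0.1, delta = 0.02, center = c(0, 0, 0),
                              direction = c(0, 0, 1),
                              name = "point-dipole") {
  if (q == 0) stop("q must be non-zero", call. = FALSE)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  u <- .unit(direction)
  xyz <- rbind(center + delta / 2 * u, center - delta / 2 * u)
  chromophore(c("C", "C"), xyz, charges = c(q, -q), name = name,
              charge_sum_tol = 1e-12)
}

#' Synthetic planar chromophore with a prescribed transition dipole
#'
#' Stands in for a quantum-chemically parameterized chromophore: a planar
#' ring of \code{n_atoms} carbons (in the z = 0 plane, centred on the
#' origin, with a seeded random angular phase and jitter) whose transition
#' charges are the minimum-norm solution of the linear constraints
#' \eqn{\sum_i q_i = 0} and \eqn{\sum_i q_i r_i = \mu_{target}} (both
#' satisfied exactly). Because all atoms lie in a plane, a target dipole
#' with an out-of-plane component is infeasible and raises an error.
#'
#' @param n_atoms Number of ring atoms, at least 4.
#' @param radius Ring radius (Å).
#' @param target_mu Target transition dipole (e·Å); third component must
#'   be 0.
#' @param seed Integer seed controlling the ring geometry.
#' @param name Chromophore name.
#' @return A \code{\link{chromophore}} with charges set.
#' @export
make_chromophore <- function(n_atoms, radius, target_mu, seed,
                             name = "synthetic-ring") {
  if (n_atoms < 4) stop("n_atoms must be at least 4", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (length(target_mu) != 3) stop("target_mu must be a 3-vector",
                                   call. = FALSE)
  if (abs(target_mu[3]) > 1e-12)
    stop("infeasible target dipole: planar (z = 0) atoms cannot carry an ",
         "out-of-plane dipole component", call. = FALSE)
  xyz <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    jit <- stats::runif(n_atoms, -0.2, 0.2) * 2 * pi / n_atoms
    th <- phase + 2 * pi * (seq_len(n_atoms) - 1) / n_atoms + jit
    cbind(radius * cos(th), radius * sin(th), 0)
  })
  # minimum-norm charges under the exact linear constraints
  A <- rbind(1, t(xyz[, 1:2]))
  b <- c(0, target_mu[1], target_mu[2])
  q <- drop(crossprod(A, solve(tcrossprod(A), b)))
  chromophore(rep("C", n_atoms), xyz, charges = q, name = name,
              charge_sum_tol = 1e-10)
}

# Rodrigues rotation taking unit vector 'from' onto unit vector 'to'
.rotation_between <- function(from, to) {
  c_ <- sum(from * to)
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s2 <- sum(v * v)
  if (s2 < 1e-24) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to 'from'
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- .unit(p - sum(p * from) * from)
    return(2 * tcrossprod(a) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s2)
}

# uniform random rotation matrix from a normalized random quaternion
.random_rotation <- function() {
  z <- stats::rnorm(4)
  z <- z / sqrt(sum(z^2))
  w <- z[1]; x <- z[2]; y <- z[3]; s <- z[4]
  matrix(c(1 - 2 * (y^2 + s^2), 2 * (x * y + w * s), 2 * (x * s - w * y),
           2 * (x * y - w * s), 1 - 2 * (x^2 + s^2), 2 * (y * s + w * x),
           2 * (x * s + w * y), 2 * (y * s - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# sample n unit vectors uniformly within a cone of half-angle (deg) about
# unit axis d0 (uniform in solid angle: cos(theta) uniform, azimuth uniform)
.cone_dirs <- function(n, d0, half_angle_deg) {
  ct_min <- cos(half_angle_deg * pi / 180)
  ct <- stats::runif(n, ct_min, 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- stats::runif(n, 0, 2 * pi)
  p <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- .unit(p - sum(p * d0) * d0)
  u2 <- c(d0[2] * u1[3] - d0[3] * u1[2],
          d0[3] * u1[1] - d0[1] * u1[3],
          d0[1] * u1[2] - d0[2] * u1[1])
  t(vapply(seq_len(n), function(i)
    ct[i] * d0 + st[i] * (cos(ph[i]) * u1 + sin(ph[i]) * u2),
    numeric(3)))
}

#' Synthetic restricted-wobble trajectory
#'
#' Emulates a dye tethered by a linker: across frames the donor's dipole
#' axis wobbles uniformly (in solid angle) within a cone of half-angle
#' \code{cone_half_angle} about its initial direction, while the
#' donor-acceptor centre distance jitters uniformly in
#' \code{R_mean +/- R_jitter} along the fixed initial separation axis. The
#' acceptor keeps its orientation unless \code{acceptor_isotropic} is
#' TRUE, in which case it is redrawn uniformly at random every frame
#' (fully isotropic ensembles have mean \eqn{\kappa^2 = 2/3}).
#'
#' The generator also reports its own large-sample mean orientation
#' factor, computed by drawing \code{n_oracle} fresh orientations and
#' evaluating the orientation factor with straight-line vector code
#' written independently of the pipeline's coupling routines, so the
#' recovery target cannot inherit a pipeline bug.
#'
#' @param donor,acceptor \code{\link{chromophore}} objects with charges
#'   set.
#' @param n_frames Number of frames.
#' @param cone_half_angle Cone half-angle in degrees (0 freezes the
#'   orientation; 180 is isotropic).
#' @param R_mean,R_jitter Centre-distance mean and half-width (Å).
#' @param seed Integer seed (frames and oracle are both reproducible).
#' @param time_step_ns Frame spacing in ns (default 0.1).
#' @param acceptor_isotropic Redraw the acceptor orientation each frame.
#' @param n_oracle Draws for the generator's own mean-\eqn{\kappa^2}
#'   target (default 1e6).
#' @return List with \code{frames} (each a list \code{donor},
#'   \code{acceptor}, \code{time}), \code{e_hat} (fixed separation axis),
#'   \code{target_mean_kappa_sq}, \code{target_se} (standard error of the
#'   oracle mean), and the generator settings.
#' @export
make_restricted_trajectory <- function(donor, acceptor, n_frames,
                                       cone_half_angle, R_mean,
                                       R_jitter = 0, seed,
                                       time_step_ns = 0.1,
                                       acceptor_isotropic = FALSE,
                                       n_oracle = 1e6) {
  stopifnot(inherits(donor, "chromophore"), inherits(acceptor, "chromophore"))
  if (n_frames < 1) stop("n_frames must be at least 1", call. = FALSE)
  if (cone_half_angle < 0 || cone_half_angle > 180)
    stop("cone_half_angle must be in [0, 180] degrees", call. = FALSE)
  if (R_mean <= R_jitter || R_jitter < 0)
    stop("need 0 <= R_jitter < R_mean", call. = FALSE)
  d0 <- .unit(transition_dipole(donor))
  a0 <- .unit(transition_dipole(acceptor))
  com_D <- center_of_mass(donor)
  com_A <- center_of_mass(acceptor)
  e_hat <- .unit(com_A - com_D)
  with_seed(seed, {
    dirs <- .cone_dirs(n_frames, d0, cone_half_angle)
    radii <- if (R_jitter > 0)
      stats::runif(n_frames, R_mean - R_jitter, R_mean + R_jitter)
    else rep(R_mean, n_frames)
    frames <- lapply(seq_len(n_frames), function(i) {
      M <- .rotation_between(d0, dirs[i, ])
      don <- donor
      don$xyz <- sweep(tcrossprod(sweep(donor$xyz, 2, com_D), M), 2,
                       com_A - radii[i] * e_hat, "+")
      acc <- acceptor
      if (acceptor_isotropic) {
        Ma <- .random_rotation()
        acc$xyz <- sweep(tcrossprod(sweep(acceptor$xyz, 2, com_A), Ma), 2,
                         com_A, "+")
      }
      list(donor = don, acceptor = acc, time = (i - 1) * time_step_ns)
    })
    # independent oracle: raw vector formula, fresh draws
    od <- .cone_dirs(n_oracle, d0, cone_half_angle)
    oa <- if (acceptor_isotropic) {
      m <- matrix(stats::rnorm(3 * n_oracle), ncol = 3)
      m / sqrt(rowSums(m^2))
    } else {
      matrix(a0, n_oracle, 3, byrow = TRUE)
    }
    k <- (od[, 1] * oa[, 1] + od[, 2] * oa[, 2] + od[, 3] * oa[, 3]) -
      3 * (od[, 1] * e_hat[1] + od[, 2] * e_hat[2] + od[, 3] * e_hat[3]) *
          (oa[, 1] * e_hat[1] + oa[, 2] * e_hat[2] + oa[, 3] * e_hat[3])
    k2 <- k * k
    list(frames = frames, e_hat = e_hat,
         target_mean_kappa_sq = mean(k2),
         target_se = stats::sd(k2) / sqrt(n_oracle),
         cone_half_angle = cone_half_angle, R_mean = R_mean,
         R_jitter = R_jitter, seed = seed,
         acceptor_isotropic = acceptor_isotropic)
  })
}

#' Synthetic partial protein shell for clash-filter testing
#'
#' Scatters \code{n_atoms} environment atoms over a spherical cap of
#' radius \code{inner_radius} about \code{center}. The cap covers the
#' fraction \code{coverage_fraction} of the full solid angle about
#' \code{axis} (directions \eqn{\hat u} with
#' \eqn{\hat u\cdot\hat a \ge 1 - 2f}). A donor whose atoms reach the
#' shell radius then clashes exactly when a protruding atom points into
#' the covered cap, which makes the removed fraction of an orientation
#' scan tunable through \code{coverage_fraction} (see
#' \code{\link{shell_occlusion_prediction}} for the grid-exact target).
#'
#' @param center Shell centre (Å).
#' @param inner_radius Shell radius (Å), positive.
#' @param coverage_fraction Solid-angle fraction covered, in [0, 1];
#'   0 returns an empty environment.
#' @param n_atoms Number of shell atoms; their surface density must be
#'   high relative to the clash cutoff for the cap to act as a solid wall.
#' @param seed Integer seed for the atom placement.
#' @param axis Cap axis (default +z; need not be normalized).
#' @return An \code{\link{environment_model}}.
#' @export
make_protein_shell <- function(center = c(0, 0, 0), inner_radius,
                               coverage_fraction, n_atoms, seed,
                               axis = c(0, 0, 1)) {
  if (inner_radius <= 0) stop("inner_radius must be positive", call. = FALSE)
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("coverage_fraction must be in [0, 1]", call. = FALSE)
  if (coverage_fraction == 0 || n_atoms == 0)
    return(environment_model(matrix(numeric(0), 0, 3),
                             source = "synthetic-shell"))
  a <- .unit(axis)
  pos <- with_seed(seed, {
    ct <- stats::runif(n_atoms, 1 - 2 * coverage_fraction, 1)
    st <- sqrt(pmax(0, 1 - ct^2))
    ph <- stats::runif(n_atoms, 0, 2 * pi)
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u1 <- .unit(p - sum(p * a) * a)
    u2 <- c(a[2] * u1[3] - a[3] * u1[2],
            a[3] * u1[1] - a[1] * u1[3],
            a[1] * u1[2] - a[2] * u1[1])
    dirs <- outer(ct, a) + (st * cos(ph)) %o% u1 + (st * sin(ph)) %o% u2
    sweep(inner_radius * dirs, 2, center, "+")
  })
  environment_model(pos, source = "synthetic-shell")
}

#' Grid-exact occlusion target for a synthetic shell
#'
#' Predicts, by pure angle counting, which fraction of a full z-y-z Euler
#' grid a shell from \code{\link{make_protein_shell}} should remove for a
#' donor with a single protruding tip: a rotation clashes when the rotated
#' tip direction falls inside the covered cap. The rotation matrices and
#' the cap test are written inline here, independently of the scan code
#' path, so this is a genuine external target for the clash filter.
#'
#' In the dense-shell limit a tip at the shell radius clashes not only
#' inside the cap (where it touches the shell surface) but also within a
#' rim of angular width \eqn{2\arcsin(cutoff / 2r)} outside the cap edge,
#' where the chord to the nearest cap atom is still below the cutoff.
#' Supplying \code{inner_radius} and \code{cutoff} includes that rim in
#' the prediction; shell discreteness then perturbs the outcome only at
#' the atom-spacing scale.
#'
#' @param tip_direction Direction (from the rotation origin) of the
#'   donor's protruding tip in the unrotated frame.
#' @param coverage_fraction Cap solid-angle fraction, as given to
#'   \code{\link{make_protein_shell}}.
#' @param step Euler grid step in degrees.
#' @param axis Cap axis (default +z).
#' @param inner_radius,cutoff Shell radius and clash cutoff (Å); when both
#'   are given the cap-edge rim is included.
#' @return Expected removed fraction of the grid, in [0, 1].
#' @export
shell_occlusion_prediction <- function(tip_direction, coverage_fraction,
                                       step, axis = c(0, 0, 1),
                                       inner_radius = NULL, cutoff = 0) {
  t0 <- .unit(tip_direction)
  a <- .unit(axis)
  theta_cap <- acos(pmin(1, pmax(-1, 1 - 2 * coverage_fraction)))
  rim <- if (!is.null(inner_radius) && cutoff > 0)
    2 * asin(min(1, cutoff / (2 * inner_radius))) else 0
  theta_eff <- min(pi, theta_cap + rim)
  ang <- seq(0, 360 - step, by = step) * pi / 180
  inside <- 0L
  total <- 0L
  for (al in ang) for (be in ang) for (ga in ang) {
    # inline z-y-z composition (independent of euler_matrix)
    v <- c(cos(al) * t0[1] - sin(al) * t0[2],
           sin(al) * t0[1] + cos(al) * t0[2], t0[3])
    v <- c(cos(be) * v[1] + sin(be) * v[3], v[2],
           -sin(be) * v[1] + cos(be) * v[3])
    v <- c(cos(ga) * v[1] - sin(ga) * v[2],
           sin(ga) * v[1] + cos(ga) * v[2], v[3])
    th <- acos(pmin(1, pmax(-1, sum(v * a))))
    inside <- inside + (th <= theta_eff)
    total <- total + 1L
  }
  inside / total
}
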