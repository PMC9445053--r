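#' Förster-equation parameter set
#'
#' Bundles the photophysical scalars of the Förster rate expression
#' \deqn{k_T = \frac{9\ln 10\,\kappa^2\varphi_D}
#'   {128\pi^5 N_A n^4 \tau_D R_{DA}^6} J,}
#' namely the orientation factor \eqn{\kappa^2}, donor fluorescence quantum
#' yield \eqn{\varphi_D}, donor lifetime \eqn{\tau_D}, spectral overlap
#' \eqn{J}, refractive index \eqn{n}, and (optionally, needed only for the
#' distance inversion) the measured transfer rate constant \eqn{k_T}.
#'
#' Unit convention for the spectral overlap: \code{J_M1cm3} is the overlap
#' integral in M\eqn{^{-1}}cm\eqn{^{3}}. Inside the Förster expressions it
#' is combined with the Avogadro constant as
#' \eqn{J' = 1000 \times J} cm\eqn{^{6}} mol\eqn{^{-1}} (the factor 1000
#' converts litres to cm\eqn{^3}). Overlap values quoted simply in
#' "cm\eqn{^6}" in the FRET literature are numerically identical to this
#' convention.
#'
#' @param kappa_sq Orientation factor, in [0, 4] (default 2/3, the dynamic
#'   isotropic mean).
#' @param phi_D Donor fluorescence quantum yield, in (0, 1].
#' @param tau_D_ns Donor fluorescence lifetime in ns, positive.
#' @param J_M1cm3 Spectral overlap in M\eqn{^{-1}}cm\eqn{^{3}}, positive.
#' @param n Refractive index of the medium, positive.
#' @param k_T_per_s Measured FRET rate constant in s\eqn{^{-1}} (optional).
#' @return An object of class \code{"forster_params"}.
#' @examples
#' # experimental parameters of a dye-protein conjugate
#' p <- forster_params(kappa_sq = 2/3, phi_D = 0.2, tau_D_ns = 0.8,
#'                     J_M1cm3 = 2.6e-13, n = 1.45, k_T_per_s = 2.7e11)
#' infer_distance(p)  # about 17.8 Angstrom
#' @export
forster_params <- function(kappa_sq = 2/3, phi_D, tau_D_ns, J_M1cm3, n,
                           k_T_per_s = NULL) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(kappa_sq) && kappa_sq >= 0 && kappa_sq <= 4,
      "kappa_sq must be in [0, 4]")
  chk(is.numeric(phi_D) && phi_D > 0 && phi_D <= 1,
      "phi_D must be in (0, 1]")
  chk(is.numeric(tau_D_ns) && tau_D_ns > 0, "tau_D_ns must be positive")
  chk(is.numeric(J_M1cm3) && J_M1cm3 > 0, "J_M1cm3 must be positive")
  chk(is.numeric(n) && n > 0, "n must be positive")
  if (!is.null(k_T_per_s))
    chk(is.numeric(k_T_per_s) && k_T_per_s > 0, "k_T_per_s must be positive")
  structure(list(kappa_sq = kappa_sq, phi_D = phi_D, tau_D_ns = tau_D_ns,
                 J_M1cm3 = J_M1cm3, n = n, k_T_per_s = k_T_per_s),
            class = "forster_params")
}

#' @export
print.forster_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Forster parameters: kappa_sq = %.4g, phi_D = %.3g, tau_D = %.3g ns,\n",
    "  J = %.3g M^-1 cm^3, n = %.3g, k_T = %s\n"),
    x$kappa_sq, x$phi_D, x$tau_D_ns, x$J_M1cm3, x$n,
    if (is.null(x$k_T_per_s)) "unset" else sprintf("%.3g s^-1", x$k_T_per_s)))
  invisible(x)
}

#' Förster distance (radius)
#'
#' The donor-acceptor separation at which the FRET efficiency is 50%:
#' \deqn{R_0^6 = \frac{9\ln 10\,\kappa^2\varphi_D}{128\pi^5 N_A n^4} J',}
#' evaluated in cm\eqn{^6} with \eqn{J' = 1000 J} cm\eqn{^6} mol\eqn{^{-1}}
#' and reported in Å.
#'
#' @param p A \code{\link{forster_params}} object (\code{k_T_per_s} not
#'   required).
#' @return \eqn{R_0} in Å.
#' @export
forster_radius <- function(p) {
  stopifnot(inherits(p, "forster_params"))
  if (p$kappa_sq <= 0) stop("kappa_sq must be positive for a finite R_0",
                            call. = FALSE)
  cc <- fret_constants()
  J_cm6_mol <- cc$liters_to_cm3 * p$J_M1cm3
  r0_6_cm6 <- 9 * log(10) * p$kappa_sq * p$phi_D * J_cm6_mol /
    (128 * pi^5 * cc$N_A * p$n^4)
  r0_6_cm6^(1 / 6) * 1e8
}

#' FRET rate constant at a given distance
#'
#' \eqn{k_T = \tau_D^{-1} (R_0 / R_{DA})^6}.
#'
#' @param p A \code{\link{forster_params}} object.
#' @param R_DA Donor-acceptor distance in Å, positive.
#' @return Rate constant in s\eqn{^{-1}}.
#' @export
fret_rate <- function(p, R_DA) {
  stopifnot(inherits(p, "forster_params"))
  if (!is.numeric(R_DA) || any(R_DA <= 0))
    stop("R_DA must be positive", call. = FALSE)
  tau_s <- p$tau_D_ns * 1e-9
  (1 / tau_s) * (forster_radius(p) / R_DA)^6
}

#' FRET efficiency
#'
#' \eqn{\eta = [1 + (R_{DA}/R_0)^6]^{-1}}; equals 0.5 at
#' \eqn{R_{DA} = R_0}.
#'
#' @param R_DA Donor-acceptor distance (Å), positive.
#' @param R_0 Förster distance (Å), positive.
#' @return Efficiency in (0, 1).
#' @export
fret_efficiency <- function(R_DA, R_0) {
  if (any(R_DA <= 0) || any(R_0 <= 0))
    stop("R_DA and R_0 must be positive", call. = FALSE)
  1 / (1 + (R_DA / R_0)^6)
}

#' Infer the donor-acceptor distance from a measured rate constant
#'
#' Inverts the Förster rate expression:
#' \eqn{R_{DA} = R_0 (k_T \tau_D)^{-1/6}}. This is the standard route from
#' a measured transfer rate to a structural distance, and the place where
#' the assumed \eqn{\kappa^2} enters the structural conclusion.
#'
#' @param p A \code{\link{forster_params}} object with \code{k_T_per_s}
#'   set.
#' @return \eqn{R_{DA}} in Å (unrounded; round to 0.1 Å with
#'   \code{\link{round_half_up}} for comparison with printed values).
#' @export
infer_distance <- function(p) {
  stopifnot(inherits(p, "forster_params"))
  if (is.null(p$k_T_per_s))
    stop("k_T_per_s is required to invert the rate equation", call. = FALSE)
  kt_tau <- p$k_T_per_s * p$tau_D_ns * 1e-9
  if (kt_tau <= 0) stop("k_T * tau_D must be positive", call. = FALSE)
  forster_radius(p) * kt_tau^(-1 / 6)
}

#' Round half away from zero
#'
#' Rounds 0.05 up to 0.1 (unlike \code{round}, which rounds half to even).
#' Used when comparing computed distances with values printed to fixed
#' decimal places.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Sensitivity of the inferred distance to spectral overlap and
#' refractive index
#'
#' Recomputes the Förster-inverted distance while varying the spectral
#' overlap (at the base refractive index) and then the refractive index
#' (at the base overlap), all other parameters held at \code{p_base}. The
#' distance scales as \eqn{J^{1/6}} and \eqn{n^{-2/3}}, so \eqn{n} is the
#' more influential of the two.
#'
#' @param p_base A \code{\link{forster_params}} object with
#'   \code{k_T_per_s} set.
#' @param J_values Overlap values to scan (M\eqn{^{-1}}cm\eqn{^{3}}); may
#'   be NULL.
#' @param n_values Refractive-index values to scan; may be NULL.
#' @return Data frame with columns \code{kappa_sq}, \code{J_M1cm3},
#'   \code{n}, \code{R_DA} (Å, unrounded), one row per varied value
#'   (J block first, then n block).
#' @export
sensitivity_table <- function(p_base, J_values = NULL, n_values = NULL) {
  stopifnot(inherits(p_base, "forster_params"))
  if (length(J_values) == 0 && length(n_values) == 0)
    stop("provide at least one J or n value to vary", call. = FALSE)
  row1 <- function(J, n) {
    p <- p_base
    p$J_M1cm3 <- J
    p$n <- n
    data.frame(kappa_sq = p$kappa_sq, J_M1cm3 = J, n = n,
               R_DA = infer_distance(p))
  }
  rows <- c(lapply(J_values, row1, n = p_base$n),
            lapply(n_values, function(n) row1(p_base$J_M1cm3, n)))
  do.call(rbind, rows)
}

#' Solve one Förster parameter for a target distance
#'
#' Closed-form inversion of the scaling laws: holding everything else at
#' \code{p}, returns the value of the free parameter that makes
#' \code{\link{infer_distance}} equal \code{target_R}. Since
#' \eqn{R \propto J^{1/6} \propto (\kappa^2)^{1/6} \propto n^{-2/3}}, the
#' solutions are \eqn{J (R_t/R)^6}, \eqn{\kappa^2 (R_t/R)^6} and
#' \eqn{n (R_t/R)^{-3/2}}.
#'
#' @param p A \code{\link{forster_params}} object with \code{k_T_per_s}
#'   set.
#' @param target_R Target distance (Å), positive.
#' @param free Which parameter to solve for: \code{"J"}, \code{"n"} or
#'   \code{"kappa_sq"}.
#' @return The solved parameter value (scalar).
#' @export
solve_parameter <- function(p, target_R, free = c("J", "n", "kappa_sq")) {
  stopifnot(inherits(p, "forster_params"))
  free <- match.arg(free)
  if (!is.numeric(target_R) || target_R <= 0)
    stop("target_R must be positive", call. = FALSE)
  ratio <- target_R / infer_distance(p)
  out <- switch(free,
    J = p$J_M1cm3 * ratio^6,
    kappa_sq = p$kappa_sq * ratio^6,
    n = p$n * ratio^(-3 / 2))
  if (!is.finite(out) || out <= 0)
    stop("target distance unreachable: solved ", free, " is not positive",
         call. = FALSE)
  if (free == "kappa_sq" && out > 4)
    stop("target distance unreachable: solved kappa_sq ", signif(out, 4),
         " exceeds the physical maximum 4", call. = FALSE)
  out
}
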