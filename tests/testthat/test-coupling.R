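test_that("transition dipole is the first moment of the charges", {
  chm <- chromophore(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)),
                     charges = c(0.1, -0.1))
  expect_equal(transition_dipole(chm), c(0, 0, 0.2))

  zero <- chromophore(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)),
                      charges = c(0, 0))
  expect_equal(transition_dipole(zero), c(0, 0, 0))

  uncharged <- chromophore("C", rbind(c(0, 0, 0)))
  expect_error(transition_dipole(uncharged), "unset")
})

test_that("kappa covers the canonical geometries and stays in [-2, 2]", {
  z <- c(0, 0, 1)
  expect_equal(kappa_factor(z, z, z), -2)              # head-to-tail
  expect_equal(kappa_factor(c(1, 0, 0), c(1, 0, 0), z), 1)  # parallel, perp
  expect_equal(kappa_factor(c(1, 0, 0), c(0, 1, 0), z), 0)  # orthogonal
  expect_error(kappa_factor(c(0, 0, 0), z, z), "zero-norm")
  expect_error(kappa_factor(z, z, 2 * z), "unit")

  set.seed(11)
  for (i in 1:200) {
    k <- kappa_factor(rand_unit(), rand_unit(), rand_unit())
    expect_true(k^2 >= 0 && k^2 <= 4)
  }
})

test_that("the angle formula for kappa^2 matches the vector form", {
  set.seed(3)
  for (i in 1:100) {
    d <- rand_unit(); a <- rand_unit(); e <- rand_unit()
    ang <- dipole_angles(d, a, e) * pi / 180
    k2_angles <- (cos(ang["theta_DA"]) -
                  3 * cos(ang["theta_D"]) * cos(ang["theta_A"]))^2
    expect_equal(unname(k2_angles), kappa_factor(d, a, e)^2,
                 tolerance = 1e-10)
  }
  expect_equal(unname(dipole_angles(c(1, 0, 0), c(1, 0, 0),
                                    c(0, 0, 1))["theta_DA"]), 0)
  expect_equal(unname(dipole_angles(c(1, 0, 0), c(0, 1, 0),
                                    c(0, 0, 1))["theta_DA"]), 90)
})

test_that("point-dipole coupling reproduces the pinned Coulomb constant
           and the R^-3 law", {
  # |mu| = 1 e Angstrom each, head-to-tail at 10 Angstrom, unscreened:
  # |V| = 2 x 116140.97 / 1000 cm^-1
  v10 <- dd_coupling(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(0, 0, 10))
  expect_equal(abs(v10$value), 232.2819, tolerance = 1e-6)
  expect_identical(v10$method, "DD")

  v20 <- dd_coupling(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(0, 0, 20))
  expect_equal(v10$value / v20$value, 8, tolerance = 1e-12)

  # kappa = 0 geometry
  v0 <- dd_coupling(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), c(0, 0, 10))
  expect_equal(v0$value, 0)
  expect_error(dd_coupling(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(0, 0, 0)),
               "zero donor-acceptor separation")
  # screening scales as 1/n^2
  v145 <- dd_coupling(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(0, 0, 10),
                      n_screen = 1.45)
  expect_equal(v145$value * 1.45^2, v10$value, tolerance = 1e-12)
})

test_that("TrESP coupling is symmetric, linear in charges, and vanishes
           for an uncharged partner", {
  set.seed(21)
  d <- make_chromophore(10, 2, c(1.5, 0.5, 0), seed = 1, name = "D")
  a0 <- make_chromophore(12, 2, c(-0.8, 1.1, 0), seed = 2, name = "A")
  a <- a0
  a$xyz <- sweep(a0$xyz, 2, c(0, 0, 18), "+")

  expect_equal(tresp_coupling(d, a)$value, tresp_coupling(a, d)$value)

  zero <- set_charges(a, rep(0, nrow(a$xyz)))
  expect_equal(tresp_coupling(d, zero)$value, 0)

  scaled <- set_charges(d, 3 * d$charges, charge_sum_tol = 1e-8)
  expect_equal(tresp_coupling(scaled, a)$value,
               3 * tresp_coupling(d, a)$value, tolerance = 1e-12)

  overlap <- a
  overlap$xyz <- d$xyz
  expect_error(tresp_coupling(d, overlap), "singular distance")
})

test_that("TrESP equals an explicit double-loop oracle to 1e-10 cm^-1", {
  d <- make_chromophore(50, 3, c(2.0, -0.7, 0), seed = 5, name = "D")
  a <- make_chromophore(50, 3, c(0.9, 1.3, 0), seed = 6, name = "A")
  a$xyz <- sweep(a$xyz, 2, c(4, -3, 20), "+")
  v <- tresp_coupling(d, a)$value
  cc <- fret_constants()
  s <- 0
  for (i in seq_len(nrow(d$xyz))) {
    for (j in seq_len(nrow(a$xyz))) {
      s <- s + d$charges[i] * a$charges[j] /
        sqrt(sum((d$xyz[i, ] - a$xyz[j, ])^2))
    }
  }
  expect_equal(v, cc$coulomb_cm1_angstrom * s, tolerance = 1e-10)
})

test_that("TrESP converges to the point-dipole coupling in the far field", {
  # delta / R = 0.02 / 30: sub-0.1% agreement already
  pr <- pd_pair(c(0, 0, 1), c(0, 0, 1), R = 30, delta = 0.02)
  vt <- tresp_coupling(pr$donor, pr$acceptor)$value
  vd <- dd_coupling(transition_dipole(pr$donor),
                    transition_dipole(pr$acceptor),
                    c(0, 0, 0), 30 * pr$e_hat)$value
  expect_lt(abs(vt - vd) / abs(vd), 1e-3)
})

test_that("the effective orientation factor hits the point-dipole limits
           and is rigidly invariant", {
  # collinear head-to-tail: kappa^2 = 4
  pr <- pd_pair(c(0, 0, 1), c(0, 0, 1), R = 25, delta = 0.001)
  expect_equal(effective_kappa_sq(pr$donor, pr$acceptor, 25), 4,
               tolerance = 1e-3)
  # orthogonal geometry: kappa^2 = 0
  pr0 <- pd_pair(c(1, 0, 0), c(0, 1, 0), R = 25, delta = 0.001)
  expect_lt(effective_kappa_sq(pr0$donor, pr0$acceptor, 25), 1e-6)

  # invariance under a global rigid rotation + translation
  pr <- pd_pair(c(0.3, -0.5, 1), c(1, 0.2, 0.4), R = 22, delta = 0.01)
  k0 <- effective_kappa_sq(pr$donor, pr$acceptor, 22)
  M <- euler_matrix(33, 147, 261)
  t <- c(5, -7, 11)
  rot <- function(ch) {
    ch$xyz <- sweep(tcrossprod(ch$xyz, M), 2, t, "+")
    ch
  }
  expect_equal(effective_kappa_sq(rot(pr$donor), rot(pr$acceptor), 22), k0,
               tolerance = 1e-9)
})

test_that("distance scans agree with single-shot couplings and locate the
           convergence distance", {
  d <- make_chromophore(8, 2, c(1.8, 0, 0), seed = 3, name = "D")
  a <- make_chromophore(8, 2, c(1.8, 0, 0), seed = 4, name = "A")
  Rs <- seq(6, 40, by = 2)
  sc <- coupling_distance_scan(d, a, c(0, 0, 1), Rs, threshold = 5)

  # consistency with single-shot computations at one R
  i <- 5
  acc <- a
  shift <- center_of_mass(d) + Rs[i] * c(0, 0, 1) - center_of_mass(a)
  acc$xyz <- sweep(a$xyz, 2, shift, "+")
  expect_equal(sc$V_tresp[i], tresp_coupling(d, acc)$value,
               tolerance = 1e-12)
  expect_equal(sc$V_dd[i],
               dd_coupling(transition_dipole(d), transition_dipole(a),
                           center_of_mass(d),
                           center_of_mass(d) + Rs[i] * c(0, 0, 1))$value,
               tolerance = 1e-12)

  # far-field R^-3: doubling R from 20 to 40 divides both by ~8
  i20 <- which(Rs == 20); i40 <- which(Rs == 40)
  expect_equal(sc$V_tresp[i20] / sc$V_tresp[i40], 8, tolerance = 0.01 * 8)
  expect_equal(sc$V_dd[i20] / sc$V_dd[i40], 8, tolerance = 1e-10)

  # convergence distance equals a direct scan over the deviations
  dev <- abs(sc$V_tresp - sc$V_dd)
  oracle <- NA
  for (j in seq_along(Rs)) {
    if (all(dev[j:length(Rs)] <= 5)) { oracle <- Rs[j]; break }
  }
  expect_equal(attr(sc, "convergence_R"), oracle)
  expect_error(coupling_distance_scan(d, a, c(0, 0, 1), c(10, 6)), "sorted")
})

test_that("acceptors rank by coupling magnitude with stable ties", {
  d <- make_point_dipole(0.5, 0.02, c(0, 0, 0), c(1, 0, 0), name = "D")
  mk <- function(z, nm) make_point_dipole(0.5, 0.02, c(0, 0, z),
                                          c(1, 0, 0), name = nm)
  ranked <- multi_acceptor_couplings(d, list(mk(30, "far"), mk(20, "near"),
                                             mk(25, "mid")))
  expect_identical(ranked$acceptor_id, c("near", "mid", "far"))
  # oracle: per-pair couplings sorted by hand
  v <- vapply(list(mk(30, "far"), mk(20, "near"), mk(25, "mid")),
              function(a) abs(tresp_coupling(d, a)$value), 0)
  expect_equal(ranked$V_abs, sort(v, decreasing = TRUE), tolerance = 1e-12)

  # mirror positions give equal couplings; input order is kept
  tie <- multi_acceptor_couplings(d, list(mk(20, "first"), mk(-20, "second")))
  expect_identical(tie$acceptor_id, c("first", "second"))
  expect_equal(tie$V_abs[1], tie$V_abs[2], tolerance = 1e-12)

  expect_equal(nrow(multi_acceptor_couplings(d, list(mk(20, "only")))), 1)
  expect_error(multi_acceptor_couplings(d, list()), "empty")
})

test_that("isotropic Monte Carlo is seeded, reproducible and near 2/3", {
  m1 <- isotropic_kappa_mc(1e5, seed = 123)
  m2 <- isotropic_kappa_mc(1e5, seed = 123)
  expect_identical(m1, m2)  # bit-identical for a fixed seed
  expect_lt(abs(m1$mean_kappa_sq - 2 / 3), 3 * m1$se_kappa_sq + 1e-12)
  expect_error(isotropic_kappa_mc(10, seed = 1), "at least 1000")
})
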