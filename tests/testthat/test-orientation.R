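test_that("Euler matrices are proper rotations with the z-y-z group
           structure", {
  expect_equal(euler_matrix(0, 0, 0), diag(3))
  # with beta = 0 the two z rotations compose additively
  set.seed(8)
  for (i in 1:5) {
    a <- stats::runif(1, 0, 360); g <- stats::runif(1, 0, 360)
    expect_equal(euler_matrix(0, 0, g) %*% euler_matrix(a, 0, 0),
                 euler_matrix(a, 0, g), tolerance = 1e-12)
  }
  for (i in 1:10) {
    M <- euler_matrix(stats::runif(1, 0, 360), stats::runif(1, 0, 360),
                      stats::runif(1, 0, 360))
    expect_equal(crossprod(M), diag(3), tolerance = 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
})

test_that("rotation about the centre of mass is rigid and rotates the
           dipole", {
  chm <- make_chromophore(9, 2.2, c(1.7, -0.6, 0), seed = 12)
  expect_equal(rotate_about_com(chm, 0, 0, 0)$xyz, chm$xyz)

  rot <- rotate_about_com(chm, 40, 100, 220)
  d0 <- as.matrix(stats::dist(chm$xyz))
  d1 <- as.matrix(stats::dist(rot$xyz))
  expect_equal(d1, d0, tolerance = 1e-10)
  expect_equal(center_of_mass(rot), center_of_mass(chm), tolerance = 1e-10)
  expect_equal(transition_dipole(rot),
               drop(euler_matrix(40, 100, 220) %*% transition_dipole(chm)),
               tolerance = 1e-10)
})

test_that("the Euler grid enumerates floor(360/step)^3 unique triples", {
  g <- euler_grid(120)
  expect_equal(nrow(g), 27)
  expect_equal(nrow(unique(g)), 27)
  expect_equal(unlist(g[1, ], use.names = FALSE), c(0, 0, 0))
  expect_equal(nrow(euler_grid(360)), 1)
  expect_error(euler_grid(0), "positive")
  expect_error(euler_grid(7), "divide")
})

test_that("clash tests use a strict brute-force minimum distance", {
  chm <- make_point_dipole(0.1, 2, c(0, 0, 0), c(0, 0, 1))
  expect_false(clash_test(chm, environment_model(matrix(numeric(0), 0, 3)),
                          cutoff = 1))
  coincident <- environment_model(rbind(c(0, 0, 1)))  # on top of an atom
  expect_true(clash_test(chm, coincident, cutoff = 1))
  # nearest pair exactly at the cutoff is NOT a clash
  at_cutoff <- environment_model(rbind(c(0, 0, 2)))   # 1.0 from the tip
  expect_false(clash_test(chm, at_cutoff, cutoff = 1))
  expect_true(clash_test(chm, at_cutoff, cutoff = 1 + 1e-9))
  expect_error(clash_test(chm, at_cutoff, cutoff = -1), "non-negative")
})

test_that("scans over an empty environment keep the whole grid and store
           recomputable orientation factors", {
  donor <- make_chromophore(6, 1.5, c(1.2, 0.3, 0), seed = 31, name = "D")
  acc <- make_chromophore(6, 1.5, c(0.9, -0.8, 0), seed = 32, name = "A")
  acc$xyz <- sweep(acc$xyz, 2, c(0, 0, 30), "+")
  env0 <- environment_model(matrix(numeric(0), 0, 3))
  grid <- euler_grid(90)  # 64 triples: fast but non-trivial
  sc <- orientation_scan(donor, acc, env0, grid, cutoff = 1, R_DA = 30)

  expect_equal(sc$summary$n_generated, 64)
  expect_equal(sc$summary$n_removed, 0)
  expect_equal(nrow(sc$kept), 64)
  expect_equal(unlist(sc$reference[, c("alpha", "beta", "gamma")],
                      use.names = FALSE), c(0, 0, 0))

  # stored values equal a from-scratch recomputation on the rotated donor
  for (i in c(1, 10, 40)) {
    r <- sc$candidates[i, ]
    rot <- rotate_about_com(donor, r$alpha, r$beta, r$gamma)
    expect_equal(r$kappa_sq_eff, effective_kappa_sq(rot, acc, 30),
                 tolerance = 1e-12)
  }
  # ranking is by decreasing kappa^2_eff
  expect_true(all(diff(sc$kept$kappa_sq_eff) <= 1e-15))
})

test_that("clash filtering is monotone in the cutoff and blind to
           environment atom order", {
  donor <- arm_donor(r_tip = 5)
  acc <- make_point_dipole(0.3, 0.02, c(0, 20, 0), c(1, 0, 0), name = "A")
  env <- make_protein_shell(c(0, 0, 0), 5, 0.5, 400, seed = 2)
  grid <- euler_grid(45)

  kept_sizes <- vapply(c(0, 0.5, 1, 2), function(co)
    orientation_scan(donor, acc, env, grid, cutoff = co,
                     R_DA = 20)$summary$n_kept, 0)
  expect_true(all(diff(kept_sizes) <= 0))
  expect_equal(kept_sizes[1], nrow(grid))  # cutoff 0 removes nothing

  sc1 <- orientation_scan(donor, acc, env, grid, cutoff = 1, R_DA = 20)
  perm <- environment_model(env$positions[rev(seq_len(nrow(env$positions))),
                                          ])
  sc2 <- orientation_scan(donor, acc, perm, grid, cutoff = 1, R_DA = 20)
  expect_identical(sc1$candidates, sc2$candidates)
})

test_that("equal orientation factors rank in lexicographic angle order", {
  # a donor dipole along z is invariant under the alpha rotation, so
  # whole families of triples share one kappa^2_eff
  donor <- make_point_dipole(0.2, 0.5, c(0, 0, 0), c(0, 0, 1), name = "D")
  acc <- make_point_dipole(0.2, 0.5, c(0, 0, 25), c(0, 0, 1), name = "A")
  env0 <- environment_model(matrix(numeric(0), 0, 3))
  sc <- orientation_scan(donor, acc, env0, euler_grid(90), cutoff = 1,
                         R_DA = 25)
  k <- sc$kept
  same <- which(abs(diff(k$kappa_sq_eff)) < 1e-12)
  expect_gt(length(same), 0)
  for (i in same) {
    expect_true(k$alpha[i] < k$alpha[i + 1] ||
                (k$alpha[i] == k$alpha[i + 1] &&
                 (k$beta[i] < k$beta[i + 1] ||
                  (k$beta[i] == k$beta[i + 1] &&
                   k$gamma[i] < k$gamma[i + 1]))))
  }
})

test_that("angle reports carry a constant acceptor angle and find the
           grid maximum", {
  donor <- make_chromophore(6, 1.5, c(1.4, 0, 0), seed = 41, name = "D")
  acc <- make_chromophore(6, 1.5, c(1.0, 0.5, 0), seed = 42, name = "A")
  acc$xyz <- sweep(acc$xyz, 2, c(0, 0, 28), "+")
  env0 <- environment_model(matrix(numeric(0), 0, 3))
  sc <- orientation_scan(donor, acc, env0, euler_grid(60), cutoff = 1,
                         R_DA = 28)
  rep5 <- report_angles(sc, donor, acc, top_k = 5)

  expect_equal(unlist(rep5[1, c("alpha", "beta", "gamma")],
                      use.names = FALSE), c(0, 0, 0))  # reference row first
  expect_lt(max(rep5$theta_A) - min(rep5$theta_A), 1e-9)

  # the reported best orientation is the brute-force grid maximum
  best <- sc$kept[1, ]
  grid <- euler_grid(60)
  oracle <- -Inf
  for (i in seq_len(nrow(grid))) {
    rot <- rotate_about_com(donor, grid$alpha[i], grid$beta[i],
                            grid$gamma[i])
    oracle <- max(oracle, effective_kappa_sq(rot, acc, 28))
  }
  expect_equal(best$kappa_sq_eff, oracle, tolerance = 1e-12)
  expect_error(report_angles(sc, donor, acc, top_k = 0), "at least 1")

  # identity-only grid reports a single (reference) row
  sc0 <- orientation_scan(donor, acc, env0,
                          data.frame(alpha = 0, beta = 0, gamma = 0),
                          cutoff = 1, R_DA = 28)
  expect_equal(nrow(report_angles(sc0, donor, acc, top_k = 1)), 1)
})
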