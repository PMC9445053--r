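# Shared builders for the test suite. All geometry is constructed in code;
# no fixture files are needed beyond tiny temporary text files.

# Experimental photophysical parameters of the dye-protein conjugate used
# throughout: phi_D = 0.2, tau_D = 0.8 ns, J = 2.6e-13 M^-1 cm^3, n = 1.45,
# measured k_T = 2.7e11 s^-1.
conjugate_params <- function(kappa_sq = 2 / 3) {
  forster_params(kappa_sq = kappa_sq, phi_D = 0.2, tau_D_ns = 0.8,
                 J_M1cm3 = 2.6e-13, n = 1.45, k_T_per_s = 2.7e11)
}

# a random unit 3-vector
rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# a pair of point-dipole chromophores with given dipole directions,
# separated by R along 'axis', with internal separation delta
pd_pair <- function(dir_D, dir_A, R, axis = c(0, 0, 1), delta = 0.01,
                    q = 0.5) {
  list(
    donor = make_point_dipole(q, delta, c(0, 0, 0), dir_D, name = "D"),
    acceptor = make_point_dipole(q, delta, R * axis / sqrt(sum(axis^2)),
                                 dir_A, name = "A"),
    e_hat = axis / sqrt(sum(axis^2)),
    R = R
  )
}

# donor with a single protruding arm: a heavy atom near the centre of mass
# and a light tip atom at 'r_tip' along +z, so rotations sweep the tip over
# a sphere of radius r_tip about the origin
arm_donor <- function(r_tip = 10, q = 0.1) {
  mC <- 12.011
  mH <- 1.008
  chromophore(c("C", "H"),
              rbind(c(0, 0, -r_tip * mH / mC), c(0, 0, r_tip)),
              charges = c(-q, q), name = "arm-donor")
}

# minimal two-conformer PDB text (altloc A and B for atom C1) plus a
# second ordinary atom
altloc_pdb_lines <- function() {
  fmt <- paste0("ATOM  %5d %-4s%1s%-3s %1s%4d    ",
                "%8.3f%8.3f%8.3f%6.2f%6.2f          %2s")
  c(sprintf(fmt, 1, " C1 ", "A", "LIG", "A", 1, 0, 0, 0, 0.6, 0, "C"),
    sprintf(fmt, 2, " C1 ", "B", "LIG", "A", 1, 9, 9, 9, 0.4, 0, "C"),
    sprintf(fmt, 3, " O1 ", " ", "LIG", "A", 1, 1, 1, 1, 1, 0, "O"),
    "END")
}
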