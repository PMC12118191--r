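atom <- function(charge = 0, rmin_half = 1.9, epsilon = 0.1) {
  list(charge = charge, rmin_half = rmin_half, epsilon = epsilon)
}

test_that("pair_energy_vdw matches the Lennard-Jones closed form", {
  a <- atom(epsilon = 0.1, rmin_half = 1.9)
  # well depth -epsilon at r = Rmin = 3.8
  expect_equal(pair_energy_vdw(a, a, 3.8), -0.1, tolerance = 1e-12)
  # rapid decay far from the minimum
  expect_lt(abs(pair_energy_vdw(a, a, 38)), 1e-5)
  # zero well depth disables the interaction at any distance
  z <- atom(epsilon = 0)
  for (r in c(0.5, 3.8, 10)) expect_identical(pair_energy_vdw(z, a, r), 0)
  expect_error(pair_energy_vdw(a, a, 0), "r must be > 0")
})

test_that("pair_energy_elec matches the screened Coulomb closed form", {
  cfg <- energetics_config()
  # hand evaluation: 332.0522173 * (0.5 * -0.5) / (4 * 4) = -5.188316
  e <- pair_energy_elec(atom(charge = 0.5), atom(charge = -0.5), 4, cfg)
  expect_equal(e, 332.0522173 * (-0.25) / 16, tolerance = 1e-12)
  expect_equal(e, -5.1883, tolerance = 1e-4)
  expect_identical(pair_energy_elec(atom(charge = 0), atom(charge = 0.7), 3, cfg), 0)
  expect_gt(pair_energy_elec(atom(charge = 0.3), atom(charge = 0.3), 3, cfg), 0)
  # swapping atoms changes nothing
  a <- atom(charge = 0.4); b <- atom(charge = -0.2)
  expect_identical(pair_energy_elec(a, b, 2.5, cfg), pair_energy_elec(b, a, 2.5, cfg))
  expect_identical(pair_energy_vdw(a, b, 2.5), pair_energy_vdw(b, a, 2.5))
})

test_that("residue_energies decomposes pairwise terms per residue", {
  cx <- tiny_complex()
  cfg <- energetics_config()
  re <- residue_energies(cx, cfg)
  expect_length(re$e_vdw, 2L)
  expect_length(re$e_elec, 2L)
  # residue 1 has two atoms, residue 2 one; check against explicit pair sums
  lig <- ligand_atoms(cx); prot <- protein_atoms(cx)
  r <- sqrt((lig$x - prot$x)^2 + (lig$y - prot$y)^2 + (lig$z - prot$z)^2)
  pv <- mapply(function(j, rr) pair_energy_vdw(lig, prot[j, ], rr), seq_len(3), r)
  pe <- mapply(function(j, rr) pair_energy_elec(lig, prot[j, ], rr, cfg), seq_len(3), r)
  expect_equal(unname(re$e_vdw), c(pv[1] + pv[2], pv[3]), tolerance = 1e-12)
  expect_equal(unname(re$e_elec), c(pe[1] + pe[2], pe[3]), tolerance = 1e-12)
})

test_that("electrostatics are linear in ligand charge, vdW unaffected", {
  cx <- tiny_complex()
  cx2 <- cx
  cx2$atoms$charge[cx2$atoms$role == "ligand"] <-
    2 * cx2$atoms$charge[cx2$atoms$role == "ligand"]
  re <- residue_energies(cx); re2 <- residue_energies(cx2)
  expect_equal(re2$e_elec, 2 * re$e_elec, tolerance = 1e-12)
  expect_equal(re2$e_vdw, re$e_vdw, tolerance = 1e-12)
})

test_that("decomposition sums equal the brute-force all-pairs total", {
  for (seed in c(2, 9, 31)) {
    cx <- make_toy_complexes(synthetic_spec(n_ligands = 1, n_residues = 4,
                                            atoms_per_residue = 4,
                                            atoms_per_ligand = 4,
                                            seed = seed))[[1]]
    cfg <- energetics_config()
    re <- residue_energies(cx, cfg)
    total <- sum(re$e_vdw) + sum(re$e_elec)
    oracle <- brute_force_total(cx, cfg)
    expect_equal(total, oracle, tolerance = 1e-9)
  }
})

test_that("energies are invariant under rigid motion and scale with 1/dielectric", {
  cx <- tiny_complex()
  re <- residue_energies(cx)
  # rigid rotation (z axis, 40 degrees) + translation
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(R)
  cx2 <- cx
  cx2$atoms$x <- xyz[, 1] + 5; cx2$atoms$y <- xyz[, 2] - 3; cx2$atoms$z <- xyz[, 3] + 1
  re2 <- residue_energies(cx2)
  expect_lt(max(abs(re2$e_vdw - re$e_vdw)), 1e-8)
  expect_lt(max(abs(re2$e_elec - re$e_elec)), 1e-8)
  # dielectric scaling
  re8 <- residue_energies(cx, energetics_config(dielectric = 8))
  expect_equal(re8$e_elec, re$e_elec / 2, tolerance = 1e-12)
  expect_equal(re8$e_vdw, re$e_vdw, tolerance = 1e-12)
})

test_that("coincident atoms are reported as a broken structure", {
  cx <- tiny_complex()
  cx$atoms[4, c("x", "y", "z")] <- cx$atoms[1, c("x", "y", "z")]
  expect_error(residue_energies(cx), "zero distance")
})

test_that("build_matrix assembles rows in input order with labeled columns", {
  cxs <- make_toy_complexes(synthetic_spec(n_ligands = 3, n_residues = 4, seed = 5))
  X <- build_matrix(cxs)
  expect_equal(dim(X), c(3L, 8L))
  expect_equal(rownames(X), c("lig001", "lig002", "lig003"))
  expect_true(all(startsWith(colnames(X)[1:4], "vdw_")))
  expect_true(all(startsWith(colnames(X)[5:8], "elec_")))

  # single complex equals its ResidueEnergies concatenation
  re <- residue_energies(cxs[[1]])
  X1 <- build_matrix(cxs[1])
  expect_equal(unname(X1[1, ]), unname(c(re$e_vdw, re$e_elec)), tolerance = 1e-12)

  # permuting inputs permutes rows identically
  Xp <- build_matrix(cxs[c(3, 1, 2)])
  expect_equal(Xp, X[c(3, 1, 2), ], tolerance = 1e-15)

  # inconsistent residue sets are rejected with the mismatch listed
  other <- make_toy_complexes(synthetic_spec(n_ligands = 1, n_residues = 5, seed = 5))
  expect_error(build_matrix(c(cxs, other)), "different residue set")
})

test_that("a distance cutoff zeroes far pairs only", {
  cx <- tiny_complex()
  re_all <- residue_energies(cx)
  re_cut <- residue_energies(cx, energetics_config(cutoff = 3))
  # only the N1 pair (2.62 A) survives a 3 A cutoff; C1 and O1 sit 4.03 A away
  expect_identical(unname(re_cut$e_vdw[2]), 0)
  expect_identical(unname(re_cut$e_elec[2]), 0)
  lig <- ligand_atoms(cx); n1 <- protein_atoms(cx)[2, ]
  r_n1 <- sqrt(sum((c(lig$x, lig$y, lig$z) - c(n1$x, n1$y, n1$z))^2))
  expect_equal(unname(re_cut$e_vdw[1]), pair_energy_vdw(lig, n1, r_n1),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(re_cut$e_vdw[1], re_all$e_vdw[1])))
})
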