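# Shared fixtures and independent oracles, all built in code.

# minimal hand-built complex: 2 single/double-atom residues + 1 ligand atom
tiny_complex <- function() {
  atoms <- data.frame(
    atom_name = c("C1", "N1", "O1", "C2"),
    element = c("C", "N", "O", "C"),
    x = c(0, 0, 4, 2), y = c(0, 1.8, 0, 3.5), z = c(0, 0, 0, 0),
    charge = c(0.2, -0.4, -0.3, 0.1),
    rmin_half = c(1.9, 1.8, 1.7, 1.9),
    epsilon = c(0.1, 0.17, 0.21, 0.1),
    residue_index = c(0L, 0L, 1L, NA),
    role = c("protein", "protein", "protein", "ligand"),
    stringsAsFactors = FALSE
  )
  parameterized_complex("tiny", atoms, c("ALA1", "GLY2"))
}

# independent brute-force total intermolecular nonbonded energy:
# scalar double loop, no vectorization shared with residue_energies()
brute_force_total <- function(complex, cfg = energetics_config()) {
  lig <- ligand_atoms(complex)
  prot <- protein_atoms(complex)
  total <- 0
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(prot))) {
      r <- sqrt((lig$x[i] - prot$x[j])^2 + (lig$y[i] - prot$y[j])^2 +
                  (lig$z[i] - prot$z[j])^2)
      if (!is.null(cfg$cutoff) && r > cfg$cutoff) next
      rmin <- lig$rmin_half[i] + prot$rmin_half[j]
      eps <- sqrt(lig$epsilon[i] * prot$epsilon[j])
      total <- total + eps * ((rmin / r)^12 - 2 * (rmin / r)^6) +
        cfg$coulomb_constant * lig$charge[i] * prot$charge[j] / (cfg$dielectric * r)
    }
  }
  total
}

# independently coded naive LOO: explicit loop, assembled Q2 by definition
naive_loo_q2 <- function(spec, pre_cfg, X, y) {
  n <- nrow(X)
  preds <- numeric(n)
  reg <- make_regressor(spec)
  for (i in seq_len(n)) {
    if (is.null(pre_cfg)) {
      tr <- X[-i, , drop = FALSE]
      te <- X[i, , drop = FALSE]
    } else {
      fp <- pretreat_fit(X[-i, , drop = FALSE], pre_cfg)
      tr <- pretreat_transform(fp, X[-i, , drop = FALSE])
      te <- pretreat_transform(fp, X[i, , drop = FALSE])
    }
    preds[i] <- reg$predict(reg$fit(tr, y[-i]), te)
  }
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

# small PDB file written literally, for parser tests
write_tiny_pdb <- function(path, ligand_res = "LIG") {
  lines <- c(
    "ATOM      1  C1  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N1  ALA A   1       0.000   1.800   0.000  1.00  0.00           N",
    "ATOM      3  O1  GLY A   2       4.000   0.000   0.000  1.00  0.00           O",
    sprintf("HETATM    4  C2  %s A   3       2.000   3.500   0.000  1.00  0.00           C", ligand_res),
    "END"
  )
  writeLines(lines, path)
  path
}

write_tiny_sidecar <- function(path, serials = 1:4) {
  df <- data.frame(atom_serial = serials,
                   charge_e = c(0.2, -0.4, -0.3, 0.1)[serials],
                   rmin_half_A = c(1.9, 1.8, 1.7, 1.9)[serials],
                   epsilon_kcal_mol = c(0.1, 0.17, 0.21, 0.1)[serials])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# small random-but-seeded benchmark shared by several test files
quick_benchmark <- function(n = 30, n_res = 4, noise_sd = 0.2, seed = 7, ...) {
  make_synthetic_benchmark(
    synthetic_spec(n_ligands = n, n_residues = n_res, noise_sd = noise_sd,
                   seed = seed, ...))
}
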