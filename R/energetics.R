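# Residue-wise intermolecular nonbonded energies and the descriptor matrix.
#
# The total ligand-protein interaction energy is decomposed per protein
# residue k into a Lennard-Jones term E_k^vdW and a screened Coulomb term
# E_k^elec; stacking [vdW block | elec block] over N complexes gives the
# N x 2*n_p descriptor matrix used downstream.

#' Energetics configuration
#'
#' @param dielectric uniform relative permittivity used to screen
#'   electrostatics (dimensionless, default 4).
#' @param coulomb_constant Coulomb prefactor in kcal.\enc{Å}{A}/(mol.e^2);
#'   default is the AMBER value 332.0522173.
#' @param cutoff optional distance cutoff in \enc{Å}{A}; pairs farther apart
#'   contribute zero. Default \code{NULL} = no cutoff (full pairwise sums).
#' @return list of class \code{energetics_config}.
#' @export
energetics_config <- function(dielectric = 4, coulomb_constant = 332.0522173,
                              cutoff = NULL) {
  if (!is.numeric(dielectric) || dielectric <= 0) stopf("dielectric must be > 0")
  if (!is.numeric(coulomb_constant) || coulomb_constant <= 0) {
    stopf("coulomb_constant must be > 0")
  }
  if (!is.null(cutoff) && (!is.numeric(cutoff) || cutoff <= 0)) {
    stopf("cutoff must be NULL or > 0")
  }
  structure(list(dielectric = dielectric, coulomb_constant = coulomb_constant,
                 cutoff = cutoff),
            class = "energetics_config")
}

#' Pairwise nonbonded energies between two atoms
#'
#' \code{pair_energy_vdw} evaluates the AMBER-convention Lennard-Jones term
#' \deqn{\epsilon_{ij}[(R_{min,ij}/r)^{12} - 2 (R_{min,ij}/r)^6]}
#' with Lorentz--Berthelot combining
#' (\eqn{R_{min,ij} = R_{min,i}/2 + R_{min,j}/2},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}); the minimum is
#' \eqn{-\epsilon_{ij}} at \eqn{r = R_{min,ij}}.
#' \code{pair_energy_elec} evaluates the uniformly screened Coulomb term
#' \eqn{k_e q_i q_j / (\epsilon_r r)}.
#'
#' @param atom_i,atom_j atom records: any list/one-row data frame with fields
#'   \code{charge}, \code{rmin_half}, \code{epsilon}.
#' @param r interatomic distance in \enc{Å}{A}; must be > 0.
#' @param cfg an \code{\link{energetics_config}}.
#' @return energy in kcal/mol.
#' @export
pair_energy_vdw <- function(atom_i, atom_j, r) {
  if (!is.numeric(r) || any(r <= 0)) stopf("distance r must be > 0")
  eps <- sqrt(atom_i$epsilon * atom_j$epsilon)
  rmin <- atom_i$rmin_half + atom_j$rmin_half
  s6 <- (rmin / r)^6
  eps * (s6^2 - 2 * s6)
}

#' @rdname pair_energy_vdw
#' @export
pair_energy_elec <- function(atom_i, atom_j, r, cfg = energetics_config()) {
  if (!is.numeric(r) || any(r <= 0)) stopf("distance r must be > 0")
  cfg$coulomb_constant * atom_i$charge * atom_j$charge / (cfg$dielectric * r)
}

#' Per-residue interaction energies of one complex
#'
#' Sums the pairwise van der Waals and electrostatic energies over every
#' (ligand atom, residue-k atom) pair, for each protein residue k. Only
#' intermolecular pairs contribute; summing both vectors over k reproduces
#' the total intermolecular nonbonded energy exactly.
#'
#' @param complex a \code{\link{parameterized_complex}}.
#' @param cfg an \code{\link{energetics_config}}.
#' @return list of class \code{residue_energies} with \code{complex_id},
#'   \code{e_vdw} and \code{e_elec} (named vectors of length \eqn{n_p},
#'   kcal/mol).
#' @export
residue_energies <- function(complex, cfg = energetics_config()) {
  lig <- ligand_atoms(complex)
  prot <- protein_atoms(complex)

  dx <- outer(lig$x, prot$x, "-")
  dy <- outer(lig$y, prot$y, "-")
  dz <- outer(lig$z, prot$z, "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r == 0)) {
    ij <- which(r == 0, arr.ind = TRUE)[1, ]
    stopf("coincident atoms: ligand atom '%s' and protein atom '%s' (residue %s) at zero distance in complex '%s'",
          lig$atom_name[ij[1]], prot$atom_name[ij[2]],
          complex$residue_labels[prot$residue_index[ij[2]] + 1L],
          complex$complex_id)
  }

  eps <- sqrt(outer(lig$epsilon, prot$epsilon))
  rmin <- outer(lig$rmin_half, prot$rmin_half, "+")
  s6 <- (rmin / r)^6
  evdw <- eps * (s6^2 - 2 * s6)
  eelec <- cfg$coulomb_constant * outer(lig$charge, prot$charge) / (cfg$dielectric * r)
  if (!is.null(cfg$cutoff)) {
    beyond <- r > cfg$cutoff
    evdw[beyond] <- 0
    eelec[beyond] <- 0
  }

  grp <- factor(prot$residue_index, levels = seq_len(n_residues(complex)) - 1L)
  e_vdw <- as.numeric(rowsum(colSums(evdw), grp))
  e_elec <- as.numeric(rowsum(colSums(eelec), grp))
  names(e_vdw) <- names(e_elec) <- complex$residue_labels
  structure(list(complex_id = complex$complex_id, e_vdw = e_vdw, e_elec = e_elec),
            class = "residue_energies")
}

#' Assemble the interaction-energy descriptor matrix
#'
#' Row i holds the concatenated per-residue energies
#' \eqn{[E^{vdW}_1 \ldots E^{vdW}_{n_p}\,|\,E^{elec}_1 \ldots E^{elec}_{n_p}]}
#' of complex i. All complexes must share the same protein residue sequence.
#'
#' @param complexes list of \code{\link{parameterized_complex}} objects
#'   sharing one protein scaffold.
#' @param cfg an \code{\link{energetics_config}}.
#' @return numeric matrix (N x 2 n_p) with complex ids as row names and
#'   \code{vdw_<residue>} / \code{elec_<residue>} column names.
#' @export
build_matrix <- function(complexes, cfg = energetics_config()) {
  if (!length(complexes)) stopf("no complexes supplied")
  ref <- complexes[[1]]$residue_labels
  for (cx in complexes) {
    if (!identical(cx$residue_labels, ref)) {
      extra <- setdiff(cx$residue_labels, ref)
      miss <- setdiff(ref, cx$residue_labels)
      stopf("complex '%s' has a different residue set (missing: %s; extra: %s)",
            cx$complex_id,
            if (length(miss)) paste(miss, collapse = ",") else "none",
            if (length(extra)) paste(extra, collapse = ",") else "none")
    }
  }
  rows <- lapply(complexes, function(cx) {
    re <- residue_energies(cx, cfg)
    c(re$e_vdw, re$e_elec)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(complexes, function(cx) cx$complex_id, character(1))
  colnames(X) <- c(paste0("vdw_", ref), paste0("elec_", ref))
  X
}
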