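# Synthetic-data generator: toy parameterized complexes sharing one protein
# scaffold, and planted descriptor -> pkoff relations with additive Gaussian
# noise. This emulates the statistical structure the pipeline assumes (one
# protein, many ligands; energies carrying the signal) without pretending to
# any chemical realism.

RES_NAMES <- c("ALA", "GLY", "SER", "VAL", "LEU", "THR")

#' Specification for a synthetic benchmark
#'
#' @param n_ligands number of complexes N.
#' @param n_residues protein residues \eqn{n_p} in the shared scaffold.
#' @param atoms_per_residue,atoms_per_ligand atom counts (default 3 and 4).
#' @param coordinate_scale radius (\enc{Å}{A}) of the shell on which residue
#'   centers sit around the ligand site (default 6).
#' @param charge_scale partial charges are drawn uniformly from
#'   \code{[-charge_scale, charge_scale]} e (default 0.4, capped at 1).
#' @param planted_weights coefficient vector over the descriptor columns used
#'   by \code{\link{plant_pkoff}}; may be left \code{NULL} at complex-building
#'   time.
#' @param noise_sd Gaussian label noise, pkoff units (default 0.3, roughly
#'   the experimental spread of koff measurements on a log10 scale).
#' @param nonlinearity \code{"none"} (linear plant) or \code{"tanh"} (gentle
#'   saturating squash \eqn{2\tanh(s/2)}), exercising a non-linear
#'   energy-to-pkoff map.
#' @param bep_alpha,bep_beta,pkd_noise_sd when \code{bep_alpha} is non-NULL,
#'   \code{\link{plant_pkoff}} also emits correlated pKd values
#'   \eqn{(pk_{off} - \beta')/\alpha' + N(0, pkd\_noise\_sd^2)}.
#' @param seed RNG seed; all generator output is deterministic given it.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_ligands, n_residues, atoms_per_residue = 3L,
                           atoms_per_ligand = 4L, coordinate_scale = 6,
                           charge_scale = 0.4, planted_weights = NULL,
                           noise_sd = 0.3, nonlinearity = c("none", "tanh"),
                           bep_alpha = NULL, bep_beta = 0.5,
                           pkd_noise_sd = 0.2, seed = 1L) {
  for (nm in c("n_ligands", "n_residues", "atoms_per_residue", "atoms_per_ligand")) {
    if (!is_count(get(nm))) stopf("%s must be a positive integer", nm)
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(
    n_ligands = as.integer(n_ligands), n_residues = as.integer(n_residues),
    atoms_per_residue = as.integer(atoms_per_residue),
    atoms_per_ligand = as.integer(atoms_per_ligand),
    coordinate_scale = coordinate_scale,
    charge_scale = min(abs(charge_scale), 1),
    planted_weights = planted_weights, noise_sd = noise_sd,
    nonlinearity = match.arg(nonlinearity),
    bep_alpha = bep_alpha, bep_beta = bep_beta, pkd_noise_sd = pkd_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# evenly spread unit directions (Fibonacci sphere)
fib_directions <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

draw_lj <- function(k) {
  list(eps = runif(k, 0.05, 0.25), rmin_half = runif(k, 1.4, 2.0))
}

#' Generate toy parameterized complexes sharing one protein scaffold
#'
#' The protein is built once per spec: residue centers sit on a shell of
#' radius \code{coordinate_scale} around the origin (evenly spread
#' directions), with atoms jittered around each center under a 1.5-\enc{Å}{A}
#' minimum interatomic distance. Each ligand is an independent short chain
#' near the origin whose atoms all end up 2.5--8 \enc{Å}{A} from the nearest
#' protein atom. Charges and Lennard-Jones parameters are drawn from
#' physically plausible ranges (|q| <= 1 e, epsilon in [0.05, 0.25] kcal/mol,
#' Rmin/2 in [1.4, 2.0] \enc{Å}{A}).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list of \code{\link{parameterized_complex}} objects (ids
#'   \code{"lig001"}, ...).
#' @export
make_toy_complexes <- function(spec) {
  with_seed(spec$seed, {
    np <- spec$n_residues
    apr <- spec$atoms_per_residue
    centers <- fib_directions(np) * spec$coordinate_scale

    place_near <- function(center, radius, existing, min_dist = 1.5,
                           max_try = 500L, extra_ok = NULL) {
      for (t in seq_len(max_try)) {
        cand <- center + runif(3, -radius, radius)
        d_ok <- !nrow(existing) || min(sqrt(rowSums(sweep(existing, 2L, cand)^2))) >= min_dist
        if (d_ok && (is.null(extra_ok) || extra_ok(cand))) return(cand)
      }
      stopf("atom placement failed after %d attempts; relax the geometry spec", max_try)
    }

    # shared protein scaffold
    prot_xyz <- matrix(0, 0, 3)
    ridx <- integer(0)
    for (k in seq_len(np)) {
      for (a in seq_len(apr)) {
        prot_xyz <- rbind(prot_xyz, place_near(centers[k, ], 1.6, prot_xyz))
        ridx <- c(ridx, k - 1L)
      }
    }
    n_pa <- nrow(prot_xyz)
    lj_p <- draw_lj(n_pa)
    q_p <- runif(n_pa, -spec$charge_scale, spec$charge_scale)
    elems <- c("C", "N", "O")
    res_names <- rep(RES_NAMES, length.out = np)
    labels <- paste0(res_names, "A", seq_len(np))

    prot_atoms <- data.frame(
      atom_name = paste0(elems[(seq_len(n_pa) - 1L) %% 3L + 1L], seq_len(n_pa)),
      element = elems[(seq_len(n_pa) - 1L) %% 3L + 1L],
      x = prot_xyz[, 1], y = prot_xyz[, 2], z = prot_xyz[, 3],
      charge = q_p, rmin_half = lj_p$rmin_half, epsilon = lj_p$eps,
      residue_index = ridx, role = "protein", stringsAsFactors = FALSE
    )

    lapply(seq_len(spec$n_ligands), function(i) {
      nl <- spec$atoms_per_ligand
      ok_range <- function(cand) {
        dmin <- min(sqrt(rowSums(sweep(prot_xyz, 2L, cand)^2)))
        dmin >= 2.5 && dmin <= 8
      }
      lig_xyz <- matrix(0, 0, 3)
      anchor <- c(0, 0, 0)
      for (a in seq_len(nl)) {
        cand <- place_near(anchor, 1.2, rbind(prot_xyz, lig_xyz),
                           min_dist = if (a == 1L) 2.5 else 1.5,
                           extra_ok = ok_range)
        lig_xyz <- rbind(lig_xyz, cand)
        anchor <- cand
      }
      lj_l <- draw_lj(nl)
      lig_atoms <- data.frame(
        atom_name = paste0(elems[(seq_len(nl) - 1L) %% 3L + 1L], seq_len(nl)),
        element = elems[(seq_len(nl) - 1L) %% 3L + 1L],
        x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
        charge = runif(nl, -spec$charge_scale, spec$charge_scale),
        rmin_half = lj_l$rmin_half, epsilon = lj_l$eps,
        residue_index = NA_integer_, role = "ligand", stringsAsFactors = FALSE
      )
      parameterized_complex(sprintf("lig%03d", i),
                            rbind(prot_atoms, lig_atoms), labels)
    })
  })
}

#' Plant a pkoff relation on a descriptor matrix
#'
#' Labels follow \eqn{pk_{off} = g(Xw) + N(0, noise\_sd^2)} with \eqn{g} the
#' identity or the tanh squash chosen in the spec. When \code{bep_alpha} is
#' set, correlated pKd values are emitted too, so BEP-fit recovery can be
#' tested. The generating parameters are attached as the
#' \code{"generator"} attribute.
#'
#' @param X descriptor matrix (columns must match
#'   \code{length(planted_weights)}).
#' @param spec a \code{\link{synthetic_spec}} with non-NULL
#'   \code{planted_weights}.
#' @return a \code{\link{kinetic_dataset}} aligned with the rows of \code{X}.
#' @export
plant_pkoff <- function(X, spec) {
  X <- as.matrix(X)
  w <- spec$planted_weights
  if (is.null(w)) stopf("spec$planted_weights is NULL")
  if (length(w) != ncol(X)) {
    stopf("planted_weights has length %d but X has %d columns", length(w), ncol(X))
  }
  with_seed(spec$seed + 1L, {
    # the plant lives on the truncated descriptors: only favorable (negative)
    # interaction energies carry signal, mirroring both the pipeline's first
    # pretreatment step and the physical reading that repulsive contacts are
    # artifacts
    s <- drop(truncate_positive(X) %*% w)
    g <- switch(spec$nonlinearity, none = s, tanh = 2 * tanh(s / 2))
    pkoff <- g + rnorm(nrow(X), 0, spec$noise_sd)
    pkd <- if (!is.null(spec$bep_alpha)) {
      (pkoff - spec$bep_beta) / spec$bep_alpha + rnorm(nrow(X), 0, spec$pkd_noise_sd)
    }
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("lig%03d", seq_len(nrow(X)))
    d <- kinetic_dataset(ids, pkoff, pkd)
    attr(d, "generator") <- spec[c("planted_weights", "noise_sd", "nonlinearity",
                                   "bep_alpha", "bep_beta", "pkd_noise_sd", "seed")]
    d
  })
}

#' Scale planted weights so the noiseless signal has unit spread
#'
#' Convenience for building plants whose signal-to-noise ratio is stated in
#' pkoff units: rescales \code{w} so that \code{sd(X w) == target_sd}.
#'
#' @param X descriptor matrix.
#' @param w raw coefficient vector.
#' @param target_sd desired standard deviation of \code{X w} (default 1).
#' @return rescaled weight vector.
#' @export
scale_planted_weights <- function(X, w, target_sd = 1) {
  s <- drop(truncate_positive(as.matrix(X)) %*% w)
  sds <- sd(s)
  if (sds == 0) stopf("X w has zero variance; choose different weights")
  w * target_sd / sds
}

#' Generate a complete synthetic benchmark
#'
#' Builds the toy complexes, featurizes them, draws planted weights touching
#' every descriptor column (standard normal, rescaled to unit signal spread)
#' when the spec leaves them NULL, and plants the labels.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param cfg an \code{\link{energetics_config}}.
#' @return list with \code{complexes}, \code{X}, \code{dataset} and the
#'   completed \code{spec}.
#' @export
make_synthetic_benchmark <- function(spec, cfg = energetics_config()) {
  complexes <- make_toy_complexes(spec)
  X <- build_matrix(complexes, cfg)
  if (is.null(spec$planted_weights)) {
    w <- with_seed(spec$seed + 2L, rnorm(ncol(X)))
    spec$planted_weights <- scale_planted_weights(X, w)
  }
  dataset <- plant_pkoff(X, spec)
  list(complexes = complexes, X = X, dataset = dataset, spec = spec)
}
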