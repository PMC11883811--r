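# Seeded recovery studies over the synthetic world. These are the package's
# own benchmark of the pipeline: each run builds a fresh toy complex,
# simulates inputs, runs the full method and scores it against the planted
# ground truth.

#' Consensus-pose recovery over seeded synthetic ensembles
#'
#' For each run: a toy complex, a 9-engine x 5-pose ensemble with
#' near-native fraction 0.6, noise sd 1 A and decoys >= 15 A, then
#' superposition, ligand-heavy RMSD clustering, Kelley selection and
#' centroid extraction. A run succeeds when the consensus centroid lies
#' within `tol_A` (default 2 A) ligand-RMSD of the planted mode.
#'
#' @param n_runs number of seeded runs.
#' @param base_seed seed offset; run i uses seeds derived from it.
#' @param tol_A success tolerance, A.
#' @return data.frame with `seed`, `centroid_rmsd`, `recovered`.
#' @export
consensus_recovery <- function(n_runs = 100, base_seed = 0, tol_A = 2) {
  res <- lapply(seq_len(n_runs), function(i) {
    sd1 <- base_seed + 2L * i
    toy <- build_toy_complex(toy_spec(seed = sd1))
    gen <- generate_pose_ensemble(toy, ensemble_spec(seed = sd1 + 1L))
    ens <- superpose_on_receptor(gen$ensemble)
    cl <- consensus_pose(ens, kelley_optimal_k(rmsd_matrix(ens)))
    lh <- select_atoms(ens$ligand_template, heavy = TRUE)
    r <- coord_rmsd(cl$centroid_pose$ligand_coords[lh, , drop = FALSE],
                    gen$truth_coords[lh, , drop = FALSE])
    data.frame(seed = sd1, centroid_rmsd = r, recovered = r <= tol_A)
  })
  do.call(rbind, res)
}

#' Kelley cluster-count recovery on planted Gaussian modes
#'
#' For each run, an ensemble with 3 planted Gaussian pose modes (sd 0.3 A,
#' mode separation >= 15 A, 15 poses each); success when the Kelley optimum
#' equals 3.
#'
#' @inheritParams consensus_recovery
#' @param n_modes planted mode count.
#' @return data.frame with `seed`, `optimal_k`, `recovered`.
#' @export
kelley_mode_recovery <- function(n_runs = 100, base_seed = 0, n_modes = 3) {
  res <- lapply(seq_len(n_runs), function(i) {
    sd1 <- base_seed + 2L * i
    toy <- build_toy_complex(toy_spec(seed = sd1))
    mo <- generate_mode_ensemble(toy, n_modes = n_modes,
                                 poses_per_mode = 15, separation = 15,
                                 noise_sd = 0.3, seed = sd1 + 1L)
    k <- kelley_optimal_k(rmsd_matrix(mo$ensemble))$optimal_k
    data.frame(seed = sd1, optimal_k = k, recovered = k == n_modes)
  })
  do.call(rbind, res)
}

#' Alanine-scan hotspot recovery on seeded toy complexes
#'
#' For each run, a toy complex with planted salt bridge, hydrogen bond and
#' hydrophobic patch is alanine-scanned over its interface residues;
#' success when the planted salt-bridge receptor residue ranks in the top
#' `top_n` by ddG.
#'
#' @inheritParams consensus_recovery
#' @param top_n rank tolerance (default 3).
#' @return data.frame with `seed`, `rank`, `recovered`.
#' @export
hotspot_recovery <- function(n_runs = 50, base_seed = 0, top_n = 3) {
  res <- lapply(seq_len(n_runs), function(i) {
    sd1 <- base_seed + 1000L + i
    toy <- build_toy_complex(toy_spec(seed = sd1))
    truth <- attr(toy, "truth")
    sb <- truth[truth$type == "salt_bridge", ][1, ]
    hs <- alanine_scan(toy)
    rk <- which(hs$chain == sb$r_chain & hs$resno == sb$r_resno)
    data.frame(seed = sd1, rank = rk, recovered = rk <= top_n)
  })
  do.call(rbind, res)
}
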