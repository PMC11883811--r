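# End-to-end analysis on synthetic input: consensus -> interface ->
# trajectory -> energy -> alanine scan, writing the declared TSV/PDB
# artifacts. Deterministic per seed (byte-identical reruns).

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full binding-mode pipeline on synthetic input
#'
#' Builds a toy complex with planted contacts, generates a multi-engine
#' pose ensemble around the planted mode, runs restraint checking,
#' RMSD clustering with Kelley selection and consensus-pose extraction,
#' detects interface interactions, simulates a jittered trajectory from the
#' consensus complex, and computes trajectory metrics, per-frame surrogate
#' binding energies and an alanine scan. All declared artifacts are written
#' to `outdir`; two runs with the same seed are byte-identical.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer master seed.
#' @param n_frames trajectory length in frames (1 ns spacing).
#' @param linkage clustering linkage.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(outdir, seed = 1, n_frames = 60,
                         linkage = "average") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  toy <- build_toy_complex(toy_spec(seed = seed))
  gen <- generate_pose_ensemble(toy, ensemble_spec(seed = seed + 1L))
  ens <- superpose_on_receptor(gen$ensemble)

  # restraints: the planted contact residues are the interacting residues
  truth <- attr(toy, "truth")
  r <- restraint(paste0(truth$r_chain, ":", truth$r_resno),
                 paste0(truth$l_chain, ":", truth$l_resno))
  centroid_ok <- check_restraints(ens$receptor,
                                  apply_pose(ens, 1L), r)

  m <- rmsd_matrix(ens)
  cl <- kelley_optimal_k(m, linkage = linkage)
  cl <- consensus_pose(ens, cl)

  write_tsv(data.frame(label = cl$labels, cluster = as.integer(cl$partition)),
            file.path(outdir, "clusters.tsv"))
  write_tsv(cl$penalty, file.path(outdir, "penalty.tsv"))
  write_tsv(data.frame(engine = names(cl$contributions),
                       percent = as.numeric(cl$contributions)),
            file.path(outdir, "contributions.tsv"))

  consensus <- complex_from_pose(ens, cl$centroid_label)
  write_pdb(consensus, file.path(outdir, "consensus.pdb"))

  ints <- detect_interactions(consensus)
  write_tsv(ints, file.path(outdir, "interactions.tsv"))

  traj <- generate_trajectory(consensus, n_frames = n_frames,
                              jitter_sd = 0.25, dt_ns = 1,
                              seed = seed + 2L)
  rs <- rmsd_series(traj, window_ns = 10)
  write_tsv(data.frame(time_ns = rs$time, rmsd = rs$rmsd),
            file.path(outdir, "rmsd.tsv"))
  write_tsv(rmsf_per_residue(traj), file.path(outdir, "rmsf.tsv"))

  tc <- cluster_trajectory(traj, stride = 10)
  rep_s <- traj$topology
  coords(rep_s) <- traj$frames[[tc$representative]]
  write_pdb(rep_s, file.path(outdir, "representative.pdb"))

  occ <- interaction_occupancy(traj)
  write_tsv(occ, file.path(outdir, "occupancy.tsv"))

  sb <- truth[truth$type == "salt_bridge", ][1, ]
  ds <- monitor_distance(traj,
                         paste(sb$r_chain, sb$r_resno, sb$r_atom, sep = ":"),
                         paste(sb$l_chain, sb$l_resno, sb$l_atom, sep = ":"))
  write_tsv(data.frame(time_ns = ds$time, distance = ds$distance),
            file.path(outdir, "distances.tsv"))

  te <- trajectory_binding_energy(traj, stride_ns = 2)
  write_tsv(te$frames, file.path(outdir, "energy.tsv"))

  hs <- alanine_scan(consensus)
  write_tsv(hs, file.path(outdir, "hotspots.tsv"))

  invisible(list(toy = toy, ensemble = ens, clustering = cl,
                 consensus = consensus, restraints = centroid_ok,
                 interactions = ints, trajectory = traj, occupancy = occ,
                 energy = te, hotspots = hs))
}

#' Assemble a full complex Structure from a pose
#'
#' Receptor chains plus the ligand template at the pose's coordinates, with
#' roles carried over.
#'
#' @param ensemble PoseEnsemble.
#' @param pose pose label, index or PoseRecord.
#' @export
complex_from_pose <- function(ensemble, pose) {
  lig <- apply_pose(ensemble, pose)
  atoms <- rbind(ensemble$receptor$atoms, lig$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  roles <- c(ensemble$receptor$roles, lig$roles)
  if (is.null(roles)) {
    roles <- c(stats::setNames(rep("receptor",
                                   length(unique(ensemble$receptor$atoms$chain))),
                               unique(ensemble$receptor$atoms$chain)),
               stats::setNames(rep("ligand", length(unique(lig$atoms$chain))),
                               unique(lig$atoms$chain)))
  }
  new_structure(atoms, id = paste0("complex_", resolve_pose(ensemble, pose)$label),
                roles = roles[!duplicated(names(roles))])
}

#' Command-line entry point
#'
#' Subcommands: `truncate --keep A:START-END in.pdb out.pdb`,
#' `synth-complex --seed N out.pdb`, `synth-traj --seed N --frames N
#' --jitter SD in.pdb out.pdb`, `pipeline --seed N outdir`.
#'
#' @param args character vector (defaults to the command line).
#' @export
bindmode_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bindmode <command> [options]",
    "  truncate --keep A:1537-1730[,..] in.pdb out.pdb",
    "  synth-complex --seed N out.pdb",
    "  synth-traj --seed N --frames N --jitter SD in.pdb out.pdb",
    "  pipeline --seed N outdir", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    v <- args[i + 1]
    args <<- args[-c(i, i + 1)]
    v
  }
  switch(cmd,
    truncate = {
      keep <- residue_ranges(strsplit(opt("--keep"), ",")[[1]])
      s <- read_pdb(args[1])
      write_pdb(truncate_structure(s, keep), args[2])
    },
    `synth-complex` = {
      seed <- as.integer(opt("--seed", "1"))
      toy <- build_toy_complex(toy_spec(seed = seed))
      write_pdb(toy, args[1])
      jsonlite::write_json(attr(toy, "truth"),
                           sub("\\.pdb$", "_truth.json", args[1]),
                           dataframe = "rows", auto_unbox = TRUE)
    },
    `synth-traj` = {
      seed <- as.integer(opt("--seed", "1"))
      nfr <- as.integer(opt("--frames", "100"))
      sdj <- as.numeric(opt("--jitter", "0.3"))
      s <- read_pdb(args[1])
      write_pdb_trajectory(generate_trajectory(s, nfr, sdj, seed = seed),
                           args[2])
    },
    pipeline = {
      seed <- as.integer(opt("--seed", "1"))
      run_pipeline(args[1], seed = seed)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
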