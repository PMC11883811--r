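# Synthetic-world generators: toy two-chain complexes with planted typed
# interface contacts, multi-engine pose ensembles with a planted consensus
# mode, and jittered trajectories. All are bit-reproducible given a seed
# (the caller's RNG state is preserved).

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# residue type used for each planted contact (receptor side, ligand side,
# functional atom names)
CONTACT_TYPES <- list(
  salt_bridge = list(r_res = "LYS", r_atom = "NZ",
                     l_res = "GLU", l_atom = "OE1", default_dist = 3.0),
  hbond = list(r_res = "SER", r_atom = "OG",
               l_res = "ASN", l_atom = "OD1", default_dist = 2.9),
  hydrophobic_patch = list(r_res = "LEU", r_atom = "CD1",
                           l_res = "LEU", l_atom = "CD1",
                           default_dist = 4.0))

FUNCTIONAL_ATOM <- c(LYS = "NZ", ARG = "NH1", ASP = "OD1", GLU = "OE1",
                     SER = "OG", THR = "OG1", ASN = "OD1", GLN = "OE1",
                     HIS = "NE2", PHE = "CZ", TYR = "OH", TRP = "NE1",
                     LEU = "CD1", ILE = "CD1", MET = "SD", CYS = "SG",
                     VAL = "CG1")

#' Specification of a synthetic toy complex
#'
#' Describes the stated world for [build_toy_complex()]: two short chains
#' in idealised extended geometry facing each other across the interface,
#' with typed contacts planted at exact target distances.
#'
#' @param receptor_length,ligand_length residue counts (>= 8).
#' @param contacts list of `list(type=, distance=)` entries with type in
#'   `salt_bridge`, `hbond`, `hydrophobic_patch`; distance defaults to the
#'   type's canonical value (3.0 / 2.9 / 4.0 A).
#' @param separation C-alpha plane separation between the chains, A.
#' @param seed integer seed (controls the small backbone jitter).
#' @param receptor_numbers,ligand_numbers optional author residue-number
#'   vectors (default 1..length).
#' @param receptor_sequence,ligand_sequence optional 3-letter-code vectors
#'   overriding the default alanine filler (contact positions are still
#'   retyped to the contact's residue).
#' @export
toy_spec <- function(receptor_length = 14, ligand_length = 10,
                     contacts = list(list(type = "salt_bridge"),
                                     list(type = "hbond"),
                                     list(type = "hydrophobic_patch")),
                     separation = 11, seed = 1,
                     receptor_numbers = NULL, ligand_numbers = NULL,
                     receptor_sequence = NULL, ligand_sequence = NULL) {
  if (receptor_length < 8 || ligand_length < 8)
    stop("chain lengths must be >= 8")
  for (ct in contacts) {
    if (!ct$type %in% names(CONTACT_TYPES))
      stop("unknown contact type: ", ct$type)
    d <- if (!is.null(ct$distance)) ct$distance else
      CONTACT_TYPES[[ct$type]]$default_dist
    lim <- switch(ct$type, salt_bridge = 4.0, hbond = 3.5,
                  hydrophobic_patch = 4.5)
    if (d <= 0 || d > lim)
      stop(ct$type, " target distance ", d, " outside detection cutoff ", lim)
  }
  if (length(contacts) * 3 + 2 > receptor_length)
    stop("too many contacts for the receptor length")
  sp <- list(receptor_length = receptor_length, ligand_length = ligand_length,
             contacts = contacts, separation = separation, seed = seed,
             receptor_numbers = receptor_numbers,
             ligand_numbers = ligand_numbers,
             receptor_sequence = receptor_sequence,
             ligand_sequence = ligand_sequence)
  class(sp) <- "ToySpec"
  sp
}

# idealised extended backbone for one residue; `flip` mirrors carbonyl/CB
# away from the interface for the ligand chain.
backbone_atoms <- function(xc, ybase, flip) {
  s <- if (flip) -1 else 1
  list(N = c(xc - 1.45, ybase + s * 0.55, 0.40),
       CA = c(xc, ybase, 0),
       C = c(xc + 1.25, ybase + s * 0.60, 0.30),
       O = c(xc + 1.20, ybase + s * 1.83, 0.35),
       CB = c(xc, ybase - s * 0.80, 1.35))
}

#' Build a toy two-chain complex with planted interface contacts
#'
#' Receptor chain A runs along x at y = 0; ligand chain B runs parallel at
#' y = `separation`. Residues are alanine filler (backbone + C-beta) except
#' at planted-contact positions, where the contact's residue types are used
#' and their functional pseudo-atoms placed in the interface plane exactly
#' at the target distance. A small seeded jitter (sd 0.02 A) decorates
#' backbone atoms only, so planted distances are exact to < 0.1 A.
#'
#' @param spec a [toy_spec()].
#' @return Structure with roles `A = receptor`, `B = ligand` and attribute
#'   `truth`: a data.frame of the planted contacts.
#' @export
build_toy_complex <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "ToySpec"))
  with_seed(spec$seed, {
    ca <- 3.8
    nr <- spec$receptor_length; nl <- spec$ligand_length
    rnum <- if (!is.null(spec$receptor_numbers)) spec$receptor_numbers else 1:nr
    lnum <- if (!is.null(spec$ligand_numbers)) spec$ligand_numbers else 1:nl
    if (length(rnum) != nr || length(lnum) != nl)
      stop("numbering vectors must match chain lengths")
    rseq <- if (!is.null(spec$receptor_sequence)) spec$receptor_sequence
    else rep("ALA", nr)
    lseq <- if (!is.null(spec$ligand_sequence)) spec$ligand_sequence
    else rep("ALA", nl)

    # contact positions: receptor index 3, 6, 9, ... paired with the ligand
    # residue directly opposite (same index, clamped)
    ctypes <- vapply(spec$contacts, `[[`, "", "type")
    r_pos <- seq(3, by = 3, length.out = length(spec$contacts))
    l_pos <- pmin(pmax(r_pos, 1), nl)
    truth <- NULL
    for (i in seq_along(spec$contacts)) {
      ct <- CONTACT_TYPES[[ctypes[i]]]
      rseq[r_pos[i]] <- ct$r_res
      lseq[l_pos[i]] <- ct$l_res
    }

    build_chain <- function(n, nums, seqs, chain, ybase, flip) {
      rows <- list()
      for (i in seq_len(n)) {
        xc <- ca * (i - 1) + if (flip) 1.9 else 0
        bb <- backbone_atoms(xc, ybase, flip)
        at <- c("N", "CA", "C", "O")
        if (seqs[i] != "GLY") at <- c(at, "CB")
        for (nm in at) {
          p <- bb[[nm]] + stats::rnorm(3, 0, 0.02)
          rows[[length(rows) + 1]] <- data.frame(
            name = nm, resname = seqs[i], chain = chain, resno = nums[i],
            x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
        }
        fa <- FUNCTIONAL_ATOM[seqs[i]]
        if (!is.na(fa) && !seqs[i] %in% c("ALA", "GLY", "PRO")) {
          s <- if (flip) -1 else 1
          p <- c(xc, ybase - s * 1.6, 2.8)   # default: points up, off-plane
          rows[[length(rows) + 1]] <- data.frame(
            name = fa, resname = seqs[i], chain = chain, resno = nums[i],
            x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }

    A <- build_chain(nr, rnum, rseq, "A", 0, FALSE)
    B <- build_chain(nl, lnum, lseq, "B", spec$separation, TRUE)
    atoms <- rbind(A, B)

    # re-place contact functional atoms in the interface plane at the exact
    # target distance, halfway along x between the paired residues
    for (i in seq_along(spec$contacts)) {
      ct <- CONTACT_TYPES[[ctypes[i]]]
      d <- if (!is.null(spec$contacts[[i]]$distance))
        spec$contacts[[i]]$distance else ct$default_dist
      xr <- ca * (r_pos[i] - 1); xl <- ca * (l_pos[i] - 1) + 1.9
      xm <- (xr + xl) / 2
      yr <- (spec$separation - d) / 2
      ri <- which(atoms$chain == "A" & atoms$resno == rnum[r_pos[i]] &
                    atoms$name == ct$r_atom)
      li <- which(atoms$chain == "B" & atoms$resno == lnum[l_pos[i]] &
                    atoms$name == ct$l_atom)
      atoms[ri, c("x", "y", "z")] <- c(xm, yr, 0)
      atoms[li, c("x", "y", "z")] <- c(xm, yr + d, 0)
      truth <- rbind(truth, data.frame(
        type = ctypes[i], r_chain = "A", r_resno = rnum[r_pos[i]],
        r_resname = ct$r_res, r_atom = ct$r_atom,
        l_chain = "B", l_resno = lnum[l_pos[i]], l_resname = ct$l_res,
        l_atom = ct$l_atom, distance = d, stringsAsFactors = FALSE))
    }
    s <- new_structure(atoms, id = sprintf("toy_seed%d", spec$seed),
                       roles = c(A = "receptor", B = "ligand"))
    attr(s, "truth") <- truth
    s
  })
}

#' Specification of a synthetic multi-engine pose ensemble
#'
#' @param n_engines number of docking "engines" (default 9, as in a
#'   nine-engine consensus run).
#' @param poses_per_engine poses per engine (default 5).
#' @param near_native_fraction fraction of each engine's poses that are
#'   perturbations of the planted true mode (default 0.6).
#' @param native_noise_sd near-native noise amplitude, A (default 1):
#'   translation magnitude sd and the matching rotation-angle scale.
#' @param decoy_displacement minimum ligand-RMSD of decoys from truth, A
#'   (default 15; must exceed 3 x `native_noise_sd`).
#' @param seed integer.
#' @export
ensemble_spec <- function(n_engines = 9, poses_per_engine = 5,
                          near_native_fraction = 0.6, native_noise_sd = 1,
                          decoy_displacement = 15, seed = 1) {
  if (near_native_fraction < 0 || near_native_fraction > 1)
    stop("near_native_fraction must be in [0,1]")
  if (decoy_displacement <= 3 * native_noise_sd)
    stop("decoy_displacement must exceed 3 * native_noise_sd")
  sp <- list(n_engines = n_engines, poses_per_engine = poses_per_engine,
             near_native_fraction = near_native_fraction,
             native_noise_sd = native_noise_sd,
             decoy_displacement = decoy_displacement, seed = seed)
  class(sp) <- "EnsembleSpec"
  sp
}

random_rotation <- function() {
  # uniform over SO(3) via quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

axis_angle_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a multi-engine pose ensemble around a planted binding mode
#'
#' For each engine, `round(near_native_fraction * poses_per_engine)` poses
#' are small rigid perturbations of the true ligand placement (translation
#' per-component sd `native_noise_sd/sqrt(3)`; rotation about the ligand
#' centroid with angle sd `native_noise_sd / r_gyr`), and the rest are
#' decoys: uniformly rotated ligands displaced to at least
#' `decoy_displacement` ligand-RMSD from truth, resampled on steric clash
#' (< 2 A cross-interface contact).
#'
#' @param truth Structure with roles (e.g. [build_toy_complex()] output).
#' @param spec an [ensemble_spec()].
#' @return list: `ensemble` (PoseEnsemble), `truth_coords` (ligand-template
#'   coordinates of the planted mode), `is_native` (named logical).
#' @export
generate_pose_ensemble <- function(truth, spec = ensemble_spec()) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  rec_idx <- role_indices(truth, "receptor")
  lig_idx <- role_indices(truth, "ligand")
  receptor <- subset_structure(truth, rec_idx)
  template <- subset_structure(truth, lig_idx)
  L0 <- coords(template)
  heavy_l <- select_atoms(template, heavy = TRUE)
  cen <- colMeans(L0)
  rg <- sqrt(mean(rowSums(sweep(L0, 2, cen)^2)))
  Xrec <- coords(receptor)

  with_seed(spec$seed, {
    poses <- list()
    native <- logical(0)
    n_nn <- round(spec$near_native_fraction * spec$poses_per_engine)
    for (e in seq_len(spec$n_engines)) {
      eng <- paste0("E", e)
      for (m in seq_len(spec$poses_per_engine)) {
        if (m <= n_nn) {
          ang <- stats::rnorm(1, 0, spec$native_noise_sd / rg)
          R <- axis_angle_rotation(stats::rnorm(3), ang)
          t <- stats::rnorm(3, 0, spec$native_noise_sd / sqrt(3))
          X <- sweep(tcrossprod(sweep(L0, 2, cen), R), 2, cen + t, `+`)
          nn <- TRUE
        } else {
          repeat {
            R <- random_rotation()
            dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
            dist <- spec$decoy_displacement + stats::runif(1, 2, 20)
            X <- sweep(tcrossprod(sweep(L0, 2, cen), R), 2,
                       cen + dist * dir, `+`)
            rmsd_truth <- coord_rmsd(X[heavy_l, , drop = FALSE],
                                     L0[heavy_l, , drop = FALSE])
            clash <- min(cross_dist2(Xrec, X)) < 4
            if (rmsd_truth >= spec$decoy_displacement && !clash) break
          }
          nn <- FALSE
        }
        poses[[length(poses) + 1]] <- pose_record(X, eng, m, 1L)
        native <- c(native, nn)
      }
    }
    ens <- pose_ensemble(receptor, template, poses)
    names(native) <- pose_labels(ens)
    list(ensemble = ens, truth_coords = L0, is_native = native)
  })
}

#' Generate an ensemble with several planted Gaussian pose modes
#'
#' Poses are drawn as per-atom Gaussian jitter (sd `noise_sd`) around
#' `n_modes` rigid translations of the true ligand placed at least
#' `separation` A apart. Used to test cluster-count selection: the Kelley
#' optimum should equal `n_modes`.
#'
#' @param truth Structure with roles.
#' @param n_modes number of planted modes (default 3).
#' @param poses_per_mode poses per mode (default 15).
#' @param separation minimum mode-mode displacement, A (default 15).
#' @param noise_sd per-atom Gaussian sd about each mode, A (default 0.3).
#' @param seed integer.
#' @return list: `ensemble`, `mode` (named integer vector of true modes).
#' @export
generate_mode_ensemble <- function(truth, n_modes = 3, poses_per_mode = 15,
                                   separation = 15, noise_sd = 0.3,
                                   seed = 1) {
  rec_idx <- role_indices(truth, "receptor")
  lig_idx <- role_indices(truth, "ligand")
  receptor <- subset_structure(truth, rec_idx)
  template <- subset_structure(truth, lig_idx)
  L0 <- coords(template)
  # mode centres on a simplex-ish frame scaled to the required separation
  dirs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  if (n_modes > nrow(dirs)) stop("at most ", nrow(dirs), " modes supported")
  with_seed(seed, {
    poses <- list(); mode <- integer(0)
    for (k in seq_len(n_modes)) {
      shift <- separation * dirs[k, ]
      for (m in seq_len(poses_per_mode)) {
        X <- sweep(L0, 2, shift, `+`) +
          matrix(stats::rnorm(length(L0), 0, noise_sd), ncol = 3)
        # stay within the X-m-n grammar (m 1-10, n 1-5) for > 10 poses/mode
        poses[[length(poses) + 1]] <- pose_record(
          X, paste0("M", k), (m - 1L) %% 10L + 1L, (m - 1L) %/% 10L + 1L)
        mode <- c(mode, k)
      }
    }
    ens <- pose_ensemble(receptor, template, poses)
    names(mode) <- pose_labels(ens)
    list(ensemble = ens, mode = mode)
  })
}

#' Generate a jittered synthetic trajectory
#'
#' Frames are the start coordinates plus isotropic per-atom Gaussian jitter
#' (sd `jitter_sd`). An optional `drift` emulates a breathing motion: a
#' sinusoidal rigid displacement of a named residue range,
#' `amplitude * sin(2 pi f / period)` along `axis`.
#'
#' @param start Structure.
#' @param n_frames number of frames (>= 2).
#' @param jitter_sd per-atom, per-coordinate Gaussian sd, A.
#' @param drift optional `list(chain=, resno=, amplitude=, period=,
#'   axis=c(..))` with `resno` a vector of residue numbers.
#' @param dt_ns frame spacing, ns.
#' @param seed integer.
#' @return a Trajectory.
#' @export
generate_trajectory <- function(start, n_frames = 100, jitter_sd = 0.3,
                                drift = NULL, dt_ns = 1, seed = 1) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  X0 <- coords(start)
  n <- nrow(X0)
  drift_idx <- NULL
  if (!is.null(drift)) {
    drift_idx <- select_atoms(start, chain = drift$chain,
                              resno = drift$resno)
    if (!length(drift_idx)) stop("drift selection matches no atoms")
    axis <- drift$axis / sqrt(sum(drift$axis^2))
  }
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      X <- X0 + matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
      if (!is.null(drift_idx)) {
        disp <- drift$amplitude * sin(2 * pi * f / drift$period)
        X[drift_idx, ] <- sweep(X[drift_idx, , drop = FALSE], 2,
                                disp * axis, `+`)
      }
      frames[[f]] <- X
    }
    new_trajectory(start, frames, dt_ns = dt_ns)
  })
}
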