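#' Docked-pose record
#'
#' One rigid placement of the ligand protein, with its provenance: docking
#' engine `X`, predicted model rank `m` and refinement rank `n`, labelled
#' `X-m-n`. Coordinates must be congruent with the ensemble's ligand
#' template (same atoms, same order).
#'
#' @param ligand_coords n x 3 matrix, Angstrom.
#' @param engine engine name.
#' @param model_rank integer m (1-10).
#' @param refinement_rank integer n (1-5).
#' @param receptor_coords optional receptor-frame coordinates for this pose
#'   (used by [superpose_on_receptor()] when engines report poses in their
#'   own frames); `NULL` means the pose already shares the ensemble frame.
#' @export
pose_record <- function(ligand_coords, engine, model_rank,
                        refinement_rank = 1L, receptor_coords = NULL) {
  stopifnot(is.matrix(ligand_coords), ncol(ligand_coords) == 3)
  if (model_rank < 1 || model_rank > 10) stop("model_rank must be in 1..10")
  if (refinement_rank < 1 || refinement_rank > 5)
    stop("refinement_rank must be in 1..5")
  p <- list(ligand_coords = ligand_coords, engine = as.character(engine),
            model_rank = as.integer(model_rank),
            refinement_rank = as.integer(refinement_rank),
            receptor_coords = receptor_coords,
            label = sprintf("%s-%d-%d", engine, model_rank, refinement_rank))
  class(p) <- "PoseRecord"
  p
}

#' Pose ensemble
#'
#' Pooled docked poses from several engines sharing one receptor frame and
#' one ligand atom template.
#'
#' @param receptor Structure (receptor chains).
#' @param ligand_template Structure giving the ligand atom identities; pose
#'   coordinate blocks are congruent with it.
#' @param poses list of [pose_record()]s.
#' @export
pose_ensemble <- function(receptor, ligand_template, poses) {
  stopifnot(inherits(receptor, "Structure"),
            inherits(ligand_template, "Structure"))
  if (length(poses) < 1) stop("ensemble needs at least one pose")
  nl <- nrow(ligand_template$atoms)
  for (p in poses) {
    if (!inherits(p, "PoseRecord")) stop("poses must be PoseRecord objects")
    if (nrow(p$ligand_coords) != nl)
      stop("pose ", p$label, " has ", nrow(p$ligand_coords),
           " atoms; template has ", nl)
  }
  labels <- vapply(poses, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate pose label: ",
                                  labels[anyDuplicated(labels)][1])
  e <- list(receptor = receptor, ligand_template = ligand_template,
            poses = poses)
  class(e) <- "PoseEnsemble"
  e
}

#' @export
print.PoseEnsemble <- function(x, ...) {
  eng <- table(vapply(x$poses, `[[`, "", "engine"))
  cat(sprintf("PoseEnsemble: %d poses from %d engines (%s); ligand %d atoms\n",
              length(x$poses), length(eng),
              paste(names(eng), eng, sep = ":", collapse = " "),
              nrow(x$ligand_template$atoms)))
  invisible(x)
}

pose_labels <- function(ensemble) vapply(ensemble$poses, `[[`, "", "label")

#' Materialise a pose as a ligand Structure
#' @param ensemble PoseEnsemble.
#' @param pose a PoseRecord, pose label, or pose index.
#' @export
apply_pose <- function(ensemble, pose) {
  p <- resolve_pose(ensemble, pose)
  lig <- ensemble$ligand_template
  coords(lig) <- p$ligand_coords
  lig$id <- p$label
  lig
}

resolve_pose <- function(ensemble, pose) {
  if (inherits(pose, "PoseRecord")) return(pose)
  if (is.character(pose)) {
    i <- match(pose, pose_labels(ensemble))
    if (is.na(i)) stop("no pose labelled ", pose)
    return(ensemble$poses[[i]])
  }
  ensemble$poses[[pose]]
}

#' Interface distance restraint
#'
#' A set of receptor-side and ligand-side residues asserted to interact:
#' each restrained residue must lie within `[lower, upper]` Angstrom
#' (minimum heavy-atom distance) of the partner's restrained residue set.
#'
#' @param receptor_residues,ligand_residues character vectors of
#'   `"chain:resno"` specs.
#' @param lower,upper distance bounds in Angstrom (defaults 2 and 10).
#' @export
restraint <- function(receptor_residues, ligand_residues,
                      lower = 2, upper = 10) {
  if (!(lower > 0 && lower < upper)) stop("need 0 < lower < upper")
  r <- list(receptor = parse_res_spec(receptor_residues),
            ligand = parse_res_spec(ligand_residues),
            lower = lower, upper = upper)
  class(r) <- "Restraint"
  r
}

#' Check interface restraints on a pose
#'
#' For every restrained residue the minimum heavy-atom distance to any
#' restrained residue of the partner is computed; a residue is satisfied iff
#' that distance lies in `[lower, upper]`, and the pose is satisfied iff all
#' residues are.
#'
#' @param receptor Structure with the receptor coordinates.
#' @param ligand Structure with the ligand coordinates for this pose (see
#'   [apply_pose()]).
#' @param r a [restraint()].
#' @return list with `report` (one row per restrained residue: side, chain,
#'   resno, min_distance, satisfied) and overall `satisfied`.
#' @export
check_restraints <- function(receptor, ligand, r) {
  res_coords <- function(s, df, what) {
    lapply(seq_len(nrow(df)), function(i) {
      idx <- select_atoms(s, heavy = TRUE, chain = df$chain[i],
                          resno = df$resno[i])
      if (length(idx) == 0L)
        stop("restrained ", what, " residue ", df$chain[i], ":", df$resno[i],
             " absent from structure")
      coords(s, idx)
    })
  }
  rc <- res_coords(receptor, r$receptor, "receptor")
  lc <- res_coords(ligand, r$ligand, "ligand")
  min_to_set <- function(x, set) {
    min(vapply(set, function(y) sqrt(min(cross_dist2(x, y))), 0))
  }
  rep_r <- data.frame(side = "receptor", r$receptor,
                      min_distance = vapply(rc, min_to_set, 0, set = lc))
  rep_l <- data.frame(side = "ligand", r$ligand,
                      min_distance = vapply(lc, min_to_set, 0, set = rc))
  report <- rbind(rep_r, rep_l)
  report$satisfied <- report$min_distance >= r$lower &
    report$min_distance <= r$upper
  rownames(report) <- NULL
  list(report = report, satisfied = all(report$satisfied))
}

# squared distances between every row of A and every row of B
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Superpose every pose onto a common receptor frame
#'
#' Poses carrying their own `receptor_coords` are rigid-body fitted (Kabsch)
#' onto the reference receptor over heavy atoms, and the same transform is
#' applied to the ligand coordinates. Poses without a receptor frame are
#' assumed already referenced and left untouched (fit RMSD 0).
#'
#' @param ensemble PoseEnsemble.
#' @param reference reference receptor Structure; defaults to the ensemble's.
#' @return the transformed ensemble, with per-pose receptor-fit RMSDs in
#'   `$fit_rmsd`.
#' @export
superpose_on_receptor <- function(ensemble, reference = NULL) {
  if (is.null(reference)) reference <- ensemble$receptor
  ref_idx <- select_atoms(reference, heavy = TRUE)
  Q <- coords(reference, ref_idx)
  fit <- numeric(length(ensemble$poses))
  for (i in seq_along(ensemble$poses)) {
    p <- ensemble$poses[[i]]
    if (is.null(p$receptor_coords)) next
    P <- p$receptor_coords[ref_idx, , drop = FALSE]
    k <- kabsch(P, Q)
    p$ligand_coords <- apply_rigid(p$ligand_coords, k$R, k$t)
    p$receptor_coords <- apply_rigid(p$receptor_coords, k$R, k$t)
    fit[i] <- k$rmsd
    ensemble$poses[[i]] <- p
  }
  ensemble$fit_rmsd <- stats::setNames(fit, pose_labels(ensemble))
  ensemble
}
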