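#' Construct a Trajectory
#'
#' A topology [new_structure()] plus a list of coordinate frames (n x 3
#' matrices, Angstrom) at uniform time spacing.
#'
#' @param topology Structure.
#' @param frames list of n x 3 matrices congruent with the topology.
#' @param dt_ns frame spacing, ns.
#' @param t0_ns time of the first frame, ns.
#' @export
new_trajectory <- function(topology, frames, dt_ns = 1, t0_ns = 0) {
  stopifnot(inherits(topology, "Structure"), is.list(frames))
  if (length(frames) < 2) stop("a trajectory needs at least 2 frames")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames))
    if (!is.matrix(frames[[i]]) || any(dim(frames[[i]]) != c(n, 3)))
      stop("frame ", i, " is not congruent with the topology")
  tr <- list(topology = topology, frames = frames,
             times = t0_ns + dt_ns * (seq_along(frames) - 1), dt_ns = dt_ns)
  class(tr) <- "Trajectory"
  tr
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ns (%g-%g ns)\n",
              length(x$frames), nrow(x$topology$atoms), x$dt_ns,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

resolve_selection <- function(s, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  switch(selection,
         calpha = select_atoms(s, name = "CA", het = FALSE),
         heavy = select_atoms(s, heavy = TRUE),
         backbone = select_atoms(s, name = c("N", "CA", "C", "O"),
                                 het = FALSE),
         all = seq_len(nrow(s$atoms)),
         stop("unknown selection: ", selection))
}

#' Per-frame RMSD with convergence calling
#'
#' Each frame is Kabsch-superposed on the reference over the selection and
#' the RMSD reported. Convergence is a declared surrogate for visual
#' inspection: the earliest time from which the sliding-window mean
#' (default window 20 ns) varies by less than `tol` (default 0.5 A) through
#' the end of the run.
#'
#' @param traj Trajectory.
#' @param reference a Structure, or a frame index (default 1).
#' @param selection `"calpha"` (default), `"heavy"`, `"backbone"`, `"all"`,
#'   or atom indices.
#' @param window_ns sliding-window length, ns.
#' @param tol convergence tolerance, Angstrom.
#' @return list: `time`, `rmsd`, `converged_at` (ns, or `NA` if never).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "calpha",
                        window_ns = 20, tol = 0.5) {
  sel <- resolve_selection(traj$topology, selection)
  if (!length(sel)) stop("selection is empty")
  ref_xyz <- if (inherits(reference, "Structure")) {
    if (nrow(reference$atoms) != nrow(traj$topology$atoms))
      stop("reference structure not congruent with trajectory topology")
    coords(reference, sel)
  } else traj$frames[[reference]][sel, , drop = FALSE]
  r <- vapply(traj$frames, function(f)
    kabsch(f[sel, , drop = FALSE], ref_xyz)$rmsd, 0)
  w <- max(1L, round(window_ns / traj$dt_ns))
  nf <- length(r)
  converged_at <- NA_real_
  if (nf >= w) {
    roll <- vapply(seq_len(nf - w + 1), function(i) mean(r[i:(i + w - 1)]), 0)
    # at least two trailing windows must agree: the final window alone is
    # trivially flat and does not demonstrate convergence
    for (i in seq_len(max(0L, length(roll) - 1L))) {
      if (diff(range(roll[i:length(roll)])) < tol) {
        converged_at <- traj$times[i]
        break
      }
    }
  }
  list(time = traj$times, rmsd = r, converged_at = converged_at)
}

#' Per-residue RMSF
#'
#' Frames are superposed on the mean structure (two rounds of iterative
#' mean-refitting) over the selection; `RMSF_i = sqrt(mean_f |x_i(f) -
#' xbar_i|^2)`. With `superpose = FALSE` raw coordinates are used.
#'
#' @param traj Trajectory.
#' @param selection default `"calpha"`; see [rmsd_series()].
#' @param superpose remove global rigid motion first (default TRUE).
#' @return data.frame: `chain`, `resno`, `resname`, `rmsf` (one row per
#'   selected atom's residue).
#' @export
rmsf_per_residue <- function(traj, selection = "calpha", superpose = TRUE) {
  sel <- resolve_selection(traj$topology, selection)
  if (!length(sel)) stop("selection is empty")
  X <- lapply(traj$frames, function(f) f[sel, , drop = FALSE])
  if (superpose) {
    for (round in 1:2) {
      mu <- Reduce(`+`, X) / length(X)
      X <- lapply(X, function(f) {
        k <- kabsch(f, mu)
        apply_rigid(f, k$R, k$t)
      })
    }
  }
  mu <- Reduce(`+`, X) / length(X)
  msd <- Reduce(`+`, lapply(X, function(f) rowSums((f - mu)^2))) / length(X)
  a <- traj$topology$atoms[sel, ]
  data.frame(chain = a$chain, resno = a$resno, resname = a$resname,
             rmsf = sqrt(msd), row.names = NULL)
}

#' Cluster a trajectory and extract the representative frame
#'
#' Frames are sampled every `stride` frames (the "frequency" setting of
#' panel-style trajectory clustering), a pairwise heavy-atom RMSD matrix is
#' built with per-pair Kabsch superposition, and the dendrogram is cut at
#' `min(max_clusters, Kelley optimum)`. The representative structure is the
#' medoid of the most populated cluster (ties: lower frame index).
#'
#' @param traj Trajectory.
#' @param stride sampling interval in frames.
#' @param max_clusters cap on the cluster count (default 10).
#' @param linkage passed to [kelley_optimal_k()].
#' @return list: `frames_used`, `partition`, `k`, `representative` (frame
#'   index into the original trajectory), `rmsd` (matrix).
#' @export
cluster_trajectory <- function(traj, stride = 10L, max_clusters = 10L,
                               linkage = "average") {
  nf <- length(traj$frames)
  if (stride > nf) stop("stride exceeds trajectory length")
  use <- seq(1L, nf, by = stride)
  m <- length(use)
  if (m < 2) stop("strided trajectory has fewer than 2 frames")
  sel <- select_atoms(traj$topology, heavy = TRUE)
  X <- lapply(use, function(i) traj$frames[[i]][sel, , drop = FALSE])
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    d[i, j] <- d[j, i] <- kabsch(X[[j]], X[[i]])$rmsd
  dimnames(d) <- list(as.character(use), as.character(use))

  if (m >= 3 && max_clusters > 1 && max(d) > 1e-9) {
    kel <- kelley_optimal_k(d, linkage = linkage)
    k <- min(max_clusters, kel$optimal_k)
    part <- stats::cutree(kel$hclust, k = k)
  } else {
    k <- 1L
    part <- rep(1L, m)
  }
  sizes <- tabulate(part)
  top <- which(sizes == max(sizes))[1]
  members <- which(part == top)
  score <- rowSums(d[members, members, drop = FALSE]^2)
  medoid <- members[which.min(score)]   # which.min ties -> lowest index
  list(frames_used = use, partition = stats::setNames(part, use), k = k,
       representative = use[medoid], rmsd = d)
}
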