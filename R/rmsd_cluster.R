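#' Pairwise pose RMSD matrix
#'
#' Plain coordinate RMSD between pose pairs with no per-pair refitting: all
#' poses share one receptor frame (see [superpose_on_receptor()]), so ligand
#' displacement relative to the fixed receptor is exactly what distinguishes
#' binding modes. Selection `"ligand-heavy"` (default) uses ligand heavy
#' atoms; `"all-heavy"` additionally includes the (shared) receptor heavy
#' atoms, reproducing the literal all-heavy-atom reading.
#'
#' @param ensemble PoseEnsemble in a common receptor frame.
#' @param selection `"ligand-heavy"` or `"all-heavy"`.
#' @return list of class `RMSDMatrix` with `labels` and symmetric `values`
#'   (Angstrom, zero diagonal).
#' @export
rmsd_matrix <- function(ensemble, selection = c("ligand-heavy", "all-heavy")) {
  selection <- match.arg(selection)
  lig_idx <- select_atoms(ensemble$ligand_template, heavy = TRUE)
  if (length(lig_idx) == 0L) stop("selection is empty")
  labels <- pose_labels(ensemble)
  flat <- t(vapply(ensemble$poses, function(p)
    as.vector(p$ligand_coords[lig_idx, , drop = FALSE]),
    numeric(3 * length(lig_idx))))
  n_atoms <- length(lig_idx)
  if (selection == "all-heavy") {
    rec_idx <- select_atoms(ensemble$receptor, heavy = TRUE)
    rec_flat <- as.vector(coords(ensemble$receptor, rec_idx))
    flat <- cbind(flat, matrix(rec_flat, nrow = nrow(flat),
                               ncol = length(rec_flat), byrow = TRUE))
    n_atoms <- n_atoms + length(rec_idx)
  }
  d <- as.matrix(stats::dist(flat)) / sqrt(n_atoms)
  dimnames(d) <- list(labels, labels)
  m <- list(labels = labels, values = d)
  class(m) <- "RMSDMatrix"
  m
}

#' Kelley-penalty selection of the cluster count
#'
#' Agglomerative clustering of the pose RMSD matrix followed by the
#' Kelley-Gardner-Sutcliffe criterion: for each level `k` in `2..N-1` the
#' average within-cluster spread (mean pairwise RMSD over non-singleton
#' clusters; levels with only singletons take spread 0) is min-max
#' normalised across levels onto `[1, N-1]`, and
#' `penalty(k) = normalised spread(k) + k`. The optimum is the argmin
#' (ties: smallest k, so runs are reproducible).
#'
#' @param m RMSDMatrix (or a plain symmetric matrix).
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return list of class `ClusteringResult`: `hclust`, `penalty`
#'   (data.frame k/spread/normalised/penalty), `optimal_k`, `partition`
#'   (named integer vector at `optimal_k`), `labels`, `matrix`.
#' @export
kelley_optimal_k <- function(m, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  vals <- if (inherits(m, "RMSDMatrix")) m$values else m
  labels <- if (inherits(m, "RMSDMatrix")) m$labels else rownames(vals)
  n <- nrow(vals)
  if (n < 3) stop("Kelley selection needs at least 3 poses")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(vals), method = method)
  ks <- 2:(n - 1)
  cuts <- matrix(stats::cutree(hc, k = ks), nrow = n)   # n x length(ks)
  spread <- vapply(seq_along(ks), function(j)
    partition_spread(cuts[, j], vals), 0)
  rng <- range(spread)
  # a spread range at numerical-noise level is flat: normalising it would
  # amplify 1e-15 jitter into the full [1, N-1] band
  flat_tol <- max(1e-9, 1e-9 * rng[2])
  normalised <- if (diff(rng) > flat_tol)
    (spread - rng[1]) / diff(rng) * (n - 2) + 1
  else rep(1, length(spread))
  penalty <- normalised + ks
  optimal_k <- ks[which.min(penalty)]
  partition <- stats::cutree(hc, k = optimal_k)
  names(partition) <- labels
  res <- list(hclust = hc,
              penalty = data.frame(k = ks, spread = spread,
                                   normalised = normalised,
                                   penalty = penalty),
              optimal_k = optimal_k, partition = partition,
              labels = labels, matrix = vals)
  class(res) <- "ClusteringResult"
  res
}

# mean over non-singleton clusters of mean pairwise distance within cluster
partition_spread <- function(assign, d) {
  sizes <- table(assign)
  ids <- as.integer(names(sizes)[sizes >= 2])
  if (length(ids) == 0L) return(0)
  mean(vapply(ids, function(cl) {
    ix <- which(assign == cl)
    sub <- d[ix, ix]
    mean(sub[upper.tri(sub)])
  }, 0))
}

#' Consensus binding mode from a clustering
#'
#' Completes a [kelley_optimal_k()] result: identifies the most populated
#' cluster (ties: smaller mean intra-cluster RMSD, then lowest member label
#' lexicographically), selects the centroid pose (minimum sum of squared
#' RMSD to all members of that cluster; ties: lowest label), and tabulates
#' per-engine contributions to the consensus cluster in percent.
#'
#' @param ensemble PoseEnsemble the clustering was computed on.
#' @param clustering ClusteringResult.
#' @return the clustering with `most_populated`, `centroid_label`,
#'   `centroid_pose`, `cluster_sizes` and `contributions` (named percentage
#'   vector summing to 100) added.
#' @export
consensus_pose <- function(ensemble, clustering) {
  part <- clustering$partition
  d <- clustering$matrix
  labels <- clustering$labels
  stopifnot(identical(sort(labels), sort(pose_labels(ensemble))))
  sizes <- table(part)
  top <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(top) > 1) {
    spread_of <- vapply(top, function(cl) {
      ix <- which(part == cl)
      if (length(ix) < 2) return(0)
      sub <- d[ix, ix]
      mean(sub[upper.tri(sub)])
    }, 0)
    top <- top[spread_of == min(spread_of)]
    if (length(top) > 1) {
      first_label <- vapply(top, function(cl) min(labels[part == cl]), "")
      top <- top[which.min(first_label)]
    }
  }
  members <- which(part == top)
  sub <- d[members, members, drop = FALSE]
  score <- rowSums(sub^2)
  best <- members[score == min(score)]
  centroid <- labels[best[order(labels[best])][1]]

  engines <- vapply(ensemble$poses, `[[`, "", "engine")
  names(engines) <- pose_labels(ensemble)
  tab <- table(engines[labels[members]])
  contributions <- 100 * as.numeric(tab) / length(members)
  names(contributions) <- names(tab)
  contributions <- sort(contributions, decreasing = TRUE)

  clustering$most_populated <- top
  clustering$cluster_sizes <- sizes
  clustering$centroid_label <- centroid
  clustering$centroid_pose <- resolve_pose(ensemble, centroid)
  clustering$contributions <- contributions
  clustering
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: %d poses, optimal k = %d (Kelley)\n",
              length(x$labels), x$optimal_k))
  if (!is.null(x$centroid_label))
    cat(sprintf("  consensus: cluster %d (%d members), centroid %s\n",
                x$most_populated,
                as.integer(x$cluster_sizes[as.character(x$most_populated)]),
                x$centroid_label))
  if (!is.null(x$contributions))
    cat("  contributions:",
        paste(sprintf("%s %.0f%%", names(x$contributions), x$contributions),
              collapse = ", "), "\n")
  invisible(x)
}
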