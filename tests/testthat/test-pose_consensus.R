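make_gen <- function(seed = 1, ...) {
  toy <- build_toy_complex(toy_spec(seed = seed))
  generate_pose_ensemble(toy, ensemble_spec(seed = seed + 100L, ...))
}

test_that("restraint checking uses minimum heavy-atom distances", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  r <- restraint(paste0("A:", truth$r_resno), paste0("B:", truth$l_resno))
  rec <- subset_structure(toy, select_atoms(toy, chain = "A"))
  lig <- subset_structure(toy, select_atoms(toy, chain = "B"))
  chk <- check_restraints(rec, lig, r)
  # planted contacts all sit within [2, 10]
  expect_true(chk$satisfied)
  expect_equal(nrow(chk$report), nrow(truth) * 2)
  # report equals the brute-force residue-pair scan
  for (i in seq_len(nrow(chk$report))) {
    row <- chk$report[i, ]
    partner <- if (row$side == "receptor") truth$l_resno else truth$r_resno
    pch <- if (row$side == "receptor") "B" else "A"
    brute <- min(vapply(partner, function(rn)
      oracle_min_dist(toy, row$chain, row$resno, pch, rn), 0))
    expect_equal(row$min_distance, brute, tolerance = 1e-9)
  }
  # a pose pushed into the receptor violates the lower bound, named
  lig2 <- lig
  coords(lig2) <- sweep(coords(lig2), 2, c(0, -9.5, 0), `+`)
  chk2 <- check_restraints(rec, lig2, r)
  expect_false(chk2$satisfied)
  expect_true(any(!chk2$report$satisfied))
  bad <- chk2$report[!chk2$report$satisfied, ]
  expect_true(all(bad$min_distance < 2))
  # absent restrained residue errors, naming it
  r_bad <- restraint("A:999", paste0("B:", truth$l_resno))
  expect_error(check_restraints(rec, lig, r_bad), "A:999")
  expect_error(restraint("A:1", "B:1", lower = 10, upper = 2), "lower")
})

test_that("superposition removes rigid motion and matches the closed form", {
  gen <- make_gen(2)
  ens <- gen$ensemble
  # already-referenced ensemble: identity transforms, fit RMSD 0
  out <- superpose_on_receptor(ens)
  expect_true(all(out$fit_rmsd == 0))
  expect_equal(out$poses[[1]]$ligand_coords, ens$poses[[1]]$ligand_coords)

  # give each pose a rigidly moved receptor frame; superposition must
  # recover it to ~1e-6 and restore the ligand placement
  set.seed(42)
  Xrec <- coords(ens$receptor)
  for (i in seq_along(ens$poses)[1:5]) {
    ax <- rnorm(3); ang <- runif(1, 0.1, 2)
    R <- bindmode:::axis_angle_rotation(ax, ang)
    t <- rnorm(3, 0, 10)
    p <- ens$poses[[i]]
    p$receptor_coords <- sweep(tcrossprod(Xrec, R), 2, t, `+`)
    p$ligand_coords <- sweep(tcrossprod(p$ligand_coords, R), 2, t, `+`)
    ens$poses[[i]] <- p
  }
  out <- superpose_on_receptor(ens)
  expect_lt(max(out$fit_rmsd), 1e-6)
  for (i in 1:5)
    expect_equal(out$poses[[i]]$ligand_coords,
                 gen$ensemble$poses[[i]]$ligand_coords, tolerance = 1e-6)

  # Kabsch residual equals the independent eigenvalue closed form
  set.seed(7)
  P <- matrix(rnorm(30), 10, 3)
  Q <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(P, Q)$rmsd, oracle_fit_rmsd(P, Q), tolerance = 1e-9)
  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "at least 3")
  coll <- cbind(1:5, 0, 0)
  expect_error(kabsch(coll, coll), "collinear")
})

test_that("RMSD matrix equals brute force and obeys closed-form limits", {
  gen <- make_gen(3)
  ens <- gen$ensemble
  m <- rmsd_matrix(ens)
  expect_true(isSymmetric(m$values))
  expect_true(all(diag(m$values) == 0))
  lh <- select_atoms(ens$ligand_template, heavy = TRUE)
  brute <- oracle_rmsd_matrix(lapply(ens$poses, function(p)
    p$ligand_coords[lh, , drop = FALSE]))
  expect_equal(unname(m$values), brute, tolerance = 1e-9)

  # translation by (3,4,0) gives RMSD exactly 5
  p1 <- ens$poses[[1]]
  p2 <- pose_record(sweep(p1$ligand_coords, 2, c(3, 4, 0), `+`), "Z", 1, 1)
  ens2 <- pose_ensemble(ens$receptor, ens$ligand_template,
                        list(p1, p2, ens$poses[[2]]))
  m2 <- rmsd_matrix(ens2)
  expect_equal(m2$values[1, 2], 5, tolerance = 1e-12)

  # invariance under a global rigid motion of the superposed ensemble
  R <- bindmode:::axis_angle_rotation(c(1, 2, 3), 0.7)
  t <- c(5, -3, 11)
  ens3 <- ens
  for (i in seq_along(ens3$poses))
    ens3$poses[[i]]$ligand_coords <-
      sweep(tcrossprod(ens3$poses[[i]]$ligand_coords, R), 2, t, `+`)
  m3 <- rmsd_matrix(ens3)
  expect_lt(max(abs(m3$values - m$values)), 1e-6)
})

test_that("Kelley penalty selects the planted level and matches brute force", {
  toy <- default_toy()
  # two tight bundles: zero-ish spread partition at k = 2 wins
  lig <- subset_structure(toy, select_atoms(toy, chain = "B"))
  L0 <- coords(lig)
  # duplicate poses within each bundle: the zero-spread partition at k = 2
  # minimises the penalty (1 + k) over every level
  mk <- function(shift, eng, m) pose_record(
    sweep(L0, 2, shift, `+`), eng, m, 1)
  rec <- subset_structure(toy, select_atoms(toy, chain = "A"))
  poses <- c(lapply(1:5, function(i) mk(c(0, 0, 0), "A", i)),
             lapply(1:5, function(i) mk(c(30, 0, 0), "B", i)))
  ens <- pose_ensemble(rec, lig, poses)
  cl <- kelley_optimal_k(rmsd_matrix(ens))
  expect_equal(cl$optimal_k, 2)
  expect_equal(sort(unique(cl$partition)), 1:2)
  expect_true(all(table(cl$partition) == 5))

  # penalty curve equals level-by-level recomputation from the dendrogram
  m <- rmsd_matrix(ens)
  oc <- oracle_kelley_curve(cl$hclust, unname(m$values))
  expect_equal(cl$penalty$penalty, oc$penalty, tolerance = 1e-9)
  expect_true(all(is.finite(cl$penalty$penalty)))

  # argmin invariant under pose relabelling (permuted matrix)
  set.seed(3)
  perm <- sample(length(poses))
  mp <- m
  mp$values <- m$values[perm, perm]
  mp$labels <- m$labels[perm]
  expect_equal(kelley_optimal_k(mp)$optimal_k, cl$optimal_k)

  expect_error(kelley_optimal_k(m$values[1:2, 1:2]), "at least 3")
})

test_that("three planted Gaussian modes give optimal k = 3", {
  toy <- default_toy()
  mo <- generate_mode_ensemble(toy, n_modes = 3, poses_per_mode = 15,
                               separation = 15, noise_sd = 0.3, seed = 9)
  cl <- kelley_optimal_k(rmsd_matrix(mo$ensemble))
  expect_equal(cl$optimal_k, 3)
  # recovered partition matches the planted modes up to relabelling
  expect_equal(length(unique(paste(cl$partition, mo$mode))), 3)
})

test_that("consensus pose: populated cluster, centroid, contributions", {
  gen <- make_gen(4)
  ens <- superpose_on_receptor(gen$ensemble)
  cl <- consensus_pose(ens, kelley_optimal_k(rmsd_matrix(ens)))
  # contributions sum to 100 +- 0.1 and block sizes sum to N
  expect_equal(sum(cl$contributions), 100, tolerance = 0.1)
  expect_equal(sum(cl$cluster_sizes), length(ens$poses))
  # centroid is a member of the most populated cluster
  expect_equal(unname(cl$partition[cl$centroid_label]),
               unname(cl$most_populated))
  # centroid equals the exhaustive argmin oracle
  members <- which(cl$partition == cl$most_populated)
  expect_equal(cl$centroid_label,
               oracle_centroid(members, cl$matrix, cl$labels))
  # engine share arithmetic: counts {A:2, B:1, C:1} -> 50/25/25
  # two duplicate bundles; the populated one has engine counts A:2 B:1 C:1
  toy <- default_toy()
  lig <- subset_structure(toy, select_atoms(toy, chain = "B"))
  rec <- subset_structure(toy, select_atoms(toy, chain = "A"))
  L0 <- coords(lig)
  mk <- function(eng, m, shift = c(0, 0, 0))
    pose_record(sweep(L0, 2, shift, `+`), eng, m, 1)
  ens2 <- pose_ensemble(rec, lig,
                        list(mk("A", 1), mk("A", 2), mk("B", 1), mk("C", 1),
                             mk("D", 1, c(40, 0, 0)), mk("D", 2, c(40, 0, 0))))
  cl2 <- consensus_pose(ens2, kelley_optimal_k(rmsd_matrix(ens2)))
  expect_equal(unname(cl2$contributions[c("A", "B", "C")]), c(50, 25, 25))
  # all-zero intra distances: centroid tie broken to the lowest label
  expect_equal(cl2$centroid_label, "A-1-1")
})
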