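test_that("separated partners have exactly zero binding energy", {
  toy <- default_toy()
  far <- toy
  bidx <- select_atoms(toy, chain = "B")
  cc <- coords(far)
  cc[bidx, 2] <- cc[bidx, 2] + 100   # far beyond every cutoff
  coords(far) <- cc
  e <- interface_energy(far)
  expect_identical(e$dG_bind, 0)
  expect_true(all(e$components == 0))
})

test_that("the end-point identity and component sum hold to machine precision", {
  for (seed in c(1, 6)) {
    toy <- build_toy_complex(toy_spec(seed = seed))
    e <- interface_energy(toy)
    # end-point identity at machine precision (a few ulp of the G terms)
    expect_equal(e$dG_bind, e$G_complex - e$G_receptor - e$G_ligand,
                 tolerance = 1e-12)
    # component sum is exact by construction
    expect_identical(e$dG_bind, sum(e$components))
  }
})

test_that("cross-interface component sums equal the double-loop oracle", {
  model <- energy_model()
  for (seed in 1:2) {
    toy <- build_toy_complex(toy_spec(seed = seed))
    e <- interface_energy(toy, model)
    brute <- oracle_cross_energy(toy, model)
    expect_equal(unname(e$components["vdw"]), brute$vdw, tolerance = 1e-9)
    expect_equal(unname(e$components["elec"]), brute$elec, tolerance = 1e-9)
    expect_equal(unname(e$components["lipo"]), brute$lipo, tolerance = 1e-9)
  }
})

test_that("dG_bind is invariant under a global rigid motion", {
  toy <- default_toy()
  e0 <- interface_energy(toy)
  R <- bindmode:::axis_angle_rotation(c(2, -1, 4), 0.9)
  moved <- toy
  coords(moved) <- sweep(tcrossprod(coords(toy), R), 2, c(7, -2, 3), `+`)
  e1 <- interface_energy(moved)
  expect_lt(abs(e1$dG_bind - e0$dG_bind), 1e-6)
})

test_that("removing an attractive contact never strengthens binding", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  e0 <- interface_energy(toy)
  for (i in seq_len(nrow(truth))) {
    broken <- toy
    li <- select_atoms(toy, chain = "B", resno = truth$l_resno[i],
                       name = truth$l_atom[i])
    cc <- coords(broken)
    cc[li, 2] <- cc[li, 2] + 30
    coords(broken) <- cc
    expect_gte(interface_energy(broken)$dG_bind, e0$dG_bind)
  }
})

test_that("trajectory energy: stride, mean, standard error", {
  toy <- default_toy()
  X0 <- coords(toy)
  # static trajectory: SE 0, mean equals the single-frame value
  tr <- new_trajectory(toy, rep(list(X0), 8), dt_ns = 1)
  te <- trajectory_binding_energy(tr, stride_ns = 2)
  expect_equal(te$se, 0)
  expect_equal(te$mean, interface_energy(toy)$dG_bind)
  expect_equal(te$n, 4)   # frames 1,3,5,7 of 8 at 2 ns stride
  # alternating two geometries: mean is the midpoint
  truth <- attr(toy, "truth")
  sbl <- select_atoms(toy, chain = "B", resno =
                        truth$l_resno[truth$type == "salt_bridge"])
  alt <- X0; alt[sbl, 2] <- alt[sbl, 2] + 50
  tr2 <- new_trajectory(toy, list(X0, alt, X0, alt), dt_ns = 2)
  te2 <- trajectory_binding_energy(tr2, stride_ns = 2)
  g1 <- interface_energy(toy)$dG_bind
  s2 <- toy; coords(s2) <- alt
  g2 <- interface_energy(s2)$dG_bind
  expect_equal(te2$mean, mean(c(g1, g2, g1, g2)))
  # mean/SE equal recomputation from the per-frame list
  tr3 <- generate_trajectory(toy, 12, jitter_sd = 0.2, seed = 4)
  te3 <- trajectory_binding_energy(tr3, stride_ns = 3)
  expect_equal(te3$mean, mean(te3$frames$dG))
  expect_equal(te3$se, sd(te3$frames$dG) / sqrt(nrow(te3$frames)))
  expect_error(trajectory_binding_energy(tr, stride_ns = 100), "stride")
})

test_that("alanine scan: exact zeros, planted hotspot, threshold", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  hs <- alanine_scan(toy)
  # planted salt-bridge residues dominate the ranking
  sb <- truth[truth$type == "salt_bridge", ]
  expect_equal(hs$resno[1], sb$r_resno)
  expect_true(hs$is_hotspot[1])
  expect_true(all(hs$ddG[hs$mutated] >= 0 | abs(hs$ddG[hs$mutated]) < 1e-9))
  # alanine -> alanine is the identity: ddG exactly 0
  hs_ala <- alanine_scan(toy, residues = "A:1")
  expect_identical(hs_ala$ddG, 0)
  # far-from-interface typed residue: exactly 0 (no cross terms touched)
  sp <- toy_spec(receptor_length = 20,
                 receptor_sequence = c("LEU", rep("ALA", 19)))
  toy2 <- build_toy_complex(sp)
  # contact placement overwrote positions 3,6,9; residue 20 stays far
  sp2 <- toy_spec(receptor_length = 20,
                  receptor_sequence = c(rep("ALA", 19), "GLN"))
  toy2 <- build_toy_complex(sp2)
  d_min <- min(bindmode:::cross_dist2(
    coords(toy2, select_atoms(toy2, chain = "A", resno = 20)),
    coords(toy2, select_atoms(toy2, chain = "B"))))
  expect_gt(sqrt(d_min), 15)
  hs_far <- alanine_scan(toy2, residues = "A:20")
  expect_identical(hs_far$ddG, 0)
  # glycine is flagged unmutated
  sp3 <- toy_spec(ligand_sequence = c(rep("ALA", 9), "GLY"))
  toy3 <- build_toy_complex(sp3)
  hs_gly <- alanine_scan(toy3, residues = "B:10")
  expect_false(hs_gly$mutated)
  expect_true(is.na(hs_gly$ddG))
  expect_error(alanine_scan(toy, residues = "A:999"), "not in structure")
})

test_that("hotspot consensus: Borda ranks, ties, flag rule", {
  toy <- default_toy()
  t1 <- alanine_scan(toy)
  # identical tables keep the input order
  cons <- hotspot_consensus(list(a = t1, b = t1))
  expect_equal(cons$resno[1], t1$resno[1])
  expect_equal(cons$consensus_hotspot[1], t1$is_hotspot[1])
  # Borda scores equal hand-computed rank sums
  t2 <- t1
  t2$ddG <- rev(t1$ddG)          # a disagreeing second scorer
  cons2 <- hotspot_consensus(list(a = t1, b = t2))
  key <- paste(cons2$chain, cons2$resno)
  for (i in seq_len(nrow(cons2))) {
    r1 <- rank(-ifelse(is.na(t1$ddG), -Inf, t1$ddG), ties.method = "min")
    o1 <- t1[order(t1$chain, t1$resno), ]
    r1 <- rank(-ifelse(is.na(o1$ddG), -Inf, o1$ddG), ties.method = "min")
    o2 <- t2[order(t2$chain, t2$resno), ]
    r2 <- rank(-ifelse(is.na(o2$ddG), -Inf, o2$ddG), ties.method = "min")
    j <- match(key[i], paste(o1$chain, o1$resno))
    expect_equal(cons2$borda[i], r1[j] + r2[j])
  }
  # two residues with fully reversed orders tie; broken by residue number
  tA <- data.frame(chain = "A", resno = c(5, 9), ddG = c(2, 1),
                   is_hotspot = c(TRUE, TRUE))
  tB <- data.frame(chain = "A", resno = c(5, 9), ddG = c(1, 2),
                   is_hotspot = c(TRUE, TRUE))
  consT <- hotspot_consensus(list(tA, tB))
  expect_equal(consT$borda, c(3, 3))
  expect_equal(consT$resno, c(5, 9))
  # mismatched residue sets error
  tC <- data.frame(chain = "A", resno = c(5, 10), ddG = c(1, 2),
                   is_hotspot = c(TRUE, FALSE))
  expect_error(hotspot_consensus(list(tA, tC)), "share")
})
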