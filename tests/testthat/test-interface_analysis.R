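test_that("planted contacts are detected and classified across the interface", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  ints <- detect_interactions(toy)
  # the planted salt bridge is reported with its exact atoms and distance
  sb <- ints[ints$type == "salt_bridge", ]
  tsb <- truth[truth$type == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(sb$r_resno, tsb$r_resno)
  expect_equal(sb$r_atom, "NZ")
  expect_equal(sb$l_atom, "OE1")
  expect_equal(sb$distance, tsb$distance, tolerance = 0.1)
  # the Lys-Glu pair also satisfies the distance-only H-bond rule
  expect_true(any(ints$type == "hbond" & ints$r_resno == tsb$r_resno))
  # the planted hbond pair is found
  thb <- truth[truth$type == "hbond", ]
  expect_true(any(ints$type == "hbond" & ints$r_resno == thb$r_resno &
                    ints$l_resno == thb$l_resno))
  # distances never exceed the type cutoff
  crit <- interaction_criteria()
  expect_true(all(ints$distance[ints$type == "hbond"] <= crit$hbond_dist))
  expect_true(all(ints$distance[ints$type == "salt_bridge"] <=
                    crit$salt_bridge_dist))
  # partners pulled 20 A apart interact nowhere
  far <- toy
  bidx <- select_atoms(toy, chain = "B")
  cc <- coords(far)
  cc[bidx, 2] <- cc[bidx, 2] + 20
  coords(far) <- cc
  expect_equal(nrow(detect_interactions(far)), 0)
  # missing role assignment errors
  noro <- toy; noro$roles <- NULL
  expect_error(detect_interactions(noro), "roles")
})

test_that("hbond/salt-bridge list equals the independent brute-force scan", {
  for (seed in 1:3) {
    toy <- build_toy_complex(toy_spec(seed = seed))
    ints <- detect_interactions(toy)
    ints <- ints[ints$type %in% c("hbond", "salt_bridge"), ]
    brute <- oracle_interactions(toy)
    key <- function(d) sort(paste(d$type, d$r_resno, d$l_resno))
    expect_identical(key(ints[!duplicated(
      paste(ints$type, ints$r_resno, ints$l_resno)), ]),
      unique(key(brute)))
    # distances agree pair by pair
    for (i in seq_len(nrow(ints))) {
      b <- brute[brute$type == ints$type[i] &
                   brute$r_resno == ints$r_resno[i] &
                   brute$l_resno == ints$l_resno[i], ]
      expect_true(any(abs(b$distance - ints$distance[i]) < 1e-9))
    }
  }
})

test_that("detection is symmetric under receptor/ligand swap", {
  toy <- default_toy()
  fwd <- detect_interactions(toy)
  swapped <- set_chain_roles(toy, c(A = "ligand", B = "receptor"))
  rev <- detect_interactions(swapped)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(fwd$type, fwd$r_resno, fwd$l_resno, round(fwd$distance, 6)),
                  paste(rev$type, rev$l_resno, rev$r_resno, round(rev$distance, 6)))
})

test_that("pi-stacking between full rings: parallel, T-shaped, and cutoffs", {
  par <- stacked_phe_complex(sep = 4.0)
  ints <- detect_interactions(par)
  ps <- ints[ints$type == "pi_stacking", ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$distance, 4.0, tolerance = 1e-6)
  # the 5.69 A centroid separation in a parallel stack still classifies
  wide <- stacked_phe_complex(sep = 5.69)
  expect_true(any(detect_interactions(wide)$type == "pi_stacking"))
  # beyond 6 A it does not
  off <- stacked_phe_complex(sep = 6.5)
  expect_false(any(detect_interactions(off)$type == "pi_stacking"))
  # T-shaped orientation passes the angular window
  tsh <- stacked_phe_complex(sep = 5.0, tshape = TRUE)
  expect_true(any(detect_interactions(tsh)$type == "pi_stacking"))
})

test_that("interface residues follow the minimum-distance rule", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  ir <- interface_residues(toy, cutoff = 4.5)
  # exactly the planted contact residues are at the interface
  expect_setequal(ir$resno[ir$side == "receptor"], truth$r_resno)
  expect_setequal(ir$resno[ir$side == "ligand"], truth$l_resno)
  # reported minima equal the brute-force scan against the whole partner
  for (i in seq_len(nrow(ir))) {
    partner_ch <- if (ir$side[i] == "receptor") "B" else "A"
    partner_res <- unique(toy$atoms$resno[toy$atoms$chain == partner_ch])
    brute <- min(vapply(partner_res, function(rn)
      oracle_min_dist(toy, ir$chain[i], ir$resno[i], partner_ch, rn), 0))
    expect_equal(ir$min_distance[i], brute, tolerance = 1e-9)
  }
  # absurdly small cutoff empties the set on a clash-free complex
  expect_equal(nrow(interface_residues(toy, cutoff = 0.1)), 0)
  # a wider cutoff is monotone: supersets only
  wide <- interface_residues(toy, cutoff = 8)
  expect_true(all(paste(ir$chain, ir$resno) %in% paste(wide$chain, wide$resno)))
})

test_that("distance monitor handles atoms, groups and statistics", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  sb <- truth[truth$type == "salt_bridge", ]
  from <- paste("A", sb$r_resno, "NZ", sep = ":")
  to <- paste("B", sb$l_resno, "OE1", sep = ":")
  # static trajectory: constant distance, sd 0
  frames <- rep(list(coords(toy)), 4)
  tr <- new_trajectory(toy, frames)
  ds <- monitor_distance(tr, from, to)
  expect_equal(ds$mean, sb$distance, tolerance = 0.1)
  expect_equal(ds$sd, 0)
  # alternating 6/8 A: mean 7, sd 1 (population-style two-point check)
  i_nz <- select_atoms(toy, chain = "A", resno = sb$r_resno, name = "NZ")
  i_oe <- select_atoms(toy, chain = "B", resno = sb$l_resno, name = "OE1")
  f6 <- coords(toy); f8 <- coords(toy)
  dirv <- f6[i_oe, ] - f6[i_nz, ]; dirv <- dirv / sqrt(sum(dirv^2))
  f6[i_oe, ] <- f6[i_nz, ] + 6 * dirv
  f8[i_oe, ] <- f8[i_nz, ] + 8 * dirv
  tr2 <- new_trajectory(toy, list(f6, f8, f6, f8))
  ds2 <- monitor_distance(tr2, from, to)
  expect_equal(ds2$mean, 7)
  expect_equal(ds2$distance, c(6, 8, 6, 8), tolerance = 1e-9)
  # sample sd of alternating 6/8 over 4 frames
  expect_equal(ds2$sd, sd(c(6, 8, 6, 8)))
  # group target: nearest atom of the group per frame
  grp <- monitor_distance(tr2, from, list(resname = "GLU",
                                          atoms = c("OE1", "CB")))
  for (f in 1:4) {
    d_oe <- sqrt(sum((tr2$frames[[f]][i_oe, ] - tr2$frames[[f]][i_nz, ])^2))
    i_cb <- select_atoms(toy, chain = "B", resno = sb$l_resno, name = "CB")
    d_cb <- sqrt(sum((tr2$frames[[f]][i_cb, ] - tr2$frames[[f]][i_nz, ])^2))
    expect_equal(grp$distance[f], min(d_oe, d_cb), tolerance = 1e-9)
  }
  expect_error(monitor_distance(tr, "A:999:NZ", to), "matches 0 atoms")
})

test_that("occupancy counts frames, flags stability at the 0.5 boundary", {
  toy <- default_toy()
  truth <- attr(toy, "truth")
  sb <- truth[truth$type == "salt_bridge", ]
  i_oe <- select_atoms(toy, chain = "B", resno = sb$l_resno, name = "OE1")
  near <- coords(toy)
  broken <- coords(toy)
  broken[i_oe, 2] <- broken[i_oe, 2] + 10   # pull the Glu oxygen away
  # present in exactly 3 of 6 frames -> occupancy 0.5, stable (inclusive)
  tr <- new_trajectory(toy, list(near, broken, near, broken, near, broken))
  occ <- interaction_occupancy(tr)
  row <- occ[occ$type == "salt_bridge" & occ$r_resno == sb$r_resno, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$occupancy, 0.5)
  expect_true(row$stable)
  expect_equal(row$mean_distance, sb$distance, tolerance = 0.1)
  # never-present contacts are absent from the table
  expect_false(any(occ$occupancy == 0))
  # occupancy equals frame-by-frame brute force for every key
  per_frame <- lapply(tr$frames, function(f) {
    s <- toy; coords(s) <- f
    d <- detect_interactions(s)
    unique(paste(d$type, d$r_resno, d$l_resno))
  })
  for (i in seq_len(nrow(occ))) {
    k <- paste(occ$type[i], occ$r_resno[i], occ$l_resno[i])
    expect_equal(occ$occupancy[i],
                 mean(vapply(per_frame, function(p) k %in% p, TRUE)))
  }
  # tightening a cutoff never raises occupancy
  tight <- interaction_occupancy(tr, interaction_criteria(salt_bridge_dist = 3.0))
  trow <- tight[tight$type == "salt_bridge" & tight$r_resno == sb$r_resno, ]
  expect_true(nrow(trow) == 0 || trow$occupancy <= row$occupancy)
})

test_that("hot regions are connected components of the Calpha graph", {
  s <- straight_chain(40)
  # two groups far apart along the chain (3.8 A spacing: 1-3 vs 31-33)
  hs <- data.frame(chain = "A", resno = c(1, 2, 3, 31, 32, 33),
                   ddG = c(3, 2, 1, 5, 4, 3))
  hr <- hot_regions(hs, s, linkage_cutoff = 12)
  expect_length(hr, 2)
  expect_setequal(hr[[1]]$members$resno, c(1, 2, 3))
  expect_setequal(hr[[2]]$members$resno, c(31, 32, 33))
  # grouping equals brute-force connected components
  X <- t(vapply(hs$resno, function(rn)
    coords(s, select_atoms(s, resno = rn, name = "CA"))[1, ], numeric(3)))
  brute <- oracle_components(X, 12)
  got <- integer(nrow(hs))
  for (k in seq_along(hr)) got[match(hr[[k]]$members$resno, hs$resno)] <- k
  expect_equal(length(unique(paste(got, brute))), length(unique(brute)))
  # single hotspot: one singleton region
  hr1 <- hot_regions(hs[1, ], s)
  expect_length(hr1, 1)
  expect_equal(hr1[[1]]$members$resno, 1)
  # larger cutoff merges everything
  hr_all <- hot_regions(hs, s, linkage_cutoff = 200)
  expect_length(hr_all, 1)
})
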