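# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain double loops and closed forms only.

oracle_rmsd <- function(A, B) {
  tot <- 0
  for (i in seq_len(nrow(A)))
    tot <- tot + sum((A[i, ] - B[i, ])^2)
  sqrt(tot / nrow(A))
}

oracle_rmsd_matrix <- function(coord_list) {
  n <- length(coord_list)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- oracle_rmsd(coord_list[[i]], coord_list[[j]])
  d
}

# optimal superposition RMSD via the eigenvalue closed form (never builds a
# rotation matrix; distinct path from the package svd-based Kabsch)
oracle_fit_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Pc) %*% Qc
  ev <- eigen(t(H) %*% H, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  sg <- sqrt(ev)
  if (det(H) < 0) sg[3] <- -sg[3]
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * sum(sg)) / nrow(P)
  sqrt(max(0, msd))
}

# Kelley penalty curve recomputed level by level from the dendrogram
oracle_kelley_curve <- function(hc, d) {
  n <- nrow(d)
  ks <- 2:(n - 1)
  spread <- numeric(length(ks))
  for (a in seq_along(ks)) {
    part <- stats::cutree(hc, k = ks[a])
    vals <- c()
    for (cl in unique(part)) {
      ix <- which(part == cl)
      if (length(ix) < 2) next
      pp <- c()
      for (i in ix) for (j in ix) if (i < j) pp <- c(pp, d[i, j])
      vals <- c(vals, mean(pp))
    }
    spread[a] <- if (length(vals)) mean(vals) else 0
  }
  rng <- range(spread)
  norm <- if (diff(rng) > 0) (spread - rng[1]) / diff(rng) * (n - 2) + 1
  else rep(1, length(spread))
  data.frame(k = ks, penalty = norm + ks)
}

oracle_centroid <- function(members, d, labels) {
  best <- NULL; best_score <- Inf
  for (i in members) {
    sc <- 0
    for (j in members) sc <- sc + d[i, j]^2
    if (sc < best_score - 1e-12 ||
        (abs(sc - best_score) <= 1e-12 && labels[i] < best)) {
      best <- labels[i]; best_score <- sc
    }
  }
  best
}

# minimum heavy-atom distance between two residues, plain loop
oracle_min_dist <- function(s, ch1, rn1, ch2, rn2) {
  a <- s$atoms
  i1 <- which(a$chain == ch1 & a$resno == rn1 & a$element != "H")
  i2 <- which(a$chain == ch2 & a$resno == rn2 & a$element != "H")
  best <- Inf
  for (i in i1) for (j in i2) {
    dd <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                 (a$z[i] - a$z[j])^2)
    if (dd < best) best <- dd
  }
  best
}

# independent typed-interaction scan with its own small chemistry tables
oracle_interactions <- function(s, hb = 3.5, sb = 4.0) {
  a <- s$atoms
  rec_ch <- names(s$roles)[s$roles == "receptor"]
  don <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), SER = "OG",
              THR = "OG1", ASN = "ND2", GLN = "NE2", TYR = "OH",
              TRP = "NE1", CYS = "SG", HIS = c("ND1", "NE2"))
  acc <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
              GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
              HIS = c("ND1", "NE2"), MET = "SD")
  pos <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  tag <- function(i, tab) {
    (a$name[i] == "N" && a$resname[i] %in% names(bindmode:::AA3) &&
       a$resname[i] != "PRO" && identical(tab, don)) ||
      (a$name[i] %in% c("O", "OXT") && a$resname[i] %in% names(bindmode:::AA3) &&
         identical(tab, acc)) ||
      (!is.null(tab[[a$resname[i]]]) && a$name[i] %in% tab[[a$resname[i]]])
  }
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (!(a$chain[i] %in% rec_ch) || (a$chain[j] %in% rec_ch)) next
    if (a$element[i] == "H" || a$element[j] == "H") next
    dd <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                 (a$z[i] - a$z[j])^2)
    if (dd <= hb && ((tag(i, don) && tag(j, acc)) ||
                     (tag(j, don) && tag(i, acc))))
      out <- rbind(out, data.frame(type = "hbond", r_resno = a$resno[i],
                                   l_resno = a$resno[j], distance = dd))
    if (dd <= sb && ((tag(i, pos) && tag(j, neg)) ||
                     (tag(j, pos) && tag(i, neg))))
      out <- rbind(out, data.frame(type = "salt_bridge",
                                   r_resno = a$resno[i],
                                   l_resno = a$resno[j], distance = dd))
  }
  out
}

# cross-interface surrogate energy components by double loop
oracle_cross_energy <- function(s, model) {
  a <- s$atoms
  rec_ch <- names(s$roles)[s$roles == "receptor"]
  vdw <- 0; lipo <- 0
  lj <- model$lj
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (!(a$chain[i] %in% rec_ch) || (a$chain[j] %in% rec_ch)) next
    if (a$element[i] == "H" || a$element[j] == "H") next
    dd <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                 (a$z[i] - a$z[j])^2)
    pi_ <- lj[lj$element == a$element[i], ]
    pj <- lj[lj$element == a$element[j], ]
    if (dd <= model$vdw_cutoff) {
      sig <- (pi_$sigma + pj$sigma) / 2
      eps <- sqrt(pi_$eps * pj$eps)
      vdw <- vdw + 4 * eps * ((sig / dd)^12 - (sig / dd)^6)
    }
    if (dd <= model$lipo_cutoff && a$element[i] %in% c("C", "S") &&
        a$element[j] %in% c("C", "S"))
      lipo <- lipo + model$lipo_reward
  }
  # electrostatics between formal charge centres
  elec <- 0
  cc <- function(chains) {
    res <- unique(paste(a$chain, a$resno)[a$chain %in% chains])
    out <- NULL
    for (r in res) {
      p <- strsplit(r, " ")[[1]]
      ix <- which(a$chain == p[1] & a$resno == as.integer(p[2]))
      fc <- model$charges[[a$resname[ix[1]]]]
      if (is.null(fc)) next
      at <- fc$atoms[fc$atoms %in% a$name[ix]]
      if (!length(at)) next
      j <- ix[a$name[ix] == at[1]][1]
      out <- rbind(out, data.frame(q = fc$q, x = a$x[j], y = a$y[j],
                                   z = a$z[j]))
    }
    out
  }
  c1 <- cc(rec_ch); c2 <- cc(setdiff(unique(a$chain), rec_ch))
  if (!is.null(c1) && !is.null(c2))
    for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
      dd <- sqrt((c1$x[i] - c2$x[j])^2 + (c1$y[i] - c2$y[j])^2 +
                   (c1$z[i] - c2$z[j])^2)
      if (dd <= model$elec_cutoff)
        elec <- elec + 332.0636 * c1$q[i] * c2$q[j] /
          (model$dielectric_factor * dd^2)
    }
  list(vdw = vdw, elec = elec, lipo = lipo)
}

# connected components on the thresholded Calpha graph, repeated scanning
oracle_components <- function(X, cutoff) {
  n <- nrow(X)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sqrt(sum((X[i, ] - X[j, ])^2)) <= cutoff &&
          comp[j] != comp[i]) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
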