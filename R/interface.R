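# Donor / acceptor / charged-group / aromatic-ring chemistry tables keyed by
# (residue name, atom name). Backbone N is a donor (except proline) and
# backbone O/OXT acceptors for every standard residue.

SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

POSITIVE_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
CARBOXYLATE_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

NUCLEOTIDE_RES <- c("GTP", "GDP", "ATP", "ADP")

#' Geometric interaction criteria
#'
#' Thresholds for [detect_interactions()]. The defaults are declared
#' surrogates for the (undisclosed) Maestro interaction-panel settings:
#' H-bond donor-acceptor heavy-atom distance <= 3.5 A with a
#' donor-H-acceptor angle >= 120 degrees when the hydrogen is present
#' (distance-only otherwise); salt bridge <= 4.0 A between a protonated-N
#' group atom and a carboxylate/phosphate oxygen; pi-stacking ring-centroid
#' distance <= 6.0 A with inter-plane angle <= 30 degrees (parallel) or
#' 60-120 degrees (T-shaped); aromatic H-bond donor heavy atom <= 4.0 A
#' from a ring centroid.
#'
#' @param hbond_dist,salt_bridge_dist,pi_centroid_dist,aromatic_hb_dist
#'   distance cutoffs, Angstrom.
#' @param hbond_angle minimum D-H-A angle in degrees.
#' @param pi_parallel_max,pi_tshape_min plane-angle limits in degrees.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                                 salt_bridge_dist = 4.0,
                                 pi_centroid_dist = 6.0,
                                 pi_parallel_max = 30, pi_tshape_min = 60,
                                 aromatic_hb_dist = 4.0) {
  stopifnot(hbond_dist > 0, salt_bridge_dist > 0, pi_centroid_dist > 0,
            aromatic_hb_dist > 0)
  list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
       salt_bridge_dist = salt_bridge_dist,
       pi_centroid_dist = pi_centroid_dist,
       pi_parallel_max = pi_parallel_max, pi_tshape_min = pi_tshape_min,
       aromatic_hb_dist = aromatic_hb_dist)
}

atom_role_table <- function(s) {
  a <- s$atoms
  std <- a$resname %in% names(AA3)
  donor <- (std & a$name == "N" & a$resname != "PRO")
  acceptor <- (std & a$name %in% c("O", "OXT"))
  for (rn in names(SIDECHAIN_DONORS))
    donor <- donor | (a$resname == rn & a$name %in% SIDECHAIN_DONORS[[rn]])
  for (rn in names(SIDECHAIN_ACCEPTORS))
    acceptor <- acceptor |
      (a$resname == rn & a$name %in% SIDECHAIN_ACCEPTORS[[rn]])
  # nucleotides: all oxygens accept
  acceptor <- acceptor |
    (a$resname %in% NUCLEOTIDE_RES & a$element == "O")

  positive <- rep(FALSE, nrow(a))
  for (rn in names(POSITIVE_ATOMS))
    positive <- positive | (a$resname == rn & a$name %in% POSITIVE_ATOMS[[rn]])
  # doubly protonated histidine carries a positive charge
  his_keys <- unique(paste(a$chain, a$resno, a$icode)[a$resname == "HIS"])
  if (length(his_keys)) {
    key <- paste(a$chain, a$resno, a$icode)
    for (k in his_keys) {
      hn <- a$name[key == k & a$element == "H"]
      if (all(c("HD1", "HE2") %in% hn))
        positive <- positive | (key == k & a$name %in% c("ND1", "NE2"))
    }
  }
  negative <- rep(FALSE, nrow(a))
  for (rn in names(CARBOXYLATE_ATOMS))
    negative <- negative |
      (a$resname == rn & a$name %in% CARBOXYLATE_ATOMS[[rn]])
  negative <- negative | (std & a$name == "OXT") |
    (a$resname %in% NUCLEOTIDE_RES & a$element == "O" &
       grepl("^O[123][ABG]$", a$name))
  list(donor = donor, acceptor = acceptor, positive = positive,
       negative = negative)
}

# rings present (>= 3 atoms) with centroid and unit normal
ring_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$icode)
  out <- list()
  for (k in unique(key[a$resname %in% names(AROMATIC_RINGS)])) {
    ix <- which(key == k)
    rn <- a$resname[ix[1]]
    for (ring in AROMATIC_RINGS[[rn]]) {
      jx <- ix[a$name[ix] %in% ring]
      if (length(jx) < 3) next
      X <- coords(s, jx)
      cen <- colMeans(X)
      sv <- svd(sweep(X, 2, cen))
      out[[length(out) + 1]] <- list(
        chain = a$chain[ix[1]], resno = a$resno[ix[1]], resname = rn,
        atoms = a$name[jx], centroid = cen, normal = sv$v[, 3])
    }
  }
  out
}

# hydrogens within 1.25 A of a donor heavy atom, same residue
donor_hydrogens <- function(s, donor_idx) {
  a <- s$atoms
  d <- a[donor_idx, ]
  ix <- which(a$element == "H" & a$chain == d$chain & a$resno == d$resno &
                a$icode == d$icode)
  if (!length(ix)) return(integer(0))
  dd <- sqrt(rowSums(sweep(coords(s, ix), 2, unlist(d[c("x", "y", "z")]))^2))
  ix[dd <= 1.25]
}

angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Detect typed noncovalent interactions across the interface
#'
#' Scans every receptor-side / ligand-side pair (cofactor chains count with
#' the ligand) and reports hydrogen bonds, salt bridges, pi-stacking and
#' aromatic hydrogen bonds satisfying the geometric criteria. A
#' salt-bridge pair that also satisfies the H-bond criterion yields both
#' records. Output order is deterministic: receptor residue, ligand
#' residue, then type.
#'
#' @param complex Structure with chain roles assigned.
#' @param criteria see [interaction_criteria()].
#' @return data.frame with columns `type`, `r_chain`, `r_resno`,
#'   `r_resname`, `r_atom`, `l_chain`, `l_resno`, `l_resname`, `l_atom`,
#'   `distance`.
#' @export
detect_interactions <- function(complex, criteria = interaction_criteria()) {
  if (is.null(complex$roles)) stop("chain roles must be assigned")
  a <- complex$atoms
  rec_idx <- role_indices(complex, "receptor")
  lig_idx <- role_indices(complex, "ligand")
  roles <- atom_role_table(complex)
  recs <- list()
  add <- function(type, ri, li, dist, r_atom = a$name[ri], l_atom = a$name[li]) {
    recs[[length(recs) + 1]] <<- data.frame(
      type = type,
      r_chain = a$chain[ri], r_resno = a$resno[ri], r_resname = a$resname[ri],
      r_atom = r_atom,
      l_chain = a$chain[li], l_resno = a$resno[li], l_resname = a$resname[li],
      l_atom = l_atom, distance = dist, stringsAsFactors = FALSE)
  }

  pair_scan <- function(idx1, idx2, cutoff) {
    if (!length(idx1) || !length(idx2)) return(NULL)
    d2 <- cross_dist2(coords(complex, idx1), coords(complex, idx2))
    hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hits)) return(NULL)
    data.frame(i = idx1[hits[, 1]], j = idx2[hits[, 2]],
               dist = sqrt(d2[hits]))
  }

  hb_check <- function(di, ai, dist) {
    hyd <- donor_hydrogens(complex, di)
    if (!length(hyd)) return(TRUE)      # distance-only when no H present
    D <- as.numeric(a[di, c("x", "y", "z")])
    A <- as.numeric(a[ai, c("x", "y", "z")])
    any(vapply(hyd, function(h) {
      H <- as.numeric(a[h, c("x", "y", "z")])
      angle_deg(D, H, A) >= criteria$hbond_angle
    }, TRUE))
  }

  # hydrogen bonds, both donor orientations
  for (dir in 1:2) {
    don_side <- if (dir == 1) rec_idx else lig_idx
    acc_side <- if (dir == 1) lig_idx else rec_idx
    don <- don_side[roles$donor[don_side]]
    acc <- acc_side[roles$acceptor[acc_side]]
    hits <- pair_scan(don, acc, criteria$hbond_dist)
    if (!is.null(hits)) for (h in seq_len(nrow(hits))) {
      if (!hb_check(hits$i[h], hits$j[h], hits$dist[h])) next
      if (dir == 1) add("hbond", hits$i[h], hits$j[h], hits$dist[h])
      else add("hbond", hits$j[h], hits$i[h], hits$dist[h])
    }
  }

  # salt bridges, both charge orientations
  for (dir in 1:2) {
    pos_side <- if (dir == 1) rec_idx else lig_idx
    neg_side <- if (dir == 1) lig_idx else rec_idx
    pos <- pos_side[roles$positive[pos_side]]
    neg <- neg_side[roles$negative[neg_side]]
    hits <- pair_scan(pos, neg, criteria$salt_bridge_dist)
    if (!is.null(hits)) for (h in seq_len(nrow(hits))) {
      if (dir == 1) add("salt_bridge", hits$i[h], hits$j[h], hits$dist[h])
      else add("salt_bridge", hits$j[h], hits$i[h], hits$dist[h])
    }
  }

  # pi-stacking between rings, and aromatic H-bonds (donor to ring centroid)
  rings <- ring_table(complex)
  if (length(rings)) {
    rec_chains <- a$chain[rec_idx]
    ring_side <- vapply(rings, function(r)
      if (r$chain %in% rec_chains) "receptor" else "ligand", "")
    rr <- rings[ring_side == "receptor"]; lr <- rings[ring_side == "ligand"]
    for (R1 in rr) for (R2 in lr) {
      dist <- sqrt(sum((R1$centroid - R2$centroid)^2))
      if (dist > criteria$pi_centroid_dist) next
      ang <- acos(pmin(1, abs(sum(R1$normal * R2$normal)))) * 180 / pi
      if (ang <= criteria$pi_parallel_max || ang >= criteria$pi_tshape_min) {
        ri <- which(a$chain == R1$chain & a$resno == R1$resno)[1]
        li <- which(a$chain == R2$chain & a$resno == R2$resno)[1]
        add("pi_stacking", ri, li, dist,
            r_atom = "ring", l_atom = "ring")
      }
    }
    # aromatic hbond: donor heavy atom near a partner ring centroid
    for (k in seq_along(rings)) {
      r <- rings[[k]]
      ri_is_ring <- ring_side[k] == "receptor"
      partner <- if (ri_is_ring) lig_idx else rec_idx
      don <- partner[roles$donor[partner]]
      if (!length(don)) next
      dd <- sqrt(rowSums(sweep(coords(complex, don), 2, r$centroid)^2))
      for (h in which(dd <= criteria$aromatic_hb_dist)) {
        if (ri_is_ring) {
          ri <- which(a$chain == r$chain & a$resno == r$resno)[1]
          add("aromatic_hbond", ri, don[h], dd[h], r_atom = "ring")
        } else {
          li <- which(a$chain == r$chain & a$resno == r$resno)[1]
          add("aromatic_hbond", don[h], li, dd[h], l_atom = "ring")
        }
      }
    }
  }

  if (!length(recs)) {
    out <- data.frame(type = character(0), r_chain = character(0),
                      r_resno = integer(0), r_resname = character(0),
                      r_atom = character(0), l_chain = character(0),
                      l_resno = integer(0), l_resname = character(0),
                      l_atom = character(0), distance = numeric(0))
    return(out)
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$r_chain, out$r_resno, out$l_chain, out$l_resno,
                   out$type, out$r_atom, out$l_atom), ]
  rownames(out) <- NULL
  out[, c("type", "r_chain", "r_resno", "r_resname", "r_atom",
          "l_chain", "l_resno", "l_resname", "l_atom", "distance")]
}

#' Interface residues by minimum heavy-atom distance
#'
#' A residue is an interface residue iff its minimum heavy-atom distance to
#' the partner side is at most `cutoff` (default 4.5 A).
#'
#' @param complex Structure with roles.
#' @param cutoff Angstrom.
#' @return data.frame with `side`, `chain`, `resno`, `resname`,
#'   `min_distance`.
#' @export
interface_residues <- function(complex, cutoff = 4.5) {
  if (is.null(complex$roles)) stop("chain roles must be assigned")
  rec <- intersect(role_indices(complex, "receptor"),
                   which(is_heavy(complex)))
  lig <- intersect(role_indices(complex, "ligand"),
                   which(is_heavy(complex)))
  d2 <- cross_dist2(coords(complex, rec), coords(complex, lig))
  a <- complex$atoms
  per_side <- function(idx, mins, side) {
    key <- paste(a$chain[idx], a$resno[idx], a$icode[idx])
    agg <- tapply(mins, key, min)
    first <- idx[!duplicated(key)]
    df <- data.frame(side = side, chain = a$chain[first],
                     resno = a$resno[first], resname = a$resname[first],
                     min_distance = as.numeric(agg[paste(
                       a$chain[first], a$resno[first], a$icode[first])]),
                     stringsAsFactors = FALSE)
    df <- df[df$min_distance <= cutoff, , drop = FALSE]
    df[order(df$chain, df$resno), , drop = FALSE]
  }
  out <- rbind(per_side(rec, sqrt(apply(d2, 1, min)), "receptor"),
               per_side(lig, sqrt(apply(d2, 2, min)), "ligand"))
  rownames(out) <- NULL
  out
}

#' Monitor an atom-atom or atom-group distance along a trajectory
#'
#' `from` is a single-atom spec `"chain:resno:name"`. `to` may be another
#' atom spec or a group (e.g. the GTP gamma-phosphate: phosphorus PG plus
#' its oxygens); for a group, the per-frame distance is to the nearest
#' group atom in that frame.
#'
#' @param traj Trajectory.
#' @param from atom spec string.
#' @param to atom spec string, or a list `list(resname=, atoms=)`, or the
#'   shorthand `"RES:gamma-phosphate"` which expands to
#'   `PG, O1G, O2G, O3G` of residue name `RES`.
#' @return list of class `DistanceSeries`: `time` (ns), `distance` (A),
#'   `mean`, `sd`.
#' @export
monitor_distance <- function(traj, from, to) {
  topo <- traj$topology
  find_atom <- function(spec) {
    p <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(p) != 3) stop("atom spec must be chain:resno:name, got ", spec)
    ix <- select_atoms(topo, chain = p[1], resno = as.integer(p[2]),
                       name = p[3])
    if (length(ix) != 1)
      stop("atom spec ", spec, " matches ", length(ix), " atoms")
    ix
  }
  i_from <- find_atom(from)
  if (is.character(to) && grepl(":gamma-phosphate$", to)) {
    rn <- sub(":gamma-phosphate$", "", to)
    to <- list(resname = rn, atoms = c("PG", "O1G", "O2G", "O3G"))
  }
  i_to <- if (is.character(to)) find_atom(to) else {
    ix <- select_atoms(topo, resname = to$resname, name = to$atoms)
    if (!length(ix)) stop("group spec matches no atoms")
    ix
  }
  dist <- vapply(traj$frames, function(f) {
    p <- f[i_from, ]
    min(sqrt(colSums((t(f[i_to, , drop = FALSE]) - p)^2)))
  }, 0)
  out <- list(time = traj$times, distance = dist,
              mean = mean(dist), sd = stats::sd(dist),
              from = from, to = to)
  class(out) <- "DistanceSeries"
  out
}

#' Interaction occupancy over a trajectory
#'
#' Runs [detect_interactions()] on every frame and collapses atom-level
#' variants to (type, residue pair) keys. Occupancy is the fraction of
#' frames in which the key is present; keys with occupancy >= 0.5 are
#' flagged stable. Pairs never observed are absent from the table.
#'
#' @param traj Trajectory whose topology has chain roles.
#' @param criteria see [interaction_criteria()].
#' @return data.frame: `type`, `r_chain`, `r_resno`, `l_chain`, `l_resno`,
#'   `n_frames`, `occupancy`, `mean_distance`, `sd_distance`, `stable`.
#' @export
interaction_occupancy <- function(traj, criteria = interaction_criteria()) {
  nf <- length(traj$frames)
  if (nf < 2) stop("occupancy needs at least 2 frames")
  s <- traj$topology
  acc <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    coords(s) <- traj$frames[[f]]
    ints <- detect_interactions(s, criteria)
    if (!nrow(ints)) next
    key <- paste(ints$type, ints$r_chain, ints$r_resno,
                 ints$l_chain, ints$l_resno, sep = "|")
    # one presence per key per frame; distance = closest variant
    dmin <- tapply(ints$distance, key, min)
    for (k in names(dmin)) {
      cur <- if (!is.null(acc[[k]])) acc[[k]] else list(n = 0L, d = numeric(0))
      acc[[k]] <- list(n = cur$n + 1L, d = c(cur$d, dmin[[k]]))
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(type = character(0), r_chain = character(0),
                      r_resno = integer(0), l_chain = character(0),
                      l_resno = integer(0), n_frames = integer(0),
                      occupancy = numeric(0), mean_distance = numeric(0),
                      sd_distance = numeric(0), stable = logical(0)))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(type = parts[, 1], r_chain = parts[, 2],
                    r_resno = as.integer(parts[, 3]),
                    l_chain = parts[, 4], l_resno = as.integer(parts[, 5]),
                    n_frames = vapply(keys, function(k) acc[[k]]$n, 0L),
                    stringsAsFactors = FALSE)
  out$occupancy <- out$n_frames / nf
  out$mean_distance <- vapply(keys, function(k) mean(acc[[k]]$d), 0)
  out$sd_distance <- vapply(keys, function(k)
    if (length(acc[[k]]$d) > 1) stats::sd(acc[[k]]$d) else 0, 0)
  out$stable <- out$occupancy >= 0.5
  out <- out[order(out$r_chain, out$r_resno, out$l_chain, out$l_resno,
                   out$type), ]
  rownames(out) <- NULL
  out
}

#' Group binding hotspots into spatial hot regions
#'
#' Single-linkage grouping of hotspot residues: two hotspots are connected
#' when their C-alpha atoms lie within `linkage_cutoff` (default 12 A);
#' regions are the connected components, sorted by decreasing size (ties:
#' smallest member residue number).
#'
#' @param hotspots data.frame with `chain`, `resno` (and optionally `ddG`).
#' @param structure Structure providing coordinates.
#' @param linkage_cutoff Angstrom.
#' @return list of regions, each `list(id, members, center)`.
#' @export
hot_regions <- function(hotspots, structure, linkage_cutoff = 12) {
  if (nrow(hotspots) < 1) stop("need at least one hotspot")
  n <- nrow(hotspots)
  X <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ix <- select_atoms(structure, chain = hotspots$chain[i],
                       resno = hotspots$resno[i], name = "CA")
    if (!length(ix))
      ix <- select_atoms(structure, heavy = TRUE, chain = hotspots$chain[i],
                         resno = hotspots$resno[i])[1]
    if (!length(ix) || is.na(ix))
      stop("hotspot residue ", hotspots$chain[i], ":", hotspots$resno[i],
           " not in structure")
    X[i, ] <- colMeans(coords(structure, ix))
  }
  adj <- as.matrix(stats::dist(X)) <= linkage_cutoff
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  ord <- order(-tabulate(comp)[comp], hotspots$resno)
  ids <- unique(comp[ord])
  lapply(seq_along(ids), function(k) {
    ix <- which(comp == ids[k])
    list(id = k, members = hotspots[ix, , drop = FALSE],
         center = colMeans(X[ix, , drop = FALSE]))
  })
}
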