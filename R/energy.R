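# Declared surrogate interface energy. This is NOT a force field fit: it is
# a transparent stand-in with the same structure as an MM-GBSA end-point
# calculation (per-frame dG_bind = G_complex - G_receptor - G_ligand under
# the single-trajectory convention), built from four components:
# 12-6 Lennard-Jones, Coulomb between per-residue formal charges with a
# distance-dependent dielectric eps(r) = 4r, a fixed reward per detected
# cross-interface hydrogen bond, and a fixed reward per apolar heavy-atom
# contact pair.

LJ_PARAMS <- data.frame(
  element = c("C", "N", "O", "S", "P", "H", "MG"),
  sigma = c(3.50, 3.25, 2.96, 3.55, 3.74, 2.42, 2.91),   # Angstrom
  eps = c(0.066, 0.170, 0.210, 0.250, 0.200, 0.030, 0.875))  # kcal/mol

# formal charge per residue with ordered candidate charge-centre atoms
FORMAL_CHARGES <- list(
  ARG = list(q = +1, atoms = c("CZ", "NH1", "NE", "CB")),
  LYS = list(q = +1, atoms = c("NZ", "CB")),
  ASP = list(q = -1, atoms = c("CG", "OD1", "CB")),
  GLU = list(q = -1, atoms = c("CD", "OE1", "CB")),
  GTP = list(q = -4, atoms = c("PB", "PG", "PA")),
  GDP = list(q = -3, atoms = c("PB", "PA")),
  ATP = list(q = -4, atoms = c("PB", "PG", "PA")),
  ADP = list(q = -3, atoms = c("PB", "PA")))

#' Surrogate interface energy model
#'
#' Parameters for [interface_energy()]. All four components are declared
#' surrogates (see the package vignette); their magnitudes are not
#' comparable with Prime MM-GBSA outputs.
#'
#' @param vdw_cutoff Lennard-Jones cutoff, A.
#' @param elec_cutoff Coulomb cutoff, A.
#' @param dielectric_factor `eps(r) = dielectric_factor * r`.
#' @param hbond_reward kcal/mol per detected cross-interface hydrogen bond
#'   (must be <= 0).
#' @param lipo_reward kcal/mol per apolar (C/S) cross-interface heavy-atom
#'   pair within `lipo_cutoff` (must be <= 0).
#' @param lipo_cutoff A.
#' @param criteria interaction criteria used for the H-bond term.
#' @export
energy_model <- function(vdw_cutoff = 10, elec_cutoff = 12,
                         dielectric_factor = 4, hbond_reward = -1.0,
                         lipo_reward = -0.1, lipo_cutoff = 4.5,
                         criteria = interaction_criteria()) {
  stopifnot(vdw_cutoff > 0, elec_cutoff > 0, lipo_cutoff > 0,
            hbond_reward <= 0, lipo_reward <= 0)
  m <- list(vdw_cutoff = vdw_cutoff, elec_cutoff = elec_cutoff,
            dielectric_factor = dielectric_factor,
            hbond_reward = hbond_reward, lipo_reward = lipo_reward,
            lipo_cutoff = lipo_cutoff, criteria = criteria,
            lj = LJ_PARAMS, charges = FORMAL_CHARGES)
  class(m) <- "EnergyModel"
  m
}

lj_lookup <- function(model, elements) {
  i <- match(elements, model$lj$element)
  if (anyNA(i))
    stop("unparameterized element: ",
         paste(unique(elements[is.na(i)]), collapse = ","))
  list(sigma = model$lj$sigma[i], eps = model$lj$eps[i])
}

# per-residue formal charge centres for a set of atom indices
charge_centres <- function(s, idx, model) {
  a <- s$atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$icode)
  res <- !duplicated(key)
  out <- list(q = numeric(0), xyz = matrix(0, 0, 3))
  for (k in which(res)) {
    rn <- a$resname[k]
    fc <- model$charges[[rn]]
    if (is.null(fc)) next
    here <- which(key == key[k])
    at <- fc$atoms[fc$atoms %in% a$name[here]]
    if (!length(at)) next
    j <- here[match(at[1], a$name[here])]
    out$q <- c(out$q, fc$q)
    out$xyz <- rbind(out$xyz, as.numeric(a[j, c("x", "y", "z")]))
  }
  out
}

# pairwise component energies between two atom index sets (cross terms)
pair_energy <- function(s, idx1, idx2, model) {
  X1 <- coords(s, idx1); X2 <- coords(s, idx2)
  d2 <- cross_dist2(X1, X2)
  d <- sqrt(d2)
  el1 <- s$atoms$element[idx1]; el2 <- s$atoms$element[idx2]
  p1 <- lj_lookup(model, el1); p2 <- lj_lookup(model, el2)
  sig <- outer(p1$sigma, p2$sigma, `+`) / 2
  eps <- sqrt(outer(p1$eps, p2$eps))
  in_vdw <- d <= model$vdw_cutoff & d > 0
  sr6 <- (sig[in_vdw] / d[in_vdw])^6
  vdw <- sum(4 * eps[in_vdw] * (sr6^2 - sr6))

  c1 <- charge_centres(s, idx1, model)
  c2 <- charge_centres(s, idx2, model)
  elec <- 0
  if (length(c1$q) && length(c2$q)) {
    dc <- sqrt(cross_dist2(c1$xyz, c2$xyz))
    qq <- outer(c1$q, c2$q)
    ok <- dc <= model$elec_cutoff & dc > 0
    elec <- sum(332.0636 * qq[ok] / (model$dielectric_factor * dc[ok]^2))
  }

  apolar1 <- el1 %in% c("C", "S"); apolar2 <- el2 %in% c("C", "S")
  lipo <- model$lipo_reward *
    sum(d[apolar1, apolar2, drop = FALSE] <= model$lipo_cutoff)

  list(vdw = vdw, elec = elec, lipo = lipo)
}

#' Surrogate binding free energy of a complex
#'
#' End-point decomposition under the single-trajectory convention: the
#' separated receptor and ligand keep the complex geometry and all
#' cross-interface terms are dropped, so the binding components are exactly
#' the cross-interface sums. `dG_bind` is defined as the sum of the four
#' components and `G_complex` as `G_receptor + G_ligand + dG_bind`, so both
#' identities (`dG = G_c - G_r - G_l` and `dG = sum(components)`) hold to
#' machine precision.
#'
#' @param complex Structure with chain roles.
#' @param model [energy_model()].
#' @return list of class `EnergyDecomposition`: `G_complex`, `G_receptor`,
#'   `G_ligand`, `dG_bind`, `components` (named: vdw, elec, hbond, lipo),
#'   `n_hbonds`.
#' @export
interface_energy <- function(complex, model = energy_model()) {
  if (is.null(complex$roles)) stop("chain roles must be assigned")
  heavy <- which(is_heavy(complex))
  rec <- intersect(role_indices(complex, "receptor"), heavy)
  lig <- intersect(role_indices(complex, "ligand"), heavy)
  cross <- pair_energy(complex, rec, lig, model)
  ints <- detect_interactions(complex, model$criteria)
  n_hb <- sum(ints$type == "hbond")
  comp <- c(vdw = cross$vdw, elec = cross$elec,
            hbond = model$hbond_reward * n_hb, lipo = cross$lipo)
  dG <- sum(comp)
  G_rec <- intra_energy(complex, rec, model)
  G_lig <- intra_energy(complex, lig, model)
  out <- list(G_complex = G_rec + G_lig + dG, G_receptor = G_rec,
              G_ligand = G_lig, dG_bind = dG, components = comp,
              n_hbonds = n_hb)
  class(out) <- "EnergyDecomposition"
  out
}

# intra-partner energy: same functional forms over non-bonded-ish pairs
# (different residues, r >= 2.5 A). Cancels exactly in dG_bind; reported so
# the G terms are physically scaled rather than zero.
intra_energy <- function(s, idx, model) {
  if (length(idx) < 2) return(0)
  X <- coords(s, idx)
  d <- as.matrix(stats::dist(X))
  a <- s$atoms[idx, ]
  same_res <- outer(paste(a$chain, a$resno, a$icode),
                    paste(a$chain, a$resno, a$icode), `==`)
  p <- lj_lookup(model, a$element)
  sig <- outer(p$sigma, p$sigma, `+`) / 2
  eps <- sqrt(outer(p$eps, p$eps))
  ok <- upper.tri(d) & !same_res & d >= 2.5 & d <= model$vdw_cutoff
  sr6 <- (sig[ok] / d[ok])^6
  sum(4 * eps[ok] * (sr6^2 - sr6))
}

#' @export
print.EnergyDecomposition <- function(x, ...) {
  cat(sprintf("dG_bind = %.3f kcal/mol (vdw %.3f, elec %.3f, hbond %.3f, lipo %.3f)\n",
              x$dG_bind, x$components["vdw"], x$components["elec"],
              x$components["hbond"], x$components["lipo"]))
  invisible(x)
}

#' Per-frame binding energy over a trajectory
#'
#' Frames are extracted every `stride_ns` (default 2 ns, i.e. every
#' `stride_ns / dt_ns` frames) and [interface_energy()] evaluated on each;
#' the mean and standard error (sd/sqrt(n), the primary report) plus the
#' plain sd are returned per component.
#'
#' @param traj Trajectory whose topology has chain roles.
#' @param model [energy_model()].
#' @param stride_ns extraction interval, ns.
#' @return list of class `TrajectoryEnergySummary`: `frames` (data.frame
#'   time/dG and components), `mean`, `se`, `sd`, `component_mean`,
#'   `component_se`.
#' @export
trajectory_binding_energy <- function(traj, model = energy_model(),
                                      stride_ns = 2) {
  span <- traj$times[length(traj$times)] - traj$times[1]
  if (stride_ns > span) stop("stride exceeds trajectory span")
  stride <- max(1L, round(stride_ns / traj$dt_ns))
  use <- seq(1L, length(traj$frames), by = stride)
  if (length(use) < 2) stop("fewer than 2 strided frames")
  s <- traj$topology
  rows <- lapply(use, function(i) {
    coords(s) <- traj$frames[[i]]
    e <- interface_energy(s, model)
    c(time = traj$times[i], dG = e$dG_bind, e$components)
  })
  df <- as.data.frame(do.call(rbind, rows))
  n <- nrow(df)
  out <- list(frames = df,
              mean = mean(df$dG), sd = stats::sd(df$dG),
              se = stats::sd(df$dG) / sqrt(n),
              component_mean = colMeans(df[, c("vdw", "elec", "hbond", "lipo")]),
              component_se = vapply(df[, c("vdw", "elec", "hbond", "lipo")],
                                    function(x) stats::sd(x) / sqrt(n), 0),
              n = n)
  class(out) <- "TrajectoryEnergySummary"
  out
}

#' Computational alanine scan
#'
#' Each residue is mutated by side-chain truncation to C-beta (atoms other
#' than N, CA, C, O, OXT, CB and backbone hydrogens removed; glycine is not
#' mutated and flagged; alanine truncates to itself, so its ddG is exactly
#' zero) and the surrogate binding energy recomputed on the unrelaxed
#' geometry. `ddG = dG_bind(mutant) - dG_bind(wild-type)`; positive values
#' mean binding weakened, and residues with `ddG >= threshold` (default
#' 1 kcal/mol) are flagged hotspots.
#'
#' @param complex Structure with roles.
#' @param residues `"chain:resno"` specs, a data.frame with `chain`/`resno`,
#'   or `"auto-interface"` (default) for [interface_residues()] at 4.5 A.
#' @param model [energy_model()].
#' @param threshold hotspot cutoff, kcal/mol.
#' @return data.frame of class `HotspotTable`: `chain`, `resno`, `resname`,
#'   `side`, `ddG`, `mutated`, `is_hotspot`, sorted by decreasing `ddG`.
#' @export
alanine_scan <- function(complex, residues = "auto-interface",
                         model = energy_model(), threshold = 1.0) {
  if (identical(residues, "auto-interface")) {
    ir <- interface_residues(complex, cutoff = 4.5)
    residues <- ir[, c("chain", "resno")]
  } else if (is.character(residues)) {
    residues <- parse_res_spec(residues)
  }
  a <- complex$atoms
  wt <- interface_energy(complex, model)
  keep_bb <- c("N", "CA", "C", "O", "OXT", "CB", "H", "HA")
  rows <- lapply(seq_len(nrow(residues)), function(i) {
    ch <- residues$chain[i]; rn <- residues$resno[i]
    here <- which(a$chain == ch & a$resno == rn)
    if (!length(here)) stop("residue ", ch, ":", rn, " not in structure")
    resname <- a$resname[here[1]]
    if (!resname %in% names(AA3))
      stop("alanine scan of non-standard residue ", resname, " at ",
           ch, ":", rn)
    side <- if (!is.null(complex$roles) &&
                  complex$roles[[ch]] == "receptor") "receptor" else "ligand"
    if (resname == "GLY")
      return(data.frame(chain = ch, resno = rn, resname = resname,
                        side = side, ddG = NA_real_, mutated = FALSE))
    drop <- here[!(a$name[here] %in% keep_bb)]
    mut <- complex
    if (length(drop)) mut <- subset_structure(complex, setdiff(seq_len(nrow(a)), drop))
    mut$atoms$resname[mut$atoms$chain == ch & mut$atoms$resno == rn] <- "ALA"
    e <- interface_energy(mut, model)
    data.frame(chain = ch, resno = rn, resname = resname, side = side,
               ddG = e$dG_bind - wt$dG_bind, mutated = TRUE)
  })
  out <- do.call(rbind, rows)
  out$is_hotspot <- !is.na(out$ddG) & out$ddG >= threshold
  out <- out[order(-ifelse(is.na(out$ddG), -Inf, out$ddG), out$resno), ]
  rownames(out) <- NULL
  class(out) <- c("HotspotTable", "data.frame")
  out
}

#' Rank-sum consensus over several hotspot tables
#'
#' Borda consensus over scanners sharing a residue set: each table ranks
#' residues by decreasing ddG (rank 1 = strongest); the consensus orders by
#' the rank sum (ties broken by residue number). A residue is a consensus
#' hotspot iff it is flagged in at least half of the tables.
#'
#' @param tables named list of `HotspotTable`s (or data.frames with
#'   `chain`, `resno`, `ddG`, `is_hotspot`).
#' @return data.frame: `chain`, `resno`, per-table ddG columns, `borda`,
#'   `consensus_rank`, `consensus_hotspot`.
#' @export
hotspot_consensus <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 hotspot tables")
  if (is.null(names(tables)))
    names(tables) <- paste0("scorer", seq_along(tables))
  keys <- lapply(tables, function(t) sort(paste(t$chain, t$resno)))
  if (!all(vapply(keys[-1], identical, TRUE, keys[[1]])))
    stop("hotspot tables do not share a residue set")
  base <- tables[[1]][order(tables[[1]]$chain, tables[[1]]$resno),
                      c("chain", "resno")]
  ranks <- matrix(0, nrow(base), length(tables))
  hot <- matrix(FALSE, nrow(base), length(tables))
  for (j in seq_along(tables)) {
    t <- tables[[j]][order(tables[[j]]$chain, tables[[j]]$resno), ]
    ddg <- ifelse(is.na(t$ddG), -Inf, t$ddG)
    ranks[, j] <- rank(-ddg, ties.method = "min")
    hot[, j] <- !is.na(t$is_hotspot) & t$is_hotspot
    base[[paste0("ddG_", names(tables)[j])]] <- t$ddG
  }
  base$borda <- rowSums(ranks)
  ord <- order(base$borda, base$resno)
  base <- base[ord, ]
  base$consensus_rank <- seq_len(nrow(base))
  base$consensus_hotspot <- rowSums(hot)[ord] >= length(tables) / 2
  rownames(base) <- NULL
  base
}
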