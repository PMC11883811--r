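#' Read a PDB file
#'
#' Parses ATOM/HETATM records into a [new_structure()] atom table. Author
#' residue numbering is kept verbatim. Alternate locations are resolved to
#' the highest-occupancy conformer (ties: first encountered). Waters are
#' dropped unless `keep_waters = TRUE`.
#'
#' @param path PDB file.
#' @param id structure label; defaults to the file name.
#' @param keep_waters keep HOH/WAT/H2O residues.
#' @param model for multi-model files, which MODEL to return (default 1).
#' @return a `Structure`.
#' @export
read_pdb <- function(path, id = basename(path), keep_waters = FALSE,
                     model = 1L) {
  frames <- read_pdb_models(path, keep_waters = keep_waters)
  if (model > length(frames$models))
    stop("model ", model, " not present (file has ", length(frames$models), ")")
  atoms <- frames$models[[model]]
  new_structure(atoms, id = id)
}

# shared parser: returns list(models = list of atom data.frames)
read_pdb_models <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  is_end <- rec == "ENDMDL"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_id <- cumsum(is_model)
  model_id[model_id == 0L] <- 1L
  atom_lines <- which(is_atom)
  bad <- atom_lines[nchar(lines[atom_lines]) < 54]
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1], " of ", path)

  parse_block <- function(ix) {
    ln <- lines[ix]
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    if (any(!is.finite(xyz))) {
      j <- which(!is.finite(rowSums(xyz)))[1]
      stop("unparseable coordinates at line ", ix[j], " of ", path)
    }
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    occ[is.na(occ)] <- 1
    bf <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    bf[is.na(bf)] <- 0
    el <- trimws(substr(ln, 77, 78))
    nm <- trimws(substr(ln, 13, 16))
    rn <- trimws(substr(ln, 18, 20))
    el[el == ""] <- guess_element(nm[el == ""], rn[el == ""])
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (any(is.na(resno))) {
      j <- which(is.na(resno))[1]
      stop("unparseable residue number at line ", ix[j], " of ", path)
    }
    a <- data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = nm,
      altloc = trimws(substr(ln, 17, 17)),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resno = resno,
      icode = trimws(substr(ln, 27, 27)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = occ, bfactor = bf, element = toupper(el),
      het = substr(ln, 1, 6) == "HETATM",
      stringsAsFactors = FALSE)
    if (any(is.na(a$serial))) a$serial[is.na(a$serial)] <- which(is.na(a$serial))
    if (!keep_waters) a <- a[!(a$resname %in% c("HOH", "WAT", "H2O")), , drop = FALSE]
    if (nrow(a) == 0L) stop("no atoms left after water removal in ", path)
    # altloc resolution: keep highest occupancy per (chain,resno,icode,name)
    if (any(a$altloc != "")) {
      key <- paste(a$chain, a$resno, a$icode, a$name, sep = "|")
      ord <- order(key, -a$occupancy, seq_len(nrow(a)))
      a <- a[ord, , drop = FALSE]
      a <- a[!duplicated(paste(a$chain, a$resno, a$icode, a$name, sep = "|")), ,
             drop = FALSE]
      a <- a[order(a$serial), , drop = FALSE]
      a$altloc <- ""
    }
    rownames(a) <- NULL
    a
  }

  models <- lapply(split(atom_lines, model_id[atom_lines]), parse_block)
  names(models) <- NULL
  list(models = models)
}

pdb_format_name <- function(name, element) {
  # column alignment: 1-char elements start in column 14
  ifelse(nchar(name) >= 4, sprintf("%-4s", name),
         ifelse(nchar(element) == 1,
                sprintf(" %-3s", name), sprintf("%-4s", name)))
}

format_atom_records <- function(a, serial_start = 1L) {
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial_start - 1L + seq_len(nrow(a)),
          pdb_format_name(a$name, a$element), " ",
          a$resname, a$chain, a$resno,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occupancy, a$bfactor,
          formatC(a$element, width = 2, flag = ""))
}

#' Write a Structure to a PDB file
#'
#' @param s Structure.
#' @param path output file.
#' @export
write_pdb <- function(s, path) {
  lines <- c(format_atom_records(s$atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' Every MODEL block must be congruent (same atoms in the same order) with
#' the first, which becomes the topology.
#'
#' @param path multi-model PDB file.
#' @param dt_ns frame spacing in ns (uniform spacing assumed).
#' @param keep_waters see [read_pdb()].
#' @return a `Trajectory` (see [new_trajectory()]).
#' @export
read_pdb_trajectory <- function(path, dt_ns = 1, keep_waters = FALSE) {
  frames <- read_pdb_models(path, keep_waters = keep_waters)$models
  topo <- new_structure(frames[[1]], id = basename(path))
  n <- nrow(topo$atoms)
  mats <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (nrow(f) != n)
      stop("model ", i, " has ", nrow(f), " atoms, topology has ", n)
    m <- as.matrix(f[, c("x", "y", "z")]); dimnames(m) <- NULL
    m
  })
  new_trajectory(topo, mats, dt_ns = dt_ns)
}

#' Write a Trajectory as a multi-model PDB
#'
#' @param traj Trajectory.
#' @param path output file.
#' @export
write_pdb_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    a$x <- traj$frames[[i]][, 1]
    a$y <- traj$frames[[i]][, 2]
    a$z <- traj$frames[[i]][, 3]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_atom_records(a), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
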