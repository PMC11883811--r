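# Atom table columns used throughout the package. Coordinates are Angstrom.
ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resno",
               "icode", "x", "y", "z", "occupancy", "bfactor", "element",
               "het")

#' Construct a Structure from an atom table
#'
#' A `Structure` is the coordinate substrate every other module operates on:
#' an ordered atom table (PDB author numbering preserved verbatim) plus an
#' optional chain-role map assigning each chain to `receptor`, `ligand` or
#' `cofactor`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`, `het`. Missing bookkeeping columns are filled
#'   with defaults; `name`, `resname`, `chain`, `resno`, `x`, `y`, `z` are
#'   required.
#' @param id label for the structure.
#' @param roles named character vector mapping chain id to one of
#'   `"receptor"`, `"ligand"`, `"cofactor"`, or `NULL`.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, id = "structure", roles = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "resname", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop("empty atom table")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$name, atoms$resname)
  if (is.null(atoms$het)) atoms$het <- !(atoms$resname %in% names(AA3))
  atoms <- atoms[, ATOM_COLS]
  atoms$resno <- as.integer(atoms$resno)
  atoms$serial <- as.integer(atoms$serial)
  rownames(atoms) <- NULL
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) triple: ",
         key[anyDuplicated(key)][1])
  s <- list(atoms = atoms, id = id, roles = NULL)
  class(s) <- "Structure"
  if (!is.null(roles)) s <- set_chain_roles(s, roles)
  s
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              x$id, nrow(a), n_residues(x),
              paste(unique(a$chain), collapse = ",")))
  if (!is.null(x$roles))
    cat("  roles:", paste(names(x$roles), x$roles, sep = "=", collapse = " "), "\n")
  invisible(x)
}

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

# Element from PDB atom name: strip leading digits, first letter.
# Two-letter metals only when the residue IS the ion (resname == atom name),
# so protein CA/NA atom names are never read as calcium/sodium.
guess_element <- function(name, resname = NULL) {
  nm <- toupper(gsub("[^A-Za-z].*?", "", gsub("^[0-9]+", "", name)))
  el <- substr(nm, 1, 1)
  two <- c("FE", "MG", "MN", "ZN", "CA", "NA", "CL", "BR")
  if (!is.null(resname)) {
    ion <- nm %in% two & toupper(resname) == nm
    el[ion] <- nm[ion]
  }
  el[el == ""] <- "C"
  el
}

#' @export
is_heavy <- function(s) s$atoms$element != "H"

#' Number of residues in a Structure
#' @param s Structure.
#' @export
n_residues <- function(s) length(unique(residue_keys(s)))

residue_keys <- function(s)
  paste(s$atoms$chain, s$atoms$resno, s$atoms$icode, sep = "|")

#' Assign chain roles
#'
#' @param s Structure.
#' @param roles named character vector, names are chain ids, values in
#'   `receptor`, `ligand`, `cofactor`.
#' @export
set_chain_roles <- function(s, roles) {
  ok <- c("receptor", "ligand", "cofactor")
  if (is.null(names(roles)) || !all(roles %in% ok))
    stop("roles must be a named vector with values receptor/ligand/cofactor")
  unknown <- setdiff(names(roles), unique(s$atoms$chain))
  if (length(unknown))
    stop("role assigned to absent chain: ", paste(unknown, collapse = ","))
  s$roles <- roles
  s
}

#' @export
chain_roles <- function(s) s$roles

# Atom indices on one side of the interface; cofactors count with the ligand.
role_indices <- function(s, side = c("receptor", "ligand")) {
  side <- match.arg(side)
  if (is.null(s$roles)) stop("structure has no chain role assignment")
  chains <- names(s$roles)[s$roles == side |
                             (side == "ligand" & s$roles == "cofactor")]
  which(s$atoms$chain %in% chains)
}

#' Extract coordinates as an n x 3 matrix
#' @param s Structure.
#' @param idx optional atom indices.
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

#' Replace coordinates
#' @param s Structure.
#' @param value n x 3 matrix.
#' @export
`coords<-` <- function(s, value) {
  stopifnot(is.matrix(value), ncol(value) == 3, nrow(value) == nrow(s$atoms))
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Select atoms by conjunction of simple selectors
#'
#' All supplied selectors are ANDed; the returned indices follow structure
#' order. `chain("B")` on a structure without chain B returns an empty
#' vector, not an error.
#'
#' @param s Structure.
#' @param heavy if TRUE keep element != H; if FALSE keep hydrogens only.
#' @param chain chain id(s).
#' @param resno residue number(s).
#' @param name atom name(s), e.g. `"CA"`.
#' @param resname residue name(s).
#' @param het TRUE for HETATM records only, FALSE for ATOM only.
#' @param role `"receptor"` or `"ligand"` (cofactor chains count as ligand).
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(s, heavy = NULL, chain = NULL, resno = NULL,
                         name = NULL, resname = NULL, het = NULL,
                         role = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(heavy)) keep <- keep & ((a$element != "H") == heavy)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(het)) keep <- keep & (a$het == het)
  if (!is.null(role)) keep <- keep & seq_len(nrow(a)) %in% role_indices(s, role)
  which(keep)
}

#' Subset a Structure by atom indices
#' @param s Structure.
#' @param idx atom indices to keep (structure order preserved).
#' @export
subset_structure <- function(s, idx) {
  if (length(idx) == 0L) stop("selection keeps zero atoms")
  idx <- sort(unique(idx))
  out <- s
  out$atoms <- s$atoms[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  if (!is.null(s$roles))
    out$roles <- s$roles[names(s$roles) %in% unique(out$atoms$chain)]
  out
}

#' Residue range set
#'
#' Parses range specifications of the form `"A:1537-1730"` (or a single
#' residue `"A:15"`). Ranges are inclusive in author numbering; residues
#' bearing insertion codes are excluded from ranges (they must be listed
#' explicitly to survive a truncation).
#'
#' @param spec character vector of `"chain:start-end"` strings, or a
#'   data.frame with columns `chain`, `start`, `end`.
#' @return data.frame of class `ResidueRangeSet`.
#' @export
residue_ranges <- function(spec) {
  if (is.data.frame(spec)) {
    df <- spec[, c("chain", "start", "end")]
  } else {
    m <- regmatches(spec, regexec("^([A-Za-z0-9]):(-?[0-9]+)(?:-(-?[0-9]+))?$", spec))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) stop("malformed range spec: ", spec[bad][1])
    df <- data.frame(
      chain = vapply(m, `[`, "", 2L),
      start = as.integer(vapply(m, `[`, "", 3L)),
      end = NA_integer_)
    end <- vapply(m, `[`, "", 4L)
    df$end <- ifelse(end == "", df$start, suppressWarnings(as.integer(end)))
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("range start exceeds end")
  for (ch in unique(df$chain)) {
    r <- df[df$chain == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
      stop("overlapping ranges on chain ", ch)
  }
  class(df) <- c("ResidueRangeSet", "data.frame")
  df
}

#' Truncate a structure to a residue range set
#'
#' Keeps exactly the residues whose (chain, author number) fall inside the
#' ranges, preserving atom order. Idempotent.
#'
#' @param s Structure.
#' @param keep `ResidueRangeSet` (see [residue_ranges()]).
#' @export
truncate_structure <- function(s, keep) {
  if (!inherits(keep, "ResidueRangeSet")) keep <- residue_ranges(keep)
  if (nrow(keep) == 0L) stop("empty range set")
  a <- s$atoms
  sel <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(keep))) {
    sel <- sel | (a$chain == keep$chain[i] & a$icode == "" &
                    a$resno >= keep$start[i] & a$resno <= keep$end[i])
  }
  if (!any(sel)) stop("range set selects zero atoms")
  subset_structure(s, which(sel))
}

# residue-level bookkeeping: one row per residue, with first-atom index
residue_table <- function(s, idx = NULL) {
  a <- s$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resname = a$resname[first],
             stringsAsFactors = FALSE)
}

# parse "A:123" or "A:123:CA" atom/residue specs
parse_res_spec <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}
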