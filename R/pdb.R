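#' @importFrom stats dist setNames rnorm runif
#' @importFrom utils packageVersion write.csv head
NULL

# Three-letter codes treated as standard amino acids for C-alpha bookkeeping.
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Read atom records from a PDB file
#'
#' Parses the fixed-column ATOM (and optionally HETATM) records of a PDB
#' coordinate file into a data frame, one row per atom. Reading is delegated
#' to \code{bio3d::read.pdb}; records are returned exactly as deposited —
#' hydrogens and alternate locations are retained at this stage and filtered
#' later by \code{\link{select_heavy_atoms}}.
#'
#' The element symbol is taken from PDB columns 77--78 when present and
#' otherwise inferred from the atom name (via \code{bio3d::atom2ele}).
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param include_hetatm Logical; keep HETATM records as well (default
#'   \code{FALSE}).
#' @return A data frame of class \code{"pdb_atoms"} with columns
#'   \code{record}, \code{serial}, \code{atom_name}, \code{alt_loc},
#'   \code{residue_name}, \code{chain_id}, \code{residue_number},
#'   \code{insertion_code}, \code{occupancy}, \code{element},
#'   \code{x}, \code{y}, \code{z} (coordinates in Angstrom).
#' @seealso \code{\link{select_heavy_atoms}}, \code{\link{write_pdb}}
#' @export
#' @examples
#' pdb <- write_pdb(make_fixture("tetrahedron"), tempfile(fileext = ".pdb"))
#' atoms <- read_pdb(pdb)
#' nrow(atoms)
read_pdb <- function(path, include_hetatm = FALSE) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path, call. = FALSE)
  }
  .check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (!include_hetatm) {
    at <- at[at$type == "ATOM", , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    stop("no ATOM records in ", path, call. = FALSE)
  }
  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  if (any(missing_el)) {
    element[missing_el] <- bio3d::atom2ele(at$elety[missing_el])
  }
  out <- data.frame(
    record = at$type,
    serial = at$eleno,
    atom_name = at$elety,
    alt_loc = ifelse(is.na(at$alt), "", at$alt),
    residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    residue_number = at$resno,
    insertion_code = ifelse(is.na(at$insert), "", at$insert),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = toupper(trimws(element)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("pdb_atoms", "data.frame")
  out
}

# Pre-scan coordinate records so malformed lines are reported with their
# line number rather than silently mangled downstream.
.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  idx <- which(is_coord)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("unparsable coordinate record at line ", i, " of ", path,
           " (record too short)", call. = FALSE)
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz))))) {
      stop("unparsable coordinate record at line ", i, " of ", path,
           " (bad coordinate field)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Select heavy atoms by chain and residue range
#'
#' Restricts a parsed atom table to the heavy (non-hydrogen) atoms of
#' standard amino-acid residues whose author residue numbers fall in an
#' inclusive range, optionally on a single chain. Alternate locations are
#' collapsed to one atom per site, keeping the highest occupancy and breaking
#' ties by the lexicographically first alternate-location indicator. Waters
#' and hetero residues are excluded. The resulting atom count is the node
#' count N of any elastic network built from the selection.
#'
#' @param atoms A \code{"pdb_atoms"} data frame from \code{\link{read_pdb}},
#'   or an existing \code{"anm_selection"} (in which case the operation is
#'   idempotent).
#' @param residue_range Inclusive integer pair \code{c(first, last)} of
#'   author residue numbers; \code{NULL} keeps all residues.
#' @param chain Optional chain identifier. Required when the range spans
#'   several chains.
#' @param label Optional label for the selection (used in reports).
#' @return An object of class \code{"anm_selection"}: a list with
#'   \code{label}, \code{atoms} (ordered data frame of heavy atoms),
#'   \code{calpha} (named index vector mapping
#'   \code{"chain:resno:insert"} to the row of that residue's CA atom) and
#'   \code{missing_calpha} (residues contributing atoms but lacking a CA).
#' @export
select_heavy_atoms <- function(atoms, residue_range = NULL, chain = NULL,
                               label = NULL) {
  if (inherits(atoms, "anm_selection")) {
    atoms <- atoms$atoms
    atoms$record <- "ATOM"
  }
  stopifnot(is.data.frame(atoms))
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    residue_range <- as.integer(residue_range)
    if (residue_range[2L] < residue_range[1L]) {
      stop("residue_range must be an inclusive pair with first <= last",
           call. = FALSE)
    }
  }
  at <- atoms
  if ("record" %in% names(at)) {
    at <- at[at$record == "ATOM", , drop = FALSE]
  }
  at <- at[at$residue_name %in% .standard_aa, , drop = FALSE]
  if (!is.null(residue_range)) {
    at <- at[at$residue_number >= residue_range[1L] &
             at$residue_number <= residue_range[2L], , drop = FALSE]
  }
  if (is.null(chain)) {
    chains <- unique(at$chain_id)
    if (length(chains) > 1L) {
      stop("residue range matches several chains (",
           paste(chains, collapse = ", "),
           "); specify `chain`", call. = FALSE)
    }
  } else {
    at <- at[at$chain_id == chain, , drop = FALSE]
  }
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("empty selection: no heavy atoms in the requested range",
         call. = FALSE)
  }
  at <- .collapse_altloc(at)
  rownames(at) <- NULL

  key <- paste(at$chain_id, at$residue_number, at$insertion_code, sep = ":")
  ca_rows <- which(at$atom_name == "CA" & at$element != "CA")
  calpha <- setNames(ca_rows, key[ca_rows])
  missing <- setdiff(unique(key), names(calpha))

  structure(
    list(
      label = if (is.null(label)) "selection" else label,
      atoms = at[, c("serial", "atom_name", "alt_loc", "residue_name",
                     "chain_id", "residue_number", "insertion_code",
                     "occupancy", "element", "x", "y", "z")],
      calpha = calpha,
      missing_calpha = missing
    ),
    class = "anm_selection"
  )
}

# Keep one atom per (chain, resno, insert, atom_name) site: highest
# occupancy wins, ties broken by lexicographically first alt_loc.
.collapse_altloc <- function(at) {
  site <- paste(at$chain_id, at$residue_number, at$insertion_code,
                at$atom_name, sep = ":")
  if (!anyDuplicated(site)) return(at)
  groups <- split(seq_len(nrow(at)), factor(site, levels = unique(site)))
  keep <- vapply(groups, function(rows) {
    if (length(rows) == 1L) return(rows)
    occ <- at$occupancy[rows]
    best <- rows[occ == max(occ)]
    if (length(best) > 1L) best <- best[order(at$alt_loc[best])][1L]
    best
  }, integer(1))
  at[sort(keep), , drop = FALSE]
}

#' Number of atoms in a selection
#' @param selection An \code{"anm_selection"}.
#' @return Integer heavy-atom count N.
#' @export
n_atoms <- function(selection) {
  stopifnot(inherits(selection, "anm_selection"))
  nrow(selection$atoms)
}

#' Coordinates of a selection
#' @param selection An \code{"anm_selection"}.
#' @return N x 3 numeric matrix of coordinates in Angstrom.
#' @export
coords <- function(selection) {
  stopifnot(inherits(selection, "anm_selection"))
  as.matrix(selection$atoms[, c("x", "y", "z")])
}

#' Locate a residue's C-alpha atom
#'
#' Returns the position (row index within the ordered selection) and the
#' coordinates of the CA atom of a residue, used to define pulling axes.
#'
#' @param selection An \code{"anm_selection"}.
#' @param residue_number Author residue number.
#' @param chain Optional chain identifier (needed only for multi-chain
#'   selections).
#' @param insertion_code Insertion code, default blank.
#' @return List with \code{index}, \code{coords} (3-vector, Angstrom) and
#'   \code{residue_name}.
#' @export
locate_calpha <- function(selection, residue_number, chain = NULL,
                          insertion_code = "") {
  stopifnot(inherits(selection, "anm_selection"))
  at <- selection$atoms
  hit <- at$residue_number == residue_number &
    at$insertion_code == insertion_code &
    at$atom_name == "CA"
  if (!is.null(chain)) hit <- hit & at$chain_id == chain
  idx <- which(hit)
  if (length(idx) == 0L) {
    stop("residue ", residue_number,
         " is absent from the selection or lacks a CA atom", call. = FALSE)
  }
  if (length(idx) > 1L) {
    stop("residue ", residue_number,
         " matches several chains; specify `chain`", call. = FALSE)
  }
  list(index = idx,
       coords = as.numeric(at[idx, c("x", "y", "z")]),
       residue_name = at$residue_name[idx])
}

#' Write a selection as a PDB fragment
#'
#' Emits the atoms of a selection as standard fixed-column ATOM records (via
#' \code{bio3d::write.pdb}), so fixtures and selections can be re-read with
#' \code{\link{read_pdb}}. Coordinates are printed at the PDB's 0.001 A
#' precision.
#'
#' @param selection An \code{"anm_selection"}.
#' @param path Output file path.
#' @return \code{path}, invisibly usable as input to \code{\link{read_pdb}}.
#' @export
write_pdb <- function(selection, path) {
  stopifnot(inherits(selection, "anm_selection"))
  at <- selection$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$residue_number,
    resid = at$residue_name,
    eleno = at$serial,
    elety = at$atom_name,
    chain = ifelse(nzchar(at$chain_id), at$chain_id, " "),
    insert = ifelse(nzchar(at$insertion_code), at$insertion_code, ""),
    o = at$occupancy,
    b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(path)
}

#' @export
print.anm_selection <- function(x, ...) {
  cat("Heavy-atom selection \"", x$label, "\": ", nrow(x$atoms),
      " atoms, ", length(unique(paste(x$atoms$chain_id,
                                      x$atoms$residue_number,
                                      x$atoms$insertion_code))),
      " residues\n", sep = "")
  if (length(x$missing_calpha)) {
    cat("  residues without a CA atom:",
        paste(x$missing_calpha, collapse = ", "), "\n")
  }
  invisible(x)
}
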