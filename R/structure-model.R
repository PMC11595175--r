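#' @importFrom stats acf sd qnorm runif rnorm setNames aggregate
#' @importFrom utils head tail read.delim write.table
NULL

PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "SEP", "HSD", "HSE", "HSP", "HID", "HIE", "HIP"
)

NUCLEIC_RESNAMES <- c("DA", "DT", "DG", "DC", "A", "T", "G", "C", "U", "DU")

#' Construct a structure model
#'
#' A `structure_model` holds a fixed topology (atom names, elements, residue
#' and chain assignment) plus one coordinate set in Angstrom.  It is the
#' topology object every trajectory and every analysis in the package is
#' defined over.
#'
#' @param atoms data.frame with columns `name`, `element`, `chain`, `resid`
#'   (residue number, integer), `resname`.  An `is_hydrogen` column is derived
#'   from `element` if absent.
#' @param coords numeric n x 3 matrix of coordinates, Angstrom.
#' @param chain_roles optional named character vector mapping chain id to one
#'   of `"H3"`, `"H4"`, `"H2A"`, `"H2B"`, `"DNA_strand_I"`, `"DNA_strand_J"`,
#'   `"other"`.  When omitted, DNA strands are inferred (a chain is DNA when
#'   more than 90 percent of its residues are standard deoxynucleotides) and
#'   all other chains are `"other"` until the user supplies histone roles.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, coords, chain_roles = NULL) {
  stopifnot(is.data.frame(atoms), is.matrix(coords), ncol(coords) == 3)
  if (nrow(atoms) != nrow(coords)) {
    stop("atoms (", nrow(atoms), ") and coords (", nrow(coords), ") differ in length")
  }
  needed <- c("name", "chain", "resid", "resname")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms$name <- as.character(atoms$name)
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- as.integer(atoms$resid)
  atoms$resname <- as.character(atoms$resname)
  if (is.null(atoms$element)) {
    atoms$element <- infer_element(atoms$name)
  }
  atoms$element <- toupper(as.character(atoms$element))
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$index <- seq_len(nrow(atoms))
  check_duplicate_atoms(atoms)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  roles <- infer_chain_roles(atoms, chain_roles)
  structure(
    list(atoms = atoms, coords = coords, chain_roles = roles),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(residue_keys(x))), "residues,",
      length(x$chain_roles), "chains\n")
  cat("  chain roles:",
      paste(names(x$chain_roles), x$chain_roles, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a model
#' @param model structure_model
#' @return integer
#' @export
n_atoms <- function(model) nrow(model$atoms)

# "chain|resid|resname" keys, one per atom
residue_keys <- function(model, which = seq_len(nrow(model$atoms))) {
  a <- model$atoms
  paste(a$chain[which], a$resid[which], a$resname[which], sep = "|")
}

check_duplicate_atoms <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicate atom name within a residue: ", dup[1])
  }
  invisible(TRUE)
}

# Element from a PDB atom name when the element column is absent.  Leading
# digits are stripped; biomolecular names assumed (no metals), so the first
# alphabetic character is the element and anything starting with H is hydrogen.
infer_element <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  first <- toupper(substr(stripped, 1, 1))
  first[first == ""] <- "X"
  first
}

infer_chain_roles <- function(atoms, chain_roles = NULL) {
  chains <- unique(atoms$chain)
  roles <- setNames(rep("other", length(chains)), chains)
  for (ch in chains) {
    res <- unique(atoms[atoms$chain == ch, c("resid", "resname")])
    frac_dna <- mean(res$resname %in% c("DA", "DT", "DG", "DC"))
    if (frac_dna > 0.9) roles[ch] <- "DNA"
  }
  dna <- names(roles)[roles == "DNA"]
  if (length(dna) >= 1) roles[dna[1]] <- "DNA_strand_I"
  if (length(dna) >= 2) roles[dna[2]] <- "DNA_strand_J"
  if (length(dna) > 2) roles[dna[-(1:2)]] <- "other"
  if (!is.null(chain_roles)) {
    allowed <- c("H3", "H4", "H2A", "H2B", "DNA_strand_I", "DNA_strand_J", "other")
    bad <- setdiff(chain_roles, allowed)
    if (length(bad)) stop("unknown chain role(s): ", paste(bad, collapse = ", "))
    unknown <- setdiff(names(chain_roles), chains)
    if (length(unknown)) stop("chain_roles names chains absent from model: ",
                              paste(unknown, collapse = ", "))
    roles[names(chain_roles)] <- chain_roles
  }
  roles
}

#' Chains holding a given role
#' @param model structure_model
#' @param role role string, e.g. `"H2A"` or `"DNA_strand_I"`
#' @return character vector of chain ids
#' @export
chains_with_role <- function(model, role) {
  names(model$chain_roles)[model$chain_roles == role]
}

#' Read a structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] that builds the package's
#' `structure_model`: atoms in file order, phosphoserine (residue name `SEP`)
#' accepted as protein, elements taken from the element column when present
#' and otherwise derived from the atom name, and chain roles inferred (DNA by
#' composition; histone roles via `chain_roles`).
#'
#' @param path PDB file path.
#' @param chain_roles optional named character vector of manual role
#'   assignments (see [structure_model()]).
#' @return `structure_model`
#' @export
read_structure <- function(path, chain_roles = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  atoms <- data.frame(
    name = pdb$atom$elety,
    chain = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    resid = pdb$atom$resno,
    resname = pdb$atom$resid,
    stringsAsFactors = FALSE
  )
  elesy <- pdb$atom$elesy
  if (!is.null(elesy) && !all(is.na(elesy) | elesy == "")) {
    el <- toupper(trimws(elesy))
    blank <- is.na(el) | el == ""
    el[blank] <- infer_element(atoms$name[blank])
    atoms$element <- el
  }
  coords <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  structure_model(atoms, coords, chain_roles = chain_roles)
}

# Cheap well-formedness scan: coordinate fields of ATOM/HETATM records must
# parse as numbers.  bio3d is forgiving; a malformed record should name its line.
validate_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      stop("malformed PDB record at line ", i, ": unparseable coordinates")
    }
  }
  invisible(TRUE)
}

#' Write a structure (or trajectory) to a PDB file
#'
#' Single coordinate sets are written as a plain PDB; a trajectory is written
#' as a multi-model PDB (one MODEL per frame).  Coordinates are written in
#' Angstrom at PDB precision (3 decimals).
#'
#' @param x `structure_model` or `md_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "md_trajectory")) {
    model <- x$model
    xyz <- x$coords
  } else {
    model <- x
    xyz <- matrix(t(model$coords), nrow = 1)
  }
  a <- model$atoms
  type <- ifelse(a$resname %in% c(PROTEIN_RESNAMES, NUCLEIC_RESNAMES), "ATOM", "HETATM")
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = type,
    resno = a$resid,
    resid = a$resname,
    eleno = seq_len(nrow(a)),
    elety = a$name,
    chain = a$chain,
    elesy = a$element
  )
  invisible(path)
}

#' Construct a trajectory object
#'
#' @param model `structure_model` giving the fixed topology.
#' @param coords numeric matrix, one row per frame, `3 * n_atoms(model)`
#'   columns in bio3d xyz layout (x1, y1, z1, x2, ...), Angstrom.
#' @param dt_ns frame spacing in nanoseconds (positive; default 1, the spacing
#'   at which production frames were saved).
#' @return object of class `md_trajectory`
#' @export
md_trajectory <- function(model, coords, dt_ns = 1.0) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.matrix(coords)) coords <- matrix(coords, nrow = 1)
  if (ncol(coords) != 3L * n_atoms(model)) {
    stop("coordinate columns (", ncol(coords), ") do not match 3 x ",
         n_atoms(model), " atoms")
  }
  if (!is.numeric(dt_ns) || length(dt_ns) != 1 || dt_ns <= 0) {
    stop("dt_ns must be a positive scalar")
  }
  structure(
    list(model = model, coords = coords, dt_ns = dt_ns),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", nrow(x$coords), "frames x", n_atoms(x$model),
      "atoms, dt =", x$dt_ns, "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory `md_trajectory`
#' @return integer
#' @export
n_frames <- function(trajectory) nrow(trajectory$coords)

#' Coordinates of one frame as an n x 3 matrix
#' @param trajectory `md_trajectory`
#' @param frame 1-based frame index
#' @return n x 3 numeric matrix, Angstrom
#' @export
frame_coords <- function(trajectory, frame) {
  stopifnot(frame >= 1, frame <= n_frames(trajectory))
  matrix(trajectory$coords[frame, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a trajectory against a known topology
#'
#' Supported on-disk formats are DCD (via [bio3d::read.dcd()]) and multi-model
#' PDB; both store Angstrom coordinates natively.  XTC is not supported by the
#' R trajectory stack; convert to DCD or multi-model PDB first.
#'
#' @param structure `structure_model` whose atom count every frame must match.
#' @param path trajectory file.
#' @param format one of `"dcd"`, `"multi_model_pdb"`, `"xtc"` (the latter
#'   errors with conversion advice).
#' @param dt_ns frame spacing in ns.
#' @return `md_trajectory`
#' @export
read_trajectory <- function(structure, path, format = c("multi_model_pdb", "dcd", "xtc"),
                            dt_ns = 1.0) {
  format <- match.arg(format)
  if (format == "xtc") {
    stop("XTC reading is not supported; convert the trajectory to DCD or ",
         "multi-model PDB (e.g. with 'mdconvert' or 'gmx trjconv')")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  xyz <- switch(format,
    dcd = unclass(bio3d::read.dcd(path, verbose = FALSE)),
    multi_model_pdb = {
      pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
      unclass(pdb$xyz)
    }
  )
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  got <- ncol(xyz) / 3
  if (got != n_atoms(structure)) {
    stop("trajectory has ", got, " atoms per frame but the structure has ",
         n_atoms(structure))
  }
  md_trajectory(structure, xyz, dt_ns = dt_ns)
}

#' Extract an H2A-H2B dimer sub-model
#'
#' Retains only the chosen residue intervals on one H2A and one H2B chain, the
#' construction used for dimer systems where disordered histone tails are
#' truncated (e.g. H2A 16-102 and H2B 34-122).  Atom order is preserved.
#'
#' @param model `structure_model`
#' @param h2a_chain,h2b_chain chain ids.
#' @param h2a_range,h2b_range integer length-2 residue intervals (inclusive).
#' @return new `structure_model` with only the retained residues.
#' @export
extract_dimer <- function(model, h2a_chain, h2b_chain, h2a_range, h2b_range) {
  stopifnot(length(h2a_range) == 2, length(h2b_range) == 2)
  for (ch in c(h2a_chain, h2b_chain)) {
    if (!ch %in% model$atoms$chain) stop("chain not in model: ", ch)
  }
  a <- model$atoms
  keep_a <- a$chain == h2a_chain & a$resid >= h2a_range[1] & a$resid <= h2a_range[2]
  keep_b <- a$chain == h2b_chain & a$resid >= h2b_range[1] & a$resid <= h2b_range[2]
  if (!any(keep_a) || !any(keep_b)) {
    empty <- if (!any(keep_a)) c(h2a_chain, h2a_range) else c(h2b_chain, h2b_range)
    stop("no atoms fall in the requested range (chain ", empty[1], " ",
         empty[2], "-", empty[3], ")")
  }
  keep <- keep_a | keep_b
  roles <- model$chain_roles[c(h2a_chain, h2b_chain)]
  structure_model(a[keep, setdiff(names(a), c("index", "is_hydrogen"))],
                  model$coords[keep, , drop = FALSE],
                  chain_roles = roles)
}

#' Validate a phosphoserine charge set against its parameterisation constraints
#'
#' Checks the three constraints a phosphoserine (SEP) residue charge template
#' must satisfy: the summed partial charges equal the target total (-2 e for
#' the doubly deprotonated phosphate), backbone atom charges match the
#' reference force-field values, and the phosphate oxygens carry identical
#' charges.  Violations are returned as data, not raised.
#'
#' @param charges named numeric vector, partial charge per atom name
#'   (elementary charge units).
#' @param reference_backbone named numeric vector of reference backbone
#'   charges; names must be a subset of `names(charges)`.
#' @param total target net charge (default -2).
#' @param phosphate_oxygens atom names of the phosphate oxygens; defaults cover
#'   both wwPDB spellings (O1P/O2P/O3P and OP1/OP2/OP3).
#' @param tol comparison tolerance in e (default 1e-4).
#' @return data.frame of violations with columns `constraint`, `atom`,
#'   `observed`, `expected`; zero rows when all constraints hold.
#' @export
validate_pser_charges <- function(charges, reference_backbone, total = -2,
                                  phosphate_oxygens = c("O1P", "O2P", "O3P",
                                                        "OP1", "OP2", "OP3"),
                                  tol = 1e-4) {
  stopifnot(is.numeric(charges), !is.null(names(charges)))
  bad_ref <- setdiff(names(reference_backbone), names(charges))
  if (length(bad_ref)) {
    stop("reference_backbone names atoms absent from the template: ",
         paste(bad_ref, collapse = ", "))
  }
  v <- list()
  s <- sum(charges)
  if (abs(s - total) > tol) {
    v[[length(v) + 1L]] <- data.frame(
      constraint = "total_charge", atom = NA_character_,
      observed = s, expected = total)
  }
  for (atom in names(reference_backbone)) {
    if (abs(charges[[atom]] - reference_backbone[[atom]]) > tol) {
      v[[length(v) + 1L]] <- data.frame(
        constraint = "backbone_match", atom = atom,
        observed = charges[[atom]], expected = reference_backbone[[atom]])
    }
  }
  po <- intersect(names(charges), phosphate_oxygens)
  if (length(po) >= 2) {
    q <- charges[po]
    if (max(q) - min(q) > tol) {
      worst <- po[which.max(abs(q - stats::median(q)))]
      v[[length(v) + 1L]] <- data.frame(
        constraint = "phosphate_oxygen_equivalence", atom = worst,
        observed = charges[[worst]], expected = stats::median(q))
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(constraint = character(), atom = character(),
               observed = numeric(), expected = numeric())
}
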