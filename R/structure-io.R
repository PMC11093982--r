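# Structure reading/writing (PDB, mmCIF via bio3d), symmetry-mate
# generation and atom/residue selection.

# internal constructor normalising the atom table
.structure <- function(atoms, entryId = "", cell = numeric(0),
                       spaceGroup = "", operators = list()) {
  if (nrow(atoms) == 0) {
    atoms <- data.frame(serial = integer(0), name = character(0),
                        resname = character(0), chain = character(0),
                        resno = integer(0), insert = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        occ = numeric(0), b = numeric(0),
                        element = character(0), record = character(0),
                        cap = logical(0), stringsAsFactors = FALSE)
  }
  rownames(atoms) <- NULL
  methods::new("Structure", entryId = entryId, atoms = atoms,
               cell = cell, spaceGroup = spaceGroup, operators = operators)
}

#' Build a Structure from an atom table
#'
#' Programmatic constructor for planted fixtures and synthetic systems.
#' Missing optional columns (insert, occ, b, cap) are filled with
#' defaults; a missing element column is inferred from atom names.
#'
#' @param atoms data.frame with at least serial, name, resname, chain,
#'   resno, x, y, z and record columns.
#' @param entryId entry identifier.
#' @param cell optional numeric(6) unit cell.
#' @param spaceGroup optional space-group symbol.
#' @return a \linkS4class{Structure}.
#' @export
buildStructure <- function(atoms, entryId = "", cell = numeric(0),
                           spaceGroup = "") {
  need <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z",
            "record")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$cap)) atoms$cap <- FALSE
  if (is.null(atoms$element))
    atoms$element <- .infer_element(atoms$name, atoms$record)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  .structure(atoms[, .atom_cols, drop = FALSE], entryId = entryId,
             cell = cell, spaceGroup = spaceGroup)
}

# element inference from an atom name, used when the element column is
# absent; two-letter elements are only plausible for HETATM records
# (polymer "CA"/"CD" are alpha/delta carbons, not metals)
.infer_element <- function(name, record = NULL) {
  two_letter <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN", "CU",
                  "CD", "SI", "CA")
  if (is.null(record)) record <- rep("HETATM", length(name))
  vapply(seq_along(name), function(i) {
    s <- gsub("[0-9' \"]", "", toupper(name[i]))
    if (nchar(s) == 0) return("C")
    # leading digit already stripped; hydrogens like 1HB2 -> HB2 -> H
    if (substr(s, 1, 1) == "H") return("H")
    if (record[i] == "HETATM" && nchar(s) == 2 &&
        substr(s, 1, 2) %in% two_letter) return(substr(s, 1, 2))
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# parse CRYST1 / REMARK 350 BIOMT from raw PDB lines
.parse_pdb_header <- function(lines) {
  out <- list(cell = numeric(0), spaceGroup = "", operators = list())
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) {
    l <- cl[1]
    cell <- suppressWarnings(as.numeric(c(
      substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33),
      substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54))))
    if (!anyNA(cell) && all(cell[1:3] > 0)) {
      out$cell <- cell
      out$spaceGroup <- trimws(substr(l, 56, 66))
    }
  }
  bm <- grep("^REMARK 350   BIOMT", lines, value = TRUE)
  if (length(bm)) {
    ids <- as.integer(sub("^REMARK 350   BIOMT[123]\\s+(\\d+).*", "\\1", bm))
    rows <- as.integer(substr(bm, 19, 19))
    vals <- t(vapply(bm, function(l) {
      suppressWarnings(as.numeric(c(substr(l, 24, 33), substr(l, 34, 43),
                                    substr(l, 44, 53), substr(l, 54, 68))))
    }, numeric(4), USE.NAMES = FALSE))
    for (id in sort(unique(ids))) {
      sel <- which(ids == id)
      if (length(sel) != 3) next
      sel <- sel[order(rows[sel])]
      R <- rbind(vals[sel[1], 1:3], vals[sel[2], 1:3], vals[sel[3], 1:3])
      tr <- c(vals[sel[1], 4], vals[sel[2], 4], vals[sel[3], 4])
      out$operators[[length(out$operators) + 1L]] <-
        list(rotation = R, translation = tr)
    }
  }
  out
}

# simple mmCIF cell extraction
.parse_cif_header <- function(lines) {
  grab <- function(tag) {
    l <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(l)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(l[1]), "\\s+")[[1]][2]))
  }
  cell <- c(grab("_cell.length_a"), grab("_cell.length_b"),
            grab("_cell.length_c"), grab("_cell.angle_alpha"),
            grab("_cell.angle_beta"), grab("_cell.angle_gamma"))
  sg <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
  sgv <- if (length(sg)) gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg[1]))) else ""
  list(cell = if (anyNA(cell)) numeric(0) else cell, spaceGroup = sgv,
       operators = list())
}

#' Read a macromolecular structure
#'
#' Reads PDB or mmCIF files (via bio3d), retaining all ATOM/HETATM
#' records. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order); waters are flagged by residue
#' name; unit cell, space group and REMARK 350 assembly operators are
#' captured when present. Hydrogens are retained when present, never
#' added.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension; default).
#' @return a \linkS4class{Structure}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("unreadable ", format, " file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  element <- if (!is.null(a$elesy)) trimws(a$elesy) else rep("", nrow(a))
  element[is.na(element)] <- ""
  missing_el <- element == ""
  if (any(missing_el)) {
    element[missing_el] <- .infer_element(trimws(a$elety[missing_el]),
                                          a$type[missing_el])
    warning(sum(missing_el), " atom(s) lacked an element symbol; inferred from atom name")
  }
  occ <- a$o
  occ[is.na(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  at <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert) | a$insert == "", "", trimws(a$insert)),
    x = a$x, y = a$y, z = a$z,
    occ = occ,
    b = ifelse(is.na(a$b), 0, a$b),
    element = toupper(element),
    record = a$type,
    cap = FALSE,
    stringsAsFactors = FALSE
  )
  # resolve altlocs: highest occupancy wins, ties go to the first in file
  alt <- if (!is.null(a$alt)) ifelse(is.na(a$alt), "", trimws(a$alt)) else rep("", nrow(a))
  if (any(alt != "")) {
    gid <- paste(at$chain, at$resno, at$insert, at$name, sep = "\r")
    # stable ordering: pick the max-occupancy row per group, first-in-file on ties
    ord <- order(gid, -at$occ, seq_len(nrow(at)))
    keep_idx <- ord[!duplicated(gid[ord])]
    at <- at[sort(keep_idx), , drop = FALSE]
  }
  hdr <- if (format == "pdb") .parse_pdb_header(readLines(path, warn = FALSE))
         else .parse_cif_header(readLines(path, warn = FALSE))
  entry <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "", basename(path),
               ignore.case = TRUE)
  .structure(at, entryId = entry, cell = hdr$cell,
             spaceGroup = hdr$spaceGroup, operators = hdr$operators)
}

#' Write a structure as PDB text
#'
#' Emits a CRYST1 record when the structure carries a unit cell, then
#' ATOM/HETATM records through bio3d. Atom names longer than four
#' characters or multi-character chain identifiers cannot be represented
#' in fixed-width PDB fields and raise an error listing the offenders.
#'
#' @param s a \linkS4class{Structure}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(s, path) {
  at <- s@atoms
  bad <- unique(c(at$name[nchar(at$name) > 4],
                  at$chain[nchar(at$chain) > 1]))
  if (length(bad))
    stop("identifiers not representable in PDB fields: ",
         paste(bad, collapse = ", "))
  header <- character(0)
  if (length(s@cell) == 6) {
    header <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                      s@cell[1], s@cell[2], s@cell[3],
                      s@cell[4], s@cell[5], s@cell[6],
                      if (nzchar(s@spaceGroup)) s@spaceGroup else "P 1")
  }
  writeLines(header, path)
  if (nrow(at) > 0) {
    xyz <- as.vector(t(.coords_of(at)))
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                     type = at$record, resno = at$resno, resid = at$resname,
                     eleno = at$serial, elety = at$name, chain = at$chain,
                     insert = ifelse(at$insert == "", NA, at$insert),
                     o = at$occ, b = at$b, elesy = at$element,
                     append = length(header) > 0, end = TRUE)
  } else if (length(header) == 0) {
    writeLines("END", path)
  }
  invisible(path)
}

#' Apply a rigid-body transform
#'
#' Returns a copy of the structure with coordinates R x + t and chain
#' identifiers suffixed (used to generate symmetry/assembly mates: the
#' crystal holds one protomer per asymmetric unit, so the functional
#' dimer is built by applying a mate operator).
#'
#' @param s a \linkS4class{Structure}.
#' @param t a \linkS4class{Transform}.
#' @param newChainSuffix string appended to every chain id (default "").
#' @return the transformed \linkS4class{Structure}; the input is untouched.
#' @export
applyTransform <- function(s, t, newChainSuffix = "") {
  stopifnot(methods::is(s, "Structure"), methods::is(t, "Transform"))
  methods::validObject(t)
  at <- s@atoms
  if (nrow(at) > 0) {
    xyz <- .coords_of(at) %*% t(t@rotation)
    at$x <- xyz[, 1] + t@translation[1]
    at$y <- xyz[, 2] + t@translation[2]
    at$z <- xyz[, 3] + t@translation[3]
    if (nzchar(newChainSuffix)) at$chain <- paste0(at$chain, newChainSuffix)
  }
  .structure(at, entryId = s@entryId, cell = s@cell,
             spaceGroup = s@spaceGroup, operators = s@operators)
}

# residue classification used by selection and the cluster builder
.classify_residues <- function(at) {
  water <- at$resname %in% .water_resnames
  polymer <- at$record == "ATOM" & !water
  ligand <- at$record == "HETATM" & !water
  data.frame(water = water, polymer = polymer, ligand = ligand)
}

#' Select a substructure
#'
#' Keeps atoms matching all given filters (logical AND). Selection is
#' idempotent; an empty result is an empty Structure, not an error.
#'
#' @param s a \linkS4class{Structure}.
#' @param chains character vector of chain ids, or NULL.
#' @param resno integer vector of residue numbers, or NULL.
#' @param resnames character vector of residue names, or NULL.
#' @param residues character vector of residue keys "chain/resno", or NULL.
#' @param water,ligand,polymer logical filters (NA = don't care).
#' @return the selected \linkS4class{Structure}.
#' @export
selectAtoms <- function(s, chains = NULL, resno = NULL, resnames = NULL,
                        residues = NULL, water = NA, ligand = NA,
                        polymer = NA) {
  at <- s@atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resnames)) keep <- keep & at$resname %in% resnames
  if (!is.null(residues)) keep <- keep & .res_keys_of(at) %in% residues
  cls <- .classify_residues(at)
  if (!is.na(water)) keep <- keep & (cls$water == water)
  if (!is.na(ligand)) keep <- keep & (cls$ligand == ligand)
  if (!is.na(polymer)) keep <- keep & (cls$polymer == polymer)
  if (!any(keep)) message("selection on '", s@entryId, "' is empty")
  .structure(at[keep, , drop = FALSE], entryId = s@entryId, cell = s@cell,
             spaceGroup = s@spaceGroup, operators = s@operators)
}

#' Concatenate two structures into one
#'
#' @param a,b \linkS4class{Structure} objects with disjoint atom sets.
#' @return combined \linkS4class{Structure}; serials renumbered when they clash.
#' @export
combineStructures <- function(a, b) {
  at <- rbind(a@atoms, b@atoms)
  if (anyDuplicated(at$serial)) at$serial <- seq_len(nrow(at))
  .structure(at, entryId = paste0(a@entryId, "+", b@entryId),
             cell = a@cell, spaceGroup = a@spaceGroup)
}
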