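# Reading protein-ligand complexes from PDB/PQR and partitioning them into
# receptor and ligand atom sets.  Atoms are held as a plain data.frame (one row
# per atom) so that downstream geometry code can stay vectorised.

WATER_RESIDUES <- c("HOH", "WAT", "DOD")

# atom-name prefixes that resolve to two-letter elements without further
# context; NA/CA/CO/CD and friends clash with common organic names and are only
# accepted when the residue name itself is the element (monoatomic ions)
TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "CU", "NI")
ION_ELEMENTS <- c("NA", "CA", "K", "CO", "CD", "HG", "LI", "SR", "CS", "BA")

#' Construct a molecular complex from receptor and ligand atom tables
#'
#' A `molecular_complex` is the unit scored by the affinity predictor: a
#' receptor atom table and a ligand atom table, each a data.frame with columns
#' `serial`, `name`, `element`, `resname`, `resno`, `insert`, `chain`,
#' `x`, `y`, `z`, `charge`, `kind`.
#'
#' @param receptor,ligand data.frames of atom records.
#' @param label complex label (used in printing and pose bookkeeping).
#' @return An object of class `molecular_complex`.
#' @export
molecular_complex <- function(receptor, ligand, label = "complex") {
  receptor <- .as_atom_table(receptor)
  ligand <- .as_atom_table(ligand)
  if (length(intersect(receptor$serial, ligand$serial)) > 0L)
    stop("receptor and ligand atom sets share serial numbers")
  xyz <- c(receptor$x, receptor$y, receptor$z, ligand$x, ligand$y, ligand$z)
  if (!all(is.finite(xyz)))
    stop("non-finite atom coordinates")
  has_q_r <- !all(is.na(receptor$charge))
  has_q_l <- !all(is.na(ligand$charge))
  if (has_q_r || has_q_l) {
    q <- c(receptor$charge, ligand$charge)
    if (any(is.na(q)))
      stop("charge-consistency error: partial charges present for some atoms ",
           "but missing for atom serial ",
           c(receptor$serial, ligand$serial)[which(is.na(q))[1L]])
  }
  structure(list(receptor = receptor, ligand = ligand, label = label),
            class = "molecular_complex")
}

.atom_cols <- c("serial", "name", "element", "resname", "resno", "insert",
                "chain", "x", "y", "z", "charge", "kind")

.as_atom_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$insert)) df$insert <- ""
  if (is.null(df$charge)) df$charge <- NA_real_
  if (is.null(df$kind)) df$kind <- "ATOM"
  missing <- setdiff(.atom_cols, names(df))
  if (length(missing) > 0L)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  df <- df[, .atom_cols]
  df$insert[is.na(df$insert)] <- ""
  df$name <- trimws(df$name)
  rownames(df) <- NULL
  df
}

#' @export
print.molecular_complex <- function(x, ...) {
  cat("Molecular complex:", x$label, "\n")
  cat("  receptor atoms:", nrow(x$receptor),
      " ligand atoms:", nrow(x$ligand), "\n")
  cat("  partial charges:", if (has_charges(x)) "present" else "absent", "\n")
  invisible(x)
}

#' Do all atoms of a complex carry partial charges?
#' @param complex a `molecular_complex`.
#' @return Logical scalar.
#' @export
has_charges <- function(complex) {
  !anyNA(c(complex$receptor$charge, complex$ligand$charge))
}

#' Residue key combining residue number and insertion code
#'
#' Insertion codes are appended to the residue number as a suffix rather than
#' renumbering, so "100" and "100A" stay distinct.
#' @param atoms an atom table.
#' @return Character vector of `chain|resno[insert]` keys.
#' @export
residue_key <- function(atoms) {
  paste0(atoms$chain, "|", atoms$resno, atoms$insert)
}

#' Infer an element symbol from a PDB atom name
#'
#' Uses the standard name-alignment conventions: a leading digit marks a
#' hydrogen name (`1HB` -> H); two-letter element prefixes (CL, BR, FE, ZN,
#' ...) are honoured for HETATM records, with ambiguous cases (CA, NA, CO ...)
#' accepted only when the residue name is the element itself (monoatomic
#' ions).  ATOM records in polymer residues use the first alphabetic
#' character, so " CA " in ALA is carbon, not calcium.
#'
#' @param name atom name(s), trimmed or column-aligned.
#' @param kind record kind, "ATOM" or "HETATM" (recycled).
#' @param resname residue name(s) (recycled).
#' @return Uppercase element symbols; `""` marks an unresolvable name (with a
#'   warning), never a silent guess.
#' @export
infer_element <- function(name, kind = "ATOM", resname = "") {
  n <- length(name)
  kind <- rep_len(kind, n)
  resname <- rep_len(trimws(resname), n)
  raw <- name
  name <- toupper(trimws(name))
  out <- character(n)
  for (i in seq_len(n)) {
    nm <- name[i]
    if (nzchar(nm) && grepl("^[0-9]", nm))
      nm <- sub("^[0-9]+", "", nm)
    if (!nzchar(nm)) {
      out[i] <- ""
      next
    }
    two <- substr(nm, 1L, 2L)
    if (grepl("^[0-9]", raw[i]) || startsWith(nm, "H")) {
      # leading-digit or H-prefixed names are hydrogens in polymer residues;
      # mercury and friends only occur as ions, caught below
      if (kind[i] == "HETATM" && two %in% ION_ELEMENTS && resname[i] == two) {
        out[i] <- two
      } else {
        out[i] <- "H"
      }
      next
    }
    if (two %in% TWO_LETTER_ELEMENTS && (kind[i] == "HETATM" || resname[i] == two)) {
      out[i] <- two
      next
    }
    if (two %in% ION_ELEMENTS && resname[i] == two) {
      out[i] <- two
      next
    }
    first <- sub("^[^A-Z]*", "", nm)
    first <- substr(first, 1L, 1L)
    if (first %in% c("C", "N", "O", "S", "P", "H", "F", "I", "K", "B", "W", "U", "V", "Y")) {
      out[i] <- first
    } else {
      out[i] <- ""
    }
  }
  if (any(out == ""))
    warning("unknown element for atom name(s): ",
            paste(unique(raw[out == ""]), collapse = ", "))
  out
}

#' Read a protein-ligand complex from a PDB or PQR file
#'
#' Water residues (HOH, WAT, DOD) are dropped.  Alternate locations are
#' resolved to the highest-occupancy copy (ties broken by file order).
#' Elements come from the PDB element column when present, otherwise from
#' [infer_element()].  PQR input populates per-atom partial charges; a sidecar
#' charge table (`serial<TAB>charge`) may be supplied for PDB input.
#'
#' @param file path to a PDB or PQR file.
#' @param ligand `"auto"` (all non-water HETATM records form the ligand) or a
#'   residue name identifying the ligand.
#' @param chain optional chain restriction for the ligand selector.
#' @param format `"auto"` (by file extension), `"pdb"` or `"pqr"`.
#' @param charges optional sidecar charge table: a path to a two-column
#'   delimited file or a data.frame with columns `serial` and `charge`.
#' @param label complex label; defaults to the file name.
#' @return A [molecular_complex()].
#' @export
read_complex <- function(file, ligand = "auto", chain = NULL,
                         format = c("auto", "pdb", "pqr"),
                         charges = NULL, label = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pqr$", file, ignore.case = TRUE)) "pqr" else "pdb"
  parsed <- if (format == "pqr") bio3d::read.pqr(file) else
    suppressWarnings(bio3d::read.pdb(file, rm.alt = FALSE))
  at <- parsed$atom
  if (nrow(at) == 0L)
    stop("parse error: no ATOM/HETATM records in ", file)

  df <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = if (is.null(at$elesy)) NA_character_ else toupper(trimws(at$elesy)),
    resname = trimws(at$resid),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", trimws(at$insert)),
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    charge = if (format == "pqr") at$o else NA_real_,
    kind = at$type,
    stringsAsFactors = FALSE)
  df$element[is.na(df$element) | df$element == ""] <- NA_character_

  # altloc resolution: keep highest occupancy per atom site, ties -> first
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- if (format == "pqr") rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  site <- paste(df$kind, df$chain, df$resno, df$insert, df$resname, df$name)
  keep <- rep(TRUE, nrow(df))
  for (s in unique(site[alt != ""])) {
    idx <- which(site == s)
    if (length(idx) > 1L) {
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]

  df <- df[!(df$resname %in% WATER_RESIDUES), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("selection error: no non-water atoms in ", file)

  need <- is.na(df$element)
  if (any(need))
    df$element[need] <- infer_element(df$name[need], df$kind[need],
                                      df$resname[need])

  if (identical(ligand, "auto")) {
    is_lig <- df$kind == "HETATM"
    if (!is.null(chain)) is_lig <- is_lig & df$chain %in% chain
  } else {
    is_lig <- df$resname %in% ligand
    if (!is.null(chain)) is_lig <- is_lig & df$chain %in% chain
  }
  if (!any(is_lig))
    stop("selection error: ligand selector matched no non-water atoms")

  if (!is.null(charges)) {
    if (is.character(charges))
      charges <- utils::read.table(charges, header = FALSE, sep = "\t",
                                   col.names = c("serial", "charge"))
    m <- match(df$serial, charges$serial)
    if (anyNA(m))
      stop("charge-consistency error: sidecar table lacks charge for atom ",
           "serial ", df$serial[which(is.na(m))[1L]])
    df$charge <- charges$charge[m]
  }

  molecular_complex(df[!is_lig, , drop = FALSE], df[is_lig, , drop = FALSE],
                    label = if (is.null(label)) basename(file) else label)
}

#' Write a complex back to PDB or PQR
#'
#' Receptor atoms are written first (as their original record kinds), then the
#' ligand atoms.  PQR output requires partial charges on every atom.
#'
#' @param complex a `molecular_complex`.
#' @param file output path.
#' @param format `"pdb"` or `"pqr"`.
#' @return `file`, invisibly.
#' @export
write_complex <- function(complex, file, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  at <- rbind(complex$receptor, complex$ligand)
  if (format == "pqr") {
    if (anyNA(at$charge))
      stop("PQR output requires partial charges on every atom")
    bio3d::write.pqr(file = file,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = at$kind, resno = at$resno, resid = at$resname,
                     eleno = at$serial, elety = at$name, chain = at$chain,
                     insert = at$insert, o = at$charge, b = rep(1.5, nrow(at)))
  } else {
    bio3d::write.pdb(file = file,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = at$kind, resno = at$resno, resid = at$resname,
                     eleno = at$serial, elety = at$name, chain = at$chain,
                     insert = at$insert, o = rep(1, nrow(at)),
                     b = rep(0, nrow(at)), elesy = at$element)
  }
  invisible(file)
}

#' Is a hydrogen atom polar?
#'
#' Polarity is decided geometrically: a hydrogen is polar iff the nearest
#' heavy atom within `threshold` angstroms (its presumed covalent partner) is
#' nitrogen, oxygen or sulfur.  PDB CONECT records are unreliable, so bonding
#' is not read from the file.
#'
#' @param h a single-row atom table (element H).
#' @param complex the `molecular_complex` the hydrogen belongs to.
#' @param threshold covalent-bond distance cutoff in angstroms.
#' @return Logical scalar; an isolated hydrogen (no heavy atom within
#'   `threshold`) is non-polar and triggers a warning.
#' @export
hydrogen_is_polar <- function(h, complex, threshold = 1.3) {
  if (toupper(h$element[1L]) != "H")
    stop("hydrogen_is_polar expects a hydrogen atom")
  at <- rbind(complex$receptor, complex$ligand)
  .polar_h_flags(at, threshold)[match(h$serial[1L], at$serial)]
}

# vectorised polarity flags for every atom in a combined atom table
# (TRUE only meaningful for hydrogens; heavy atoms get NA)
.polar_h_flags <- function(at, threshold = 1.3) {
  flags <- rep(NA, nrow(at))
  is_h <- toupper(at$element) == "H"
  if (!any(is_h)) return(flags)
  heavy <- which(!is_h & at$element != "")
  hx <- as.matrix(at[is_h, c("x", "y", "z"), drop = FALSE])
  if (length(heavy) == 0L) {
    warning("hydrogen atom(s) with no heavy atom within ", threshold, " A")
    flags[is_h] <- FALSE
    return(flags)
  }
  gx <- as.matrix(at[heavy, c("x", "y", "z"), drop = FALSE])
  d2 <- outer(rowSums(hx^2), rowSums(gx^2), "+") - 2 * tcrossprod(hx, gx)
  d2[d2 < 0] <- 0
  nearest <- apply(d2, 1L, which.min)
  near_d <- sqrt(d2[cbind(seq_len(nrow(hx)), nearest)])
  bonded <- near_d <= threshold
  if (any(!bonded))
    warning(sum(!bonded), " hydrogen atom(s) with no heavy atom within ",
            threshold, " A; treated as non-polar")
  polar <- bonded & at$element[heavy][nearest] %in% c("N", "O", "S")
  flags[is_h] <- polar
  flags
}
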