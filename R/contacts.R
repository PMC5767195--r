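# Intermolecular atomic contacts at a distance cutoff, classified by the
# elements involved: C, N and O map to themselves, every other heavy element
# and polar hydrogens map to the catch-all class X, and non-polar hydrogens
# are excluded from counting (united-atom convention).

CONTACT_CLASSES <- c("C", "N", "O", "X")
CONTACT_PAIR_KEYS <- c("CC", "CN", "CO", "CX", "NN", "NO", "NX", "OO", "OX", "XX")

#' Contact class of an atom
#'
#' @param element element symbol(s).
#' @param polar_h logical, recycled: is each hydrogen polar? (ignored for
#'   heavy atoms).
#' @return Character vector over `{"C","N","O","X","NONE"}`; `"NONE"` marks
#'   atoms excluded from contact counting (non-polar hydrogens, unknown
#'   elements — the latter with a warning).
#' @export
contact_class <- function(element, polar_h = FALSE) {
  element <- toupper(element)
  polar_h <- rep_len(polar_h, length(element))
  out <- ifelse(element %in% c("C", "N", "O"), element, "X")
  out[element == "H"] <- ifelse(polar_h[element == "H"], "X", "NONE")
  unknown <- is.na(element) | element == ""
  if (any(unknown)) {
    warning("unknown element(s) assigned contact class NONE")
    out[unknown] <- "NONE"
  }
  out
}

# canonical unordered pair key, e.g. ("O","C") -> "CO"
.pair_key <- function(a, b) {
  paste0(pmin(a, b), pmax(a, b))
}

#' Count intermolecular atomic contacts
#'
#' Every (receptor atom, ligand atom) pair with Euclidean distance `<= cutoff`
#' (inclusive boundary) and both contact classes not `NONE` increments the
#' count of its unordered class pair.  Hydrogens enter as class X when polar
#' and are excluded otherwise; polarity is decided by [hydrogen_is_polar()]
#' geometry over the whole complex.
#'
#' @param complex a `molecular_complex` with a non-empty ligand.
#' @param cutoff contact distance threshold in angstroms.
#' @param polar_h_threshold covalent-bond cutoff for hydrogen polarity.
#' @return A `contact_profile`: counts for the 10 unordered class pairs
#'   (CC, CN, CO, CX, NN, NO, NX, OO, OX, XX), the cutoff used, and the atom
#'   counts.
#' @export
count_contacts <- function(complex, cutoff = 10.5, polar_h_threshold = 1.3) {
  stopifnot(inherits(complex, "molecular_complex"))
  if (nrow(complex$ligand) == 0L)
    stop("empty ligand: nothing to count contacts against")
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive")

  at <- rbind(complex$receptor, complex$ligand)
  flags <- .polar_h_flags(at, polar_h_threshold)
  n_r <- nrow(complex$receptor)
  cls <- suppressWarnings(contact_class(at$element, ifelse(is.na(flags), FALSE, flags)))
  cls_r <- cls[seq_len(n_r)]
  cls_l <- cls[(n_r + 1L):nrow(at)]

  counts <- stats::setNames(integer(length(CONTACT_PAIR_KEYS)), CONTACT_PAIR_KEYS)
  keep_r <- which(cls_r != "NONE")
  keep_l <- which(cls_l != "NONE")
  if (length(keep_r) > 0L && length(keep_l) > 0L) {
    rx <- as.matrix(complex$receptor[keep_r, c("x", "y", "z"), drop = FALSE])
    lx <- as.matrix(complex$ligand[keep_l, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * tcrossprod(rx, lx)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      keys <- .pair_key(cls_r[keep_r][hit[, 1L]], cls_l[keep_l][hit[, 2L]])
      tab <- table(keys)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  structure(list(counts = counts, cutoff = cutoff,
                 n_receptor_atoms = n_r, n_ligand_atoms = nrow(complex$ligand)),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Contact profile (cutoff", x$cutoff, "A):",
      x$n_receptor_atoms, "receptor x", x$n_ligand_atoms, "ligand atoms\n")
  print(x$counts)
  invisible(x)
}

#' Feature vector for the contact-based affinity model
#'
#' Extracts the electrostatic energy and the four homogeneous contact counts
#' (CC, NN, OO, XX) in model order.  Under `xx_mode = "fold_hetero"` the XX
#' feature instead absorbs every pair that is not CC, NN or OO.
#'
#' @param profile a `contact_profile`.
#' @param e_elec intermolecular electrostatic energy in kcal/mol.
#' @param xx_mode `"strict"` (default: XX counts only X-X pairs) or
#'   `"fold_hetero"`.
#' @return Named numeric vector `(e_elec, ac_cc, ac_nn, ac_oo, ac_xx)`.
#' @export
feature_vector <- function(profile, e_elec = 0,
                           xx_mode = c("strict", "fold_hetero")) {
  stopifnot(inherits(profile, "contact_profile"))
  xx_mode <- match.arg(xx_mode)
  cts <- profile$counts
  xx <- if (xx_mode == "strict") cts[["XX"]] else
    sum(cts) - cts[["CC"]] - cts[["NN"]] - cts[["OO"]]
  c(e_elec = as.numeric(e_elec), ac_cc = as.numeric(cts[["CC"]]),
    ac_nn = as.numeric(cts[["NN"]]), ac_oo = as.numeric(cts[["OO"]]),
    ac_xx = as.numeric(xx))
}

#' Write a contact profile as a two-column table
#' @param profile a `contact_profile`.
#' @param file output path (TSV: pair, count).
#' @return `file`, invisibly.
#' @export
write_contact_profile <- function(profile, file) {
  utils::write.table(
    data.frame(pair = names(profile$counts), count = as.integer(profile$counts)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
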