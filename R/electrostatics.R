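# Intermolecular Coulomb electrostatics with a shifted potential, evaluated
# on the given coordinates (no minimisation).  The shift S(r) = (1-(r/rc)^2)^2
# takes the energy smoothly to zero at the cutoff.

#' Electrostatics parameters
#'
#' Defaults follow the refinement conventions the affinity model was trained
#' under: dielectric constant 10, 8.5 A cutoff with a shifting function.
#' `coulomb_constant` is in kcal.A/(mol.e^2).
#'
#' @param dielectric relative dielectric constant (> 0).
#' @param cutoff pair cutoff in angstroms (> 0).
#' @param coulomb_constant Coulomb prefactor in kcal.A/(mol.e^2).
#' @param shift shifting function S(r, rc); the default is the standard
#'   potential shift `(1 - (r/rc)^2)^2`.
#' @return A list of class `elec_params`.
#' @export
elec_params <- function(dielectric = 10, cutoff = 8.5,
                        coulomb_constant = 332.0636, shift = NULL) {
  if (dielectric <= 0) stop("dielectric must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(shift))
    shift <- function(r, rc) (1 - (r / rc)^2)^2
  structure(list(dielectric = dielectric, cutoff = cutoff,
                 coulomb_constant = coulomb_constant, shift = shift),
            class = "elec_params")
}

#' Intermolecular electrostatic energy of a complex
#'
#' Sums `k * q_i * q_j / (eps * r) * S(r)` over all receptor-ligand atom pairs
#' with `r <= cutoff`; pairs beyond the cutoff contribute zero.  Charges are
#' inputs (PQR or sidecar table) and are never assigned internally.
#'
#' @param complex a `molecular_complex` whose atoms all carry partial charges.
#' @param params an [elec_params()] object.
#' @return Energy in kcal/mol.
#' @export
e_elec <- function(complex, params = elec_params()) {
  stopifnot(inherits(complex, "molecular_complex"))
  q_all <- c(complex$receptor$charge, complex$ligand$charge)
  if (anyNA(q_all)) {
    ser <- c(complex$receptor$serial, complex$ligand$serial)
    stop("missing partial charge for atom serial ", ser[which(is.na(q_all))[1L]])
  }
  rx <- as.matrix(complex$receptor[, c("x", "y", "z")])
  lx <- as.matrix(complex$ligand[, c("x", "y", "z")])
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * tcrossprod(rx, lx)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  within <- r <= params$cutoff & r > 0
  if (!any(within)) return(0)
  qq <- tcrossprod(complex$receptor$charge, complex$ligand$charge)
  s <- params$shift(r[within], params$cutoff)
  sum(params$coulomb_constant * qq[within] / (params$dielectric * r[within]) * s)
}
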