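# The linear contact-based affinity score: a named-coefficient linear model
# over (E_elec, AC_CC, AC_NN, AC_OO, AC_XX), shipped with the published
# default coefficients, plus the weighted score combiner used at the docking
# refinement stage, pose-averaged scoring and ligand ranking.

#' Construct a linear affinity model
#'
#' @param coefficients named numeric vector of feature coefficients.
#' @param intercept numeric intercept.
#' @param feature_order evaluation order of the features; defaults to
#'   `names(coefficients)`.
#' @return An object of class `affinity_model`.
#' @export
affinity_model <- function(coefficients, intercept,
                           feature_order = names(coefficients)) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named")
  if (!all(feature_order %in% names(coefficients)))
    stop("every feature in feature_order needs a coefficient")
  coefficients <- coefficients[feature_order]
  structure(list(coefficients = coefficients,
                 intercept = as.numeric(intercept),
                 feature_order = feature_order),
            class = "affinity_model")
}

#' The shipped default contact-based affinity model
#'
#' Linear score over the intermolecular electrostatic energy and the four
#' homogeneous contact counts at the 10.5 A cutoff; lower scores mean
#' stronger predicted binding (the training target was RT ln(Ki), more
#' negative for stronger binders).
#'
#' @return An `affinity_model`.
#' @export
default_affinity_model <- function() {
  affinity_model(
    coefficients = c(e_elec = 0.343794, ac_cc = -0.037597, ac_nn = 0.138738,
                     ac_oo = 0.160043, ac_xx = -3.088861),
    intercept = 187.011384)
}

#' @export
print.affinity_model <- function(x, digits = 6, ...) {
  cat("Linear affinity model:", length(x$feature_order), "features\n")
  print(round(c(x$coefficients, `(Intercept)` = x$intercept), digits))
  invisible(x)
}

#' @export
coef.affinity_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.affinity_model <- function(object, newdata, ...) {
  dg_score(newdata, object)
}

#' Evaluate the linear affinity score
#'
#' `intercept + sum(coefficient * feature)`.  `features` may be a numeric
#' vector aligned with `model$feature_order` (by name when named, by position
#' otherwise) or a matrix / data.frame with one row per observation.
#'
#' @param features feature vector, matrix or data.frame.
#' @param model an `affinity_model`; default the shipped model.
#' @return Numeric score(s).
#' @export
dg_score <- function(features, model = default_affinity_model()) {
  fo <- model$feature_order
  if (is.data.frame(features)) features <- as.matrix(features)
  if (is.matrix(features)) {
    if (!is.null(colnames(features))) {
      if (!all(fo %in% colnames(features)))
        stop("feature columns missing: ",
             paste(setdiff(fo, colnames(features)), collapse = ", "))
      features <- features[, fo, drop = FALSE]
    } else if (ncol(features) != length(fo)) {
      stop("feature length mismatch: expected ", length(fo), ", got ",
           ncol(features))
    }
    return(as.numeric(features %*% model$coefficients + model$intercept))
  }
  if (!is.null(names(features))) {
    if (!all(fo %in% names(features)))
      stop("features missing: ", paste(setdiff(fo, names(features)), collapse = ", "))
    features <- features[fo]
  } else if (length(features) != length(fo)) {
    stop("feature length mismatch: expected ", length(fo), ", got ",
         length(features))
  }
  sum(model$coefficients * as.numeric(features)) + model$intercept
}

#' Refinement-stage score combiner
#'
#' Weighted sum `1.0*E_vdW + 1.0*E_elec + 1.0*E_desol - 0.01*BSA` used for
#' ranking poses at the semi-flexible refinement stage.  All four terms are
#' supplied by the caller (only the electrostatic term can be computed here,
#' via [e_elec()]).
#'
#' @param e_vdw,e_elec,e_desol energies in kcal/mol.
#' @param bsa buried surface area in square angstroms.
#' @return Numeric score(s); vectorised.
#' @export
haddock_it1_score <- function(e_vdw, e_elec, e_desol, bsa) {
  1.0 * e_vdw + 1.0 * e_elec + 1.0 * e_desol - 0.01 * bsa
}

#' Serialize / deserialize an affinity model as JSON
#'
#' @param model an `affinity_model`.
#' @param file path to a JSON file.
#' @return `write_affinity_model` returns `file` invisibly;
#'   `read_affinity_model` returns the model.
#' @export
write_affinity_model <- function(model, file) {
  jsonlite::write_json(
    list(feature_order = model$feature_order,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_affinity_model
#' @export
read_affinity_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  affinity_model(unlist(obj$coefficients), obj$intercept,
                 feature_order = obj$feature_order)
}

#' Pose-averaged affinity score for one ligand
#'
#' Scores the first `min(top_n, available)` poses (file order = docking rank)
#' with [count_contacts()], [e_elec()] and [dg_score()], and records their
#' arithmetic mean.  Poses without partial charges are scored with the
#' electrostatic feature set to zero, with a warning.
#'
#' @param poses list of `molecular_complex` poses for one ligand, ordered by
#'   docking rank.
#' @param model an `affinity_model`.
#' @param ligand_id ligand identifier; defaults to the first pose's label.
#' @param top_n number of top poses to average over.
#' @param cutoff contact cutoff in angstroms.
#' @param params [elec_params()] for the electrostatic feature.
#' @param xx_mode passed to [feature_vector()].
#' @return A `pose_score`: ligand id, per-pose scores, their mean, and the
#'   number of poses used.
#' @export
score_poses <- function(poses, model = default_affinity_model(),
                        ligand_id = NULL, top_n = 10, cutoff = 10.5,
                        params = elec_params(),
                        xx_mode = c("strict", "fold_hetero")) {
  xx_mode <- match.arg(xx_mode)
  if (length(poses) == 0L) stop("no poses supplied")
  if (is.null(ligand_id)) ligand_id <- poses[[1L]]$label
  use <- poses[seq_len(min(top_n, length(poses)))]
  warned <- FALSE
  scores <- vapply(use, function(p) {
    prof <- count_contacts(p, cutoff = cutoff)
    ee <- if (has_charges(p)) e_elec(p, params) else {
      if (!warned) {
        warning("pose(s) without partial charges: electrostatic feature set to 0 for ",
                ligand_id)
        warned <<- TRUE
      }
      0
    }
    dg_score(feature_vector(prof, ee, xx_mode), model)
  }, numeric(1L))
  structure(list(ligand_id = ligand_id, per_pose_scores = scores,
                 mean_score = mean(scores), n_poses_used = length(scores)),
            class = "pose_score")
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf("Pose score %s: mean %.4f over %d pose(s)\n",
              x$ligand_id, x$mean_score, x$n_poses_used))
  invisible(x)
}

#' Rank ligands by pose-averaged score
#'
#' Ascending mean score (lower = stronger predicted binding); ties broken
#' lexicographically by ligand id.
#'
#' @param scores list of `pose_score` objects with unique ligand ids.
#' @return Character vector of ligand ids, best first.
#' @export
rank_ligands <- function(scores) {
  ids <- vapply(scores, function(s) s$ligand_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate ligand ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  means <- vapply(scores, function(s) s$mean_score, numeric(1L))
  ids[order(means, ids, method = "radix")]
}
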