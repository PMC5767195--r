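# Ranking and pose-quality metrics: Kendall tau-b, Pearson r, positive
# predictive value / enrichment curves for ranked virtual screening, ligand
# RMSD after receptor-backbone superposition, and top-N success rates.

#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie correction, over all pairs.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  stats::cor(x, y, method = "kendall")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length with nonzero variance.
#' @return r in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  stats::cor(x, y)
}

#' Positive-predictive-value and enrichment curves for a ranking
#'
#' A compound is a true positive at depth N when it appears within the top N
#' of both the predicted and the experimental ranking, so
#' `PPV(N) = |topN(pred) intersect topN(exp)| / N`.  The enrichment factor is
#' PPV relative to the random-prediction diagonal: `EF(N) = PPV(N) / (N/n)`.
#'
#' @param predicted_rank,experimental_rank character vectors of the same id
#'   set, ordered best first.
#' @return data.frame with columns `n_top`, `ppv`, `rp` (random baseline
#'   `N/n`) and `ef`.
#' @export
ppv_curve <- function(predicted_rank, experimental_rank) {
  if (length(predicted_rank) != length(experimental_rank) ||
      !setequal(predicted_rank, experimental_rank) ||
      anyDuplicated(predicted_rank) || anyDuplicated(experimental_rank))
    stop("rankings must be permutations of the same id set")
  n <- length(predicted_rank)
  # position of each predicted id in the experimental ranking
  pos <- match(predicted_rank, experimental_rank)
  hits <- vapply(seq_len(n), function(N) sum(pos[seq_len(N)] <= N), integer(1L))
  ppv <- hits / seq_len(n)
  rp <- seq_len(n) / n
  data.frame(n_top = seq_len(n), ppv = ppv, rp = rp, ef = ppv / rp)
}

#' Evaluate a predicted ranking against experimental values
#'
#' @param predicted named numeric scores (lower = better predicted).
#' @param experimental named numeric values (lower = better), same ids.
#' @return A `ranking_evaluation`: n, Kendall tau-b, Pearson r and the
#'   [ppv_curve()] of the induced rankings.
#' @export
evaluate_ranking <- function(predicted, experimental) {
  ids <- names(predicted)
  if (is.null(ids) || !setequal(ids, names(experimental)))
    stop("predicted and experimental must be named over the same ids")
  experimental <- experimental[ids]
  ord_p <- ids[order(predicted, ids, method = "radix")]
  ord_e <- ids[order(experimental, ids, method = "radix")]
  structure(list(n = length(ids),
                 kendall_tau = kendall_tau(predicted, experimental),
                 pearson_r = pearson(predicted, experimental),
                 curve = ppv_curve(ord_p, ord_e)),
            class = "ranking_evaluation")
}

#' @export
print.ranking_evaluation <- function(x, ...) {
  cat(sprintf("Ranking evaluation over %d compounds\n", x$n))
  cat(sprintf("  Kendall tau-b: %.4f   Pearson r: %.4f\n",
              x$kendall_tau, x$pearson_r))
  top <- x$curve[x$curve$n_top %in% unique(pmin(x$n, c(1, 5, 10, ceiling(x$n / 4)))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

# Kabsch superposition of model coordinates onto reference using a fitted
# subset, via bio3d's least-squares rotation
.superpose <- function(model_xyz, ref_xyz, fit_idx) {
  n <- nrow(model_xyz)
  flags <- rep(FALSE, n)
  flags[fit_idx] <- TRUE
  fitted <- bio3d::rot.lsq(as.numeric(t(model_xyz)), as.numeric(t(ref_xyz)),
                           xfit = rep(flags, each = 3L))
  matrix(fitted, ncol = 3L, byrow = TRUE)
}

#' Ligand RMSD after receptor-backbone superposition
#'
#' Pairs receptor backbone atoms (N, CA, C, O) between model and reference by
#' (chain, residue, atom name), superposes the model onto the reference with
#' an optimal least-squares (Kabsch) fit on those atoms, and reports the RMSD
#' over paired ligand heavy atoms.  Ligand atoms pair by name; if the name
#' sets disagree, pairing falls back to file order with a warning.
#'
#' @param model,reference `molecular_complex` objects.
#' @param backbone atom names used for the receptor fit.
#' @return RMSD in angstroms.
#' @export
ligand_rmsd <- function(model, reference, backbone = c("N", "CA", "C", "O")) {
  bm <- model$receptor[model$receptor$name %in% backbone, , drop = FALSE]
  br <- reference$receptor[reference$receptor$name %in% backbone, , drop = FALSE]
  key_m <- paste(residue_key(bm), bm$name)
  key_r <- paste(residue_key(br), br$name)
  common <- intersect(key_m, key_r)
  if (length(common) < 3L)
    stop("fewer than 3 paired backbone atoms")
  bm <- bm[match(common, key_m), ]
  br <- br[match(common, key_r), ]

  lm_ <- model$ligand[toupper(model$ligand$element) != "H", , drop = FALSE]
  lr <- reference$ligand[toupper(reference$ligand$element) != "H", , drop = FALSE]
  if (nrow(lm_) == 0L || nrow(lr) == 0L) stop("no ligand heavy atoms to pair")
  if (setequal(lm_$name, lr$name) && !anyDuplicated(lm_$name) &&
      nrow(lm_) == nrow(lr)) {
    lr <- lr[match(lm_$name, lr$name), ]
  } else {
    if (nrow(lm_) != nrow(lr))
      stop("ligand heavy atoms cannot be paired: ", nrow(lm_), " vs ", nrow(lr))
    warning("ligand atom names disagree; pairing by file order")
  }

  mx <- as.matrix(rbind(bm[, c("x", "y", "z")], lm_[, c("x", "y", "z")]))
  rx <- as.matrix(rbind(br[, c("x", "y", "z")], lr[, c("x", "y", "z")]))
  fitted <- .superpose(mx, rx, seq_len(nrow(bm)))
  lig_idx <- (nrow(bm) + 1L):nrow(mx)
  sqrt(mean(rowSums((fitted[lig_idx, , drop = FALSE] -
                     rx[lig_idx, , drop = FALSE])^2)))
}

#' Top-N pose success rate
#'
#' Fraction of targets whose best ligand RMSD among their first `top_n` poses
#' beats the cutoff (strict `<` by default).
#'
#' @param lrmsd_per_target list of per-target numeric vectors of pose l-RMSDs,
#'   ordered by pose rank.
#' @param cutoff success cutoff in angstroms.
#' @param top_n number of top poses considered per target.
#' @param strict use strict `<` (default) rather than `<=`.
#' @return Fraction of successful targets in `[0, 1]`.
#' @export
success_rate <- function(lrmsd_per_target, cutoff = 2.5, top_n = 1,
                         strict = TRUE) {
  if (length(lrmsd_per_target) == 0L) stop("no targets")
  ok <- vapply(lrmsd_per_target, function(v) {
    if (length(v) == 0L) stop("target with no poses")
    best <- min(v[seq_len(min(top_n, length(v)))])
    if (strict) best < cutoff else best <= cutoff
  }, logical(1L))
  mean(ok)
}
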