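# Ligand-based affinity machinery: heavy-atom molecule graphs from SD/MOL
# V2000 records, Carhart atom-pair fingerprints, Tanimoto similarity kernels
# and epsilon-SVR on the precomputed kernel.  Atom typing follows Carhart
# (element, heavy-neighbour count, pi-electron count); topological distances
# are shortest-path bond counts.

#' Construct a heavy-atom molecule graph
#'
#' Hydrogens are suppressed: they are dropped from the atom list (heavy
#' neighbour counts are unaffected since they count heavy atoms only).
#' Per-atom pi-electron counts are derived from incident bond orders: each
#' double bond contributes 1, each triple bond 2 and each aromatic bond 1 to
#' both endpoints.
#'
#' @param elements character vector of element symbols (may include H).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 4 = aromatic).
#' @param id molecule identifier.
#' @return A `molecule_graph` with heavy-atom `atoms` (element, n_heavy,
#'   n_pi) and `bonds` reindexed to the heavy atoms.
#' @export
molecule_graph <- function(elements, bonds, id = "mol") {
  elements <- toupper(trimws(elements))
  n <- length(elements)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)))
    stop("bond endpoints out of range")
  if (nrow(bonds) > 0 && !all(bonds$order %in% c(1, 2, 3, 4)))
    stop("bond orders must be 1, 2, 3 or 4 (aromatic)")
  heavy <- elements != "H"
  pi_per_bond <- c(`1` = 0, `2` = 1, `3` = 2, `4` = 1)
  n_pi <- integer(n)
  n_heavy <- integer(n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    add <- pi_per_bond[[as.character(bonds$order[b])]]
    n_pi[i] <- n_pi[i] + add
    n_pi[j] <- n_pi[j] + add
    if (heavy[j]) n_heavy[i] <- n_heavy[i] + 1L
    if (heavy[i]) n_heavy[j] <- n_heavy[j] + 1L
  }
  idx <- which(heavy)
  remap <- match(seq_len(n), idx)
  kb <- bonds[heavy[bonds$i] & heavy[bonds$j], , drop = FALSE]
  kb$i <- remap[kb$i]; kb$j <- remap[kb$j]
  rownames(kb) <- NULL
  structure(list(
    atoms = data.frame(element = elements[idx], n_heavy = n_heavy[idx],
                       n_pi = n_pi[idx], stringsAsFactors = FALSE),
    bonds = kb, id = id), class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("Molecule %s: %d heavy atoms, %d bonds\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Read molecule graphs from an SD/MOL V2000 file
#'
#' One graph per record, ids taken from the title lines (records with blank
#' titles get `mol<index>`).  Aromatic bond type 4 is honoured; explicit
#' hydrogens are suppressed on read.
#'
#' @param file path to an SD file.
#' @return List of [molecule_graph()] objects.
#' @export
read_sdf <- function(file) {
  lines <- readLines(file)
  # light validation of each record's counts line before delegating parsing
  starts <- c(1L, which(lines == "$$$$") + 1L)
  starts <- starts[starts + 3L <= length(lines) + 1L & starts <= length(lines)]
  for (ri in seq_along(starts)) {
    s <- starts[ri]
    if (s + 3L > length(lines)) break
    counts <- lines[s + 3L]
    if (!grepl("V2000", counts) ||
        is.na(suppressWarnings(as.integer(substr(counts, 1, 3)))))
      stop("parse error in SD record ", ri, ": malformed counts line")
  }
  sdfs <- ChemmineR::read.SDFset(file)
  ids <- ChemmineR::sdfid(sdfs)
  out <- vector("list", length(sdfs))
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
      data.frame(i = integer(0), j = integer(0), order = integer(0)) else
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    id <- if (is.na(ids[i]) || !nzchar(trimws(ids[i]))) paste0("mol", i) else
      trimws(ids[i])
    out[[i]] <- molecule_graph(elements, bonds, id = id)
  }
  out
}

# breadth-first shortest-path distances (in bonds) from one atom
.bfs_dist <- function(adj, start, n) {
  d <- rep(NA_integer_, n)
  d[start] <- 0L
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(d[nxt])]
    if (length(nxt) == 0) break
    d[nxt] <- d[frontier[1L]] + 1L
    frontier <- nxt
  }
  d
}

.atom_type <- function(atoms) {
  paste(atoms$element, atoms$n_heavy, atoms$n_pi, sep = ".")
}

#' Carhart atom-pair fingerprint
#'
#' For every unordered pair of heavy atoms, emits the descriptor
#' `(type_i, type_j, d)` with canonical `type_i <= type_j`, where the type is
#' `(element, heavy-neighbour count, pi-electron count)` and `d >= 1` is the
#' shortest-path bond distance (breadth-first search).  Pairs across
#' disconnected components are skipped with a warning.
#'
#' @param mol a [molecule_graph()].
#' @return An `ap_fingerprint`: a named integer multiset of descriptor counts
#'   with keys `type_i|type_j|d`, and attribute `n_heavy`.
#' @export
atom_pair_fingerprint <- function(mol) {
  stopifnot(inherits(mol, "molecule_graph"))
  n <- nrow(mol$atoms)
  if (n < 2L) {
    warning("fewer than 2 heavy atoms: empty fingerprint for ", mol$id)
    return(structure(stats::setNames(integer(0), character(0)),
                     n_heavy = n, class = "ap_fingerprint"))
  }
  adj <- rep(list(integer(0)), n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  types <- .atom_type(mol$atoms)
  keys <- character(0)
  skipped <- FALSE
  for (i in seq_len(n - 1L)) {
    d <- .bfs_dist(adj, i, n)
    for (j in (i + 1L):n) {
      if (is.na(d[j])) { skipped <- TRUE; next }
      ti <- types[i]; tj <- types[j]
      keys <- c(keys, paste(min(ti, tj), max(ti, tj), d[j], sep = "|"))
    }
  }
  if (skipped)
    warning("disconnected molecule ", mol$id,
            ": pairs across components skipped")
  tab <- table(keys)
  structure(stats::setNames(as.integer(tab), names(tab)),
            n_heavy = n, class = "ap_fingerprint")
}

#' Tanimoto similarity of two atom-pair fingerprints
#'
#' `sum_k min(a_k, b_k) / sum_k max(a_k, b_k)` over the union of descriptor
#' keys.  Two empty fingerprints compare as 0 with a warning.
#'
#' @param a,b `ap_fingerprint` objects.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  keys <- union(names(a), names(b))
  if (length(keys) == 0L) {
    warning("both fingerprints empty: Tanimoto defined as 0")
    return(0)
  }
  av <- rep(0L, length(keys)); bv <- rep(0L, length(keys))
  av[match(names(a), keys)] <- as.integer(a)
  bv[match(names(b), keys)] <- as.integer(b)
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Pairwise Tanimoto similarity kernel
#'
#' @param mols list of [molecule_graph()] objects (or precomputed
#'   `ap_fingerprint`s) with unique ids.
#' @return Symmetric matrix of Tanimoto values with unit diagonal, row and
#'   column names = molecule ids.
#' @export
similarity_matrix <- function(mols) {
  fps <- .as_fingerprints(mols)
  k <- length(fps)
  m <- diag(1, k)
  if (k > 1) for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
  dimnames(m) <- list(names(fps), names(fps))
  m
}

#' Cross-similarity between query and reference molecules
#'
#' @param queries,refs lists of [molecule_graph()] objects or fingerprints.
#' @return Matrix of Tanimoto values, queries in rows, references in columns.
#' @export
cross_similarity <- function(queries, refs) {
  fq <- .as_fingerprints(queries)
  fr <- .as_fingerprints(refs)
  m <- matrix(0, length(fq), length(fr), dimnames = list(names(fq), names(fr)))
  for (i in seq_along(fq)) for (j in seq_along(fr))
    m[i, j] <- tanimoto(fq[[i]], fr[[j]])
  m
}

.as_fingerprints <- function(mols) {
  if (inherits(mols, "molecule_graph") || inherits(mols, "ap_fingerprint"))
    mols <- list(mols)
  fps <- lapply(mols, function(m)
    if (inherits(m, "ap_fingerprint")) m else atom_pair_fingerprint(m))
  ids <- vapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    if (inherits(m, "molecule_graph")) m$id
    else if (!is.null(names(mols)[i]) && nzchar(names(mols)[i])) names(mols)[i]
    else paste0("mol", i)
  }, character(1L))
  stats::setNames(fps, ids)
}

#' Most similar reference molecule
#'
#' Used to pick the receptor conformation whose co-crystallised ligand best
#' matches a query ligand.  Ties (including the all-zero-similarity case,
#' which warns) resolve to the first reference in input order.
#'
#' @param query a [molecule_graph()] or fingerprint.
#' @param refs non-empty list of references.
#' @return The id of the most similar reference.
#' @export
most_similar_reference <- function(query, refs) {
  if (length(refs) == 0L) stop("no reference molecules")
  sims <- cross_similarity(list(query), refs)[1L, ]
  if (all(sims == 0))
    warning("query shares no descriptors with any reference; returning first")
  names(sims)[which.max(sims)]
}

#' Fit an epsilon-SVR on a precomputed similarity kernel
#'
#' Trains support vector regression with epsilon-insensitive loss on the
#' Tanimoto kernel (solver: kernlab).  The Tanimoto (min/max) kernel is
#' positive semi-definite; an optional diagonal jitter guards against
#' round-off.
#'
#' @param kernel square symmetric training kernel with row/column ids.
#' @param targets numeric targets, e.g. `ln(IC50)`, one per kernel row.
#' @param C cost parameter.
#' @param epsilon width of the insensitive tube.
#' @param jitter value added to the kernel diagonal.
#' @return An `ap_svr` model.
#' @export
fit_ap_svr <- function(kernel, targets, C = 1, epsilon = 0.1, jitter = 1e-8) {
  kernel <- as.matrix(kernel)
  if (nrow(kernel) != ncol(kernel) || nrow(kernel) != length(targets))
    stop("kernel dimensions must match the number of targets")
  if (any(!is.finite(targets))) stop("targets must be finite")
  ids <- rownames(kernel)
  if (is.null(ids)) ids <- paste0("x", seq_len(nrow(kernel)))
  K <- kernel + diag(jitter, nrow(kernel))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), targets, type = "eps-svr",
                       C = C, epsilon = epsilon, scaled = FALSE)
  structure(list(fit = fit, train_ids = ids,
                 sv_index = kernlab::SVindex(fit)),
            class = "ap_svr")
}

#' @export
print.ap_svr <- function(x, ...) {
  cat(sprintf("Kernel epsilon-SVR: %d training molecules, %d support vectors\n",
              length(x$train_ids), length(x$sv_index)))
  invisible(x)
}

#' Predict from a kernel SVR
#'
#' @param object an `ap_svr` model.
#' @param newkernel matrix of similarities between query molecules (rows) and
#'   the training molecules (columns, in training order).
#' @param ... unused.
#' @return Numeric predictions, one per query row.
#' @export
predict.ap_svr <- function(object, newkernel, ...) {
  newkernel <- as.matrix(newkernel)
  if (ncol(newkernel) != length(object$train_ids))
    stop("newkernel must have one column per training molecule")
  as.numeric(kernlab::predict(
    object$fit,
    kernlab::as.kernelMatrix(newkernel[, object$sv_index, drop = FALSE])))
}
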