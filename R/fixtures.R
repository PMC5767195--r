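# Deterministic generators for toy protein-ligand complexes, synthetic
# training tables and toy molecule sets, each shipped with independently
# computed brute-force oracles (naive double loops, Floyd-Warshall) kept
# separate from the production code paths.  Everything is reproducible from
# (spec, seed) alone; generators never touch the caller's RNG state.

#' Specification for a toy complex generator
#'
#' @param seed integer seed; fully determines the output.
#' @param n_receptor_atoms,n_ligand_atoms atom counts.
#' @param pocket_radius radius (angstroms) of the receptor shell; ligand
#'   atoms are placed inside the pocket.
#' @param element_frequencies named sampling probabilities (must sum to 1).
#' @param charge_range partial charges drawn uniformly from
#'   `[-charge_range, charge_range]`; 0 disables charges.
#' @param noise_sd Gaussian noise level (kcal/mol) for derived training data.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_receptor_atoms = 50, n_ligand_atoms = 10,
                         pocket_radius = 8,
                         element_frequencies = c(C = 0.55, N = 0.2, O = 0.2, S = 0.05),
                         charge_range = 0.5, noise_sd = 1.5) {
  if (abs(sum(element_frequencies) - 1) > 1e-8)
    stop("element frequencies must sum to 1")
  if (is.null(names(element_frequencies)))
    stop("element frequencies must be named by element")
  structure(list(seed = seed, n_receptor_atoms = n_receptor_atoms,
                 n_ligand_atoms = n_ligand_atoms,
                 pocket_radius = pocket_radius,
                 element_frequencies = element_frequencies,
                 charge_range = charge_range, noise_sd = noise_sd),
            class = "fixture_spec")
}

# cutoffs whose boundaries generated geometries must stay clear of
.PROTECTED_CUTOFFS <- c(10.5, 8.5)

#' Generate a toy protein-ligand complex with brute-force oracles
#'
#' Receptor atoms sit on a spherical shell of radius `pocket_radius` to
#' `pocket_radius + 4`; ligand atoms sit inside the pocket (radius
#' `0.35 * pocket_radius`).  Inter-atomic distances are kept at least 1e-3 A
#' away from the standard contact and electrostatic cutoffs so boundary
#' conventions cannot flip test outcomes.  The returned oracles (contact
#' profile, electrostatic energy) are computed by naive double loops that are
#' independent of the production code.
#'
#' @param spec a [fixture_spec()].
#' @return List with `complex` (a [molecular_complex()]), `profile`
#'   (brute-force `contact_profile` at 10.5 A), and `e_elec` (closed-form
#'   brute-force energy at the default [elec_params()], `NA` when charges are
#'   disabled).
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_ligand_atoms < 1L) stop("need at least one ligand atom")
  if (spec$n_receptor_atoms < 1L) stop("need at least one receptor atom")
  if (spec$n_ligand_atoms > max(1, floor((0.4 * spec$pocket_radius)^3)))
    stop("infeasible geometry: too many ligand atoms for pocket radius")
  if (spec$n_receptor_atoms > floor(4 * pi * spec$pocket_radius^2))
    stop("infeasible geometry: too many receptor atoms for shell radius")

  out <- .with_seed(spec$seed, {
    nr <- spec$n_receptor_atoms; nl <- spec$n_ligand_atoms
    dirs <- matrix(stats::rnorm(3 * nr), nr, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    rx <- dirs * stats::runif(nr, spec$pocket_radius, spec$pocket_radius + 4)
    lx <- matrix(stats::runif(3 * nl, -1, 1), nl, 3)
    lx <- lx / pmax(1, sqrt(rowSums(lx^2))) * (0.35 * spec$pocket_radius)
    # nudge ligand atoms off protected cutoff boundaries
    for (iter in seq_len(100L)) {
      d <- sqrt(outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * tcrossprod(rx, lx))
      bad <- rep(FALSE, nl)
      for (rc in .PROTECTED_CUTOFFS)
        bad <- bad | apply(abs(d - rc) < 1e-3, 2L, any)
      if (!any(bad)) break
      lx[bad, ] <- lx[bad, , drop = FALSE] +
        matrix(stats::rnorm(3 * sum(bad), 0, 0.01), sum(bad), 3)
    }
    els_r <- sample(names(spec$element_frequencies), nr, replace = TRUE,
                    prob = spec$element_frequencies)
    els_l <- sample(names(spec$element_frequencies), nl, replace = TRUE,
                    prob = spec$element_frequencies)
    has_q <- spec$charge_range > 0
    q_r <- if (has_q) round(stats::runif(nr, -spec$charge_range, spec$charge_range), 4) else NA_real_
    q_l <- if (has_q) round(stats::runif(nl, -spec$charge_range, spec$charge_range), 4) else NA_real_
    list(rx = round(rx, 3), lx = round(lx, 3), els_r = els_r, els_l = els_l,
         q_r = q_r, q_l = q_l)
  })

  receptor <- data.frame(
    serial = seq_len(spec$n_receptor_atoms),
    name = paste0(out$els_r, seq_len(spec$n_receptor_atoms)),
    element = out$els_r, resname = "GLY",
    resno = seq_len(spec$n_receptor_atoms), insert = "", chain = "A",
    x = out$rx[, 1], y = out$rx[, 2], z = out$rx[, 3],
    charge = out$q_r, kind = "ATOM", stringsAsFactors = FALSE)
  ligand <- data.frame(
    serial = spec$n_receptor_atoms + seq_len(spec$n_ligand_atoms),
    name = paste0(out$els_l, seq_len(spec$n_ligand_atoms)),
    element = out$els_l, resname = "LIG",
    resno = 900L, insert = "", chain = "B",
    x = out$lx[, 1], y = out$lx[, 2], z = out$lx[, 3],
    charge = out$q_l, kind = "HETATM", stringsAsFactors = FALSE)
  cx <- molecular_complex(receptor, ligand,
                          label = paste0("toy-seed", spec$seed))
  list(complex = cx,
       profile = .naive_contact_profile(cx, cutoff = 10.5),
       e_elec = if (spec$charge_range > 0) .naive_e_elec(cx) else NA_real_)
}

# --- naive oracles (independent of the production modules) -----------------

.naive_class <- function(el) {
  el <- toupper(el)
  if (el %in% c("C", "N", "O")) el else "X"
}

.naive_contact_profile <- function(complex, cutoff = 10.5) {
  counts <- stats::setNames(integer(10),
    c("CC", "CN", "CO", "CX", "NN", "NO", "NX", "OO", "OX", "XX"))
  for (i in seq_len(nrow(complex$receptor))) {
    for (j in seq_len(nrow(complex$ligand))) {
      a <- complex$receptor[i, ]; b <- complex$ligand[j, ]
      d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      if (d <= cutoff) {
        cls <- sort(c(.naive_class(a$element), .naive_class(b$element)))
        key <- paste0(cls[1], cls[2])
        counts[key] <- counts[key] + 1L
      }
    }
  }
  structure(list(counts = counts, cutoff = cutoff,
                 n_receptor_atoms = nrow(complex$receptor),
                 n_ligand_atoms = nrow(complex$ligand)),
            class = "contact_profile")
}

.naive_e_elec <- function(complex, dielectric = 10, cutoff = 8.5,
                          k = 332.0636) {
  e <- 0
  for (i in seq_len(nrow(complex$receptor))) {
    for (j in seq_len(nrow(complex$ligand))) {
      a <- complex$receptor[i, ]; b <- complex$ligand[j, ]
      r <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      if (r <= cutoff && r > 0)
        e <- e + k * a$charge * b$charge / (dielectric * r) *
          (1 - (r / cutoff)^2)^2
    }
  }
  e
}

#' Generate a synthetic affinity training table
#'
#' Feature columns emulate the statistical structure of contact features for
#' drug-sized ligands at the 10.5 A cutoff: carbon-carbon contacts are by far
#' the most numerous, heteroatom pairs are rare, and the electrostatic energy
#' is negative-skewed.  The target is the true model applied to the features
#' plus Gaussian noise.
#'
#' @param n number of complexes (>= 10).
#' @param true_model generating [affinity_model()]; default the shipped model.
#' @param noise_sd Gaussian noise standard deviation in kcal/mol.
#' @param seed integer seed.
#' @return List with `table` (a [training_table()] whose features are
#'   `e_elec` plus the ten contact-pair counts) and `true_model`.
#' @export
make_training_table <- function(n = 200, true_model = default_affinity_model(),
                                noise_sd = 1.5, seed = 1) {
  if (n < 10) stop("need n >= 10")
  df <- .with_seed(seed, {
    feats <- data.frame(
      e_elec = -stats::rgamma(n, shape = 4, scale = 7),
      ac_cc = pmax(0, round(stats::rnorm(n, 430, 60))),
      ac_cn = stats::rpois(n, 60),
      ac_co = stats::rpois(n, 80),
      ac_cx = stats::rpois(n, 25),
      ac_nn = stats::rpois(n, 12),
      ac_no = stats::rpois(n, 10),
      ac_nx = stats::rpois(n, 5),
      ac_oo = stats::rpois(n, 20),
      ac_ox = stats::rpois(n, 7),
      ac_xx = stats::rpois(n, 8))
    mu <- dg_score(as.matrix(feats[, true_model$feature_order, drop = FALSE]),
                   true_model)
    feats$dg <- mu + stats::rnorm(n, 0, noise_sd)
    feats
  })
  df <- cbind(complex_id = sprintf("cx%04d", seq_len(n)), df,
              stringsAsFactors = FALSE)
  list(table = training_table(df), true_model = true_model)
}

#' Generate a set of random tree-structured toy molecules
#'
#' Each molecule is a random heavy-atom tree (elements C/N/O/S, bond orders
#' 1 or 2) written as a valid MOL V2000 record.  Brute-force oracles —
#' fingerprints from Floyd-Warshall all-pairs shortest paths and the naive
#' Tanimoto kernel — are returned alongside.
#'
#' @param k number of molecules (>= 2).
#' @param seed integer seed.
#' @param n_atoms inclusive range of heavy-atom counts per molecule.
#' @return List with `sdf` (character vector of SD-file lines), `graphs`
#'   (list of [molecule_graph()]), `fingerprints` (brute-force oracle) and
#'   `kernel` (brute-force Tanimoto matrix).
#' @export
make_molecule_set <- function(k, seed = 1, n_atoms = c(5L, 12L)) {
  if (k < 2) stop("need at least 2 molecules")
  raw <- .with_seed(seed, lapply(seq_len(k), function(m) {
    n <- sample(seq(n_atoms[1], n_atoms[2]), 1L)
    elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                       prob = c(0.6, 0.2, 0.15, 0.05))
    bonds <- if (n > 1) data.frame(
      i = vapply(2:n, function(a) sample.int(a - 1L, 1L), integer(1L)),
      j = 2:n,
      order = sample(c(1L, 2L), n - 1L, replace = TRUE, prob = c(0.8, 0.2)))
    else data.frame(i = integer(0), j = integer(0), order = integer(0))
    coords <- matrix(round(stats::runif(3 * n, -5, 5), 4), n, 3)
    list(id = sprintf("tree%02d", m), elements = elements, bonds = bonds,
         coords = coords)
  }))
  sdf <- unlist(lapply(raw, function(m)
    .write_v2000(m$id, m$elements, m$coords, m$bonds)))
  graphs <- lapply(raw, function(m)
    molecule_graph(m$elements, m$bonds, id = m$id))
  fps <- lapply(raw, function(m) .naive_ap(m$elements, m$bonds))
  names(fps) <- vapply(raw, `[[`, character(1L), "id")
  kern <- diag(1, k)
  dimnames(kern) <- list(names(fps), names(fps))
  if (k > 1) for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    kern[i, j] <- kern[j, i] <- .naive_tanimoto(fps[[i]], fps[[j]])
  list(sdf = sdf, graphs = graphs, fingerprints = fps, kernel = kern)
}

.write_v2000 <- function(id, elements, coords, bonds) {
  c(id,
    "  ligaff-fixture",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(elements), nrow(bonds)),
    vapply(seq_along(elements), function(a) sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[a, 1], coords[a, 2], coords[a, 3], elements[a]), character(1L)),
    if (nrow(bonds) > 0)
      vapply(seq_len(nrow(bonds)), function(b) sprintf(
        "%3d%3d%3d  0", bonds$i[b], bonds$j[b], bonds$order[b]), character(1L)),
    "M  END",
    "$$$$")
}

# naive atom-pair fingerprint: Floyd-Warshall all-pairs shortest paths over
# the heavy-atom graph, types recomputed from scratch
.naive_ap <- function(elements, bonds) {
  elements <- toupper(elements)
  heavy <- which(elements != "H")
  n_all <- length(elements)
  pi_add <- c(`1` = 0, `2` = 1, `3` = 2, `4` = 1)
  npi <- integer(n_all); nh <- integer(n_all)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    npi[i] <- npi[i] + pi_add[[as.character(bonds$order[b])]]
    npi[j] <- npi[j] + pi_add[[as.character(bonds$order[b])]]
    if (elements[j] != "H") nh[i] <- nh[i] + 1L
    if (elements[i] != "H") nh[j] <- nh[j] + 1L
  }
  n <- length(heavy)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (b in seq_len(nrow(bonds))) {
    i <- match(bonds$i[b], heavy); j <- match(bonds$j[b], heavy)
    if (!is.na(i) && !is.na(j)) D[i, j] <- D[j, i] <- 1
  }
  for (via in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, via] + D[via, j] < D[i, j]) D[i, j] <- D[i, via] + D[via, j]
  types <- paste(elements[heavy], nh[heavy], npi[heavy], sep = ".")
  keys <- character(0)
  if (n >= 2) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (is.finite(D[i, j]))
      keys <- c(keys, paste(min(types[i], types[j]),
                            max(types[i], types[j]), D[i, j], sep = "|"))
  }
  tab <- table(keys)
  structure(stats::setNames(as.integer(tab), names(tab)),
            n_heavy = n, class = "ap_fingerprint")
}

.naive_tanimoto <- function(a, b) {
  keys <- union(names(a), names(b))
  if (length(keys) == 0L) return(0)
  num <- 0; den <- 0
  for (k in keys) {
    av <- if (k %in% names(a)) a[[k]] else 0L
    bv <- if (k %in% names(b)) b[[k]] else 0L
    num <- num + min(av, bv)
    den <- den + max(av, bv)
  }
  num / den
}
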