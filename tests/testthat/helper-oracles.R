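# Independent oracles and small in-code fixtures shared across the suite.
# These deliberately use naive algorithms (double loops, repeated-min sorts)
# kept apart from the package's production code paths.

# tau-b by explicit O(n^2) pair counting with tie correction
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# ranking by repeated minimum extraction (ties: lexicographic id)
brute_rank <- function(ids, scores) {
  out <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining) > 0) {
    sc <- scores[remaining]
    cand <- remaining[sc == min(sc)]
    pick <- cand[which(ids[cand] == min(ids[cand]))[1]]
    out <- c(out, ids[pick])
    remaining <- setdiff(remaining, pick)
  }
  out
}

# PPV by explicit top-N set intersections
brute_ppv <- function(pred, exp) {
  n <- length(pred)
  vapply(seq_len(n), function(N)
    length(intersect(pred[seq_len(N)], exp[seq_len(N)])) / N, numeric(1))
}

with_seed_rnorm <- function(seed, n, sd = 1) {
  withr::with_seed(seed, rnorm(n, sd = sd))
}

with_seed_perm <- function(seed, n) {
  withr::with_seed(seed, sample.int(n))
}

# a bare atom table row
atom_row <- function(serial, name, element, resname = "ALA", resno = 1,
                     chain = "A", x = 0, y = 0, z = 0, charge = NA_real_,
                     kind = "ATOM", insert = "") {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, insert = insert, chain = chain,
             x = x, y = y, z = z, charge = charge, kind = kind,
             stringsAsFactors = FALSE)
}

# two-atom complex at a given separation along x
two_atom_complex <- function(d, el_r = "C", el_l = "C",
                             q_r = NA_real_, q_l = NA_real_) {
  molecular_complex(
    atom_row(1, paste0(el_r, "1"), el_r, charge = q_r),
    atom_row(2, paste0(el_l, "1"), el_l, resname = "LIG", resno = 9,
             chain = "B", x = d, charge = q_l, kind = "HETATM"))
}

# receptor with nres residues carrying N/CA/C/O backbone atoms at random
# positions, plus a 5-heavy-atom ligand; used by the l-RMSD tests
backbone_complex <- function(nres = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  serial <- 0
  for (r in seq_len(nres)) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1
      el <- if (nm == "N") "N" else if (nm == "O") "O" else "C"
      rows[[serial]] <- atom_row(serial, nm, el, resname = "GLY", resno = r,
                                 x = rnorm(1, 3 * r, 1), y = rnorm(1),
                                 z = rnorm(1))
    }
  }
  receptor <- do.call(rbind, rows)
  lig <- do.call(rbind, lapply(1:5, function(i)
    atom_row(serial + i, paste0("C", i), "C", resname = "LIG", resno = 900,
             chain = "B", x = rnorm(1, 5), y = rnorm(1, 5), z = rnorm(1, 5),
             kind = "HETATM")))
  molecular_complex(receptor, lig)
}

# apply a rigid rotation + translation to every atom of a complex
transform_complex <- function(cx, angle = 0.7, axis = c(0, 0, 1),
                              shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  for (part in c("receptor", "ligand")) {
    xyz <- as.matrix(cx[[part]][, c("x", "y", "z")])
    xyz <- xyz %*% t(R) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
    cx[[part]]$x <- xyz[, 1]; cx[[part]]$y <- xyz[, 2]; cx[[part]]$z <- xyz[, 3]
  }
  cx
}
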