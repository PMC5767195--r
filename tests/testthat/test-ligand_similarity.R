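# hand-built V2000 records used across several tests
sdf_record <- function(id, elements, bonds, coords = NULL) {
  n <- length(elements)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  c(id, "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)),
    vapply(seq_len(n), function(a) sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[a, 1], coords[a, 2], coords[a, 3], elements[a]), character(1)),
    if (nrow(bonds) > 0) vapply(seq_len(nrow(bonds)), function(b) sprintf(
      "%3d%3d%3d  0", bonds$i[b], bonds$j[b], bonds$order[b]), character(1)),
    "M  END", "$$$$")
}

write_sdf_records <- function(...) {
  f <- withr::local_tempfile(fileext = ".sdf", .local_envir = parent.frame())
  writeLines(unlist(list(...)), f)
  f
}

ethane_bonds <- data.frame(i = 1, j = 2, order = 1)
propane_bonds <- data.frame(i = c(1, 2), j = c(2, 3), order = 1)
butane_bonds <- data.frame(i = 1:3, j = 2:4, order = 1)

test_that("SD records parse into heavy-atom graphs", {
  f <- write_sdf_records(sdf_record("ethane", c("C", "C"), ethane_bonds))
  gs <- read_sdf(f)
  expect_length(gs, 1)
  expect_equal(gs[[1]]$id, "ethane")
  expect_equal(nrow(gs[[1]]$atoms), 2)
  expect_equal(nrow(gs[[1]]$bonds), 1)
})

test_that("aromatic bonds give every benzene carbon pi electrons", {
  benz <- sdf_record("benzene", rep("C", 6),
                     data.frame(i = 1:6, j = c(2:6, 1), order = 4))
  gs <- read_sdf(write_sdf_records(benz))
  expect_true(all(gs[[1]]$atoms$n_pi > 0))
  expect_true(all(gs[[1]]$atoms$n_heavy == 2))
})

test_that("explicit hydrogens are suppressed without changing heavy counts", {
  # methanol with explicit hydroxyl hydrogen: C-O-H
  rec <- sdf_record("methanol", c("C", "O", "H"),
                    data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  g <- read_sdf(write_sdf_records(rec))[[1]]
  expect_equal(g$atoms$element, c("C", "O"))
  expect_equal(g$atoms$n_heavy, c(1, 1))  # H does not count as heavy
  expect_equal(nrow(g$bonds), 1)
})

test_that("generated molecule sets round-trip through SD text", {
  ms <- make_molecule_set(5, seed = 3)
  f <- write_sdf_records(ms$sdf)
  gs <- read_sdf(f)
  expect_length(gs, 5)
  expect_equal(vapply(gs, function(g) g$id, character(1)),
               vapply(ms$graphs, function(g) g$id, character(1)))
  for (i in 1:5) {
    expect_equal(gs[[i]]$atoms, ms$graphs[[i]]$atoms)
    expect_equal(gs[[i]]$bonds$i, ms$graphs[[i]]$bonds$i)
    expect_equal(gs[[i]]$bonds$j, ms$graphs[[i]]$bonds$j)
  }
})

test_that("malformed counts lines fail with the record index", {
  lines <- c(sdf_record("ok", c("C", "C"), ethane_bonds),
             c("broken", "", "", "garbage counts", "M  END", "$$$$"))
  f <- write_sdf_records(lines)
  expect_error(read_sdf(f), "record 2")
})

test_that("atom pairs enumerate hand-checked alkanes", {
  eth <- molecule_graph(c("C", "C"), ethane_bonds, id = "ethane")
  fp <- atom_pair_fingerprint(eth)
  expect_equal(length(fp), 1L)
  expect_equal(names(fp), "C.1.0|C.1.0|1")
  expect_equal(unname(fp[1]), 1L)

  pro <- molecule_graph(c("C", "C", "C"), propane_bonds, id = "propane")
  fpp <- atom_pair_fingerprint(pro)
  # 3 pairs: two (terminal, central, d=1), one (terminal, terminal, d=2)
  expect_equal(sum(fpp), 3L)
  expect_equal(unname(fpp["C.1.0|C.2.0|1"]), 2L)
  expect_equal(unname(fpp["C.1.0|C.1.0|2"]), 1L)
})

test_that("total pairs equal n(n-1)/2 for connected molecules", {
  ms <- make_molecule_set(6, seed = 8)
  for (g in ms$graphs) {
    n <- nrow(g$atoms)
    expect_equal(sum(atom_pair_fingerprint(g)), n * (n - 1) / 2)
  }
})

test_that("fingerprints match the Floyd-Warshall oracle on random trees", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 30
    elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    bonds <- data.frame(
      i = vapply(2:n, function(a) sample.int(a - 1, 1), integer(1)),
      j = 2:n,
      order = sample(c(1L, 2L), n - 1, replace = TRUE))
    g <- molecule_graph(elements, bonds, id = "tree")
    got <- atom_pair_fingerprint(g)
    want <- ligaff:::.naive_ap(elements, bonds)
    expect_identical(got[sort(names(got))],
                     unclass(want)[sort(names(want))],
                     ignore_attr = TRUE)
    expect_equal(sort(names(got)), sort(names(want)))
  }
})

test_that("fingerprints are invariant under atom reordering", {
  ms <- make_molecule_set(3, seed = 12)
  g <- ms$graphs[[1]]
  n <- nrow(g$atoms)
  perm <- with_seed_perm(4, n)
  inv <- match(seq_len(n), perm)
  g2 <- molecule_graph(g$atoms$element[perm],
                       data.frame(i = inv[g$bonds$i], j = inv[g$bonds$j],
                                  order = g$bonds$order),
                       id = "permuted")
  f1 <- atom_pair_fingerprint(g)
  f2 <- atom_pair_fingerprint(g2)
  expect_identical(f1[sort(names(f1))], f2[sort(names(f2))],
                   ignore_attr = TRUE)
  expect_equal(sort(names(f1)), sort(names(f2)))
})

test_that("single-atom and disconnected molecules warn", {
  single <- molecule_graph("C", data.frame(i = integer(0), j = integer(0),
                                           order = integer(0)), id = "c1")
  expect_warning(fp <- atom_pair_fingerprint(single), "fewer than 2")
  expect_length(fp, 0)
  disc <- molecule_graph(c("C", "C", "C", "C"),
                         data.frame(i = c(1, 3), j = c(2, 4), order = 1),
                         id = "dimer")
  expect_warning(fpd <- atom_pair_fingerprint(disc), "disconnected")
  expect_equal(sum(fpd), 2L)  # only within-component pairs
})

test_that("Tanimoto similarity matches hand-computed multiset ratios", {
  eth <- atom_pair_fingerprint(molecule_graph(c("C", "C"), ethane_bonds))
  pro <- atom_pair_fingerprint(molecule_graph(c("C", "C", "C"), propane_bonds))
  but <- atom_pair_fingerprint(molecule_graph(rep("C", 4), butane_bonds))
  expect_equal(tanimoto(eth, eth), 1)
  # ethane's only descriptor (terminal-terminal at d=1) never occurs in
  # propane, so the sets are disjoint
  expect_equal(tanimoto(eth, pro), 0)
  # butane vs propane: shared 2x (terminal,central,1); union has 7 descriptors
  expect_equal(tanimoto(but, pro), 2 / 7)
  empty <- structure(setNames(integer(0), character(0)),
                     class = "ap_fingerprint")
  expect_warning(z <- tanimoto(empty, empty), "empty")
  expect_equal(z, 0)
})

test_that("similarity kernels are symmetric with unit diagonal and match the oracle", {
  ms <- make_molecule_set(10, seed = 5)
  K <- similarity_matrix(ms$graphs)
  expect_equal(diag(K), setNames(rep(1, 10), rownames(K)))
  expect_identical(K, t(K))
  expect_true(all(K >= 0 & K <= 1))
  expect_equal(K, ms$kernel, tolerance = 1e-12)
})

test_that("the most similar reference is the argmax with first-wins ties", {
  ms <- make_molecule_set(10, seed = 6)
  refs <- ms$graphs[1:9]
  expect_equal(most_similar_reference(ms$graphs[[4]], refs), "tree04")
  # a query disjoint from every reference warns and returns the first
  lone <- molecule_graph(c("P", "P"), data.frame(i = 1, j = 2, order = 3),
                         id = "odd")
  expect_warning(pick <- most_similar_reference(lone, refs), "no descriptors")
  expect_equal(pick, "tree01")
  expect_error(most_similar_reference(lone, list()), "no reference")
})

test_that("kernel SVR interpolates training points at large C", {
  ms <- make_molecule_set(15, seed = 9)
  y <- with_seed_rnorm(2, 15)
  m <- fit_ap_svr(ms$kernel, y, C = 1000, epsilon = 0.01)
  pred <- predict(m, ms$kernel)
  expect_true(all(abs(pred - y) <= 0.01 + 0.05))
})

test_that("an uninformative kernel collapses predictions to a constant", {
  K <- diag(1, 12)
  dimnames(K) <- list(paste0("m", 1:12), paste0("m", 1:12))
  y <- with_seed_rnorm(3, 12)
  m <- fit_ap_svr(K, y, C = 1, epsilon = 0.1)
  # unseen queries share nothing with any training molecule
  pred <- predict(m, matrix(0, 4, 12))
  expect_lt(diff(range(pred)), 1e-8)
})

test_that("SVR recovers a similarity-driven target on held-out molecules", {
  # a graded family (alkane chains of increasing length) so that fingerprint
  # similarity actually carries information about the target
  chain <- function(n, id) molecule_graph(
    rep("C", n), data.frame(i = seq_len(n - 1), j = 2:n, order = 1), id = id)
  mols <- lapply(4:33, function(n) chain(n, sprintf("chain%02d", n)))
  K <- similarity_matrix(mols)
  y <- 0.5 * (4:33) + with_seed_rnorm(7, 30, sd = 0.3)
  train <- which((1:30) %% 2 == 0); test <- which((1:30) %% 2 == 1)
  m <- fit_ap_svr(K[train, train], y[train], C = 10, epsilon = 0.01)
  pred <- predict(m, K[test, train])
  expect_gt(cor(pred, y[test]), 0.9)
})

test_that("SVR rejects malformed inputs", {
  K <- diag(1, 5)
  expect_error(fit_ap_svr(K, 1:4), "match")
  expect_error(fit_ap_svr(K, c(1, 2, 3, 4, NA)), "finite")
  m <- fit_ap_svr(K, rnorm(5))
  expect_error(predict(m, matrix(0, 2, 4)), "column")
})
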