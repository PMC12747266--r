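# Featurization: vocabulary contracts, graph features against frozen
# per-atom/per-bond oracle values, descriptor and fingerprint behaviour,
# and normalizer algebra.

test_that("vocabulary is the labelled Cartesian product plus unknown bucket", {
  v <- build_atom_vocab(c("C", "N"), c("SP2", "SP3"))
  expect_equal(v$size, 5L)
  expect_equal(v$unknown_index, 5L)
  i1 <- vocab_lookup(v, "C", "SP3")
  expect_identical(i1, vocab_lookup(v, "C", "SP3"))
  expect_true(i1 >= 1 && i1 <= 4)
  # out-of-vocabulary element or hybridization hits the unknown bucket
  expect_equal(vocab_lookup(v, "Xx", "SP"), v$unknown_index)
  expect_equal(vocab_lookup(build_atom_vocab(), "Xx", "SP"),
               build_atom_vocab()$unknown_index)
  # unrecognised hybridization labels fold into OTHER, not unknown
  vd <- build_atom_vocab()
  expect_equal(vocab_lookup(vd, "C", "UNSPECIFIED"),
               vocab_lookup(vd, "C", "OTHER"))
  expect_error(build_atom_vocab(c("C", "C"), "SP3"), "duplicate")
  expect_error(build_atom_vocab(character(0), "SP3"), "non-empty")
})

test_that("ethanol graph matches the per-atom/per-bond oracle", {
  g <- smiles_to_graph("CCO")
  expect_equal(g$n_nodes, 3L)
  expect_equal(ncol(g$edge_index), 4L)  # 2 bonds x 2 directions
  expect_equal(ncol(g$node_features), 11L)
  expect_equal(ncol(g$edge_features), 5L)
  # frozen oracle values (atomic number, degree, charge, H, aromatic, ring,
  # R, S, smallest ring, valence)
  expect_equal(unname(g$node_features[, -1]), rbind(
    c(6, 1, 0, 3, 0, 0, 0, 0, 0, 4),
    c(6, 2, 0, 2, 0, 0, 0, 0, 0, 4),
    c(8, 1, 0, 1, 0, 0, 0, 0, 0, 2)
  ))
  v <- build_atom_vocab()
  expect_equal(g$node_vocab_ids, unname(vocab_lookup(v, c("C", "C", "O"), "SP3")))
  expect_true(all(g$edge_features[, "bond_type"] == 1))
  expect_equal(g$mol_size, 20L)
})

test_that("benzene and pyridine graphs match the oracle", {
  b <- smiles_to_graph("c1ccccc1")
  expect_equal(b$n_nodes, 6L)
  expect_equal(ncol(b$edge_index), 12L)
  expect_true(all(b$node_features[, "aromatic"] == 1))
  expect_true(all(b$node_features[, "in_ring"] == 1))
  expect_true(all(b$node_features[, "smallest_ring"] == 6))
  expect_true(all(b$node_features[, "total_valence"] == 4))
  v <- build_atom_vocab()
  expect_true(all(b$node_vocab_ids == vocab_lookup(v, "C", "SP2")))
  expect_true(all(b$edge_features[, "bond_type"] == 4))  # aromatic code
  expect_true(all(b$edge_features[, "aromatic"] == 1))
  expect_true(all(b$edge_features[, "conjugated"] == 1))
  expect_equal(b$mol_size, 36L)

  p <- smiles_to_graph("c1ccncc1")
  n_row <- p$node_features[p$node_features[, "atomic_num"] == 7, ]
  expect_equal(unname(n_row[c("total_h", "total_valence", "aromatic", "smallest_ring")]),
               c(0, 3, 1, 6))
})

test_that("chirality flags follow CIP assignment and never overlap", {
  a <- smiles_to_graph("C[C@H](N)C(=O)O")  # L-alanine: S center
  chiral <- a$node_features[, "chiral_r"] + a$node_features[, "chiral_s"]
  expect_true(all(chiral <= 1))
  expect_equal(sum(a$node_features[, "chiral_s"]), 1)
  expect_equal(sum(a$node_features[, "chiral_r"]), 0)
  r <- smiles_to_graph("C[C@@H](N)C(=O)O")  # mirror image: R center
  expect_equal(sum(r$node_features[, "chiral_r"]), 1)
  # no stereocenters: both flags zero everywhere
  e <- smiles_to_graph("CCO")
  expect_true(all(e$node_features[, c("chiral_r", "chiral_s")] == 0))
})

test_that("methane is a single node with no edges", {
  m <- smiles_to_graph("C")
  expect_equal(m$n_nodes, 1L)
  expect_equal(ncol(m$edge_index), 0L)
  expect_equal(unname(m$node_features[1, c("degree", "total_h")]), c(0, 4))
  expect_equal(m$mol_size, 6L)
  expect_error(smiles_to_graph("C1CC"), "unparsable|failed")
})

test_that("every directed edge has its mirrored twin with identical features", {
  for (g in panel_graphs()) {
    E <- ncol(g$edge_index)
    if (E == 0) next
    key <- paste(g$edge_index[1, ], g$edge_index[2, ],
                 apply(g$edge_features, 1, paste, collapse = ","))
    rev_key <- paste(g$edge_index[2, ], g$edge_index[1, ],
                     apply(g$edge_features, 1, paste, collapse = ","))
    expect_setequal(key, rev_key)
  }
})

test_that("graph featurization is invariant to atom ordering", {
  pairs <- list(
    c("CCO", "OCC"),
    c("c1ccccc1C", "Cc1ccccc1"),
    c("C(=O)(O)c1ccccc1", "OC(=O)c1ccccc1"),
    c("n1ccccc1", "c1ccncc1")
  )
  for (p in pairs) {
    g1 <- smiles_to_graph(p[1])
    g2 <- smiles_to_graph(p[2])
    expect_equal(g1$n_nodes, g2$n_nodes)
    expect_equal(g1$mol_size, g2$mol_size)
    # equal multisets of node feature rows
    rows1 <- sort(apply(g1$node_features, 1, paste, collapse = ","))
    rows2 <- sort(apply(g2$node_features, 1, paste, collapse = ","))
    expect_identical(rows1, rows2)
    # equal multisets of (source row, target row, edge features) triples
    trip <- function(g) {
      nf <- apply(g$node_features, 1, paste, collapse = ",")
      sort(paste(nf[g$edge_index[1, ]], nf[g$edge_index[2, ]],
                 apply(g$edge_features, 1, paste, collapse = ",")))
    }
    expect_identical(trip(g1), trip(g2))
  }
})

test_that("molecular size sums heavy-atom atomic numbers", {
  expect_equal(molecular_size(c("CCO", "C", "c1ccccc1")), c(20L, 6L, 36L))
})

test_that("physchem descriptors carry 32 named values with expected anchors", {
  pc <- panel_physchem()
  expect_equal(ncol(pc), 32L)
  benz <- pc["c1ccccc1", ]
  expect_equal(unname(benz[c("ArR", "Rings", "HA", "FCsp3")]), c(1, 1, 6, 0))
  ethane <- compute_physchem("CC")[1, ]
  expect_equal(unname(ethane[c("FCsp3", "RotB")]), c(1, 0))
  methane <- compute_physchem("C")[1, ]
  expect_equal(unname(methane[c("FC", "Het")]), c(0, 0))
  expect_error(compute_physchem("C1CC"), "unparsable|failed")
})

test_that("all 32 descriptors match the independent toolkit oracle", {
  pc <- panel_physchem()
  oracle <- oracle_physchem(oracle_panel)
  expect_equal(dim(oracle), dim(pc))
  for (j in seq_len(ncol(pc))) {
    ok <- relative_match(pc[, j], oracle[, j], 6)
    expect_true(all(ok),
                info = sprintf("descriptor %s disagrees with oracle", colnames(pc)[j]))
  }
})

test_that("fingerprints are deterministic 512-bit vectors matching the oracle", {
  fp <- compute_fingerprint(oracle_panel)
  expect_equal(ncol(fp), 512L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp, compute_fingerprint(oracle_panel))
  expect_false(identical(fp["C1CCCCC1" == oracle_panel, ],
                         fp["c1ccccc1" == oracle_panel, ]))
  oracle <- oracle_fingerprint(oracle_panel)
  expect_equal(unname(fp), oracle)
})

test_that("combined descriptor vector is [fingerprint || physchem] of length 544", {
  d <- compute_descriptors(c("CCO", "c1ccccc1"))
  expect_equal(ncol(d), 544L)
  expect_equal(unname(d[, 1:512]), unname(compute_fingerprint(c("CCO", "c1ccccc1"))),
               ignore_attr = TRUE)
  expect_equal(unname(d[, 513:544]), unname(compute_physchem(c("CCO", "c1ccccc1"))))
})

test_that("normalizer follows z-score algebra with a zero-variance guard", {
  x <- rbind(c(0, 5, 1), c(2, 5, 3))
  norm <- fit_normalizer(x)
  expect_equal(unname(norm$means), c(1, 5, 2))
  expect_equal(unname(norm$stds), c(1, 0, 1))  # population std of {0,2} is 1
  z <- apply_normalizer(norm, x)
  expect_equal(unname(colMeans(z)), c(0, 0, 0))
  expect_equal(unname(z[, 1]), c(-1, 1))
  # constant dimension maps to 0 whatever the input
  z2 <- apply_normalizer(norm, c(1, 99, 2))
  expect_equal(unname(z2), c(0, 0, 0))
  # x = mean + std -> 1 on non-constant dims
  z3 <- apply_normalizer(norm, c(2, 5, 3))
  expect_equal(unname(z3[c(1, 3)]), c(1, 1))
  expect_error(fit_normalizer(x[1, , drop = FALSE]), "at least 2")
  expect_error(apply_normalizer(norm, c(1, 2)), "does not match")
})

test_that("featurize_dataset assembles graphs, descriptors and labels", {
  feats <- tiny_features()
  expect_s3_class(feats, "mol_features")
  expect_equal(ncol(feats$desc), 544L)
  expect_length(feats$graphs, 6L)
  expect_equal(feats$y[1], 2)
  # normalized training descriptors have mean 0 / sd 1 on varying columns
  varying <- feats$normalizer$stds > 0
  expect_lt(max(abs(colMeans(feats$desc[, varying]))), 1e-10)
  sds <- sqrt(colMeans(sweep(feats$desc[, varying], 2,
                             colMeans(feats$desc[, varying]))^2))
  expect_equal(range(sds), c(1, 1), tolerance = 1e-10)
})
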