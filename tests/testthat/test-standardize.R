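test_that("desalt keeps the largest fragment", {
  g <- desalt(pg("CCO"))
  expect_identical(attr(g, "removed_fragments"), 0L)
  expect_identical(canonical_key(g), canonical_key(pg("CCO")))

  g <- desalt(pg("CC(=O)[O-].[Na+]"))
  expect_identical(attr(g, "removed_fragments"), 1L)
  expect_identical(canonical_key(g), canonical_key(pg("CC(=O)[O-]")))

  g <- desalt(pg("CCO.Cl"))
  expect_identical(canonical_key(g), canonical_key(pg("CCO")))
})

test_that("desalt output is a single component with maximal heavy atoms", {
  cases <- c("CCO.Cl.Br", "c1ccccc1.CCN.[K+]", "CC.CCC.CCCC")
  for (smi in cases) {
    g0 <- pg(smi)
    comp <- graph_components(g0)
    max_heavy <- max(vapply(seq_len(max(comp)), function(ci)
      heavy_atom_count(molprep:::subgraph(g0, which(comp == ci))), numeric(1)))
    g <- desalt(g0)
    expect_identical(max(graph_components(g)), 1L, label = smi)
    expect_identical(heavy_atom_count(g), as.integer(max_heavy), label = smi)
  }
})

test_that("desalt ties break deterministically by weight then key", {
  # equal heavy atoms: CCO (46.07) vs CCN (45.08) -> heavier wins
  g <- desalt(pg("CCO.CCN"))
  expect_identical(canonical_key(g), canonical_key(pg("CCO")))
  # identical fragments: stable result either way
  g <- desalt(pg("CCO.CCO"))
  expect_identical(canonical_key(g), canonical_key(pg("CCO")))
  expect_error(desalt(structure(list(), class = "mol_graph")), "empty")
})
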