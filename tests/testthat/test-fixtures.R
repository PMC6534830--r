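test_that("the demonstration set has the advertised structures", {
  recs <- example_molecules()
  expect_length(recs, 7)
  ids <- vapply(recs, `[[`, character(1), "identifier")
  by_id <- setNames(recs, ids)
  expect_identical(molecular_formula(by_id[["butan-2-one"]]$graph), "C4H8O")
  g <- by_id[["bromochlorofluoroiodomethane"]]$graph
  centers <- potential_stereocenters(g)
  expect_length(centers, 1)
  expect_identical(g$atoms$parity[centers], 0L)  # unspecified
  expect_identical(molecular_formula(by_id[["oseltamivir-carboxylate"]]$graph),
                   "C14H24N2O4")
  expect_identical(molecular_formula(by_id[["folic-acid"]]$graph), "C19H19N7O6")
  expect_identical(count_aromatic_rings(by_id[["folic-acid"]]$graph), 3L)
  expect_identical(count_aromatic_rings(by_id[["cis-1,4-di-tert-butylcyclohexane"]]$graph), 0L)
  # all parse and none failed
  expect_true(all(!vapply(recs, `[[`, logical(1), "failed")))
})

test_that("synthetic library meets feature fractions exactly and is deterministic", {
  lib <- synthetic_library(100, seed = 9, frac_salt = 0.3)
  expect_length(lib, 100)
  n_salt <- sum(vapply(lib, function(r) max(graph_components(r$graph)) > 1, logical(1)))
  expect_identical(n_salt, 30L)
  # every SMILES parses
  expect_true(all(vapply(lib, function(r) inherits(r$graph, "mol_graph"), logical(1))))
  # determinism
  lib2 <- synthetic_library(100, seed = 9, frac_salt = 0.3)
  expect_identical(vapply(lib, `[[`, character(1), "smiles"),
                   vapply(lib2, `[[`, character(1), "smiles"))
  lib3 <- synthetic_library(100, seed = 10, frac_salt = 0.3)
  expect_false(identical(vapply(lib, `[[`, character(1), "smiles"),
                         vapply(lib3, `[[`, character(1), "smiles")))
})

test_that("requested feature mixes are constructed, not sampled", {
  lib <- synthetic_library(50, seed = 1, frac_ionizable = 0.4, frac_stereo = 0.2,
                           frac_ring = 0.2, frac_salt = 0)
  n_ring <- sum(vapply(lib, function(r)
    length(extract_nonaromatic_rings(r$graph)) > 0, logical(1)))
  expect_gte(n_ring, 10L)  # ring scaffolds (aromatic phenol counts as ionizable)
  n_ion <- sum(vapply(lib, function(r)
    length(molprep:::find_ionizable_sites(r$graph)) > 0, logical(1)))
  expect_gte(n_ion, 20L)
})
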