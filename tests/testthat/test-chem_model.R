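test_that("net_formal_charge sums atomic charges", {
  expect_identical(net_formal_charge(pg("CCO")), 0L)
  expect_identical(net_formal_charge(pg("CC(=O)[O-]")), -1L)
  # dianion: expected value by direct count over the constructed atoms
  g <- pg("[O-]CC[O-]")
  expect_identical(sum(g$atoms$charge), -2L)
  expect_identical(net_formal_charge(g), -2L)
  expect_identical(net_formal_charge(pg("[NH3+]CC(=O)[O-]")), 0L)
})

test_that("canonical_key is equal up to atom renumbering, distinct otherwise", {
  expect_identical(canonical_key(pg("OCC")), canonical_key(pg("CCO")))
  # stereo is part of identity
  expect_false(canonical_key(pg("F[C@H](Cl)Br")) == canonical_key(pg("F[C@@H](Cl)Br")))
  # connectivity is part of identity (keto vs enol of butan-2-one)
  expect_false(canonical_key(pg("CCC(C)=O")) == canonical_key(pg("CC=C(C)O")))
  # charge and H count are part of identity
  expect_false(canonical_key(pg("CC(=O)O")) == canonical_key(pg("CC(=O)[O-]")))
  # Kekule structure choice is not part of identity
  expect_identical(canonical_key(pg("Fc1ccccc1F")), canonical_key(pg("FC1=C(F)C=CC=C1")))
})

test_that("canonical_key is invariant under random atom permutations", {
  cases <- c("CCO", "c1ccc2ccccc2c1", "N[C@@H](C)C(=O)O", "F/C=C/F",
             "CC(C)(C)[C@H]1CC[C@@H](C(C)(C)C)CC1",
             "O=c1cccc[nH]1", "CC(=O)[O-]")
  set.seed(42)
  for (smi in cases) {
    g <- pg(smi)
    k0 <- canonical_key(g)
    for (rep in 1:5) {
      perm <- sample(n_atoms(g))
      expect_identical(canonical_key(molprep:::subgraph(g, perm)), k0,
                       label = sprintf("%s perm %d", smi, rep))
    }
  }
})

test_that("aromatic ring and chiral center counts match hand counts", {
  expect_identical(count_aromatic_rings(pg("c1ccccc1")), 1L)
  expect_identical(count_chiral_centers(pg("c1ccccc1")), 0L)
  expect_identical(count_aromatic_rings(pg("FC(Cl)(Br)I")), 0L)
  expect_identical(count_chiral_centers(pg("FC(Cl)(Br)I")), 1L)
  # naphthalene: SSSR has two six-membered rings, both aromatic
  expect_identical(count_aromatic_rings(pg("c1ccc2ccccc2c1")), 2L)
  # assigned and assignable centers both count
  expect_identical(count_chiral_centers(pg("N[C@@H](C)C(=O)O")), 1L)
  expect_identical(count_chiral_centers(pg("NC(C)C(=O)O")), 1L)
})

test_that("graphs expose consistent formulas, weights and components", {
  g <- pg("CCO.Cl")
  expect_identical(max(graph_components(g)), 2L)
  expect_identical(molecular_formula(pg("CCC(C)=O")), "C4H8O")
  expect_identical(molecular_formula(pg("Nc1nc2ncc(CNc3ccc(C(=O)N[C@@H](CCC(=O)O)C(=O)O)cc3)nc2c(=O)[nH]1")),
                   "C19H19N7O6")
  expect_equal(mol_weight(pg("CCO")), 46.07, tolerance = 1e-3)
  expect_identical(heavy_atom_count(pg("CCO")), 3L)
})

test_that("parser rejects malformed SMILES and bad valences", {
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(C"), "parenthesis")
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
})

test_that("SMILES round trip preserves identity including stereo", {
  cases <- c("CCO", "c1ccc2ccccc2c1", "N[C@@H](C)C(=O)O", "F/C=C/F",
             "F/C=C\\F", "Cl/C(F)=C(/Br)I", "O=c1cccc[nH]1",
             "O[C@@H]([C@@H](O)C(O)=O)C(O)=O", "[NH3+]CC(=O)[O-]")
  for (smi in cases) {
    g <- pg(smi)
    g2 <- pg(write_smiles(g))
    expect_identical(canonical_key(g2), canonical_key(g), label = smi)
  }
})
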