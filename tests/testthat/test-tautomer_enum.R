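test_that("benzene has no tautomers; the input is always included", {
  tl <- enumerate_tautomers(pg("c1ccccc1"))
  expect_length(tl, 1)
  expect_identical(canonical_key(tl[[1]]), canonical_key(pg("c1ccccc1")))
})

test_that("butan-2-one enumerates keto and enol forms", {
  tl <- enumerate_tautomers(pg("CCC(C)=O"))
  keys <- vapply(tl, canonical_key, character(1))
  expect_true(canonical_key(pg("CCC(C)=O")) %in% keys)       # keto
  expect_true(canonical_key(pg("CC=C(C)O")) %in% keys)       # but-2-en-2-ol
})

test_that("2-pyridone enumerates 2-hydroxypyridine and survives filtering", {
  parent <- pg("O=c1cccc[nH]1")
  tl <- enumerate_tautomers(parent)
  keys <- vapply(tl, canonical_key, character(1))
  expect_true(canonical_key(pg("Oc1ccccn1")) %in% keys)
  kept <- filter_tautomers(tl, parent)
  kept_keys <- vapply(kept, function(v) canonical_key(v$graph), character(1))
  expect_setequal(kept_keys, c(canonical_key(parent), canonical_key(pg("Oc1ccccn1"))))
})

test_that("filters reject the blacklist and count-changing forms", {
  # terminal-alkene enol of butan-2-one
  parent <- pg("CCC(C)=O")
  kept <- filter_tautomers(enumerate_tautomers(parent), parent)
  kept_keys <- vapply(kept, function(v) canonical_key(v$graph), character(1))
  expect_false(canonical_key(pg("C=C(O)CC")) %in% kept_keys)
  expect_true(canonical_key(pg("CC=C(C)O")) %in% kept_keys)

  # geminal vinyl diol tautomer of acetic acid
  parent <- pg("CC(=O)O")
  kept <- filter_tautomers(enumerate_tautomers(parent), parent)
  kept_keys <- vapply(kept, function(v) canonical_key(v$graph), character(1))
  expect_false(canonical_key(pg("OC(O)=C")) %in% kept_keys)

  # phenol's keto form breaks aromaticity: ring count 1 -> 0
  parent <- pg("Oc1ccccc1")
  kept <- filter_tautomers(enumerate_tautomers(parent), parent)
  expect_length(kept, 1)
  expect_identical(canonical_key(kept[[1]]$graph), canonical_key(parent))
})

test_that("every retained tautomer preserves the molecular formula", {
  for (smi in c("CCC(C)=O", "CC(=O)O", "O=c1cccc[nH]1", "CC(=O)NC", "CCN=O")) {
    parent <- pg(smi)
    kept <- filter_tautomers(enumerate_tautomers(parent), parent)
    expect_true(all(vapply(kept, function(v)
      molecular_formula(v$graph) == molecular_formula(parent), logical(1))),
      label = smi)
  }
})

test_that("filtering is idempotent and the clean parent survives", {
  parent <- pg("CCC(C)=O")
  kept1 <- filter_tautomers(enumerate_tautomers(parent), parent)
  g1 <- lapply(kept1, `[[`, "graph")
  kept2 <- filter_tautomers(g1, parent)
  expect_identical(sort(vapply(kept2, function(v) canonical_key(v$graph), character(1))),
                   sort(vapply(kept1, function(v) canonical_key(v$graph), character(1))))
  keys <- vapply(kept1, function(v) canonical_key(v$graph), character(1))
  expect_true(canonical_key(parent) %in% keys)
})

test_that("tautomerization voids stereo on rearranged double bonds", {
  # specified C=C stereo where the enol/keto shift changes the bond
  parent <- pg("C/C=C(/O)C")  # enol of butan-2-one with specified geometry
  tl <- enumerate_tautomers(parent)
  kept <- filter_tautomers(tl, parent)
  # the keto form exists, and the re-emitted enol lost its cis/trans spec
  kept_keys <- vapply(kept, function(v) canonical_key(v$graph), character(1))
  expect_true(canonical_key(pg("CCC(C)=O")) %in% kept_keys)
  enols <- Filter(function(v) smarts_has_match(v$graph, "[OX2H1][CX3]=[CX3]"), kept)
  expect_true(all(vapply(enols, function(v)
    all(v$graph$bonds$stereo == "none"), logical(1))))
})

test_that("the enumeration cap truncates with a warning", {
  expect_warning(
    enumerate_tautomers(pg("OC(O)C(O)C(O)C(=O)C(O)C(O)C(=O)CC(=O)CC=O"), cap = 16L),
    "truncated")
})
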