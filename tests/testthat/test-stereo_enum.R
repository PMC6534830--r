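test_that("unspecified tetrahedral centers enumerate to both enantiomers", {
  vs <- enumerate_chiral(pg("FC(Cl)(Br)I"))
  expect_length(vs, 2)
  keys <- vapply(vs, function(v) canonical_key(v$graph), character(1))
  expect_identical(length(unique(keys)), 2L)
  labels <- sort(vapply(vs, function(v) {
    centers <- potential_stereocenters(v$graph)
    cip_label(v$graph, centers[1])
  }, character(1)))
  expect_identical(labels, c("R", "S"))
})

test_that("specified centers are left untouched", {
  g <- pg("F[C@@H](Cl)Br")
  vs <- enumerate_chiral(g)
  expect_length(vs, 1)
  expect_identical(canonical_key(vs[[1]]$graph), canonical_key(g))
  # mixed: one specified + one unspecified -> only the free one varies
  g2 <- pg("C[C@H](N)C(O)C")
  vs2 <- enumerate_chiral(g2)
  expect_length(vs2, 2)
  specified <- vapply(vs2, function(v) {
    w <- write_smiles(v$graph)
    grepl("@", w, fixed = TRUE)
  }, logical(1))
  expect_true(all(specified))
})

test_that("meso forms deduplicate: tartaric skeleton gives 3 variants", {
  vs <- enumerate_chiral(pg("OC(C(O)C(O)=O)C(O)=O"))
  expect_length(vs, 3)
  keys <- vapply(vs, function(v) canonical_key(v$graph), character(1))
  expect_identical(length(unique(keys)), 3L)
})

test_that("unspecified stereogenic double bonds enumerate to E and Z", {
  vs <- enumerate_cis_trans(pg("ClC(F)=C(Br)I"))
  expect_length(vs, 2)
  # 1,1-identical substituents: not stereogenic
  vs <- enumerate_cis_trans(pg("C=C(F)F"))
  expect_length(vs, 1)
  # two unspecified stereogenic bonds -> 4 variants before pruning
  # (asymmetric diene: EZ and ZE are distinct molecules)
  vs <- enumerate_cis_trans(pg("CC=CC=CF"))
  expect_length(vs, 4)
  # symmetric diene: EZ and ZE coincide, deduplication leaves 3
  vs <- enumerate_cis_trans(pg("CC=CC=CC"))
  expect_length(vs, 3)
  # specified bonds remain unchanged
  g <- pg("C/C=C/C")
  vs <- enumerate_cis_trans(g)
  expect_length(vs, 1)
  expect_identical(canonical_key(vs[[1]]$graph), canonical_key(g))
})

test_that("small-ring internal double bonds are not enumerated", {
  vs <- enumerate_cis_trans(pg("C1=CCCCC1"))  # cyclohexene: forced cis
  expect_length(vs, 1)
})

test_that("pre-deduplication output size is 2^(n+b)", {
  cases <- list(
    list(smi = "CC(N)C(O)CC", n = 2L),   # two centers, distinct ends -> 4
    list(smi = "CC=CC(O)C", n = 2L),     # one bond + one center -> 4
    list(smi = "FC(Cl)(Br)I", n = 1L)
  )
  for (cs in cases) {
    g <- pg(cs$smi)
    nc <- length(potential_stereocenters(g))
    nb <- length(stereogenic_double_bonds(g))
    expect_identical(nc + nb, cs$n, label = cs$smi)
    ch <- enumerate_chiral(g)
    total <- 0L
    for (v in ch) total <- total + length(enumerate_cis_trans(v$graph))
    expect_lte(total, 2^(nc + nb))
    expect_gte(total, 1L)
  }
})

test_that("cis/trans enumeration round-trips through SMILES", {
  vs <- enumerate_cis_trans(pg("CC=CC"))
  expect_length(vs, 2)
  smis <- vapply(vs, function(v) write_smiles(v$graph), character(1))
  reparsed <- vapply(smis, function(s) canonical_key(pg(s)), character(1))
  orig <- vapply(vs, function(v) canonical_key(v$graph), character(1))
  expect_setequal(reparsed, orig)
})
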