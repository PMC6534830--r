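test_that("molecules without ionizable sites pass through unchanged", {
  vs <- enumerate_ionization_states(pg("CC"), 6.4, 8.4, 1.0)
  expect_length(vs, 1)
  expect_identical(canonical_key(vs[[1]]$graph), canonical_key(pg("CC")))
  # aliphatic alcohols never ionize inside a physiological window
  vs <- enumerate_ionization_states(pg("CCCO"), 6.4, 8.4, 1.0)
  expect_length(vs, 1)
  expect_identical(net_formal_charge(vs[[1]]$graph), 0L)
})

test_that("oseltamivir carboxylate is deprotonated at pH 7.4", {
  g <- pg("CCC(CC)O[C@@H]1C=C(C(=O)O)C[C@@H](N)[C@H]1NC(C)=O")
  vs <- enumerate_ionization_states(g, 7.4, 7.4, 1.0, "oseltamivir")
  has_carboxylate <- vapply(vs, function(v)
    smarts_has_match(v$graph, "[CX3](=O)[OX1-]"), logical(1))
  expect_true(any(has_carboxylate))
  expect_true(all(vapply(vs, function(v)
    any(vapply(v$provenance, function(s) s$stage == "ionize", logical(1))),
    logical(1))))
})

test_that("glycine-like window rule matches the brute-force site grid", {
  # two sites: alpha-carboxyl (pKa 2.3 +/- 0.5) and alpha-amine (9.6 +/- 0.5);
  # brute force over the 2x2 site-state grid with the window rule
  min_ph <- 6.4; max_ph <- 8.4; prec <- 1.0
  acid_states <- c(deprot = 2.3 - prec < max_ph, prot = 2.3 + prec > min_ph)
  amine_states <- c(deprot = 9.6 - prec < max_ph, prot = 9.6 + prec > min_ph)
  expected_states <- expand.grid(acid = names(which(acid_states)),
                                 amine = names(which(amine_states)))
  vs <- enumerate_ionization_states(pg("NCC(=O)O"), min_ph, max_ph, prec)
  expect_length(vs, nrow(expected_states))  # 1 combination: zwitterion
  keys <- vapply(vs, function(v) canonical_key(v$graph), character(1))
  expect_true(canonical_key(pg("[NH3+]CC(=O)[O-]")) %in% keys)
})

test_that("both forms are emitted when the pKa window straddles the pH window", {
  # thiol pKa 9.1 with precision 1.0: deprotonated allowed (8.1 < 8.4) and
  # protonated allowed (10.1 > 6.4) -> both forms
  vs <- enumerate_ionization_states(pg("CCS"), 6.4, 8.4, 1.0)
  q <- sort(vapply(vs, function(v) net_formal_charge(v$graph), integer(1)))
  expect_identical(q, c(-1L, 0L))
})

test_that("ionization variants share the heavy-atom skeleton", {
  for (smi in c("NCC(=O)O", "CCS", "Oc1ccc(CC(N)C(=O)O)cc1")) {
    g <- pg(smi)
    vs <- enumerate_ionization_states(g, 6.4, 8.4, 1.0)
    skel <- function(gg) {
      gg$atoms$charge <- 0L; gg$atoms$hcount <- 0L
      canonical_key(gg)
    }
    expect_identical(unique(vapply(vs, function(v) skel(v$graph), character(1))),
                     skel(g), label = smi)
  }
})

test_that("formal-charge pruning follows the closest-to-zero baseline rule", {
  keep_charges <- function(charges) {
    out <- prune_by_formal_charge(charged_variants(charges))
    sort(vapply(out, function(v) net_formal_charge(v$graph), integer(1)))
  }
  expect_identical(keep_charges(0L), 0L)
  # baseline 0; -4 deviates by 4 >= 3 and is eliminated
  expect_identical(keep_charges(c(-4L, -2L, -1L, 0L, 1L)), c(-2L, -1L, 0L, 1L))
  # baseline is the charge closest to zero (-2), not zero itself
  expect_identical(keep_charges(c(-3L, -2L)), c(-3L, -2L))
  # baseline tie resolves to the more negative candidate
  expect_identical(keep_charges(c(-3L, -1L, 1L)), c(-3L, -1L, 1L))
  expect_identical(keep_charges(c(-1L, 1L, 2L)), c(-1L, 1L))
})

test_that("retained charge span after pruning never exceeds 4 e", {
  set.seed(11)
  for (rep in 1:20) {
    charges <- sample(-5:5, sample(2:8, 1), replace = TRUE)
    out <- prune_by_formal_charge(charged_variants(charges))
    q <- vapply(out, function(v) net_formal_charge(v$graph), integer(1))
    expect_gte(length(q), 1)
    expect_lte(diff(range(q)), 4L)
    # brute-force application of the rule
    q0 <- min(charges[abs(charges) == min(abs(charges))])
    expect_identical(sort(q), sort(charges[abs(charges - q0) <= 2]))
  }
})
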