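test_that("sets at or under the budget pass through without embedding", {
  cs <- counting_stub()
  vs <- alkane_variants(3)
  out <- prune_variants(vs, m = 5, t = 3, seed = 1, backend = cs$backend)
  expect_length(out, 3)
  expect_length(cs$log$calls, 0)           # no embedding performed
  expect_identical(vapply(out, function(v) variant_key(v), character(1)),
                   vapply(vs, function(v) variant_key(v), character(1)))
})

test_that("32 variants with m=5, t=3: exactly 15 embedded, 5 retained", {
  cs <- counting_stub()
  out <- prune_variants(alkane_variants(32), m = 5, t = 3, seed = 2,
                        backend = cs$backend)
  expect_length(cs$log$calls, 15)
  expect_length(out, 5)
  expect_true(all(vapply(out, function(v) !is.na(v$energy), logical(1))))
})

test_that("injected energies 1..15: exactly the 5 lowest retained, order stable", {
  # energy assigned per embedding call: call i gets energy i
  counter <- new.env(); counter$i <- 0
  be <- stub_backend(energy_fun = function(smi, ci) {
    counter$i <- counter$i + 1
    counter$i
  })
  vs <- alkane_variants(32)
  out <- prune_variants(vs, m = 5, t = 3, seed = 4, backend = be)
  expect_length(out, 5)
  expect_identical(sort(vapply(out, function(v) v$energy, numeric(1))),
                   as.numeric(1:5))
  # deterministic: same seed, same retained keys
  counter$i <- 0
  out2 <- prune_variants(vs, m = 5, t = 3, seed = 4, backend = be)
  expect_identical(vapply(out, variant_key, character(1)),
                   vapply(out2, variant_key, character(1)))
})

test_that("sampling is uniform: chi-square over repeated runs", {
  vs <- alkane_variants(32)
  smis <- vapply(vs, function(v) write_smiles(v$graph), character(1))
  hits <- setNames(numeric(32), smis)
  n_runs <- 120
  for (run in seq_len(n_runs)) {
    cs <- counting_stub()
    prune_variants(vs, m = 5, t = 3, seed = 1000 + run, backend = cs$backend)
    hits[cs$log$calls] <- hits[cs$log$calls] + 1
  }
  expected <- n_runs * 15 / 32
  chisq <- sum((hits - expected)^2 / expected)
  # df = 31; 0.999 quantile ~ 61.1 -- generous but catches systematic bias
  expect_lt(chisq, stats::qchisq(0.999, df = 31))
  expect_true(all(hits > 0))
})

test_that("finalize passes optimized conformers through bitwise-identical", {
  be <- stub_backend()
  g <- pg("CCO")
  conf <- conformer3d(matrix(1:27 / 10, ncol = 3), c(g$atoms$element, rep("H", 6)),
                      c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 3L), energy = -1,
                      optimized = TRUE)
  v <- variant("x", g, provenance = list(provenance_step("ionize")), energy = -1,
               conformer = conf)
  out <- finalize_variants(list(v), backend = be)
  expect_identical(out[[1]]$conformer$coords, conf$coords)
  expect_identical(out[[1]]$energy, -1)
})

test_that("finalize optimizes unoptimized variants (energy never rises)", {
  be <- stub_backend()
  g <- pg("CCC")
  confs <- embed_models(g, 1, seed = 3, backend = be, optimize = FALSE)
  v <- variant("x", g, provenance = list(provenance_step("ionize")),
               energy = confs[[1]]$energy, conformer = confs[[1]])
  out <- finalize_variants(list(v), backend = be)
  expect_true(out[[1]]$conformer$optimized)
  expect_lte(out[[1]]$conformer$energy, confs[[1]]$energy)
  # empty input
  expect_identical(finalize_variants(list(), backend = be), list())
})
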