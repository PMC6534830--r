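# Bounding the combinatorial explosion: after each enumeration stage the
# live variant set is pruned to at most m variants by random sampling of
# m * t candidates, single-point force-field scoring of one embedded
# conformer each (no geometry optimization), and retention of the m
# best-energy variants.

#' Prune a variant set by sampling and energy ranking
#'
#' With `|variants| <= m` the set is returned untouched (no embedding).
#' Otherwise `min(|variants|, m * t)` variants are sampled without
#' replacement, one conformer is embedded per sampled variant and scored
#' with a single-point force-field energy, and the `m` lowest-energy
#' variants are retained (energy ties broken by canonical key).
#'
#' @param variants list of [variant()]s
#' @param m max variants per compound (default 5).
#' @param t thoroughness multiplier (default 3).
#' @param seed RNG seed for the sampling.
#' @param backend geometry backend.
#' @return list of at most `m` variants with energies (and unoptimized
#'   conformers) attached; attribute `error` set when every sampled variant
#'   failed to embed
#' @export
prune_variants <- function(variants, m = 5L, t = 3L, seed = 1L,
                           backend = default_backend()) {
  stopifnot(m >= 1L, t >= 1L)
  n <- length(variants)
  if (n <= m) return(variants)
  n_sample <- min(n, m * t)
  sel <- with_rng(derive_seed(seed, "prune-sample"),
                  sort(sample.int(n, n_sample)))
  sampled <- variants[sel]
  jobs <- lapply(seq_along(sampled), function(i) {
    list(graph = sampled[[i]]$graph, n_confs = 1L,
         seed = derive_seed(seed, "prune-embed", i), optimize = FALSE)
  })
  res <- backend_run(backend, jobs)
  ok <- vapply(res, function(r) isTRUE(r$ok) && length(r$conformers) > 0, logical(1))
  if (!any(ok)) {
    out <- list()
    attr(out, "error") <- "all sampled variants failed to embed"
    return(out)
  }
  if (any(!ok)) {
    warning(sprintf("%d of %d sampled variants failed to embed and were dropped",
                    sum(!ok), length(sampled)))
  }
  sampled <- sampled[ok]
  res <- res[ok]
  for (i in seq_along(sampled)) {
    sampled[[i]]$conformer <- res[[i]]$conformers[[1]]
    sampled[[i]]$energy <- res[[i]]$conformers[[1]]$energy
  }
  energies <- vapply(sampled, function(v) v$energy, numeric(1))
  keys <- vapply(sampled, variant_key, character(1))
  keep <- order(energies, keys)[seq_len(min(m, length(sampled)))]
  sampled[sort(keep)]
}

#' Final geometry optimization
#'
#' Ensures every variant carries an optimized conformer: variants already
#' optimized (ring-conformation stage) pass through untouched; others are
#' optimized from their existing conformer, or embedded first when no
#' conformer is present. Optimization failures drop the variant with a
#' warning.
#'
#' @param variants list of [variant()]s
#' @param backend geometry backend.
#' @param seed RNG seed used when a variant must be embedded from scratch.
#' @return list of variants whose conformers all have `optimized = TRUE`
#' @export
finalize_variants <- function(variants, backend = default_backend(), seed = 1L) {
  if (!length(variants)) return(list())
  todo <- which(vapply(variants, function(v) {
    is.null(v$conformer) || !isTRUE(v$conformer$optimized)
  }, logical(1)))
  if (!length(todo)) return(variants)
  jobs <- lapply(todo, function(i) {
    v <- variants[[i]]
    if (!is.null(v$conformer)) {
      list(graph = v$graph, n_confs = 1L, seed = derive_seed(seed, "final", i),
           optimize = TRUE, coords = v$conformer)
    } else {
      list(graph = v$graph, n_confs = 1L, seed = derive_seed(seed, "final", i),
           optimize = TRUE)
    }
  })
  res <- backend_run(backend, jobs)
  drop <- integer(0)
  for (j in seq_along(todo)) {
    i <- todo[j]
    if (isTRUE(res[[j]]$ok) && length(res[[j]]$conformers)) {
      variants[[i]]$conformer <- res[[j]]$conformers[[1]]
      variants[[i]]$energy <- res[[j]]$conformers[[1]]$energy
      variants[[i]] <- add_provenance(variants[[i]], "optimize",
                                      "final UFF geometry optimization")
    } else {
      warning(sprintf("final optimization failed for a variant of %s; dropped",
                      variants[[i]]$parent_id))
      drop <- c(drop, i)
    }
  }
  if (length(drop)) variants <- variants[-drop]
  variants
}
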