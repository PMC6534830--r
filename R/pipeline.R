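# Pipeline orchestration: desalt -> ionization (+ charge pruning) ->
# tautomers -> chirality -> cis/trans, with sampling/energy pruning after
# each enumeration stage, then ring-conformer expansion (or plain
# embedding) and final geometry optimization. Per-record seeds are derived
# from (global seed, record index), so serial and parallel execution give
# identical results.

#' Pipeline configuration
#'
#' @param min_ph,max_ph pH window for ionization (defaults 6.4, 8.4).
#' @param pka_precision +/- pH window around site pKas (default 1.0).
#' @param thoroughness sampling multiplier t (default 3).
#' @param max_variants_per_compound output bound m per input molecule
#'   (default 5).
#' @param skip_making_tautomers skip the tautomer stage (default FALSE).
#' @param job_manager "serial", "multiprocessing" or "mpi" (mpi accepted but
#'   executed with the multiprocessing chunking contract).
#' @param num_processors worker count for multiprocessing (default 1).
#' @param seed global RNG seed (default 1).
#' @param output_sdf,output_pdb,output_html output format flags.
#' @param backend geometry backend (default: RDKit when available).
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(min_ph = 6.4, max_ph = 8.4, pka_precision = 1.0,
                            thoroughness = 3L, max_variants_per_compound = 5L,
                            skip_making_tautomers = FALSE,
                            job_manager = c("serial", "multiprocessing", "mpi"),
                            num_processors = 1L, seed = 1L,
                            output_sdf = TRUE, output_pdb = FALSE,
                            output_html = FALSE, backend = NULL) {
  job_manager <- match.arg(job_manager)
  stopifnot(min_ph <= max_ph, pka_precision >= 0,
            thoroughness >= 1L, max_variants_per_compound >= 1L,
            num_processors >= 1L)
  structure(list(min_ph = min_ph, max_ph = max_ph, pka_precision = pka_precision,
                 thoroughness = as.integer(thoroughness),
                 max_variants_per_compound = as.integer(max_variants_per_compound),
                 skip_making_tautomers = isTRUE(skip_making_tautomers),
                 job_manager = job_manager,
                 num_processors = as.integer(num_processors),
                 seed = as.integer(seed),
                 output_sdf = output_sdf, output_pdb = output_pdb,
                 output_html = output_html, backend = backend),
            class = "pipeline_config")
}

config_backend <- function(config) {
  if (is.null(config$backend)) default_backend() else config$backend
}

# Apply a per-variant enumeration op and merge provenance.
expand_stage <- function(variants, fn) {
  out <- list()
  for (v in variants) {
    for (nv in fn(v)) {
      nv$parent_id <- v$parent_id
      nv$provenance <- c(v$provenance, nv$provenance)
      nv$energy <- NA_real_
      nv$conformer <- NULL
      out[[length(out) + 1L]] <- nv
    }
  }
  dedupe_variants(out)
}

#' Process a single molecule record through the full pipeline
#'
#' @param record a [molecule_record()]
#' @param config a [pipeline_config()]
#' @param backend geometry backend override (default from config).
#' @return list(record, variants, failed, reason, stage_counts)
#' @export
process_record <- function(record, config = pipeline_config(),
                           backend = NULL) {
  if (is.null(backend)) backend <- config_backend(config)
  m <- config$max_variants_per_compound
  t <- config$thoroughness
  rec_seed <- derive_seed(config$seed, record$source_index, record$identifier)
  fail <- function(reason, counts = NULL) {
    list(record = record, variants = list(), failed = TRUE, reason = reason,
         stage_counts = counts)
  }
  if (record$failed) return(fail(record$reason))
  if (is.null(record$graph)) {
    g <- tryCatch(parse_smiles(record$smiles), error = function(e) e)
    if (inherits(g, "error")) return(fail(conditionMessage(g)))
    record$graph <- g
  }
  counts <- c()
  res <- tryCatch({
    g <- desalt(record$graph)
    v0 <- variant(record$identifier, g)
    if (attr(g, "removed_fragments") > 0L) {
      v0 <- add_provenance(v0, "desalt",
                           sprintf("removed %d fragment(s)", attr(g, "removed_fragments")))
    }
    live <- list(v0)

    # ionization + formal-charge pruning
    live <- expand_stage(live, function(v)
      enumerate_ionization_states(v$graph, config$min_ph, config$max_ph,
                                  config$pka_precision, record$identifier))
    live <- prune_by_formal_charge(live)
    counts["ionize_enumerated"] <- length(live)
    live <- prune_variants(live, m, t, derive_seed(rec_seed, "ionize"), backend)
    counts["ionize"] <- length(live)
    if (!length(live)) return(fail(attr(live, "error") %||% "pruning emptied the set", counts))

    if (!config$skip_making_tautomers) {
      live <- expand_stage(live, function(v)
        filter_tautomers(enumerate_tautomers(v$graph), v$graph, record$identifier))
      counts["tautomerize_enumerated"] <- length(live)
      live <- prune_variants(live, m, t, derive_seed(rec_seed, "tautomerize"), backend)
      counts["tautomerize"] <- length(live)
      if (!length(live)) return(fail(attr(live, "error") %||% "pruning emptied the set", counts))
    }

    live <- expand_stage(live, function(v) enumerate_chiral(v$graph, record$identifier))
    counts["chirality_enumerated"] <- length(live)
    live <- prune_variants(live, m, t, derive_seed(rec_seed, "chirality"), backend)
    counts["chirality"] <- length(live)
    if (!length(live)) return(fail(attr(live, "error") %||% "pruning emptied the set", counts))

    live <- expand_stage(live, function(v) enumerate_cis_trans(v$graph, record$identifier))
    counts["cis_trans_enumerated"] <- length(live)
    live <- prune_variants(live, m, t, derive_seed(rec_seed, "cis_trans"), backend)
    counts["cis_trans"] <- length(live)
    if (!length(live)) return(fail(attr(live, "error") %||% "pruning emptied the set", counts))

    # ring conformers (molecules with non-aromatic rings) or plain embedding
    expanded <- list()
    ring_err <- NULL
    for (vi in seq_along(live)) {
      v <- live[[vi]]
      outs <- generate_ring_conformers(v, m, t,
                                       derive_seed(rec_seed, "ring", vi), backend)
      if (!length(outs)) { ring_err <- attr(outs, "error"); next }
      expanded <- c(expanded, outs)
    }
    if (!length(expanded)) return(fail(ring_err %||% "embedding failed", counts))
    live <- expanded
    counts["ring_conformer"] <- length(live)

    live <- finalize_variants(live, backend, derive_seed(rec_seed, "final"))
    if (!length(live)) return(fail("final optimization failed", counts))

    # global per-molecule bound
    if (length(live) > m) {
      energies <- vapply(live, function(v) ifelse(is.na(v$energy), Inf, v$energy),
                         numeric(1))
      keys <- vapply(live, variant_key, character(1))
      live <- live[sort(order(energies, keys)[seq_len(m)])]
    }
    counts["final"] <- length(live)
    list(record = record, variants = live, failed = FALSE, reason = NA_character_,
         stage_counts = counts)
  }, error = function(e) fail(conditionMessage(e), counts))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the preparation pipeline over a set of records
#'
#' @param records list of [molecule_record()]s
#' @param config a [pipeline_config()]
#' @return object of class `molprep_result`: list(results, config); each
#'   result is the return value of [process_record()]. Failures never abort
#'   the batch.
#' @export
run_pipeline <- function(records, config = pipeline_config()) {
  backend <- config_backend(config)
  results <- lapply(records, process_record, config = config, backend = backend)
  structure(list(results = results, config = config), class = "molprep_result")
}

#' @export
print.molprep_result <- function(x, ...) {
  nok <- sum(!vapply(x$results, `[[`, logical(1), "failed"))
  nv <- sum(vapply(x$results, function(r) length(r$variants), integer(1)))
  cat(sprintf("<molprep_result> %d/%d records processed, %d models\n",
              nok, length(x$results), nv))
  invisible(x)
}

#' Split inputs into near-equal chunks
#'
#' Static load balancing: chunk sizes sum to `n_inputs` and differ by at
#' most one.
#' @param n_inputs number of inputs (>= 0)
#' @param n_workers number of workers (>= 1)
#' @return integer vector of length `n_workers`
#' @export
chunk_inputs <- function(n_inputs, n_workers) {
  stopifnot(n_inputs >= 0, n_workers >= 1)
  base <- as.integer(n_inputs %/% n_workers)
  rem <- as.integer(n_inputs %% n_workers)
  c(rep(base + 1L, rem), rep(base, as.integer(n_workers) - rem))
}

#' Run the pipeline with multiprocessing
#'
#' Forked workers (`parallel::mclapply`); output is identical to serial mode
#' under the same seed for any worker count because all stage seeds derive
#' from (global seed, record). On platforms without fork support execution
#' falls back to serial with a warning.
#'
#' @inheritParams run_pipeline
#' @return `molprep_result`, record order preserved
#' @export
run_parallel <- function(records, config = pipeline_config()) {
  if (!length(records)) return(structure(list(results = list(), config = config),
                                         class = "molprep_result"))
  nw <- config$num_processors
  if (.Platform$OS.type == "windows" && nw > 1L) {
    warning("multiprocessing is not available on Windows; running serially")
    return(run_pipeline(records, config))
  }
  backend <- config_backend(config)
  results <- parallel::mclapply(records, function(rec) {
    tryCatch(process_record(rec, config, backend),
             error = function(e) list(record = rec, variants = list(),
                                      failed = TRUE, reason = conditionMessage(e),
                                      stage_counts = NULL))
  }, mc.cores = max(1L, nw))
  # a crashed worker yields a try-error; mark those records failed
  for (i in seq_along(results)) {
    if (inherits(results[[i]], "try-error") || !is.list(results[[i]])) {
      results[[i]] <- list(record = records[[i]], variants = list(),
                           failed = TRUE, reason = "worker failure",
                           stage_counts = NULL)
    }
  }
  structure(list(results = results, config = config), class = "molprep_result")
}

#' Write pipeline outputs
#'
#' @param result `molprep_result`
#' @param output_folder directory for output files
#' @return invisibly, the paths written
#' @export
write_outputs <- function(result, output_folder) {
  dir.create(output_folder, showWarnings = FALSE, recursive = TRUE)
  all_variants <- unlist(lapply(result$results, `[[`, "variants"), recursive = FALSE)
  paths <- character(0)
  cfg <- result$config
  if (isTRUE(cfg$output_sdf)) {
    p <- file.path(output_folder, "molprep_output.sdf")
    write_sdf(all_variants, p); paths <- c(paths, p)
  }
  if (isTRUE(cfg$output_pdb)) {
    paths <- c(paths, write_pdb(all_variants, file.path(output_folder, "pdb")))
  }
  if (isTRUE(cfg$output_html)) {
    p <- file.path(output_folder, "molprep_output.html")
    write_html(all_variants, p); paths <- c(paths, p)
  }
  failures <- Filter(function(r) r$failed, result$results)
  if (length(failures)) {
    p <- file.path(output_folder, "failures.txt")
    writeLines(vapply(failures, function(r)
      sprintf("%s\t%s", r$record$identifier, r$reason), character(1)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
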