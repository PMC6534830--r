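# Geometry backend contract. Two operations are required of any backend:
# embed (graph -> one or more 3D conformers with energies, optionally
# force-field optimized) and optimize-from-coordinates (used by the final
# optimization pass). The default adapter drives RDKit's ETKDG embedder and
# the Universal Force Field through a batched python subprocess; a
# deterministic pure-R stub backend serves tests that only exercise
# sampling/ranking contracts.

#' Construct the RDKit geometry backend
#'
#' Embedding uses ETKDG (v2) with a per-job random seed; energies and
#' geometry optimization use UFF. Jobs are batched into a single python
#' subprocess call to amortize interpreter startup.
#'
#' @param python path to the python executable (default: `python` on PATH).
#' @return object of class `rdkit_backend` / `geometry_backend`
#' @export
rdkit_backend <- function(python = Sys.which("python")) {
  script <- system.file("python", "geometry_backend.py", package = "molprep")
  if (!nzchar(script)) script <- file.path("inst", "python", "geometry_backend.py")
  structure(list(python = python, script = script),
            class = c("rdkit_backend", "geometry_backend"))
}

#' Is the RDKit backend usable?
#' @return logical
#' @export
rdkit_available <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    py <- Sys.which("python")
    ok <- nzchar(py) && {
      res <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                      stdout = FALSE, stderr = FALSE))
      identical(res, 0L)
    }
    cache <<- ok
    ok
  }
})

#' Construct the stub geometry backend
#'
#' Produces deterministic pseudo-random coordinates and energies from the
#' molecule's canonical SMILES and the job seed. `energy_fun(smiles,
#' conf_index)` can be injected to control energies in tests. The optimize
#' contract (energy never increases) is honored.
#'
#' @param energy_fun optional function(smiles, conf_index) -> numeric
#' @return object of class `stub_backend` / `geometry_backend`
#' @export
stub_backend <- function(energy_fun = NULL) {
  structure(list(energy_fun = energy_fun),
            class = c("stub_backend", "geometry_backend"))
}

#' Run a batch of geometry jobs
#'
#' @param backend a `geometry_backend`
#' @param jobs list of jobs, each `list(graph =, n_confs =, seed =,
#'   optimize =, coords = NULL|conformer3d, max_iters =)`
#' @return list parallel to `jobs`: each `list(ok =, conformers = list of
#'   [conformer3d()], error =)`
#' @export
backend_run <- function(backend, jobs) UseMethod("backend_run")

#' @export
backend_run.rdkit_backend <- function(backend, jobs) {
  if (!length(jobs)) return(list())
  sws <- lapply(jobs, function(j) smiles_with_order(j$graph))
  pjobs <- lapply(seq_along(jobs), function(i) {
    j <- jobs[[i]]
    pj <- list(id = as.character(i), smiles = sws[[i]]$smiles,
               n_confs = if (is.null(j$n_confs)) 1L else j$n_confs,
               seed = if (is.null(j$seed)) 1L else j$seed,
               optimize = !isFALSE(j$optimize),
               max_iters = if (is.null(j$max_iters)) 500L else j$max_iters)
    if (!is.null(j$coords)) {
      pj$coords <- conformer_to_backend_rows(j$coords, j$graph, sws[[i]]$order)
    }
    pj
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(jobs = pjobs), fin, auto_unbox = TRUE, digits = NA)
  status <- system2(backend$python, c(backend$script, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout))
    stop("geometry backend subprocess failed (status ", status, ")")
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  lapply(seq_along(jobs), function(i) {
    r <- res$jobs[[i]]
    if (!isTRUE(r$ok)) return(list(ok = FALSE, conformers = list(), error = r$error))
    confs <- lapply(r$conformers, function(cf) {
      backend_rows_to_conformer(cf, r, jobs[[i]]$graph, sws[[i]]$order)
    })
    list(ok = TRUE, conformers = confs, error = NULL)
  })
}

# conformer3d (graph order + H rows) -> backend row layout (SMILES order +
# H rows unchanged)
conformer_to_backend_rows <- function(conf, graph, order) {
  nh <- n_atoms(graph)
  rows <- conf$coords
  out <- rows
  for (p in seq_len(nh)) out[p, ] <- rows[order[p], ]
  lapply(seq_len(nrow(out)), function(r) as.numeric(out[r, ]))
}

# backend job result conformer -> conformer3d with heavy rows in graph order
backend_rows_to_conformer <- function(cf, r, graph, order) {
  raw <- do.call(rbind, lapply(cf$coords, function(p) as.numeric(unlist(p))))
  nh <- n_atoms(graph)
  coords <- raw
  elements <- unlist(r$elements)
  hp <- unlist(r$h_parent)
  # heavy rows: smiles position p corresponds to graph atom order[p]
  for (p in seq_len(nh)) coords[order[p], ] <- raw[p, ]
  elements[seq_len(nh)] <- graph$atoms$element  # graph order
  h_parent <- integer(nrow(raw))
  if (nrow(raw) > nh) {
    for (p in (nh + 1L):nrow(raw)) {
      h_parent[p] <- order[hp[p] + 1L]  # python 0-based smiles index -> graph
    }
  }
  conformer3d(coords, elements, h_parent, energy = cf$energy,
              optimized = isTRUE(cf$optimized))
}

#' @export
backend_run.stub_backend <- function(backend, jobs) {
  lapply(jobs, function(j) {
    smi <- write_smiles(j$graph)
    n_confs <- if (is.null(j$n_confs)) 1L else j$n_confs
    optimize <- !isFALSE(j$optimize)
    nh <- n_atoms(j$graph)
    ntot <- nh + sum(j$graph$atoms$hcount)
    elements <- c(j$graph$atoms$element, rep("H", ntot - nh))
    h_parent <- integer(ntot)
    if (ntot > nh) {
      hs <- rep(seq_len(nh), j$graph$atoms$hcount)
      h_parent[(nh + 1L):ntot] <- hs
    }
    if (!is.null(j$coords)) {
      e0 <- j$coords$energy
      e <- if (!is.null(backend$energy_fun)) backend$energy_fun(smi, 1L)
           else e0 - abs(e0) * 0.01 - 0.1
      conf <- conformer3d(j$coords$coords, j$coords$elements, j$coords$h_parent,
                          energy = min(e, e0), optimized = TRUE)
      return(list(ok = TRUE, conformers = list(conf), error = NULL))
    }
    confs <- lapply(seq_len(n_confs), function(ci) {
      sd <- derive_seed(smi, j$seed, ci)
      with_rng(sd, {
        coords <- matrix(stats::rnorm(ntot * 3, sd = 2), ncol = 3)
        e <- if (!is.null(backend$energy_fun)) backend$energy_fun(smi, ci)
             else stats::runif(1, -100, 100)
        conformer3d(coords, elements, h_parent, energy = e, optimized = optimize)
      })
    })
    list(ok = TRUE, conformers = confs, error = NULL)
  })
}

#' Default geometry backend
#'
#' The RDKit backend when python + rdkit are available, otherwise the stub
#' backend (with a warning: stub geometries are not chemically meaningful).
#' @return a `geometry_backend`
#' @export
default_backend <- function() {
  if (rdkit_available()) rdkit_backend()
  else {
    warning("python/rdkit not found; falling back to the stub geometry backend")
    stub_backend()
  }
}
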