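# Readers for SMILES line files and flat SDF (V2000); writers for SDF with
# provenance data fields, PDB, and a self-contained 2D HTML summary.
# Unparseable inputs become failed records, never aborts: record counts are
# conserved (successes + failures = input lines/blocks).

#' Read a SMILES file
#'
#' One record per non-empty, non-comment (#) line: SMILES, optional
#' whitespace, optional name (everything after the first token). Unparseable
#' lines produce failed records.
#'
#' @param path file path
#' @return list of [molecule_record()]s in file order
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) {
    warning("empty SMILES file: ", path)
    return(list())
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    smi <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    g <- tryCatch(parse_smiles(smi), error = function(e) e)
    if (inherits(g, "error")) {
      out[[i]] <- molecule_record(name, smi, i - 1L, failed = TRUE,
                                  reason = conditionMessage(g))
    } else {
      out[[i]] <- molecule_record(name, smi, i - 1L, graph = g)
    }
  }
  out
}

#' Read a flat SDF file
#'
#' V2000 molecule blocks; any 3D coordinates present are ignored (inputs are
#' treated as flat). The title line provides the identifier when non-empty.
#' Explicit hydrogens are folded into heavy-atom hydrogen counts. Malformed
#' blocks (truncated, bogus atom symbols) produce failed records.
#'
#' @param path file path
#' @return list of [molecule_record()]s in file order
#' @export
read_sdf_flat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    warning("empty SDF file: ", path)
    return(list())
  }
  # split into blocks on $$$$
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- list()
  for (bi in seq_along(starts)) {
    if (starts[bi] > length(lines)) break
    block <- lines[starts[bi]:min(ends[bi], length(lines))]
    if (!any(nzchar(trimws(block)))) next
    idx <- bi - 1L
    rec <- tryCatch(parse_sdf_block(block, idx), error = function(e) {
      molecule_record(identifier = "", smiles = "", source_index = idx,
                      failed = TRUE, reason = conditionMessage(e))
    })
    out[[length(out) + 1L]] <- rec
  }
  out
}

parse_sdf_block <- function(block, source_index) {
  if (length(block) < 4L) stop("truncated molecule block")
  title <- trimws(block[1])
  counts <- block[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L) stop("bad counts line")
  if (length(block) < 4L + na + nb) stop("truncated molecule block")
  atom_lines <- block[5:(4 + na)]
  bond_lines <- if (nb > 0) block[(5 + na):(4 + na + nb)] else character(0)
  element <- trimws(substr(atom_lines, 32, 34))
  bad <- !element %in% names(PERIODIC$number) | element == ""
  if (any(bad)) stop("improper atom symbol(s): ", paste(unique(element[bad]), collapse = ", "))
  atoms <- data.frame(element = element, charge = 0L, hcount = 0L,
                      aromatic = FALSE, isotope = 0L, parity = 0L,
                      stringsAsFactors = FALSE)
  if (nb > 0) {
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    o <- as.integer(substr(bond_lines, 7, 9))
    if (anyNA(a1) || anyNA(a2) || anyNA(o) || any(a1 > na) || any(a2 > na))
      stop("bad bond block")
    if (any(o == 4L)) o[o == 4L] <- 1L  # aromatic bond type: kekulization not attempted
    bonds <- data.frame(a1 = a1, a2 = a2, order = o, arom = FALSE,
                        stereo = "none", sref1 = 0L, sref2 = 0L,
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        arom = FALSE, stereo = character(0),
                        sref1 = integer(0), sref2 = integer(0))
  }
  # M  CHG property lines override
  for (ln in block[grepl("^M  CHG", block)]) {
    toks <- strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]
    n <- as.integer(toks[1])
    for (j in seq_len(n)) {
      ai <- as.integer(toks[2 * j]); ch <- as.integer(toks[2 * j + 1])
      atoms$charge[ai] <- ch
    }
  }
  g <- mol_graph(atoms, bonds)
  # fold explicit hydrogens into heavy-atom hcounts, fill implicit ones
  osum <- bond_order_sums(g)
  heavy <- which(g$atoms$element != "H")
  nbl <- adjacency(g)
  for (i in heavy) {
    nH <- sum(g$atoms$element[nbl[[i]]] == "H")
    g$atoms$hcount[i] <- nH + implied_hcount(g$atoms$element[i],
                                             g$atoms$charge[i], osum[i])
  }
  if (length(heavy) < n_atoms(g)) g <- subgraph(g, heavy)
  g <- perceive_aromaticity(g)
  validate_valences(g, sprintf("<sdf block %d>", source_index))
  molecule_record(title, write_smiles(g), source_index, graph = g)
}

#' Write variants to an SDF file
#'
#' One V2000 molecule block per variant with 3D coordinates (explicit
#' hydrogens included), `M  CHG` charge lines, and the provenance data
#' fields `Parent`, `Genealogy` and `VariantIndex`.
#'
#' @param variants list of [variant()]s, each carrying a [conformer3d()]
#' @param path output file
#' @return invisibly, the number of blocks written
#' @export
write_sdf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- 0L
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    if (is.null(v$conformer))
      stop(sprintf("variant %d (parent %s) has no 3D coordinates", vi, v$parent_id))
    writeLines(sdf_block(v, vi), con)
    n <- n + 1L
  }
  invisible(n)
}

sdf_block <- function(v, vi) {
  g <- v$graph
  conf <- v$conformer
  nheavy <- n_atoms(g)
  ntot <- nrow(conf$coords)
  bonds <- g$bonds
  # hydrogen bonds: each H row bonds to its parent heavy atom
  hb1 <- integer(0); hb2 <- integer(0)
  if (ntot > nheavy) {
    for (p in (nheavy + 1L):ntot) { hb1 <- c(hb1, conf$h_parent[p]); hb2 <- c(hb2, p) }
  }
  natoms <- ntot
  nbonds <- nrow(bonds) + length(hb1)
  out <- c(sprintf("%s", v$parent_id),
           "  molprep 3D",
           "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nbonds))
  for (i in seq_len(ntot)) {
    el <- if (i <= nheavy) g$atoms$element[i] else "H"
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          conf$coords[i, 1], conf$coords[i, 2], conf$coords[i, 3], el))
  }
  for (k in seq_len(nrow(bonds))) {
    out <- c(out, sprintf("%3d%3d%3d  0", bonds$a1[k], bonds$a2[k], bonds$order[k]))
  }
  for (j in seq_along(hb1)) {
    out <- c(out, sprintf("%3d%3d%3d  0", hb1[j], hb2[j], 1L))
  }
  chg <- which(g$atoms$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, g$atoms$charge[grp]),
                                  collapse = "")))
    }
  }
  out <- c(out, "M  END")
  genealogy <- paste(vapply(v$provenance, function(s)
    sprintf("%s: %s", s$stage, s$detail), character(1)), collapse = "; ")
  out <- c(out,
           "> <Parent>", v$parent_id, "",
           "> <Genealogy>", if (nzchar(genealogy)) genealogy else "(input form)", "",
           "> <VariantIndex>", as.character(vi), "")
  if (!is.na(v$energy)) out <- c(out, "> <Energy>", sprintf("%.4f", v$energy), "")
  c(out, "$$$$")
}

#' Write variants as PDB files
#'
#' One file per variant (`<parent>_<index>.pdb`) with HETATM records.
#' @param variants list of [variant()]s with conformers
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_pdb <- function(variants, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    if (is.null(v$conformer))
      stop(sprintf("variant %d (parent %s) has no 3D coordinates", vi, v$parent_id))
    conf <- v$conformer
    safe <- gsub("[^A-Za-z0-9_.-]", "_", v$parent_id)
    path <- file.path(dir, sprintf("%s_%d.pdb", safe, vi))
    lines <- c(sprintf("COMPND    %s", v$parent_id))
    for (i in seq_len(nrow(conf$coords))) {
      el <- conf$elements[i]
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, substr(paste0(el, i), 1, 4), conf$coords[i, 1], conf$coords[i, 2],
        conf$coords[i, 3], el))
    }
    writeLines(c(lines, "END"), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a 2D HTML summary
#'
#' Self-contained HTML with one entry per variant: an SVG depiction (heavy
#' atoms projected onto their two principal axes) plus a caption with the
#' parent identifier, formula, net charge and provenance.
#'
#' @param variants list of [variant()]s with conformers
#' @param path output file
#' @return invisibly, the number of entries written
#' @export
write_html <- function(variants, path) {
  entries <- character(0)
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    if (is.null(v$conformer))
      stop(sprintf("variant %d (parent %s) has no 3D coordinates", vi, v$parent_id))
    g <- v$graph
    xy <- project_2d(v$conformer$coords[seq_len(n_atoms(g)), , drop = FALSE])
    svg <- depiction_svg(g, xy)
    genealogy <- paste(vapply(v$provenance, function(s)
      sprintf("%s: %s", s$stage, s$detail), character(1)), collapse = "; ")
    entries <- c(entries, sprintf(
      '<div class="variant"><h3>%s &mdash; variant %d</h3>%s<p>%s; net charge %+d</p><p class="gen">%s</p></div>',
      v$parent_id, vi, svg, molecular_formula(g), net_formal_charge(g), genealogy))
  }
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'><title>molprep output</title>",
            "<style>body{font-family:sans-serif}.variant{border:1px solid #ccc;margin:8px;padding:8px;display:inline-block}.gen{color:#666;font-size:small}</style>",
            "</head><body><h1>molprep generated models</h1>", entries, "</body></html>")
  writeLines(html, path)
  invisible(length(entries))
}

project_2d <- function(coords) {
  if (nrow(coords) == 1L) return(matrix(0, 1, 2))
  centered <- sweep(coords, 2, colMeans(coords))
  pc <- svd(centered)$v[, 1:2, drop = FALSE]
  centered %*% pc
}

depiction_svg <- function(g, xy) {
  w <- 240; h <- 200; pad <- 24
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  sc <- function(v, rng, size) {
    if (diff(rng) < 1e-9) return(rep(size / 2, length(v)))
    pad + (v - rng[1]) / diff(rng) * (size - 2 * pad)
  }
  X <- sc(xy[, 1], rngx, w); Y <- sc(xy[, 2], rngy, h)
  parts <- sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">', w, h)
  for (k in seq_len(nrow(g$bonds))) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    parts <- c(parts, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black" stroke-width="%d"/>',
      X[a1], Y[a1], X[a2], Y[a2], g$bonds$order[k]))
  }
  for (i in seq_len(n_atoms(g))) {
    if (g$atoms$element[i] != "C" || g$atoms$charge[i] != 0L) {
      lab <- g$atoms$element[i]
      if (g$atoms$charge[i] > 0L) lab <- paste0(lab, "+")
      if (g$atoms$charge[i] < 0L) lab <- paste0(lab, "-")
      parts <- c(parts, sprintf(
        '<text x="%.1f" y="%.1f" font-size="11" fill="darkblue" text-anchor="middle">%s</text>',
        X[i], Y[i], lab))
    }
  }
  paste(c(parts, "</svg>"), collapse = "")
}
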