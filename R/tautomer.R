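# Tautomer enumeration by rule-based 1,3 proton shifts (H-D-Y=A  <->
# D=Y-A-H), closed over repeated application up to a cap, followed by the
# plausibility filters: tautomers must preserve the aromatic-ring count and
# the chiral-center count, and must not contain a terminal-alkene enol, a
# geminal vinyl diol, or a carbanion. The generic shift covers keto/enol,
# imine/enamine, amide/iminol, nitroso/oxime and aromatic-heterocycle
# hydrogen shifts; shifts between two carbons are excluded (at least one of
# donor/acceptor must be N, O or S).

TAUTOMER_CAP_DEFAULT <- 64L

#' Enumerate tautomers of a molecule
#'
#' Closure of single 1,3 proton shifts, deduplicated by canonical key. The
#' input graph is always element one of the result.
#'
#' @param g single-fragment mol_graph
#' @param cap maximum number of enumerated forms before filtering
#'   (default 64); reaching it truncates the closure with a warning.
#' @return list of mol_graphs
#' @export
enumerate_tautomers <- function(g, cap = TAUTOMER_CAP_DEFAULT) {
  if (max(graph_components(g)) != 1L) stop("enumerate_tautomers: graph must be a single fragment")
  seen <- new.env(parent = emptyenv())
  out <- list(g)
  assign(canonical_key(g), TRUE, envir = seen)
  frontier <- list(g)
  truncated <- FALSE
  while (length(frontier) && length(out) < cap) {
    nxt <- list()
    for (gf in frontier) {
      for (g2 in proton_shifts(gf)) {
        key <- canonical_key(g2)
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- g2
          nxt[[length(nxt) + 1L]] <- g2
          if (length(out) >= cap) { truncated <- TRUE; break }
        }
      }
      if (length(out) >= cap) break
    }
    frontier <- nxt
  }
  if (truncated) warning(sprintf("tautomer enumeration truncated at cap = %d", cap))
  out
}

# All single 1,3 proton shifts applicable to g.
proton_shifts <- function(g) {
  nb <- adjacency(g)
  res <- list()
  hetero <- c("N", "O", "S")
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != 2L) next
    # double bond Y=A, both orientations
    for (orient in 1:2) {
      y <- if (orient == 1L) g$bonds$a1[k] else g$bonds$a2[k]
      a <- if (orient == 1L) g$bonds$a2[k] else g$bonds$a1[k]
      if (!g$atoms$element[a] %in% c("C", "N", "O", "S")) next
      for (d in setdiff(nb[[y]], a)) {
        if (g$atoms$hcount[d] < 1L) next
        if (!g$atoms$element[d] %in% c("C", "N", "O", "S")) next
        if (!(g$atoms$element[d] %in% hetero || g$atoms$element[a] %in% hetero)) next
        kb <- bond_index(g, d, y)
        if (g$bonds$order[kb] != 1L) next
        # donor must be saturated: promoting d-y next to an existing double
        # bond on d would create a cumulene
        if (any(g$bonds$order[g$bonds$a1 == d | g$bonds$a2 == d] >= 2L)) next
        g2 <- apply_shift(g, d, y, a, kb, k)
        if (!is.null(g2)) res[[length(res) + 1L]] <- g2
      }
    }
  }
  res
}

# Move H from donor d to acceptor a across d-y=a; promotes d-y to a double
# bond. Returns NULL when the result would be chemically inconsistent.
apply_shift <- function(g, d, y, a, bond_dy, bond_ya) {
  g$atoms$hcount[d] <- g$atoms$hcount[d] - 1L
  g$atoms$hcount[a] <- g$atoms$hcount[a] + 1L
  g$bonds$order[bond_dy] <- 2L
  g$bonds$order[bond_ya] <- 1L
  # d and a change hybridization: any tetrahedral assignment there is void
  for (x in c(d, a)) {
    g$atoms$parity[x] <- 0L
    g$chiral_order[x] <- list(NULL)
  }
  # bond stereo attached to the two rearranged bonds is void as well
  for (kb in c(bond_dy, bond_ya)) {
    g$bonds$stereo[kb] <- "none"
    g$bonds$sref1[kb] <- 0L; g$bonds$sref2[kb] <- 0L
  }
  # stereo on other double bonds that reference d or a as a neighbor survives
  g <- perceive_aromaticity(g)
  ok <- tryCatch({ validate_valences(g, "<tautomer>"); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(NULL)
  g
}

# packaged blacklist of improbable-tautomer substructures
tautomer_blacklist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "tautomer_blacklist.json", package = "molprep")
      if (!nzchar(path)) path <- file.path("inst", "extdata", "tautomer_blacklist.json")
      raw <- jsonlite::read_json(path, simplifyVector = FALSE)
      cache <<- lapply(raw, function(e) {
        list(name = e$name, pattern = parse_smarts(e$smarts))
      })
    }
    cache
  }
})

#' Filter enumerated tautomers
#'
#' Applies the plausibility rules: a candidate is kept only when it preserves
#' the parent's aromatic-ring count and chiral-center count and matches none
#' of the blacklist substructures (terminal-alkene enol, geminal vinyl diol,
#' carbanion). When every candidate is rejected the parent form is retained.
#' Double bonds whose order changed in any candidate have their cis/trans
#' annotation reset (to be re-enumerated downstream).
#'
#' @param candidates list of mol_graphs from [enumerate_tautomers()]
#' @param parent the parent mol_graph
#' @param parent_id identifier recorded on the emitted variants
#' @return list of [variant()]s
#' @export
filter_tautomers <- function(candidates, parent, parent_id = "") {
  n_ar <- count_aromatic_rings(parent)
  n_ch <- count_chiral_centers(parent)
  parent_key <- canonical_key(parent)
  bl <- tautomer_blacklist()

  # double bonds of the parent that become single in some candidate
  reset_bonds <- integer(0)
  for (cand in candidates) {
    if (nrow(cand$bonds) != nrow(parent$bonds)) next
    changed <- which(parent$bonds$order == 2L & cand$bonds$order != 2L)
    reset_bonds <- union(reset_bonds, changed)
  }

  keep <- list()
  for (cand in candidates) {
    if (count_aromatic_rings(cand) != n_ar) next
    if (count_chiral_centers(cand) != n_ch) next
    bad <- FALSE
    for (b in bl) {
      if (smarts_has_match(cand, b$pattern)) { bad <- TRUE; break }
    }
    if (bad) next
    keep[[length(keep) + 1L]] <- cand
  }
  if (!length(keep)) keep <- list(parent)

  out <- lapply(keep, function(cand) {
    for (k in reset_bonds) {
      if (k <= nrow(cand$bonds) && cand$bonds$order[k] == 2L) {
        cand$bonds$stereo[k] <- "none"
        cand$bonds$sref1[k] <- 0L; cand$bonds$sref2[k] <- 0L
      }
    }
    key <- canonical_key(cand)
    v <- variant(parent_id, cand)
    detail <- if (key == parent_key) "parent form" else "shifted form"
    add_provenance(v, "tautomerize", detail)
  })
  dedupe_variants(out)
}
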