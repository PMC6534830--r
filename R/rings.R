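# Ring perception (SSSR), kekulization of aromatic SMILES input, and the
# single aromaticity model used by the whole pipeline.
#
# Aromaticity model (documented contract): a ring from the SSSR basis is
# aromatic when every ring atom can contribute to the pi system -- 1 electron
# for an atom with a double bond to another ring atom, 0 for an atom whose
# only double bond is exocyclic (e.g. the carbonyl carbon of a fused
# pyridinone), 2 for a lone-pair heteroatom (pyrrole-type N, O, S, carbanion)
# -- and the electron total satisfies Hueckel's 4n + 2 rule. Ring size >= 5.
# Tautomer filtering compares ring counts under this one model for both
# parent and candidate, which is all the pipeline requires of it.

#' Smallest set of smallest rings
#'
#' @param g mol_graph
#' @return list of integer vectors, each an ordered atom cycle
#' @export
sssr <- function(g) {
  nbnd <- nrow(g$bonds)
  rank <- nbnd - n_atoms(g) + length(unique(graph_components(g)))
  if (rank <= 0L) return(list())
  nb <- adjacency(g)

  # shortest cycle through each bond: BFS from a1 to a2 avoiding the bond
  cycles <- list()
  for (k in seq_len(nbnd)) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    par <- rep(0L, n_atoms(g)); par[a1] <- -1L
    queue <- a1; found <- FALSE
    while (length(queue) && !found) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (v == a1 && w == a2) next
        if (par[w] == 0L) {
          par[w] <- v
          if (w == a2) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (found) {
      path <- a2
      v <- a2
      while (par[v] > 0L) { v <- par[v]; path <- c(path, v) }
      cycles[[length(cycles) + 1L]] <- rev(path)  # a1 ... a2, closed by bond k
    }
  }
  if (!length(cycles)) return(list())
  sizes <- lengths(cycles)
  cycles <- cycles[order(sizes)]
  # greedy GF(2)-independent selection over bond incidence vectors
  bond_id <- function(i, j) bond_index(g, i, j)
  to_vec <- function(cy) {
    v <- rep(FALSE, nbnd)
    m <- length(cy)
    for (i in seq_len(m)) v[bond_id(cy[i], cy[i %% m + 1L])] <- TRUE
    v
  }
  basis <- matrix(FALSE, nrow = 0, ncol = nbnd)
  chosen <- list()
  seen_keys <- character(0)
  for (cy in cycles) {
    if (length(chosen) >= rank) break
    key <- paste(sort(cy), collapse = ",")
    if (key %in% seen_keys) next
    v <- to_vec(cy)
    # reduce against current basis
    red <- v
    if (nrow(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ])[1]
        if (red[piv]) red <- xor(red, basis[r, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      # keep basis in row-echelon-ish form: reorder rows by pivot
      basis <- basis[order(apply(basis, 1, function(x) which(x)[1])), , drop = FALSE]
      chosen[[length(chosen) + 1L]] <- cy
      seen_keys <- c(seen_keys, key)
    }
  }
  chosen
}

# atoms that sit in at least one ring
ring_membership <- function(g, rings = NULL) {
  if (is.null(rings)) rings <- sssr(g)
  mem <- rep(FALSE, n_atoms(g))
  for (r in rings) mem[r] <- TRUE
  mem
}

# Kekulize: assign alternating double bonds within the aromatic subgraph
# flagged by the SMILES parser. Backtracking perfect matching over atoms
# that require one in-ring double bond.
kekulize <- function(g) {
  arom_atoms <- which(g$atoms$aromatic)
  if (!length(arom_atoms)) return(g)
  osum <- bond_order_sums(g)
  nb <- adjacency(g)

  has_explicit_double <- vapply(seq_len(n_atoms(g)), function(i) {
    any((g$bonds$a1 == i | g$bonds$a2 == i) & g$bonds$order >= 2L & !g$bonds$arom)
  }, logical(1))

  needs <- vapply(seq_len(n_atoms(g)), function(i) {
    if (!g$atoms$aromatic[i]) return(FALSE)
    el <- g$atoms$element[i]; chg <- g$atoms$charge[i]
    deg <- length(nb[[i]]); hc <- g$atoms$hcount[i]
    if (is.na(hc)) hc <- 0L
    if (has_explicit_double[i]) return(FALSE)
    if (el %in% c("O", "S", "Se")) return(FALSE)
    if (el %in% c("N", "P")) {
      if (chg < 0L) return(FALSE)
      if (chg == 0L) return(deg + hc <= 2L)
      return(deg + hc <= 3L)   # pyridinium-type n+
    }
    if (el == "C" && chg == -1L) return(FALSE)
    TRUE
  }, logical(1))

  arom_bond_idx <- which(g$bonds$arom)
  cand <- lapply(seq_len(n_atoms(g)), function(i) integer(0))
  for (k in arom_bond_idx) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    if (needs[a1] && needs[a2]) {
      cand[[a1]] <- c(cand[[a1]], a2)
      cand[[a2]] <- c(cand[[a2]], a1)
    }
  }
  todo <- which(needs)
  match <- integer(n_atoms(g))  # 0 = unmatched

  solve <- function() {
    un <- todo[match[todo] == 0L]
    if (!length(un)) return(TRUE)
    # pick the unmatched atom with fewest available partners
    avail <- lapply(un, function(i) cand[[i]][match[cand[[i]]] == 0L])
    i <- un[which.min(lengths(avail))]
    opts <- cand[[i]][match[cand[[i]]] == 0L]
    if (!length(opts)) return(FALSE)
    for (j in opts) {
      match[i] <<- j; match[j] <<- i
      if (solve()) return(TRUE)
      match[i] <<- 0L; match[j] <<- 0L
    }
    FALSE
  }
  if (!solve()) stop("kekulization failed: cannot assign alternating bonds")

  for (k in arom_bond_idx) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    g$bonds$order[k] <- if (match[a1] == a2) 2L else 1L
  }
  g
}

#' Perceive aromaticity
#'
#' Recomputes the per-atom and per-bond aromatic flags from the kekulized
#' graph under the package's single aromaticity model (simple Hueckel count
#' over SSSR rings). Called by the parser and after any bond-rearranging
#' stage so that ring-count comparisons are always made under one model.
#'
#' @param g mol_graph
#' @return mol_graph with refreshed aromatic flags
#' @export
perceive_aromaticity <- function(g) {
  rings <- sssr(g)
  g$atoms$aromatic <- FALSE
  g$bonds$arom <- FALSE
  if (!length(rings)) return(g)
  inring <- ring_membership(g, rings)
  for (cy in rings) {
    if (length(cy) < 5L) next
    total <- 0L; ok <- TRUE
    for (a in cy) {
      contrib <- pi_contribution(g, a, inring)
      if (is.na(contrib)) { ok <- FALSE; break }
      total <- total + contrib
    }
    if (ok && total %% 4L == 2L) {
      g$atoms$aromatic[cy] <- TRUE
      m <- length(cy)
      for (i in seq_len(m)) {
        k <- bond_index(g, cy[i], cy[i %% m + 1L])
        if (k > 0L) g$bonds$arom[k] <- TRUE
      }
    }
  }
  g
}

# Electrons one atom contributes to a candidate aromatic ring; NA = cannot
# take part in an aromatic system.
pi_contribution <- function(g, a, inring) {
  el <- g$atoms$element[a]; chg <- g$atoms$charge[a]
  dbl <- which((g$bonds$a1 == a | g$bonds$a2 == a) & g$bonds$order == 2L)
  if (length(dbl)) {
    partners <- ifelse(g$bonds$a1[dbl] == a, g$bonds$a2[dbl], g$bonds$a1[dbl])
    if (any(inring[partners])) return(1L)
    return(0L)  # exocyclic double bond (e.g. ring C=O)
  }
  if (el %in% c("N", "P") && chg <= 0L) return(2L)
  if (el %in% c("O", "S", "Se") && chg == 0L) return(2L)
  if (el == "C" && chg == -1L) return(2L)
  if (el == "C" && chg == 1L) return(0L)
  NA_integer_
}

#' Count aromatic rings
#'
#' SSSR-based count under the package's aromaticity model.
#' @param g mol_graph
#' @return integer
#' @export
count_aromatic_rings <- function(g) {
  g <- perceive_aromaticity(g)
  rings <- sssr(g)
  n <- 0L
  for (cy in rings) {
    m <- length(cy)
    all_arom <- all(g$atoms$aromatic[cy]) && all(vapply(seq_len(m), function(i) {
      k <- bond_index(g, cy[i], cy[i %% m + 1L])
      k > 0L && g$bonds$arom[k]
    }, logical(1)))
    if (all_arom) n <- n + 1L
  }
  n
}
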