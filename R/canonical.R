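# Morgan-style canonicalization: iterative neighborhood refinement with
# branching tie-breaks. Canonical ranks drive both the canonical key (a
# Kekule-independent serialization used for deduplication) and the canonical
# SMILES writer. Symmetry classes (refinement without tie-breaking) decide
# substituent distinctness for stereocenter perception.

initial_invariants <- function(g) {
  inring <- ring_membership(g)
  deg <- lengths(adjacency(g))
  paste(atomic_number(g$atoms$element), g$atoms$charge, g$atoms$hcount,
        deg, as.integer(g$atoms$aromatic), g$atoms$isotope, as.integer(inring),
        sep = ":")
}

rank_codes <- function(codes) match(codes, sort(unique(codes)))

refine_ranks <- function(g, ranks) {
  nb <- adjacency(g)
  bond_label <- function(k) if (g$bonds$arom[k]) "a" else as.character(g$bonds$order[k])
  # per-atom list of (bond label, neighbor) pairs, bond indices cached
  inc <- vector("list", n_atoms(g))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]; lb <- bond_label(k)
      inc[[a1]] <- c(inc[[a1]], list(c(lb, a2)))
      inc[[a2]] <- c(inc[[a2]], list(c(lb, a1)))
    }
  }
  repeat {
    # zero-padded ranks keep the refinement order-preserving (lexicographic
    # comparison == numeric comparison), which guarantees termination
    codes <- vapply(seq_len(n_atoms(g)), function(i) {
      nbc <- vapply(inc[[i]],
                    function(p) sprintf("%s.%06d", p[1], ranks[as.integer(p[2])]),
                    character(1))
      sprintf("%06d;%s", ranks[i], paste(sort(nbc), collapse = "|"))
    }, character(1))
    new_ranks <- rank_codes(codes)
    if (identical(new_ranks, ranks)) return(ranks)
    ranks <- new_ranks
  }
}

#' Symmetry classes of atoms
#'
#' Atoms sharing a class are indistinguishable under iterative neighborhood
#' refinement (constitutionally equivalent for all practical purposes at
#' drug-like sizes). Used to decide whether a tetrahedral atom or double bond
#' is stereogenic.
#' @param g mol_graph
#' @return integer vector of class labels
#' @export
symmetry_classes <- function(g) {
  refine_ranks(g, rank_codes(initial_invariants(g)))
}

# Canonical ranks: refinement plus branching tie-breaks, minimizing the
# canonical serialization. Returns the rank vector of the best leaf.
canonical_ranks <- function(g, max_leaves = 64L) {
  best <- new.env(parent = emptyenv())
  best$key <- NULL; best$ranks <- NULL; best$leaves <- 0L

  recurse <- function(ranks) {
    ranks <- refine_ranks(g, ranks)
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    if (!length(tied)) {
      key <- serialize_graph(g, ranks)
      if (is.null(best$key) || key < best$key) { best$key <- key; best$ranks <- ranks }
      best$leaves <- best$leaves + 1L
      return(invisible(NULL))
    }
    cls <- min(tied)
    members <- which(ranks == cls)
    if (best$leaves >= max_leaves) members <- members[1]
    for (a in members) {
      # drop atom a strictly below the rest of its tied class
      codes <- sprintf("%09d", ranks * 2L)
      codes[a] <- sprintf("%09d", ranks[a] * 2L - 1L)
      recurse(rank_codes(codes))
      if (best$leaves >= max_leaves && !is.null(best$key)) break
    }
  }
  recurse(rank_codes(initial_invariants(g)))
  best$ranks
}

#' Canonical key of a molecular graph
#'
#' A string equal for graphs identical up to atom renumbering (and up to the
#' choice of Kekule structure for aromatic systems) and distinct for graphs
#' differing in connectivity, charge, hydrogen count, or stereo assignment.
#' Used to deduplicate enumerated variants.
#'
#' @param g mol_graph
#' @return character scalar
#' @export
canonical_key <- function(g) {
  if (!inherits(g, "mol_graph")) stop("canonical_key() needs a mol_graph")
  serialize_graph(g, canonical_ranks(g))
}

# Deterministic DFS serialization given a complete rank ordering.
# Atom token: [Z,charge,hcount,aromatic,parity*]; bond labels 'a' for
# perceived-aromatic bonds, else the integer order. Tetrahedral parity is
# normalized to the written neighbor order; double-bond stereo is appended
# as a suffix keyed by visit positions with references normalized to the
# lowest-position neighbor on each end.
serialize_graph <- function(g, ranks) {
  plan <- dfs_plan(g, ranks)
  pos <- integer(n_atoms(g)); pos[plan$order] <- seq_along(plan$order)

  token <- function(i) {
    par_sym <- ""
    if (g$atoms$parity[i] != 0L) {
      p <- normalized_parity(g, i, plan$nbr_order[[i]])
      par_sym <- if (p == 1L) "@" else if (p == 2L) "@@" else ""
    }
    paste0("[", atomic_number(g$atoms$element[i]), ",", g$atoms$charge[i], ",",
           g$atoms$hcount[i], ",", as.integer(g$atoms$aromatic[i]), par_sym, "]")
  }
  bond_lab <- function(k) {
    if (k == 0L) "" else if (g$bonds$arom[k]) "a" else as.character(g$bonds$order[k])
  }
  emit <- function(u) {
    out <- token(u)
    for (cl in plan$closures[[u]]) {
      out <- paste0(out, bond_lab(cl$bond), "%", cl$digit)
    }
    kids <- plan$children[[u]]
    if (length(kids)) {
      for (j in seq_along(kids)) {
        v <- kids[j]
        piece <- paste0(bond_lab(bond_index(g, u, v)), emit(v))
        out <- if (j < length(kids)) paste0(out, "(", piece, ")")
               else paste0(out, piece)
      }
    }
    out
  }
  body <- paste(vapply(plan$roots, emit, character(1)), collapse = ".")

  st <- character(0)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      if (g$bonds$stereo[k] %in% c("cis", "trans")) {
        a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
        norm <- normalize_db_stereo(g, k, pos)
        if (is.null(norm)) next
        p1 <- pos[a1]; p2 <- pos[a2]
        st <- c(st, paste0(min(p1, p2), "-", max(p1, p2), ":", norm))
      }
    }
  }
  if (length(st)) body <- paste0(body, "|", paste(sort(st), collapse = ","))
  body
}

# Re-express a cis/trans annotation relative to the lowest-position neighbor
# on each end. Returns "cis"/"trans" or NULL when references are missing.
normalize_db_stereo <- function(g, k, pos) {
  a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
  s1 <- g$bonds$sref1[k]; s2 <- g$bonds$sref2[k]
  if (s1 == 0L || s2 == 0L) return(NULL)
  nb <- adjacency(g)
  n1 <- setdiff(nb[[a1]], a2); n2 <- setdiff(nb[[a2]], a1)
  if (!length(n1) || !length(n2)) return(NULL)
  c1 <- n1[which.min(pos[n1])]; c2 <- n2[which.min(pos[n2])]
  rel <- g$bonds$stereo[k]
  if (c1 != s1) rel <- flip_rel(rel)
  if (c2 != s2) rel <- flip_rel(rel)
  rel
}

flip_rel <- function(rel) if (rel == "cis") "trans" else "cis"

# Parity of atom i re-expressed in the written neighbor order `out_order`
# (0 denotes the implicit-hydrogen slot). Returns 0 when the reference order
# is unusable.
normalized_parity <- function(g, i, out_order) {
  p <- g$atoms$parity[i]
  ref <- g$chiral_order[[i]]
  if (p == 0L || is.null(ref) || length(ref) < 3L) return(0L)
  if (length(ref) != length(out_order)) {
    # implicit-H slot may be absent from one of the two orders
    if (length(ref) == length(out_order) + 1L && 0L %in% ref && !0L %in% out_order) {
      out_order <- c(out_order[1], 0L, out_order[-1])
    } else if (length(out_order) == length(ref) + 1L && 0L %in% out_order && !0L %in% ref) {
      ref <- c(ref[1], 0L, ref[-1])
    } else return(0L)
  }
  if (!setequal(ref, out_order)) return(0L)
  perm <- match(out_order, ref)
  if (anyNA(perm)) return(0L)
  if (permutation_is_even(perm)) p else (3L - p)
}

permutation_is_even <- function(perm) {
  inv <- 0L
  n <- length(perm)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) if (perm[i] > perm[j]) inv <- inv + 1L
  inv %% 2L == 0L
}

# DFS plan shared by the serializer and the SMILES writer: visit order,
# children per atom (sorted by rank), ring-closure records and the written
# neighbor order per atom (parent, implicit-H slot, closures, children).
dfs_plan <- function(g, ranks) {
  n <- n_atoms(g)
  nb <- adjacency(g)
  visited <- rep(FALSE, n)
  parent <- integer(n)
  children <- vector("list", n)
  closures <- vector("list", n)  # each: list(partner, digit, bond)
  for (i in seq_len(n)) closures[[i]] <- list()
  order <- integer(0)
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(u, v) paste(min(u, v), max(u, v))
  digit_counter <- 0L
  free_digits <- integer(0)

  visit <- function(u, par) {
    visited[u] <<- TRUE
    parent[u] <<- par
    order <<- c(order, u)
    nbrs <- setdiff(nb[[u]], par)
    nbrs <- nbrs[order(ranks[nbrs])]
    kids <- integer(0)
    for (v in nbrs) {
      k <- ekey(u, v)
      if (!is.null(edge_used[[k]])) next
      if (visited[v]) {
        edge_used[[k]] <- TRUE
        if (length(free_digits)) {
          d <- free_digits[1]; free_digits <<- free_digits[-1]
        } else { digit_counter <<- digit_counter + 1L; d <- digit_counter }
        b <- bond_index(g, u, v)
        closures[[u]] <<- c(closures[[u]], list(list(partner = v, digit = d, bond = b)))
        closures[[v]] <<- c(closures[[v]], list(list(partner = u, digit = d, bond = b)))
      } else {
        edge_used[[k]] <- TRUE
        kids <- c(kids, v)
        visit(v, u)
      }
    }
    children[[u]] <<- kids
  }

  roots <- integer(0)
  comp <- graph_components(g)
  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    root <- members[which.min(ranks[members])]
    roots <- c(roots, root)
    visit(root, 0L)
  }

  nbr_order <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- integer(0)
    if (parent[i] > 0L) ord <- c(ord, parent[i])
    if (g$atoms$hcount[i] > 0L && g$atoms$parity[i] != 0L) ord <- c(ord, 0L)
    for (cl in closures[[i]]) ord <- c(ord, cl$partner)
    ord <- c(ord, children[[i]])
    nbr_order[[i]] <- ord
  }
  list(order = order, roots = roots, parent = parent, children = children,
       closures = closures, nbr_order = nbr_order)
}
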