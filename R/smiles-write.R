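# Kekule SMILES writer. Output is plain uppercase SMILES with explicit
# double/triple bonds, bracket atoms where charge / hydrogen count / isotope /
# chirality require them, and directional bonds for double-bond stereo.
# Canonical atom ordering (Morgan ranks) makes the output deterministic.

#' Write a SMILES string
#'
#' @param g mol_graph
#' @param canonical order atoms canonically (default) or by index.
#' @param with_stereo include tetrahedral and double-bond stereo.
#' @return character scalar SMILES
#' @export
write_smiles <- function(g, canonical = TRUE, with_stereo = TRUE) {
  smiles_with_order(g, canonical, with_stereo)$smiles
}

# Returns list(smiles, order): `order` is the atom visit order, i.e. the
# atom index (into g) of the 1st, 2nd, ... atom of the written SMILES. The
# geometry backend relies on this to map conformer coordinates back onto
# graph atoms.
smiles_with_order <- function(g, canonical = TRUE, with_stereo = TRUE) {
  ranks <- if (canonical) canonical_ranks(g) else seq_len(n_atoms(g))
  plan <- dfs_plan(g, ranks)
  dirmap <- if (with_stereo) assign_bond_directions(g) else list()

  osum <- bond_order_sums(g)
  atom_token <- function(i) {
    el <- g$atoms$element[i]
    chg <- g$atoms$charge[i]
    iso <- g$atoms$isotope[i]
    hc <- g$atoms$hcount[i]
    par <- if (with_stereo) normalized_parity(g, i, plan$nbr_order[[i]]) else 0L
    plain_ok <- el %in% ORGANIC_SUBSET && chg == 0L && iso == 0L && par == 0L &&
      hc == implied_hcount(el, 0L, osum[i])
    if (plain_ok) return(el)
    tok <- "["
    if (iso > 0L) tok <- paste0(tok, iso)
    tok <- paste0(tok, el)
    if (par == 1L) tok <- paste0(tok, "@")
    if (par == 2L) tok <- paste0(tok, "@@")
    if (hc == 1L) tok <- paste0(tok, "H")
    if (hc > 1L) tok <- paste0(tok, "H", hc)
    if (chg != 0L) {
      tok <- paste0(tok, if (chg > 0L) "+" else "-",
                    if (abs(chg) > 1L) abs(chg) else "")
    }
    paste0(tok, "]")
  }

  bond_sym <- function(u, v) {
    k <- bond_index(g, u, v)
    if (k == 0L) return("")
    o <- g$bonds$order[k]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    d <- dirmap[[dir_key(u, v)]]
    if (!is.null(d)) {
      # d is the ascent direction for min(u,v) -> max(u,v); written u -> v
      asc <- if (u < v) d else -d
      return(if (asc > 0L) "/" else "\\")
    }
    ""
  }

  emit <- function(u) {
    out <- atom_token(u)
    for (cl in plan$closures[[u]]) {
      dg <- if (cl$digit > 9L) paste0("%", cl$digit) else as.character(cl$digit)
      out <- paste0(out, bond_sym(u, cl$partner), dg)
    }
    kids <- plan$children[[u]]
    for (j in seq_along(kids)) {
      v <- kids[j]
      piece <- paste0(bond_sym(u, v), emit(v))
      out <- if (j < length(kids)) paste0(out, "(", piece, ")")
             else paste0(out, piece)
    }
    out
  }
  smiles <- paste(vapply(plan$roots, emit, character(1)), collapse = ".")
  list(smiles = smiles, order = plan$order)
}

dir_key <- function(u, v) paste(min(u, v), max(u, v))

# Choose ascent directions (+1 / -1, stored for min(u,v) -> max(u,v)) for the
# single bonds flanking stereo double bonds. Equal n->a ascent on both ends
# encodes cis references, opposite encodes trans. Shared single bonds between
# conjugated stereo bonds are propagated; a genuine conflict drops the later
# bond's annotation with a warning.
assign_bond_directions <- function(g) {
  dirmap <- list()
  if (!nrow(g$bonds)) return(dirmap)
  set_dir <- function(n, a, d) {
    # d is ascent n -> a; store relative to min -> max
    key <- dir_key(n, a)
    stored <- if (n < a) d else -d
    if (!is.null(dirmap[[key]]) && dirmap[[key]] != stored) return(FALSE)
    dirmap[[key]] <<- stored
    TRUE
  }
  get_dir <- function(n, a) {
    key <- dir_key(n, a)
    if (is.null(dirmap[[key]])) return(0L)
    if (n < a) dirmap[[key]] else -dirmap[[key]]
  }
  for (k in seq_len(nrow(g$bonds))) {
    if (!g$bonds$stereo[k] %in% c("cis", "trans")) next
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    s1 <- g$bonds$sref1[k]; s2 <- g$bonds$sref2[k]
    if (s1 == 0L || s2 == 0L) next
    d1 <- get_dir(s1, a1)
    if (d1 == 0L) { d1 <- 1L; set_dir(s1, a1, d1) }
    d2 <- if (g$bonds$stereo[k] == "cis") d1 else -d1
    if (!set_dir(s2, a2, d2)) {
      warning("conflicting double-bond stereo annotations; dropping one")
    }
  }
  dirmap
}
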