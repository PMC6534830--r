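# Stereocenter / stereobond perception and enumeration. Unspecified
# tetrahedral centers are varied over both parities; unspecified stereogenic
# double bonds over cis and trans. Specified stereo is never touched.

#' Potential tetrahedral stereocenters
#'
#' Carbon (and silicon) atoms with four substituents -- counting at most one
#' implicit hydrogen -- whose substituents fall in pairwise-distinct symmetry
#' classes. Includes both assigned and assignable centers.
#' @param g mol_graph
#' @return integer vector of atom indices
#' @export
potential_stereocenters <- function(g) {
  nb <- adjacency(g)
  cls <- symmetry_classes(g)
  out <- integer(0)
  for (i in seq_len(n_atoms(g))) {
    if (!g$atoms$element[i] %in% c("C", "Si")) next
    if (g$atoms$aromatic[i]) next
    deg <- length(nb[[i]]); hc <- g$atoms$hcount[i]
    if (deg + hc != 4L || hc > 1L) next
    if (any(g$bonds$order[g$bonds$a1 == i | g$bonds$a2 == i] > 1L)) next
    ncls <- cls[nb[[i]]]
    if (anyDuplicated(ncls)) next
    out <- c(out, i)
  }
  out
}

#' Stereogenic double bonds
#'
#' Non-aromatic double bonds whose two ends each carry distinguishable
#' substituents. Bonds inside rings smaller than `min_ring` atoms are
#' excluded (geometrically forced cis).
#' @param g mol_graph
#' @param min_ring smallest ring size whose internal double bonds are
#'   considered stereogenic (default 8).
#' @return integer vector of bond indices
#' @export
stereogenic_double_bonds <- function(g, min_ring = 8L) {
  if (!nrow(g$bonds)) return(integer(0))
  nb <- adjacency(g)
  cls <- symmetry_classes(g)
  rings <- sssr(g)
  in_small_ring <- function(k) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    for (cy in rings) {
      if (length(cy) < min_ring && a1 %in% cy && a2 %in% cy) return(TRUE)
    }
    FALSE
  }
  end_ok <- function(a, partner) {
    others <- setdiff(nb[[a]], partner)
    hc <- g$atoms$hcount[a]
    if (length(others) + hc != 2L) return(FALSE)  # allenes/cumulenes out of scope
    if (length(others) == 2L) return(cls[others[1]] != cls[others[2]])
    length(others) == 1L && hc == 1L  # substituent vs H; =CH2 is not stereogenic
  }
  out <- integer(0)
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != 2L || g$bonds$arom[k]) next
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    if (!g$atoms$element[a1] %in% c("C", "N") ||
        !g$atoms$element[a2] %in% c("C", "N")) next
    if (in_small_ring(k)) next
    if (end_ok(a1, a2) && end_ok(a2, a1)) out <- c(out, k)
  }
  out
}

#' Enumerate unspecified tetrahedral stereocenters
#'
#' Cartesian product of both parities over every unspecified center;
#' explicitly assigned centers are left untouched. Duplicate forms (meso
#' compounds) are removed by canonical key.
#'
#' @param g mol_graph
#' @param parent_id identifier recorded on the emitted variants.
#' @return list of [variant()]s (a single identity variant when nothing is
#'   enumerable)
#' @export
enumerate_chiral <- function(g, parent_id = "") {
  centers <- potential_stereocenters(g)
  centers <- centers[g$atoms$parity[centers] == 0L]
  centers <- sort(centers)  # fixed enumeration order: atom index
  if (!length(centers)) return(list(variant(parent_id, g)))
  nb <- adjacency(g)
  out <- list()
  combos <- expand.grid(rep(list(1:2), length(centers)))
  for (r in seq_len(nrow(combos))) {
    g2 <- g
    for (j in seq_along(centers)) {
      a <- centers[j]
      g2$atoms$parity[a] <- as.integer(combos[r, j])
      ord <- sort(nb[[a]])
      if (g2$atoms$hcount[a] > 0L) ord <- c(ord, 0L)
      g2$chiral_order[[a]] <- ord
    }
    detail <- paste(sprintf("atom%d:%s", centers,
                            ifelse(unlist(combos[r, ]) == 1L, "@", "@@")),
                    collapse = " ")
    v <- variant(parent_id, g2)
    v <- add_provenance(v, "chirality", detail)
    out[[length(out) + 1L]] <- v
  }
  dedupe_variants(out)
}

#' Enumerate unspecified cis/trans double-bond isomers
#'
#' Cartesian product of cis and trans over every unspecified stereogenic
#' double bond; explicitly specified bonds are left untouched.
#'
#' @inheritParams enumerate_chiral
#' @return list of [variant()]s
#' @export
enumerate_cis_trans <- function(g, parent_id = "") {
  bnds <- stereogenic_double_bonds(g)
  bnds <- bnds[g$bonds$stereo[bnds] == "none"]
  bnds <- sort(bnds)  # fixed enumeration order: bond index
  if (!length(bnds)) return(list(variant(parent_id, g)))
  nb <- adjacency(g)
  out <- list()
  combos <- expand.grid(rep(list(c("cis", "trans")), length(bnds)),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    g2 <- g
    for (j in seq_along(bnds)) {
      k <- bnds[j]
      a1 <- g2$bonds$a1[k]; a2 <- g2$bonds$a2[k]
      o1 <- setdiff(nb[[a1]], a2); o2 <- setdiff(nb[[a2]], a1)
      g2$bonds$sref1[k] <- min(o1)
      g2$bonds$sref2[k] <- min(o2)
      g2$bonds$stereo[k] <- combos[r, j]
    }
    detail <- paste(sprintf("bond%d:%s", bnds, unlist(combos[r, ])), collapse = " ")
    v <- variant(parent_id, g2)
    v <- add_provenance(v, "cis_trans", detail)
    out[[length(out) + 1L]] <- v
  }
  dedupe_variants(out)
}

#' Approximate R/S label for an assigned tetrahedral center
#'
#' Substituent priorities use atomic number with Morgan-rank tie-breaking
#' (implicit hydrogen lowest) -- a CIP approximation that is exact for simple
#' centers without like-element priority subtleties.
#'
#' @param g mol_graph
#' @param atom index of an atom with assigned parity
#' @return "R", "S", or NA when no parity is assigned
#' @export
cip_label <- function(g, atom) {
  p <- g$atoms$parity[atom]
  ref <- g$chiral_order[[atom]]
  if (p == 0L || is.null(ref)) return(NA_character_)
  # priority: implicit H (0) lowest; otherwise atomic number then a rank of
  # the neighbor's environment (heavier environments first)
  cls <- refine_ranks(g, rank_codes(vapply(seq_len(n_atoms(g)), function(i) {
    sprintf("%03d:%+03d:%d", atomic_number(g$atoms$element[i]),
            g$atoms$charge[i], g$atoms$hcount[i])
  }, character(1))))
  pr <- vapply(ref, function(x) if (x == 0L) -1 else
               atomic_number(g$atoms$element[x]) * 1e6 + cls[x], numeric(1))
  # order neighbors by decreasing priority; view from highest, ask whether
  # remaining three descend clockwise (R) or counterclockwise (S)
  ord <- order(-pr)
  perm <- match(ref[ord], ref)
  # parity flips with odd permutations of the reference order
  p_sorted <- if (permutation_is_even(perm)) p else 3L - p
  # In the sorted frame (highest first), '@' (=1) means the 2nd..4th run
  # counterclockwise when viewed from the 1st (highest); CIP views from the
  # side OPPOSITE the lowest. With priorities sorted descending, '@@' = R.
  if (p_sorted == 2L) "R" else "S"
}
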