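# Desalting: multi-fragment inputs are reduced to the presumed compound of
# interest -- the fragment with the most heavy atoms. Ties fall back to
# molecular weight, then to canonical key, so output is deterministic.

#' Desalt a molecular graph
#'
#' Keeps the largest connected component (most heavy atoms; ties broken by
#' molecular weight, then lowest canonical key). The number of removed
#' fragments is attached as attribute `removed_fragments`.
#'
#' @param g mol_graph with at least one atom.
#' @return single-fragment mol_graph
#' @export
desalt <- function(g) {
  if (!inherits(g, "mol_graph") || is.null(g$atoms) || nrow(g$atoms) == 0L)
    stop("desalt: empty graph")
  comp <- graph_components(g)
  ncomp <- max(comp)
  if (ncomp == 1L) {
    attr(g, "removed_fragments") <- 0L
    return(g)
  }
  frags <- lapply(seq_len(ncomp), function(ci) subgraph(g, which(comp == ci)))
  heavies <- vapply(frags, heavy_atom_count, numeric(1))
  cand <- which(heavies == max(heavies))
  if (length(cand) > 1L) {
    mws <- vapply(frags[cand], mol_weight, numeric(1))
    cand <- cand[mws == max(mws)]
  }
  if (length(cand) > 1L) {
    keys <- vapply(frags[cand], canonical_key, character(1))
    cand <- cand[order(keys)][1]
  }
  out <- frags[[cand[1]]]
  attr(out, "removed_fragments") <- ncomp - 1L
  out
}
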