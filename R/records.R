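# Domain types shared by every pipeline stage: input records, enumerated
# variants with provenance, and 3D conformers.

PROVENANCE_STAGES <- c("desalt", "ionize", "tautomerize", "chirality",
                       "cis_trans", "ring_conformer", "optimize")

#' Create an input molecule record
#'
#' @param identifier compound name (non-empty); auto-generated from
#'   `source_index` when missing.
#' @param smiles SMILES string as read from the input file.
#' @param source_index 0-based position in the input file.
#' @param graph parsed [mol_graph()] or NULL for failed records.
#' @param failed TRUE when the input could not be parsed.
#' @param reason parse-failure message.
#' @return object of class `molecule_record`
#' @export
molecule_record <- function(identifier, smiles, source_index,
                            graph = NULL, failed = FALSE, reason = NA_character_) {
  if (is.null(identifier) || !nzchar(identifier))
    identifier <- sprintf("mol_%d", source_index)
  structure(list(identifier = identifier, smiles = smiles,
                 source_index = as.integer(source_index),
                 graph = graph, failed = isTRUE(failed), reason = reason),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s (%s)%s\n", x$identifier, x$smiles,
              if (x$failed) paste0(" FAILED: ", x$reason) else ""))
  invisible(x)
}

#' Create a provenance step
#' @param stage one of desalt, ionize, tautomerize, chirality, cis_trans,
#'   ring_conformer, optimize.
#' @param detail free-text description of what the stage did.
#' @return list with class `provenance_step`
#' @export
provenance_step <- function(stage, detail = "") {
  stage <- match.arg(stage, PROVENANCE_STAGES)
  structure(list(stage = stage, detail = detail), class = "provenance_step")
}

#' Create a molecular variant
#'
#' An enumerated form of an input compound: molecular graph plus the ordered
#' provenance of the steps that produced it, and (once embedded) a 3D
#' conformer with a force-field energy.
#'
#' @param parent_id identifier of the input record.
#' @param graph [mol_graph()]
#' @param provenance list of [provenance_step()]s.
#' @param energy force-field energy (kcal/mol) or NA.
#' @param conformer [conformer3d()] or NULL.
#' @return object of class `variant`
#' @export
variant <- function(parent_id, graph, provenance = list(),
                    energy = NA_real_, conformer = NULL) {
  structure(list(parent_id = parent_id, graph = graph,
                 provenance = provenance, energy = energy,
                 conformer = conformer, key = NULL),
            class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  steps <- vapply(x$provenance, function(s) s$stage, character(1))
  cat(sprintf("<variant> parent=%s formula=%s steps=[%s]%s\n", x$parent_id,
              molecular_formula(x$graph), paste(steps, collapse = ","),
              if (!is.na(x$energy)) sprintf(" E=%.2f", x$energy) else ""))
  invisible(x)
}

add_provenance <- function(v, stage, detail = "") {
  v$provenance <- c(v$provenance, list(provenance_step(stage, detail)))
  v
}

# Cached canonical key on a variant (graphs are immutable once wrapped).
variant_key <- function(v) {
  if (is.null(v$key)) v$key <- canonical_key(v$graph)
  v$key
}

# Deduplicate a list of variants by canonical key, keeping first occurrence.
dedupe_variants <- function(variants) {
  keys <- vapply(variants, function(v) variant_key(v), character(1))
  variants[!duplicated(keys)]
}

#' Create a 3D conformer
#'
#' @param coords numeric matrix (n x 3), one row per atom in Angstroms. Rows
#'   1..heavy follow the graph's atom order; hydrogen rows follow.
#' @param elements element symbol per row.
#' @param h_parent for hydrogen rows, the (graph) index of the bonded heavy
#'   atom; 0 for heavy-atom rows.
#' @param energy force-field energy (kcal/mol).
#' @param optimized TRUE when geometry-optimized.
#' @return object of class `conformer3d`
#' @export
conformer3d <- function(coords, elements, h_parent, energy, optimized = FALSE) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elements),
            length(h_parent) == length(elements))
  if (!all(is.finite(coords))) stop("conformer coordinates must be finite")
  structure(list(coords = coords, elements = elements,
                 h_parent = as.integer(h_parent),
                 energy = as.numeric(energy), optimized = isTRUE(optimized)),
            class = "conformer3d")
}

#' Count assigned plus assignable tetrahedral stereocenters
#'
#' A tetrahedral atom counts when its substituents (including an implicit
#' hydrogen) fall in pairwise-distinct symmetry classes -- i.e. both centers
#' already carrying a configuration and centers that could carry one.
#' @param g mol_graph
#' @return integer
#' @export
count_chiral_centers <- function(g) length(potential_stereocenters(g))
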