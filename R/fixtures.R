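# Deterministic fixture molecules: the named demonstration compounds that
# exercise every pipeline stage, plus a synthetic library generator for
# stress/benchmark-style inputs. No downloads required.

FIXTURE_SMILES <- c(
  "oseltamivir-carboxylate" = "CCC(CC)O[C@@H]1C=C(C(=O)O)C[C@@H](N)[C@H]1NC(C)=O",
  "butan-2-one" = "CCC(C)=O",
  "bromochlorofluoroiodomethane" = "FC(Cl)(Br)I",
  "1-bromo-2-chloro-2-fluoro-1-iodoethene" = "ClC(F)=C(Br)I",
  "cis-1,4-di-tert-butylcyclohexane" = "CC(C)(C)[C@H]1CC[C@@H](C(C)(C)C)CC1",
  "propan-1-ol" = "CCCO",
  "folic-acid" = "Nc1nc2ncc(CNc3ccc(C(=O)N[C@@H](CCC(=O)O)C(=O)O)cc3)nc2c(=O)[nH]1"
)

#' Named demonstration molecules
#'
#' Seven compounds covering every stage: a carboxylic acid that deprotonates
#' at physiological pH (oseltamivir carboxylate), a ketone with an internal
#' enol (butan-2-one), a one-stereocenter halomethane, an unspecified
#' cis/trans alkene, a cyclohexane whose cis-1,4 substituents favor the
#' twist-boat, a featureless alcohol (exactly one output model), and folic
#' acid (fused heteroaromatics plus two acids).
#'
#' @return list of 7 [molecule_record()]s with stable identifiers
#' @export
example_molecules <- function() {
  out <- vector("list", length(FIXTURE_SMILES))
  for (i in seq_along(FIXTURE_SMILES)) {
    out[[i]] <- molecule_record(names(FIXTURE_SMILES)[i], FIXTURE_SMILES[[i]],
                                i - 1L, graph = parse_smiles(FIXTURE_SMILES[[i]]))
  }
  out
}

# building blocks for the synthetic library: scaffolds carrying specific
# features, combined constructively so requested fractions hold exactly
SYNTH_CORES <- c("CCO", "CCC", "CCN", "CCCC", "CC(C)C", "CCOC", "CCCN", "CCS")
SYNTH_IONIZABLE <- c("CC(=O)O", "CCC(=O)O", "NCC", "NCCC", "Oc1ccccc1", "CCN(C)C")
SYNTH_STEREO <- c("CC(N)C(=O)O", "CC(O)CC", "CC(F)CCO", "CC(Cl)CC")
SYNTH_RING <- c("C1CCCCC1", "C1CCCC1", "C1CCOCC1", "CC1CCCCC1", "OC1CCCCC1")
SYNTH_IONS <- c("[Na+]", "Cl", "[K+]", "Br")

#' Generate a synthetic molecule library
#'
#' Constructive generation (not rejection sampling): the requested feature
#' fractions are met exactly. Deterministic under the seed.
#'
#' @param n number of records (>= 1)
#' @param seed RNG seed
#' @param frac_ionizable fraction with an ionizable group
#' @param frac_stereo fraction with an unspecified stereocenter
#' @param frac_ring fraction with a non-aromatic ring
#' @param frac_salt fraction written as multi-fragment salts
#' @return list of n [molecule_record()]s
#' @export
synthetic_library <- function(n, seed = 1L, frac_ionizable = 0.3,
                              frac_stereo = 0.2, frac_ring = 0.2,
                              frac_salt = 0.1) {
  stopifnot(n >= 1)
  counts <- c(ion = floor(n * frac_ionizable), st = floor(n * frac_stereo),
              ring = floor(n * frac_ring))
  n_salt <- floor(n * frac_salt)
  feats <- c(rep("ion", counts["ion"]), rep("st", counts["st"]),
             rep("ring", counts["ring"]))
  feats <- c(feats, rep("plain", n - length(feats)))
  with_rng(derive_seed(seed, "synthlib"), {
    feats <- sample(feats)
    salt_idx <- sample.int(n, n_salt)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      base <- switch(feats[i],
        ion = sample(SYNTH_IONIZABLE, 1),
        st = sample(SYNTH_STEREO, 1),
        ring = sample(SYNTH_RING, 1),
        plain = sample(SYNTH_CORES, 1))
      if (i %in% salt_idx) base <- paste0(base, ".", sample(SYNTH_IONS, 1))
      out[[i]] <- molecule_record(sprintf("synth_%04d", i), base, i - 1L,
                                  graph = parse_smiles(base))
    }
    out
  })
}

#' Write records to a .smi file
#' @param records list of [molecule_record()]s
#' @param path output path
#' @return invisibly, the path
#' @export
write_smiles_file <- function(records, path) {
  writeLines(vapply(records, function(r) paste(r$smiles, r$identifier),
                    character(1)), path)
  invisible(path)
}
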