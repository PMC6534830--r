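#' @keywords internal
"_PACKAGE"

# Atomic data used across the package. Weights are IUPAC 2021 abridged values;
# default valences follow the SMILES organic-subset rules.
PERIODIC <- list(
  number = c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
             Cl = 17L, Br = 35L, I = 53L, Si = 14L, Se = 34L, Na = 11L, K = 19L,
             Li = 3L, Mg = 12L, Ca = 20L, Zn = 30L, Fe = 26L, Cu = 29L, Mn = 25L,
             As = 33L, Al = 13L),
  weight = c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
             F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
             I = 126.904, Si = 28.085, Se = 78.971, Na = 22.990, K = 39.098,
             Li = 6.94, Mg = 24.305, Ca = 40.078, Zn = 65.38, Fe = 55.845,
             Cu = 63.546, Mn = 54.938, As = 74.922, Al = 26.982)
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Allowed valence states per element (smallest state >= bond-order sum wins).
DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

#' Construct a molecular graph
#'
#' The in-memory molecule representation used by every pipeline stage. Atoms
#' carry element, formal charge, total hydrogen count, an aromaticity flag
#' (perceived, see [perceive_aromaticity()]) and an optional tetrahedral
#' parity; bonds carry integer order (1, 2, 3) plus optional double-bond
#' stereo. Hydrogens are implicit (counts, not nodes); bonds are stored
#' kekulized even for aromatic systems.
#'
#' @param atoms data.frame with columns `element`, `charge`, `hcount`,
#'   `aromatic`, `isotope`, `parity` (0 none/unspecified, 1 = `@`, 2 = `@@`).
#' @param bonds data.frame with columns `a1`, `a2`, `order`, `arom`,
#'   `stereo` ("none", "cis", "trans"), `sref1`, `sref2` (reference neighbor
#'   atoms for cis/trans; 0 when unset).
#' @param chiral_order list indexed by atom: integer vector of neighbor atom
#'   ids in the reference order for that atom's parity (0 = implicit H slot).
#' @return object of class `mol_graph`
#' @export
mol_graph <- function(atoms, bonds, chiral_order = NULL) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  need_a <- c("element", "charge", "hcount", "aromatic", "isotope", "parity")
  for (cc in setdiff(need_a, names(atoms))) {
    atoms[[cc]] <- switch(cc, aromatic = FALSE, element = stop("element required"), 0L)
  }
  need_b <- c("a1", "a2", "order", "arom", "stereo", "sref1", "sref2")
  for (cc in setdiff(need_b, names(bonds))) {
    bonds[[cc]] <- switch(cc, arom = FALSE, stereo = "none", 0L)
  }
  if (is.null(chiral_order)) chiral_order <- vector("list", nrow(atoms))
  g <- structure(list(atoms = atoms[, need_a], bonds = bonds[, need_b],
                      chiral_order = chiral_order),
                 class = "mol_graph")
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds, formula %s\n",
              n_atoms(x), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

#' Number of heavy (non-hydrogen) atoms
#' @param g mol_graph
#' @return integer
#' @export
heavy_atom_count <- function(g) sum(g$atoms$element != "H")

# Neighbor list: for atom i, integer vector of bonded atom ids.
adjacency <- function(g) {
  nb <- vector("list", n_atoms(g))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
      nb[[a1]] <- c(nb[[a1]], a2)
      nb[[a2]] <- c(nb[[a2]], a1)
    }
  }
  nb
}

# index of the bond between atoms i and j (0 if absent)
bond_index <- function(g, i, j) {
  hit <- which((g$bonds$a1 == i & g$bonds$a2 == j) |
               (g$bonds$a1 == j & g$bonds$a2 == i))
  if (length(hit)) hit[1] else 0L
}

# Sum of bond orders incident to each atom.
bond_order_sums <- function(g) {
  s <- numeric(n_atoms(g))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[k]
      s[g$bonds$a1[k]] <- s[g$bonds$a1[k]] + o
      s[g$bonds$a2[k]] <- s[g$bonds$a2[k]] + o
    }
  }
  s
}

# Implied hydrogen count for an organic-subset atom given current bonds and
# charge (SMILES valence model; charge shifts the target valence for N/P up
# and, for O/S/C anions, down).
implied_hcount <- function(element, charge, order_sum) {
  vals <- DEFAULT_VALENCES[[element]]
  if (is.null(vals)) return(0L)
  adj <- 0L
  if (element %in% c("N", "P") && charge > 0) adj <- charge
  if (element %in% c("N", "P") && charge < 0) adj <- charge
  if (element %in% c("O", "S") && charge != 0) adj <- charge
  if (element == "C" && charge != 0) adj <- -abs(charge)
  if (element == "B" && charge < 0) adj <- 1L
  vals <- vals + adj
  for (v in vals) if (order_sum <= v) return(as.integer(v - order_sum))
  0L
}

#' Connected components of a molecular graph
#' @param g mol_graph
#' @return integer vector of component labels (1-based) per atom
#' @export
graph_components <- function(g) {
  n <- n_atoms(g)
  comp <- integer(n)
  nb <- adjacency(g)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# Extract the induced subgraph on a set of atoms (renumbered 1..k in the
# order given). Chiral reference orders and stereo refs are remapped;
# stereo whose reference atoms fall outside the subset is dropped.
subgraph <- function(g, keep) {
  keep <- as.integer(keep)
  map <- integer(n_atoms(g)); map[keep] <- seq_along(keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- g$bonds$a1 %in% keep & g$bonds$a2 %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  rownames(bonds) <- NULL
  if (nrow(bonds)) {
    bonds$a1 <- map[bonds$a1]; bonds$a2 <- map[bonds$a2]
    for (k in seq_len(nrow(bonds))) {
      for (f in c("sref1", "sref2")) {
        r <- bonds[[f]][k]
        if (r > 0L) {
          bonds[[f]][k] <- if (map[r] > 0L) map[r] else 0L
        }
      }
      if (bonds$stereo[k] != "none" && (bonds$sref1[k] == 0L || bonds$sref2[k] == 0L))
        bonds$stereo[k] <- "none"
    }
  }
  ch <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    co <- g$chiral_order[[keep[i]]]
    if (!is.null(co)) {
      co2 <- vapply(co, function(x) if (x == 0L) 0L else map[x], integer(1))
      if (any(co2 == 0L & co != 0L)) {
        atoms$parity[i] <- 0L
      } else {
        ch[[i]] <- co2
      }
    }
  }
  mol_graph(atoms, bonds, ch)
}

#' Net formal charge of a molecule
#'
#' Sum of per-atom formal charges, in units of the elementary charge.
#' @param g mol_graph
#' @return integer
#' @export
net_formal_charge <- function(g) as.integer(sum(g$atoms$charge))

#' Molecular formula (Hill order)
#' @param g mol_graph
#' @return string such as "C4H8O"
#' @export
molecular_formula <- function(g) {
  counts <- table(g$atoms$element)
  cnt <- as.list(counts)
  cnt[["H"]] <- (if (is.null(cnt[["H"]])) 0 else cnt[["H"]]) + sum(g$atoms$hcount)
  els <- names(cnt)
  ord <- if ("C" %in% els) {
    c("C", if (cnt[["H"]] > 0) "H", sort(setdiff(els, c("C", "H"))))
  } else {
    sort(els[vapply(els, function(e) cnt[[e]] > 0, logical(1))])
  }
  paste0(vapply(ord, function(e) {
    k <- cnt[[e]]
    if (k == 0) "" else if (k == 1) e else paste0(e, k)
  }, character(1)), collapse = "")
}

#' Molecular weight (average atomic masses, g/mol)
#' @param g mol_graph
#' @return numeric
#' @export
mol_weight <- function(g) {
  w <- sum(vapply(g$atoms$element, function(e) {
    m <- PERIODIC$weight[[e]]
    if (is.null(m) || is.na(m)) 0 else m
  }, numeric(1)))
  w + sum(g$atoms$hcount) * PERIODIC$weight[["H"]]
}

atomic_number <- function(element) {
  z <- PERIODIC$number[element]
  z[is.na(z)] <- 0L
  as.integer(z)
}
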