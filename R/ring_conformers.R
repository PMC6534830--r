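# Alternate non-aromatic ring conformations. Multiple 3D models are embedded
# and force-field optimized; each model's non-aromatic rings are reduced to a
# ring-conformation fingerprint f_m -- the vector of per-ring minimum RMSDs
# against the first model -- and k-means clustering of the fingerprints picks
# at most max_variants_per_compound geometrically distinct models (cluster
# medoids).

#' Non-aromatic SSSR rings
#'
#' @param g mol_graph
#' @return list of ordered atom-index vectors (possibly empty)
#' @export
extract_nonaromatic_rings <- function(g) {
  g <- perceive_aromaticity(g)
  rings <- sssr(g)
  keep <- list()
  for (cy in rings) {
    m <- length(cy)
    arom <- all(g$atoms$aromatic[cy]) && all(vapply(seq_len(m), function(i) {
      k <- bond_index(g, cy[i], cy[i %% m + 1L])
      k > 0L && g$bonds$arom[k]
    }, logical(1)))
    if (!arom) keep[[length(keep) + 1L]] <- cy
  }
  keep
}

#' Least-squares superposition RMSD (Kabsch)
#'
#' Minimum RMSD between two corresponded coordinate sets when one is free to
#' rotate and translate; closed-form via SVD after centroid alignment.
#'
#' @param c1,c2 numeric matrices (n x 3), positional correspondence.
#' @return RMSD in Angstroms (>= 0)
#' @export
superposition_rmsd <- function(c1, c2) {
  c1 <- as.matrix(c1); c2 <- as.matrix(c2)
  if (!all(dim(c1) == dim(c2)) || ncol(c1) != 3L || nrow(c1) < 3L)
    stop("superposition_rmsd: coordinate sets must be equal-size n x 3, n >= 3")
  p <- sweep(c1, 2, colMeans(c1))
  q <- sweep(c2, 2, colMeans(c2))
  a <- crossprod(p, q)           # 3x3 covariance
  sv <- svd(a)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  ssum <- sv$d[1] + sv$d[2] + d * sv$d[3]
  msd <- (sum(p^2) + sum(q^2) - 2 * ssum) / nrow(p)
  # cancellation noise below (1e-6 A)^2 is numerically indistinguishable
  # from an exact superposition
  if (msd < 1e-12) return(0)
  sqrt(msd)
}

#' Ring-conformation fingerprints
#'
#' For model m with ring geometries `s_m` (an ordered list of per-ring
#' coordinate matrices), the fingerprint is
#' `f_m[r] = RMSD(c_{m,r}, c_{1,r})`; the first model's fingerprint is the
#' zero vector by construction.
#'
#' @param models list of models, each an ordered list of R ring-coordinate
#'   matrices (identical ring order and atom ordering across models).
#' @return numeric matrix (M x R); row m is `f_m`
#' @export
ring_fingerprints <- function(models) {
  m_n <- length(models)
  stopifnot(m_n >= 1)
  r_n <- length(models[[1]])
  out <- matrix(0, nrow = m_n, ncol = r_n)
  if (r_n == 0L) return(out)
  for (m in seq_len(m_n)) {
    stopifnot(length(models[[m]]) == r_n)
    if (m == 1L) next  # f_1 is the zero vector by definition
    for (r in seq_len(r_n)) {
      out[m, r] <- superposition_rmsd(models[[m]][[r]], models[[1]][[r]])
    }
  }
  out
}

#' Select medoid models by k-means clustering of ring fingerprints
#'
#' Clusters the fingerprints into `k = min(k_max, #distinct fingerprints)`
#' groups (k-means++ initialization, 10 restarts, best inertia kept) and
#' returns, per cluster, the index of the member nearest the cluster centroid
#' (ties: lowest model index).
#'
#' @param fingerprints numeric matrix (M x R) from [ring_fingerprints()].
#' @param k_max maximum number of retained models.
#' @param seed RNG seed for initialization.
#' @return sorted integer vector of model indices (length <= k_max)
#' @export
select_ring_medoids <- function(fingerprints, k_max, seed = 1L) {
  fp <- as.matrix(fingerprints)
  stopifnot(nrow(fp) >= 1, k_max >= 1)
  keys <- apply(round(fp, 6), 1, paste, collapse = ",")
  n_distinct <- length(unique(keys))
  k <- min(k_max, n_distinct)
  if (k == 1L) return(1L)
  if (n_distinct <= k) {
    # every distinct fingerprint is its own cluster; medoid = first holder
    idx <- vapply(unique(keys), function(kk) which(keys == kk)[1], integer(1))
    return(sort(unname(idx)))
  }
  best <- NULL
  for (restart in seq_len(10L)) {
    centers <- with_rng(derive_seed(seed, "kmeans", restart),
                        kmeanspp_centers(fp, k))
    km <- tryCatch(
      suppressWarnings(stats::kmeans(fp, centers = centers,
                                     algorithm = "Lloyd", iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on ring fingerprints")
  medoids <- integer(0)
  for (cl in seq_len(k)) {
    members <- which(best$cluster == cl)
    if (!length(members)) next
    d2 <- rowSums((fp[members, , drop = FALSE] -
                   matrix(best$centers[cl, ], nrow = length(members),
                          ncol = ncol(fp), byrow = TRUE))^2)
    medoids <- c(medoids, members[which.min(d2)])  # which.min: lowest index tie-break
  }
  sort(unique(medoids))
}

# k-means++ seeding: first center uniform, then points weighted by squared
# distance to the nearest chosen center. Returns a k x R matrix of distinct
# data points.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      # fewer distinct points than k (caller prevents this); fall back
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

#' Embed and optimize multiple 3D models
#'
#' @param g mol_graph (single fragment)
#' @param n_models number of models M.
#' @param seed RNG seed (embedding is deterministic given the seed).
#' @param backend geometry backend.
#' @param optimize force-field optimize each model (default TRUE).
#' @return list of [conformer3d()]s; attribute `error` carries the failure
#'   message when embedding failed (empty list returned)
#' @export
embed_models <- function(g, n_models, seed = 1L, backend = default_backend(),
                         optimize = TRUE) {
  res <- backend_run(backend, list(list(graph = g, n_confs = n_models,
                                        seed = derive_seed(seed, "embed"),
                                        optimize = optimize)))[[1]]
  if (!isTRUE(res$ok)) {
    out <- list()
    attr(out, "error") <- res$error
    return(out)
  }
  res$conformers
}

# ring torsion angles (degrees) around an ordered ring coordinate matrix
ring_torsions <- function(coords) {
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    p <- coords[c(i, i %% n + 1L, (i + 1L) %% n + 1L, (i + 2L) %% n + 1L), , drop = FALSE]
    dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  }, numeric(1))
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

#' Classify a six-membered ring conformation by its torsion pattern
#'
#' Chair: alternating torsion signs, magnitudes in roughly 40-75 degrees.
#' Twist-boat: non-alternating signs, no near-zero torsion. Boat: two
#' near-zero torsions. Planar: all torsions near zero.
#'
#' @param coords ordered ring-atom coordinate matrix (6 x 3)
#' @return one of "chair", "twist_boat", "boat", "planar", "other"
#' @export
classify_ring_conformation <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 6L) return("other")
  tors <- ring_torsions(coords)
  if (all(abs(tors) < 12)) return("planar")
  signs <- sign(tors)
  alternating <- all(signs == rep_len(c(1, -1), 6)) ||
                 all(signs == rep_len(c(-1, 1), 6))
  near_zero <- sum(abs(tors) < 12)
  if (alternating && all(abs(tors) > 40 & abs(tors) < 75)) return("chair")
  if (near_zero >= 2L) return("boat")
  if (!alternating) return("twist_boat")
  "other"
}

#' Axial/equatorial orientation of a ring substituent
#'
#' Measures the angle between the exocyclic bond vector and the mean-plane
#' normal of the ring: bonds near-parallel to the normal are axial, bonds
#' near the ring plane equatorial.
#'
#' @param ring_coords ordered ring-atom coordinates (A x 3)
#' @param atom_coord coordinate of the ring atom bearing the substituent
#' @param sub_coord coordinate of the substituent's first atom
#' @return "axial", "equatorial", or "isoclinal"
#' @export
substituent_orientation <- function(ring_coords, atom_coord, sub_coord) {
  ring_coords <- as.matrix(ring_coords)
  centered <- sweep(ring_coords, 2, colMeans(ring_coords))
  normal <- svd(centered)$v[, 3]
  bv <- sub_coord - atom_coord
  ct <- abs(sum(bv * normal) / sqrt(sum(bv^2)))
  if (ct > 0.65) "axial" else if (ct < 0.45) "equatorial" else "isoclinal"
}

#' Expand a variant into distinct ring-conformer models
#'
#' The full ring-conformation stage for one variant: embed `m * t` models
#' (ETKDG + force-field optimization), fingerprint their non-aromatic rings,
#' cluster, and keep the medoid models. Molecules without non-aromatic rings
#' are returned unchanged.
#'
#' @param v a [variant()]
#' @param m max variants per compound (cluster count bound).
#' @param t thoroughness multiplier; `m * t` models are embedded.
#' @param seed RNG seed.
#' @param backend geometry backend.
#' @return list of variants, each carrying an optimized conformer; attribute
#'   `error` set when embedding failed
#' @export
generate_ring_conformers <- function(v, m, t, seed = 1L,
                                     backend = default_backend()) {
  rings <- extract_nonaromatic_rings(v$graph)
  if (!length(rings)) return(list(v))
  n_models <- m * t
  confs <- embed_models(v$graph, n_models, seed = seed, backend = backend,
                        optimize = TRUE)
  if (!length(confs)) {
    out <- list()
    attr(out, "error") <- attr(confs, "error")
    return(out)
  }
  models <- lapply(confs, function(cf) {
    lapply(rings, function(cy) cf$coords[cy, , drop = FALSE])
  })
  fps <- ring_fingerprints(models)
  sel <- select_ring_medoids(fps, k_max = m, seed = derive_seed(seed, "medoid"))
  lapply(sel, function(mi) {
    v2 <- v
    v2$conformer <- confs[[mi]]
    v2$energy <- confs[[mi]]$energy
    add_provenance(v2, "ring_conformer",
                   sprintf("model %d of %d (medoid of %d clusters, %d rings)",
                           mi, length(confs), length(sel), length(rings)))
  })
}
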