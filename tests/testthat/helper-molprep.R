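# Shared test helpers: quick constructors, counting stub backends, and the
# independent numeric oracles used by the geometry tests.

pg <- function(smiles) parse_smiles(smiles)

# A stub backend whose energy function records every embedding call.
counting_stub <- function(energies = NULL) {
  log <- new.env(parent = emptyenv())
  log$calls <- character(0)
  fn <- function(smi, ci) {
    log$calls <- c(log$calls, smi)
    if (is.null(energies)) 0 else {
      if (is.function(energies)) energies(smi, ci)
      else energies[[length(log$calls)]]
    }
  }
  list(backend = stub_backend(energy_fun = fn), log = log)
}

# n distinct trivial variants (linear alkanes of increasing length)
alkane_variants <- function(n, parent = "alk") {
  lapply(seq_len(n), function(i) {
    variant(parent, pg(paste(rep("C", i + 1), collapse = "")),
            provenance = list(provenance_step("ionize", "test")))
  })
}

# a variant list with prescribed net formal charges (alkoxide / ammonium
# substituents on an alkane chain; chain length i keeps all graphs distinct)
charged_variants <- function(charges, parent = "chg") {
  lapply(seq_along(charges), function(i) {
    q <- charges[i]
    smi <- paste0("C", strrep("C", i),
                  if (q < 0) strrep("C(C[O-])", -q)
                  else if (q > 0) strrep("C(C[NH3+])", q) else "",
                  "C")
    g <- pg(smi)
    stopifnot(net_formal_charge(g) == q)
    variant(parent, g)
  })
}

# random rigid transform of a coordinate matrix
rigid_transform <- function(x, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0, -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  x %*% t(rz %*% ry %*% rx) + matrix(stats::runif(3, -5, 5), nrow(x), 3, byrow = TRUE)
}

euler_rotation <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# Independent RMSD oracle: centroid alignment, then dense grid over Euler
# angles polished by Nelder-Mead. Never uses the closed-form SVD path.
grid_rmsd_oracle <- function(c1, c2, steps = 14) {
  p <- sweep(as.matrix(c1), 2, colMeans(c1))
  q <- sweep(as.matrix(c2), 2, colMeans(c2))
  f <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = steps + 1)[-(steps + 1)]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (cc in grid) {
    v <- f(c(a, b, cc))
    if (v < best) { best <- v; best_ang <- c(a, b, cc) }
  }
  opt <- stats::optim(best_ang, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  min(best, opt$value)
}

# Idealized cyclohexane geometries (ring radius 1.25 A, pucker amplitudes
# giving textbook torsion patterns: chair ~56 deg alternating, twist-boat
# ~30/60 non-alternating).
ideal_cyclohexane <- function(kind) {
  th <- 2 * pi * (0:5) / 6
  z <- switch(kind,
    chair = 0.2 * (-1)^(0:5),
    boat = 0.4 * cos(2 * th),
    twist = 0.4 * sin(2 * th))
  cbind(1.25 * cos(th), 1.25 * sin(th), z)
}

# Exhaustive-assignment k-means oracle for small point sets: all k^n
# assignments, minimal total within-cluster SS; returns medoid indices.
exhaustive_medoid_oracle <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 12)
  best_ss <- Inf; best_assign <- NULL
  idx <- rep(1L, n)
  repeat {
    if (length(unique(idx)) == k) {
      ss <- 0
      for (cl in seq_len(k)) {
        pts <- x[idx == cl, , drop = FALSE]
        if (nrow(pts)) {
          ctr <- colMeans(pts)
          ss <- ss + sum(sweep(pts, 2, ctr)^2)
        }
      }
      if (ss < best_ss - 1e-12) { best_ss <- ss; best_assign <- idx }
    }
    j <- n
    while (j >= 1 && idx[j] == k) { idx[j] <- 1L; j <- j - 1L }
    if (j < 1) break
    idx[j] <- idx[j] + 1L
  }
  medoids <- integer(0)
  for (cl in seq_len(k)) {
    members <- which(best_assign == cl)
    ctr <- colMeans(x[members, , drop = FALSE])
    d2 <- rowSums((x[members, , drop = FALSE] -
                   matrix(ctr, length(members), ncol(x), byrow = TRUE))^2)
    medoids <- c(medoids, members[which.min(d2)])
  }
  sort(medoids)
}
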