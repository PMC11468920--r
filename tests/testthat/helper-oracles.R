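# Independent reference implementations used to cross-check the package's
# statistics: deliberately naive (per-position flood fill, explicit loops)
# and structurally different from the library code paths.

# Direct evaluation of the classifier-information formula.
info_oracle <- function(d, l) {
  zd <- (d - mean(d)) / sqrt(sum((d - mean(d))^2) / length(d))
  sum(zd * l) / length(d)
}

# Neighbor lists for the TFCE oracle.
chain_nbrs <- function(n) {
  lapply(seq_len(n), function(i) {
    c(if (i > 1) i - 1L, if (i < n) i + 1L)
  })
}

lattice_nbrs <- function(dims) {
  n <- prod(dims)
  coords <- arrayInd(seq_len(n), dims)
  lapply(seq_len(n), function(i) {
    nb <- integer(0)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      cc <- coords[i, ]
      cc[ax] <- cc[ax] + s
      if (cc[ax] >= 1 && cc[ax] <= dims[ax]) {
        nb <- c(nb, cc[1] + dims[1] * (cc[2] - 1) +
                  dims[1] * dims[2] * (cc[3] - 1))
      }
    }
    nb
  })
}

# Per-position threshold loop with breadth-first flood fill.
tfce_oracle_pos <- function(stat, nbrs, E, H, dh) {
  n <- length(stat)
  out <- numeric(n)
  top <- max(stat)
  if (top <= 0) return(out)
  if (is.null(dh)) dh <- top / 100
  for (p in seq_len(n)) {
    for (h in seq(dh, top, by = dh)) {
      if (stat[p] < h) break
      active <- stat >= h
      seen <- logical(n)
      queue <- p
      seen[p] <- TRUE
      while (length(queue)) {
        cur <- queue[1]
        queue <- queue[-1]
        for (nb in nbrs[[cur]]) {
          if (active[nb] && !seen[nb]) {
            seen[nb] <- TRUE
            queue <- c(queue, nb)
          }
        }
      }
      out[p] <- out[p] + sum(seen)^E * h^H * dh
    }
  }
  out
}

tfce_oracle <- function(stat, nbrs, E, H, dh, two_sided = TRUE) {
  pos <- tfce_oracle_pos(stat, nbrs, E, H, dh)
  if (!two_sided) return(pos)
  pos - tfce_oracle_pos(-stat, nbrs, E, H, dh)
}

# Literal triple-loop lattice enumeration of sphere membership.
sphere_count_oracle <- function(radius, strict = FALSE) {
  r <- ceiling(radius)
  count <- 0L
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    d2 <- dx^2 + dy^2 + dz^2
    if ((strict && d2 < radius^2) || (!strict && d2 <= radius^2)) {
      count <- count + 1L
    }
  }
  count
}

# Hard-margin SVM margin via an interior-point QP solver on the dual.
svm_margin_qp_oracle <- function(X, y, C = 1e6) {
  K <- X %*% t(X)
  H <- (y %*% t(y)) * K
  n <- length(y)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 9)
  alpha <- kernlab::primal(sol)
  w <- drop(t(X) %*% (alpha * y))
  1 / sqrt(sum(w^2))
}

# Small default ground truth used across tests (modest sizes, fixed seed).
test_gt <- function(...) {
  ground_truth(seed = 42L, ...)
}
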