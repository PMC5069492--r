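# Independent reference implementations used to cross-check the package.
# Each oracle deliberately follows a different computational route than the
# implementation it validates.

# Torsion by explicit orthonormal-basis projection: build a basis in the
# plane perpendicular to the b2 axis and read off the signed angle between
# the projections of -b1 and b3.
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  e1 <- b2 / sqrt(sum(b2^2))
  u <- -b1 - sum(-b1 * e1) * e1          # projection of -b1 onto the plane
  v <- b3 - sum(b3 * e1) * e1            # projection of b3
  e2 <- u / sqrt(sum(u^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  atan2(sum(v * e3), sum(v * e2)) * 180 / pi
}

# Horn's quaternion method for least-RMSD superposition: the optimal
# rotation comes from the leading eigenvector of the 4x4 key matrix, a
# route independent of the Kabsch SVD used by the package.
oracle_pair_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- crossprod(Ac, Bc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Brute-force GROMOS clustering: recompute the full RMSD matrix (via the
# quaternion oracle) and the neighbour counts from scratch at every step.
oracle_gromos <- function(coords, cutoff) {
  nf <- dim(coords)[3]
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf)
    D[i, j] <- D[j, i] <- oracle_pair_rmsd(coords[, , i], coords[, , j])
  assignments <- integer(nf)
  k <- 0L
  repeat {
    left <- which(assignments == 0L)
    if (length(left) == 0L) break
    counts <- vapply(left, function(i) sum(D[i, left] <= cutoff), 0L)
    center <- left[which(counts == max(counts))[1]]
    members <- left[D[center, left] <= cutoff]
    k <- k + 1L
    assignments[members] <- k
    attr(assignments, paste0("center", k)) <- center
  }
  assignments
}

# Spearman by hand: explicit average ranks via sorted positions, then the
# product-moment formula on the ranks.
oracle_spearman <- function(x, y) {
  hand_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    pos <- 1L
    while (pos <= length(v)) {
      run <- which(v == v[o[pos]])
      r[run] <- mean(seq.int(pos, pos + length(run) - 1L))
      pos <- pos + length(run)
    }
    r
  }
  rx <- hand_rank(x); ry <- hand_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Welch two-sample t statistic from the textbook formula.
oracle_welch_t <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
}

# Brute-force contact map: all atom pairs, frame by frame.
oracle_contact_map <- function(traj) {
  topo <- traj$topology
  labs <- topo$blocks$label
  nb <- length(labs)
  M <- matrix(0, nb, nb, dimnames = list(labs, labs))
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    ai <- which(topo$atoms$block_id == topo$blocks$block_id[i] &
                  topo$atoms$atom_name != "CM")
    aj <- which(topo$atoms$block_id == topo$blocks$block_id[j] &
                  topo$atoms$atom_name != "CM")
    vals <- vapply(seq_len(n_frames(traj)), function(f) {
      fr <- traj$coords[, , f]
      min(vapply(ai, function(a) min(sqrt(colSums((t(fr[aj, , drop = FALSE]) -
                                                     fr[a, ])^2))), 0))
    }, 0)
    M[i, j] <- M[j, i] <- mean(vals)
  }
  M
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
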