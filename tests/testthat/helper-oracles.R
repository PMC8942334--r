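# Independent oracles and fixture builders shared across the suite.

# Quaternion-based superposition oracle (Horn's method): minimal RMSD of P
# onto Q via the largest eigenvalue of the 4x4 key matrix. Independent of
# the SVD route used by kabsch().
quaternion_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  E0 <- sum(Pc^2) + sum(Qc^2)
  sqrt(max(0, (E0 - 2 * lam) / n))
}

# Brute-force rotation-grid oracle: coarse 10-degree Euler sweep refined
# locally at 2 degrees; returns the minimal RMSD over the grid.
grid_rmsd <- function(P, Q, coarse = 10, fine = 2) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(a, b, c) {
    structphylo::rotation_matrix(c(0, 0, 1), a) %*%
      structphylo::rotation_matrix(c(0, 1, 0), b) %*%
      structphylo::rotation_matrix(c(1, 0, 0), c)
  }
  eval_r <- function(a, b, c) {
    sqrt(mean(rowSums((Pc %*% t(rotmat(a, b, c)) - Qc)^2)))
  }
  best <- c(Inf, 0, 0, 0)
  for (a in seq(0, 350, coarse)) for (b in seq(0, 170, coarse))
    for (c in seq(0, 350, coarse)) {
      r <- eval_r(a, b, c)
      if (r < best[1]) best <- c(r, a, b, c)
    }
  for (a in seq(best[2] - coarse, best[2] + coarse, fine))
    for (b in seq(best[3] - coarse, best[3] + coarse, fine))
      for (c in seq(best[4] - coarse, best[4] + coarse, fine)) {
        r <- eval_r(a, b, c)
        if (r < best[1]) best <- c(r, a, b, c)
      }
  best[1]
}

# self-avoiding random walk with 3.8 Angstrom steps, as a ca_trace
random_walk_trace <- function(n, seed) {
  xyz <- structphylo:::with_seed(seed, {
    p <- matrix(0, n, 3)
    for (i in 2:n) {
      repeat {
        st <- rnorm(3); st <- 3.8 * st / sqrt(sum(st^2))
        cand <- p[i - 1, ] + st
        if (i < 3 ||
            min(sqrt(rowSums(sweep(p[1:(i - 2), , drop = FALSE], 2,
                                   cand)^2))) > 2) break
      }
      p[i, ] <- cand
    }
    p
  })
  structure(list(labels = data.frame(res_seq = seq_len(n), insert = "",
                                     res_name = "ALA", aa = "A",
                                     stringsAsFactors = FALSE),
                 xyz = xyz, breaks = integer(0)), class = "ca_trace")
}

# standard 7-helix test bundle
bundle7 <- function(seed = 1, loops = rep(6L, 6)) {
  make_bundle(c(12, 14, 10, 12, 11, 15, 9), loops, seed = seed)
}

# bundle + copy with helices 1-3 hinge-rotated by `angle` about `axis`
# through the centroid of the third loop
hinge_pair <- function(seed = 7, angle = 115, axis = c(0, 0, 1)) {
  s <- bundle7(seed, loops = c(4L, 5L, 4L, 4L, 5L, 4L))
  lay <- attr(s, "layout")
  piv_res <- lay$loops[[3]]
  at <- s$models[[1]]
  pivot <- colMeans(as.matrix(at[at$res_seq %in% piv_res,
                                 c("x", "y", "z")]))
  s2 <- apply_block_rotation(s, 1:max(piv_res), axis, angle, pivot)
  attr(s2, "layout") <- lay
  list(a = s, b = s2)
}

# random rigid transform of a ca_trace (seeded)
random_rigid <- function(t, seed) {
  structphylo:::with_seed(seed, {
    R <- structphylo::rotation_matrix(rnorm(3), runif(1, 0, 360))
    shift <- rnorm(3, sd = 20)
    t$xyz <- sweep(t$xyz %*% t(R), 2, shift, `+`)
    t
  })
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed) {
  structphylo:::with_seed(seed, {
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    list(tree = tr, d = d)
  })
}

# find a residue pocket that is exactly realizable as a ligand-contact set:
# scan candidate interior points and pick the one whose distance shell has
# the widest empty margin around the cutoff
find_pocket <- function(s, cutoff = 8, min_size = 3) {
  tr <- ca_trace(select_chain(s))
  lay <- attr(s, "layout")
  cand <- lapply(lay$loops, function(lp) colMeans(tr$xyz[lp, , drop = FALSE]))
  ctrs <- lapply(lay$helices, function(h) colMeans(tr$xyz[h, , drop = FALSE]))
  for (i in seq_along(ctrs)) for (j in seq_along(ctrs)) if (i < j)
    cand[[length(cand) + 1]] <- (ctrs[[i]] + ctrs[[j]]) / 2
  best <- NULL
  for (q in cand) {
    d <- sqrt(rowSums(sweep(tr$xyz, 2, q)^2))
    margin <- min(abs(d - cutoff))
    inside <- which(d < cutoff)
    if (length(inside) >= min_size &&
        (is.null(best) || margin > best$margin))
      best <- list(q = q, pocket = tr$labels$res_seq[inside],
                   margin = margin)
  }
  best
}
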