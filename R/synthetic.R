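# Seeded generators of synthetic Calpha structures: ideal helices, packed
# multi-helix bundles with random-walk loops, coordinate noise, planted
# hinge rotations, ligands planted in pockets, and families of structures
# diverged along a known guide tree. Every generator is a pure function of
# its seed, so ground truth is available for every pipeline stage.

#' Ideal alpha-helix Calpha trace
#'
#' Canonical geometry: 1.5 Angstrom rise per residue, 2.3 Angstrom radius,
#' 100 degrees turn per residue, axis along z.
#'
#' @param n number of residues (>= 5)
#' @return a [ca_trace()]
#' @export
ideal_helix <- function(n) {
  if (n < 5) stop("helix needs >= 5 residues")
  t <- 0:(n - 1)
  xyz <- ideal_helix_xyz(n)
  structure(list(labels = data.frame(res_seq = t + 1L, insert = "",
                                     res_name = "ALA", aa = "A",
                                     stringsAsFactors = FALSE),
                 xyz = xyz, breaks = integer(0)),
            class = "ca_trace")
}

# bare ideal-helix coordinates (also the detection template)
ideal_helix_xyz <- function(n) {
  t <- 0:(n - 1)
  th <- t * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * t)
}

# ca_trace -> single-chain pdb_structure with a residue sequence
trace_to_structure <- function(xyz, seqs, id, layout = NULL) {
  n <- nrow(xyz)
  three <- names(AA_THREE_TO_ONE)[1:20]
  res_name <- three[match(seqs, unname(AA_THREE_TO_ONE[three]))]
  at <- data.frame(type = "ATOM", serial = seq_len(n), atom_name = "CA",
                   alt_loc = "", res_name = res_name, chain_id = "A",
                   res_seq = seq_len(n), insert = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, element = "C", stringsAsFactors = FALSE)
  s <- structure(list(id = id, models = list(at)), class = "pdb_structure")
  attr(s, "layout") <- layout
  s
}

#' Generate a synthetic multi-helix bundle
#'
#' Ideal helices are placed side by side (spacing `spacing` Angstrom,
#' antiparallel, axes along z) and joined by jittered random-walk loops
#' with ~3.8 Angstrom steps. The residue sequence is drawn uniformly from
#' the 20 standard amino acids. Deterministic given `seed`; helix and loop
#' residue ranges are stored in `attr(, "layout")`.
#'
#' @param helix_lengths residue count per helix (each >= 5)
#' @param loop_lengths residue count per connecting loop (length =
#'   helices - 1, each >= 2)
#' @param spacing inter-helix spacing in Angstrom
#' @param seed RNG seed
#' @param id structure identifier
#' @return a single-chain, Calpha-only `pdb_structure`
#' @export
make_bundle <- function(helix_lengths, loop_lengths = NULL, spacing = 10,
                        seed = 1L, id = "bundle") {
  H <- length(helix_lengths)
  if (any(helix_lengths < 5)) stop("helix lengths must be >= 5")
  loop_lengths <- loop_lengths %||% rep(4L, H - 1)
  if (H > 1 && (length(loop_lengths) != H - 1 || any(loop_lengths < 2)))
    stop("need H-1 loop lengths, each >= 2")
  with_seed(seed, {
    for (attempt in 1:100) {
      jit <- if (attempt == 1) rep(0, H) else runif(H, -1.5, 1.5)
      hel <- vector("list", H)
      for (k in seq_len(H)) {
        hx <- ideal_helix(helix_lengths[k])$xyz
        if (k %% 2 == 0) {  # antiparallel: flip about x axis
          hx <- hx %*% diag(c(1, -1, -1))
          hx[, 3] <- hx[, 3] - min(hx[, 3])
        }
        hx[, 1] <- hx[, 1] + (k - 1) * spacing + jit[k]
        hel[[k]] <- hx
      }
      # clash check between non-adjacent helix atoms
      ok <- TRUE
      if (H > 1) {
        allh <- do.call(rbind, hel)
        grp <- rep(seq_len(H), vapply(hel, nrow, 0L))
        dd <- as.matrix(dist(allh))
        dd[outer(grp, grp, `==`)] <- Inf
        ok <- min(dd) >= 2
      }
      if (ok) break
      if (attempt == 100) stop("could not place helices without clashes")
    }
    coords <- hel[[1]]
    hl_ranges <- list(1:nrow(hel[[1]]))
    loop_ranges <- list()
    for (k in seq_len(H - 1)) {
      from <- hel[[k]][nrow(hel[[k]]), ]
      to <- hel[[k + 1]][1, ]
      L <- loop_lengths[k]
      loop <- bridge_walk(from, to, L)
      i0 <- nrow(coords)
      coords <- rbind(coords, loop, hel[[k + 1]])
      loop_ranges[[k]] <- (i0 + 1):(i0 + L)
      hl_ranges[[k + 1]] <- (i0 + L + 1):(i0 + L + nrow(hel[[k + 1]]))
    }
    seqs <- sample(unname(AA_THREE_TO_ONE[1:20]), nrow(coords),
                   replace = TRUE)
    trace_to_structure(coords, seqs, id,
                       layout = list(helices = hl_ranges,
                                     loops = loop_ranges))
  })
}

# jittered bridge between two points: L intermediate residues with step
# lengths kept inside the 2.0-4.5 Angstrom Calpha window
bridge_walk <- function(from, to, L) {
  for (try in 1:100) {
    sigma <- 0.8 / try
    tt <- seq_len(L) / (L + 1)
    base <- outer(1 - tt, from) + outer(tt, to)
    env <- sin(pi * tt)
    pts <- base + matrix(rnorm(3 * L, sd = sigma), L, 3) * env
    path <- rbind(from, pts, to)
    st <- sqrt(rowSums(diff(path)^2))
    if (all(st >= 2.0 & st <= 4.5)) return(pts)
  }
  # fall back to the straight interpolation
  base
}

#' Add Gaussian coordinate noise to a structure
#'
#' i.i.d. Gaussian noise (sd `sigma`) on every polymer (ATOM) coordinate;
#' `sigma = 0` is the identity. Deterministic given `seed`.
#'
#' @param s a `pdb_structure`
#' @param sigma noise standard deviation per coordinate (Angstrom)
#' @param seed RNG seed
#' @return the perturbed structure
#' @export
perturb <- function(s, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(s)
  with_seed(seed, {
    for (mi in seq_along(s$models)) {
      at <- s$models[[mi]]
      sel <- at$type == "ATOM"
      nz <- sum(sel)
      at[sel, c("x", "y", "z")] <- at[sel, c("x", "y", "z")] +
        matrix(rnorm(3 * nz, sd = sigma), nz, 3)
      s$models[[mi]] <- at
    }
    s
  })
}

#' Rigidly rotate a residue block within a structure
#'
#' Residues with `res_seq` in `residue_range` are rotated by `angle_deg`
#' about the axis through `pivot`; all other atoms are untouched.
#'
#' @param s a `pdb_structure`
#' @param residue_range integer vector of res_seq values to rotate
#' @param axis rotation axis (3-vector)
#' @param angle_deg rotation angle in degrees
#' @param pivot point on the axis (3-vector)
#' @return the modified structure
#' @export
apply_block_rotation <- function(s, residue_range, axis, angle_deg, pivot) {
  R <- rotation_matrix(axis, angle_deg)
  if (!any(s$models[[1]]$res_seq %in% residue_range))
    stop("residue range out of bounds")
  for (mi in seq_along(s$models)) {
    at <- s$models[[mi]]
    sel <- at$res_seq %in% residue_range & at$type == "ATOM"
    if (!any(sel)) next
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    at[sel, c("x", "y", "z")] <-
      sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, `+`)
    s$models[[mi]] <- at
  }
  s
}

#' Evolve a family of structures along a guide tree
#'
#' Walks the guide tree from the root. Along each branch of length b the
#' structure receives Gaussian coordinate noise with sd `noise_rate * b`
#' and, with probability `min(1, hinge_rate * b)`, one hinge event: the
#' region C-terminal to a randomly chosen loop is rotated about a random
#' axis through that loop's centroid by an angle drawn from
#' Normal(0, `hinge_angle_sd`). Fully seeded: each branch uses an RNG
#' substream hashed from (node label, seed), so results do not depend on
#' traversal order.
#'
#' @param ancestor a [make_bundle()] structure (its `layout` attribute
#'   locates the loops)
#' @param guide_tree rooted `phylo` tree with branch lengths, >= 3 leaves
#' @param noise_rate Angstrom of coordinate noise per unit branch length
#' @param hinge_rate hinge events per unit branch length (probability)
#' @param hinge_angle_sd degrees
#' @param seed RNG seed
#' @return named list of leaf structures
#' @export
evolve_family <- function(ancestor, guide_tree, noise_rate = 0.4,
                          hinge_rate = 0, hinge_angle_sd = 30, seed = 1L) {
  if (length(guide_tree$tip.label) < 3) stop("guide tree needs >= 3 leaves")
  if (noise_rate < 0 || hinge_rate < 0) stop("rates must be >= 0")
  layout <- attr(ancestor, "layout")
  n_tip <- length(guide_tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(guide_tree$edge)), guide_tree$edge[, 1])
  node_name <- function(v) if (v <= n_tip) guide_tree$tip.label[v]
                           else paste0("node", v)
  out <- list()
  walk <- function(v, s) {
    for (e in children[[as.character(v)]] %||% integer(0)) {
      child <- guide_tree$edge[e, 2]
      b <- guide_tree$edge.length[e]
      bs <- hash_seed(node_name(child), seed)
      s2 <- perturb(s, noise_rate * b, seed = bs)
      if (hinge_rate > 0) {
        s2 <- with_seed(bs + 1L, {
          if (runif(1) < min(1, hinge_rate * b) && length(layout$loops) > 0) {
            lp <- layout$loops[[sample(length(layout$loops), 1)]]
            ang <- rnorm(1, 0, hinge_angle_sd)
            ax <- rnorm(3)
            at <- s2$models[[1]]
            piv <- colMeans(as.matrix(at[at$res_seq %in% lp,
                                         c("x", "y", "z")]))
            apply_block_rotation(s2, (max(lp) + 1):max(at$res_seq),
                                 ax, ang, piv)
          } else s2
        })
      }
      if (child <= n_tip) out[[guide_tree$tip.label[child]]] <<- s2
      else walk(child, s2)
    }
  }
  walk(root, ancestor)
  out[guide_tree$tip.label]
}

#' Plant a synthetic ligand in a pocket
#'
#' Places `n_atoms` hetero atoms near the centroid of the named pocket
#' residues so that exactly those residues fall within the default
#' Calpha-contact cutoff; returns the modified structure and the pose.
#'
#' @param s a `pdb_structure`
#' @param pocket_residue_indices res_seq values defining the pocket
#' @param n_atoms number of ligand atoms
#' @param seed RNG seed
#' @param cutoff contact cutoff the placement must reproduce (Angstrom)
#' @return list with `structure` (ligand appended as HETATM residue `LIG`)
#'   and `pose` (a `ligand_pose`)
#' @export
plant_ligand <- function(s, pocket_residue_indices, n_atoms = 5L, seed = 1L,
                         cutoff = 8.0) {
  at <- s$models[[1]]
  ca <- at[at$type == "ATOM" & at$atom_name == "CA", , drop = FALSE]
  if (!all(pocket_residue_indices %in% ca$res_seq))
    stop("pocket residues not present in structure")
  pocket_xyz <- as.matrix(ca[ca$res_seq %in% pocket_residue_indices,
                             c("x", "y", "z")])
  ctr <- colMeans(pocket_xyz)
  tr <- ca_trace(at)
  pocket_idx <- which(tr$labels$res_seq %in% pocket_residue_indices)
  with_seed(seed, {
    q <- ctr
    all_xyz <- tr$xyz
    want <- sort(pocket_idx)
    for (attempt in 1:300) {
      xyz <- sweep(matrix(rnorm(3 * n_atoms, sd = 0.25), n_atoms, 3), 2,
                   q, `+`)
      pose <- structure(list(ligand_name = "LIG",
                             atom_names = paste0("C", seq_len(n_atoms)),
                             xyz = xyz),
                        class = "ligand_pose")
      got <- contact_residues(tr, pose, cutoff = cutoff, mode = "ca")$indices
      if (!identical(got, want)) {
        # constraint-driven update: pull towards missed pocket residues,
        # push away from captured outsiders, plus a little jitter
        dall <- sqrt(rowSums(sweep(all_xyz, 2, q)^2))
        missed <- setdiff(want, got)
        extra <- setdiff(got, want)
        grad <- c(0, 0, 0)
        for (i in missed)
          grad <- grad + (all_xyz[i, ] - q) / max(dall[i], 1e-6)
        for (i in extra)
          grad <- grad - (all_xyz[i, ] - q) / max(dall[i], 1e-6)
        q <- q + 0.4 * grad + rnorm(3, sd = 0.15)
      }
      if (identical(got, want)) {
        het <- data.frame(type = "HETATM",
                          serial = max(at$serial) + seq_len(n_atoms),
                          atom_name = pose$atom_names, alt_loc = "",
                          res_name = "LIG", chain_id = "A",
                          res_seq = max(at$res_seq) + 1L, insert = "",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          occupancy = 1, element = "C",
                          stringsAsFactors = FALSE)
        s$models[[1]] <- rbind(at, het)
        return(list(structure = s, pose = pose))
      }
    }
    stop("infeasible ligand placement: pocket cannot be reproduced exactly")
  })
}
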