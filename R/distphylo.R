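# Similarity -> distance transforms and distance-matrix phylogenetics:
# UPGMA, neighbor joining, Fitch-Margoliash (WLS + NNI), midpoint rooting,
# majority-rule consensus, Robinson-Foulds, Newick and matrix I/O.
# Trees are ape "phylo" objects throughout.

#' Cap similarity scores
#'
#' Outlier scores above `cap` are converted to `cap` before distance
#' transformation, so the distance scale is bounded in [0, 1].
#'
#' @param m labelled square similarity matrix
#' @param cap score ceiling (default 1000)
#' @return the capped matrix
#' @export
cap_scores <- function(m, cap = 1000) {
  m[m > cap] <- cap
  m
}

#' Convert a similarity score to a distance
#'
#' `d = |score/1000 - 1|`; with scores capped at 1000 this equals
#' `1 - score/1000`, mapping 1000 to 0 and 0 to 1.
#'
#' @param score numeric score(s), >= 0
#' @param cap score ceiling used before the transform
#' @return distance(s) in [0, 1]
#' @export
similarity_to_distance <- function(score, cap = 1000) {
  if (any(score < 0)) stop("negative similarity score")
  abs(pmin(score, cap) / cap - 1)
}

#' Convert a similarity matrix to a distance matrix
#'
#' Applies [cap_scores()] then [similarity_to_distance()] elementwise; the
#' diagonal is forced to zero.
#'
#' @param m labelled square symmetric similarity matrix
#' @param cap score ceiling
#' @return labelled square symmetric distance matrix, entries in [0, 1]
#' @export
sim_to_dist_matrix <- function(m, cap = 1000) {
  d <- similarity_to_distance(m, cap)
  diag(d) <- 0
  d
}

#' Elementwise mean of similarity matrices
#' @param ms list of similarity matrices with identical labels
#' @return mean matrix
#' @export
mean_similarity <- function(ms) {
  labs <- rownames(ms[[1]])
  for (m in ms)
    if (!identical(rownames(m), labs) || !identical(colnames(m), labs))
      stop("similarity matrices have mismatched labels")
  Reduce(`+`, ms) / length(ms)
}

check_dist <- function(d, min_n = 2) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix")
  if (nrow(d) < min_n) stop("distance matrix too small (need >= ", min_n, ")")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree.
#' Ties are broken by the lowest pair of original label indices, so equal
#' all-pairs matrices yield a deterministic caterpillar.
#'
#' @param d labelled square symmetric distance matrix, zero diagonal
#' @return rooted `phylo` tree (ultrametric)
#' @export
upgma_tree <- function(d) {
  check_dist(d, 2)
  labs <- rownames(d)
  n <- nrow(d)
  # active clusters: newick fragment, size, height, min original index
  cl <- lapply(seq_len(n), function(i)
    list(nwk = labs[i], size = 1L, h = 0, minidx = i))
  D <- d
  while (length(cl) > 1) {
    m <- length(cl)
    bi <- bj <- 1L; bd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      key_ij <- sort(c(cl[[i]]$minidx, cl[[j]]$minidx))
      better <- D[i, j] < bd - 1e-12
      tie <- abs(D[i, j] - bd) <= 1e-12
      if (better || (tie && {
        key_b <- sort(c(cl[[bi]]$minidx, cl[[bj]]$minidx))
        key_ij[1] < key_b[1] || (key_ij[1] == key_b[1] && key_ij[2] < key_b[2])
      })) { bd <- D[i, j]; bi <- i; bj <- j }
    }
    h <- bd / 2
    new <- list(
      nwk = sprintf("(%s:%.10g,%s:%.10g)", cl[[bi]]$nwk, h - cl[[bi]]$h,
                    cl[[bj]]$nwk, h - cl[[bj]]$h),
      size = cl[[bi]]$size + cl[[bj]]$size, h = h,
      minidx = min(cl[[bi]]$minidx, cl[[bj]]$minidx))
    # average-linkage update (weighted by cluster sizes = unweighted on leaves)
    keep <- setdiff(seq_len(m), c(bi, bj))
    newrow <- vapply(keep, function(k)
      (D[bi, k] * cl[[bi]]$size + D[bj, k] * cl[[bj]]$size) /
        (cl[[bi]]$size + cl[[bj]]$size), 0)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow),
               c(newrow, 0))
    cl <- c(cl[keep], list(new))
  }
  ape::read.tree(text = paste0(cl[[1]]$nwk, ";"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration by the Q criterion; negative branch lengths are
#' clamped to zero with a warning; ties are broken by the lowest pair of
#' original label indices.
#'
#' @param d labelled square symmetric distance matrix, n >= 3
#' @return unrooted `phylo` tree
#' @export
nj_tree <- function(d) {
  check_dist(d, 3)
  labs <- rownames(d)
  clamped <- FALSE
  bl <- function(v) { if (v < 0) clamped <<- TRUE; max(0, v) }
  cl <- lapply(seq_along(labs), function(i) list(nwk = labs[i], minidx = i))
  D <- d
  while (length(cl) > 3) {
    m <- length(cl)
    r <- rowSums(D)
    bi <- bj <- 1L; bq <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      better <- q < bq - 1e-12
      tie <- abs(q - bq) <= 1e-12
      if (better || (tie && {
        key_ij <- sort(c(cl[[i]]$minidx, cl[[j]]$minidx))
        key_b <- sort(c(cl[[bi]]$minidx, cl[[bj]]$minidx))
        key_ij[1] < key_b[1] || (key_ij[1] == key_b[1] && key_ij[2] < key_b[2])
      })) { bq <- q; bi <- i; bj <- j }
    }
    vi <- D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    vj <- D[bi, bj] - vi
    new <- list(nwk = sprintf("(%s:%.10g,%s:%.10g)", cl[[bi]]$nwk, bl(vi),
                              cl[[bj]]$nwk, bl(vj)),
                minidx = min(cl[[bi]]$minidx, cl[[bj]]$minidx))
    keep <- setdiff(seq_len(m), c(bi, bj))
    newrow <- vapply(keep, function(k)
      (D[bi, k] + D[bj, k] - D[bi, bj]) / 2, 0)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow), c(newrow, 0))
    cl <- c(cl[keep], list(new))
  }
  # final three-point join
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", cl[[1]]$nwk, bl(v1),
                 cl[[2]]$nwk, bl(v2), cl[[3]]$nwk, bl(v3))
  if (clamped) warning("negative branch length(s) clamped to zero")
  ape::read.tree(text = nwk)
}

# pairwise path-indicator matrix: rows = leaf pairs (i<j), cols = edges
path_matrix <- function(tree) {
  n <- length(tree$tip.label)
  E <- nrow(tree$edge)
  pr <- t(utils::combn(n, 2))
  X <- matrix(0, nrow(pr), E)
  # parent pointers
  parent <- integer(max(tree$edge)); edge_of <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(E)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(v) {
    out <- integer(0)
    while (v != root) { out <- c(out, edge_of[v]); v <- parent[v] }
    out
  }
  paths <- lapply(seq_len(n), path_to_root)
  for (k in seq_len(nrow(pr))) {
    e1 <- paths[[pr[k, 1]]]; e2 <- paths[[pr[k, 2]]]
    sym <- c(setdiff(e1, e2), setdiff(e2, e1))
    X[k, sym] <- 1
  }
  list(X = X, pairs = pr)
}

# weighted least-squares branch lengths for a fixed topology;
# weights 1/d^2 (capped), non-negativity by clamping
wls_fit <- function(tree, d, w_cap = 1e6) {
  labs <- tree$tip.label
  pm <- path_matrix(tree)
  y <- d[cbind(labs[pm$pairs[, 1]], labs[pm$pairs[, 2]])]
  w <- ifelse(y > 0, pmin(1 / y^2, w_cap), w_cap)
  XtW <- t(pm$X * w)
  b <- tryCatch(solve(XtW %*% pm$X, XtW %*% y),
                error = function(e) {
                  MASS_ginv(XtW %*% pm$X) %*% (XtW %*% y)
                })
  b <- pmax(0, as.numeric(b))
  resid <- y - as.numeric(pm$X %*% b)
  tree$edge.length <- b
  list(tree = tree, objective = sum(w * resid^2))
}

# small pseudo-inverse fallback (avoids a MASS dependency)
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fitch-Margoliash tree from a distance matrix
#'
#' Branch lengths by weighted least squares with weights `1/d^2`
#' (Fitch-Margoliash weighting; zero distances get a capped weight), with
#' non-negativity enforced by clamping. The topology is searched by
#' nearest-neighbor-interchange hill climbing from a neighbor-joining
#' starting tree; the weighted residual objective never increases across
#' accepted steps.
#'
#' @param d labelled square symmetric distance matrix, n >= 3
#' @param w_cap weight cap for zero/near-zero distances
#' @param max_iter maximum NNI improvement sweeps
#' @return unrooted `phylo` tree with attribute `objective` (weighted
#'   residual sum of squares)
#' @export
fitch_margoliash <- function(d, w_cap = 1e6, max_iter = 50L) {
  check_dist(d, 3)
  cur <- wls_fit(ape::unroot(nj_tree(d)), d, w_cap)
  if (length(cur$tree$tip.label) > 3) {
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      nbs <- tryCatch(phangorn::nni(cur$tree), error = function(e) list())
      for (bi in seq_along(nbs)) {
        fit <- wls_fit(nbs[[bi]], d, w_cap)  # [[ restores compressed labels
        if (fit$objective < cur$objective - 1e-12) {
          cur <- fit; improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  out <- cur$tree
  attr(out, "objective") <- cur$objective
  out
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two farthest leaves are equidistant from the root.
#'
#' @param t unrooted `phylo` tree with branch lengths
#' @return rooted `phylo` tree
#' @export
midpoint_root <- function(t) {
  if (is.null(t$edge.length) || sum(t$edge.length) <= 0)
    stop("degenerate rooting: tree has no positive branch lengths")
  phangorn::midpoint(t)
}

# canonical split key: side not containing the first leaf of `labs`,
# as a sorted comma-joined label string
split_keys <- function(tree, labs) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  out <- list()
  pp <- ape::prop.part(tree)
  # prop.part gives clades of the (arbitrary) root; convert to splits
  for (k in seq_along(pp)) {
    side <- tree$tip.label[pp[[k]]]
    if (labs[1] %in% side) side <- setdiff(labs, side)
    if (length(side) == 0 || length(side) >= n - 1) next  # trivial
    out[[length(out) + 1]] <- paste(sort(side), collapse = ",")
  }
  unique(unlist(out)) %||% character(0)
}

# branch length of the edge realizing a given split in a tree (NA if absent)
split_length <- function(tree, key, labs) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  node_ids <- (length(tree$tip.label) + 1):(length(tree$tip.label) + length(pp))
  for (k in seq_along(pp)) {
    side <- tree$tip.label[pp[[k]]]
    if (labs[1] %in% side) side <- setdiff(labs, side)
    if (identical(paste(sort(side), collapse = ","), key)) {
      e <- which(tree$edge[, 2] == node_ids[k])
      if (length(e) == 1) return(tree$edge.length[e])
    }
  }
  NA_real_
}

#' Majority-rule consensus of trees
#'
#' Keeps the unrooted splits occurring in more than `threshold` of the
#' input trees. Support is the occurrence fraction (stored as internal node
#' labels); the branch length of a kept split is the mean over the trees
#' containing it.
#'
#' @param trees list of `phylo` trees on the same leaf set
#' @param threshold split-frequency threshold (strict, default 0.5)
#' @return unrooted `phylo` consensus tree with node labels = supports
#' @export
consensus_tree <- function(trees, threshold = 0.5) {
  if (length(trees) < 2) stop("need at least 2 trees")
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), labs)) stop("leaf-set mismatch")
  keysets <- lapply(trees, split_keys, labs = labs)
  all_keys <- unique(unlist(keysets))
  freq <- vapply(all_keys, function(k)
    mean(vapply(keysets, function(ks) k %in% ks, TRUE)), 0)
  kept <- all_keys[freq > threshold]
  # mean branch length over trees containing each kept split
  mean_len <- vapply(kept, function(k) {
    v <- vapply(trees, split_length, 0, key = k, labs = labs)
    mean(v, na.rm = TRUE)
  }, 0)
  # leaf edges: mean over all trees
  leaf_len <- vapply(labs, function(lf) {
    mean(vapply(trees, function(tr) {
      tr <- ape::unroot(tr)
      tr$edge.length[tr$edge[, 2] == match(lf, tr$tip.label)]
    }, 0))
  }, 0)
  # build the tree by nesting kept clusters (all exclude labs[1], so they
  # form a laminar family rooted beside labs[1])
  clusters <- strsplit(kept, ",", fixed = TRUE)
  ord <- order(vapply(clusters, length, 0L))  # smallest first
  node <- setNames(sprintf("%s:%.10g", labs, leaf_len), labs)
  owner <- setNames(rep("", length(labs)), labs)  # cluster id holding leaf
  for (ci in ord) {
    cl <- clusters[[ci]]
    # children = current top-level nodes fully inside cl (compatibility of
    # majority splits + smallest-first order guarantees full containment)
    ids <- unique(ifelse(owner[cl] == "", cl, owner[cl]))
    parts <- node[ids]
    sup <- freq[match(kept[ci], all_keys)]
    new_id <- paste0("#", ci)
    node[new_id] <- sprintf("(%s)%.3g:%.10g", paste(parts, collapse = ","),
                            sup, mean_len[match(kept[ci], kept)])
    owner[cl] <- new_id
    node <- node[setdiff(names(node), ids)]
  }
  top <- unique(ifelse(owner == "", names(owner), owner))
  nwk <- sprintf("(%s);", paste(node[top], collapse = ","))
  ape::read.tree(text = nwk)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the unrooted split sets.
#'
#' @param t1,t2 `phylo` trees on the same leaf set
#' @return non-negative integer
#' @export
robinson_foulds <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label)))
    stop("leaf-set mismatch")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Serialize a tree as Newick
#' @param t a `phylo` tree
#' @param digits significant digits for branch lengths
#' @return single Newick string
#' @export
write_newick <- function(t, digits = 6) {
  # ape::write.tree rewrites blanks even inside quotes; shield labels with
  # spaces via a placeholder so they survive verbatim (quoted) in the output
  sp <- grepl(" ", t$tip.label)
  t$tip.label[sp] <- paste0("'", gsub(" ", "\01", t$tip.label[sp]), "'")
  out <- ape::write.tree(t, digits = digits)
  gsub("\01", " ", out, fixed = TRUE)
}

#' Parse a Newick string
#' @param s Newick string
#' @return a `phylo` tree
#' @export
parse_newick <- function(s) {
  opens <- cumsum((strsplit(s, "")[[1]] == "(") -
                    (strsplit(s, "")[[1]] == ")"))
  if (any(opens < 0) || tail(opens, 1) != 0)
    stop("unbalanced parentheses at position ",
         if (any(opens < 0)) which(opens < 0)[1] else nchar(s))
  out <- ape::read.tree(text = s)
  if (is.null(out)) stop("malformed Newick string")
  out$tip.label <- sub("^'(.*)'$", "\\1", out$tip.label)
  out
}

#' Write a labelled distance (or similarity) matrix as square TSV
#' @param m labelled square matrix
#' @param path output file
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
}

#' Read a labelled square matrix from TSV
#' @param path file written by [write_matrix_tsv()]
#' @return labelled matrix
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}

#' Read a PHYLIP lower-triangular distance matrix
#'
#' First line: number of taxa; then one row per taxon: label followed by
#' the distances to the preceding taxa.
#'
#' @param path file path
#' @return labelled square symmetric matrix
#' @export
read_phylip_lower <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  n <- as.integer(trimws(ln[1]))
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(ln[i + 1]), "\\s+")[[1]]
    labs[i] <- parts[1]
    if (i > 1) d[i, 1:(i - 1)] <- as.numeric(parts[2:i])
  }
  d <- d + t(d)
  dimnames(d) <- list(labs, labs)
  d
}
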