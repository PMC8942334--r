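# Rigid and flexible Calpha structure alignment: Kabsch superposition,
# aligned-fragment-pair (AFP) detection, monotone chaining with optional
# hinge twists, similarity scoring, empirical P-values, and measurement of
# inter-block hinge rotations.

#' Default alignment parameters
#'
#' AFP window length, AFP RMSD cutoff, chaining gap cap, twist budget and
#' penalty, and the raw-score constants. `s0` points per well-superposed
#' equivalent position gives scores on a 0-1000 scale for domains of a few
#' hundred residues; `d_c` is the deviation (Angstrom) at which a position
#' stops contributing; `t0` is the per-twist penalty. `rot_tol_deg` /
#' `trans_tol` bound how much two fragment transforms may disagree and
#' still be chained into one rigid block.
#'
#' @param afp_len AFP window length (residues)
#' @param afp_rmsd_max AFP superposition RMSD cutoff (Angstrom)
#' @param gap_max maximum per-axis gap between chained AFPs (residues)
#' @param max_twists maximum rigid-block changes in flexible mode
#' @param twist_penalty score penalty per twist (`t0`)
#' @param s0 score points per equivalent position
#' @param d_c deviation scale of the score (Angstrom)
#' @param rot_tol_deg rigid-block rotation agreement tolerance (degrees)
#' @param trans_tol rigid-block translation agreement tolerance (Angstrom)
#' @return named list of parameters
#' @export
align_params <- function(afp_len = 8L, afp_rmsd_max = 3.0, gap_max = 30L,
                         max_twists = 5L, twist_penalty = 50, s0 = 4.0,
                         d_c = 5.0, rot_tol_deg = 30, trans_tol = 5.0) {
  list(afp_len = as.integer(afp_len), afp_rmsd_max = afp_rmsd_max,
       gap_max = as.integer(gap_max), max_twists = as.integer(max_twists),
       twist_penalty = twist_penalty, s0 = s0, d_c = d_c,
       rot_tol_deg = rot_tol_deg, trans_tol = trans_tol)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `P` mapped onto `Q` (`x -> R x + t`); reflections are excluded.
#'
#' @param P,Q n x 3 coordinate matrices (rows are points), n >= 3
#' @return object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom)
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("P and Q must have identical dimensions")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (min(svd(Pc)$d) < 1e-9 && min(svd(Qc)$d) < 1e-9)
    stop("degenerate (collinear) point set")
  C <- crossprod(Pc, Qc)           # sum p q^T
  sv <- svd(C)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, sgn))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cq - as.numeric(R %*% cp)
  dev <- Qc - Pc %*% t(R)
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(rowSums(dev^2)))),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix
#' @param sup a `superposition`
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' Find aligned fragment pairs (AFPs) between two traces
#'
#' Scans all windows of `afp_len` residues in A against all windows in B and
#' keeps those whose Kabsch superposition RMSD is at most `afp_rmsd_max`.
#'
#' @param A,B [ca_trace()] objects
#' @param afp_len window length (residues)
#' @param afp_rmsd_max RMSD cutoff (Angstrom)
#' @return data frame with columns `i`, `j` (1-based window starts in A and
#'   B) and `rmsd`
#' @export
find_afps <- function(A, B, afp_len = 8L, afp_rmsd_max = 3.0) {
  if (nrow(A$xyz) < afp_len || nrow(B$xyz) < afp_len)
    stop("trace shorter than the AFP window")
  sc <- .afp_scan_cpp(A$xyz, B$xyz, as.integer(afp_len), afp_rmsd_max)
  data.frame(i = sc$i + 1L, j = sc$j + 1L, rmsd = sc$rmsd)
}

# shared engine behind rigid_align / flexible_align
align_engine <- function(A, B, params, flexible) {
  L <- params$afp_len
  if (nrow(A$xyz) < L || nrow(B$xyz) < L)
    stop("trace shorter than the AFP window")
  # same-diagonal AFP runs are thinned to stride 4 (ends kept): the union of
  # the retained windows covers the same residues, at a fraction of the
  # chaining cost
  sc <- .afp_scan_cpp(A$xyz, B$xyz, L, params$afp_rmsd_max, 4L)
  empty <- structure(list(pairs = matrix(integer(0), 0, 2), twists = list(),
                          blocks = integer(0), superpositions = list(),
                          rmsd = NA_real_, n_equiv = 0L, raw_score = 0,
                          p_value = 1, seq_identity = NA_real_,
                          flexible = flexible),
                     class = "struct_alignment")
  if (length(sc$i) == 0) return(empty)
  w <- params$s0 * L * pmax(0, 1 - (sc$rmsd / params$d_c)^2)
  ch <- .chain_afps_cpp(sc$i, sc$j, w, sc$rot, sc$ca, sc$cb, L,
                        params$gap_max, params$twist_penalty,
                        if (flexible) params$max_twists else 0L,
                        params$rot_tol_deg, params$trans_tol)
  if (length(ch$chain) == 0) return(empty)
  ci <- sc$i[ch$chain] + 1L
  cj <- sc$j[ch$chain] + 1L
  block_of_afp <- cumsum(c(TRUE, ch$twist_before[-1]))
  # union of window positions; an overlapped position keeps its first block
  off <- 0:(L - 1)
  pa <- rep(ci, each = L) + off
  pb <- rep(cj, each = L) + off
  blk <- rep(block_of_afp, each = L)
  keep <- !duplicated(pa)
  pairs <- cbind(a = pa[keep], b = pb[keep])
  blk <- blk[keep]
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  blk <- blk[o]
  nblk <- max(blk)
  sups <- vector("list", nblk)
  d <- numeric(nrow(pairs))
  for (bi in seq_len(nblk)) {
    sel <- blk == bi
    sup <- kabsch(A$xyz[pairs[sel, 1], , drop = FALSE],
                  B$xyz[pairs[sel, 2], , drop = FALSE])
    sups[[bi]] <- sup
    moved <- apply_superposition(A$xyz[pairs[sel, 1], , drop = FALSE], sup)
    d[sel] <- sqrt(rowSums((moved - B$xyz[pairs[sel, 2], , drop = FALSE])^2))
  }
  if (!flexible && nblk == 1) {
    # single global superposition over the whole equivalence set
    sup <- kabsch(A$xyz[pairs[, 1], , drop = FALSE],
                  B$xyz[pairs[, 2], , drop = FALSE])
    sups <- list(sup)
    moved <- apply_superposition(A$xyz[pairs[, 1], , drop = FALSE], sup)
    d <- sqrt(rowSums((moved - B$xyz[pairs[, 2], , drop = FALSE])^2))
  }
  twists <- if (nblk > 1) {
    bstart <- which(!duplicated(blk))[-1]
    lapply(seq_along(bstart), function(k)
      list(boundary = bstart[k], transform = sups[[k + 1]]))
  } else list()
  seqid <- 100 * mean(A$labels$aa[pairs[, 1]] == B$labels$aa[pairs[, 2]])
  structure(list(pairs = pairs, twists = twists, blocks = blk,
                 superpositions = sups, rmsd = sqrt(mean(d^2)),
                 n_equiv = nrow(pairs),
                 raw_score = alignment_score(d, nblk - 1L, params$s0,
                                             params$d_c, params$twist_penalty),
                 p_value = NA_real_, seq_identity = seqid,
                 flexible = flexible),
            class = "struct_alignment")
}

#' Rigid structural alignment of two Calpha traces
#'
#' Chains AFPs monotonically (both index sequences strictly increasing,
#' per-axis gaps capped) by dynamic programming, requiring every chained
#' fragment to be consistent with a single rigid transform; the final
#' superposition is refitted by Kabsch on the full equivalence set.
#'
#' @param A,B [ca_trace()] objects
#' @param params parameter list from [align_params()]
#' @return object of class `struct_alignment` with elements `pairs`
#'   (n_equiv x 2 matrix of equivalenced trace indices), `twists` (empty),
#'   `superpositions`, `rmsd`, `n_equiv`, `raw_score`, `p_value` (NA until
#'   calibrated) and `seq_identity` (percent)
#' @export
rigid_align <- function(A, B, params = align_params()) {
  align_engine(A, B, params, flexible = FALSE)
}

#' Flexible structural alignment allowing hinge twists
#'
#' As [rigid_align()], but the chaining may open a new rigid block (a
#' "twist") between consecutive AFPs at a score penalty, up to
#' `params$max_twists` blocks; per-block superpositions are reported and the
#' RMSD is computed after applying each block's transform.
#'
#' @inheritParams rigid_align
#' @return a `struct_alignment` (see [rigid_align()])
#' @export
flexible_align <- function(A, B, params = align_params()) {
  align_engine(A, B, params, flexible = TRUE)
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf(
    "<struct_alignment> %s: n_equiv %d, rmsd %.2f A, raw score %.1f, %d twist(s)%s\n",
    if (x$flexible) "flexible" else "rigid", x$n_equiv, x$rmsd, x$raw_score,
    length(x$twists),
    if (is.na(x$p_value)) "" else sprintf(", P = %.3g", x$p_value)))
  invisible(x)
}

#' Raw similarity score from per-position deviations
#'
#' `score = s0 * sum_k max(0, 1 - (d_k / d_c)^2) - t0 * n_twists`, floored
#' at zero. With the defaults, 250 perfectly superposed positions and no
#' twist give 1000.
#'
#' @param d numeric vector of per-position deviations (Angstrom, >= 0)
#' @param n_twists number of twists used by the alignment
#' @param s0,d_c,t0 score constants (see [align_params()])
#' @return raw score (dimensionless)
#' @export
alignment_score <- function(d, n_twists = 0L, s0 = 4.0, d_c = 5.0, t0 = 50) {
  if (any(d < 0)) stop("deviations must be non-negative")
  max(0, s0 * sum(pmax(0, 1 - (d / d_c)^2)) - t0 * n_twists)
}

#' Percent sequence identity over an alignment's equivalenced positions
#' @param aln a `struct_alignment`
#' @param seqA,seqB one-letter sequences (single strings) of the two traces
#' @return percent identity (0-100)
#' @export
seq_identity <- function(aln, seqA, seqB) {
  if (aln$n_equiv == 0) stop("empty alignment: sequence identity undefined")
  a <- strsplit(seqA, "")[[1]][aln$pairs[, 1]]
  b <- strsplit(seqB, "")[[1]][aln$pairs[, 2]]
  100 * mean(a == b)
}

#' Calibrate the null distribution of raw scores
#'
#' Aligns `n` independent pairs of random synthetic helix bundles (matched
#' length distribution) with [flexible_align()] and fits a Gumbel (extreme
#' value) distribution to the resulting raw scores by maximum likelihood.
#' The fit converts raw scores into P-values via [score_pvalue()].
#'
#' @param bundle_generator function(seed) returning a `ca_trace`; the
#'   default generates random bundles of 4-8 helices
#' @param n number of null pairs (>= 50)
#' @param seed RNG seed
#' @param params alignment parameters
#' @return object of class `null_calibration`: list with `location`,
#'   `scale`, `n_samples`, `seed` and the null `scores` themselves
#' @export
calibrate_null <- function(bundle_generator = NULL, n = 200L, seed = 1L,
                           params = align_params()) {
  if (n < 50) stop("need at least 50 null samples")
  if (is.null(bundle_generator)) {
    bundle_generator <- function(s) {
      with_seed(s, {
        nh <- sample(4:8, 1)
        make_bundle(helix_lengths = sample(8:20, nh, replace = TRUE),
                    loop_lengths = sample(4:8, nh - 1, replace = TRUE),
                    seed = hash_seed("bundle", s)) |> select_chain() |> ca_trace()
      })
    }
  }
  scores <- vapply(seq_len(n), function(k) {
    A <- bundle_generator(hash_seed(paste0("nullA", k), seed))
    B <- bundle_generator(hash_seed(paste0("nullB", k), seed))
    flexible_align(A, B, params)$raw_score
  }, 0)
  if (diff(range(scores)) < 1e-9)
    stop("degenerate null scores: calibration impossible")
  # Gumbel MLE, parameterized (location mu, log scale)
  nll <- function(p) {
    z <- (scores - p[1]) / exp(p[2])
    sum(p[2] + z + exp(-z))
  }
  init <- c(mean(scores) - 0.5772 * sd(scores) * sqrt(6) / pi,
            log(sd(scores) * sqrt(6) / pi))
  fit <- optim(init, nll, method = "Nelder-Mead")
  structure(list(location = fit$par[1], scale = exp(fit$par[2]),
                 n_samples = n, seed = seed, scores = scores),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("<null_calibration> Gumbel(location %.1f, scale %.1f), n = %d, seed = %d\n",
              x$location, x$scale, x$n_samples, x$seed))
  invisible(x)
}

#' P-value of a raw score under a null calibration
#'
#' Upper-tail Gumbel probability
#' `p = 1 - exp(-exp(-(score - location)/scale))`, clamped to (1e-300, 1].
#'
#' @param score raw alignment score
#' @param cal a [calibrate_null()] result
#' @return P-value in (0, 1]
#' @export
score_pvalue <- function(score, cal) {
  stopifnot(inherits(cal, "null_calibration"))
  p <- 1 - exp(-exp(-(score - cal$location) / cal$scale))
  pmin(1, pmax(1e-300, p))
}

#' Measure the hinge rotation between two helix blocks
#'
#' Superposes the reference block of A onto the reference block of B,
#' applies that transform to A's moving block, and reports the axis-angle of
#' the residual rotation mapping the transformed moving block onto B's.
#' Matched helices are truncated to a common residue count from their
#' N-terminal (aligned) ends so the two blocks have equal Calpha counts.
#'
#' @param A,B [ca_trace()] objects
#' @param core a [assign_core()] result matching A's and B's helices
#' @param ref core labels of the reference block (default c4-c6)
#' @param moving core labels of the moving block (default c1-c3)
#' @return object of class `rotation_report`: list with `axis` (unit
#'   vector), `angle` (degrees, in 0-180), `reference_block`,
#'   `moving_block`, `n_ref`, `n_moving`
#' @export
block_rotation <- function(A, B, core, ref = c("c4", "c5", "c6"),
                           moving = c("c1", "c2", "c3")) {
  labs <- vapply(core, `[[`, "", "label")
  miss <- setdiff(c(ref, moving), labs)
  if (length(miss) > 0)
    stop("core label(s) not present: ", paste(miss, collapse = ", "))
  block_xyz <- function(labels) {
    xa <- NULL; xb <- NULL
    for (lb in labels) {
      p <- core[[match(lb, labs)]]
      la <- p$a$end - p$a$start + 1
      lbn <- p$b$end - p$b$start + 1
      m <- min(la, lbn)
      xa <- rbind(xa, A$xyz[p$a$start:(p$a$start + m - 1), , drop = FALSE])
      xb <- rbind(xb, B$xyz[p$b$start:(p$b$start + m - 1), , drop = FALSE])
    }
    list(a = xa, b = xb)
  }
  rb <- block_xyz(ref); mb <- block_xyz(moving)
  if (nrow(rb$a) < 9 || nrow(mb$a) < 9)
    stop("block too small for a well-conditioned rotation (need >= 9 residues)")
  sup_ref <- kabsch(rb$a, rb$b)
  moved <- apply_superposition(mb$a, sup_ref)
  resid <- kabsch(moved, mb$b)
  aa <- axis_angle(resid$rotation)
  structure(list(axis = aa$axis, angle = aa$angle,
                 reference_block = ref, moving_block = moving,
                 n_ref = nrow(rb$a), n_moving = nrow(mb$a)),
            class = "rotation_report")
}

#' @export
print.rotation_report <- function(x, ...) {
  cat(sprintf("<rotation_report> %s relative to %s: %.1f deg about (%.2f, %.2f, %.2f)\n",
              paste(x$moving_block, collapse = ","),
              paste(x$reference_block, collapse = ","),
              x$angle, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
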