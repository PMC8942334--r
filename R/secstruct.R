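# Helix detection from Calpha geometry and assignment of the matched
# helix core (c1..cK) between two aligned structures.

#' Detect alpha-helical segments from Calpha geometry
#'
#' A residue i opens a helical window when the 5-residue Calpha fragment
#' i..i+4 superposes onto an ideal alpha-helix template (1.5 Angstrom rise,
#' 2.3 Angstrom radius, 100 degrees per residue) with Kabsch RMSD at most
#' `template_rmsd_max`, all five residues lying within the same unbroken
#' chain segment. Maximal runs of flagged window starts become segments (a
#' segment spans from the first flagged start to the last flagged start
#' + 4) when the implied helix has at least `min_len` residues; runs
#' separated by exactly one non-helical start are merged. The criterion is
#' superposition-based, hence invariant under rigid motion of the trace,
#' and tolerates moderate coordinate noise (the expected template residual
#' under isotropic noise sigma is about `sigma * sqrt(8/5)`, well below the
#' default threshold for sigma up to ~0.3 Angstrom).
#'
#' Segment boundaries for the purpose of detection are residue-numbering
#' gaps and gross geometric breaks (consecutive Calpha step > 6 Angstrom);
#' the milder 2.0-4.5 Angstrom flags recorded by [ca_trace()] are not
#' treated as boundaries, since moderate noise routinely trips them.
#'
#' @param t a [ca_trace()]
#' @param min_len minimum helix length in residues (default 8)
#' @param template_rmsd_max per-window RMSD threshold against the ideal
#'   helix template (Angstrom)
#' @return list of helix segments, each a list with `start`, `end`
#'   (1-based inclusive trace indices), `axis` (unit vector, N to C) and
#'   `centroid`
#' @export
detect_helices <- function(t, min_len = 8L, template_rmsd_max = 0.7) {
  n <- nrow(t$xyz)
  if (n < 5) stop("trace too short for helix detection (need >= 5 residues)")
  step <- sqrt(rowSums((t$xyz[-1, , drop = FALSE] -
                          t$xyz[-n, , drop = FALSE])^2))
  gap <- diff(t$labels$res_seq) > 1 & t$labels$insert[-n] == "" &
    t$labels$insert[-1] == ""
  seg_id <- cumsum(c(1L, as.integer(step > 6.0 | gap)))
  tmpl <- ideal_helix_xyz(5L)
  sc <- .afp_scan_cpp(t$xyz, tmpl, 5L, template_rmsd_max)
  flag <- logical(n)
  flag[sc$i + 1L] <- TRUE
  same_seg <- seg_id[pmin(seq_len(n) + 4L, n)] == seg_id
  flag <- flag & same_seg & seq_len(n) <= n - 4L
  # maximal runs of flagged window starts
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 5 >= min_len, , drop = FALSE]
  if (nrow(runs) > 1) {  # merge runs separated by exactly one residue
    keep <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$start[k] - last$end == 2 &&
          seg_id[runs$start[k]] == seg_id[last$end]) {
        keep[[length(keep)]]$end <- runs$end[k]
      } else keep[[length(keep) + 1]] <- runs[k, ]
    }
    runs <- do.call(rbind, keep)
  }
  lapply(seq_len(nrow(runs)), function(k) {
    s <- runs$start[k]
    e <- min(runs$end[k] + 4L, n)  # flagged window [i, i+4] covers i..i+4
    xyz <- t$xyz[s:e, , drop = FALSE]
    ctr <- colMeans(xyz)
    ax <- prcomp(xyz, center = TRUE)$rotation[, 1]
    if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
    list(start = s, end = e, axis = ax / sqrt(sum(ax^2)), centroid = ctr)
  })
}

#' Assign the matched helix core between two structures
#'
#' Two helices (one per structure) are matched when at least `overlap_min`
#' of the shorter segment's residues are equivalenced, by the structural
#' alignment, to residues of the other segment. The returned core is the
#' longest ordered run of matched pairs with no intervening unmatched helix
#' in either structure; pairs are labelled c1..cK from the N-terminus.
#'
#' @param helA,helB helix lists from [detect_helices()] for structures A, B
#' @param aln a `struct_alignment` of A onto B (see [rigid_align()])
#' @param overlap_min matching threshold (fraction of the shorter segment)
#' @return object of class `core_assignment`: list of matched pairs, each
#'   with `label`, `a` and `b` (helix segments)
#' @export
assign_core <- function(helA, helB, aln, overlap_min = 0.6) {
  if (length(helA) == 0 || length(helB) == 0)
    stop("empty helix list")
  b_of_a <- rep(NA_integer_, max(aln$pairs[, 1]))
  b_of_a[aln$pairs[, 1]] <- aln$pairs[, 2]
  matched <- matrix(FALSE, length(helA), length(helB))
  for (p in seq_along(helA)) {
    ia <- helA[[p]]$start:helA[[p]]$end
    jb <- b_of_a[ia[ia <= length(b_of_a)]]
    jb <- jb[!is.na(jb)]
    for (q in seq_along(helB)) {
      lb <- helB[[q]]$start:helB[[q]]$end
      shorter <- min(length(ia), length(lb))
      matched[p, q] <- sum(jb %in% lb) >= overlap_min * shorter
    }
  }
  if (!any(matched)) stop("no matched helix pairs: empty core")
  # longest run of consecutive (p,q),(p+1,q+1),... matched pairs
  best <- NULL
  for (p in seq_along(helA)) for (q in seq_along(helB)) {
    if (!matched[p, q]) next
    if (p > 1 && q > 1 && matched[p - 1, q - 1]) next  # not a run start
    len <- 0
    while (p + len <= length(helA) && q + len <= length(helB) &&
           matched[p + len, q + len]) len <- len + 1
    if (is.null(best) || len > best$len) best <- list(p = p, q = q, len = len)
  }
  pairs <- lapply(seq_len(best$len), function(k) {
    list(label = paste0("c", k),
         a = helA[[best$p + k - 1]], b = helB[[best$q + k - 1]])
  })
  structure(pairs, class = "core_assignment")
}

#' @export
print.core_assignment <- function(x, ...) {
  cat(sprintf("<core_assignment> %d matched helix pairs (%s)\n", length(x),
              paste(vapply(x, `[[`, "", "label"), collapse = " ")))
  invisible(x)
}

#' Extract the Calpha trace of selected core helices
#'
#' @param t the [ca_trace()] of one of the two structures in `core`
#' @param core a [assign_core()] result
#' @param which character vector of core labels, e.g. `c("c1","c2","c3")`
#' @param side `"a"` or `"b"`: which structure of the assignment `t` is
#' @return a `ca_trace` of the concatenated helices, N-to-C order
#' @export
core_block <- function(t, core, which, side = c("a", "b")) {
  side <- match.arg(side)
  if (length(which) == 0) stop("empty core-helix selection")
  labs <- vapply(core, `[[`, "", "label")
  miss <- setdiff(which, labs)
  if (length(miss) > 0)
    stop("core label(s) not present: ", paste(miss, collapse = ", "))
  idx <- unlist(lapply(core[match(which[order(match(which, labs))], labs)],
                       function(p) p[[side]]$start:p[[side]]$end))
  subset_trace(t, idx)
}
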