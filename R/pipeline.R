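# End-to-end orchestration: all-vs-all alignment matrices, the score ->
# distance transform, tree inference by all configured methods, consensus,
# and the mean-score ("radial") tree, with optional on-disk reports.

#' All-vs-all structural similarity matrices
#'
#' Aligns every unordered pair of structures once per alignment method and
#' mirrors the score (the aligner, like any chaining heuristic, is not
#' exactly symmetric; the matrix is treated as symmetric downstream).
#' Diagonals hold self-alignment scores. A failed pair is recorded as
#' score 0 / P 1 with a warning and the run continues.
#'
#' @param structures named list of `pdb_structure` or `ca_trace` objects
#' @param methods subset of `c("rigid", "flexible")`
#' @param params alignment parameters ([align_params()])
#' @param calibration optional [calibrate_null()] result; when supplied,
#'   per-pair P-values are computed
#' @return list with `matrices` (one labelled similarity matrix per
#'   method) and `report` (data frame of per-pair records: method, a, b,
#'   raw_score, rmsd, n_equiv, n_twists, seq_identity, p_value)
#' @export
run_matrix <- function(structures, methods = c("rigid", "flexible"),
                       params = align_params(), calibration = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(structures) < 2) stop("need at least 2 structures")
  labs <- names(structures) %||% vapply(structures, function(s)
    s$id %||% "structure", "")
  if (is.null(names(structures))) names(structures) <- labs
  traces <- lapply(structures, function(s) {
    if (inherits(s, "ca_trace")) s else ca_trace(select_chain(s))
  })
  n <- length(traces)
  aligner <- list(rigid = rigid_align, flexible = flexible_align)
  mats <- list()
  rep_rows <- list()
  for (mth in methods) {
    M <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n)) {
      M[i, i] <- tryCatch(
        aligner[[mth]](traces[[i]], traces[[i]], params)$raw_score,
        error = function(e) 0)
    }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      aln <- tryCatch(aligner[[mth]](traces[[i]], traces[[j]], params),
                      error = function(e) {
                        warning(sprintf("alignment %s vs %s failed: %s",
                                        labs[i], labs[j], conditionMessage(e)))
                        NULL
                      })
      if (is.null(aln)) {
        M[i, j] <- M[j, i] <- 0
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          method = mth, a = labs[i], b = labs[j], raw_score = 0,
          rmsd = NA_real_, n_equiv = 0L, n_twists = 0L,
          seq_identity = NA_real_, p_value = 1)
        next
      }
      p <- if (is.null(calibration)) NA_real_
           else score_pvalue(aln$raw_score, calibration)
      M[i, j] <- M[j, i] <- aln$raw_score
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        method = mth, a = labs[i], b = labs[j], raw_score = aln$raw_score,
        rmsd = aln$rmsd, n_equiv = aln$n_equiv,
        n_twists = length(aln$twists), seq_identity = aln$seq_identity,
        p_value = p)
    }
    mats[[mth]] <- M
  }
  list(matrices = mats, report = do.call(rbind, rep_rows))
}

#' Infer, root and amalgamate trees from similarity matrices
#'
#' For each (similarity matrix, tree method) combination: cap scores,
#' transform to distances, infer the tree, and midpoint-root it. A
#' majority-rule consensus is assembled across all trees, and a
#' Fitch-Margoliash tree of the mean similarity matrix (the "radial" tree)
#' is additionally produced.
#'
#' @param matrices named list of labelled similarity matrices (e.g. from
#'   [run_matrix()]`$matrices`)
#' @param tree_methods subset of `c("upgma", "nj", "fm")`
#' @param consensus_threshold majority threshold for [consensus_tree()]
#' @param cap score ceiling ([cap_scores()])
#' @param out_dir optional directory: Newick trees, distance matrices and a
#'   run manifest are written there
#' @return list with `trees` (named list, one rooted `phylo` per
#'   matrix-method pair), `consensus`, and `radial`
#' @export
run_trees <- function(matrices, tree_methods = c("upgma", "nj", "fm"),
                      consensus_threshold = 0.5, cap = 1000,
                      out_dir = NULL) {
  tree_methods <- match.arg(tree_methods, several.ok = TRUE)
  if (length(matrices) < 1) stop("need at least one similarity matrix")
  if (is.null(names(matrices)))
    names(matrices) <- paste0("m", seq_along(matrices))
  infer <- list(upgma = upgma_tree, nj = nj_tree, fm = fitch_margoliash)
  trees <- list()
  for (mn in names(matrices)) {
    dm <- sim_to_dist_matrix(cap_scores(matrices[[mn]], cap), cap)
    for (tm in tree_methods) {
      tr <- infer[[tm]](dm)
      if (!ape::is.rooted(tr) || tm != "upgma") tr <- midpoint_root(tr)
      trees[[paste(mn, tm, sep = "_")]] <- tr
    }
  }
  cons <- if (length(trees) >= 2)
    consensus_tree(unname(trees), threshold = consensus_threshold)
  else trees[[1]]
  mean_dm <- sim_to_dist_matrix(cap_scores(mean_similarity(matrices), cap),
                                cap)
  radial <- midpoint_root(fitch_margoliash(mean_dm))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(trees))
      writeLines(write_newick(trees[[nm]]),
                 file.path(out_dir, paste0(nm, ".nwk")))
    writeLines(write_newick(cons), file.path(out_dir, "consensus.nwk"))
    writeLines(write_newick(radial), file.path(out_dir, "radial.nwk"))
    for (mn in names(matrices))
      write_matrix_tsv(matrices[[mn]],
                       file.path(out_dir, paste0(mn, "_similarity.tsv")))
    manifest <- c(
      sprintf("structphylo run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("matrices: %s", paste(names(matrices), collapse = ", ")),
      sprintf("tree methods: %s", paste(tree_methods, collapse = ", ")),
      sprintf("consensus threshold: %g", consensus_threshold),
      sprintf("score cap: %g", cap),
      sprintf("labels: %s", paste(rownames(matrices[[1]]), collapse = ", ")),
      sprintf("R version: %s", R.version.string))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  list(trees = trees, consensus = cons, radial = radial)
}

#' Guide trees for the topology-recovery experiment
#'
#' Random bifurcating 10-leaf topologies with branch lengths drawn as the
#' square root of Uniform(0.3, 1). Under the family generator's noise model
#' (per-branch displacement sd = noise_rate x branch length), pairwise
#' structural divergence accumulates with the squared branch length, so
#' drawing lengths on the square-root scale makes the expected
#' score-derived distances additive with effective edge weights bounded
#' away from zero - the regime in which distance methods are guaranteed to
#' recover the topology.
#'
#' @param n_leaves number of leaves
#' @param seed RNG seed
#' @return a `phylo` guide tree
#' @export
recovery_guide_tree <- function(n_leaves = 10L, seed = 1L) {
  with_seed(seed, {
    g <- ape::rtree(n_leaves)
    g$edge.length <- sqrt(runif(nrow(g$edge), 0.3, 1))
    g
  })
}

#' End-to-end topology-recovery experiment
#'
#' For each replicate: generate a guide tree ([recovery_guide_tree()]) and a
#' seven-helix ancestor (~200 residues, the size of a nuclear-receptor
#' ligand-binding domain), evolve a family of structures along the guide
#' tree, run the full pipeline (pairwise alignment matrices with both
#' engines, score capping, distance transform, UPGMA / NJ /
#' Fitch-Margoliash, majority-rule consensus), and record the
#' Robinson-Foulds distance of the consensus tree to the guide tree.
#'
#' @param n_replicates number of seeded replicates
#' @param n_leaves family size
#' @param noise_rate Angstrom of coordinate noise per unit branch length
#' @param seed master seed; replicate seeds are derived from it
#' @param methods alignment engines for the matrices
#' @return data frame with one row per replicate: `replicate`, `rf`
#'   (consensus vs guide), and per-method RF columns
#' @export
topology_recovery <- function(n_replicates = 20L, n_leaves = 10L,
                              noise_rate = 0.4, seed = 1L,
                              methods = c("rigid", "flexible")) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    guide <- recovery_guide_tree(n_leaves,
                                 seed = hash_seed(paste0("guide", r), seed))
    anc <- make_bundle(c(24, 26, 22, 24, 23, 25, 20), rep(6L, 6),
                       seed = hash_seed(paste0("anc", r), seed))
    fam <- evolve_family(anc, guide, noise_rate = noise_rate,
                         seed = hash_seed(paste0("fam", r), seed))
    rm <- run_matrix(fam, methods = methods)
    rt <- suppressWarnings(run_trees(rm$matrices))
    out <- data.frame(replicate = r,
                      rf = robinson_foulds(rt$consensus, guide))
    for (nm in names(rt$trees))
      out[[paste0("rf_", nm)]] <- robinson_foulds(rt$trees[[nm]], guide)
    out
  })
  do.call(rbind, rows)
}
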