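test_that("score capping and the distance transform follow the stated rules", {
  m <- matrix(c(0, 1500, 486, 1500, 0, 1000, 486, 1000, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  capped <- cap_scores(m)
  expect_equal(capped["a", "b"], 1000)
  expect_equal(capped["a", "c"], 486)
  expect_equal(cap_scores(matrix(numeric(0), 0, 0)),
               matrix(numeric(0), 0, 0))

  expect_equal(similarity_to_distance(1000), 0)
  expect_equal(similarity_to_distance(0), 1)
  expect_equal(similarity_to_distance(486), 0.514)
  expect_error(similarity_to_distance(-5), "negative")

  d <- sim_to_dist_matrix(m)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("mean_similarity averages elementwise with matched labels", {
  m <- matrix(runif(16, 0, 900), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  m <- (m + t(m)) / 2
  expect_equal(mean_similarity(list(m, m)), m)
  expect_equal(mean_similarity(list(m, 3 * m)), 2 * m)
  m3 <- list(m, 2 * m, 4 * m)
  expect_equal(mean_similarity(m3), (m + 2 * m + 4 * m) / 3)
  bad <- m; rownames(bad) <- colnames(bad) <- letters[5:8]
  expect_error(mean_similarity(list(m, bad)), "mismatch")
})

test_that("upgma_tree agglomerates correctly with deterministic ties", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  d4 <- matrix(0.6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4[1, 2] <- d4[2, 1] <- 0.2; d4[3, 4] <- d4[4, 3] <- 0.2; diag(d4) <- 0
  t4 <- upgma_tree(d4)
  expect_equal(robinson_foulds(
    t4, parse_newick("((A:1,B:1):1,(C:1,D:1):1);")), 0)
  cop <- ape::cophenetic.phylo(t4)
  expect_equal(cop["A", "B"], 0.2)
  expect_equal(cop["A", "C"], 0.6)
  # ultrametric: equal root-to-leaf depths
  depths <- ape::node.depth.edgelength(t4)[1:4]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)

  # equal all-pairs matrix: deterministic caterpillar by lowest-index ties
  de <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  expect_equal(write_newick(upgma_tree(de)), write_newick(upgma_tree(de)))
  expect_equal(robinson_foulds(
    upgma_tree(de), parse_newick("(((A:1,B:1):1,C:2):1,D:3);")), 0)

  expect_error(upgma_tree(d4[1, 1, drop = FALSE]), "small|labelled")
})

test_that("upgma_tree recovers ultrametric matrices exactly", {
  for (k in 1:30) {
    gen <- structphylo:::with_seed(400 + k, ape::rcoal(sample(4:12, 1)))
    d <- ape::cophenetic.phylo(gen)
    t2 <- upgma_tree(d)
    expect_equal(robinson_foulds(gen, t2), 0)
    expect_equal(ape::cophenetic.phylo(t2)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("nj_tree is exact on additive matrices and clamps negatives", {
  # 3-leaf closed form
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  cop <- ape::cophenetic.phylo(t3)
  expect_equal(cop["A", "B"], 3)
  expect_equal(cop["A", "C"], 4)
  expect_equal(cop["B", "C"], 5)

  # additivity oracle: distances from a known tree are reproduced exactly,
  # and the installed NJ implementation agrees
  for (k in 1:100) {
    ra <- random_additive(sample(4:12, 1), seed = 600 + k)
    t2 <- nj_tree(ra$d)
    expect_equal(robinson_foulds(ra$tree, t2), 0)
    expect_equal(ape::cophenetic.phylo(t2)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
    expect_equal(robinson_foulds(t2, ape::nj(ra$d)), 0)
  }

  # Atteson condition: perturbation below half the smallest internal edge
  ra <- random_additive(6, seed = 12)
  internal <- ra$tree$edge.length[ra$tree$edge[, 2] >
                                    length(ra$tree$tip.label)]
  eps <- 0.4 * min(internal)
  pert <- structphylo:::with_seed(5, {
    e <- matrix(runif(36, -eps / 2, eps / 2), 6, 6)
    e <- (e + t(e)) / 2; diag(e) <- 0
    pmax(ra$d + e, 0)
  })
  diag(pert) <- 0
  expect_equal(robinson_foulds(nj_tree(pert), ra$tree), 0)

  dneg <- matrix(c(0, 1, 1, 4, 1, 0, 1, 1, 1, 1, 0, 1, 4, 1, 1, 0), 4, 4,
                 dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(nj_tree(dneg), "clamped")
  expect_error(nj_tree(dneg[1:2, 1:2]), "small")
})

test_that("fitch_margoliash fits branch lengths by weighted least squares", {
  ra <- random_additive(8, seed = 77)
  fm <- fitch_margoliash(ra$d)
  expect_lt(attr(fm, "objective"), 1e-12)
  expect_equal(robinson_foulds(fm, ra$tree), 0)
  expect_equal(ape::cophenetic.phylo(fm)[rownames(ra$d), colnames(ra$d)],
               ra$d, tolerance = 1e-6)

  # objective never above the NJ starting tree's fit
  pd <- structphylo:::with_seed(3, {
    e <- matrix(runif(64, -0.05, 0.05), 8, 8); e <- (e + t(e)) / 2
    diag(e) <- 0
    pmax(ra$d + e, 0.01)
  })
  diag(pd) <- 0
  start_fit <- structphylo:::wls_fit(ape::unroot(nj_tree(pd)), pd)
  fm2 <- fitch_margoliash(pd)
  expect_lte(attr(fm2, "objective"), start_fit$objective + 1e-12)
  expect_gt(attr(fm2, "objective"), 0)

  # 4-leaf brute-force oracle: optimize the 5 edge lengths numerically on
  # the same topology and compare fitted branch lengths
  d4 <- matrix(c(0, 2, 5, 6, 2, 0, 5.4, 6, 5, 5.4, 0, 3, 6, 6, 3, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  fm4 <- fitch_margoliash(d4)
  pm <- structphylo:::path_matrix(fm4)
  y <- d4[cbind(fm4$tip.label[pm$pairs[, 1]], fm4$tip.label[pm$pairs[, 2]])]
  w <- 1 / y^2
  obj <- function(b) sum(w * (y - as.numeric(pm$X %*% b))^2)
  oracle <- optim(rep(1, ncol(pm$X)), obj, method = "L-BFGS-B",
                  lower = 0, control = list(maxit = 2000, factr = 1e3))
  expect_equal(attr(fm4, "objective"), oracle$value, tolerance = 1e-6)
  expect_equal(fm4$edge.length, oracle$par, tolerance = 1e-3)

  # zero off-diagonal distances are handled by the weight cap
  dz <- ra$d; dz["t1", "t2"] <- dz["t2", "t1"] <- 0
  expect_no_error(fitch_margoliash(dz))
})

test_that("midpoint rooting balances the two farthest leaves", {
  t3 <- parse_newick("(A:1,B:2,C:3);")
  r <- midpoint_root(t3)
  dep <- ape::node.depth.edgelength(r)
  far <- sort(dep[match(c("B", "C"), r$tip.label)])
  expect_equal(unname(far), c(2.5, 2.5))

  q <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  rq <- midpoint_root(ape::unroot(q))
  dq <- ape::node.depth.edgelength(rq)[1:4]
  expect_equal(max(dq), 2)

  again <- midpoint_root(r)
  expect_equal(robinson_foulds(again, r), 0)
  expect_equal(sort(again$edge.length), sort(r$edge.length))

  z <- parse_newick("(A:0,B:0,C:0);")
  expect_error(midpoint_root(z), "degenerate")
})

test_that("consensus_tree keeps majority splits with supports and lengths", {
  ts <- list(parse_newick("((A:1,B:1):1,(C:1,D:1):1,E:1);"),
             parse_newick("((A:1,B:1):2,(C:1,D:1):2,E:1);"),
             parse_newick("((A:1,C:1):1,(B:1,D:1):1,E:1);"))
  same <- consensus_tree(ts[c(1, 1)])
  expect_equal(robinson_foulds(same, ts[[1]]), 0)
  expect_true(all(as.numeric(same$node.label[nzchar(same$node.label)]) == 1))

  cs <- consensus_tree(ts)
  expect_equal(robinson_foulds(cs, ts[[1]]), 0)  # majority topology
  sup <- as.numeric(cs$node.label[nzchar(cs$node.label)])
  expect_equal(sort(sup), c(2 / 3, 2 / 3), tolerance = 1e-3)
  # mean branch length over the trees containing the {A,B} split
  key_edge <- cs$edge.length[cs$edge[, 2] > length(cs$tip.label)]
  expect_true(all(abs(key_edge - 1.5) < 1e-9))
  # installed implementation agrees on the topology
  expect_equal(robinson_foulds(cs, ape::consensus(ts, p = 0.5)), 0)

  # a strict threshold collapses minority splits to a star
  star <- consensus_tree(ts, threshold = 0.99)
  expect_equal(star$Nnode, 1)

  bad <- parse_newick("((A:1,B:1):1,(C:1,X:1):1,E:1);")
  expect_error(consensus_tree(list(ts[[1]], bad)), "mismatch")
})

test_that("robinson_foulds counts split differences symmetrically", {
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(t2, t1), robinson_foulds(t1, t2))
  expect_error(robinson_foulds(t1, parse_newick("((A:1,B:1):1,(C:1,X:1):1);")),
               "mismatch")
})

test_that("newick and matrix I/O round-trip", {
  for (k in 1:10) {
    tr <- structphylo:::with_seed(800 + k, ape::rtree(sample(3:15, 1)))
    back <- parse_newick(write_newick(tr))
    expect_equal(robinson_foulds(tr, back), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-5)
  }
  two <- parse_newick("(A:1,B:1);")
  expect_equal(sort(two$tip.label), c("A", "B"))
  quoted <- parse_newick("('tip one':1,'tip two':2,C:1);")
  expect_true("tip one" %in% quoted$tip.label)
  expect_error(parse_newick("((A:1,B:1):1;"), "parenthes")

  m <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m <- (m + t(m)) / 2; diag(m) <- 0
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m, tolerance = 1e-12)

  ph <- tempfile()
  writeLines(c("3", "alpha", "beta 0.5", "gamma 0.3 0.4"), ph)
  dm <- read_phylip_lower(ph)
  expect_equal(dm["beta", "alpha"], 0.5)
  expect_equal(dm["gamma", "beta"], 0.4)
  expect_equal(dm, t(dm))
})

test_that("tree inference is invariant under label permutation", {
  ra <- random_additive(8, seed = 55)
  perm <- structphylo:::with_seed(9, sample(8))
  dp <- ra$d[perm, perm]
  expect_equal(robinson_foulds(nj_tree(dp), nj_tree(ra$d)), 0)
  expect_equal(robinson_foulds(fitch_margoliash(dp),
                               fitch_margoliash(ra$d)), 0)
  du <- ape::cophenetic.phylo(structphylo:::with_seed(2, ape::rcoal(8)))
  pu <- structphylo:::with_seed(10, sample(8))
  expect_equal(robinson_foulds(upgma_tree(du[pu, pu]), upgma_tree(du)), 0)
})
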