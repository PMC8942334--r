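test_that("kabsch recovers exact and noisy superpositions", {
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  idp <- kabsch(P, P)
  expect_equal(idp$rmsd, 0, tolerance = 1e-10)
  expect_equal(idp$rotation, diag(3), tolerance = 1e-8)

  R90 <- rotation_matrix(c(0, 0, 1), 90)
  Q <- sweep(P %*% t(R90), 2, c(5, 0, 0), `+`)
  sup <- kabsch(P, Q)
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)
  aa <- structphylo:::axis_angle(sup$rotation)
  expect_equal(aa$angle, 90, tolerance = 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(P, sup), Q, tolerance = 1e-8)

  expect_error(kabsch(P, P[1:5, ]), "dimension")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch equals the quaternion oracle on random point sets", {
  worst <- 0
  for (k in 1:100) {
    pq <- structphylo:::with_seed(k, {
      P <- matrix(rnorm(24, sd = 4), 8, 3)
      R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
      Q <- sweep(P %*% t(R), 2, rnorm(3, sd = 10), `+`) +
        matrix(rnorm(24, sd = 0.5), 8, 3)
      list(P = P, Q = Q)
    })
    diff <- abs(kabsch(pq$P, pq$Q)$rmsd - quaternion_rmsd(pq$P, pq$Q))
    worst <- max(worst, diff)
  }
  expect_lt(worst, 1e-6)
})

test_that("kabsch matches a brute-force rotation-grid oracle", {
  for (k in 1:3) {
    pq <- structphylo:::with_seed(300 + k, {
      P <- matrix(rnorm(24, sd = 4), 8, 3)
      R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
      Q <- P %*% t(R) + matrix(rnorm(24, sd = 0.5), 8, 3)
      list(P = P, Q = Q)
    })
    km <- kabsch(pq$P, pq$Q)$rmsd
    gm <- grid_rmsd(pq$P, pq$Q)
    expect_lte(km, gm + 1e-9)        # analytic optimum never above the grid
    expect_lt(abs(km - gm), 0.05)
  }
})

test_that("find_afps enumerates matching windows", {
  tr <- ca_trace(select_chain(make_bundle(c(20), NULL, seed = 2)))
  afps <- find_afps(tr, tr)
  diag_hits <- afps[afps$i == afps$j, ]
  expect_setequal(diag_hits$i, 1:13)
  expect_true(all(diag_hits$rmsd < 1e-6))

  line <- structure(list(labels = data.frame(res_seq = 1:20, insert = "",
                                             res_name = "ALA", aa = "A"),
                         xyz = cbind(3.8 * (0:19), 0, 0),
                         breaks = integer(0)), class = "ca_trace")
  expect_equal(nrow(find_afps(ideal_helix(20), line)), 0)

  # diverged pair: every diagonal window still present
  s <- bundle7(seed = 31)
  t1 <- ca_trace(select_chain(perturb(s, 0.2, seed = 1)))
  t2 <- ca_trace(select_chain(perturb(s, 0.2, seed = 2)))
  afps2 <- find_afps(t1, t2)
  expect_true(all(1:(length(t1) - 7) %in% afps2$i[afps2$i == afps2$j]))
})

test_that("rigid and flexible alignment handle identity and rigid copies", {
  s <- make_bundle(c(20, 20, 20, 20, 20, 20, 14), rep(5L, 6), seed = 9)
  tr <- ca_trace(select_chain(s))
  expect_gte(length(tr), 150)
  self <- rigid_align(tr, tr)
  expect_equal(self$n_equiv, length(tr))
  expect_lt(self$rmsd, 0.01)
  expect_length(self$twists, 0)

  rot <- random_rigid(tr, seed = 5)
  a2 <- rigid_align(tr, rot)
  expect_equal(a2$pairs, self$pairs)
  expect_lt(a2$rmsd, 0.01)

  # flexible self-alignment never pays for a twist
  fs <- flexible_align(tr, tr)
  expect_length(fs$twists, 0)
  expect_equal(fs$n_equiv, length(tr))
})

test_that("planted hinges separate rigid from flexible alignment", {
  hp <- hinge_pair(seed = 7, angle = 115)
  ta <- ca_trace(select_chain(hp$a))
  tb <- ca_trace(select_chain(hp$b))
  r <- rigid_align(ta, tb)
  f <- flexible_align(ta, tb)
  expect_lt(r$n_equiv / length(ta), 0.60)
  expect_gte(f$n_equiv / length(ta), 0.95)
  expect_length(f$twists, 1)
  expect_lt(f$rmsd, 1.0)
  # flexible can always reproduce the rigid solution up to one twist penalty
  expect_gte(f$raw_score, r$raw_score - align_params()$twist_penalty)
})

test_that("alignment is invariant under rigid motion and nearly symmetric", {
  s <- bundle7(seed = 21)
  t1 <- ca_trace(select_chain(perturb(s, 0.2, seed = 3)))
  t2 <- ca_trace(select_chain(perturb(s, 0.2, seed = 4)))
  base <- flexible_align(t1, t2)
  moved <- flexible_align(random_rigid(t1, 11), random_rigid(t2, 12))
  expect_equal(moved$pairs, base$pairs)
  expect_equal(moved$rmsd, base$rmsd, tolerance = 1e-3)

  # raw-score symmetry on diverged copies, 20 seeded pairs
  rel <- vapply(1:20, function(k) {
    s0 <- bundle7(seed = 100 + k)
    a <- ca_trace(select_chain(perturb(s0, runif(1, 0.1, 0.4), seed = 2 * k)))
    b <- ca_trace(select_chain(perturb(s0, runif(1, 0.1, 0.4),
                                       seed = 2 * k + 1)))
    ab <- flexible_align(a, b)$raw_score
    ba <- flexible_align(b, a)$raw_score
    abs(ab - ba) / max(ab, ba)
  }, 0)
  expect_true(all(rel < 0.01))
})

test_that("raw score follows its closed form", {
  expect_equal(alignment_score(rep(0, 250), 0), 1000)
  expect_equal(alignment_score(rep(0, 250), 2), 900)
  expect_equal(alignment_score(rep(5, 100), 0), 0)
  expect_equal(alignment_score(c(0, 2.5), 0), 4 * (1 + 0.75))
  expect_error(alignment_score(c(-1, 0)), "non-negative")
})

test_that("sequence identity is computed over equivalenced positions", {
  tr <- ca_trace(select_chain(make_bundle(c(10, 10), c(4), seed = 2)))
  aln <- rigid_align(tr, tr)
  sq <- trace_sequence(tr)
  expect_equal(seq_identity(aln, sq, sq), 100)
  other <- paste(rep("X", nchar(sq)), collapse = "")  # X never generated
  expect_equal(seq_identity(aln, sq, other), 0)
  half <- paste0(substr(sq, 1, aln$n_equiv / 2),
                 paste(rep("W", nchar(sq) - aln$n_equiv / 2), collapse = ""))
  expect_equal(seq_identity(aln, sq, half), 50, tolerance = 2)
})

test_that("null calibration yields usable Gumbel P-values", {
  cal <- calibrate_null(n = 60, seed = 4)
  cal2 <- calibrate_null(n = 60, seed = 4)
  expect_equal(cal$location, cal2$location)
  expect_equal(cal$scale, cal2$scale)
  expect_gt(cal$scale, 0)

  # P at the Gumbel location is 1 - 1/e by construction
  expect_equal(score_pvalue(cal$location, cal), 1 - exp(-1),
               tolerance = 1e-12)
  # the median of the fitted null sample maps to p ~ 0.5
  expect_equal(score_pvalue(median(cal$scores), cal), 0.5,
               tolerance = 0.05)

  # self-alignment of a 150-residue bundle is far in the upper tail
  tr <- ca_trace(select_chain(make_bundle(c(20, 20, 20, 20, 20, 14),
                                          c(5, 5, 5, 5, 4), seed = 2)))
  expect_lt(score_pvalue(rigid_align(tr, tr)$raw_score, cal), 0.05)

  # monotone decreasing in score, bounded in (0, 1]
  grid <- seq(-50, 2000, by = 50)
  pv <- score_pvalue(grid, cal)
  expect_true(all(diff(pv) <= 0))
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("block_rotation recovers planted hinge angles", {
  s <- bundle7(seed = 3, loops = c(4L, 5L, 4L, 4L, 5L, 4L))
  tr <- ca_trace(select_chain(s))
  hel <- detect_helices(tr)
  core_self <- assign_core(hel, hel, rigid_align(tr, tr))
  r0 <- block_rotation(tr, tr, core_self)
  expect_equal(r0$angle, 0, tolerance = 1e-6)

  for (ang in c(10, 45, 90, 115, 160)) {
    hp <- hinge_pair(seed = 3, angle = ang, axis = c(0, 0, 1))
    ta <- ca_trace(select_chain(hp$a)); tb <- ca_trace(select_chain(hp$b))
    core <- assign_core(detect_helices(ta), detect_helices(tb),
                        flexible_align(ta, tb))
    rep <- block_rotation(ta, tb, core)
    expect_equal(rep$angle, ang, tolerance = 1)
    expect_equal(sqrt(sum(rep$axis^2)), 1, tolerance = 1e-9)
  }

  # noisy hinge: within 5 degrees at sigma = 0.5
  hp <- hinge_pair(seed = 8, angle = 115)
  a5 <- perturb(hp$a, 0.5, seed = 41)
  b5 <- perturb(hp$b, 0.5, seed = 42)
  ta <- ca_trace(select_chain(a5)); tb <- ca_trace(select_chain(b5))
  core <- assign_core(detect_helices(ta, template_rmsd_max = 1),
                      detect_helices(tb, template_rmsd_max = 1),
                      flexible_align(ta, tb))
  expect_equal(block_rotation(ta, tb, core)$angle, 115, tolerance = 5)

  expect_error(block_rotation(tr, tr, core_self, ref = c("c8")),
               "not present")
})
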