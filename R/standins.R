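# Synthetic stand-ins emulating the terpene-synthase / nuclear-receptor
# comparison geometry. Real crystal structures are deliberately not bundled;
# these generators plant the published geometry (a shared seven-helix core
# and a ~115 degree rotation of the N-terminal three-helix block) so the
# full pipeline can be exercised and validated offline against known ground
# truth. Everything here is synthetic and labelled as such.

#' Synthetic TS-like / NR-like structure pair with a planted hinge
#'
#' Builds two synthetic Calpha bundles that share a seven-helix core: a
#' "TS-like" copy with two extra N-terminal helices, and an "NR-like" copy
#' whose first three core helices (c1-c3) have been rotated by
#' `hinge_angle` degrees about the z axis through the c3/c4 loop, emulating
#' the block rearrangement observed between farnesyl-pyrophosphate-synthase
#' type enzymes and nuclear-receptor ligand-binding domains. Both copies
#' receive Gaussian coordinate noise `sigma`.
#'
#' @param seed RNG seed
#' @param hinge_angle planted rotation of the c1-c3 block (degrees)
#' @param sigma coordinate noise (Angstrom)
#' @return list with `a` (TS-like `pdb_structure`), `b` (NR-like),
#'   `hinge_angle`, and `core_helices` (number of shared core helices)
#' @export
synthetic_ts_nr_pair <- function(seed = 42L, hinge_angle = 115, sigma = 0.3) {
  core_h <- c(14, 12, 10, 11, 10, 15, 9)
  core_l <- c(4, 5, 4, 4, 5, 4)
  a <- make_bundle(c(10, 12, core_h), c(3, 4, core_l), seed = seed,
                   id = "TSlike_synthetic")
  b <- make_bundle(core_h, core_l, seed = seed + 1L, id = "NRlike_synthetic")
  # rotate B's c1-c3 block (helices 1-3) about z through the c3/c4 loop
  lay <- attr(b, "layout")
  piv_res <- lay$loops[[3]]
  at <- b$models[[1]]
  pivot <- colMeans(as.matrix(at[at$res_seq %in% piv_res, c("x", "y", "z")]))
  block <- 1:max(piv_res)
  b <- apply_block_rotation(b, block, axis = c(0, 0, 1),
                            angle_deg = hinge_angle, pivot = pivot)
  attr(b, "layout") <- lay
  if (sigma > 0) {
    layA <- attr(a, "layout")
    a <- perturb(a, sigma, seed = seed + 2L); attr(a, "layout") <- layA
    b <- perturb(b, sigma, seed = seed + 3L); attr(b, "layout") <- lay
  }
  list(a = a, b = b, hinge_angle = hinge_angle, core_helices = 7L)
}

#' Synthetic FPP-synthase-like sequence with duplicated Asp-rich motifs
#'
#' A deterministic synthetic 366-residue sequence emulating the motif
#' layout of avian farnesyl pyrophosphate synthase: a DDxxD motif in the
#' first aspartate-rich region (around position 117) and a second DDxxD in
#' the second aspartate-rich region (around position 257). It is a
#' synthetic stand-in, not a database sequence.
#'
#' @return single character string (one-letter amino-acid codes)
#' @export
synthetic_fpps_like_seq <- function() {
  aa <- unname(AA_THREE_TO_ONE[1:20])
  s <- with_seed(20220203L, paste(sample(aa, 366, replace = TRUE),
                                  collapse = ""))
  # avoid spurious Asp-rich matches in the random background
  s <- gsub("D", "E", s)
  substr(s, 117, 121) <- "DDIMD"   # first Asp-rich (catalytic) motif
  substr(s, 257, 261) <- "DDYLD"   # second, duplicated motif
  s
}
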