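# Shared small helpers: seeded evaluation, rotations, 3-letter/1-letter codes.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @param seed integer seed
#' @param expr expression
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  eval.parent(substitute(expr))
}

# deterministic 31-bit hash of a character label combined with a seed,
# for per-branch RNG substreams
hash_seed <- function(label, seed) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(as.character(label))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be unit length)
#' @param angle_deg rotation angle in degrees (right-handed about `axis`)
#' @return 3x3 rotation matrix
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  nm <- sqrt(sum(a^2))
  if (nm <= 0) stop("axis must be non-zero")
  a <- a / nm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# axis-angle decomposition of a proper rotation; angle in [0, 180] degrees,
# axis chosen right-handed
axis_angle <- function(R) {
  tr <- sum(diag(R))
  ct <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(ct)
  if (th < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(th - pi) < 1e-6) {
    # axis from largest diagonal element of (R + I)/2
    M <- (R + diag(3)) / 2
    k <- which.max(diag(M))
    ax <- M[, k] / sqrt(M[k, k])
  } else {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(th))
  }
  ax <- ax / sqrt(sum(ax^2))
  list(axis = ax, angle = th * 180 / pi)
}

# 3-letter -> 1-letter amino acid table, with common nonstandard parents
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", CSO = "C", SEP = "S", TPO = "T",
  PTR = "Y", MLY = "K", HYP = "P", KCX = "K", CME = "C", CSD = "C"
)

aa_one <- function(res_name) {
  out <- AA_THREE_TO_ONE[toupper(res_name)]
  out[is.na(out)] <- "X"
  unname(out)
}

STANDARD_AA <- names(AA_THREE_TO_ONE)

`%||%` <- function(a, b) if (is.null(a)) b else a
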