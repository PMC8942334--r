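# Sequence-motif localization (DDxxD, WRS, basic replacements), rigid
# transfer of ligand poses through structural superpositions, and
# ligand-contact mapping / conservation scoring.

MOTIF_PATTERNS <- c(
  DDxxD = "DD..D",   # Asp-rich catalytic/metal-binding motif
  WRS   = "WRS",     # ESR1 contact motif containing the key arginine
  BASIC = "[RKQ]"    # basic-residue replacement (Arg, Lys or Gln)
)

#' Find sequence motifs
#'
#' Built-in patterns: `DDxxD` (D,D,any,any,D), `WRS`, and `BASIC` (a single
#' Arg, Lys or Gln). Matches are reported left to right; overlapping
#' matches are reported when they start at distinct positions.
#'
#' @param seq one-letter amino-acid string
#' @param pattern_name one of `names(structphylo:::MOTIF_PATTERNS)` or a
#'   custom name when `pattern` is supplied
#' @param pattern optional custom regular expression
#' @param residue_numbers optional vector of author residue numbers, one per
#'   sequence position, carried into the hits for reporting
#' @return data frame with columns `pattern_name`, `start` (1-based),
#'   `matched_text`, `residue_first` (author numbering of the first matched
#'   residue, NA when not supplied)
#' @export
find_motifs <- function(seq, pattern_name, pattern = NULL,
                        residue_numbers = NULL) {
  if (!nzchar(seq)) stop("empty sequence")
  if (is.null(pattern)) {
    if (!pattern_name %in% names(MOTIF_PATTERNS))
      stop("unknown pattern '", pattern_name, "'; built-ins: ",
           paste(names(MOTIF_PATTERNS), collapse = ", "))
    pattern <- MOTIF_PATTERNS[[pattern_name]]
  }
  # lookahead so overlapping matches at distinct starts are all reported
  m <- gregexpr(paste0("(?=(", pattern, "))"), seq, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(pattern_name = character(), start = integer(),
                      matched_text = character(), residue_first = integer()))
  starts <- as.integer(m)
  lens <- attr(m, "capture.length")[, 1]
  data.frame(
    pattern_name = pattern_name,
    start = starts,
    matched_text = substring(seq, starts, starts + lens - 1),
    residue_first = if (is.null(residue_numbers)) NA_integer_
                    else residue_numbers[starts])
}

#' Rigidly transfer a ligand pose through a superposition
#'
#' Maps every ligand atom `x -> R x + t`; atom names are preserved and all
#' intra-ligand distances are unchanged. This transfers a crystallographic
#' pose into the frame of an aligned partner structure.
#'
#' @param pose a `ligand_pose` (see [extract_ligands()])
#' @param sup a [kabsch()] superposition
#' @return the transformed `ligand_pose`
#' @export
transfer_ligand <- function(pose, sup) {
  pose$xyz <- apply_superposition(pose$xyz, sup)
  pose
}

#' Residues in contact with a ligand
#'
#' A residue is included iff the minimum distance from its Calpha (mode
#' `"ca"`) or any of its atoms (mode `"all"`) to any ligand atom is at most
#' `cutoff`.
#'
#' @param x a [ca_trace()] (mode `"ca"`) or a chain atom data frame from
#'   [select_chain()] (mode `"all"`)
#' @param pose a `ligand_pose`
#' @param cutoff contact distance in Angstrom (defaults: 8.0 for `"ca"`,
#'   4.5 for `"all"`)
#' @param mode `"ca"` or `"all"`
#' @return object of class `contact_set`: list with `indices` (sorted
#'   1-based trace/residue indices), `cutoff`, `mode`
#' @export
contact_residues <- function(x, pose, cutoff = NULL, mode = c("ca", "all")) {
  mode <- match.arg(mode)
  if (is.null(pose$xyz) || nrow(pose$xyz) == 0) stop("empty ligand pose")
  cutoff <- cutoff %||% if (mode == "ca") 8.0 else 4.5
  if (cutoff <= 0) stop("cutoff must be positive")
  if (mode == "ca") {
    stopifnot(inherits(x, "ca_trace"))
    res_xyz <- x$xyz
    res_id <- seq_len(nrow(res_xyz))
  } else {
    at <- x[x$type == "ATOM", , drop = FALSE]
    res_xyz <- as.matrix(at[, c("x", "y", "z")])
    key <- paste(at$res_seq, at$insert)
    res_id <- match(key, unique(key))
  }
  # min distance of each protein atom to any ligand atom
  d2 <- outer(rowSums(res_xyz^2), rowSums(pose$xyz^2), `+`) -
    2 * res_xyz %*% t(pose$xyz)
  mind <- sqrt(pmax(0, apply(d2, 1, min)))
  idx <- sort(unique(res_id[mind <= cutoff]))
  structure(list(indices = idx, cutoff = cutoff, mode = mode),
            class = "contact_set")
}

#' Conservation of ligand-contact sites across an alignment
#'
#' Reports the fraction of contact residues of A whose equivalenced partner
#' (via the structural alignment) is a contact residue of B, the reverse
#' fraction, and the Jaccard index over equivalenced pairs.
#'
#' @param aln a `struct_alignment` of A onto B
#' @param cA,cB [contact_residues()] sets for A and B
#' @return list with `a_in_b`, `b_in_a`, `jaccard`
#' @export
contact_overlap <- function(aln, cA, cB) {
  if (length(cA$indices) == 0) stop("empty contact set for structure A")
  b_of_a <- setNames(aln$pairs[, 2], aln$pairs[, 1])
  a_of_b <- setNames(aln$pairs[, 1], aln$pairs[, 2])
  partner_a <- b_of_a[as.character(cA$indices)]
  partner_b <- a_of_b[as.character(cB$indices)]
  a_in_b <- mean(!is.na(partner_a) & partner_a %in% cB$indices)
  b_in_a <- if (length(cB$indices) == 0) NA_real_
            else mean(!is.na(partner_b) & partner_b %in% cA$indices)
  in_a <- aln$pairs[, 1] %in% cA$indices
  in_b <- aln$pairs[, 2] %in% cB$indices
  jac <- if (any(in_a | in_b)) sum(in_a & in_b) / sum(in_a | in_b)
         else NA_real_
  list(a_in_b = a_in_b, b_in_a = b_in_a, jaccard = jac)
}
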