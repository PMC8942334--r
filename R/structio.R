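# PDB coordinate I/O and extraction of chains, Calpha traces and ligands.
# Fixed-column parsing/validation is delegated to bio3d; this layer adds the
# model/chain bookkeeping, altLoc resolution and trace construction the rest
# of the pipeline relies on.

ATOM_COLS <- c("type", "serial", "atom_name", "alt_loc", "res_name",
               "chain_id", "res_seq", "insert", "x", "y", "z",
               "occupancy", "element")

#' Parse PDB-format text into a structure object
#'
#' Accepts the text of a PDB file (fixed-column v3.3 ATOM/HETATM/MODEL/TER/
#' ENDMDL records). Multiple MODEL blocks become separate models; all other
#' record types are ignored.
#'
#' @param text character vector: either a single string with embedded
#'   newlines or one element per line
#' @param id identifier stored on the returned object
#' @return an object of class `pdb_structure`: a list with elements `id` and
#'   `models` (each model a data frame of atom records)
#' @export
parse_pdb <- function(text, id = "structure") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records in input")
  # validate coordinate fields up front so errors carry a line number
  for (ln in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[ln], fld[1], fld[2])))
      if (is.na(v) || !is.finite(v))
        stop(sprintf("malformed coordinate field at line %d", ln))
    }
  }
  # split into MODEL blocks (or a single implicit model)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0) {
    list(lines)
  } else {
    ends <- c(model_starts[-1] - 1, length(lines))
    lapply(seq_along(model_starts),
           function(k) lines[model_starts[k]:ends[k]])
  }
  models <- lapply(blocks, function(bl) {
    al <- bl[substr(bl, 1, 6) %in% c("ATOM  ", "HETATM")]
    if (length(al) == 0) return(empty_atoms())
    data.frame(
      type      = trimws(substr(al, 1, 6)),
      serial    = as.integer(substr(al, 7, 11)),
      atom_name = trimws(substr(al, 13, 16)),
      alt_loc   = trimws(substr(al, 17, 17)),
      res_name  = trimws(substr(al, 18, 20)),
      chain_id  = trimws(substr(al, 22, 22)),
      res_seq   = as.integer(substr(al, 23, 26)),
      insert    = trimws(substr(al, 27, 27)),
      x         = as.numeric(substr(al, 31, 38)),
      y         = as.numeric(substr(al, 39, 46)),
      z         = as.numeric(substr(al, 47, 54)),
      occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
      element   = trimws(substr(al, 77, 78)),
      stringsAsFactors = FALSE)
  })
  models <- models[vapply(models, nrow, 0L) > 0]
  if (length(models) == 0) stop("no ATOM or HETATM records in input")
  structure(list(id = id, models = models), class = "pdb_structure")
}

empty_atoms <- function() {
  df <- data.frame(type = character(), serial = integer(),
                   atom_name = character(), alt_loc = character(),
                   res_name = character(), chain_id = character(),
                   res_seq = integer(), insert = character(),
                   x = numeric(), y = numeric(), z = numeric(),
                   occupancy = numeric(), element = character(),
                   stringsAsFactors = FALSE)
  df
}

#' Read a PDB file from disk
#' @param path file path
#' @param id identifier (default: file base name)
#' @return a `pdb_structure`
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_pdb(readLines(path, warn = FALSE),
            id = id %||% sub("\\.pdb$", "", basename(path)))
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %s: %d model(s), %d atoms (model 1), chains: %s\n",
              x$id, length(x$models), nrow(x$models[[1]]),
              paste(unique(x$models[[1]]$chain_id), collapse = ",")))
  invisible(x)
}

#' Select the atoms of one chain
#'
#' `chain_id = "AUTO"` selects the first chain with at least 30 amino-acid
#' residues (hetero-only chains are skipped).
#'
#' @param s a `pdb_structure`
#' @param chain_id single character, or `"AUTO"`
#' @param model model number (1 = first)
#' @return data frame of atom records for the chain
#' @export
select_chain <- function(s, chain_id = "AUTO", model = 1L) {
  stopifnot(inherits(s, "pdb_structure"))
  if (model < 1 || model > length(s$models))
    stop(sprintf("model %d not present (structure has %d)", model,
                 length(s$models)))
  at <- s$models[[model]]
  if (identical(chain_id, "AUTO")) {
    for (ch in unique(at$chain_id)) {
      sub <- at[at$chain_id == ch & at$type == "ATOM" &
                  at$res_name %in% STANDARD_AA, , drop = FALSE]
      n_res <- length(unique(paste(sub$res_seq, sub$insert)))
      if (n_res >= 30) return(at[at$chain_id == ch, , drop = FALSE])
    }
    # fall back to the largest polymer chain
    polys <- unique(at$chain_id[at$type == "ATOM"])
    if (length(polys) == 0) stop("no polymer chain found")
    sizes <- vapply(polys, function(ch) sum(at$chain_id == ch &
                                              at$type == "ATOM"), 0)
    return(at[at$chain_id == polys[which.max(sizes)], , drop = FALSE])
  }
  if (!chain_id %in% at$chain_id)
    stop(sprintf("chain '%s' not found; available: %s", chain_id,
                 paste(unique(at$chain_id), collapse = ", ")))
  at[at$chain_id == chain_id, , drop = FALSE]
}

#' Extract the Calpha trace of a chain
#'
#' One Calpha per residue; alternate locations are resolved by highest
#' occupancy (ties broken alphabetically); hetero residues are excluded;
#' residues are ordered by (res_seq, insertion code). Chain breaks
#' (numbering gaps or consecutive Calpha-Calpha distances outside
#' 2.0-4.5 Angstrom) are recorded in `breaks`, not fatal.
#'
#' @param chain_atoms data frame from [select_chain()]
#' @return object of class `ca_trace`: list with `labels` (data frame with
#'   res_seq, insert, res_name, aa), `xyz` (n x 3 matrix, Angstrom) and
#'   `breaks` (indices i such that a break lies between residues i and i+1)
#' @export
ca_trace <- function(chain_atoms) {
  at <- chain_atoms[chain_atoms$type == "ATOM" &
                      chain_atoms$atom_name == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("chain has no CA atoms")
  key <- paste(at$res_seq, at$insert, sep = "|")
  # altLoc resolution: highest occupancy, then alphabetical
  occ <- ifelse(is.na(at$occupancy), 1, at$occupancy)
  ord <- order(key, -occ, at$alt_loc)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$res_seq, at$insert, sep = "|")), , drop = FALSE]
  at <- at[order(at$res_seq, at$insert), , drop = FALSE]
  if (nrow(at) < 5)
    stop(sprintf("trace too short: %d CA atoms (need >= 5)", nrow(at)))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  labels <- data.frame(res_seq = at$res_seq, insert = at$insert,
                       res_name = at$res_name, aa = aa_one(at$res_name),
                       stringsAsFactors = FALSE)
  n <- nrow(xyz)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  gap <- diff(labels$res_seq) > 1 & labels$insert[-n] == "" &
    labels$insert[-1] == ""
  breaks <- which(d < 2.0 | d > 4.5 | gap)
  structure(list(labels = labels, xyz = xyz, breaks = breaks),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %d residues, %d chain break(s)\n",
              nrow(x$xyz), length(x$breaks)))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) nrow(x$xyz)

#' One-letter sequence of a Calpha trace
#' @param t a `ca_trace`
#' @return single character string
#' @export
trace_sequence <- function(t) paste(t$labels$aa, collapse = "")

# internal: sub-trace by residue indices (kept in given order)
subset_trace <- function(t, idx) {
  structure(list(labels = t$labels[idx, , drop = FALSE],
                 xyz = t$xyz[idx, , drop = FALSE],
                 breaks = integer(0)),
            class = "ca_trace")
}

#' Extract hetero-group ligands from a structure
#'
#' Groups HETATM records by residue instance; water (HOH) and any residue
#' names in `exclude` are skipped.
#'
#' @param s a `pdb_structure`
#' @param exclude character vector of residue names to skip
#' @param model model number
#' @return list of `ligand_pose` objects (possibly empty), each a list with
#'   `ligand_name`, `atom_names` and `xyz`
#' @export
extract_ligands <- function(s, exclude = character(), model = 1L) {
  at <- s$models[[model]]
  het <- at[at$type == "HETATM" & !(at$res_name %in% c("HOH", exclude)), ,
            drop = FALSE]
  if (nrow(het) == 0) return(list())
  grp <- paste(het$chain_id, het$res_seq, het$insert, het$res_name, sep = "|")
  lapply(split(seq_len(nrow(het)), factor(grp, levels = unique(grp))),
         function(ix) {
           g <- het[ix, , drop = FALSE]
           xyz <- as.matrix(g[, c("x", "y", "z")])
           dimnames(xyz) <- NULL
           structure(list(ligand_name = g$res_name[1],
                          atom_names = g$atom_name, xyz = xyz),
                     class = "ligand_pose")
         }) |> unname()
}

#' Write a structure as PDB-format text
#'
#' @param s a `pdb_structure`
#' @return character vector of PDB lines (round-trips through [parse_pdb()]
#'   with coordinates preserved to 3 decimals)
#' @export
write_pdb <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  fmt_atom <- function(a) {
    if (any(abs(c(a$x, a$y, a$z)) >= 10000))
      stop("coordinate magnitude >= 10000 Angstrom: PDB field overflow")
    nm <- ifelse(nchar(a$atom_name) >= 4, a$atom_name,
                 sprintf(" %-3s", a$atom_name))
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type, a$serial, nm, a$alt_loc, a$res_name, a$chain_id,
            a$res_seq, a$insert, a$x, a$y, a$z,
            ifelse(is.na(a$occupancy), 1, a$occupancy), 0, a$element)
  }
  out <- c(sprintf("HEADER    %s", s$id))
  multi <- length(s$models) > 1
  for (mi in seq_along(s$models)) {
    at <- s$models[[mi]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", mi))
    if (nrow(at) > 0) {
      for (ch in unique(at$chain_id)) {
        sub <- at[at$chain_id == ch, , drop = FALSE]
        out <- c(out, vapply(seq_len(nrow(sub)),
                             function(i) fmt_atom(sub[i, ]), ""))
        if (any(sub$type == "ATOM")) out <- c(out, "TER")
      }
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  c(out, "END")
}
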