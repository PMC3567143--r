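# Reading and filtering CA-trace domain structures and SCOP-style
# classification tables.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Construct a CA-trace domain structure
#'
#' A `domain_structure` holds one protein domain as an ordered CA trace:
#' an identifier, one 3D coordinate per residue (in Angstrom), the
#' one-letter amino-acid sequence, and an optional SCOP `sccs`
#' classification string (e.g. `"b.121.1.1"`).
#'
#' @param id Domain identifier.
#' @param ca_coords Numeric matrix, L x 3, one CA coordinate per residue in
#'   file order.
#' @param sequence One-letter amino-acid string of length L (`"X"` allowed);
#'   defaults to all-`"G"`.
#' @param chain_id Chain identifier (single character).
#' @param sccs Optional SCOP classification string.
#' @return An object of class `domain_structure` with fields `id`,
#'   `chain_id`, `L`, `ca_coords`, `sequence`, `sccs`.
#' @export
domain_structure <- function(id, ca_coords, sequence = NULL, chain_id = "A",
                             sccs = NULL) {
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  if (ncol(ca_coords) != 3L) stop("ca_coords must be an L x 3 matrix")
  if (!all(is.finite(ca_coords))) stop("all coordinates must be finite")
  L <- nrow(ca_coords)
  if (L < 1L) stop("structure must contain at least one residue")
  if (is.null(sequence)) sequence <- strrep("G", L)
  if (nchar(sequence) != L) {
    stop("sequence length (", nchar(sequence), ") must equal residue count (",
         L, ")")
  }
  dimnames(ca_coords) <- NULL
  structure(
    list(id = as.character(id), chain_id = as.character(chain_id), L = L,
         ca_coords = ca_coords, sequence = sequence, sccs = sccs),
    class = "domain_structure"
  )
}

#' @export
print.domain_structure <- function(x, ...) {
  cat("<domain_structure> ", x$id, " chain ", x$chain_id, ", ", x$L,
      " residues", if (!is.null(x$sccs)) paste0(", sccs ", x$sccs), "\n",
      sep = "")
  invisible(x)
}

#' Read a CA trace from PDB-format text
#'
#' Parses `ATOM` records for one chain using fixed PDB columns, keeping the
#' CA atom of each residue. Only the first `MODEL` is read; alternate
#' locations other than blank or `"A"` are dropped; `HETATM` records are
#' ignored; residues carrying insertion codes are kept as distinct
#' residues. The sequence is derived from the 3-letter residue names
#' (unknown names become `"X"`).
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text.
#' @param chain_id Chain identifier to extract.
#' @param id Identifier for the returned structure (default
#'   `"domain_<chain>"`).
#' @return A [domain_structure()].
#' @export
read_ca_trace <- function(pdb_text, chain_id, id = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(pdb_text)
  }
  # first MODEL only
  ends <- grep("^ENDMDL", lines)
  if (length(ends) > 0L) lines <- lines[seq_len(ends[1] - 1L)]
  keep <- grepl("^ATOM", lines)
  coords <- NULL
  seq3 <- character(0)
  for (k in which(keep)) {
    ln <- lines[k]
    if (nchar(ln) < 54L) next
    if (substr(ln, 22, 22) != chain_id) next
    if (trimws(substr(ln, 13, 16)) != "CA") next
    alt <- substr(ln, 17, 17)
    if (!alt %in% c(" ", "A", "")) next
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("unparseable coordinate field at line ", k)
    }
    coords <- rbind(coords, xyz)
    seq3 <- c(seq3, trimws(substr(ln, 18, 20)))
  }
  if (is.null(coords) || nrow(coords) == 0L) {
    stop("empty chain: no CA atoms found for chain '", chain_id, "'")
  }
  aa <- unname(AA3TO1[seq3])
  aa[is.na(aa)] <- "X"
  if (is.null(id)) id <- paste0("domain_", chain_id)
  domain_structure(id = id, ca_coords = coords,
                   sequence = paste(aa, collapse = ""), chain_id = chain_id)
}

#' Filter domains by minimum length
#'
#' Retains domains with at least `min_len` residues (boundary inclusive),
#' preserving order. Short peptides assume very simple topologies and are
#' excluded from fold-space comparisons.
#'
#' @param domains List of [domain_structure()] objects.
#' @param min_len Minimum residue count (default 80).
#' @return Filtered list, order preserved.
#' @export
filter_min_length <- function(domains, min_len = 80L) {
  domains[vapply(domains, function(d) d$L >= min_len, logical(1))]
}

#' Filter domains by maximum length
#'
#' Removes domains longer than `max_len` residues (strictly greater), used
#' to compare sets of comparable domain sizes.
#'
#' @param domains List of [domain_structure()] objects.
#' @param max_len Maximum residue count (default 600).
#' @return Filtered list, order preserved.
#' @export
filter_max_length <- function(domains, max_len = 600L) {
  domains[vapply(domains, function(d) d$L <= max_len, logical(1))]
}

#' Extract the fold identifier from an sccs string
#'
#' The SCOP fold is the `class.fold` prefix of the full sccs string
#' (class.fold.superfamily.family), e.g. `"b.121.1.1"` -> `"b.121"`.
#'
#' @param sccs SCOP classification string(s).
#' @return Character vector of fold identifiers.
#' @export
fold_of <- function(sccs) {
  vapply(as.character(sccs), function(s) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("malformed sccs '", s, "': need at least class.fold")
    }
    paste(parts[1:2], collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a SCOP/ASTRAL-style classification table
#'
#' Parses tab-separated classification text in the ASTRAL `dir.cla` dialect
#' (columns: sid, pdb code, residue description, sccs, sunid; `#` comment
#' lines skipped) into a map from domain identifier to fold label.
#'
#' @param cla_text Character scalar or vector of lines.
#' @return Named list mapping sid to a `fold_label` list with fields `sccs`
#'   and `fold_id`. Rows with malformed sccs are skipped with a warning;
#'   duplicate sids keep the first occurrence.
#' @export
read_scop_classification <- function(cla_text) {
  lines <- if (length(cla_text) == 1L && grepl("\n", cla_text)) {
    strsplit(cla_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(cla_text)
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  bad <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
    }
    if (length(f) < 4L) {
      bad <- c(bad, ln)
      next
    }
    sid <- f[1]
    sccs <- f[4]
    fid <- tryCatch(fold_of(sccs), error = function(e) NA_character_)
    cls <- strsplit(sccs, ".", fixed = TRUE)[[1]][1]
    ok <- !is.na(fid) && grepl("^[a-z]$", cls) &&
      grepl("^[a-z]\\.[0-9]+", sccs)
    if (!ok) {
      bad <- c(bad, ln)
      next
    }
    if (sid %in% names(out)) {
      warning("duplicate sid '", sid, "': keeping first occurrence")
      next
    }
    out[[sid]] <- structure(list(sccs = sccs, fold_id = fid),
                            class = "fold_label")
  }
  if (length(bad) > 0L) {
    warning(length(bad), " row(s) skipped with malformed sccs")
  }
  out
}
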