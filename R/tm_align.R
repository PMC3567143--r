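# TM-score structural alignment and the (1 - TM-score) structural distance.
#
# The alignment engine (fragment seeding, iterative DP refinement, the
# TM-score "Max" superposition search) is implemented in src/tmalign.cpp;
# this file provides the user-facing surface and the distance-matrix layer.

#' TM-score distance scale d0
#'
#' Length-dependent normalization scale that makes the TM-score independent
#' of protein size: `d0(L) = max(1.24 * (L - 15)^(1/3) - 1.8, 0.5)` Angstrom.
#'
#' @param L_norm Normalization length (positive integer, vectorized).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_norm) {
  if (any(L_norm < 1)) stop("L_norm must be >= 1")
  raw <- ifelse(L_norm > 15, 1.24 * (L_norm - 15)^(1 / 3) - 1.8, 0.5)
  pmax(raw, 0.5)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of matched point set B onto A, with the
#' reflection case corrected so the returned rotation is always proper.
#'
#' @param points_A,points_B Numeric n x 3 matrices of matched points, n >= 3.
#' @return List with `rotation` (3 x 3, proper orthonormal), `translation`
#'   (length 3), and `rmsd` (Angstrom). The transform maps B onto A:
#'   `B %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(points_A, points_B) {
  A <- as.matrix(points_A)
  B <- as.matrix(points_B)
  if (!all(dim(A) == dim(B))) stop("point sets must have matching dimensions")
  if (nrow(A) < 3L) stop("need at least 3 points")
  # degenerate (collinear) geometry leaves the rotation under-determined
  if (qr(sweep(A, 2, colMeans(A)))$rank < 2L ||
      qr(sweep(B, 2, colMeans(B)))$rank < 2L) {
    stop("degenerate geometry: points are collinear")
  }
  res <- .cpp_kabsch(A, B)
  res$translation <- as.numeric(res$translation)
  res
}

#' TM-score of a fixed residue correspondence
#'
#' Evaluates `max over superpositions of (1/L_norm) * sum_i 1 / (1 +
#' (d_i/d0)^2)` for a given set of aligned coordinate pairs. The Max term is
#' searched by seeding superpositions from contiguous aligned fragments
#' (lengths L_ali, L_ali/2, L_ali/4, minimum 4) and refining each on the
#' subset of pairs closer than a growing inclusion cutoff until that subset
#' is stable.
#'
#' @param coords_A,coords_B Matched n x 3 coordinate matrices of the aligned
#'   residue pairs (n >= 3), in alignment order.
#' @param L_norm Normalization length.
#' @return List with `score`, `rotation`, `translation`.
#' @export
tm_score_given_alignment <- function(coords_A, coords_B, L_norm) {
  A <- as.matrix(coords_A)
  B <- as.matrix(coords_B)
  if (nrow(A) < 3L) stop("need at least 3 aligned pairs")
  if (!all(dim(A) == dim(B))) stop("aligned coordinate sets must match")
  res <- .cpp_tm_search(A, B, tm_d0(L_norm), L_norm)
  res$translation <- as.numeric(res$translation)
  res
}

#' Structural alignment of two domains
#'
#' Heuristic TM-score alignment in the fr-TM-align spirit: seed alignments
#' come from gapless threading at strided offsets, from the best-matching
#' pair of contiguous 8-residue fragments, and from a dynamic-programming
#' alignment of 3-state secondary-structure strings assigned from CA
#' pseudo-dihedrals. Each seed is refined by iterating superposition ->
#' TM-score matrix -> sequential DP (constant gap penalty, free terminal
#' gaps) until the pair set repeats. The alignment maximizing the
#' symmetrized score `tm_sym = (tm_norm_A + tm_norm_B)/2` is reported.
#'
#' @param A,B [domain_structure()] objects with at least 5 residues each.
#' @param gap_penalty Constant DP gap penalty (default -0.6).
#' @param max_iter Maximum refinement iterations per seed (default 30).
#' @param seed_stride Offset stride for threading seeds; `NULL` (default)
#'   uses `ceiling(max(L_A, L_B) / 20)`.
#' @return An `alignment_result`: `pairs` (m x 2 matrix of aligned residue
#'   indices, strictly increasing in both columns), `rotation`,
#'   `translation` (mapping B onto A), `per_pair_distance` (Angstrom),
#'   `tm_norm_A` (normalized by L_A), `tm_norm_B` (by L_B), `tm_sym`, and
#'   `distance = 1 - tm_sym`.
#' @export
align_structures <- function(A, B, gap_penalty = -0.6, max_iter = 30L,
                             seed_stride = NULL) {
  stopifnot(inherits(A, "domain_structure"), inherits(B, "domain_structure"))
  if (A$L < 5L || B$L < 5L) {
    stop("structure too short: alignment needs at least 5 residues")
  }
  stride <- if (is.null(seed_stride)) -1L else as.integer(seed_stride)
  res <- .cpp_align_pair(A$ca_coords, B$ca_coords, gap_penalty,
                         as.integer(max_iter), stride)
  out <- list(
    id_A = A$id, id_B = B$id,
    pairs = res$pairs,
    rotation = res$rotation,
    translation = as.numeric(res$translation),
    per_pair_distance = as.numeric(res$per_pair_distance),
    tm_norm_A = res$tm_norm_A,
    tm_norm_B = res$tm_norm_B,
    tm_sym = res$tm_sym,
    distance = 1 - res$tm_sym
  )
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$id_A, " vs ", x$id_B, ": ",
      nrow(x$pairs), " aligned pairs, tm_sym = ", signif(x$tm_sym, 4),
      ", distance = ", signif(x$distance, 4), "\n", sep = "")
  invisible(x)
}

#' Structural distance between two domains
#'
#' `1 - tm_sym`, where `tm_sym` is the mean of the two single-length
#' normalized TM-scores. Symmetry is enforced by canonical argument
#' ordering (lexicographic by id), so `structural_distance(A, B)` is
#' bitwise equal to `structural_distance(B, A)`.
#'
#' @inheritParams align_structures
#' @return Distance in `[0, 1)`.
#' @export
structural_distance <- function(A, B, gap_penalty = -0.6, max_iter = 30L,
                                seed_stride = NULL) {
  if (A$id > B$id) {
    tmp <- A; A <- B; B <- tmp
  }
  align_structures(A, B, gap_penalty = gap_penalty, max_iter = max_iter,
                   seed_stride = seed_stride)$distance
}

#' All-against-all structural distance matrix
#'
#' Computes the symmetric matrix of pairwise structural distances with a
#' zero diagonal. Evaluation over workers (via forked processes where
#' available) is guaranteed to give results identical to serial evaluation:
#' each pair is computed independently and deterministically.
#'
#' @param domains List of [domain_structure()] objects (>= 2), with unique
#'   ids.
#' @param parallel_workers Optional number of worker processes (default 1,
#'   serial).
#' @param ... Passed to [align_structures()].
#' @return Symmetric numeric matrix with id dimnames.
#' @export
distance_matrix <- function(domains, parallel_workers = 1L, ...) {
  n <- length(domains)
  if (n < 2L) stop("need at least 2 domains")
  ids <- vapply(domains, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("domain ids must be unique")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  compute_one <- function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    tryCatch(
      structural_distance(domains[[i]], domains[[j]], ...),
      error = function(e) {
        stop("distance for pair (", ids[i], ", ", ids[j], ") failed: ",
             conditionMessage(e))
      }
    )
  }
  vals <- if (parallel_workers > 1L && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(seq_len(nrow(idx)), compute_one,
                              mc.cores = parallel_workers))
  } else {
    vapply(seq_len(nrow(idx)), compute_one, numeric(1))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- vals
  D <- D + t(D)
  D
}

#' Write a distance matrix as TSV
#'
#' Writes both the square form (header row of ids) and, optionally, a
#' long-format table (`id_a`, `id_b`, `distance`).
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param file Path for the square TSV.
#' @param long_file Optional path for the long-format TSV.
#' @return Invisibly, `file`.
#' @export
write_distance_matrix <- function(D, file, long_file = NULL) {
  write.table(data.frame(id = rownames(D), D, check.names = FALSE),
              file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_file)) {
    iu <- which(upper.tri(D), arr.ind = TRUE)
    long <- data.frame(id_a = rownames(D)[iu[, 1]],
                       id_b = colnames(D)[iu[, 2]],
                       distance = D[iu])
    write.table(long, file = long_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(file)
}

#' Long-format pairwise alignment table
#'
#' Aligns every unordered pair of domains and tabulates both single-sided
#' TM-scores, the symmetrized score and the structural distance --- the
#' long-format companion of [distance_matrix()] for users who want to
#' re-threshold on either normalization.
#'
#' @inheritParams distance_matrix
#' @param file Optional TSV path to write the table to.
#' @return Data frame with columns `id_a`, `id_b`, `tm_a`, `tm_b`,
#'   `tm_sym`, `distance`.
#' @export
alignment_table <- function(domains, file = NULL, ...) {
  n <- length(domains)
  if (n < 2L) stop("need at least 2 domains")
  ids <- vapply(domains, function(d) d$id, character(1))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- domains[[i]]
      b <- domains[[j]]
      if (a$id > b$id) {
        tmp <- a; a <- b; b <- tmp
      }
      res <- align_structures(a, b, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = a$id, id_b = b$id, tm_a = res$tm_norm_A, tm_b = res$tm_norm_B,
        tm_sym = res$tm_sym, distance = res$distance
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.table(out, file = file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out
}

#' Read a square distance-matrix TSV written by [write_distance_matrix()]
#'
#' @param file Path to the square TSV.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
read_distance_matrix <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  D <- as.matrix(df[, -1, drop = FALSE])
  dimnames(D) <- list(ids, colnames(df)[-1])
  storage.mode(D) <- "double"
  D
}
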