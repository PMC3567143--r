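# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  si <- sum(choose(tab, 2))
  ex <- sr * sc / choose(n, 2)
  denom <- (sr + sc) / 2 - ex
  if (denom == 0) return(1)
  (si - ex) / denom
}

# Naive O(n^3) unweighted average-linkage agglomeration. Returns the list of
# member-set partitions after each merge (from n clusters down to 1) and the
# merge heights.
naive_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(partitions = partitions, heights = heights)
}

# Partition (member-set list) -> label vector over 1..n.
partition_labels <- function(parts, n) {
  lab <- integer(n)
  for (k in seq_along(parts)) lab[parts[[k]]] <- k
  lab
}

# Minimal-k partition by exhaustive scan over the naive tree's cuts:
# independent route to the optimal_partition result.
naive_minimal_partition <- function(D, threshold) {
  n <- nrow(D)
  tree <- naive_average_linkage(D)
  # cuts at k clusters = state after n - k merges (k = n is the start state)
  for (k in seq_len(n)) {
    parts <- if (k == n) as.list(seq_len(n)) else tree$partitions[[n - k]]
    ok <- all(vapply(parts, function(m) {
      length(m) < 2L || max(D[m, m][upper.tri(D[m, m])]) < threshold
    }, logical(1)))
    if (ok) return(list(k = length(parts), labels = partition_labels(parts, n)))
  }
}

# Random squashed distance matrix from latent points (symmetric, zero diag,
# values in [0, 1), generically tie-free).
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n)
  e <- as.matrix(dist(X))
  D <- e / (e + 1)
  dimnames(D) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  D
}

# Free-end-gap Needleman-Wunsch DP over the full lattice: optimal global
# score with match +1, mismatch 0, internal linear gap -1, terminal gaps
# free (traceback-free formulation: best over last row/column).
naive_nw_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  na <- length(x)
  nb <- length(y)
  F <- matrix(-Inf, na + 1, nb + 1)
  F[1, ] <- 0  # free leading gaps
  F[, 1] <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      F[i + 1, j + 1] <- max(F[i, j] + (x[i] == y[j]),
                             F[i, j + 1] - 1,
                             F[i + 1, j] - 1)
    }
  }
  max(F[na + 1, ], F[, nb + 1])  # free trailing gaps
}

# Brute-force superposition oracle: minimize RMSD over rotations
# parameterized by Euler angles (coarse grid + Nelder-Mead refinement),
# independent of the SVD route.
oracle_superpose_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A0 - B0 %*% t(rot(ang)))^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0)
  best_v <- obj(best)
  for (a1 in grid) for (a2 in grid[grid < pi]) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_v) {
      best_v <- v
      best <- c(a1, a2, a3)
    }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}

# Hand-built PDB text: one CA ATOM record per row of coords.
make_pdb_text <- function(coords, chain = "A", resname = "GLY",
                          model_header = FALSE, extra_model = NULL) {
  fmt <- function(xyz, serial, ch) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resname, ch, serial, xyz[1], xyz[2], xyz[3])
  }
  lines <- character(0)
  if (model_header || !is.null(extra_model)) lines <- c(lines, "MODEL        1")
  lines <- c(lines, vapply(seq_len(nrow(coords)),
                           function(i) fmt(coords[i, ], i, chain), character(1)))
  if (model_header || !is.null(extra_model)) lines <- c(lines, "ENDMDL")
  if (!is.null(extra_model)) {
    lines <- c(lines, "MODEL        2",
               vapply(seq_len(nrow(extra_model)),
                      function(i) fmt(extra_model[i, ], i, chain), character(1)),
               "ENDMDL")
  }
  c(lines, "END")
}

# Small rigid motion helper.
rotate_translate <- function(coords, angle = 0.7, axis = "z",
                             shift = c(1, 2, 3)) {
  c1 <- cos(angle); s1 <- sin(angle)
  R <- switch(axis,
              z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3),
              x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3))
  coords %*% t(R) + matrix(shift, nrow(coords), 3, byrow = TRUE)
}
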