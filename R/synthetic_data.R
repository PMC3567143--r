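# Synthetic inputs with the statistical structure the analysis assumes:
# latent fold-family distance matrices with focus displacement, and
# ideal-geometry CA-trace structure sets for exercising the aligner.

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", U = "SEC", O = "PYL", X = "UNK"
)

#' Configuration for the latent fold-family generator
#'
#' Families live as Gaussian clouds around isotropically drawn centers in a
#' latent Euclidean space; designated focus families are additionally
#' displaced along a fixed direction, emulating a protein class whose folds
#' are structurally segregated from the rest. Euclidean distances `e` are
#' squashed to `d = e / (e + c)` in `[0, 1)`, mirroring the bounded
#' (1 - TM-score) structural distance.
#'
#' Defaults describe the study conditions the pipeline targets at desk
#' scale: 24 families of 4 members (96 domains) of which 8 families form a
#' structurally displaced focus class, within-family distances typically
#' below 0.4 and cross-family distances typically above 0.6, and a focus
#' displacement of 10 x `center_scale` placing focus families beyond 0.6
#' from everything else.
#'
#' @param n_families Number of fold families.
#' @param members_per_family Members per family (scalar or per-family
#'   vector).
#' @param latent_dim Latent space dimension (default 8).
#' @param within_sd Within-family standard deviation `sigma_w` (default
#'   0.3).
#' @param center_scale Scale of isotropic family centers (default 1.0).
#' @param squash_scale Squashing constant `c` (default 2.5).
#' @param focus_families Integer indices of focus families (default 1:8).
#' @param focus_displacement Offset applied to focus-family centers along a
#'   fixed direction (default 10).
#' @param seed Integer seed.
#' @return A `latent_config` list.
#' @export
latent_config <- function(n_families = 24L, members_per_family = 4L,
                          latent_dim = 8L, within_sd = 0.3,
                          center_scale = 1.0, squash_scale = 2.5,
                          focus_families = 1:8, focus_displacement = 10,
                          seed = 1L) {
  if (length(members_per_family) == 1L) {
    members_per_family <- rep(as.integer(members_per_family), n_families)
  }
  stopifnot(length(members_per_family) == n_families,
            all(members_per_family >= 1L),
            all(focus_families %in% seq_len(n_families)),
            center_scale > 0, squash_scale > 0, within_sd >= 0,
            focus_displacement >= 0)
  structure(
    list(n_families = as.integer(n_families),
         members_per_family = members_per_family,
         latent_dim = as.integer(latent_dim), within_sd = within_sd,
         center_scale = center_scale, squash_scale = squash_scale,
         focus_families = as.integer(focus_families),
         focus_displacement = focus_displacement, seed = as.integer(seed)),
    class = "latent_config"
  )
}

#' Generate a latent fold-family dataset
#'
#' Draws family centers isotropically at `center_scale`, displaces focus
#' family centers by `focus_displacement` along the first latent axis,
#' places members as `center + N(0, sigma_w^2 I)`, and squashes pairwise
#' Euclidean distances `e` to `d = e / (e + c)`. Deterministic under
#' `config$seed`.
#'
#' @param config A [latent_config()].
#' @return List with `D` (squashed distance matrix with id dimnames),
#'   `fold_labels` (named character vector, id -> `"f<family>"`),
#'   `focus_ids`, `family` (named integer vector) and `config`.
#' @export
generate_latent_dataset <- function(config) {
  stopifnot(inherits(config, "latent_config"))
  set.seed(config$seed)
  p <- config$latent_dim
  centers <- matrix(rnorm(config$n_families * p, sd = config$center_scale),
                    nrow = config$n_families)
  shift <- c(config$focus_displacement, rep(0, p - 1L))
  centers[config$focus_families, ] <-
    sweep(centers[config$focus_families, , drop = FALSE], 2, -shift)
  fam <- rep(seq_len(config$n_families), config$members_per_family)
  n <- length(fam)
  X <- centers[fam, , drop = FALSE] +
    matrix(rnorm(n * p, sd = config$within_sd), nrow = n)
  ids <- sprintf("dom%03d", seq_len(n))
  e <- as.matrix(dist(X))
  D <- e / (e + config$squash_scale)
  dimnames(D) <- list(ids, ids)
  fold_labels <- setNames(sprintf("f%02d", fam), ids)
  list(D = D, fold_labels = fold_labels,
       focus_ids = ids[fam %in% config$focus_families],
       family = setNames(fam, ids), config = config)
}

#' Configuration for the toy-structure generator
#'
#' @param template One of `"helix_bundle"` (four antiparallel ideal
#'   helices), `"beta_meander"` (eight antiparallel strands in one sheet)
#'   or `"sandwich_jellyroll_like"` (eight strands in two packed sheets
#'   with cross-sheet connectivity, echoing the two-sheet sandwich motif).
#' @param n_residues Target residue count (>= 30).
#' @param coordinate_noise_sd Isotropic Gaussian coordinate noise per copy,
#'   Angstrom (default 0).
#' @param loop_length_jitter Maximum +/- residues of per-copy length jitter
#'   (default 0).
#' @param n_copies Number of structures to generate (default 1).
#' @param seed Integer seed.
#' @return A `structure_template_config` list.
#' @export
structure_template_config <- function(template = c("helix_bundle",
                                                   "beta_meander",
                                                   "sandwich_jellyroll_like"),
                                      n_residues = 120L,
                                      coordinate_noise_sd = 0,
                                      loop_length_jitter = 0L,
                                      n_copies = 1L, seed = 1L) {
  template <- match.arg(template)
  stopifnot(n_residues >= 30L, coordinate_noise_sd >= 0,
            loop_length_jitter >= 0L, n_copies >= 1L)
  structure(
    list(template = template, n_residues = as.integer(n_residues),
         coordinate_noise_sd = coordinate_noise_sd,
         loop_length_jitter = as.integer(loop_length_jitter),
         n_copies = as.integer(n_copies), seed = as.integer(seed)),
    class = "structure_template_config"
  )
}

# Connect two anchor points with intermediate residues on a bulged arc so
# that consecutive CA-CA steps stay within [2.8, 4.2] Angstrom.
.bridge_points <- function(p, q, target_step = 3.5) {
  d <- sqrt(sum((q - p)^2))
  n_seg <- max(1L, round(d / target_step))
  if (d / n_seg > 4.2) n_seg <- n_seg + 1L
  if (n_seg == 1L) return(NULL)  # direct step already acceptable
  v <- (q - p) / d
  # perpendicular direction for the bulge
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * v) * v
  u <- u / sqrt(sum(u^2))
  ts <- seq_len(n_seg - 1L) / n_seg
  for (b in seq(0, 6, by = 0.05)) {
    mid <- t(vapply(ts, function(s) p + s * (q - p) + b * sin(pi * s) * u,
                    numeric(3)))
    pts <- rbind(p, mid, q)
    steps <- sqrt(rowSums(diff(pts)^2))
    if (all(steps >= 2.8 & steps <= 4.2)) return(mid)
  }
  mid  # last resort; noise-free templates never reach this
}

# Ideal alpha-helix CA trace: 1.5 A rise, 100 deg twist, 2.3 A radius.
.helix_points <- function(n, origin, direction = 1) {
  k <- seq_len(n) - 1L
  ang <- k * 100 * pi / 180
  cbind(origin[1] + 2.3 * cos(ang), origin[2] + 2.3 * sin(ang),
        origin[3] + direction * 1.5 * k)
}

# Ideal beta-strand CA trace: 3.3 A rise with alternating 0.9 A pleat.
.strand_points <- function(n, origin, direction = 1, pleat_axis = c(1, 0, 0)) {
  k <- seq_len(n) - 1L
  pleat <- 0.9 * ifelse(k %% 2 == 0, 1, -1)
  base <- matrix(origin, nrow = n, ncol = 3, byrow = TRUE)
  base[, 3] <- base[, 3] + direction * 3.3 * k
  base + outer(pleat, pleat_axis)
}

.build_template <- function(template, n_residues) {
  segs <- list()
  if (template == "helix_bundle") {
    h <- ceiling(n_residues / 4)
    anchors <- list(c(0, 0, 0), c(9, 0, 0), c(9, 9, 0), c(0, 9, 0))
    for (s in seq_len(4)) {
      dir <- if (s %% 2 == 1) 1 else -1
      org <- anchors[[s]]
      if (dir == -1) org[3] <- 1.5 * (h - 1)
      segs[[length(segs) + 1L]] <- .helix_points(h, org, dir)
    }
  } else {
    m <- ceiling(n_residues / 8)
    top <- 3.3 * (m - 1)
    if (template == "beta_meander") {
      order <- lapply(0:7, function(s) c(x = 4.8 * s, y = 0))
    } else {
      # two packed sheets of four; connectivity alternates between sheets
      order <- lapply(seq_len(8), function(k) {
        i <- ceiling(k / 2)                       # sheet position 1..4
        sheet <- 2L - (k %% 2L)                   # 1, 2, 1, 2, ...
        c(x = 4.8 * (i - 1L), y = 9 * (sheet - 1L))
      })
    }
    for (s in seq_len(8)) {
      dir <- if (s %% 2 == 1) 1 else -1
      org <- c(order[[s]][["x"]], order[[s]][["y"]], if (dir == 1) 0 else top)
      segs[[length(segs) + 1L]] <- .strand_points(m, org, dir,
                                                  pleat_axis = c(0, 1, 0))
    }
  }
  # stitch segments with bridging loop residues
  pts <- segs[[1]]
  for (s in seq_along(segs)[-1]) {
    p <- pts[nrow(pts), ]
    q <- segs[[s]][1, ]
    mid <- .bridge_points(p, q)
    pts <- rbind(pts, mid, segs[[s]])
  }
  rownames(pts) <- NULL
  if (nrow(pts) < n_residues) {
    # extend the final secondary-structure element to reach the target
    extra <- n_residues - nrow(pts)
    last_dir <- pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]
    step <- last_dir / sqrt(sum(last_dir^2)) * 3.5
    ext <- t(vapply(seq_len(extra),
                    function(k) pts[nrow(pts), ] + k * step, numeric(3)))
    pts <- rbind(pts, ext)
  }
  pts[seq_len(n_residues), , drop = FALSE]
}

#' Generate toy CA-trace structures from an ideal-geometry template
#'
#' Builds an ideal-geometry backbone (helices: 1.5 A rise, 100 deg twist;
#' strands: 3.3 A rise, one or two sheets depending on the template) with
#' bridging loops keeping adjacent CA-CA distances within [2.8, 4.2] A
#' before noise, then perturbs each copy with isotropic Gaussian coordinate
#' noise and per-copy length jitter.
#'
#' @param config A [structure_template_config()].
#' @return List of [domain_structure()] objects, ids
#'   `"<template>_<copy>"`.
#' @export
generate_toy_structures <- function(config) {
  stopifnot(inherits(config, "structure_template_config"))
  set.seed(config$seed)
  out <- vector("list", config$n_copies)
  for (k in seq_len(config$n_copies)) {
    jit <- if (config$loop_length_jitter > 0L) {
      sample(seq(-config$loop_length_jitter, config$loop_length_jitter), 1L)
    } else 0L
    n_k <- max(30L, config$n_residues + jit)
    pts <- .build_template(config$template, n_k)
    if (config$coordinate_noise_sd > 0) {
      pts <- pts + matrix(rnorm(length(pts), sd = config$coordinate_noise_sd),
                          nrow = nrow(pts))
    }
    out[[k]] <- domain_structure(
      id = sprintf("%s_%02d", config$template, k), ca_coords = pts
    )
  }
  out
}

#' Write a domain structure as PDB-format text
#'
#' One `ATOM` record per residue (CA atom, residue names from the
#' sequence), fixed-width PDB columns, a single `MODEL`. The structure id
#' is placed in the 4-character idCode field of the `HEADER` record and
#' truncated with a warning when longer.
#'
#' @param structure A [domain_structure()].
#' @param file Optional path; when `NULL` (default) the text is returned.
#' @return PDB-format text (invisibly when `file` is given).
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "domain_structure"))
  id <- structure$id
  if (nchar(id) > 4L) {
    warning("id '", id, "' longer than the 4-character PDB idCode field; ",
            "truncated")
    id <- substr(id, 1, 4)
  }
  chain <- structure$chain_id
  if (nchar(chain) > 1L) {
    warning("chain_id '", chain, "' truncated to one character")
    chain <- substr(chain, 1, 1)
  }
  aa <- strsplit(structure$sequence, "")[[1]]
  res3 <- unname(AA1TO3[aa])
  res3[is.na(res3)] <- "UNK"
  lines <- c(
    sprintf("HEADER    SYNTHETIC CA TRACE                      %4s", id),
    "MODEL        1",
    sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(structure$L), res3, chain, seq_len(structure$L),
      structure$ca_coords[, 1], structure$ca_coords[, 2],
      structure$ca_coords[, 3]
    ),
    "ENDMDL",
    "END"
  )
  text <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(text))
  }
  text
}

#' Write fold labels and focus flags as TSV
#'
#' @param fold_labels Named character vector, id -> fold/family label.
#' @param focus_ids Ids belonging to the focus subset.
#' @param file Output TSV path (`id`, `family`, `is_focus`).
#' @return Invisibly, `file`.
#' @export
write_fold_labels <- function(fold_labels, focus_ids, file) {
  df <- data.frame(id = names(fold_labels), family = unname(fold_labels),
                   is_focus = names(fold_labels) %in% focus_ids)
  write.table(df, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
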