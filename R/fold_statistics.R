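# The shared-folds test statistic, nearest-neighbor ECDF curves, and the
# permutation-test null with self-fold exclusion.

#' Nearest-focus-set distances
#'
#' For each non-focus domain, the minimum structural distance to any member
#' of the focus set.
#'
#' @param focus_ids Non-empty character vector of focus-set ids.
#' @param other_ids Character vector of non-focus ids (disjoint from
#'   `focus_ids`).
#' @param D Distance matrix covering all ids.
#' @return Named numeric vector: id -> nearest-focus distance.
#' @export
nearest_focus_distance <- function(focus_ids, other_ids, D) {
  if (length(focus_ids) == 0L) stop("focus set must be non-empty")
  if (length(intersect(focus_ids, other_ids)) > 0L) {
    stop("focus and non-focus sets must be disjoint")
  }
  missing <- setdiff(c(focus_ids, other_ids), rownames(D))
  if (length(missing) > 0L) {
    stop("ids missing from distance matrix: ", paste(missing, collapse = ", "))
  }
  sub <- D[other_ids, focus_ids, drop = FALSE]
  setNames(do.call(pmin, c(as.data.frame(sub), list(na.rm = FALSE))),
           other_ids)
}

#' Shared folds below a distance cutoff
#'
#' The overlap statistic: non-focus domains whose nearest-focus distance is
#' strictly below the cutoff are the focus set's structural "relatives";
#' the statistic is the number of distinct SCOP folds they cover. With
#' `exclude_self = TRUE`, folds already present in the focus set ("self
#' folds") are removed, a conservative lower bound on folds shared with
#' non-self proteins.
#'
#' @param nn Named numeric vector of nearest-focus distances (from
#'   [nearest_focus_distance()]).
#' @param fold_labels Named character vector (or list) mapping id ->
#'   fold_id. Retained ids without a label still count as relatives but
#'   contribute no fold.
#' @param cutoff Retention cutoff (default 0.6, strict `<`).
#' @param exclude_self Remove focus-set folds from the count?
#' @param focus_folds Character vector of fold_ids present in the focus set
#'   (required when `exclude_self = TRUE`).
#' @return A `shared_fold_result`: `cutoff`, `retained_ids`, `nn_distance`,
#'   `n_relatives`, `folds`, `n_folds`, `excluded_self_folds`.
#' @export
shared_folds <- function(nn, fold_labels, cutoff = 0.6, exclude_self = FALSE,
                         focus_folds = NULL) {
  retained <- names(nn)[nn < cutoff]
  lab <- unlist(fold_labels)[retained]
  unlabeled <- retained[is.na(lab)]
  if (length(unlabeled) > 0L) {
    message(length(unlabeled), " retained id(s) without fold label counted ",
            "as relatives but contributing no fold")
  }
  folds <- unique(lab[!is.na(lab)])
  excluded <- NULL
  if (isTRUE(exclude_self)) {
    if (is.null(focus_folds)) {
      stop("focus_folds required when exclude_self = TRUE")
    }
    excluded <- intersect(folds, focus_folds)
    folds <- setdiff(folds, focus_folds)
  }
  structure(
    list(cutoff = cutoff, retained_ids = retained,
         nn_distance = nn[retained], n_relatives = length(retained),
         folds = folds, n_folds = length(folds),
         excluded_self_folds = excluded),
    class = "shared_fold_result"
  )
}

#' @export
print.shared_fold_result <- function(x, ...) {
  cat("<shared_fold_result> cutoff ", x$cutoff, ": ", x$n_relatives,
      " relatives covering ", x$n_folds, " folds",
      if (!is.null(x$excluded_self_folds))
        paste0(" (", length(x$excluded_self_folds), " self folds excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' Empirical CDF of nearest-neighbor distances
#'
#' Right-continuous step ECDF of the nearest-focus distances, as sorted
#' (distance, cumulative fraction) pairs; the final fraction is 1.
#'
#' @param nn Named numeric vector of nearest-neighbor distances.
#' @return Data frame with columns `distance` and `fraction`.
#' @export
nn_ecdf <- function(nn) {
  if (length(nn) == 0L) stop("nn must be non-empty")
  x <- sort(unique(nn))
  data.frame(distance = x, fraction = ecdf(nn)(x))
}

# Shared-fold count for one partition of ids into A (focus) and complement,
# with self-fold exclusion. Used by the permutation loop; works on a plain
# fold vector aligned with rownames(D) for speed.
.null_shared_fold_count <- function(a_idx, D, folds, cutoff) {
  nn <- do.call(pmin, as.data.frame(D[-a_idx, a_idx, drop = FALSE]))
  close_folds <- unique(folds[-a_idx][nn < cutoff])
  close_folds <- close_folds[!is.na(close_folds)]
  length(setdiff(close_folds, unique(folds[a_idx])))
}

#' Permutation-test null for the shared-folds statistic
#'
#' Estimates how often a random partition of the total set would produce as
#' few shared folds as observed. Per permutation, a set A of `focus_size`
#' ids is drawn uniformly without replacement from all ids; its complement
#' B is scanned for members within `cutoff` of A, and the distinct folds
#' they cover are counted after removing A's own ("self") folds. The
#' one-tailed p-value is the left-tail probability of counts less than or
#' equal to the observed statistic -- a small overlap is the alternative of
#' interest.
#'
#' @param all_ids Character vector of all ids in the total set.
#' @param fold_labels Named character vector/list mapping id -> fold_id.
#' @param D Distance matrix covering `all_ids`.
#' @param focus_size Size of the random set A (must be < number of ids).
#' @param n_perm Number of independent permutations (default 10000).
#' @param cutoff Retention cutoff (default 0.6).
#' @param observed Observed shared-fold count to compare against.
#' @param seed Integer seed for the permutation stream.
#' @return A `permutation_result`: `observed`, `null_counts`, `n_perm`,
#'   `p_raw` (fraction of null counts `<=` observed), `p_conservative`
#'   (`(b + 1) / (n_perm + 1)`), `seed`. When no null count reaches the
#'   observed value, report the upper bound "p < 1/n_perm".
#' @export
permutation_test <- function(all_ids, fold_labels, D, focus_size,
                             n_perm = 10000L, cutoff = 0.6, observed,
                             seed = 1L) {
  n <- length(all_ids)
  if (focus_size >= n) stop("focus_size must be smaller than the total set")
  if (focus_size < 1L) stop("focus_size must be positive")
  missing <- setdiff(all_ids, rownames(D))
  if (length(missing) > 0L) {
    stop("ids missing from distance matrix: ", paste(missing, collapse = ", "))
  }
  D <- D[all_ids, all_ids]
  folds <- unname(unlist(fold_labels)[all_ids])
  rng <- local({
    set.seed(seed)
    replicate(n_perm, sample.int(n, focus_size), simplify = FALSE)
  })
  null_counts <- vapply(rng, .null_shared_fold_count, integer(1),
                        D = D, folds = folds, cutoff = cutoff)
  b <- sum(null_counts <= observed)
  structure(
    list(observed = observed, null_counts = null_counts,
         n_perm = n_perm, p_raw = b / n_perm,
         p_conservative = (b + 1) / (n_perm + 1), seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  p_str <- if (x$p_raw == 0) {
    paste0("p < ", signif(1 / x$n_perm, 3), " (upper bound; conservative ",
           signif(x$p_conservative, 3), ")")
  } else {
    paste0("p_raw = ", signif(x$p_raw, 4), ", p_conservative = ",
           signif(x$p_conservative, 4))
  }
  cat("<permutation_result> observed ", x$observed, " shared folds vs ",
      x$n_perm, " permutations: ", p_str, "\n", sep = "")
  invisible(x)
}

#' Write the null distribution as a histogram TSV
#'
#' @param perm A `permutation_result`.
#' @param file Output TSV path (`shared_folds`, `count`).
#' @return Invisibly, `file`.
#' @export
write_null_distribution <- function(perm, file) {
  tab <- table(factor(perm$null_counts,
                      levels = seq(min(perm$null_counts),
                                   max(perm$null_counts))))
  write.table(data.frame(shared_folds = as.integer(names(tab)),
                         count = as.integer(tab)),
              file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
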