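# End-to-end orchestration: load -> filter -> cluster the focus set ->
# medoids -> nearest-neighbor distances -> shared folds -> permutation test
# -> reports.

.log_line <- function(log_file, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(line)
}

#' Pipeline run configuration
#'
#' Bundles the inputs and the fixed analysis constants: the 80-residue
#' minimum and optional 600-residue maximum length filters, the 40%
#' sequence-identity redundancy threshold for the focus set, the 0.6
#' intra-cluster distance criterion, the relative-retention cutoffs, and
#' the permutation-test size.
#'
#' Exactly one input mode must be supplied: a synthetic [latent_config()];
#' a precomputed distance matrix with fold labels and focus ids; or a
#' directory of PDB files plus a classification table and focus-id list.
#'
#' @param synthetic Optional [latent_config()].
#' @param D,fold_labels,focus_ids Optional precomputed symmetric distance
#'   matrix, named fold-label vector and focus id vector.
#' @param pdb_dir,classification_file,focus_file Optional directory of
#'   per-domain PDB files (chain A read from each), ASTRAL-style
#'   classification TSV, and focus-id list file (one id per line).
#' @param min_len,max_len Length filters (defaults 80 and 600; set
#'   `max_len = NULL` to skip the maximum filter).
#' @param identity_threshold Focus-set redundancy threshold (default 0.40).
#' @param cluster_threshold Intra-cluster distance criterion (default 0.6).
#' @param relative_cutoffs Retention cutoffs for the shared-fold reports
#'   (default `c(0.5, 0.6)`, sorted increasing).
#' @param test_cutoff Cutoff used for the permutation-test statistic
#'   (default 0.6).
#' @param observed_exclude_self Compute the observed statistic with
#'   self-fold exclusion? Default `FALSE`; null permutations always use
#'   exclusion.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Master seed; stage substreams are derived from it.
#' @param output_dir Directory for artifacts (created if missing); `NULL`
#'   disables file output.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL, D = NULL, fold_labels = NULL,
                       focus_ids = NULL, pdb_dir = NULL,
                       classification_file = NULL, focus_file = NULL,
                       min_len = 80L, max_len = 600L,
                       identity_threshold = 0.40, cluster_threshold = 0.6,
                       relative_cutoffs = c(0.5, 0.6), test_cutoff = 0.6,
                       observed_exclude_self = FALSE, n_perm = 10000L,
                       seed = 1L, output_dir = NULL) {
  modes <- c(synthetic = !is.null(synthetic), matrix = !is.null(D),
             pdb = !is.null(pdb_dir))
  if (sum(modes) != 1L) {
    stop("exactly one input mode required: synthetic, D(+labels), or pdb_dir")
  }
  if (modes[["matrix"]] && (is.null(fold_labels) || is.null(focus_ids))) {
    stop("matrix mode needs fold_labels and focus_ids")
  }
  if (modes[["pdb"]] && (is.null(classification_file) || is.null(focus_file))) {
    stop("pdb mode needs classification_file and focus_file")
  }
  stopifnot(cluster_threshold > 0, cluster_threshold < 1,
            all(relative_cutoffs > 0), all(relative_cutoffs < 1),
            !is.unsorted(relative_cutoffs),
            identity_threshold > 0, identity_threshold < 1,
            test_cutoff > 0, test_cutoff < 1, n_perm >= 1L)
  structure(
    list(mode = names(modes)[modes], synthetic = synthetic, D = D,
         fold_labels = fold_labels, focus_ids = focus_ids,
         pdb_dir = pdb_dir, classification_file = classification_file,
         focus_file = focus_file, min_len = min_len, max_len = max_len,
         identity_threshold = identity_threshold,
         cluster_threshold = cluster_threshold,
         relative_cutoffs = relative_cutoffs, test_cutoff = test_cutoff,
         observed_exclude_self = observed_exclude_self,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

.load_inputs <- function(config, log_file) {
  if (config$mode == "synthetic") {
    ds <- generate_latent_dataset(config$synthetic)
    .log_line(log_file, "load: synthetic latent dataset with ",
              nrow(ds$D), " domains (", length(ds$focus_ids), " focus)")
    return(list(D = ds$D, fold_labels = ds$fold_labels,
                focus_ids = ds$focus_ids, domains = NULL))
  }
  if (config$mode == "matrix") {
    D <- validate_distance_matrix(config$D)
    .log_line(log_file, "load: precomputed distance matrix with ",
              nrow(D), " domains (", length(config$focus_ids), " focus)")
    return(list(D = D, fold_labels = unlist(config$fold_labels),
                focus_ids = config$focus_ids, domains = NULL))
  }
  # pdb mode
  files <- sort(list.files(config$pdb_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  domains <- lapply(files, function(f) {
    read_ca_trace(readLines(f), chain_id = "A",
                  id = sub("\\.pdb$", "", basename(f)))
  })
  n0 <- length(domains)
  .log_line(log_file, "load: ", n0, " PDB domains from ", config$pdb_dir)
  domains <- filter_min_length(domains, config$min_len)
  .log_line(log_file, "length filter >= ", config$min_len, ": ",
            length(domains), " kept (", n0 - length(domains), " removed)")
  if (!is.null(config$max_len)) {
    n1 <- length(domains)
    domains <- filter_max_length(domains, config$max_len)
    .log_line(log_file, "length filter <= ", config$max_len, ": ",
              length(domains), " kept (", n1 - length(domains), " removed)")
  }
  cla <- read_scop_classification(readLines(config$classification_file))
  fold_labels <- vapply(cla, `[[`, character(1), "fold_id")
  focus_ids <- trimws(readLines(config$focus_file))
  focus_ids <- focus_ids[nzchar(focus_ids)]
  ids <- vapply(domains, function(d) d$id, character(1))
  focus_ids <- intersect(focus_ids, ids)
  # identity filter applies to the focus set only
  fi <- match(focus_ids, ids)
  nr <- nonredundant_set(domains[fi], threshold = config$identity_threshold)
  .log_line(log_file, "identity filter at ", config$identity_threshold,
            " on focus set: ", length(nr$retained_ids), " of ",
            length(focus_ids), " kept")
  keep <- ids %in% c(setdiff(ids, focus_ids), nr$retained_ids)
  domains <- domains[keep]
  ids <- ids[keep]
  missing <- setdiff(ids, names(fold_labels))
  if (length(missing) > 0L) {
    stop("missing fold labels for: ", paste(missing, collapse = ", "))
  }
  .log_line(log_file, "computing all-against-all structural distances for ",
            length(domains), " domains")
  D <- distance_matrix(domains)
  list(D = D, fold_labels = fold_labels[ids],
       focus_ids = nr$retained_ids, domains = domains)
}

#' Run the full fold-space overlap analysis
#'
#' Executes the pipeline stages in order: load inputs, length/identity
#' filters (PDB mode), clustering of the focus set under the intra-cluster
#' criterion, medoid extraction, nearest-neighbor distances from every
#' non-focus domain to the medoid set, shared-fold counts at each retention
#' cutoff, and the permutation test. Every stage logs a line with its
#' counts and, when an output directory is configured, writes its artifact.
#'
#' @param config A [run_config()].
#' @param cluster_focus Cluster the focus set and use medoids (default
#'   `TRUE`); functional-class runs set this to `FALSE`.
#' @return A `run_report` list: `counts` (per-stage bookkeeping),
#'   `partition`, `medoid_ids`, `nn`, `ecdf`, `shared` (one
#'   `shared_fold_result` per cutoff), `permutation`, `summary`.
#' @export
run_full_analysis <- function(config, cluster_focus = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_file <- file.path(out_dir, "run.log")
    if (file.exists(log_file)) file.remove(log_file)
  }
  inputs <- .load_inputs(config, log_file)
  D <- inputs$D
  fold_labels <- inputs$fold_labels
  focus_ids <- inputs$focus_ids
  all_ids <- rownames(D)
  missing <- setdiff(all_ids, names(fold_labels))
  if (length(missing) > 0L) {
    stop("missing fold labels for: ", paste(missing, collapse = ", "))
  }
  if (length(focus_ids) == 0L) stop("focus set is empty")
  other_ids <- setdiff(all_ids, focus_ids)

  # focus-set clustering and medoid reduction
  if (cluster_focus && length(focus_ids) >= 2L) {
    Df <- D[focus_ids, focus_ids]
    tree <- average_linkage_tree(Df)
    partition <- optimal_partition(tree, Df,
                                   threshold = config$cluster_threshold)
    medoid_ids <- partition$medoid_ids
    sep <- separation_stats(partition, Df)
    .log_line(log_file, "clustering: ", partition$n_clusters,
              " clusters over ", length(focus_ids),
              " focus domains; max intra ", signif(partition$max_intra, 3),
              "; ", sep$count, " inter-cluster pairs closer than 0.4 (",
              signif(100 * sep$fraction, 3), "%)")
    if (!is.null(out_dir)) {
      write_clusters(partition, tree, file.path(out_dir, "clusters.tsv"),
                     newick_file = file.path(out_dir, "tree.nwk"))
    }
  } else {
    partition <- NULL
    tree <- NULL
    medoid_ids <- focus_ids
    .log_line(log_file, "clustering skipped: focus set of ",
              length(focus_ids), " used directly")
  }

  # nearest-neighbor distances to the (reduced) focus set
  nn <- nearest_focus_distance(medoid_ids, other_ids, D)
  curve <- nn_ecdf(nn)
  .log_line(log_file, "nearest-neighbor distances for ", length(nn),
            " non-focus domains against ", length(medoid_ids),
            " focus representatives")

  focus_folds <- unique(unname(fold_labels[focus_ids]))
  shared <- lapply(config$relative_cutoffs, function(cu) {
    shared_folds(nn, fold_labels, cutoff = cu,
                 exclude_self = config$observed_exclude_self,
                 focus_folds = focus_folds)
  })
  names(shared) <- sprintf("cutoff_%g", config$relative_cutoffs)
  for (s in shared) {
    .log_line(log_file, "shared folds at cutoff ", s$cutoff, ": ",
              s$n_relatives, " relatives covering ", s$n_folds, " folds")
  }

  observed <- shared_folds(nn, fold_labels, cutoff = config$test_cutoff,
                           exclude_self = config$observed_exclude_self,
                           focus_folds = focus_folds)$n_folds
  perm <- permutation_test(all_ids, fold_labels, D,
                           focus_size = length(medoid_ids),
                           n_perm = config$n_perm,
                           cutoff = config$test_cutoff,
                           observed = observed,
                           seed = config$seed + 211L)
  .log_line(log_file, "permutation test: observed ", observed,
            " shared folds at cutoff ", config$test_cutoff, "; p_raw ",
            signif(perm$p_raw, 4), ", p_conservative ",
            signif(perm$p_conservative, 4), " over ", config$n_perm,
            " permutations")

  summary <- list(
    n_total = length(all_ids), n_focus = length(focus_ids),
    n_focus_representatives = length(medoid_ids),
    n_clusters = if (!is.null(partition)) partition$n_clusters else NA,
    shared = lapply(shared, function(s)
      list(cutoff = s$cutoff, n_relatives = s$n_relatives,
           n_folds = s$n_folds)),
    observed = observed, test_cutoff = config$test_cutoff,
    n_perm = config$n_perm, p_raw = perm$p_raw,
    p_conservative = perm$p_conservative, seed = config$seed
  )

  if (!is.null(out_dir)) {
    write_distance_matrix(D, file.path(out_dir, "distances.tsv"),
                          long_file = file.path(out_dir, "distances_long.tsv"))
    write.table(curve, file.path(out_dir, "nn_ecdf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_null_distribution(perm, file.path(out_dir, "null_distribution.tsv"))
    fold_report <- .fold_report(nn, fold_labels, max(config$relative_cutoffs),
                                focus_folds)
    write.table(fold_report, file.path(out_dir, "fold_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }

  structure(
    list(counts = list(n_total = length(all_ids),
                       n_focus = length(focus_ids),
                       n_other = length(other_ids),
                       n_representatives = length(medoid_ids)),
         partition = partition, tree = tree, medoid_ids = medoid_ids,
         nn = nn, ecdf = curve, shared = shared, permutation = perm,
         summary = summary),
    class = "run_report"
  )
}

# Per-fold accounting of relatives below a cutoff
.fold_report <- function(nn, fold_labels, cutoff, focus_folds) {
  retained <- names(nn)[nn < cutoff]
  lab <- unname(fold_labels[retained])
  keep <- !is.na(lab)
  df <- data.frame(id = retained[keep], fold_id = lab[keep],
                   nn_distance = unname(nn[retained])[keep])
  if (nrow(df) == 0L) {
    return(data.frame(fold_id = character(0), n_relatives = integer(0),
                      min_distance = numeric(0),
                      contains_focus = logical(0)))
  }
  agg <- do.call(rbind, lapply(split(df, df$fold_id), function(g) {
    data.frame(fold_id = g$fold_id[1], n_relatives = nrow(g),
               min_distance = min(g$nn_distance))
  }))
  agg$contains_focus <- agg$fold_id %in% focus_folds
  agg[order(agg$fold_id), ]
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$counts$n_total, " domains (",
      x$counts$n_focus, " focus, ", x$counts$n_representatives,
      " representatives); observed ", x$summary$observed,
      " shared folds at cutoff ", x$summary$test_cutoff,
      "; p_conservative = ", signif(x$summary$p_conservative, 4), "\n",
      sep = "")
  invisible(x)
}

#' Run the analysis for one functional class
#'
#' Identical machinery to [run_full_analysis()] with the focus set replaced
#' by the class member list and no structural-clustering reduction (class
#' members are used directly, matching the way functional classes are
#' compared at full size).
#'
#' @param config A [run_config()]; its focus definition is overridden.
#' @param class_ids Character vector of class member ids (non-empty).
#' @param cluster_focus Apply the clustering reduction anyway? Default
#'   `FALSE`.
#' @return A `run_report`.
#' @export
run_functional_class <- function(config, class_ids, cluster_focus = FALSE) {
  if (length(class_ids) == 0L) stop("class id list is empty")
  if (config$mode == "matrix") {
    config$focus_ids <- class_ids
  } else if (config$mode == "synthetic") {
    ds <- generate_latent_dataset(config$synthetic)
    missing <- setdiff(class_ids, rownames(ds$D))
    if (length(missing) > 0L) {
      stop("class ids not in dataset: ", paste(missing, collapse = ", "))
    }
    config <- run_config(
      D = ds$D, fold_labels = ds$fold_labels, focus_ids = class_ids,
      min_len = config$min_len, max_len = config$max_len,
      identity_threshold = config$identity_threshold,
      cluster_threshold = config$cluster_threshold,
      relative_cutoffs = config$relative_cutoffs,
      test_cutoff = config$test_cutoff,
      observed_exclude_self = config$observed_exclude_self,
      n_perm = config$n_perm, seed = config$seed,
      output_dir = config$output_dir
    )
  } else {
    stop("functional-class runs need matrix or synthetic input")
  }
  run_full_analysis(config, cluster_focus = cluster_focus)
}
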