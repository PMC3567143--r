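# Curated reference table of the SCOP folds found among non-capsid
# structural relatives of viral capsid proteins (distance < 0.5), shipped
# as plain TSV in inst/extdata.

#' Reference table of capsid-relative folds
#'
#' The curated list of SCOP folds covered by close non-capsid structural
#' relatives of viral capsid proteins, with the SCOP topology description,
#' whether the fold itself contains capsid proteins, and an example
#' relative per fold.
#'
#' @return Data frame with columns `fold_id`, `fold_name`, `topology`,
#'   `contains_capsid` (`"Yes"`/`"No"`), `example_relative`, `example_sid`.
#' @export
capsid_relative_folds <- function() {
  path <- system.file("extdata", "capsid_relative_folds.tsv",
                      package = "sharedfolds", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Fold accounting for a capsid-relative fold table
#'
#' Summarizes a fold table in the terms used to describe capsid fold
#' space: total distinct folds, folds that themselves contain capsid
#' proteins, folds specific to non-capsid proteins, and folds whose SCOP
#' topology description mentions the greek-key or jelly-roll motifs (the
#' jelly-roll being a variation of the greek-key).
#'
#' @param tbl A fold table as returned by [capsid_relative_folds()].
#' @return List with `n_folds`, `n_capsid_containing`, `n_noncapsid_only`,
#'   `n_greek_or_jellyroll`.
#' @export
fold_accounting <- function(tbl = capsid_relative_folds()) {
  stopifnot(all(c("fold_id", "topology", "contains_capsid") %in% names(tbl)))
  gk <- grepl("greek-key|jelly-roll", tbl$topology, ignore.case = TRUE)
  capsid <- tbl$contains_capsid == "Yes"
  list(
    n_folds = length(unique(tbl$fold_id)),
    n_capsid_containing = sum(capsid),
    n_noncapsid_only = sum(!capsid),
    n_greek_or_jellyroll = sum(gk)
  )
}
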