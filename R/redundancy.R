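# Sequence-identity redundancy filtering (default threshold 40%).

#' Global sequence identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, linear gap
#' penalty -1 and free terminal gaps, computed with
#' [Biostrings::pairwiseAlignment()]. Identity is the number of identical
#' aligned positions divided by the length of the shorter sequence -- the
#' conservative denominator convention usual for domain-level redundancy
#' culling.
#'
#' @param seq_a,seq_b Non-empty one-letter amino-acid strings (`"X"`
#'   allowed).
#' @return List with `identity` (fraction in `[0, 1]`), `aligned_length`
#'   (alignment columns in the overlap region), `matches`, and `score`
#'   (the optimal alignment score under the +1/0/-1 scheme).
#' @export
global_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  letters_all <- unique(c(Biostrings::AA_ALPHABET, "X"))
  submat <- matrix(0, length(letters_all), length(letters_all),
                   dimnames = list(letters_all, letters_all))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "overlap", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 1
  )
  matches <- Biostrings::nmatch(aln)
  aligned_length <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(
    identity = matches / min(nchar(seq_a), nchar(seq_b)),
    aligned_length = aligned_length,
    matches = matches,
    score = Biostrings::score(aln)
  )
}

#' Greedy sequence-redundancy filtering
#'
#' Greedy culling at a pairwise identity threshold: domains are visited
#' longest-first (ties by lexicographic id) and kept iff their identity to
#' every already-kept domain is below the threshold. The retained set is an
#' antichain (all retained pairs below threshold) and every removed domain
#' has identity at or above threshold to at least one retained domain.
#'
#' @param domains List of [domain_structure()] objects with sequences.
#' @param threshold Identity threshold (default 0.40).
#' @param order Visit order: `"length"` (longest first, default) or `"id"`
#'   (lexicographic).
#' @return List with `retained_ids` (character vector in visit order) and
#'   `removals` (data.frame: `removed_id`, `culprit_id`, `identity`).
#' @export
nonredundant_set <- function(domains, threshold = 0.40, order = c("length", "id")) {
  order <- match.arg(order)
  if (length(domains) == 0L) {
    return(list(retained_ids = character(0),
                removals = data.frame(removed_id = character(0),
                                      culprit_id = character(0),
                                      identity = numeric(0))))
  }
  ids <- vapply(domains, function(d) d$id, character(1))
  lens <- vapply(domains, function(d) d$L, integer(1))
  ord <- if (order == "length") order(-lens, ids) else order(ids)
  kept <- integer(0)
  removed <- character(0)
  culprit <- character(0)
  idval <- numeric(0)
  for (i in ord) {
    hit <- NA_integer_
    hit_id <- NA_real_
    for (j in kept) {
      idt <- global_identity(domains[[i]]$sequence, domains[[j]]$sequence)$identity
      if (idt >= threshold) {
        hit <- j
        hit_id <- idt
        break
      }
    }
    if (is.na(hit)) {
      kept <- c(kept, i)
    } else {
      removed <- c(removed, ids[i])
      culprit <- c(culprit, ids[hit])
      idval <- c(idval, hit_id)
    }
  }
  list(
    retained_ids = ids[kept],
    removals = data.frame(removed_id = removed, culprit_id = culprit,
                          identity = idval)
  )
}

#' Read sequences from FASTA
#'
#' @param file Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  # FASTA headers may carry descriptions after the id
  nm <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  setNames(as.character(aa), nm)
}
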