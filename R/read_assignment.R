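# Assign collapsed sequences to amplicons by projecting them at the
# selected discriminating positions and matching amplicon signatures.

#' Assign collapsed sequences to amplicons via primer signatures
#'
#' Reads the characters of each spliced sequence at the catalog's selected
#' positions (positions count from the start of the sequence, which after
#' index trimming is the start of the forward primer) and matches the
#' resulting signature exactly against the per-amplicon signatures.
#' Sequences shorter than the largest selected position, or whose
#' signature matches no amplicon, are labelled unassigned (`NA`) and kept
#' for reporting rather than dropped.
#'
#' A sequence carrying a variant at a signature position would fail the
#' exact match; with `rescue = TRUE` such unassigned sequences are
#' re-examined by banded local alignment of their primer-region prefix
#' against every forward primer and adopted by the unique best primer
#' whose alignment leaves at most `rescue_k_max` characters unmatched.
#'
#' @param collapsed Collapsed-sequence tibble from [collapse_pairs()].
#' @param catalog A `feature_catalog` from [select_positions()].
#' @param rescue Attempt alignment-based rescue of unassigned sequences
#'   (default `FALSE`).
#' @param rescue_k_max k-statistic cutoff for rescue (default 2).
#' @return `collapsed` with columns `signature`, `amplicon_id` (`NA` when
#'   unassigned) and `rescued` added.
#' @export
assign_reads <- function(collapsed, catalog, rescue = FALSE,
                         rescue_k_max = 2L) {
  stopifnot(inherits(catalog, "feature_catalog"))
  pos <- catalog$selected_positions
  sigs <- catalog$signatures
  if (anyDuplicated(sigs)) stop("catalog signatures are not injective")
  sig_of <- function(seqs) {
    out <- rep("", length(seqs))
    for (p in pos) out <- paste0(out, substr(seqs, p, p))
    out
  }
  long_enough <- nchar(collapsed$spliced_seq) >= max(pos)
  signature <- ifelse(long_enough, sig_of(collapsed$spliced_seq),
                      NA_character_)
  amplicon_id <- names(sigs)[match(signature, sigs)]
  rescued <- rep(FALSE, nrow(collapsed))
  if (rescue && any(is.na(amplicon_id))) {
    primers <- attr(catalog, "fwd_primers")
    if (is.null(primers)) {
      stop("rescue requires a catalog built by select_positions() on a panel",
           call. = FALSE)
    }
    plen <- max(nchar(primers))
    for (idx in which(is.na(amplicon_id))) {
      prefix <- substr(collapsed$spliced_seq[idx], 1L, plen + 2L)
      if (nchar(prefix) == 0L) next
      ks <- vapply(primers, function(p) {
        align_local(p, prefix, epsilon = max(nchar(p), nchar(prefix)))$k
      }, integer(1L))
      ok <- which(ks <= rescue_k_max)
      if (length(ok) && sum(ks == min(ks[ok])) == 1L) {
        best <- which.min(replace(ks, ks > rescue_k_max, NA))
        amplicon_id[idx] <- names(primers)[best]
        rescued[idx] <- TRUE
      }
    }
  }
  dplyr::mutate(collapsed, signature = signature,
                amplicon_id = amplicon_id, rescued = rescued)
}
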