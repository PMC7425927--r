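# Read cleaning: public-sequence (capture failure) removal and
# index-bleed trimming / R1 truncation.

#' Drop read pairs that contain the public capture sequence
#'
#' The public sequence captures the target DNA; when capture fails it is
#' sequenced instead of the target, so its presence marks a useless pair.
#' A pair is dropped — both mates — when R1 contains the public sequence
#' as an exact substring, or R2 contains its reverse complement (R2 reads
#' the opposite strand). All other pairs pass unmodified.
#'
#' @param pairs Read-pair tibble (see [read_fastq_pair()]).
#' @param public_seq Panel-wide public sequence (non-empty DNA string).
#' @return The surviving pairs, with a one-row report tibble
#'   (`input_pairs`, `dropped_public`, `surviving_pairs`) attached as the
#'   `cleaning_report` attribute (see [cleaning_report()]).
#' @export
clean_public <- function(pairs, public_seq) {
  stopifnot(is.character(public_seq), length(public_seq) == 1L,
            nchar(public_seq) >= 1L)
  hit_r1 <- grepl(public_seq, pairs$r1_seq, fixed = TRUE)
  hit_r2 <- grepl(revcomp(public_seq), pairs$r2_seq, fixed = TRUE)
  drop <- hit_r1 | hit_r2
  out <- pairs[!drop, , drop = FALSE]
  attr(out, "cleaning_report") <- tibble::tibble(
    input_pairs = nrow(pairs),
    dropped_public = sum(drop),
    surviving_pairs = nrow(out)
  )
  out
}

#' Retrieve the cleaning report attached by a cleaning step
#' @param pairs A tibble returned by [clean_public()] or [clean_index()].
#' @return The report tibble, or `NULL` if none is attached.
#' @export
cleaning_report <- function(pairs) attr(pairs, "cleaning_report")

#' Trim index bleed-through from R2 and truncate over-long R1
#'
#' When the insert is short, the sample index bleeds into the start of R2:
#' the first `nchar(index) + 2` characters of R2 are searched for the
#' index allowing up to `max_mismatch` substitutions (no gaps); at the
#' leftmost hit the R2 prefix through the end of the match is removed.
#' Independently, when the amplicon target is shorter than 150 bp, R1 is
#' truncated to the target length so index/adapter read-through at its 3'
#' end cannot masquerade as variation.
#'
#' @param pairs Read-pair tibble.
#' @param index Index (sample tag) sequence.
#' @param target_len Length of the amplicon target; `NULL` skips the R1
#'   truncation rule (used before reads are assigned to amplicons).
#' @param max_mismatch Mismatch budget for the index search (default 3).
#' @param read_cap Read length above which R1 truncation applies
#'   (default 150, the platform read length).
#' @return The pairs with trimmed `r2_seq` (and truncated `r1_seq` when
#'   applicable); a report (`index_trimmed`, `r1_truncated`) is attached
#'   as the `cleaning_report` attribute. Qualities are trimmed in step.
#' @export
clean_index <- function(pairs, index, target_len = NULL, max_mismatch = 3L,
                        read_cap = 150L) {
  stopifnot(is.character(index), length(index) == 1L, nchar(index) >= 1L)
  trim_at <- index_match_end(pairs$r2_seq, index, max_mismatch)
  trimmed <- !is.na(trim_at)
  out <- pairs
  out$r2_seq[trimmed] <- substring(out$r2_seq[trimmed],
                                   trim_at[trimmed] + 1L)
  if ("r2_qual" %in% names(out)) {
    keep <- trimmed & !is.na(out$r2_qual)
    out$r2_qual[keep] <- substring(out$r2_qual[keep], trim_at[keep] + 1L)
  }
  n_trunc <- 0L
  if (!is.null(target_len) && target_len < read_cap) {
    too_long <- nchar(out$r1_seq) > target_len
    out$r1_seq[too_long] <- substr(out$r1_seq[too_long], 1L, target_len)
    if ("r1_qual" %in% names(out)) {
      keep <- too_long & !is.na(out$r1_qual)
      out$r1_qual[keep] <- substr(out$r1_qual[keep], 1L, target_len)
    }
    n_trunc <- sum(too_long)
  }
  attr(out, "cleaning_report") <- tibble::tibble(
    index_trimmed = sum(trimmed), r1_truncated = n_trunc
  )
  out
}

# For each read: 1-based end position of the leftmost placement of `index`
# within the first nchar(index)+2 characters at <= max_mismatch
# substitutions, or NA. Reads shorter than the window are searched over
# their full length.
index_match_end <- function(reads, index, max_mismatch) {
  k <- nchar(index)
  idx_chars <- chars(index)
  vapply(reads, function(r) {
    win <- min(nchar(r), k + 2L)
    if (win < k) return(NA_integer_)
    rc <- chars(substr(r, 1L, win))
    for (s in 0:(win - k)) {
      if (sum(rc[s + seq_len(k)] != idx_chars) <= max_mismatch) {
        return(s + k)
      }
    }
    NA_integer_
  }, integer(1L), USE.NAMES = FALSE)
}
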