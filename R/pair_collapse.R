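# Duplicate collapse: splice each pair into one key (R2 + revcomp(R1)),
# count identical keys, and filter at the occurrence threshold phi.

#' Collapse read pairs into unique spliced sequences with counts
#'
#' Each pair is spliced into a single key — `r2_seq` followed by the
#' reverse complement of `r1_seq`, i.e. both mates in the same strand
#' orientation — and identical keys are counted. Entries are sorted by
#' frequency descending (ties broken lexicographically by sequence, so the
#' ordering is deterministic) and entries seen fewer than `phi` times are
#' discarded. With `phi = 1` (the default) every distinct sequence is kept.
#'
#' @param pairs Read-pair tibble.
#' @param phi Minimum occurrence count (integer \eqn{\ge} 1).
#' @return A tibble with columns `spliced_seq`, `frequency`, and `r2_len`
#'   (the R2 length of the contributing pairs, needed to split the key
#'   back into mates). The total input pair count is attached as the
#'   `input_pairs` attribute so that frequency mass can be audited.
#' @seealso [split_collapsed()]
#' @export
collapse_pairs <- function(pairs, phi = 1L) {
  stopifnot(phi >= 1L)
  if (nrow(pairs) == 0L) {
    out <- tibble::tibble(spliced_seq = character(), frequency = integer(),
                          r2_len = integer())
    attr(out, "input_pairs") <- 0L
    return(out)
  }
  out <- pairs |>
    dplyr::mutate(spliced_seq = paste0(.data$r2_seq, revcomp(.data$r1_seq)),
                  r2_len = nchar(.data$r2_seq)) |>
    dplyr::count(.data$spliced_seq, .data$r2_len, name = "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$spliced_seq) |>
    dplyr::select("spliced_seq", "frequency", "r2_len")
  attr_total <- nrow(pairs)
  out <- out[out$frequency >= phi, , drop = FALSE]
  attr(out, "input_pairs") <- attr_total
  out
}

#' Split a spliced sequence back into its R2 and R1 parts
#'
#' Inverse of the splice performed by [collapse_pairs()]: the prefix of
#' length `r2_len` is the R2 sequence and the reverse complement of the
#' remaining suffix restores R1 in its original orientation.
#'
#' @param spliced_seq A spliced key (character scalar or vector).
#' @param r2_len R2 length(s); must satisfy `0 < r2_len < nchar(spliced_seq)`.
#' @return A tibble with columns `r2_part` and `r1_part`.
#' @export
split_collapsed <- function(spliced_seq, r2_len) {
  if (any(r2_len <= 0L | r2_len >= nchar(spliced_seq))) {
    stop("r2_len out of range (need 0 < r2_len < nchar(spliced_seq))",
         call. = FALSE)
  }
  tibble::tibble(
    r2_part = substr(spliced_seq, 1L, r2_len),
    r1_part = revcomp(substring(spliced_seq, r2_len + 1L))
  )
}
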