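# Primer feature extraction: pairwise difference sets (FS), enumeration of
# valid discriminating position combinations (CoPo), and selection of a
# minimal discriminating set with per-amplicon signatures.

#' Pairwise characteristic set of two primer sequences
#'
#' Lists every position (1-based, over the common prefix
#' `1..min(nchar(r), nchar(s))`) at which the two sequences carry
#' different characters, together with both characters. Reading a
#' sequenced read at any such position tells the two primers apart.
#'
#' @param r,s Non-empty DNA strings.
#' @return A tibble with columns `position`, `char_a` (character of `r`)
#'   and `char_b` (character of `s`); zero rows when the sequences agree
#'   over the compared range.
#' @examples
#' pairwise_fs("ACGTGC", "ACGCGC")  # differs only at position 4 (T vs C)
#' @export
pairwise_fs <- function(r, s) {
  stopifnot(nchar(r) >= 1L, nchar(s) >= 1L)
  L <- min(nchar(r), nchar(s))
  rc <- chars(substr(r, 1L, L))
  sc <- chars(substr(s, 1L, L))
  pos <- which(rc != sc)
  tibble::tibble(position = pos, char_a = rc[pos], char_b = sc[pos])
}

# character matrix: one row per primer, columns = common prefix positions
primer_matrix <- function(fwd_primers) {
  L <- min(nchar(fwd_primers))
  do.call(rbind, lapply(substr(fwd_primers, 1L, L), chars))
}

# do the projections of the primer matrix onto `positions` separate all rows?
is_discriminating <- function(mat, positions) {
  sigs <- apply(mat[, positions, drop = FALSE], 1L, paste, collapse = "")
  !anyDuplicated(sigs)
}

#' Enumerate all minimal discriminating position combinations (CoPo)
#'
#' Exhaustively searches position subsets of the primers' common prefix in
#' increasing cardinality and returns every subset of the smallest
#' cardinality whose per-primer character projections are pairwise
#' distinct.
#'
#' @param panel An `amplicon_panel` (or any tibble with distinct
#'   `fwd_primer` values).
#' @return A tibble with a list-column `positions` (sorted integer
#'   vectors) and `size`; one row per valid minimal combination, in
#'   lexicographic order of the position tuple.
#' @export
copo_sets <- function(panel) {
  mat <- primer_matrix(panel$fwd_primer)
  if (anyDuplicated(apply(mat, 1L, paste, collapse = ""))) {
    stop("primers are identical over their common prefix; ",
         "no discriminating set exists", call. = FALSE)
  }
  informative <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  for (k in seq_along(informative)) {
    combos <- utils::combn(informative, k, simplify = FALSE)
    ok <- combos[vapply(combos, function(p) is_discriminating(mat, p),
                        logical(1L))]
    if (length(ok)) {
      return(tibble::tibble(positions = ok, size = k))
    }
  }
  stop("no discriminating position set exists within the common prefix",
       call. = FALSE)
}

#' Select a minimal discriminating position set and build signatures
#'
#' Finds the smallest set of positions in the forward primers' common
#' prefix whose per-primer projections are pairwise distinct, and records
#' each amplicon's signature (its primer characters at those positions).
#' The canonical `"exhaustive"` method enumerates subsets in increasing
#' cardinality and, among valid sets of minimal size, picks the
#' lexicographically smallest position tuple; `"greedy"` repeatedly adds
#' the position that separates the most still-colliding primer pairs (a
#' fast path for large panels, not guaranteed minimal).
#'
#' At least `ceil(log4(n))` positions are information-theoretically
#' required to separate `n` primers over a 4-letter alphabet; the selected
#' set always satisfies this bound.
#'
#' @param panel An `amplicon_panel`.
#' @param method `"exhaustive"` (canonical, default) or `"greedy"`.
#' @return A `feature_catalog`: list with `selected_positions` (sorted
#'   integer vector), `signatures` (named character vector, amplicon id ->
#'   signature), `pairwise` (tibble of all pairwise difference positions),
#'   and `primer_prefix_len`.
#' @export
select_positions <- function(panel, method = c("exhaustive", "greedy")) {
  method <- match.arg(method)
  mat <- primer_matrix(panel$fwd_primer)
  positions <- switch(
    method,
    exhaustive = copo_sets(panel)$positions[[1L]],
    greedy = greedy_positions(mat)
  )
  positions <- sort(positions)
  sigs <- apply(mat[, positions, drop = FALSE], 1L, paste, collapse = "")
  names(sigs) <- panel$amplicon_id
  if (anyDuplicated(sigs)) {
    stop("internal error: selected positions do not separate all primers",
         call. = FALSE)
  }
  ids <- panel$amplicon_id
  pw <- purrr::map_dfr(utils::combn(seq_along(ids), 2L, simplify = FALSE),
                       function(ij) {
    fs <- pairwise_fs(panel$fwd_primer[ij[1L]], panel$fwd_primer[ij[2L]])
    dplyr::mutate(fs, primer_a = ids[ij[1L]], primer_b = ids[ij[2L]],
                  .before = 1L)
  })
  structure(
    list(selected_positions = positions, signatures = sigs,
         pairwise = pw, primer_prefix_len = ncol(mat)),
    fwd_primers = stats::setNames(panel$fwd_primer, panel$amplicon_id),
    class = "feature_catalog"
  )
}

# add the position separating the most currently-colliding primer pairs;
# ties go to the smallest position
greedy_positions <- function(mat) {
  n <- nrow(mat)
  pairs <- utils::combn(n, 2L)
  unresolved <- rep(TRUE, ncol(pairs))
  chosen <- integer()
  while (any(unresolved)) {
    gain <- vapply(seq_len(ncol(mat)), function(p) {
      if (p %in% chosen) return(-1L)
      sum(unresolved & mat[pairs[1L, ], p] != mat[pairs[2L, ], p])
    }, integer(1L))
    if (max(gain) <= 0L) {
      stop("greedy search stalled: primers not separable over common prefix",
           call. = FALSE)
    }
    best <- which.max(gain)
    chosen <- c(chosen, best)
    unresolved <- unresolved &
      !(mat[pairs[1L, ], best] != mat[pairs[2L, ], best])
  }
  chosen
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("<feature_catalog>\n")
  cat("  positions:", paste(x$selected_positions, collapse = ", "), "\n")
  cat("  signatures:\n")
  for (id in names(x$signatures)) {
    cat(sprintf("    %-12s %s\n", id, x$signatures[[id]]))
  }
  invisible(x)
}

#' @describeIn select_positions Tidy the catalog into a tibble of
#'   amplicon ids and signatures.
#' @param x A `feature_catalog`.
#' @param ... Unused.
#' @export
tidy.feature_catalog <- function(x, ...) {
  tibble::tibble(amplicon_id = names(x$signatures),
                 signature = unname(x$signatures))
}
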