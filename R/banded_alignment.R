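# Band-restricted local alignment.
#
# Scoring: +1 for a matching diagonal step, 0 for a mismatching diagonal
# step, -1 per gap character, with every cell floored at 0 and cells
# outside the band |i - j| <= epsilon fixed at 0. The k-statistic is the
# number of characters of the shorter sequence left unmatched on the
# optimal path: k = min(m, n) - matched_count; k = 0 means the shorter
# sequence is entirely contained in the longer one.

#' Default band half-width for a pair of sequence lengths
#'
#' The band is set to the length difference plus one, `|m - n| + 1`: wide
#' enough that an alignment shifted by the full length difference stays
#' inside the band, while keeping the filled area of the matrix linear in
#' the sequence length.
#'
#' @param m,n Sequence lengths (positive integers).
#' @return The band half-width as an integer.
#' @examples
#' band_width(9, 11)  # 3
#' @export
band_width <- function(m, n) {
  stopifnot(m >= 1L, n >= 1L)
  as.integer(abs(m - n) + 1L)
}

#' Banded local alignment of two DNA sequences
#'
#' Fills the `(m+1) x (n+1)` score matrix with first row and column zero,
#' the recurrence `d[i,j] = max(d[i-1,j-1] + p(s_i,t_j), d[i-1,j] - 1,
#' d[i,j-1] - 1, 0)` where `p` is 1 on match and 0 on mismatch, and every
#' cell with `|i - j| > epsilon` held at 0. The maximum cell (ties: the
#' smallest `i`, then the smallest `j`) starts the traceback, which at
#' equal scores prefers the vertical move, then horizontal, then diagonal,
#' and stops at a zero cell.
#'
#' @param s Query sequence (e.g. a read fragment), length `m`.
#' @param t Subject sequence (e.g. the amplicon target), length `n`.
#' @param epsilon Band half-width; defaults to [band_width()] of the two
#'   lengths. Any `epsilon >= max(m, n)` makes the band vacuous, giving
#'   plain (unbanded) local alignment.
#' @return An object of class `amplicall_alignment`: a list with `score`
#'   (DP maximum), `matched_count`, `k`, `path` (two-column matrix of
#'   `(i, j)` cells from the maximum back to the terminating zero cell),
#'   `aligned` (tibble of diagonal steps: `s_pos`, `t_pos`, `s_char`,
#'   `t_char`, `match`), `gaps` (tibble: `kind` `"INS"` for a gap in `t`
#'   / `"DEL"` for a gap in `s`, `t_pos` and `s_pos` anchors, `seq`,
#'   `len`), the
#'   aligned spans `s_start`/`s_end`/`t_start`/`t_end`, and `epsilon`.
#' @seealso [is_local_optimal()]
#' @examples
#' align_local("CGTGAGCTG", "CGTCGAGCTGA")
#' @export
align_local <- function(s, t, epsilon = band_width(nchar(s), nchar(t))) {
  stopifnot(nchar(s) >= 1L, nchar(t) >= 1L, epsilon >= 0L)
  sc <- chars(s)
  tc <- chars(t)
  m <- length(sc)
  n <- length(tc)
  D <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
  for (i in seq_len(m)) {
    jlo <- max(1L, i - epsilon)
    jhi <- min(n, i + epsilon)
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      diag <- D[i, j] + (sc[i] == tc[j])
      up <- D[i, j + 1L] - 1L
      left <- D[i + 1L, j] - 1L
      D[i + 1L, j + 1L] <- max(diag, up, left, 0L)
    }
  }
  best <- max(D)
  empty_aligned <- tibble::tibble(
    s_pos = integer(), t_pos = integer(), s_char = character(),
    t_char = character(), match = logical()
  )
  empty_gaps <- tibble::tibble(kind = character(), t_pos = integer(),
                               s_pos = integer(), seq = character(),
                               len = integer())
  if (best == 0L) {
    return(new_alignment(
      score = 0L, matched_count = 0L, k = min(m, n),
      path = matrix(integer(), ncol = 2L), aligned = empty_aligned,
      gaps = empty_gaps, s_start = NA_integer_, s_end = NA_integer_,
      t_start = NA_integer_, t_end = NA_integer_,
      s = s, t = t, epsilon = epsilon
    ))
  }
  hit <- which(D == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
  i <- hit[[1L]] - 1L   # 1-based sequence coordinates
  j <- hit[[2L]] - 1L
  mi <- i
  mj <- j
  path <- list(c(i, j))
  moves <- character()
  while (D[i + 1L, j + 1L] > 0L) {
    v <- D[i + 1L, j + 1L]
    if (i >= 1L && D[i, j + 1L] - 1L == v) {
      moves <- c(moves, "up")
      i <- i - 1L
    } else if (j >= 1L && D[i + 1L, j] - 1L == v) {
      moves <- c(moves, "left")
      j <- j - 1L
    } else if (i >= 1L && j >= 1L &&
               D[i, j] + (sc[i] == tc[j]) == v) {
      moves <- c(moves, "diag")
      i <- i - 1L
      j <- j - 1L
    } else {
      stop("internal error: traceback found no consistent predecessor")
    }
    path <- c(path, list(c(i, j)))
  }
  moves <- rev(moves)  # forward order, from (i, j) up to the max cell
  si <- i
  tj <- j
  srt <- list()
  gap_runs <- list()
  run <- NULL
  flush_run <- function(run) {
    if (is.null(run)) return(NULL)
    gap_runs[[length(gap_runs) + 1L]] <<- run
    NULL
  }
  for (mv in moves) {
    if (mv == "diag") {
      run <- flush_run(run)
      si <- si + 1L
      tj <- tj + 1L
      srt[[length(srt) + 1L]] <- c(si, tj)
    } else if (mv == "up") {          # consumes s, gap in t: insertion
      if (!is.null(run) && run$kind != "INS") run <- flush_run(run)
      si <- si + 1L
      if (is.null(run)) {
        run <- list(kind = "INS", t_pos = tj, s_pos = si, chars = sc[si])
      } else {
        run$chars <- c(run$chars, sc[si])
      }
    } else {                          # left: consumes t, gap in s: deletion
      if (!is.null(run) && run$kind != "DEL") run <- flush_run(run)
      tj <- tj + 1L
      if (is.null(run)) {
        run <- list(kind = "DEL", t_pos = tj, s_pos = si, chars = tc[tj])
      } else {
        run$chars <- c(run$chars, tc[tj])
      }
    }
  }
  flush_run(run)
  aligned <- if (length(srt)) {
    ij <- do.call(rbind, srt)
    tibble::tibble(
      s_pos = ij[, 1L], t_pos = ij[, 2L],
      s_char = sc[ij[, 1L]], t_char = tc[ij[, 2L]],
      match = sc[ij[, 1L]] == tc[ij[, 2L]]
    )
  } else empty_aligned
  gaps <- if (length(gap_runs)) {
    tibble::tibble(
      kind = vapply(gap_runs, `[[`, "", "kind"),
      t_pos = vapply(gap_runs, function(g) as.integer(g$t_pos), integer(1L)),
      s_pos = vapply(gap_runs, function(g) as.integer(g$s_pos), integer(1L)),
      seq = vapply(gap_runs, function(g) paste(g$chars, collapse = ""), ""),
      len = vapply(gap_runs, function(g) length(g$chars), integer(1L))
    )
  } else empty_gaps
  matched <- sum(aligned$match)
  new_alignment(
    score = as.integer(best), matched_count = as.integer(matched),
    k = as.integer(min(m, n) - matched),
    path = do.call(rbind, path), aligned = aligned, gaps = gaps,
    s_start = i + 1L, s_end = mi, t_start = j + 1L, t_end = mj,
    s = s, t = t, epsilon = as.integer(epsilon)
  )
}

new_alignment <- function(...) {
  structure(list(...), class = "amplicall_alignment")
}

#' Does an alignment meet the k-statistic acceptance rule?
#'
#' An alignment is accepted as locally optimal when at most `k_max`
#' characters of the shorter sequence are left unmatched (`k <= k_max`);
#' `k = 0` means the shorter sequence is a complete subset of the longer.
#'
#' @param result An `amplicall_alignment` from [align_local()].
#' @param k_max Maximum tolerated unmatched characters (default 2).
#' @return Logical scalar.
#' @export
is_local_optimal <- function(result, k_max = 2L) {
  stopifnot(inherits(result, "amplicall_alignment"))
  result$k <= k_max
}

#' @export
print.amplicall_alignment <- function(x, ...) {
  cat(sprintf("<amplicall_alignment> score=%d matched=%d k=%d epsilon=%d\n",
              x$score, x$matched_count, x$k, x$epsilon))
  if (nrow(x$aligned) == 0L) {
    cat("  (no local similarity)\n")
    return(invisible(x))
  }
  fmt <- format_alignment(x)
  cat("  S ", fmt$s_line, "\n    ", fmt$bar, "\n  T ", fmt$t_line, "\n",
      sep = "")
  invisible(x)
}

# gapped rendering of the aligned region (debug/inspection aid)
format_alignment <- function(x) {
  sc <- chars(x$s)
  tc <- chars(x$t)
  si <- x$s_start - 1L
  tj <- x$t_start - 1L
  s_line <- character()
  t_line <- character()
  bar <- character()
  # replay the path moves in forward order
  path <- x$path[rev(seq_len(nrow(x$path))), , drop = FALSE]
  for (r in seq_len(nrow(path) - 1L)) {
    di <- path[r + 1L, 1L] - path[r, 1L]
    dj <- path[r + 1L, 2L] - path[r, 2L]
    if (di == 1L && dj == 1L) {
      si <- si + 1L
      tj <- tj + 1L
      s_line <- c(s_line, sc[si])
      t_line <- c(t_line, tc[tj])
      bar <- c(bar, if (sc[si] == tc[tj]) "|" else ".")
    } else if (di == 1L) {
      si <- si + 1L
      s_line <- c(s_line, sc[si])
      t_line <- c(t_line, "-")
      bar <- c(bar, " ")
    } else {
      tj <- tj + 1L
      s_line <- c(s_line, "-")
      t_line <- c(t_line, tc[tj])
      bar <- c(bar, " ")
    }
  }
  list(s_line = paste(s_line, collapse = ""),
       bar = paste(bar, collapse = ""),
       t_line = paste(t_line, collapse = ""))
}
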