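# Variant calling: split assigned collapsed sequences into mates, align
# each against the amplicon target, accumulate frequency-weighted base
# counts per target position, and emit SNP/indel calls.

#' Calling thresholds
#'
#' @param snp_ref_fraction A position is variant when the reference base's
#'   frequency fraction falls below this value (default 0.90; a fraction
#'   of exactly 1 is definitively non-variant, and no call is made
#'   anywhere at or above the threshold).
#' @param k_max Maximum unmatched characters for an alignment to be
#'   accepted as locally optimal (default 2).
#' @param min_depth Minimum column depth (total supporting frequency) for
#'   a call (default 10; the frequency ratio is unstable at tiny depths).
#' @param epsilon Band half-width; `NULL` (default) uses the automatic
#'   `|m - n| + 1` rule per alignment.
#' @param read_cap Platform read length used by the R1 truncation rule
#'   (default 150).
#' @return A `calling_thresholds` list.
#' @export
calling_thresholds <- function(snp_ref_fraction = 0.90, k_max = 2L,
                               min_depth = 10L, epsilon = NULL,
                               read_cap = 150L) {
  stopifnot(snp_ref_fraction > 0, snp_ref_fraction <= 1,
            k_max >= 0L, min_depth >= 1L)
  structure(list(snp_ref_fraction = snp_ref_fraction, k_max = k_max,
                 min_depth = min_depth, epsilon = epsilon,
                 read_cap = read_cap),
            class = "calling_thresholds")
}

#' Align the mates of assigned collapsed sequences to their target
#'
#' Each spliced sequence is split back into its R2 and R1 parts
#' ([split_collapsed()]); when the target is shorter than the read cap the
#' R1 part is truncated to the target length (per-amplicon application of
#' the index-cleaning truncation rule). Known primer bases are stripped by
#' length — the forward primer from the start of the R2 part, the reverse
#' primer from the (reverse-complemented) R1 part — and each remaining
#' fragment is locally aligned against the amplicon target with the
#' banded recurrence.
#'
#' Acceptance is tracked twice: `snp_ok` is the strict `k <= k_max` rule
#' used for the base-frequency pileup, while `indel_ok` additionally
#' forgives characters that the optimal path explains as inserted
#' (`k - inserted_len <= k_max`), since an insertion of length L
#' necessarily leaves L characters of the shorter sequence unmatched.
#'
#' The band `|i - j| <= epsilon` is anchored on the main diagonal, i.e. on
#' alignments that share their start. The R2 fragment is a target prefix
#' and aligns at offset 0; the R1 fragment is a target suffix, whose
#' natural offset `n - m` sits at the band edge and would push
#' insertion-shifted paths outside the band. The R1 fragment is therefore
#' aligned in its native orientation against the reverse-complemented
#' target — a prefix alignment again — and its pileup/gap coordinates
#' mapped back to target space (`orientation == "rev"` rows).
#'
#' @param assigned Rows of an [assign_reads()] table belonging to one
#'   amplicon (`spliced_seq`, `frequency`, `r2_len`).
#' @param amplicon One-row amplicon tibble (a row of the panel).
#' @param thresholds A [calling_thresholds()] object.
#' @return A tibble with one row per aligned fragment: `mate` (`"R2"` or
#'   `"R1"`), `orientation` (`"fwd"`: aligned against the target,
#'   `"rev"`: against its reverse complement), `frequency`, `k`,
#'   `inserted_len`, `snp_ok`, `indel_ok`, the covered target span
#'   `t_start`/`t_end` (always in target coordinates), and the
#'   list-column `alignment` (in the row's own orientation).
#' @export
align_assigned <- function(assigned, amplicon, thresholds = calling_thresholds()) {
  target <- amplicon$target_seq
  n <- nchar(target)
  rc_target <- revcomp(target)
  fwd_len <- nchar(amplicon$fwd_primer)
  rev_len <- nchar(amplicon$rev_primer)
  rows <- list()
  for (r in seq_len(nrow(assigned))) {
    parts <- split_collapsed(assigned$spliced_seq[r], assigned$r2_len[r])
    r1p <- parts$r1_part
    if (n < thresholds$read_cap && nchar(r1p) > n) {
      r1p <- substr(r1p, 1L, n)
    }
    frag2 <- substring(parts$r2_part, fwd_len + 1L)
    # R1 starts at the reverse primer; dropping it leaves the reverse
    # complement of the target suffix, compared against rc(target)
    frag1 <- substring(r1p, rev_len + 1L)
    for (mate in c("R2", "R1")) {
      frag <- if (mate == "R2") frag2 else frag1
      ref <- if (mate == "R2") target else rc_target
      if (nchar(frag) == 0L) next
      eps <- thresholds$epsilon %||% band_width(nchar(frag), nchar(ref))
      aln <- align_local(frag, ref, epsilon = eps)
      ins_len <- sum(aln$gaps$len[aln$gaps$kind == "INS"])
      span <- if (mate == "R2" || is.na(aln$t_start)) {
        c(aln$t_start, aln$t_end)
      } else {
        c(n + 1L - aln$t_end, n + 1L - aln$t_start)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mate = mate, orientation = if (mate == "R2") "fwd" else "rev",
        frequency = assigned$frequency[r],
        k = aln$k, inserted_len = ins_len,
        snp_ok = aln$k <= thresholds$k_max,
        indel_ok = (aln$k - ins_len) <= thresholds$k_max,
        t_start = span[1L], t_end = span[2L],
        alignment = list(aln)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      mate = character(), orientation = character(), frequency = integer(),
      k = integer(), inserted_len = integer(), snp_ok = logical(),
      indel_ok = logical(), t_start = integer(), t_end = integer(),
      alignment = list()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Frequency-weighted base-count pileup over an amplicon target
#'
#' Accumulates, for every target position, the number of A, C, G, T and N
#' characters aligned to it across all accepted alignments (`k <= k_max`),
#' each weighted by the collapsed sequence's frequency. Gap columns do not
#' contribute (indel evidence is handled by [call_indels()]).
#'
#' @inheritParams align_assigned
#' @param alignments Optionally a precomputed [align_assigned()] table.
#' @return A tibble with one row per target position: `position`, `ref`,
#'   counts `A`, `C`, `G`, `T`, `N`, `depth`, and `p_ref` (the reference
#'   base's fraction of depth; `NA` at zero depth).
#' @export
pileup_amplicon <- function(assigned, amplicon,
                            thresholds = calling_thresholds(),
                            alignments = NULL) {
  if (is.null(alignments)) {
    alignments <- align_assigned(assigned, amplicon, thresholds)
  }
  target <- amplicon$target_seq
  n <- nchar(target)
  counts <- matrix(0L, nrow = n, ncol = 5L,
                   dimnames = list(NULL, DNA_ALPHABET))
  keep <- which(alignments$snp_ok)
  for (r in keep) {
    aln <- alignments$alignment[[r]]
    freq <- alignments$frequency[r]
    a <- aln$aligned
    if (alignments$orientation[r] == "rev") {
      a$t_pos <- n + 1L - a$t_pos
      a$s_char <- complement_chars(a$s_char)
    }
    for (b in DNA_ALPHABET) {
      sel <- a$t_pos[a$s_char == b]
      if (length(sel)) {
        counts[sel, b] <- counts[sel, b] + freq
      }
    }
  }
  ref <- chars(target)
  depth <- as.integer(rowSums(counts))
  ref_count <- counts[cbind(seq_len(n), match(ref, DNA_ALPHABET))]
  tibble::tibble(
    position = seq_len(n), ref = ref,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"], N = counts[, "N"],
    depth = depth,
    p_ref = ifelse(depth > 0L, ref_count / depth, NA_real_)
  )
}

#' Call SNPs from a pileup
#'
#' For every column with depth at or above `min_depth`, the reference
#' base's fraction of the five-way (A/C/G/T/N) depth is computed; a SNP is
#' emitted iff that fraction is below `snp_ref_fraction`. The alternate
#' allele is the highest-count non-reference base (ties broken
#' alphabetically) and its fraction of depth is reported.
#'
#' @param columns Pileup tibble from [pileup_amplicon()].
#' @inheritParams align_assigned
#' @return A variant tibble (see [variant_tibble()]) of SNP records.
#' @export
call_snps <- function(columns, amplicon, thresholds = calling_thresholds()) {
  out <- variant_tibble()
  eligible <- columns[columns$depth >= thresholds$min_depth &
                        !is.na(columns$p_ref) &
                        columns$p_ref < thresholds$snp_ref_fraction, ,
                      drop = FALSE]
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(nrow(eligible))) {
    col <- eligible[r, ]
    alt_counts <- unlist(col[bases])
    if (col$ref %in% bases) alt_counts[col$ref] <- -1L
    if (max(alt_counts) <= 0L) next  # depleted by N only: no alt evidence
    alt <- bases[which.max(alt_counts)]
    out <- dplyr::bind_rows(out, tibble::tibble(
      amplicon_id = amplicon$amplicon_id, position = col$position,
      ref = col$ref, alt = alt, kind = "SNP",
      alt_fraction = max(alt_counts) / col$depth,
      depth = as.integer(col$depth)
    ))
  }
  out
}

#' Call insertions and deletions from alignment gap operations
#'
#' A gap in the target on the optimal path (read characters with no
#' target partner) is insertion evidence; a gap in the read (target
#' characters skipped) is deletion evidence. Because a mismatch scores 0
#' while a gap scores -1, the optimal path splits a long gap around any
#' accidental interior match; same-kind gap runs separated by at most
#' `merge_gap` aligned columns are therefore coalesced and the composite
#' event re-derived exactly from the read and target strings (runs are
#' left split whenever no single contiguous event reproduces the read).
#' Events are then normalised to their leftmost equivalent placement
#' (homopolymer/repeat ambiguity), aggregated across alignments with
#' frequency weights, and emitted when their support reaches `min_depth`.
#' Records are left-anchored with one shared reference base (VCF
#' convention); an event at target position 1 is right-anchored instead.
#'
#' @param alignments An [align_assigned()] table.
#' @param merge_gap Maximum number of aligned columns between same-kind
#'   gap runs that are coalesced into one event (default 10, the scale of
#'   the longest indels expected; merging is validated by exact
#'   reconstruction, so a generous window cannot create spurious events).
#' @inheritParams align_assigned
#' @return A variant tibble of INS/DEL records.
#' @export
call_indels <- function(alignments, amplicon,
                        thresholds = calling_thresholds(),
                        merge_gap = 10L) {
  target <- amplicon$target_seq
  n <- nchar(target)
  rc_target <- revcomp(target)
  keep <- which(alignments$indel_ok)
  events <- list()
  for (r in keep) {
    aln <- alignments$alignment[[r]]
    g <- aln$gaps
    if (nrow(g) == 0L) next
    rev <- alignments$orientation[r] == "rev"
    g <- coalesce_gap_runs(g, aln, if (rev) rc_target else target,
                           merge_gap)
    if (rev) g <- remap_gaps(g, n)
    for (e in seq_len(nrow(g))) {
      norm <- if (g$kind[e] == "DEL") {
        normalize_del(g$t_pos[e], g$seq[e], target)
      } else {
        normalize_ins(g$t_pos[e], g$seq[e], target)
      }
      key <- paste(g$kind[e], norm$pos, norm$seq, sep = "|")
      events[[key]] <- (events[[key]] %||% 0L) + alignments$frequency[r]
    }
  }
  out <- variant_tibble()
  if (!length(events)) return(out)
  for (key in names(events)) {
    support <- events[[key]]
    if (support < thresholds$min_depth) next
    f <- strsplit(key, "|", fixed = TRUE)[[1L]]
    kind <- f[1L]
    pos <- as.integer(f[2L])
    allele <- f[3L]
    rec <- anchor_indel(kind, pos, allele, target)
    if (is.null(rec)) next
    cover <- alignments$indel_ok &
      !is.na(alignments$t_start) &
      alignments$t_start <= rec$position &
      alignments$t_end >= rec$position
    depth <- sum(alignments$frequency[cover])
    out <- dplyr::bind_rows(out, tibble::tibble(
      amplicon_id = amplicon$amplicon_id, position = rec$position,
      ref = rec$ref, alt = rec$alt, kind = kind,
      alt_fraction = min(1, support / max(depth, support)),
      depth = as.integer(max(depth, support))
    ))
  }
  dplyr::arrange(out, .data$position, .data$kind)
}

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

# map gap events found against the reverse-complemented target back into
# forward target coordinates
remap_gaps <- function(g, n) {
  out <- g
  for (e in seq_len(nrow(g))) {
    if (g$kind[e] == "DEL") {
      # rc positions p..p+len-1 <-> target positions n-p-len+2 .. n-p+1
      out$t_pos[e] <- n - g$t_pos[e] - g$len[e] + 2L
    } else {
      # insertion after rc position p <-> after target position n - p
      out$t_pos[e] <- n - g$t_pos[e]
    }
    out$seq[e] <- revcomp(g$seq[e])
  }
  out
}

# Coalesce same-kind gap runs separated by <= merge_gap aligned columns
# into single composite events, re-derived exactly from read and target.
coalesce_gap_runs <- function(g, aln, target, merge_gap) {
  if (nrow(g) < 2L) return(g)
  g <- g[order(g$t_pos), , drop = FALSE]
  sep_next <- vapply(seq_len(nrow(g) - 1L), function(i) {
    if (g$kind[i] != g$kind[i + 1L]) return(Inf)
    if (g$kind[i] == "DEL") {
      g$t_pos[i + 1L] - (g$t_pos[i] + g$len[i])
    } else {
      g$t_pos[i + 1L] - g$t_pos[i]
    }
  }, double(1L))
  cluster <- cumsum(c(0L, sep_next > merge_gap))
  out <- list()
  for (cl in unique(cluster)) {
    members <- g[cluster == cl, , drop = FALSE]
    if (nrow(members) == 1L) {
      out[[length(out) + 1L]] <- members
      next
    }
    merged <- if (members$kind[1L] == "DEL") {
      rebuild_del_cluster(members, aln, target)
    } else {
      rebuild_ins_cluster(members, aln, target)
    }
    out[[length(out) + 1L]] <- merged %||% members
  }
  dplyr::bind_rows(out)
}

# one contiguous deletion reproducing a split-gap cluster, or NULL
rebuild_del_cluster <- function(members, aln, target) {
  a <- members$t_pos[1L]
  d <- members$t_pos[nrow(members)] + members$len[nrow(members)] - 1L
  W <- substr(target, a, d)
  D <- sum(members$len)
  mid <- aln$aligned[aln$aligned$t_pos >= a & aln$aligned$t_pos <= d, ,
                     drop = FALSE]
  mid <- mid[order(mid$t_pos), , drop = FALSE]
  r_mid <- paste(mid$s_char, collapse = "")
  if (nchar(r_mid) != nchar(W) - D) return(NULL)
  for (q in seq_len(nchar(W) - D + 1L)) {
    if (paste0(substr(W, 1L, q - 1L), substring(W, q + D)) == r_mid) {
      return(tibble::tibble(kind = "DEL", t_pos = a + q - 1L,
                            s_pos = members$s_pos[1L],
                            seq = substr(W, q, q + D - 1L), len = D))
    }
  }
  NULL
}

# one contiguous insertion reproducing a split-gap cluster, or NULL
rebuild_ins_cluster <- function(members, aln, target) {
  p1 <- members$t_pos[1L]
  p_last <- members$t_pos[nrow(members)]
  s1 <- members$s_pos[1L]
  s_end <- members$s_pos[nrow(members)] + members$len[nrow(members)] - 1L
  r_w <- substr(aln$s, s1, s_end)
  t_mid <- if (p_last > p1) substr(target, p1 + 1L, p_last) else ""
  D <- sum(members$len)
  if (nchar(r_w) != nchar(t_mid) + D) return(NULL)
  for (q in 0:nchar(t_mid)) {
    if (substr(r_w, 1L, q) == substr(t_mid, 1L, q) &&
        substring(r_w, q + D + 1L) == substring(t_mid, q + 1L)) {
      return(tibble::tibble(kind = "INS", t_pos = p1 + q, s_pos = s1,
                            seq = substr(r_w, q + 1L, q + D), len = D))
    }
  }
  NULL
}

# shift a deletion of target[pos .. pos+len-1] to its leftmost
# equivalent placement
normalize_del <- function(pos, del_seq, target) {
  len <- nchar(del_seq)
  tc <- chars(target)
  while (pos > 1L && tc[pos - 1L] == tc[pos + len - 1L]) {
    pos <- pos - 1L
  }
  list(pos = pos, seq = paste(tc[pos:(pos + len - 1L)], collapse = ""))
}

# shift an insertion (of string `ins` after target position pos) left
normalize_ins <- function(pos, ins, target) {
  tc <- chars(target)
  ic <- chars(ins)
  len <- length(ic)
  while (pos >= 1L && tc[pos] == ic[len]) {
    ic <- c(tc[pos], ic[-len])
    pos <- pos - 1L
  }
  list(pos = pos, seq = paste(ic, collapse = ""))
}

# produce a left-anchored (or, at the target edge, right-anchored)
# VCF-style (position, ref, alt) for a normalised indel event
anchor_indel <- function(kind, pos, allele, target) {
  tc <- chars(target)
  n <- length(tc)
  len <- nchar(allele)
  if (kind == "DEL") {
    if (pos > 1L) {
      a <- pos - 1L
      list(position = a,
           ref = paste(tc[a:(pos + len - 1L)], collapse = ""),
           alt = tc[a])
    } else if (pos + len <= n) {
      list(position = 1L,
           ref = paste(tc[1L:(len + 1L)], collapse = ""),
           alt = tc[len + 1L])
    } else {
      NULL  # deletion of the entire target: unanchorable
    }
  } else {
    if (pos >= 1L) {
      list(position = pos, ref = tc[pos], alt = paste0(tc[pos], allele))
    } else {
      list(position = 1L, ref = tc[1L], alt = paste0(allele, tc[1L]))
    }
  }
}

#' Call all variants for one amplicon
#'
#' Aligns the amplicon's assigned collapsed sequences once, then runs the
#' SNP pileup caller and the indel caller on the shared alignments.
#'
#' @inheritParams align_assigned
#' @return A variant tibble with the amplicon's SNP, INS and DEL records;
#'   the pileup is attached as the `pileup` attribute.
#' @export
call_variants <- function(assigned, amplicon,
                          thresholds = calling_thresholds()) {
  alignments <- align_assigned(assigned, amplicon, thresholds)
  columns <- pileup_amplicon(assigned, amplicon, thresholds,
                             alignments = alignments)
  out <- dplyr::bind_rows(
    call_snps(columns, amplicon, thresholds),
    call_indels(alignments, amplicon, thresholds)
  )
  out <- dplyr::arrange(out, .data$position, .data$kind)
  attr(out, "pileup") <- columns
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
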