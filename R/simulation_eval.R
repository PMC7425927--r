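# Paired-end amplicon read simulation with SNP/indel spike-in, plus
# recall / TPR / FPR / accuracy evaluation against the simulated truth.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Generate a synthetic amplicon panel
#'
#' Builds a random panel mimicking a targeted exon design: per-amplicon
#' forward/reverse primers flanking a target (exon) sequence, one
#' panel-wide sample index and a public capture sequence. Targets default
#' to 160–190 bp — under the 200 bp design ceiling so that 150 bp mates
#' overlap, and at least the read length so that the automatic band
#' half-width always spans indel-shifted alignment paths. Forward primers
#' are redrawn until pairwise distinct.
#'
#' @param n_amplicons Number of amplicons (default 20).
#' @param target_len Integer range (`c(min, max)`) of target lengths.
#' @param primer_len Primer length (default 7).
#' @param index_len Sample index length (default 8).
#' @param public_len Public sequence length (default 20).
#' @param seed Optional RNG seed for reproducibility.
#' @return An [amplicon_panel()].
#' @export
sim_panel <- function(n_amplicons = 20L, target_len = c(160L, 190L),
                      primer_len = 7L, index_len = 8L, public_len = 20L,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    fwd <- random_dna(n_amplicons, primer_len)
    if (!anyDuplicated(fwd)) break
  }
  lens <- sample(target_len[1L]:target_len[2L], n_amplicons, replace = TRUE)
  amplicon_panel(
    tibble::tibble(
      amplicon_id = sprintf("amp%02d", seq_len(n_amplicons)),
      fwd_primer = fwd,
      rev_primer = random_dna(n_amplicons, primer_len),
      index = random_dna(1L, index_len),
      target_seq = vapply(lens, function(L) random_dna(1L, L), character(1L))
    ),
    public_seq = random_dna(1L, public_len)
  )
}

#' Spike a random truth set of SNPs and indels into a panel
#'
#' Draws variant sites uniformly over the panel's targets, keeping every
#' site at least `margin` bases from the target ends and `2 * margin`
#' bases from any other site on the same amplicon, so that events do not
#' overlap and left-shift normalisation stays local.
#'
#' @param panel An `amplicon_panel`.
#' @param n_snps,n_indels Numbers of SNP and indel sites (defaults 30, 20).
#' @param allele_fraction Fraction of reads carrying each variant
#'   (default 0.5).
#' @param indel_len Integer range of indel lengths (default 2–10 bp).
#' @param margin Minimum distance from target ends (default 12).
#' @param seed Optional RNG seed.
#' @return A truth tibble: `amplicon_id`, `position` (1-based in the
#'   target; for INS the insertion follows this position), `kind`, `ref`
#'   (SNP reference base, `"."` otherwise), `allele` (SNP alternate base,
#'   inserted sequence, or deleted reference sequence), `allele_fraction`.
#' @export
sim_truth <- function(panel, n_snps = 30L, n_indels = 20L,
                      allele_fraction = 0.5, indel_len = c(2L, 10L),
                      margin = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- n_snps + n_indels
  used <- lapply(stats::setNames(nm = panel$amplicon_id), function(x) integer())
  rows <- list()
  kinds <- c(rep("SNP", n_snps),
             rep(c("INS", "DEL"), length.out = n_indels))
  for (kind in kinds) {
    for (attempt in 1:500) {
      a <- sample(nrow(panel), 1L)
      target <- panel$target_seq[a]
      id <- panel$amplicon_id[a]
      L <- nchar(target)
      len <- if (kind == "SNP") 1L else
        sample(indel_len[1L]:indel_len[2L], 1L)
      lo <- margin
      hi <- L - margin - len
      if (hi < lo) next
      pos <- sample(lo:hi, 1L)
      if (any(abs(used[[id]] - pos) < 2L * margin)) next
      used[[id]] <- c(used[[id]], pos)
      ref_base <- substr(target, pos, pos)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        amplicon_id = id, position = pos, kind = kind,
        ref = if (kind == "SNP") ref_base else ".",
        allele = switch(kind,
          SNP = sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L),
          INS = random_dna(1L, len),
          DEL = substr(target, pos, pos + len - 1L)
        ),
        allele_fraction = allele_fraction
      )
      break
    }
  }
  if (length(rows) < n_total) {
    stop("could not place all variants; enlarge the panel or reduce margin",
         call. = FALSE)
  }
  empty <- tibble::tibble(amplicon_id = character(), position = integer(),
                          kind = character(), ref = character(),
                          allele = character(), allele_fraction = double())
  dplyr::arrange(dplyr::bind_rows(empty, rows),
                 .data$amplicon_id, .data$position)
}

# apply a subset of truth rows (one amplicon) to its target sequence;
# events are non-overlapping, so apply right-to-left
apply_variants <- function(target, vars) {
  if (nrow(vars) == 0L) return(target)
  vars <- vars[order(-vars$position), , drop = FALSE]
  for (r in seq_len(nrow(vars))) {
    p <- vars$position[r]
    al <- vars$allele[r]
    target <- switch(vars$kind[r],
      SNP = paste0(substr(target, 1L, p - 1L), al,
                   substring(target, p + 1L)),
      INS = paste0(substr(target, 1L, p), al, substring(target, p + 1L)),
      DEL = paste0(substr(target, 1L, p - 1L),
                   substring(target, p + nchar(al)))
    )
  }
  target
}

#' Simulate paired-end reads over a panel with spiked variants
#'
#' For every amplicon, `depth` read pairs are drawn from the library
#' molecule `index + fwd_primer + haplotype + rev_primer`, where the
#' haplotype carries each of the amplicon's truth variants independently
#' with probability `allele_fraction`. R2 reads the molecule from the
#' index end, R1 reads the reverse complement from the other end; both
#' are clipped to `read_length` (shorter molecules yield shorter reads —
#' no synthetic adapter read-through). Substitution errors are injected
#' uniformly at `error_rate`. Optionally a fraction of capture-failure
#' pairs carrying the public sequence is appended, which the cleaning
#' stage is expected to drop. Fully deterministic given `seed`.
#'
#' @param panel An `amplicon_panel`.
#' @param truth Truth tibble from [sim_truth()] (may be zero rows).
#' @param depth Read pairs per amplicon (default 50).
#' @param read_length Read length in bp (default 150).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param capture_fail_rate Fraction of additional public-sequence pairs
#'   relative to the total (default 0).
#' @param seed RNG seed (default 1).
#' @return A read-pair tibble; the truth is attached as the `truth`
#'   attribute.
#' @export
sim_reads <- function(panel, truth = NULL, depth = 50L, read_length = 150L,
                      error_rate = 0, capture_fail_rate = 0, seed = 1L) {
  set.seed(seed)
  if (is.null(truth)) truth <- sim_truth(panel, n_snps = 0L, n_indels = 0L)
  bad <- dplyr::anti_join(truth, panel, by = "amplicon_id")
  if (nrow(bad)) stop("truth references unknown amplicon", call. = FALSE)
  for (r in seq_len(nrow(truth))) {
    tlen <- nchar(panel$target_seq[match(truth$amplicon_id[r],
                                         panel$amplicon_id)])
    span <- truth$position[r] +
      (if (truth$kind[r] == "DEL") nchar(truth$allele[r]) - 1L else 0L)
    if (truth$position[r] < 1L || span > tlen) {
      stop("truth variant outside its target", call. = FALSE)
    }
  }
  out <- list()
  for (a in seq_len(nrow(panel))) {
    id <- panel$amplicon_id[a]
    vars <- truth[truth$amplicon_id == id, , drop = FALSE]
    hap_cache <- new.env(parent = emptyenv())
    for (i in seq_len(depth)) {
      carry <- stats::runif(nrow(vars)) < vars$allele_fraction
      key <- paste0("k", paste(which(carry), collapse = ","))
      hap <- get0(key, envir = hap_cache)
      if (is.null(hap)) {
        hap <- apply_variants(panel$target_seq[a],
                              vars[carry, , drop = FALSE])
        assign(key, hap, envir = hap_cache)
      }
      molecule <- paste0(panel$index[a], panel$fwd_primer[a], hap,
                         panel$rev_primer[a])
      r2 <- substr(molecule, 1L, min(read_length, nchar(molecule)))
      r1 <- substr(revcomp(molecule), 1L, min(read_length, nchar(molecule)))
      out[[length(out) + 1L]] <- c(sprintf("%s_r%04d", id, i),
                                   inject_errors(r1, error_rate),
                                   inject_errors(r2, error_rate))
    }
  }
  n_fail <- round(capture_fail_rate * length(out))
  pub <- public_seq(panel)
  for (i in seq_len(n_fail)) {
    flank_l <- random_dna(1L, 9L)
    flank_r <- random_dna(1L, max(read_length + 20L - 9L - nchar(pub), 5L))
    mol <- paste0(flank_l, pub, flank_r)
    out[[length(out) + 1L]] <- c(
      sprintf("fail_r%04d", i),
      substr(mol, 1L, read_length),
      substr(revcomp(mol), 1L, read_length)
    )
  }
  mat <- do.call(rbind, out)
  pairs <- tibble::tibble(read_id = mat[, 1L], r1_seq = mat[, 2L],
                          r2_seq = mat[, 3L])
  attr(pairs, "truth") <- truth
  pairs
}

inject_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  sc <- chars(seq)
  hit <- which(stats::runif(length(sc)) < rate)
  for (i in hit) {
    sc[i] <- sample(setdiff(c("A", "C", "G", "T"), sc[i]), 1L)
  }
  paste(sc, collapse = "")
}

#' Write / read a truth table as TSV
#' @param truth Truth tibble from [sim_truth()].
#' @param path File path.
#' @return The truth tibble (invisibly for the writer).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    amplicon_id = "c", position = "i", kind = "c", ref = "c",
    allele = "c", allele_fraction = "d"
  ), progress = FALSE)
}

# Matching and metrics -------------------------------------------------------

# canonical event key (kind, left-shifted position, allele) per record
truth_keys <- function(truth, panel) {
  vapply(seq_len(nrow(truth)), function(r) {
    target <- panel$target_seq[match(truth$amplicon_id[r],
                                     panel$amplicon_id)]
    kind <- truth$kind[r]
    norm <- switch(kind,
      SNP = list(pos = truth$position[r], seq = truth$allele[r]),
      DEL = normalize_del(truth$position[r], truth$allele[r], target),
      INS = normalize_ins(truth$position[r], truth$allele[r], target)
    )
    paste(truth$amplicon_id[r], kind, norm$pos, norm$seq, sep = "|")
  }, character(1L))
}

# decompose a VCF-anchored call back into event form, then canonicalise
call_keys <- function(calls, panel) {
  vapply(seq_len(nrow(calls)), function(r) {
    target <- panel$target_seq[match(calls$amplicon_id[r],
                                     panel$amplicon_id)]
    kind <- calls$kind[r]
    pos <- calls$position[r]
    ref <- calls$ref[r]
    alt <- calls$alt[r]
    norm <- if (kind == "SNP") {
      list(pos = pos, seq = alt)
    } else if (kind == "DEL") {
      if (substr(ref, 1L, 1L) == alt) {          # left-anchored
        normalize_del(pos + 1L, substring(ref, 2L), target)
      } else {                                    # right-anchored at pos 1
        normalize_del(1L, substr(ref, 1L, nchar(ref) - 1L), target)
      }
    } else {
      if (substr(alt, 1L, 1L) == ref) {           # left-anchored
        normalize_ins(pos, substring(alt, 2L), target)
      } else {                                    # right-anchored at pos 1
        normalize_ins(0L, substr(alt, 1L, nchar(alt) - 1L), target)
      }
    }
    paste(calls$amplicon_id[r], kind, norm$pos, norm$seq, sep = "|")
  }, character(1L))
}

#' Confusion counts of a call set against a simulated truth
#'
#' Calls and truth records are reduced to canonical events — exact
#' position and allele for SNPs, left-shift-normalised position and
#' allele for indels — and matched. `TP`/`FN` count truth events
#' recovered / missed; `FP` counts called events absent from the truth.
#' True negatives are positional: `TN` is the number of target positions
#' that neither carry a truth event nor a (non-matching) call, summed
#' over the panel. This positional reading makes FPR and accuracy
#' well-defined for a caller, where per-site negatives are otherwise
#' ambiguous.
#'
#' @param calls Variant tibble (caller output).
#' @param truth Truth tibble from [sim_truth()].
#' @param panel The `amplicon_panel` both refer to.
#' @return A one-row tibble with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(calls, truth, panel) {
  tk <- if (nrow(truth)) truth_keys(truth, panel) else character()
  ck <- if (nrow(calls)) call_keys(calls, panel) else character()
  TP <- sum(tk %in% ck)
  FN <- sum(!tk %in% ck)
  FP <- sum(!ck %in% tk)
  pos_of <- function(keys) unique(sub("^([^|]+)\\|[^|]+\\|(\\d+)\\|.*$",
                                      "\\1|\\2", keys))
  truth_pos <- pos_of(tk)
  call_pos <- pos_of(ck)
  total_pos <- sum(nchar(panel$target_seq))
  TN <- total_pos - length(truth_pos) -
    length(setdiff(call_pos, truth_pos))
  tibble::tibble(TP = TP, FP = FP, FN = FN, TN = as.integer(TN))
}

#' Recall of a confusion table
#'
#' `TP / (TP + FN)`; `NA` when no positives exist.
#'
#' @param counts One-row tibble (or list) with `TP`, `FP`, `FN`, `TN`.
#' @return A numeric scalar (possibly `NA`).
#' @export
recall <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) NA_real_ else counts$TP / den
}

#' True-positive rate, false-positive rate and accuracy
#'
#' `TPR = TP/(TP+FN)` (identical to recall), `FPR = FP/(FP+TN)`,
#' `accuracy = (TP+TN)/(TP+FP+FN+TN)`; zero denominators give `NA`.
#'
#' @inheritParams recall
#' @return A one-row tibble with `TPR`, `FPR`, `accuracy`.
#' @export
tpr_fpr_accuracy <- function(counts) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    TPR = safe(counts$TP, counts$TP + counts$FN),
    FPR = safe(counts$FP, counts$FP + counts$TN),
    accuracy = safe(counts$TP + counts$TN,
                    counts$TP + counts$FP + counts$FN + counts$TN)
  )
}

#' All evaluation metrics in one row
#' @inheritParams recall
#' @return A one-row tibble: `TP`, `FP`, `FN`, `TN`, `recall`, `TPR`,
#'   `FPR`, `accuracy`.
#' @export
eval_metrics <- function(counts) {
  dplyr::bind_cols(tibble::as_tibble(counts),
                   tibble::tibble(recall = recall(counts)),
                   tpr_fpr_accuracy(counts))
}
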