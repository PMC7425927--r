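# Independent oracles and shared fixtures for the test suite.

# Full (unbanded) Smith-Waterman score with the pipeline's scoring
# (match +1, mismatch 0, gap -1), written as a rolling-row DP so it shares
# no code path with align_local().
sw_oracle_score <- function(s, t) {
  sc <- strsplit(s, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  prev <- integer(length(tc) + 1L)
  best <- 0L
  for (i in seq_along(sc)) {
    cur <- integer(length(tc) + 1L)
    for (j in seq_along(tc)) {
      cur[j + 1L] <- max(prev[j] + (sc[i] == tc[j]),
                         prev[j + 1L] - 1L,
                         cur[j] - 1L,
                         0L)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# Exhaustive minimal discriminating position sets by bitmask enumeration,
# independent of copo_sets()/select_positions().
brute_force_min_sets <- function(primers) {
  L <- min(nchar(primers))
  mat <- do.call(rbind, lapply(substr(primers, 1, L),
                               function(p) strsplit(p, "")[[1]]))
  for (size in 1:L) {
    sets <- utils::combn(L, size, simplify = FALSE)
    ok <- Filter(function(ps) {
      sigs <- apply(mat[, ps, drop = FALSE], 1, paste, collapse = "")
      !anyDuplicated(sigs)
    }, sets)
    if (length(ok)) return(list(size = size, sets = ok))
  }
  NULL
}

# The four forward primers of the published feature-extraction example.
example_primers <- c("ACGGGTG", "ACAGCTG", "ACCGATG", "ACCTAGG")

example_panel <- function(target_len = 160) {
  set.seed(20)
  amplicon_panel(
    tibble::tibble(
      amplicon_id = paste0("r", 1:4),
      fwd_primer = example_primers,
      rev_primer = c("TTGACCA", "GGATTCA", "CATGGTA", "TCCAGGA"),
      index = "ACGTTGCA",
      target_seq = vapply(1:4, function(i) {
        paste(sample(c("A", "C", "G", "T"), target_len, replace = TRUE),
              collapse = "")
      }, character(1))
    ),
    public_seq = "GATTACAGATTACAGATTAC"
  )
}

# A random panel of small primers for property tests.
random_primer_panel <- function(n_primers, primer_len) {
  repeat {
    primers <- vapply(seq_len(n_primers), function(i) {
      paste(sample(c("A", "C", "G", "T"), primer_len, replace = TRUE),
            collapse = "")
    }, character(1))
    if (!anyDuplicated(primers)) break
  }
  amplicon_panel(
    tibble::tibble(
      amplicon_id = paste0("p", seq_len(n_primers)),
      fwd_primer = primers,
      rev_primer = "ACGT", index = "AACCGGTT",
      target_seq = strrep("ACGT", 10)
    ),
    public_seq = "GGGGGCCCCCAAAAATTTTT"
  )
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Build an assigned-collapsed tibble for a toy amplicon from raw mate
# sequences (as the pipeline would after index trimming).
toy_assigned <- function(r1, r2, frequency) {
  tibble::tibble(
    spliced_seq = paste0(r2, revcomp(r1)),
    frequency = as.integer(frequency),
    r2_len = nchar(r2)
  )
}

# One-row amplicon tibble for direct calls into the calling layer.
toy_amplicon <- function(target, fwd = "ACGTC", rev = "G",
                         id = "toy", index = "AACCGGTT") {
  tibble::tibble(amplicon_id = id, fwd_primer = fwd, rev_primer = rev,
                 index = index, target_seq = target)
}

# Mates for a haplotype of a toy amplicon: R2 reads index-trimmed
# fwd+hap (read stops at the haplotype end); R1 reads 30 bases past the
# reverse primer from the other strand, keeping the toy R1 fragment well
# shorter than the target so its automatic band stays generous.
toy_mates <- function(hap, amp) {
  list(r2 = paste0(amp$fwd_primer, hap),
       r1 = substr(revcomp(paste0(amp$fwd_primer, hap, amp$rev_primer)),
                   1, nchar(amp$rev_primer) + 30L))
}
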