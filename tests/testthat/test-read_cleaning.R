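make_pairs <- function(r1, r2) {
  tibble::tibble(read_id = sprintf("q%03d", seq_along(r1)),
                 r1_seq = r1, r2_seq = r2)
}

test_that("a pair is dropped when either mate carries the public sequence", {
  pub <- "GATTACAGATTAC"
  set.seed(1)
  clean1 <- random_dna_str(80)
  clean2 <- random_dna_str(80)
  hit_r1 <- paste0(random_dna_str(20), pub, random_dna_str(20))
  hit_r2 <- paste0(random_dna_str(20), revcomp(pub), random_dna_str(20))
  pairs <- make_pairs(c(clean1, hit_r1, clean1),
                      c(clean2, clean2, hit_r2))
  out <- clean_public(pairs, pub)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_id, "q001")
  rep <- cleaning_report(out)
  expect_equal(rep$input_pairs, 3L)
  expect_equal(rep$dropped_public, 2L)
  expect_equal(rep$surviving_pairs, 1L)
})

test_that("public cleaning matches a brute-force scan and is idempotent", {
  pub <- "TTGGCCAATTGG"
  set.seed(42)
  n <- 100
  r1 <- vapply(1:n, function(i) random_dna_str(90), character(1))
  r2 <- vapply(1:n, function(i) random_dna_str(90), character(1))
  # 13 R1 hits, 7 R2 hits, 3 of them the same pairs
  r1_hit <- 1:13
  r2_hit <- c(11:13, 14:17)
  for (i in r1_hit) r1[i] <- paste0(substr(r1[i], 1, 30), pub,
                                    substr(r1[i], 31, 78))
  for (i in r2_hit) r2[i] <- paste0(substr(r2[i], 1, 30), revcomp(pub),
                                    substr(r2[i], 31, 78))
  pairs <- make_pairs(r1, r2)
  out <- clean_public(pairs, pub)
  # independent oracle: plain substring scan
  oracle_drop <- vapply(1:n, function(i) {
    grepl(pub, r1[i], fixed = TRUE) ||
      grepl(revcomp(pub), r2[i], fixed = TRUE)
  }, logical(1))
  expect_equal(cleaning_report(out)$dropped_public, sum(oracle_drop))
  expect_equal(cleaning_report(out)$dropped_public, 17L)
  expect_setequal(out$read_id, pairs$read_id[!oracle_drop])
  # survivors never contain the public sequence on either mate
  expect_false(any(grepl(pub, out$r1_seq, fixed = TRUE)))
  expect_false(any(grepl(revcomp(pub), out$r2_seq, fixed = TRUE)))
  # idempotence
  again <- clean_public(out, pub)
  expect_equal(again, out, ignore_attr = TRUE)
  expect_equal(cleaning_report(again)$dropped_public, 0L)
})

test_that("index trimming obeys the 3-mismatch budget over the search window", {
  idx <- "ACGTACGT"
  tail_seq <- strrep("TG", 40)
  mm <- function(k) {               # index with k leading substitutions
    s <- strsplit(idx, "")[[1]]
    for (i in seq_len(k)) s[i] <- setdiff(c("A", "C", "G", "T"), s[i])[1]
    paste(s, collapse = "")
  }
  pairs <- make_pairs(
    r1 = rep(strrep("AC", 40), 4),
    r2 = c(paste0(idx, tail_seq),          # exact
           paste0(mm(3), tail_seq),        # 3 substitutions: trimmed
           paste0(mm(4), tail_seq),        # 4 substitutions: untouched
           paste0("GG", idx, tail_seq))    # offset 2, still in window
  )
  out <- clean_index(pairs, idx)
  expect_equal(out$r2_seq[1], tail_seq)
  expect_equal(out$r2_seq[2], tail_seq)
  expect_equal(out$r2_seq[3], pairs$r2_seq[3])
  expect_equal(out$r2_seq[4], tail_seq)
  expect_equal(cleaning_report(out)$index_trimmed, 3L)
})

test_that("the leftmost index hit wins and short reads use their full length", {
  idx <- "AAAA"
  pairs <- make_pairs("ACGTACGT", paste0("AAAAA", strrep("C", 20)))
  # window is nchar(idx)+2 = 6; offsets 0 and 1 both match, leftmost used
  out <- clean_index(pairs, idx)
  expect_equal(out$r2_seq, paste0("A", strrep("C", 20)))
  tiny <- make_pairs("ACGT", "AA")   # shorter than the index itself
  expect_equal(clean_index(tiny, idx)$r2_seq, "AA")
})

test_that("R1 is truncated to the target length only for short targets", {
  r1 <- strrep("ACGTA", 30)  # 150 bp
  pairs <- make_pairs(r1, strrep("G", 150))
  out <- clean_index(pairs, "TTTTTTTT", target_len = 120)
  expect_equal(nchar(out$r1_seq), 120L)
  expect_equal(out$r1_seq, substr(r1, 1, 120))
  expect_equal(cleaning_report(out)$r1_truncated, 1L)
  out2 <- clean_index(pairs, "TTTTTTTT", target_len = 170)
  expect_equal(out2$r1_seq, r1)
})

test_that("index cleaning never lengthens a read", {
  set.seed(7)
  for (i in 1:25) {
    idx <- random_dna_str(sample(4:10, 1))
    pairs <- make_pairs(random_dna_str(sample(20:150, 1)),
                        random_dna_str(sample(20:150, 1)))
    out <- clean_index(pairs, idx, target_len = sample(50:200, 1))
    expect_lte(nchar(out$r1_seq), nchar(pairs$r1_seq))
    expect_lte(nchar(out$r2_seq), nchar(pairs$r2_seq))
  }
})
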