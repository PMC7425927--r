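toy_target <- "ACGTCATGGATCCGATTGCAGTACCAGTTAGCAACGGTAC"  # 40 bp

make_columns <- function(ref, counts) {
  # counts: named list base -> count for a single column
  col <- tibble::tibble(position = 1L, ref = ref,
                        A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  for (b in names(counts)) col[[b]] <- as.integer(counts[[b]])
  col$depth <- as.integer(col$A + col$C + col$G + col$T + col$N)
  col$p_ref <- ifelse(col$depth > 0, col[[ref]] / col$depth, NA_real_)
  col
}

test_that("a perfectly matching sequence fills the pileup with reference", {
  amp <- toy_amplicon(toy_target)
  m <- toy_mates(toy_target, amp)
  assigned <- toy_assigned(m$r1, m$r2, frequency = 5L)
  cols <- pileup_amplicon(assigned, amp)
  expect_true(all(cols$depth >= 5L))
  expect_true(all(cols$p_ref == 1))
  # conservation: depth equals the frequency mass of covering alignments
  alns <- align_assigned(assigned, amp)
  for (p in c(1L, 20L, 40L)) {
    covering <- alns$snp_ok & alns$t_start <= p & alns$t_end >= p
    expect_equal(cols$depth[p], sum(alns$frequency[covering]))
  }
})

test_that("alignments failing the k rule contribute nothing to the pileup", {
  amp <- toy_amplicon(toy_target)
  hap <- toy_target
  for (p in c(5L, 15L, 25L, 35L)) {   # four substitutions: k = 4 > 2
    old <- substr(hap, p, p)
    substr(hap, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  m <- toy_mates(hap, amp)
  cols <- pileup_amplicon(toy_assigned(m$r1, m$r2, 8L), amp)
  expect_true(all(cols$depth == 0L))
})

test_that("the 90% reference-fraction rule forces and forbids SNP calls", {
  amp <- toy_amplicon(toy_target)
  amp$target_seq <- paste0("A", substring(toy_target, 2))
  # P(ref) = 100%: no call
  expect_equal(nrow(call_snps(make_columns("A", list(A = 100)), amp)), 0L)
  # P(ref) = 85% < 90%: SNP with the alternate base and its fraction
  out <- call_snps(make_columns("A", list(A = 85, G = 15)), amp)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "G")
  expect_equal(out$alt_fraction, 0.15)
  expect_equal(out$kind, "SNP")
  # P(ref) = 92% and the exact 90% boundary: conservative, no call
  expect_equal(nrow(call_snps(make_columns("A", list(A = 92, G = 8)), amp)), 0L)
  expect_equal(nrow(call_snps(make_columns("A", list(A = 90, G = 10)), amp)), 0L)
  # below min_depth nothing is called regardless of fraction
  expect_equal(nrow(call_snps(make_columns("A", list(A = 4, G = 4)), amp)), 0L)
  # N-only depletion yields no alternate evidence, hence no call
  expect_equal(nrow(call_snps(make_columns("A", list(A = 80, N = 20)), amp)), 0L)
  # alternate ties break alphabetically
  tie <- call_snps(make_columns("A", list(A = 70, C = 15, G = 15)), amp)
  expect_equal(tie$alt, "C")
})

test_that("a deleted block is called as one left-anchored DEL record", {
  amp <- toy_amplicon(toy_target)
  # delete ATG at positions 6-8; flanks differ, so no left shift applies
  hap <- paste0(substr(toy_target, 1, 5), substring(toy_target, 9))
  m <- toy_mates(hap, amp)
  calls <- call_variants(toy_assigned(m$r1, m$r2, 20L), amp)
  dels <- calls[calls$kind == "DEL", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$position, 5L)          # anchor base before the block
  expect_equal(dels$ref, "CATG")           # anchor + 3 deleted bases
  expect_equal(dels$alt, "C")
  expect_equal(dels$alt_fraction, 1)
})

test_that("an inserted block is called as one left-anchored INS record", {
  amp <- toy_amplicon(toy_target)
  # insert TTAG after position 10 (an A, so no left shift applies)
  hap <- paste0(substr(toy_target, 1, 10), "TTAG", substring(toy_target, 11))
  m <- toy_mates(hap, amp)
  calls <- call_variants(toy_assigned(m$r1, m$r2, 20L), amp)
  ins <- calls[calls$kind == "INS", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$position, 10L)
  expect_equal(ins$ref, "A")
  expect_equal(ins$alt, "ATTAG")
})

test_that("indels in homopolymers are shifted to their leftmost placement", {
  target <- "ACGTAAAAAACGTTGCAGGTCCATGGTACCAGTTAGCAAC"  # A-run at 5..10
  amp <- toy_amplicon(target)
  # delete three A's from the right end of the run (positions 8-10)
  hap <- paste0(substr(target, 1, 7), substring(target, 11))
  m <- toy_mates(hap, amp)
  calls <- call_variants(toy_assigned(m$r1, m$r2, 20L), amp)
  dels <- calls[calls$kind == "DEL", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$position, 4L)          # anchored before the A-run
  expect_equal(dels$ref, "TAAA")
  expect_equal(dels$alt, "T")
})

test_that("a read identical to the target yields no variant records", {
  amp <- toy_amplicon(toy_target)
  m <- toy_mates(toy_target, amp)
  calls <- call_variants(toy_assigned(m$r1, m$r2, 30L), amp)
  expect_equal(nrow(calls), 0L)
})

test_that("a 5 bp insertion yields one INS record and no SNP calls", {
  amp <- toy_amplicon(toy_target)
  hap <- paste0(substr(toy_target, 1, 20), "TTTTT", substring(toy_target, 21))
  m <- toy_mates(hap, amp)
  assigned <- toy_assigned(m$r1, m$r2, 15L)
  alns <- align_assigned(assigned, amp)
  # the read is longer than the target, so the target (the shorter side)
  # is fully matched across the gap: k = 0 and the insertion is carried
  fwd <- alns[alns$orientation == "fwd", ]
  expect_equal(fwd$k, 0L)
  expect_equal(fwd$inserted_len, 5L)
  expect_true(fwd$indel_ok)
  calls <- call_variants(assigned, amp)
  ins <- calls[calls$kind == "INS", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$position, 20L)
  expect_equal(ins$alt, "ATTTTT")
  expect_equal(sum(calls$kind == "SNP"), 0L)
})

test_that("indel support below min_depth is not reported", {
  amp <- toy_amplicon(toy_target)
  hap <- paste0(substr(toy_target, 1, 5), substring(toy_target, 9))
  m <- toy_mates(hap, amp)
  calls <- call_variants(toy_assigned(m$r1, m$r2, 4L), amp)  # support 4 < 10
  expect_equal(nrow(calls[calls$kind == "DEL", ]), 0L)
})
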