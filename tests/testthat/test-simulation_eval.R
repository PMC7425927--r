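test_that("the simulator is deterministic given panel, truth and seed", {
  panel <- sim_panel(n_amplicons = 4, seed = 5)
  truth <- sim_truth(panel, n_snps = 4, n_indels = 2, seed = 5)
  a <- sim_reads(panel, truth, depth = 20, seed = 99)
  b <- sim_reads(panel, truth, depth = 20, seed = 99)
  expect_identical(a$r1_seq, b$r1_seq)
  expect_identical(a$r2_seq, b$r2_seq)
  d <- withr::local_tempdir()
  write_fastq_pair(a, file.path(d, "a1.fq"), file.path(d, "a2.fq"))
  write_fastq_pair(b, file.path(d, "b1.fq"), file.path(d, "b2.fq"))
  expect_identical(readLines(file.path(d, "a1.fq")),
                   readLines(file.path(d, "b1.fq")))
})

test_that("a variant-free error-free amplicon collapses to one sequence", {
  panel <- sim_panel(n_amplicons = 1, seed = 8)
  pairs <- sim_reads(panel, depth = 10, seed = 8)
  expect_equal(nrow(pairs), 10L)
  collapsed <- collapse_pairs(pairs)
  expect_equal(nrow(collapsed), 1L)
  expect_equal(collapsed$frequency, 10L)
})

test_that("error-free reads keep their primer intact and fully assignable", {
  panel <- sim_panel(n_amplicons = 6, seed = 14)
  truth <- sim_truth(panel, n_snps = 6, n_indels = 3, seed = 14)
  pairs <- sim_reads(panel, truth, depth = 30, seed = 14)
  trimmed <- clean_index(pairs, unique(panel$index))
  out <- assign_reads(collapse_pairs(trimmed), select_positions(panel))
  expect_true(all(!is.na(out$amplicon_id)))
})

test_that("allele-carrying read counts are binomial-like and reproducible", {
  panel <- sim_panel(n_amplicons = 1, target_len = c(170, 170), seed = 2)
  target <- panel$target_seq[1]
  truth <- tibble::tibble(
    amplicon_id = panel$amplicon_id[1], position = 60L, kind = "SNP",
    ref = substr(target, 60, 60),
    allele = setdiff(c("A", "C", "G", "T"), substr(target, 60, 60))[1],
    allele_fraction = 0.5
  )
  count_alt <- function(seed) {
    pairs <- sim_reads(panel, truth, depth = 100, seed = seed)
    # the spiked base sits in R2 at offset index + fwd + 60
    off <- nchar(panel$index[1]) + nchar(panel$fwd_primer[1]) + 60L
    sum(substr(pairs$r2_seq, off, off) == truth$allele)
  }
  n1 <- count_alt(123)
  expect_identical(n1, count_alt(123))            # reproducible
  expect_gt(n1, qbinom(0.0005, 100, 0.5))         # plausibly Binomial(100, .5)
  expect_lt(n1, qbinom(0.9995, 100, 0.5))
})

test_that("variants outside the target are refused", {
  panel <- sim_panel(n_amplicons = 1, seed = 4)
  truth <- tibble::tibble(
    amplicon_id = panel$amplicon_id[1],
    position = nchar(panel$target_seq[1]) + 5L,
    kind = "SNP", ref = "A", allele = "C", allele_fraction = 1
  )
  expect_error(sim_reads(panel, truth, depth = 5, seed = 1),
               "outside its target")
})

test_that("homozygous spiked SNPs are recovered exactly end to end", {
  panel <- sim_panel(n_amplicons = 4, seed = 33)
  truth <- sim_truth(panel, n_snps = 5, n_indels = 0,
                     allele_fraction = 1, seed = 33)
  pairs <- sim_reads(panel, truth, depth = 30, seed = 33)
  res <- call_pipeline(pairs, panel)
  calls <- tidy(res)
  expect_equal(nrow(calls), 5L)
  expect_true(all(calls$kind == "SNP"))
  expect_equal(
    dplyr::arrange(calls[, c("amplicon_id", "position", "alt")],
                   amplicon_id, position),
    dplyr::arrange(
      tibble::tibble(amplicon_id = truth$amplicon_id,
                     position = truth$position, alt = truth$allele),
      amplicon_id, position))
  expect_true(all(calls$alt_fraction == 1))
})

test_that("the metric formulas follow their definitions", {
  expect_equal(recall(list(TP = 9, FN = 1)), 0.9)
  expect_true(is.na(recall(list(TP = 0, FN = 0))))
  m <- tpr_fpr_accuracy(list(TP = 95, FN = 5, FP = 0, TN = 100))
  expect_equal(m$TPR, 0.95)
  expect_equal(m$FPR, 0)
  expect_equal(m$accuracy, 0.975)
  m0 <- tpr_fpr_accuracy(list(TP = 0, FN = 0, FP = 0, TN = 0))
  expect_true(all(is.na(c(m0$TPR, m0$FPR, m0$accuracy))))
  # identities: TPR equals recall; accuracy is 1 when FP = FN = 0
  cc <- list(TP = 7, FN = 3, FP = 2, TN = 88)
  expect_equal(tpr_fpr_accuracy(cc)$TPR, recall(cc))
  perfect <- list(TP = 10, FN = 0, FP = 0, TN = 90)
  expect_equal(tpr_fpr_accuracy(perfect)$accuracy, 1)
})

test_that("confusion counts agree with an independent brute-force matcher", {
  panel <- sim_panel(n_amplicons = 8, seed = 55)
  truth <- sim_truth(panel, n_snps = 10, n_indels = 6, seed = 55)
  pairs <- sim_reads(panel, truth, depth = 40, seed = 55)
  calls <- tidy(call_pipeline(pairs, panel))
  got <- confusion_counts(calls, truth, panel)

  # oracle: expand both sides into every left-shift-equivalent placement
  # and match greedily
  placements <- function(kind, pos, allele, target) {
    keys <- character()
    repeat {
      keys <- c(keys, paste(kind, pos, allele))
      tc <- strsplit(target, "")[[1]]
      len <- nchar(allele)
      if (kind == "DEL" && pos > 1 && tc[pos - 1] == tc[pos + len - 1]) {
        pos <- pos - 1
        allele <- paste(tc[pos:(pos + len - 1)], collapse = "")
      } else if (kind == "INS" && pos >= 1 &&
                 tc[pos] == substr(allele, len, len)) {
        allele <- paste0(tc[pos], substr(allele, 1, len - 1))
        pos <- pos - 1
      } else break
    }
    keys
  }
  truth_sets <- lapply(seq_len(nrow(truth)), function(r) {
    tg <- panel$target_seq[match(truth$amplicon_id[r], panel$amplicon_id)]
    paste(truth$amplicon_id[r],
          placements(truth$kind[r], truth$position[r], truth$allele[r], tg))
  })
  call_events <- lapply(seq_len(nrow(calls)), function(r) {
    tg <- panel$target_seq[match(calls$amplicon_id[r], panel$amplicon_id)]
    kind <- calls$kind[r]
    if (kind == "SNP") {
      ev <- list(pos = calls$position[r], allele = calls$alt[r])
    } else if (kind == "DEL") {
      ev <- list(pos = calls$position[r] + 1,
                 allele = substring(calls$ref[r], 2))
    } else {
      ev <- list(pos = calls$position[r], allele = substring(calls$alt[r], 2))
    }
    paste(calls$amplicon_id[r], placements(kind, ev$pos, ev$allele, tg))
  })
  tp <- sum(vapply(truth_sets, function(ts) {
    any(vapply(call_events, function(cs) any(cs %in% ts), logical(1)))
  }, logical(1)))
  fp <- sum(vapply(call_events, function(cs) {
    !any(vapply(truth_sets, function(ts) any(cs %in% ts), logical(1)))
  }, logical(1)))
  expect_equal(got$TP, tp)
  expect_equal(got$FP, fp)
  expect_equal(got$FN, nrow(truth) - tp)
})

test_that("capture-failure pairs are generated and cleaned away", {
  panel <- sim_panel(n_amplicons = 3, seed = 6)
  pairs <- sim_reads(panel, depth = 20, capture_fail_rate = 0.1, seed = 6)
  expect_equal(nrow(pairs), 66L)   # 60 genuine + 6 failures
  out <- clean_public(pairs, public_seq(panel))
  expect_equal(cleaning_report(out)$dropped_public, 6L)
  expect_equal(nrow(out), 60L)
})
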