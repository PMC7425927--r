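# File formats and core record types: FASTQ pairs, the amplicon panel TSV,
# and minimal VCF 4.2 output.

#' Read a pair of FASTQ files into a read-pair tibble
#'
#' Reads two FASTQ files (R1/R2 of a paired-end run) and pairs records by
#' file order. Mate-id suffixes (`/1`, `/2`) and space-separated tags are
#' stripped from the stored `read_id`, but pairing never relies on id
#' parsing. Sequences are uppercased.
#'
#' @param path_r1,path_r2 Paths to the R1 and R2 FASTQ files.
#' @return A tibble with columns `read_id`, `r1_seq`, `r2_seq`, `r1_qual`,
#'   `r2_qual` (qualities are `NA` when a file carries placeholder
#'   qualities is not detectable; they are kept verbatim otherwise).
#' @seealso [write_fastq_pair()]
#' @export
read_fastq_pair <- function(path_r1, path_r2) {
  for (p in c(path_r1, path_r2)) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
  }
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("pairing error: %d records in R1 but %d in R2",
                 nrow(r1), nrow(r2)), call. = FALSE)
  }
  tibble::tibble(
    read_id = strip_mate_tag(r1$id),
    r1_seq = toupper(r1$seq), r2_seq = toupper(r2$seq),
    r1_qual = r1$qual, r2_qual = r2$qual
  )
}

# one FASTQ file -> tibble(id, seq, qual); strict 4-line records
read_fastq_one <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines (not a multiple of 4)",
                 path, n), call. = FALSE)
  }
  idx <- seq_len(n %/% 4L)
  hdr <- lines[4L * idx - 3L]
  seq <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop(sprintf("malformed FASTQ '%s': line %d does not start with '@'",
                 path, 4L * bad_hdr[1L] - 3L), call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop(sprintf("malformed FASTQ '%s': line %d does not start with '+'",
                 path, 4L * bad_plus[1L] - 1L), call. = FALSE)
  }
  bad_len <- which(nchar(qual) != nchar(seq))
  if (length(bad_len)) {
    stop(sprintf(
      "malformed FASTQ '%s': quality length differs from sequence at line %d",
      path, 4L * bad_len[1L]), call. = FALSE)
  }
  tibble::tibble(id = sub("^@", "", hdr), seq = seq, qual = qual)
}

strip_mate_tag <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

#' Write a read-pair tibble as two FASTQ files
#'
#' Inverse of [read_fastq_pair()]. Pairs lacking qualities are written with
#' a constant `"I"` quality string (error-free simulated data).
#'
#' @param pairs Read-pair tibble (`read_id`, `r1_seq`, `r2_seq`, optionally
#'   `r1_qual`, `r2_qual`).
#' @param path_r1,path_r2 Output paths.
#' @return `pairs`, invisibly.
#' @export
write_fastq_pair <- function(pairs, path_r1, path_r2) {
  stopifnot(all(c("read_id", "r1_seq", "r2_seq") %in% names(pairs)))
  q1 <- if ("r1_qual" %in% names(pairs)) pairs$r1_qual else NA_character_
  q2 <- if ("r2_qual" %in% names(pairs)) pairs$r2_qual else NA_character_
  write_fastq_one(pairs$read_id, "/1", pairs$r1_seq, q1, path_r1)
  write_fastq_one(pairs$read_id, "/2", pairs$r2_seq, q2, path_r2)
  invisible(pairs)
}

write_fastq_one <- function(id, mate, seq, qual, path) {
  qual <- ifelse(is.na(qual), strrep("I", nchar(seq)), qual)
  out <- character(4L * length(seq))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", id, mate)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(out, path)
}

# Amplicon panel -------------------------------------------------------------

#' Construct and validate an amplicon panel
#'
#' An amplicon panel is a tibble with one row per amplicon (columns
#' `amplicon_id`, `fwd_primer`, `rev_primer`, `index`, `target_seq`) and the
#' panel-wide public (capture/adapter) sequence attached as the
#' `public_seq` attribute. Forward primers must be pairwise distinct —
#' otherwise no discriminating position set can exist — and ids unique.
#' Targets of 200 bp or more draw a warning (amplicon designs keep the exon
#' region under 200 bp so that 150 bp mates overlap), but are not rejected.
#'
#' @param amplicons Data frame with the five columns above.
#' @param public_seq Single DNA string shared across the panel.
#' @return A validated `amplicon_panel` tibble.
#' @export
amplicon_panel <- function(amplicons, public_seq) {
  amplicons <- tibble::as_tibble(amplicons)
  need <- c("amplicon_id", "fwd_primer", "rev_primer", "index", "target_seq")
  missing <- setdiff(need, names(amplicons))
  if (length(missing)) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(amplicons) == 0L) stop("panel has no amplicons", call. = FALSE)
  if (anyDuplicated(amplicons$amplicon_id)) {
    stop("duplicate amplicon_id in panel", call. = FALSE)
  }
  if (anyDuplicated(amplicons$fwd_primer)) {
    stop("duplicate forward primers: discriminating positions cannot exist",
         call. = FALSE)
  }
  for (col in c("fwd_primer", "rev_primer", "index", "target_seq")) {
    assert_dna(toupper(amplicons[[col]]), col)
    amplicons[[col]] <- toupper(amplicons[[col]])
  }
  stopifnot(is.character(public_seq), length(public_seq) == 1L,
            nchar(public_seq) >= 1L)
  assert_dna(toupper(public_seq), "public_seq")
  if (any(nchar(amplicons$target_seq) == 0L)) {
    stop("empty target_seq in panel", call. = FALSE)
  }
  if (any(nchar(amplicons$fwd_primer) == 0L)) {
    stop("empty fwd_primer in panel", call. = FALSE)
  }
  long <- nchar(amplicons$target_seq) >= 200L
  if (any(long)) {
    warning(sum(long), " target(s) are 200 bp or longer; mates may not span",
            call. = FALSE)
  }
  structure(amplicons,
            public_seq = toupper(public_seq),
            class = c("amplicon_panel", class(amplicons)))
}

#' Public sequence of a panel
#' @param panel An `amplicon_panel`.
#' @return The panel's public (adapter/capture) sequence.
#' @export
public_seq <- function(panel) attr(panel, "public_seq")

#' Load an amplicon panel from TSV
#'
#' The panel format is a TSV with columns `amplicon_id`, `fwd_primer`,
#' `rev_primer`, `index`, `target_seq`, preceded by a pragma line
#' `#public_seq=<DNA>` carrying the panel-wide public sequence.
#'
#' @param path Path to the panel TSV.
#' @return A validated `amplicon_panel`.
#' @seealso [write_panel()], [amplicon_panel()]
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty panel file: ", path, call. = FALSE)
  pragma <- grep("^#public_seq=", lines, value = TRUE)
  if (length(pragma) != 1L) {
    stop("panel file must contain exactly one '#public_seq=' pragma line",
         call. = FALSE)
  }
  pub <- sub("^#public_seq=", "", pragma)
  body <- lines[!startsWith(lines, "#")]
  amplicons <- readr::read_tsv(I(paste(body, collapse = "\n")),
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  amplicon_panel(amplicons, pub)
}

#' Write an amplicon panel to TSV
#' @param panel An `amplicon_panel`.
#' @param path Output path.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#public_seq=", public_seq(panel)), con)
  utils::write.table(as.data.frame(panel), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(panel)
}

# Variant records and VCF ----------------------------------------------------

#' An empty variant-record tibble
#'
#' Variant records are tibbles with one row per call: `amplicon_id`,
#' 1-based `position` within the amplicon target, `ref` and `alt` allele
#' strings (indels left-anchored with one shared base, VCF convention),
#' `kind` (`"SNP"`, `"INS"` or `"DEL"`), `alt_fraction` and `depth`.
#'
#' @return A zero-row variant tibble with the canonical columns.
#' @export
variant_tibble <- function() {
  tibble::tibble(
    amplicon_id = character(), position = integer(),
    ref = character(), alt = character(), kind = character(),
    alt_fraction = double(), depth = integer()
  )
}

validate_variants <- function(calls) {
  calls <- tibble::as_tibble(calls)
  need <- names(variant_tibble())
  missing <- setdiff(need, names(calls))
  if (length(missing)) {
    stop("variant table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(calls$ref == calls$alt)) stop("alt equals ref", call. = FALSE)
  if (any(!calls$kind %in% c("SNP", "INS", "DEL"))) {
    stop("kind must be SNP, INS or DEL", call. = FALSE)
  }
  calls
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' `CHROM` is the amplicon id, `POS` the 1-based position within the
#' amplicon target, and `INFO` carries `DP` (depth) and `AF` (alt allele
#' fraction). Indel records are expected already left-anchored (shared
#' leading base), as produced by the caller.
#'
#' @param calls Variant tibble (see [variant_tibble()]).
#' @param path Output path.
#' @param contigs Optional tibble (`amplicon_id`, `length`) written as
#'   `##contig` header lines; defaults to the amplicons present in `calls`.
#' @return `calls`, invisibly.
#' @seealso [read_variants()]
#' @export
write_variants <- function(calls, path, contigs = NULL) {
  calls <- validate_variants(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=amplicall",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth at site">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
    '##INFO=<ID=KIND,Number=1,Type=String,Description="SNP, INS or DEL">'
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$amplicon_id, as.integer(contigs$length)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  body <- if (nrow(calls)) {
    calls <- dplyr::arrange(calls, .data$amplicon_id, .data$position)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s;KIND=%s",
            calls$amplicon_id, as.integer(calls$position), calls$ref,
            calls$alt, as.integer(calls$depth),
            format(calls$alt_fraction, trim = TRUE, digits = 6),
            calls$kind)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(calls)
}

#' Read an amplicall VCF back into a variant tibble
#'
#' Field-level inverse of [write_variants()] for files this package wrote.
#'
#' @param path Path to a VCF written by [write_variants()].
#' @return A variant tibble.
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(variant_tibble())
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    sub(paste0("^;?", key, "="), "", m)
  }
  tibble::tibble(
    amplicon_id = vapply(f, `[[`, "", 1L),
    position = as.integer(vapply(f, `[[`, "", 2L)),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    kind = get_info("KIND"),
    alt_fraction = as.double(get_info("AF")),
    depth = as.integer(get_info("DP"))
  )
}
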