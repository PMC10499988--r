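#' Read a paired FASTQ run into a read-pair tibble
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files (optionally
#'   gzip-compressed).
#' @return Tibble with columns `id`, `fwd_seq`, `rev_seq`, `fwd_qual`,
#'   `rev_qual` (qualities as Phred+33 strings).
#' @export
read_fastq_pair <- function(r1, r2) {
  f <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(f) != length(r)) {
    stop("R1 and R2 have different numbers of reads", call. = FALSE)
  }
  tibble::tibble(
    id = if (is.null(names(f))) as.character(seq_along(f)) else names(f),
    fwd_seq = as.character(f),
    rev_seq = as.character(r),
    fwd_qual = as.character(S4Vectors::mcols(f)$qualities),
    rev_qual = as.character(S4Vectors::mcols(r)$qualities)
  )
}

#' Per-base quality filter
#'
#' A read pair fails when any base of either mate has Phred quality below
#' `min_q`. Both mates lie entirely within the sequenced construct (barcode,
#' constant regions, variable region), so the whole read is interrogated.
#'
#' @param fwd_qual,rev_qual Phred+33 quality strings.
#' @param min_q Minimum acceptable per-base Phred score; `min_q <= 0` passes
#'   everything.
#' @return Logical vector, `TRUE` where the pair passes.
#' @export
quality_filter <- function(fwd_qual, rev_qual, min_q = 20L) {
  if (min_q <= 0L) return(rep(TRUE, length(fwd_qual)))
  # any character below chr(33 + min_q) is a base with Phred < min_q
  pat <- sprintf("[\\x01-\\x%02x]", 33L + as.integer(min_q) - 1L)
  !(grepl(pat, fwd_qual, perl = TRUE) | grepl(pat, rev_qual, perl = TRUE))
}

#' Exact barcode demultiplexing
#'
#' Matches the leading `barcode_length` bases of the forward read exactly
#' against the barcode map; a single substitution in the barcode leaves the
#' read unassigned (priming regions, not barcodes, get the one-substitution
#' tolerance).
#'
#' @param fwd_seq Character vector of forward-read sequences.
#' @param barcodes Named character vector (experiment -> barcode), all the
#'   same length and mutually distinct.
#' @return Character vector of experiment names, `"UNASSIGNED"` where no
#'   barcode matches.
#' @export
demultiplex <- function(fwd_seq, barcodes) {
  if (length(barcodes) == 0L) stop("empty barcode map", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in map", call. = FALSE)
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) stop("barcodes must all have the same length",
                             call. = FALSE)
  hit <- match(substr(fwd_seq, 1L, bl), barcodes)
  ifelse(is.na(hit), "UNASSIGNED", names(barcodes)[hit])
}

# Hamming distance of equal-length windows of `seqs` against one reference
# string, vectorised over seqs. Windows start at `offset` (1-based). Windows
# running past the end of a read count every missing position as a mismatch.
hamming_to_ref <- function(seqs, ref, offset = 1L) {
  l <- nchar(ref)
  d <- integer(length(seqs))
  for (i in seq_len(l)) {
    p <- offset + i - 1L
    d <- d + (substr(seqs, p, p) != substr(ref, i, i))
  }
  d
}

#' Match a constant (priming) region at a fixed offset
#'
#' Hamming comparison of `seq[offset .. offset+|expected|-1]` against
#' `expected`; a match tolerates at most `max_sub` substitutions. There is no
#' indel search: offsets are fully determined by the design lengths.
#'
#' @param seq Character vector of read sequences.
#' @param expected The expected constant-region DNA.
#' @param offset 1-based start of the window within `seq`.
#' @param max_sub Maximum substitutions tolerated (default 1).
#' @return Tibble with `match` (logical) and `substitutions` (integer;
#'   windows truncated by the read end count missing bases as mismatches).
#' @export
match_constant_region <- function(seq, expected, offset = 1L, max_sub = 1L) {
  d <- hamming_to_ref(seq, expected, offset)
  tibble::tibble(match = d <= max_sub, substitutions = d)
}

#' Merge a read pair and extract the variable-region insert
#'
#' The reverse mate is reverse-complemented, the variable-region windows of
#' the two mates are compared base by base, and any disagreement fails the
#' pair (`NA` in the output): the zero-mismatch forward-reverse agreement
#' rule. Windows are located from the design lengths: on the forward read the
#' insert follows the barcode and 5' constant region; on the
#' reverse-complemented reverse mate it precedes the 3' constant region,
#' which ends at the construct's (and hence the read's) last base.
#'
#' @param fwd_seq,rev_seq Character vectors of mate sequences.
#' @param design A [library_design()].
#' @param n Ring size giving the insert length (scalar or vector).
#' @return Character vector of inserts, `NA` where the mates disagree.
#' @export
merge_pair_extract <- function(fwd_seq, rev_seq, design, n) {
  var_len <- 3L * (as.integer(n) + 4L)
  f_start <- design$barcode_length + nchar(design$constant_5p) + 1L
  fwd_win <- substr(fwd_seq, f_start, f_start + var_len - 1L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev_seq)))
  r_end <- nchar(rc) - nchar(design$constant_3p)
  rev_win <- substr(rc, r_end - var_len + 1L, r_end)
  ifelse(nchar(fwd_win) == var_len & fwd_win == rev_win, fwd_win,
         NA_character_)
}

#' Deconvolve a paired-end run into a peptide count table
#'
#' Composition of the whole read-processing chain, in order: per-base quality
#' filter, exact barcode demultiplexing, 5' priming-region match on the
#' forward read (at most one substitution), architecture resolution plus 3'
#' priming-region match on both mates (at most one substitution each),
#' zero-mismatch forward-reverse agreement over the variable region,
#' translation, and architecture classification. Stop-codon inserts are
#' discarded (`FAIL_STOP`); off-design peptides are kept and flagged, since
#' deletion-derived ring sizes outside the designed architecture are real
#' and have yielded hits. Every input read lands in exactly one audit cell,
#' so audit totals conserve the input read count.
#'
#' @param r1,r2 FASTQ paths, or a read tibble from [read_fastq_pair()] as
#'   `r1` with `r2 = NULL`.
#' @param design A [library_design()].
#' @param barcodes Named character vector (experiment -> barcode).
#' @param min_q Per-base Phred threshold for the quality filter (default 20).
#' @param keep_records Return the per-read `ProcessedRecord` tibble as well.
#' @return A `count_table` (see [count_table()]); when `keep_records = TRUE`,
#'   its `records` element holds one row per read with `id`, `experiment`,
#'   `status`, `dna_insert`, `peptide`, `architecture_class`.
#' @export
process_run <- function(r1, r2 = NULL, design, barcodes, min_q = 20L,
                        keep_records = FALSE) {
  reads <- if (is.data.frame(r1)) r1 else read_fastq_pair(r1, r2)
  n_in <- nrow(reads)
  status <- rep(NA_character_, n_in)
  experiment <- demultiplex(reads$fwd_seq, barcodes)
  insert <- rep(NA_character_, n_in)
  peptide <- rep(NA_character_, n_in)
  arch <- rep(NA_character_, n_in)

  ok_q <- quality_filter(reads$fwd_qual, reads$rev_qual, min_q)
  status[!ok_q] <- "FAIL_QUALITY"
  live <- is.na(status)

  status[live & experiment == "UNASSIGNED"] <- "FAIL_BARCODE"
  live <- is.na(status)

  bl <- design$barcode_length
  c5 <- design$constant_5p
  c3 <- design$constant_3p

  if (any(live)) {
    m5 <- match_constant_region(reads$fwd_seq[live], c5, offset = bl + 1L)
    idx <- which(live)[!m5$match]
    status[idx] <- "FAIL_PRIMER_F"
    live <- is.na(status)
  }

  # Resolve the ring size per read from the forward read: the visible prefix
  # of the 3' constant region must match (<= 1 substitution) at the offset
  # implied by each candidate n; the candidate with the fewest substitutions
  # wins, smaller n on ties.
  n_of <- rep(NA_integer_, n_in)
  if (any(live)) {
    li <- which(live)
    fwd <- reads$fwd_seq[li]
    rl <- nchar(fwd)
    best_d <- rep(Inf, length(li))
    for (k in design$cycle_sizes) {
      var_len <- 3L * (k + 4L)
      off <- bl + nchar(c5) + var_len + 1L
      vis <- min(nchar(c3), max(rl) - off + 1L)
      if (vis < 1L) next
      d <- hamming_to_ref(fwd, substr(c3, 1L, vis), offset = off)
      upd <- d <= 1L & d < best_d
      best_d[upd] <- d[upd]
      n_of[li[upd]] <- k
    }
    status[li[is.infinite(best_d)]] <- "FAIL_PRIMER_F"
    live <- is.na(status)
  }

  # 3' priming region on the reverse mate: full-length match at the end of
  # the reverse-complemented read (<= 1 substitution).
  if (any(live)) {
    li <- which(live)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$rev_seq[li])))
    off <- nchar(rc) - nchar(c3) + 1L
    d <- integer(length(li))
    for (i in seq_len(nchar(c3))) {
      p <- off + i - 1L
      d <- d + (substr(rc, p, p) != substr(c3, i, i))
    }
    status[li[d > 1L]] <- "FAIL_PRIMER_R"
    live <- is.na(status)

    if (any(live)) {
      l2 <- which(live)
      sel <- match(l2, li)
      var_len <- 3L * (n_of[l2] + 4L)
      f_start <- bl + nchar(c5) + 1L
      fwd_win <- substr(reads$fwd_seq[l2], f_start, f_start + var_len - 1L)
      r_end <- nchar(rc[sel]) - nchar(c3)
      rev_win <- substr(rc[sel], r_end - var_len + 1L, r_end)
      agree <- nchar(fwd_win) == var_len & fwd_win == rev_win
      status[l2[!agree]] <- "FAIL_FR_MISMATCH"
      insert[l2[agree]] <- fwd_win[agree]
      live <- is.na(status)
    }
  }

  # Translate unique inserts only; reads with uncalled (non-ACGT) bases in
  # the insert are low-quality by definition.
  if (any(live)) {
    li <- which(live)
    ins <- insert[li]
    bad <- grepl("[^ACGT]", ins)
    status[li[bad]] <- "FAIL_QUALITY"
    li <- li[!bad]; ins <- ins[!bad]
    if (length(li)) {
      u <- unique(ins)
      tr <- translate_variable_region(u, design)
      m <- match(ins, u)
      peptide[li] <- tr$peptide[m]
      arch[li] <- tr$architecture_class[m]
      stop_hit <- tr$contains_stop[m]
      status[li[stop_hit]] <- "FAIL_STOP"
      li <- li[!stop_hit]
      status[li] <- ifelse(arch[li] == "off_design", "OFF_DESIGN_KEPT", "OK")
    }
  }

  records <- tibble::tibble(
    id = reads$id, experiment = experiment, status = status,
    dna_insert = insert, peptide = peptide, architecture_class = arch
  )
  ct <- count_table_from_records(records, names(barcodes), n_in)
  if (keep_records) ct$records <- records
  ct
}

# Build the count_table object from per-read processed records.
count_table_from_records <- function(records, experiments, n_input) {
  kept <- dplyr::filter(records, .data$status %in% c("OK", "OFF_DESIGN_KEPT"))
  counts_long <- kept |>
    dplyr::count(.data$peptide, .data$experiment, name = "count")
  meta <- kept |>
    dplyr::count(.data$peptide, .data$dna_insert, .data$architecture_class) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(peptide = "peptide", dna = "dna_insert",
                  architecture = "architecture_class")
  wide <- counts_long |>
    tidyr::pivot_wider(names_from = "experiment", values_from = "count",
                       values_fill = 0L)
  for (e in setdiff(experiments, names(wide))) wide[[e]] <- 0L
  counts <- dplyr::left_join(meta, wide, by = "peptide") |>
    dplyr::arrange(.data$peptide)
  audit <- records |>
    dplyr::count(.data$experiment, .data$status, name = "reads")
  count_table(counts, experiments = experiments, audit = audit,
              n_input = n_input)
}

#' Construct a peptide count table
#'
#' The central container between read processing and differential
#' enrichment: a wide tibble of per-peptide counts with one column per
#' experiment, plus per-experiment sequencing depth and a per-status read
#' audit. `depth` is recomputed from the counts, so the conservation
#' invariant `depth[e] = sum(counts[, e])` holds by construction.
#'
#' @param counts Tibble with columns `peptide` and one integer column per
#'   experiment; optional `dna` and `architecture` columns are preserved.
#' @param experiments Experiment (column) names; defaults to all non-metadata
#'   columns of `counts`.
#' @param audit Optional tibble (`experiment`, `status`, `reads`).
#' @param n_input Total raw reads that produced the table, if known.
#' @return An object of class `count_table` with elements `counts`, `depth`,
#'   `audit`, `n_input`.
#' @export
count_table <- function(counts, experiments = NULL, audit = NULL,
                        n_input = NA_integer_) {
  counts <- tibble::as_tibble(counts)
  meta_cols <- intersect(c("peptide", "dna", "architecture"), names(counts))
  if (is.null(experiments)) experiments <- setdiff(names(counts), meta_cols)
  stopifnot("peptide" %in% names(counts), length(experiments) > 0)
  for (e in experiments) {
    if (any(counts[[e]] < 0)) stop("negative counts", call. = FALSE)
  }
  depth <- vapply(experiments, function(e) sum(counts[[e]]), numeric(1))
  structure(list(counts = counts, experiments = experiments, depth = depth,
                 audit = audit, n_input = n_input),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " peptides x ",
      length(x$experiments), " experiments\n", sep = "")
  cat("  depth:", paste0(x$experiments, "=", x$depth, collapse = ", "), "\n")
  if (!is.na(x$n_input)) cat("  input reads:", x$n_input, "\n")
  print(utils::head(x$counts, 5))
  invisible(x)
}

#' Write / read a count table as TSV
#'
#' The TSV holds the wide counts tibble (`peptide`, `dna`, `architecture`,
#' one count column per experiment). This is also the documented entry point
#' for externally exported count tables (e.g. server exports of processed
#' selections): any TSV with a `peptide` column and per-experiment count
#' columns is accepted.
#'
#' @param ct A `count_table`.
#' @param path Output TSV path.
#' @return `write_count_table`: the path, invisibly. `read_count_table`: a
#'   `count_table`.
#' @export
write_count_table <- function(ct, path) {
  utils::write.table(ct$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param experiments Optional experiment column names; defaults to all
#'   columns other than `peptide`, `dna`, `architecture`.
#' @export
read_count_table <- function(path, experiments = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  count_table(df, experiments = experiments)
}
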