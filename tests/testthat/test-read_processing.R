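test_that("per-base quality filter is strict within the read and monotone in min_q", {
  q_hi <- strrep("F", 30)                     # Q37 everywhere
  q_low <- paste0(strrep("F", 10), "#", strrep("F", 19))  # one Q2 base
  expect_true(quality_filter(q_hi, q_hi, min_q = 20))
  expect_false(quality_filter(q_low, q_hi, min_q = 20))
  expect_false(quality_filter(q_hi, q_low, min_q = 20))
  expect_true(quality_filter(q_low, q_low, min_q = 0))
  expect_true(quality_filter(q_low, q_hi, min_q = 2))   # Q2 passes at min_q 2
  expect_false(quality_filter(q_low, q_hi, min_q = 3))

  # monotonicity: the pass set shrinks as min_q rises
  set.seed(1)
  quals <- vapply(1:200, function(i) {
    paste(intToUtf8(33 + sample(0:40, 20, replace = TRUE), multiple = TRUE),
          collapse = "")
  }, character(1))
  prev <- rep(TRUE, 200)
  for (q in c(0, 5, 10, 20, 30, 41)) {
    cur <- quality_filter(quals, quals, min_q = q)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("demultiplexing is exact-match only", {
  bc <- c(expA = "ACGTACGT", expB = "TTTTCCCC")
  expect_equal(demultiplex("ACGTACGTGGGG", bc), "expA")
  expect_equal(demultiplex("ACGTACGAGGGG", bc), "UNASSIGNED")  # 1 substitution
  expect_equal(demultiplex(c("TTTTCCCCAA", "GGGGGGGGAA"), bc),
               c("expB", "UNASSIGNED"))
  expect_error(demultiplex("ACGT", character()), "empty")
  expect_error(demultiplex("ACGT", c(a = "AC", b = "AC")), "duplicate")
})

test_that("constant-region matching tolerates at most one substitution at a fixed offset", {
  ref <- "ACGTACGTAC"
  seq_exact <- paste0("NN", ref, "TT")
  m <- match_constant_region(seq_exact, ref, offset = 3)
  expect_true(m$match); expect_equal(m$substitutions, 0L)

  seq_1sub <- paste0("NN", "ACGTACGTAG", "TT")
  m <- match_constant_region(seq_1sub, ref, offset = 3)
  expect_true(m$match); expect_equal(m$substitutions, 1L)

  seq_2sub <- paste0("NN", "TCGTACGTAG", "TT")
  m <- match_constant_region(seq_2sub, ref, offset = 3)
  expect_false(m$match); expect_equal(m$substitutions, 2L)

  # window running past the read end counts missing bases as mismatches
  m <- match_constant_region("NNACGTACG", ref, offset = 3)
  expect_false(m$match)
})

test_that("pair merging reverse-complements and enforces zero mismatches", {
  d <- tiny_design()
  dna <- reverse_translate("SICRFFC")
  pair <- make_pair(dna, "AAAA", d)
  expect_equal(merge_pair_extract(pair$fwd_seq, pair$rev_seq, d, n = 3), dna)

  # single-base disagreement planted on the reverse mate
  rev_bad <- pair$rev_seq
  substr(rev_bad, 15, 15) <- if (substr(rev_bad, 15, 15) == "A") "C" else "A"
  expect_true(is.na(merge_pair_extract(pair$fwd_seq, rev_bad, d, n = 3)))

  # the reverse mate only matches after reverse complementation
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pair$rev_seq)))
  expect_true(is.na(merge_pair_extract(pair$fwd_seq, rc, d, n = 3)))
})

test_that("process_run composes the stages with a faithful audit", {
  d <- tiny_design()
  good <- reverse_translate("SICRFFC")
  stop_dna <- paste0("TCT", "TAA", substr(good, 7, 21))  # stop at codon 2
  reads <- dplyr::bind_rows(
    make_pair(good, "AAAA", d, id = "ok1"),
    make_pair(good, "AAAA", d, id = "ok2"),
    make_pair(good, "CCCC", d, id = "ok3"),
    make_pair(stop_dna, "AAAA", d, id = "stop1"),
    make_pair(good, "TTTT", d, id = "badbc"),       # unregistered barcode
    make_pair(good, "AAAA", d, id = "lowq", qual_char = "#")
  )
  ct <- process_run(reads, design = d, barcodes = tiny_barcodes,
                    keep_records = TRUE)
  expect_equal(sum(ct$audit$reads), nrow(reads))
  expect_equal(ct$depth[["naive"]], 2)
  expect_equal(ct$depth[["target"]], 1)
  st <- ct$records$status
  names(st) <- ct$records$id
  expect_equal(unname(st[c("ok1", "stop1", "badbc", "lowq")]),
               c("OK", "FAIL_STOP", "FAIL_BARCODE", "FAIL_QUALITY"))
})

test_that("primer failures are detected on the correct mate", {
  d <- tiny_design()
  dna <- reverse_translate("SLCKREC")
  p <- make_pair(dna, "AAAA", d)

  two_sub_5p <- p
  substr(two_sub_5p$fwd_seq, 5, 6) <- "TT"   # constant_5p starts ACGTAC
  ct <- process_run(two_sub_5p, design = d, barcodes = tiny_barcodes,
                    keep_records = TRUE)
  expect_equal(ct$records$status, "FAIL_PRIMER_F")

  one_sub_5p <- p
  substr(one_sub_5p$fwd_seq, 5, 5) <- "T"
  ct <- process_run(one_sub_5p, design = d, barcodes = tiny_barcodes,
                    keep_records = TRUE)
  expect_equal(ct$records$status, "OK")      # one substitution tolerated

  two_sub_3p_rev <- p
  # constant_3p sits at the end of the reverse-complemented reverse mate,
  # i.e. at the start of the reverse mate: mutate its first two bases
  substr(two_sub_3p_rev$rev_seq, 1, 2) <- "TT"
  ct <- process_run(two_sub_3p_rev, design = d, barcodes = tiny_barcodes,
                    keep_records = TRUE)
  expect_equal(ct$records$status, "FAIL_PRIMER_R")
})

test_that("a run of stop-codon inserts yields zero depth, all FAIL_STOP", {
  d <- tiny_design()
  stop_dna <- paste0("TCT", "TAA", substr(reverse_translate("SICRFFC"), 7, 21))
  reads <- dplyr::bind_rows(lapply(1:20, function(i) {
    make_pair(stop_dna, "AAAA", d, id = paste0("r", i))
  }))
  ct <- process_run(reads, design = d, barcodes = tiny_barcodes)
  expect_equal(sum(ct$depth), 0)
  expect_equal(ct$audit$reads[ct$audit$status == "FAIL_STOP"], 20)
  expect_equal(nrow(ct$counts), 0)
})

test_that("off-design inserts are kept, flagged, and counted into depth", {
  d <- tiny_design()
  # mutate the fixed serine codon so the peptide starts with F: off-design
  off_dna <- paste0("TTT", substr(reverse_translate("SICRFFC"), 4, 21))
  reads <- dplyr::bind_rows(
    make_pair(off_dna, "AAAA", d, id = "off"),
    make_pair(reverse_translate("SICRFFC"), "AAAA", d, id = "ok")
  )
  ct <- process_run(reads, design = d, barcodes = tiny_barcodes,
                    keep_records = TRUE)
  expect_equal(ct$depth[["naive"]], 2)
  expect_setequal(ct$records$status, c("OFF_DESIGN_KEPT", "OK"))
  expect_equal(ct$counts$architecture[ct$counts$peptide == "FICRFFC"],
               "off_design")
})

test_that("read conservation holds across random noisy simulations", {
  d <- tiny_design()
  for (seed in 1:5) {
    cfg <- sim_config(n_variants = 30, reads_per_experiment = 400,
                      error_rate = 0.02, low_quality_fraction = 0.05,
                      read_length = 40, seed = seed, barcodes = tiny_barcodes)
    pop <- generate_naive_population(d, cfg)
    dir <- withr::local_tempdir()
    render_fastq_run(list(naive = pop, target = pop), d, cfg, dir)
    ct <- process_run(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"),
                      d, tiny_barcodes)
    expect_equal(sum(ct$audit$reads), 800)
    expect_equal(ct$n_input, 800)
    for (e in c("naive", "target")) {
      expect_equal(ct$depth[[e]], sum(ct$counts[[e]]))
    }
  }
})

test_that("substitution errors at 1e-3 keep at least 85% of reads OK", {
  d <- library_design()   # full-length constants: realistic ~100 nt span
  bcs <- c(naive = "ACGTACGT")
  cfg <- sim_config(n_variants = 100, reads_per_experiment = 10000,
                    error_rate = 0.001, seed = 17, barcodes = bcs)
  pop <- generate_naive_population(d, cfg)
  dir <- withr::local_tempdir()
  render_fastq_run(list(naive = pop), d, cfg, dir)
  ct <- process_run(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"),
                    d, bcs)
  expect_gte(sum(ct$depth) / 10000, 0.85)
})

test_that("process_run agrees with a brute-force per-read oracle", {
  d <- tiny_design()
  cfg <- sim_config(n_variants = 40, reads_per_experiment = 300,
                    error_rate = 0.03, read_length = 40, seed = 31,
                    barcodes = tiny_barcodes)
  pop <- generate_naive_population(d, cfg)
  dir <- withr::local_tempdir()
  render_fastq_run(list(naive = pop, target = pop), d, cfg, dir)
  reads <- read_fastq_pair(file.path(dir, "R1.fastq"),
                           file.path(dir, "R2.fastq"))

  # independent oracle: per-read loop over explicit character comparisons
  revcomp1 <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  oracle_status <- character(nrow(reads))
  oracle_pep <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    fwd <- reads$fwd_seq[i]; rev <- reads$rev_seq[i]
    bc <- substr(fwd, 1, 4)
    exp_name <- names(tiny_barcodes)[match(bc, tiny_barcodes)]
    if (is.na(exp_name)) { oracle_status[i] <- "FAIL_BARCODE"; next }
    if (ham(substr(fwd, 5, 10), d$constant_5p) > 1) {
      oracle_status[i] <- "FAIL_PRIMER_F"; next
    }
    vis3 <- substr(d$constant_3p, 1, nchar(fwd) - 4 - 6 - 21)
    if (ham(substr(fwd, 32, 31 + nchar(vis3)), vis3) > 1) {
      oracle_status[i] <- "FAIL_PRIMER_F"; next
    }
    rc <- revcomp1(rev)
    if (ham(substr(rc, nchar(rc) - 5, nchar(rc)), d$constant_3p) > 1) {
      oracle_status[i] <- "FAIL_PRIMER_R"; next
    }
    ins_f <- substr(fwd, 11, 31)
    ins_r <- substr(rc, nchar(rc) - 6 - 21 + 1, nchar(rc) - 6)
    if (ins_f != ins_r) { oracle_status[i] <- "FAIL_FR_MISMATCH"; next }
    pep <- translate_variable_region(ins_f)
    if (pep$contains_stop) { oracle_status[i] <- "FAIL_STOP"; next }
    cls <- classify_architecture(pep$peptide, d)
    oracle_status[i] <- if (cls == "off_design") "OFF_DESIGN_KEPT" else "OK"
    oracle_pep[i] <- pep$peptide
  }

  ct <- process_run(reads, design = d, barcodes = tiny_barcodes,
                    keep_records = TRUE)
  expect_identical(ct$records$status, oracle_status)
  kept <- oracle_status %in% c("OK", "OFF_DESIGN_KEPT")
  expect_identical(ct$records$peptide[kept], oracle_pep[kept])
})

test_that("count tables survive a TSV round trip", {
  counts <- tibble::tibble(peptide = c("SICRFFC", "SFCPMFC"),
                           dna = reverse_translate(c("SICRFFC", "SFCPMFC")),
                           architecture = c("n3", "n3"),
                           naive = c(10L, 20L), target = c(100L, 5L))
  ct <- count_table(counts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  ct2 <- read_count_table(path)
  expect_equal(ct2$counts$peptide, ct$counts$peptide)
  expect_equal(ct2$depth, ct$depth)
  expect_equal(ct2$experiments, c("naive", "target"))
})
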