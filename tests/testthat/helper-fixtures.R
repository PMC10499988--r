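# Shared fixtures: a down-scaled library design with short constant regions
# so unit-test reads stay small, plus read-pair builders used across files.

tiny_design <- function(cycle_sizes = 3L, alphabet = setdiff(AA_CANONICAL, "C")) {
  library_design(name = "tiny", cycle_sizes = cycle_sizes,
                 alphabet = alphabet,
                 constant_5p = "ACGTAC", constant_3p = "GGATCC",
                 barcode_length = 4L)
}

tiny_barcodes <- c(naive = "AAAA", target = "CCCC", control = "GGGG")

# Build one synthetic read pair for a given variable-region DNA insert,
# mirroring the construct layout barcode + 5' constant + insert + 3' constant.
make_pair <- function(dna, barcode, design, read_len = NULL, id = "r1",
                      qual_char = "F") {
  construct <- paste0(barcode, design$constant_5p, dna, design$constant_3p)
  if (is.null(read_len)) read_len <- nchar(construct)
  read_len <- min(read_len, nchar(construct))
  fwd <- substr(construct, 1L, read_len)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(construct, nchar(construct) - read_len + 1L, nchar(construct)))))
  tibble::tibble(id = id, fwd_seq = fwd, rev_seq = rev,
                 fwd_qual = strrep(qual_char, nchar(fwd)),
                 rev_qual = strrep(qual_char, nchar(rev)))
}

# Random in-design peptides for property tests.
random_peptides <- function(n, design, seed = 1) {
  withr::with_seed(seed, {
    k <- design$cycle_sizes[sample.int(length(design$cycle_sizes), n,
                                       replace = TRUE)]
    vapply(k, function(ki) {
      xs <- paste(sample(design$alphabet, ki + 1L, replace = TRUE),
                  collapse = "")
      paste0("S", substr(xs, 1, 1), "C", substr(xs, 2, nchar(xs)), "C")
    }, character(1))
  })
}

# Count-level selection simulation: naive + selected count tables without
# rendering FASTQ, for the DE power / type-I studies.
simulate_count_experiment <- function(n_variants, reads, planted = NULL,
                                      seed = 1, design = tiny_design()) {
  cfg <- sim_config(n_variants = n_variants, planted = planted,
                    reads_per_experiment = reads, seed = seed,
                    barcodes = tiny_barcodes)
  naive <- generate_naive_population(design, cfg)
  sel <- simulate_selection_round(naive, planted, label = "target")
  naive_c <- sample_population_counts(naive, reads)
  sel_c <- sample_population_counts(sel, reads)
  counts <- tibble::tibble(peptide = naive$peptide,
                           naive = naive_c$count, target = sel_c$count)
  count_table(counts, experiments = c("naive", "target"))
}
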