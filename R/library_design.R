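#' Define an SXCX(n)C phage-display library architecture
#'
#' A library design describes the displayed macrocycle scaffold: a fixed
#' N-terminal serine, one variable residue, a fixed cysteine, `n` variable
#' residues and a closing fixed cysteine (`SXCX(n)C`). The two cysteines are
#' chemically cross-linked by a perfluoroaromatic linchpin after display, but
#' for sequence analysis only the peptide architecture matters. The design
#' also carries the DNA context each clone is sequenced in: a 5' constant
#' (priming) region, a 3' constant region, and the length of the multiplexing
#' barcode that precedes the construct on the forward read.
#'
#' The default constant regions are the priming regions of the library
#' construction template, with the variable region `TCT X TGT X X X TGT`
#' (Ser codon, one variable codon, Cys codon, `n` variable codons, Cys codon)
#' sitting between them.
#'
#' @param name Label for the design.
#' @param cycle_sizes Integer vector of supported ring sizes `n` (number of
#'   variable residues between the two cysteines); any subset of `3:5`.
#' @param alphabet Character vector of amino-acid letters allowed at X
#'   positions. Defaults to the 19 canonical residues excluding cysteine,
#'   since a stray cysteine would compete for the linchpin.
#' @param constant_5p,constant_3p Uppercase ACGT strings flanking the
#'   variable region in the sequenced construct.
#' @param barcode_length Barcode length in nucleotides at the start of the
#'   forward read.
#' @param codon_policy How variable-position codons are drawn in simulation;
#'   `"single_codon"` uses one fixed trinucleotide per amino acid, mirroring
#'   trinucleotide-codon library synthesis.
#'
#' @return An object of class `library_design`.
#' @examples
#' d <- library_design()
#' theoretical_diversity(d, n = 3, alphabet_size = 20)
#' @export
library_design <- function(name = "SXCX3C",
                           cycle_sizes = 3L,
                           alphabet = setdiff(AA_CANONICAL, "C"),
                           constant_5p = "CCCGGGTACCTTTCTATTCTCACTCT",
                           constant_3p = "GGTGGAGGTTCGGCCGGGCGCTTGATT",
                           barcode_length = 8L,
                           codon_policy = "single_codon") {
  cycle_sizes <- sort(unique(as.integer(cycle_sizes)))
  if (length(cycle_sizes) == 0L || !all(cycle_sizes %in% 3:5)) {
    stop("`cycle_sizes` must be a non-empty subset of 3:5", call. = FALSE)
  }
  alphabet <- unique(toupper(alphabet))
  if (!all(alphabet %in% AA_CANONICAL)) {
    stop("`alphabet` must be canonical amino-acid letters", call. = FALSE)
  }
  for (cr in list(constant_5p = constant_5p, constant_3p = constant_3p)) {
    if (!nzchar(cr) || grepl("[^ACGT]", cr)) {
      stop("constant regions must be nonempty uppercase ACGT strings",
           call. = FALSE)
    }
  }
  structure(
    list(
      name = name,
      cycle_sizes = cycle_sizes,
      alphabet = alphabet,
      constant_5p = constant_5p,
      constant_3p = constant_3p,
      barcode_length = as.integer(barcode_length),
      codon_policy = codon_policy
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design> ", x$name, "\n", sep = "")
  cat("  cycle sizes n: ", paste(x$cycle_sizes, collapse = ", "),
      "  (patterns ", paste(vapply(x$cycle_sizes, fixed_pattern, "", design = x),
                            collapse = ", "), ")\n", sep = "")
  cat("  X alphabet: ", paste(x$alphabet, collapse = ""),
      " (", length(x$alphabet), " letters)\n", sep = "")
  cat("  constant 5': ", x$constant_5p, "\n", sep = "")
  cat("  constant 3': ", x$constant_3p, "\n", sep = "")
  cat("  barcode length: ", x$barcode_length, " nt\n", sep = "")
  invisible(x)
}

#' Load a library design from a YAML or JSON config file
#'
#' Recognised keys: `name`, `cycle_sizes`, `alphabet`, `constant_5p`,
#' `constant_3p`, `barcode_length`, `codon_policy`. Missing keys fall back to
#' the shipped defaults. `alphabet` may be a single string of letters or a
#' list of letters.
#'
#' @param path Path to a YAML (or JSON: YAML is a superset) file.
#' @return A [library_design()].
#' @export
read_library_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$name)) args$name <- cfg$name
  if (!is.null(cfg$cycle_sizes)) args$cycle_sizes <- unlist(cfg$cycle_sizes)
  if (!is.null(cfg$alphabet)) {
    ab <- unlist(cfg$alphabet)
    if (length(ab) == 1L && nchar(ab) > 1L) ab <- strsplit(ab, "")[[1]]
    args$alphabet <- ab
  }
  for (k in c("constant_5p", "constant_3p", "barcode_length", "codon_policy")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(library_design, args)
}

#' The 20 canonical amino-acid letters
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# One representative codon per amino acid, used when simulation draws
# trinucleotide codons ("single_codon" policy). The serine and cysteine
# entries are the template's fixed TCT / TGT codons.
AA_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
  G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
  M = "ATG", N = "AAT", P = "CCG", Q = "CAG", R = "CGT",
  S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT"
)

#' Fixed peptide pattern for a given ring size
#'
#' @param n Ring size (number of variable residues between the cysteines).
#' @param design Optional [library_design()]; if supplied, `n` must be one of
#'   its `cycle_sizes`.
#' @return A string such as `"SXCXXXC"` for `n = 3`.
#' @export
fixed_pattern <- function(n, design = NULL) {
  n <- as.integer(n)
  if (!is.null(design) && !n %in% design$cycle_sizes) {
    stop("unsupported architecture: n = ", n, " is not in this design",
         call. = FALSE)
  }
  paste0("SXC", strrep("X", n), "C")
}

# Number of variable (X) positions in the pattern for ring size n: one after
# the serine plus n inside the ring.
n_x_positions <- function(n) as.integer(n) + 1L

#' Theoretical diversity of one architecture
#'
#' Number of distinct peptides of the `SXCX(n)C` architecture given an
#' alphabet of `alphabet_size` letters at each X position: the library has
#' `n + 1` variable positions, so diversity is `alphabet_size^(n + 1)`.
#' For the `SXCX3C` library with a 20-letter alphabet this is the published
#' 160,000-variant figure; with the 19-letter cysteine-free alphabet the
#' design actually encodes, it is 130,321. Both conventions are one call away
#' because the count is parametric in `alphabet_size`.
#'
#' @param design A [library_design()].
#' @param n Ring size; must be one of `design$cycle_sizes`.
#' @param alphabet_size Number of letters available at each X position;
#'   defaults to the design's alphabet size.
#' @return A single number (exact for the library sizes in question).
#' @examples
#' theoretical_diversity(library_design(), 3, alphabet_size = 20) # 160000
#' theoretical_diversity(library_design(), 3)                    # 19^4
#' @export
theoretical_diversity <- function(design, n, alphabet_size = length(design$alphabet)) {
  n <- as.integer(n)
  if (!n %in% design$cycle_sizes) {
    stop("unsupported architecture: n = ", n, " is not in this design",
         call. = FALSE)
  }
  if (alphabet_size < 1) stop("`alphabet_size` must be >= 1", call. = FALSE)
  as.numeric(alphabet_size)^n_x_positions(n)
}

#' Translate variable-region DNA into peptide records
#'
#' Applies the standard genetic code to each DNA string. A stop codon
#' anywhere truncates the peptide at the stop and sets `contains_stop`;
#' downstream stages discard such records but the truncated peptide is kept
#' for auditing. Input must be in frame (length divisible by 3) and strictly
#' ACGT.
#'
#' @param dna Character vector of variable-region DNA (the full
#'   `TCT X TGT ... TGT` insert, or any in-frame ACGT string).
#' @param design Optional [library_design()]; when given, an
#'   `architecture_class` column is added via [classify_architecture()].
#' @return A tibble with columns `dna`, `peptide`, `contains_stop` (and
#'   `architecture_class` when `design` is supplied).
#' @examples
#' translate_variable_region("TCTATTTGTCGTTTTTTTTGT")
#' @export
translate_variable_region <- function(dna, design = NULL) {
  if (length(dna) == 0L) {
    out <- tibble::tibble(dna = character(), peptide = character(),
                          contains_stop = logical())
    if (!is.null(design)) out$architecture_class <- character()
    return(out)
  }
  if (any(grepl("[^ACGT]", dna))) {
    stop("malformed sequence: non-ACGT character in variable region",
         call. = FALSE)
  }
  if (any(nchar(dna) %% 3L != 0L)) {
    stop("frame error: variable-region length not divisible by 3",
         call. = FALSE)
  }
  raw <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna), no.init.codon = TRUE))
  contains_stop <- grepl("*", raw, fixed = TRUE)
  peptide <- sub("\\*.*$", "", raw)
  out <- tibble::tibble(dna = dna, peptide = peptide,
                        contains_stop = contains_stop)
  if (!is.null(design)) {
    out$architecture_class <- ifelse(
      contains_stop, "off_design",
      classify_architecture(ifelse(nzchar(peptide), peptide, "X"), design))
  }
  out
}

#' Classify a peptide against the SXCX(n)C architectures
#'
#' A peptide belongs to class `n<k>` when it has length `k + 4`, serine at
#' position 1 and cysteine at positions 3 and `k + 4` (1-based), i.e. it
#' matches the fixed pattern `SXCX(k)C`. Anything else — wrong length, wrong
#' fixed residues, or non-canonical letters — is `off_design`. Off-design
#' sequences are first-class citizens downstream: ring sizes outside the
#' designed architecture arise as rare deletion variants in real libraries
#' and have produced genuine hits.
#'
#' @param peptide Character vector of uppercase peptides.
#' @param design A [library_design()]; classification is attempted for every
#'   `n` in `design$cycle_sizes`.
#' @return Character vector over `{"n3","n4","n5","off_design"}`.
#' @examples
#' classify_architecture(c("SICRFFC", "STCHDITC", "AICRFFC"),
#'                       library_design(cycle_sizes = 3:5))
#' @export
classify_architecture <- function(peptide, design) {
  if (length(peptide) == 0L) return(character())
  if (any(is.na(peptide) | !nzchar(peptide))) {
    stop("malformed sequence: empty peptide", call. = FALSE)
  }
  out <- rep("off_design", length(peptide))
  canonical <- !grepl(paste0("[^", paste(AA_CANONICAL, collapse = ""), "]"),
                      peptide)
  len <- nchar(peptide)
  for (k in design$cycle_sizes) {
    sel <- canonical & len == k + 4L &
      substr(peptide, 1L, 1L) == "S" &
      substr(peptide, 3L, 3L) == "C" &
      substr(peptide, k + 4L, k + 4L) == "C"
    out[sel] <- paste0("n", k)
  }
  out
}

#' Reverse-translate peptides with the simulation codon table
#'
#' Inverse of [translate_variable_region()] under the `"single_codon"`
#' policy: each amino acid maps to one fixed trinucleotide, so translation
#' after reverse translation is the identity on stop-free peptides.
#'
#' @param peptide Character vector of canonical-letter peptides.
#' @return Character vector of DNA strings.
#' @export
reverse_translate <- function(peptide) {
  if (any(grepl(paste0("[^", paste(AA_CANONICAL, collapse = ""), "]"), peptide))) {
    stop("malformed sequence: non-canonical amino-acid letter", call. = FALSE)
  }
  vapply(strsplit(peptide, ""), function(aa) paste(AA_CODON[aa], collapse = ""),
         character(1))
}
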