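#' Configure a synthetic selection campaign
#'
#' Bundles everything the simulator needs to emulate a one-round selection
#' experiment sequenced on a paired-end short-read run: how many distinct
#' library members exist, how skewed their naive abundances are, which
#' binder peptides are planted and how strongly they enrich, sequencing
#' depth, per-base substitution error rate, and the barcode assigned to each
#' multiplexed experiment.
#'
#' The defaults are the simulated analogue of a single-round solution-panning
#' campaign on a fully NGS-coverable library: a long-tailed log-normal naive
#' abundance distribution (`meanlog = 0`, `sdlog = 1`), 1e5 read pairs per
#' experiment, and an Illumina-like 1e-3 substitution error rate.
#'
#' @param n_variants Number of distinct in-design variants in the naive pool.
#' @param abundance_model `"log_normal"` or `"uniform"` naive abundances.
#' @param meanlog,sdlog Parameters of the log-normal abundance model.
#' @param planted Tibble/data frame with columns `peptide` and `enrichment`
#'   (the per-sequence enrichment factor lambda >= 0), and optionally
#'   `naive_frequency` to pin a planted peptide's naive abundance.
#' @param reads_per_experiment Read pairs sampled per experiment.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param read_length Read length per mate (nt).
#' @param barcodes Named character vector: experiment name -> barcode DNA of
#'   the design's `barcode_length`.
#' @param low_quality_fraction Fraction of read pairs given one Phred-2 base
#'   on the forward mate, to exercise the quality filter. Default 0.
#' @param seed Integer seed; everything downstream is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_variants = 10000L,
                       abundance_model = c("log_normal", "uniform"),
                       meanlog = 0, sdlog = 1,
                       planted = NULL,
                       reads_per_experiment = 100000L,
                       error_rate = 0.001,
                       read_length = 75L,
                       barcodes = c(naive = "ACGTACGT",
                                    target = "TGCATGCA",
                                    control = "GATCGATC"),
                       low_quality_fraction = 0,
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  if (error_rate < 0 || error_rate >= 1) {
    stop("`error_rate` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("peptide", "enrichment") %in% names(planted)))
    if (any(planted$enrichment < 0)) {
      stop("planted enrichment factors must be >= 0", call. = FALSE)
    }
  }
  if (is.null(names(barcodes)) || anyDuplicated(barcodes)) {
    stop("`barcodes` must be a named vector of distinct barcodes", call. = FALSE)
  }
  structure(
    list(n_variants = as.integer(n_variants),
         abundance_model = abundance_model,
         meanlog = meanlog, sdlog = sdlog,
         planted = planted,
         reads_per_experiment = as.integer(reads_per_experiment),
         error_rate = error_rate,
         read_length = as.integer(read_length),
         barcodes = barcodes,
         low_quality_fraction = low_quality_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Draw k distinct variable-region peptides from the design, uniformly over
# architecture cycle sizes. Returns a tibble(peptide, dna).
draw_variants <- function(design, k, exclude = character()) {
  out <- character(0)
  # rejection sampling over random X draws; collisions are rare until k
  # approaches the theoretical diversity, so loop until k distinct
  while (length(out) < k) {
    need <- k - length(out)
    n <- design$cycle_sizes[sample.int(length(design$cycle_sizes), need,
                                       replace = TRUE)]
    xs <- vapply(n, function(ni) {
      paste(sample(design$alphabet, n_x_positions(ni), replace = TRUE),
            collapse = "")
    }, character(1))
    pep <- paste0("S", substr(xs, 1L, 1L), "C",
                  substr(xs, 2L, nchar(xs)), "C")
    out <- setdiff(unique(c(out, setdiff(pep, exclude))), character(0))
  }
  out <- out[seq_len(k)]
  tibble::tibble(peptide = out, dna = reverse_translate(out))
}

#' Generate a ground-truth naive population
#'
#' Draws `n_variants` distinct in-design peptides and assigns naive
#' frequencies from the configured abundance model, normalised to sum to 1.
#' Planted peptides from `config$planted` are always included; when a
#' `naive_frequency` column is present their frequencies are pinned and the
#' remaining mass is shared by the background variants.
#'
#' @param design A [library_design()].
#' @param config A [sim_config()].
#' @return A `population`: tibble with columns `peptide`, `dna`, `frequency`
#'   and attribute `label`.
#' @export
generate_naive_population <- function(design, config) {
  total_div <- sum(vapply(design$cycle_sizes, function(n) {
    theoretical_diversity(design, n)
  }, numeric(1)))
  if (config$n_variants > total_div) {
    stop("capacity error: n_variants exceeds the design's theoretical diversity",
         call. = FALSE)
  }
  set.seed(config$seed)
  planted <- config$planted
  planted_pep <- if (is.null(planted)) character() else planted$peptide
  if (length(planted_pep)) {
    cls <- classify_architecture(planted_pep, design)
    if (any(cls == "off_design")) {
      stop("planted peptides must match the design architecture", call. = FALSE)
    }
  }
  n_bg <- config$n_variants - length(planted_pep)
  if (n_bg < 0) stop("more planted peptides than n_variants", call. = FALSE)
  bg <- draw_variants(design, n_bg, exclude = planted_pep)
  pop <- dplyr::bind_rows(
    tibble::tibble(peptide = planted_pep,
                   dna = if (length(planted_pep)) reverse_translate(planted_pep)
                         else character()),
    bg
  )
  w <- switch(config$abundance_model,
    log_normal = stats::rlnorm(nrow(pop), config$meanlog, config$sdlog),
    uniform = rep(1, nrow(pop))
  )
  freq <- w / sum(w)
  if (!is.null(planted) && "naive_frequency" %in% names(planted)) {
    pin <- planted$naive_frequency
    if (sum(pin) >= 1) stop("pinned naive frequencies must sum to < 1",
                            call. = FALSE)
    idx <- seq_along(planted_pep)
    freq[-idx] <- freq[-idx] / sum(freq[-idx]) * (1 - sum(pin))
    freq[idx] <- pin
  }
  pop$frequency <- freq
  attr(pop, "label") <- "naive"
  pop
}

#' Apply one round of selection as frequency reweighting
#'
#' Each planted peptide's naive frequency is multiplied by its enrichment
#' factor lambda (lambda = 1 for everything else) and the population is
#' renormalised: `f_i' = lambda_i f_i / sum_j lambda_j f_j`. This abstracts a
#' single-round panning experiment down to what the downstream count
#' statistics can see; no phage amplification kinetics are modelled.
#'
#' @param population A population tibble from [generate_naive_population()].
#' @param planted Tibble with `peptide` and `enrichment`; defaults to no
#'   reweighting. Peptides absent from the population are an error.
#' @param label Experiment label for the output population.
#' @return A population tibble with updated `frequency`.
#' @export
simulate_selection_round <- function(population, planted = NULL,
                                     label = "selected") {
  lambda <- rep(1, nrow(population))
  if (!is.null(planted) && nrow(planted)) {
    idx <- match(planted$peptide, population$peptide)
    if (anyNA(idx)) {
      stop("planted peptides must be present in the naive population",
           call. = FALSE)
    }
    lambda[idx] <- planted$enrichment
  }
  w <- lambda * population$frequency
  if (sum(w) <= 0) {
    stop("degenerate selection: all reweighted frequencies are zero",
         call. = FALSE)
  }
  out <- population
  out$frequency <- w / sum(w)
  attr(out, "label") <- label
  out
}

#' Multinomially sample sequencing counts from a population
#'
#' @param population A population tibble.
#' @param n_reads Total reads to draw.
#' @return The population with an integer `count` column (sums to `n_reads`).
#' @export
sample_population_counts <- function(population, n_reads) {
  out <- population
  out$count <- if (n_reads > 0) {
    as.integer(stats::rmultinom(1, n_reads, population$frequency))
  } else {
    integer(nrow(population))
  }
  out
}

# Vectorised substitution errors: mutates characters of `seqs` in place at a
# per-base rate. Returns the mutated character vector.
apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  pos <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_i <- findInterval(pos - 1L, ends) + 1L
  within <- pos - c(0L, ends)[read_i]
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(n_err)) {
    i <- read_i[j]; p <- within[j]
    old <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
  }
  seqs
}

#' Render a multiplexed paired-end FASTQ run from populations
#'
#' The inverse of read deconvolution: for each experiment, `reads_per_experiment`
#' clones are drawn multinomially from the population frequencies and written
#' as read pairs. The forward read is the prefix of
#' `barcode + constant_5p + variable DNA + constant_3p`; the reverse read is
#' the reverse complement of the construct's 3' end (so it always covers the
#' 3' constant region and the variable region). Substitution errors are
#' applied independently per base at `config$error_rate`; all bases carry
#' Phred 37 qualities unless the low-quality injection mode is enabled, in
#' which case a fraction of forward reads get one Phred-2 base inside the
#' variable region.
#'
#' @param populations Named list of population tibbles; names must appear in
#'   `config$barcodes`.
#' @param design A [library_design()].
#' @param config A [sim_config()].
#' @param dir Output directory; `R1.fastq`, `R2.fastq` and `manifest.tsv`
#'   are written there.
#' @return The run manifest: tibble with `experiment`, `peptide`, `dna`,
#'   `true_count`, `frequency` (invisibly also written as TSV).
#' @export
render_fastq_run <- function(populations, design, config, dir) {
  stopifnot(is.list(populations), !is.null(names(populations)))
  if (!all(names(populations) %in% names(config$barcodes))) {
    stop("every population needs a barcode assignment in `config$barcodes`",
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed + 1L)

  bl <- design$barcode_length
  if (any(nchar(config$barcodes) != bl)) {
    stop("barcodes must have the design's barcode_length", call. = FALSE)
  }
  rl <- config$read_length

  fwd_all <- character(0); rev_all <- character(0)
  fq_fwd <- character(0); fq_rev <- character(0)
  ids <- character(0)
  manifest <- vector("list", length(populations))

  for (i in seq_along(populations)) {
    exp_name <- names(populations)[i]
    pop <- sample_population_counts(populations[[i]],
                                    config$reads_per_experiment)
    manifest[[i]] <- tibble::tibble(
      experiment = exp_name, peptide = pop$peptide, dna = pop$dna,
      true_count = pop$count, frequency = pop$frequency
    )
    keep <- pop$count > 0
    if (!any(keep)) next
    construct <- paste0(config$barcodes[[exp_name]], design$constant_5p,
                        pop$dna[keep], design$constant_3p)
    clen <- nchar(construct)
    fwd_u <- substr(construct, 1L, pmin(rl, clen))
    rev_u <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substr(construct, pmax(1L, clen - rl + 1L), clen))))
    reps <- pop$count[keep]
    fwd_all <- c(fwd_all, rep.int(fwd_u, reps))
    rev_all <- c(rev_all, rep.int(rev_u, reps))
    ids <- c(ids, paste0(exp_name, ":", seq_len(sum(reps))))
  }

  fwd_all <- apply_substitutions(fwd_all, config$error_rate)
  rev_all <- apply_substitutions(rev_all, config$error_rate)

  q37 <- strrep("F", max(nchar(c(fwd_all, rev_all, "")), 0L))
  fq_fwd <- substr(rep(q37, length(fwd_all)), 1L, nchar(fwd_all))
  fq_rev <- substr(rep(q37, length(rev_all)), 1L, nchar(rev_all))
  if (config$low_quality_fraction > 0 && length(fwd_all)) {
    n_low <- round(config$low_quality_fraction * length(fwd_all))
    if (n_low > 0) {
      sel <- sample.int(length(fwd_all), n_low)
      # one Phred-2 base inside the variable-region span of the forward read
      pos <- bl + nchar(design$constant_5p) + 1L +
        floor(stats::runif(n_low) * 3L)
      for (j in seq_len(n_low)) {
        substr(fq_fwd[sel[j]], pos[j], pos[j]) <- "#"
      }
    }
  }

  write_fastq(file.path(dir, "R1.fastq"), ids, fwd_all, fq_fwd)
  write_fastq(file.path(dir, "R2.fastq"), ids, rev_all, fq_rev)
  manifest <- dplyr::bind_rows(manifest)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

write_fastq <- function(path, ids, seqs, quals) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}
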