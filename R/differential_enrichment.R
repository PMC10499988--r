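#' Differential-enrichment configuration
#'
#' Thresholds and options for hit nomination. The defaults are the screen's
#' published decision rule: a peptide is a per-comparison hit when its raw
#' p-value is below 0.05 and its (pseudocounted) fold change exceeds 3, both
#' strict inequalities, and the final hit list intersects the per-comparison
#' hits across all control comparisons.
#'
#' @param pseudocount Added to both counts for the fold change only (the
#'   exact test uses raw counts), keeping fold finite when the control count
#'   is zero. Default 1.
#' @param p_threshold Raw p-value threshold (strict `<`). Default 0.05.
#' @param fold_threshold Fold-change threshold (strict `>`). Default 3.
#' @param adjust `"none"` (nominate on raw p, as published) or
#'   `"benjamini_hochberg"` to also nominate on BH-adjusted p.
#' @param nomination_rule `"intersection"` (hit in every comparison) or
#'   `"any"`.
#' @return An object of class `de_config`.
#' @export
de_config <- function(pseudocount = 1, p_threshold = 0.05, fold_threshold = 3,
                      adjust = c("none", "benjamini_hochberg"),
                      nomination_rule = c("intersection", "any")) {
  stopifnot(pseudocount >= 0, p_threshold > 0, fold_threshold > 0)
  structure(list(pseudocount = pseudocount,
                 p_threshold = p_threshold,
                 fold_threshold = fold_threshold,
                 adjust = match.arg(adjust),
                 nomination_rule = match.arg(nomination_rule)),
            class = "de_config")
}

#' Depth-normalise a count table to counts per million
#'
#' @param ct A [count_table()]; every experiment must have positive depth.
#' @return Tibble like `ct$counts` with counts replaced by CPM; each
#'   experiment column sums to 1e6.
#' @export
normalize_cpm <- function(ct) {
  if (any(ct$depth <= 0)) {
    stop("empty experiment: zero sequencing depth", call. = FALSE)
  }
  out <- ct$counts
  for (e in ct$experiments) out[[e]] <- 1e6 * out[[e]] / ct$depth[[e]]
  out
}

# Two-sided exact conditional binomial p-value for one peptide. Conditional
# on k = c_test + c_ctrl observations, c_test ~ Binomial(k, pi0) with
# pi0 = N_test / (N_test + N_ctrl) under the null of equal frequency. The
# two-sided p sums P(X = j) over all outcomes j no more likely than the
# observed one (the minimum-likelihood method, with the customary 1 + 1e-7
# relative slack on the tie comparison).
exact_conditional_p <- function(c_test, k, pi0) {
  if (k == 0L) return(1)
  d <- stats::dbinom(0:k, k, pi0)
  p <- sum(d[d <= d[c_test + 1L] * (1 + 1e-7)])
  min(1, p)
}

#' Exact conditional binomial differential-enrichment test
#'
#' The per-peptide statistic of the screen: given the peptide's counts in a
#' test and a control selection with sequencing depths `N_test` and `N_ctrl`,
#' the fold change is the ratio of pseudocounted frequencies,
#' `((c_test + a)/N_test) / ((c_ctrl + a)/N_ctrl)`, and the p-value is the
#' two-sided exact conditional binomial test: conditional on
#' `k = c_test + c_ctrl` total observations, `c_test` is Binomial(k, pi0)
#' with `pi0 = N_test/(N_test + N_ctrl)` under the null of equal underlying
#' frequency, and the two-sided p sums the probabilities of all outcomes no
#' more likely than the observed one. The test uses raw counts; the
#' pseudocount touches only the fold change. Suited to single-round
#' selections with no replicates: no dispersion is estimated.
#'
#' @param c_test,c_ctrl Integer count vectors (one entry per peptide).
#' @param n_test,n_ctrl Sequencing depths (scalars or vectors).
#' @param pseudocount Fold-change pseudocount `a` (default 1).
#' @return Tibble with `c_test`, `c_ctrl`, `n_test`, `n_ctrl`, `freq_test`,
#'   `freq_ctrl` (CPM), `fold`, `p_raw`.
#' @examples
#' de_test(50, 5, 1e4, 1e4)
#' @export
de_test <- function(c_test, c_ctrl, n_test, n_ctrl, pseudocount = 1) {
  m <- length(c_test)
  n_test <- rep_len(n_test, m); n_ctrl <- rep_len(n_ctrl, m)
  if (any(n_test <= 0 | n_ctrl <= 0)) {
    stop("depths must be positive", call. = FALSE)
  }
  if (any(c_test > n_test | c_ctrl > n_ctrl)) {
    stop("inconsistent input: count exceeds depth", call. = FALSE)
  }
  fold <- ((c_test + pseudocount) / n_test) /
    ((c_ctrl + pseudocount) / n_ctrl)
  k <- c_test + c_ctrl
  pi0 <- n_test / (n_test + n_ctrl)
  p_raw <- vapply(seq_len(m), function(i) {
    exact_conditional_p(c_test[i], k[i], pi0[i])
  }, numeric(1))
  tibble::tibble(c_test = c_test, c_ctrl = c_ctrl,
                 n_test = n_test, n_ctrl = n_ctrl,
                 freq_test = 1e6 * c_test / n_test,
                 freq_ctrl = 1e6 * c_ctrl / n_ctrl,
                 fold = fold, p_raw = p_raw)
}

#' Benjamini-Hochberg adjustment over a comparison's peptide set
#'
#' Adds a `p_adj` column (step-up BH over all rows, or within each
#' `comparison` group when that column is present). Provided as an option;
#' the published decision rule nominates on raw p.
#'
#' @param results Tibble with a `p_raw` column.
#' @return `results` with a `p_adj` column.
#' @export
adjust_bh <- function(results) {
  if ("comparison" %in% names(results)) {
    results |>
      dplyr::group_by(.data$comparison) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p_raw, method = "BH")) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(results, p_adj = stats::p.adjust(.data$p_raw, method = "BH"))
  }
}

#' Differential enrichment of one test selection against controls
#'
#' Runs [de_test()] for the test experiment against each control over the
#' full peptide universe of the count table and stacks the per-comparison
#' results, BH-adjusted per comparison.
#'
#' @param ct A [count_table()].
#' @param test Name of the test experiment.
#' @param controls Character vector of control experiment names.
#' @param config A [de_config()].
#' @return Long tibble with one row per peptide per comparison: `peptide`,
#'   `comparison` (`"test_vs_control"`), the [de_test()] columns, `p_adj`,
#'   and the per-comparison `hit` flag.
#' @export
compare_enrichment <- function(ct, test, controls, config = de_config()) {
  stopifnot(test %in% ct$experiments, all(controls %in% ct$experiments))
  if (length(controls) == 0L) stop("no control experiments", call. = FALSE)
  res <- purrr::map_dfr(controls, function(ctl) {
    r <- de_test(ct$counts[[test]], ct$counts[[ctl]],
                 ct$depth[[test]], ct$depth[[ctl]],
                 pseudocount = config$pseudocount)
    dplyr::bind_cols(
      tibble::tibble(peptide = ct$counts$peptide,
                     comparison = paste0(test, "_vs_", ctl)),
      r)
  })
  res <- adjust_bh(res)
  p_nom <- if (config$adjust == "benjamini_hochberg") res$p_adj else res$p_raw
  res$hit <- p_nom < config$p_threshold & res$fold > config$fold_threshold
  res
}

#' Nominate final hits across comparisons
#'
#' Applies the nomination rule to per-comparison hit flags: with
#' `"intersection"` a peptide must be a hit in every comparison, with
#' `"any"` in at least one. The final list is ranked by ascending p
#' (the maximum raw p across comparisons, i.e. the weakest evidence), ties
#' by descending fold (the minimum across comparisons), then
#' lexicographically by peptide.
#'
#' @param results Long results tibble from [compare_enrichment()] (possibly
#'   several stacked calls; must carry `peptide`, `comparison`, `p_raw`,
#'   `fold`, `hit`).
#' @param config A [de_config()].
#' @return Tibble of final hits: `peptide`, `n_hit`, `n_comparisons`,
#'   `p_max`, `fold_min`, in rank order.
#' @export
nominate_hits <- function(results, config = de_config()) {
  if (nrow(results) == 0L || length(unique(results$comparison)) == 0L) {
    stop("no comparisons to nominate from", call. = FALSE)
  }
  n_cmp <- length(unique(results$comparison))
  agg <- results |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(n_hit = sum(.data$hit),
                     n_comparisons = dplyr::n(),
                     p_max = max(.data$p_raw),
                     fold_min = min(.data$fold),
                     .groups = "drop")
  keep <- switch(config$nomination_rule,
                 intersection = agg$n_hit == n_cmp,
                 any = agg$n_hit > 0)
  agg[keep, ] |>
    dplyr::arrange(.data$p_max, dplyr::desc(.data$fold_min), .data$peptide)
}

#' Volcano-plot table
#'
#' Exact transforms of the stored per-comparison results: `log2(fold)` and
#' `-log10(p_raw)`, with the per-comparison hit flag, sorted by decreasing
#' `-log10(p_raw)`.
#'
#' @param results Tibble from [compare_enrichment()].
#' @return Tibble with `peptide`, `comparison`, `log2_fold`, `neg_log10_p`,
#'   `hit`.
#' @export
volcano_table <- function(results) {
  stopifnot(all(results$fold > 0))
  results |>
    dplyr::transmute(peptide = .data$peptide,
                     comparison = .data$comparison,
                     log2_fold = log2(.data$fold),
                     neg_log10_p = -log10(.data$p_raw),
                     hit = .data$hit) |>
    dplyr::arrange(dplyr::desc(.data$neg_log10_p))
}

#' Volcano plot of a differential-enrichment comparison
#'
#' @param results Tibble from [compare_enrichment()].
#' @param config A [de_config()] supplying the threshold guide lines.
#' @return A ggplot object, faceted by comparison.
#' @export
plot_volcano <- function(results, config = de_config()) {
  vt <- volcano_table(results)
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$log2_fold, y = .data$neg_log10_p,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(config$p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = log2(config$fold_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p (exact test)",
                  colour = "hit") +
    ggplot2::theme_minimal()
}
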