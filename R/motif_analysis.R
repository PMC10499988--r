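#' Position-frequency matrix of a hit set
#'
#' Column-normalised amino-acid frequencies per position over a set of
#' equal-architecture peptides — the numeric content of a hit heat map or
#' sequence logo.
#'
#' @param hits Character vector of peptides sharing one architecture
#'   (equal length).
#' @return A `pfm`: tibble with `position` (1-based), `residue`, `frequency`;
#'   frequencies at each position sum to 1.
#' @examples
#' position_frequency_matrix(c("SICRFFC", "SFCPMFC"))
#' @export
position_frequency_matrix <- function(hits) {
  if (length(hits) == 0L) {
    stop("empty hit list", call. = FALSE)
  }
  if (length(unique(nchar(hits))) != 1L) {
    stop("heterogeneous architectures: hits must share one length",
         call. = FALSE)
  }
  L <- nchar(hits[[1]])
  mat <- do.call(rbind, strsplit(hits, ""))
  out <- purrr::map_dfr(seq_len(L), function(p) {
    tab <- table(factor(mat[, p], levels = AA_CANONICAL))
    tibble::tibble(position = p, residue = names(tab),
                   frequency = as.numeric(tab) / length(hits))
  })
  class(out) <- c("pfm", class(out))
  out
}

#' Export a PFM as a positions-by-residues matrix
#'
#' Sequence-logo-ready wide form of [position_frequency_matrix()].
#'
#' @param pfm A `pfm` tibble.
#' @return Numeric matrix, rows = positions, columns = the 20 residues.
#' @export
pfm_matrix <- function(pfm) {
  wide <- tidyr::pivot_wider(pfm, names_from = "residue",
                             values_from = "frequency")
  m <- as.matrix(wide[, AA_CANONICAL])
  rownames(m) <- wide$position
  m
}

#' @method autoplot pfm
#' @export
autoplot.pfm <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$position),
                                       y = .data$residue,
                                       fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy") +
    ggplot2::labs(x = "position", y = "residue", fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Select the top-k hits for display
#'
#' Ranks a final hit list by the nomination ordering (ascending worst p,
#' descending fold, then peptide) and returns the first `k` peptides,
#' restricted to the modal architecture length so the set is heat-mappable.
#'
#' @param hits Final hit tibble from [nominate_hits()].
#' @param k Number of hits to keep (default 25).
#' @return Character vector of at most `k` peptides of equal length.
#' @export
top_hits <- function(hits, k = 25L) {
  pep <- hits$peptide
  len <- nchar(pep)
  modal <- as.integer(names(which.max(table(len))))
  utils::head(pep[len == modal], k)
}

#' Dipeptide (ordered adjacent pair) enrichment of a hit set
#'
#' Counts every ordered pair of adjacent residues over each full peptide
#' (fixed serine/cysteine positions included) and compares against an
#' expected count from a background model scaled to the same total:
#' `"positional_independence"` forms expected pair frequencies as the outer
#' product of the hit set's overall single-residue frequencies;
#' `"naive_frequencies"` uses single-residue frequencies from a supplied
#' background peptide set (e.g. the naive library).
#'
#' @param hits Character vector of peptides (lengths may differ).
#' @param background `"positional_independence"` or `"naive_frequencies"`.
#' @param naive Character vector of background peptides (required for
#'   `"naive_frequencies"`).
#' @param pseudocount Added to observed and expected in the ratio. Default 1.
#' @return Tibble with `aa1`, `aa2`, `observed`, `expected`, `enrichment`
#'   (= `(observed + pseudocount) / (expected + pseudocount)`), 400 rows.
#'   Total observed equals `sum(nchar(hits) - 1)`.
#' @examples
#' dipeptide_enrichment(c("SICRFFC", "SFCPMFC"))
#' @export
dipeptide_enrichment <- function(hits,
                                 background = c("positional_independence",
                                                "naive_frequencies"),
                                 naive = NULL, pseudocount = 1) {
  background <- match.arg(background)
  if (length(hits) == 0L) stop("empty hit list", call. = FALSE)
  chars <- strsplit(hits, "")
  pairs <- purrr::map_dfr(chars, function(a) {
    if (length(a) < 2L) return(NULL)
    tibble::tibble(aa1 = a[-length(a)], aa2 = a[-1])
  })
  grid <- tidyr::expand_grid(aa1 = AA_CANONICAL, aa2 = AA_CANONICAL)
  obs <- pairs |>
    dplyr::count(.data$aa1, .data$aa2, name = "observed")
  out <- dplyr::left_join(grid, obs, by = c("aa1", "aa2")) |>
    dplyr::mutate(observed = dplyr::coalesce(.data$observed, 0L))

  bg_src <- switch(background,
                   positional_independence = unlist(chars),
                   naive_frequencies = {
                     if (is.null(naive)) {
                       stop("`naive` background peptides required",
                            call. = FALSE)
                     }
                     unlist(strsplit(naive, ""))
                   })
  f <- as.numeric(table(factor(bg_src, levels = AA_CANONICAL)))
  f <- f / sum(f)
  total <- sum(out$observed)
  out$expected <- f[match(out$aa1, AA_CANONICAL)] *
    f[match(out$aa2, AA_CANONICAL)] * total
  out$enrichment <- (out$observed + pseudocount) /
    (out$expected + pseudocount)
  out
}

#' Heat map of dipeptide enrichment
#'
#' @param dp Tibble from [dipeptide_enrichment()].
#' @return A ggplot tile plot of log2 enrichment.
#' @export
plot_dipeptide_enrichment <- function(dp) {
  ggplot2::ggplot(dp, ggplot2::aes(x = .data$aa2, y = .data$aa1,
                                   fill = log2(.data$enrichment))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "second residue", y = "first residue",
                  fill = "log2 enrichment") +
    ggplot2::theme_minimal()
}

#' Cluster hits into families by Hamming distance
#'
#' Single-linkage families: two peptides are linked when their Hamming
#' distance is at most `max_hamming`, and families are the connected
#' components of the resulting graph. Families are ordered by decreasing
#' size, ties by the lexicographically smallest member; members are sorted
#' within each family.
#'
#' @param hits Character vector of distinct equal-length peptides.
#' @param max_hamming Linkage radius (default 2); 0 makes every distinct
#'   sequence its own family.
#' @return Tibble with `peptide` and integer `family` (1 = largest family).
#' @examples
#' cluster_families(c("AAAA", "AAAB", "CCCC"), max_hamming = 1)
#' @export
cluster_families <- function(hits, max_hamming = 2L) {
  hits <- unique(hits)
  if (length(hits) == 0L) stop("empty hit list", call. = FALSE)
  if (length(unique(nchar(hits))) != 1L) {
    stop("heterogeneous architectures: hits must share one length",
         call. = FALSE)
  }
  n <- length(hits)
  mat <- do.call(rbind, strsplit(hits, ""))
  edges <- NULL
  if (n > 1L) {
    idx <- utils::combn(n, 2L)
    d <- vapply(seq_len(ncol(idx)), function(j) {
      sum(mat[idx[1, j], ] != mat[idx[2, j], ])
    }, numeric(1))
    edges <- idx[, d <= max_hamming, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && ncol(edges)) {
    g <- igraph::add_edges(g, as.vector(edges))
  }
  comp <- igraph::components(g)$membership
  fam <- tibble::tibble(peptide = hits, comp = comp)
  order_tbl <- fam |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(size = dplyr::n(), rep = min(.data$peptide),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$rep) |>
    dplyr::mutate(family = dplyr::row_number())
  fam |>
    dplyr::left_join(order_tbl[, c("comp", "family")], by = "comp") |>
    dplyr::select("peptide", "family") |>
    dplyr::arrange(.data$family, .data$peptide)
}

#' Consensus sequence of a peptide family
#'
#' Per-position modal residue; ties are broken alphabetically and flagged.
#'
#' @param family Character vector of equal-length peptides.
#' @return The consensus string, with attribute `ties`: integer vector of
#'   tied positions (empty when every position has a unique mode).
#' @examples
#' consensus_from_family(c("KAC", "KAC", "KGC"))
#' @export
consensus_from_family <- function(family) {
  if (length(family) == 0L) stop("empty family", call. = FALSE)
  if (length(unique(nchar(family))) != 1L) {
    stop("heterogeneous family: members must share one length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(family, ""))
  L <- ncol(mat)
  res <- character(L)
  ties <- integer(0)
  for (p in seq_len(L)) {
    tab <- sort(table(mat[, p]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) ties <- c(ties, p)
    res[p] <- min(top)
  }
  structure(paste(res, collapse = ""), ties = ties)
}
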