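# Independent brute-force oracle: enumerate the conditional binomial
# distribution of c_test given k = c_test + c_ctrl and sum the probabilities
# of outcomes no more likely than the observed one.
brute_force_p <- function(c_test, c_ctrl, n_test, n_ctrl) {
  k <- c_test + c_ctrl
  if (k == 0) return(1)
  pi0 <- n_test / (n_test + n_ctrl)
  probs <- vapply(0:k, function(j) {
    choose(k, j) * pi0^j * (1 - pi0)^(k - j)
  }, numeric(1))
  obs <- probs[c_test + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

test_that("CPM normalisation rescales each experiment to one million", {
  counts <- tibble::tibble(peptide = c("A1", "A2", "A3"),
                           expA = c(5L, 9995L, 0L), expB = c(1L, 1L, 2L))
  ct <- count_table(counts)
  cpm <- normalize_cpm(ct)
  expect_equal(cpm$expA[1], 500)           # 5 of 10^4
  expect_equal(cpm$expA[3], 0)
  expect_equal(sum(cpm$expA), 1e6)
  expect_equal(sum(cpm$expB), 1e6)

  empty <- count_table(tibble::tibble(peptide = "A1", expA = 0L))
  expect_error(normalize_cpm(empty), "depth")
})

test_that("de_test reproduces the exact-test examples", {
  # symmetric counts at equal depth: fold 1, p 1
  r <- de_test(10, 10, 1e4, 1e4)
  expect_equal(r$fold, 1)
  expect_equal(r$p_raw, 1)

  # 50 vs 5 at equal depths, pseudocount 1: fold 51/6, p from the exact
  # two-sided binomial tail over all 56 outcomes
  r <- de_test(50, 5, 1e4, 1e4)
  expect_equal(r$fold, 51 / 6)
  expect_equal(r$p_raw, brute_force_p(50, 5, 1e4, 1e4), tolerance = 1e-12)
  expect_equal(r$p_raw, stats::binom.test(50, 55, 0.5)$p.value,
               tolerance = 1e-12)

  # swapping test and control inverts the fold, p unchanged at equal depth
  r2 <- de_test(5, 50, 1e4, 1e4)
  expect_equal(r2$fold, 6 / 51)
  expect_equal(r2$p_raw, r$p_raw)

  expect_error(de_test(5, 1, 3, 10), "count exceeds depth")
  expect_error(de_test(1, 0, 0, 10), "depths")
})

test_that("p-values match brute-force enumeration for all totals up to 30", {
  for (depths in list(c(1e4, 1e4), c(5e4, 2e4), c(1234, 9876))) {
    for (k in 0:30) {
      ct <- 0:k
      r <- de_test(ct, k - ct, depths[1], depths[2])
      oracle <- mapply(brute_force_p, ct, k - ct,
                       MoreArgs = list(n_test = depths[1],
                                       n_ctrl = depths[2]))
      expect_equal(r$p_raw, unname(oracle), tolerance = 1e-12)
    }
  }
})

test_that("p-values agree with the standard exact binomial test", {
  set.seed(4)
  for (i in 1:50) {
    c1 <- sample(0:80, 1); c2 <- sample(0:80, 1)
    n1 <- sample(1e3:1e5, 1); n2 <- sample(1e3:1e5, 1)
    r <- de_test(c1, c2, n1, n2)
    expect_equal(r$p_raw,
                 stats::binom.test(c1, c1 + c2, n1 / (n1 + n2))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("fold change is monotone in c_test and the pseudocount vanishes in the limit", {
  r <- de_test(0:20, 5, 1e4, 1e4)
  expect_true(all(diff(r$fold) > 0))

  r_small <- de_test(12, 4, 1e4, 2e4, pseudocount = 1e-9)
  expect_equal(r_small$fold, (12 / 1e4) / (4 / 2e4), tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up rule", {
  r1 <- adjust_bh(tibble::tibble(p_raw = 0.04))
  expect_equal(r1$p_adj, 0.04)

  r3 <- adjust_bh(tibble::tibble(p_raw = c(0.01, 0.02, 0.03)))
  expect_equal(r3$p_adj, c(0.03, 0.03, 0.03))

  rall <- adjust_bh(tibble::tibble(p_raw = rep(1, 5)))
  expect_equal(rall$p_adj, rep(1, 5))

  set.seed(9)
  rr <- adjust_bh(tibble::tibble(p_raw = runif(100)))
  expect_true(all(rr$p_adj >= rr$p_raw))
})

test_that("per-comparison hit flags use strict thresholds and rules compose", {
  rows <- tibble::tibble(
    peptide = paste0("P", 1:5),
    comparison = "t_vs_c",
    p_raw = c(0.01, 0.01, 0.2, 0.04, 0.05),
    fold = c(5, 2, 10, 3.01, 4))
  cfg <- de_config()
  rows$hit <- rows$p_raw < cfg$p_threshold & rows$fold > cfg$fold_threshold
  expect_equal(rows$peptide[rows$hit], c("P1", "P4"))  # 0.05 fails strict <

  # intersection vs any across two comparisons
  res <- dplyr::bind_rows(
    tibble::tibble(peptide = "SICRFFC", comparison = "t_vs_naive",
                   p_raw = 0.001, fold = 10, hit = TRUE),
    tibble::tibble(peptide = "SICRFFC", comparison = "t_vs_T4GP",
                   p_raw = 0.002, fold = 8, hit = TRUE),
    tibble::tibble(peptide = "SICRFFC", comparison = "t_vs_ConA",
                   p_raw = 0.5, fold = 1.1, hit = FALSE))
  expect_equal(nrow(nominate_hits(res, de_config())), 0)
  got <- nominate_hits(res, de_config(nomination_rule = "any"))
  expect_equal(got$peptide, "SICRFFC")
  expect_error(nominate_hits(res[0, ], de_config()), "comparisons")
})

test_that("final hits are ranked by worst p, then fold, then peptide", {
  res <- tibble::tibble(
    peptide = c("BBB", "AAA", "CCC", "DDD"),
    comparison = "t_vs_c",
    p_raw = c(0.01, 0.001, 0.01, 0.3),
    fold = c(8, 5, 9, 10),
    hit = c(TRUE, TRUE, TRUE, FALSE))
  got <- nominate_hits(res, de_config())
  expect_equal(got$peptide, c("AAA", "CCC", "BBB"))
})

test_that("the volcano table transforms stored fields exactly", {
  res <- tibble::tibble(peptide = c("A", "B"), comparison = "t_vs_c",
                        p_raw = c(1, 0.001), fold = c(1, 8.5),
                        hit = c(FALSE, TRUE))
  vt <- volcano_table(res)
  expect_equal(vt$log2_fold[vt$peptide == "B"], log2(8.5))
  expect_equal(vt$log2_fold[vt$peptide == "A"], 0)
  expect_equal(vt$neg_log10_p[vt$peptide == "A"], 0)
  expect_equal(vt$peptide, c("B", "A"))  # sorted by -log10 p descending
  expect_identical(vt$hit, c(TRUE, FALSE))
})

test_that("compare_enrichment recovers a planted binder end to end", {
  planted <- tibble::tibble(peptide = "SICRFFC", enrichment = 10,
                            naive_frequency = 1e-3)
  ct <- simulate_count_experiment(2000, 1e5, planted, seed = 42)
  res <- compare_enrichment(ct, test = "target", controls = "naive")
  hit_row <- res[res$peptide == "SICRFFC", ]
  expect_lt(hit_row$p_raw, 0.05)
  expect_gt(hit_row$fold, 3)
  expect_true(hit_row$hit)
  hits <- nominate_hits(res, de_config())
  expect_true("SICRFFC" %in% hits$peptide)

  p <- plot_volcano(res)
  expect_s3_class(p, "ggplot")
})

test_that("null selections keep the false-positive rate near nominal", {
  # all lambda = 1: any p < 0.05 call is a false positive; the exact test is
  # conservative for discrete counts so the rate should sit at or below 5%,
  # with a small margin for simulation noise
  n_tested <- 0L; n_fp <- 0L
  for (seed in 1:20) {
    ct <- simulate_count_experiment(500, 1e4, planted = NULL, seed = seed)
    res <- compare_enrichment(ct, "target", "naive")
    n_tested <- n_tested + nrow(res)
    n_fp <- n_fp + sum(res$p_raw < 0.05)
  }
  expect_lte(n_fp / n_tested, 0.07)
})
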