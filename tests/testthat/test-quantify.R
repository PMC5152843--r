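mk_result <- function(vols, labels = "s1", keys = NULL) {
  # one sample per label, same keys/volumes in each
  if (is.null(keys))
    keys <- sprintf("[1,1,%d,0,2]", seq_along(vols))
  long <- do.call(rbind, lapply(labels, function(lab)
    data.frame(key = keys, dp = key_dp(keys), sample_label = lab,
               score = 0.5, total_volume = vols, stringsAsFactors = FALSE)))
  structure(long, class = c("comparison_result", "data.frame"),
            labels = labels, profile = "enoxaparin")
}

test_that("top_n_normalize: equal volumes, arithmetic oracle, degenerate n", {
  # 10 equal volumes -> each 0.1
  res <- top_n_normalize(mk_result(rep(7, 10)), n = 10)
  expect_equal(res$normalized, rep(0.1, 10))
  # 12 keys, volumes 1..12, n = 10 -> denominator 3+4+...+12 = 75
  res <- top_n_normalize(mk_result(1:12), n = 10)
  expect_equal(sum(3:12), 75)
  expect_equal(max(res$normalized), 12 / 75)
  expect_equal(sort(res$normalized), (1:12) / 75)
  # fewer keys than n -> abundances sum to 1
  res <- top_n_normalize(mk_result(c(5, 2, 3)), n = 10)
  expect_equal(sum(res$normalized), 1)
  expect_error(top_n_normalize(mk_result(c(0, 0))), "zero")
})

test_that("ties at rank n: all tied keys enter the denominator", {
  vols <- c(rep(10, 4), rep(1, 8))   # rank-4..12 all tied at 1 for n = 5
  res <- top_n_normalize(mk_result(vols), n = 5)
  expect_equal(res$normalized, vols / (4 * 10 + 8 * 1))
})

test_that("normalization is per-sample scale invariant", {
  base <- mk_result(c(4, 9, 1, 6, 2), labels = c("a", "b"))
  scaled <- base
  scaled$total_volume[scaled$sample_label == "a"] <-
    scaled$total_volume[scaled$sample_label == "a"] * 137.5
  n1 <- top_n_normalize(base, n = 3)
  n2 <- top_n_normalize(scaled, n = 3)
  expect_equal(n1$normalized, n2$normalized)
})

test_that("fdr_evaluate matches brute-force set arithmetic", {
  # worked example shape: 5 retained, 3 true -> 40%
  ev <- fdr_evaluate(sprintf("[1,1,%d,0,2]", 1:5),
                     sprintf("[1,1,%d,0,2]", 1:3))
  expect_equal(ev$retained, 5L)
  expect_equal(ev$false_positive_rate, 0.4)
  expect_equal(ev$false_negatives, 0L)
  # perfect and disjoint cases
  keys <- sprintf("[1,1,%d,0,2]", 1:4)
  expect_equal(fdr_evaluate(keys, keys)$false_positive_rate, 0)
  expect_equal(fdr_evaluate(keys, "[0,9,9,0,1]")$false_positive_rate, 1)
  # nothing retained -> NA, not 0
  expect_message(ev0 <- fdr_evaluate(character(0), keys), "undefined")
  expect_true(is.na(ev0$false_positive_rate))
  expect_equal(ev0$false_negatives, 4L)
  # random fuzz vs direct set arithmetic
  withr::with_seed(23, {
    pool <- sprintf("[1,1,%d,0,2]", 1:30)
    for (i in 1:50) {
      r <- sample(pool, sample(1:20, 1))
      t <- sample(pool, sample(1:20, 1))
      ev <- fdr_evaluate(r, t)
      expect_equal(ev$false_positive_rate,
                   length(setdiff(r, t)) / length(r))
      expect_equal(ev$false_negatives, length(setdiff(t, r)))
    }
  })
})

test_that("read_truth strips comments and validates keys", {
  f <- write_fixture(c("# manual annotation", "[1,2,3,1,4]  # confirmed",
                       "", "[1,2,3,1,5]"))
  expect_equal(read_truth(f), c("[1,2,3,1,4]", "[1,2,3,1,5]"))
  expect_error(read_truth(write_fixture("# only comments")), "empty")
  expect_error(read_truth(write_fixture("[1,2]")), "5 fields")
})

test_that("grouped_report orders by (anhydro, dp, key) with one column per sample", {
  keys <- c("[1,4,5,2,7]", "[1,2,3,1,4]", "[1,2,3,1,5]")
  res <- mk_result(c(3, 2, 1), labels = c("a", "b"), keys = keys)
  res <- top_n_normalize(res, n = 10)
  rep <- grouped_report(res)
  # dp6 rows precede dp10 rows
  expect_equal(rep$dp, c(6L, 6L, 10L))
  expect_equal(rep$key[1:2], c("[1,2,3,1,4]", "[1,2,3,1,5]"))
  # schema: anhydro, dp, key + one column per sample
  expect_equal(ncol(rep), 3L + 2L)
  expect_named(rep, c("anhydro", "dp", "key", "a", "b"))
  # anhydro/non-anhydro partition into two sections
  rep2 <- grouped_report(res, anhydro = c(TRUE, FALSE, FALSE))
  expect_equal(rep2$anhydro, c(FALSE, FALSE, TRUE))
  expect_error(grouped_report(mk_result(1:3)), "top_n_normalize")
})
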