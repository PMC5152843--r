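mk_records <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample_label = r[[1]], compound_key_raw = r[[2]],
               score = as.numeric(r[[3]]), total_volume = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
  attr(out, "labels") <- unique(out$sample_label)
  out
}

test_that("all_presence_filter keeps exactly keys seen under every label", {
  rec <- mk_records(
    list("L1", "[1,1,1,0,2]", 0.1, 10), list("L2", "[1,1,1,0,2] 1NH3", 0.2, 20),
    list("L3", "[1,1,1,0,2]", 0.3, 30),
    list("L1", "[1,1,2,0,3]", 0.4, 40), list("L2", "[1,1,2,0,3]", 0.5, 50))
  attr(rec, "labels") <- c("L1", "L2", "L3")
  kept <- all_presence_filter(rec)
  expect_equal(unique(kept$key), "[1,1,1,0,2]")
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$total_volume, c(10, 20, 30))   # order preserved
})

test_that("many rows over all labels are retained; many rows in fewer are not", {
  # 4 rows spread over all 3 labels -> all 4 retained
  rec <- mk_records(
    list("L1", "[1,2,2,0,4]", 0.1, 1), list("L1", "[1,2,2,0,4] 2NH3", 0.2, 2),
    list("L2", "[1,2,2,0,4]", 0.3, 3), list("L3", "[1,2,2,0,4]", 0.4, 4),
    # 3 rows but only 2 distinct labels -> deleted as noise
    list("L1", "[0,3,3,0,5]", 0.5, 5), list("L1", "[0,3,3,0,5] 1NH3", 0.6, 6),
    list("L2", "[0,3,3,0,5]", 0.7, 7))
  attr(rec, "labels") <- c("L1", "L2", "L3")
  kept <- all_presence_filter(rec)
  expect_equal(nrow(kept), 4L)
  expect_equal(unique(kept$key), "[1,2,2,0,4]")
})

test_that("filter degenerate and error cases", {
  rec <- mk_records(list("L1", "[1,1,1,0,2]", 0.1, 1))
  expect_error(all_presence_filter(rec, labels = c("L2", "L3")),
               "labeled outside")
  empty <- rec[0, , drop = FALSE]
  attr(empty, "labels") <- c("L1", "L2")
  expect_equal(nrow(all_presence_filter(empty)), 0L)
  expect_error(all_presence_filter(rec, labels = "L1"), ">= 2")
})

test_that("merge keeps max score and sums volumes per (key, sample)", {
  rec <- mk_records(
    list("L1", "[1,4,5,2,7] 1NH3", 0.3, 100),
    list("L1", "[1,4,5,2,7] 2NH3", 0.5, 200),
    list("L2", "[1,4,5,2,7]", 0.4, 50))
  kept <- all_presence_filter(rec, labels = c("L1", "L2"))
  res <- merge_adduct_groups(kept)
  expect_s3_class(res, "comparison_result")
  l1 <- res[res$sample_label == "L1", ]
  expect_equal(l1$score, 0.5)
  expect_equal(l1$total_volume, 300)
  l2 <- res[res$sample_label == "L2", ]
  expect_equal(l2$score, 0.4)       # single row passes through unchanged
  expect_equal(l2$total_volume, 50)
  expect_equal(unique(res$dp), 10L)
})

test_that("merged results are invariant to input row permutation", {
  rec <- random_records(99, k = 3L)
  kept <- all_presence_filter(rec)
  res <- merge_adduct_groups(kept)
  withr::with_seed(1, {
    for (i in 1:5) {
      perm <- kept[sample.int(nrow(kept)), , drop = FALSE]
      attr(perm, "labels") <- attr(kept, "labels")
      res2 <- merge_adduct_groups(perm)
      expect_equal(res2$key, res$key)
      expect_equal(res2$score, res$score)
      expect_equal(res2$total_volume, res$total_volume)
    }
  })
})

test_that("passthrough columns survive from the max-score row", {
  rec <- mk_records(
    list("L1", "[1,1,1,0,2] 1NH3", 0.2, 10), list("L1", "[1,1,1,0,2]", 0.9, 20),
    list("L2", "[1,1,1,0,2]", 0.5, 5))
  rec$note <- c("low", "high", "other")
  kept <- all_presence_filter(rec, labels = c("L1", "L2"))
  res <- merge_adduct_groups(kept)
  expect_equal(res$note[res$sample_label == "L1"], "high")
})

test_that("on exact score ties the earlier pooled row's extras survive", {
  # mirrors the merging pseudocode: the earlier-sorted row is retained
  rec <- mk_records(
    list("L1", "[1,1,1,0,2]", 0.5, 10), list("L1", "[1,1,1,0,2] 1NH3", 0.5, 20),
    list("L2", "[1,1,1,0,2]", 0.5, 5))
  rec$note <- c("first", "second", "other")
  kept <- all_presence_filter(rec, labels = c("L1", "L2"))
  res <- merge_adduct_groups(kept)
  expect_equal(res$note[res$sample_label == "L1"], "first")
  expect_equal(res$total_volume[res$sample_label == "L1"], 30)
})

test_that("compare_tables runs the full pipeline and is symmetric on duplicates", {
  lines <- c("Compound Key\tScore\tTotal Volume",
             "[1,1,1,0,2] 1NH3\t0.4\t100", "[1,1,1,0,2]\t0.6\t50",
             "\t0.1\t7", "[0,2,2,0,4]\t0.2\t30")
  p1 <- write_fixture(lines); p2 <- write_fixture(lines)
  res <- compare_tables(c(p1, p2), labels = c("a", "b"), quiet = TRUE)
  expect_setequal(unique(res$key), c("[1,1,1,0,2]", "[0,2,2,0,4]"))
  for (k in unique(res$key)) {
    sub <- res[res$key == k, ]
    expect_equal(sub$total_volume[1], sub$total_volume[2])
    expect_equal(sub$score[1], sub$score[2])
  }
  expect_error(compare_tables(p1), "at least 2")
})

test_that("min_score pre-filter applies before the presence filter", {
  lines1 <- c("Compound Key\tScore\tTotal Volume",
              "[1,1,1,0,2]\t0.05\t100", "[0,2,2,0,4]\t0.5\t30")
  lines2 <- c("Compound Key\tScore\tTotal Volume",
              "[1,1,1,0,2]\t0.8\t100", "[0,2,2,0,4]\t0.6\t30")
  p1 <- write_fixture(lines1); p2 <- write_fixture(lines2)
  res <- compare_tables(c(p1, p2), labels = c("a", "b"), min_score = 0.1,
                        quiet = TRUE)
  # the low-score row drops out of sample a, so the key fails all-presence
  expect_equal(unique(res$key), "[0,2,2,0,4]")
})

test_that("removing one sample can only grow or preserve the retained key set", {
  withr::with_seed(17, seeds <- sample.int(1e6, 10))
  for (s in seeds) {
    rec <- random_records(s, k = 3L)
    labels <- attr(rec, "labels")
    keys3 <- unique(all_presence_filter(rec)$key)
    rec2 <- rec[rec$sample_label != labels[3], , drop = FALSE]
    attr(rec2, "labels") <- labels[1:2]
    keys2 <- unique(all_presence_filter(rec2)$key)
    expect_true(all(keys3 %in% keys2))
  }
})

test_that("comparison_wide lays out one row per key with per-sample pairs", {
  rec <- random_records(5, k = 3L)
  res <- merge_adduct_groups(all_presence_filter(rec))
  wide <- comparison_wide(res)
  expect_equal(nrow(wide), length(unique(res$key)))
  expect_true(all(c("score.lot1", "total_volume.lot3") %in% names(wide)))
  # round-trip through the TSV writer/reader
  f <- tempfile(fileext = ".tsv")
  write_match_table(res, f)
  back <- read_comparison(f)
  expect_equal(back$key, res$key)
  expect_equal(back$total_volume, res$total_volume, tolerance = 1e-9)
  expect_equal(attr(back, "labels"), attr(res, "labels"))
})
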