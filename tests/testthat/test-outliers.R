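# Brute-force set logic used as the oracle for the screen's set operations.
screen_oracle <- function(stats, fraction) {
  count <- max(1L, round(fraction * nrow(stats)))
  top <- function(v) {
    ord <- order(-v, stats$site_id, na.last = TRUE)
    stats$site_id[ord[seq_len(count)]]
  }
  sd_pre <- top(stats$sd_pre); sd_post <- top(stats$sd_post)
  scor_pre <- top(stats$scor_pre); scor_post <- top(stats$scor_post)
  conc <- intersect(sd_post, scor_post)
  list(post_concordant = sort(conc),
       candidates = sort(setdiff(conc, union(sd_pre, scor_pre))))
}

random_stats <- function(n, seed) {
  set.seed(seed)
  sid <- sprintf("cg%04d", sample.int(n))
  tab <- data.frame(site_id = sid, chrom = "1", pos = seq_len(n),
                    sd_pre = round(runif(n), 2), sd_post = round(runif(n), 2),
                    scor_pre = round(runif(n, -1, 1), 2),
                    scor_post = round(runif(n, -1, 1), 2),
                    n_pre = 100L, n_post = 50L,
                    npairs_pre = 30L, npairs_post = 20L,
                    stringsAsFactors = FALSE)
  tab$rank_sd_pre <- rank_descending(tab$sd_pre, sid)
  tab$rank_sd_post <- rank_descending(tab$sd_post, sid)
  tab$rank_scor_pre <- rank_descending(tab$scor_pre, sid)
  tab$rank_scor_post <- rank_descending(tab$scor_post, sid)
  class(tab) <- c("site_stat_table", "data.frame")
  tab
}

test_that("rank_descending ranks largest first with the documented tie rule", {
  expect_equal(unname(rank_descending(c(0.3, 0.1, 0.2), c("a", "b", "c"))),
               c(1L, 3L, 2L))
  # ties broken lexicographically
  expect_equal(unname(rank_descending(c(0.2, 0.2, 0.1), c("a", "b", "c"))),
               c(1L, 2L, 3L))
  expect_equal(unname(rank_descending(c(0.2, 0.2, 0.1), c("b", "a", "c"))),
               c(2L, 1L, 3L))
  # missing values rank last, by id among themselves
  r <- rank_descending(c(NA, 0.5, NA), c("z", "m", "a"))
  expect_equal(unname(r), c(3L, 1L, 2L))
  # always a permutation, even with heavy ties
  set.seed(3)
  v <- sample(c(0, 0.5, NA), 200, replace = TRUE)
  expect_setequal(rank_descending(v, sprintf("s%03d", 1:200)), 1:200)
})

test_that("select_outliers returns exactly the requested count", {
  sid <- sprintf("s%03d", 1:100)
  set.seed(4)
  v <- sample(c(0.1, 0.2, 0.3), 100, replace = TRUE)  # massive ties
  r <- rank_descending(v, sid)
  for (k in c(1L, 7L, 50L, 100L)) {
    expect_length(select_outliers(r, k), k)
  }
  expect_setequal(select_outliers(r, 100L), sid)
  expect_error(select_outliers(r, 0L), "outside")
  expect_error(select_outliers(r, 101L), "outside")
  # distinct values: top-k really are the k largest
  v2 <- seq(0.01, 1, length.out = 100)
  top2 <- select_outliers(rank_descending(v2, sid), 2L)
  expect_setequal(top2, sid[order(-v2)][1:2])
})

test_that("threshold_count applies the rounding rule", {
  expect_equal(threshold_count(0.001, 450000L), 450L)
  expect_equal(threshold_count(0.005, 5000L), 25L)
  expect_equal(threshold_count(0.001, 100L), 1L)  # floor of one site
  expect_error(threshold_count(0, 100L))
})

test_that("set operations follow the screen's definitions", {
  expect_equal(concordant_outliers(c("s1", "s2", "s3"), c("s2", "s3", "s4")),
               c("s2", "s3"))
  expect_length(concordant_outliers(c("a", "b"), c("c", "d")), 0L)
  expect_setequal(candidate_responsive_sites(c("s1", "s2", "s3"),
                                             sd_pre = "s2", scor_pre = "x"),
                  c("s1", "s3"))
  expect_length(candidate_responsive_sites(character(0), "a", "b"), 0L)

  to <- outlier_turnover(pre_set = c("a", "x", "y", "z"),
                         post_set = c("a", "b", "c", "d"))
  expect_equal(to$count, 3L)
  expect_equal(to$fraction, 0.75)
  expect_equal(outlier_turnover(letters[1:4], letters[1:4])$fraction, 0)
  expect_equal(outlier_turnover(letters[1:4], letters[5:8])$fraction, 1)
  expect_error(outlier_turnover(letters[1:4], character(0)), "undefined")
})

test_that("pipeline agrees with a brute-force set-logic oracle on random tables", {
  for (seed in 1:6) {
    stats <- random_stats(400, seed)
    for (f in c(0.005, 0.02, 0.05)) {
      got <- run_outlier_pipeline(stats, f, numeric(0))
      want <- screen_oracle(stats, f)
      expect_equal(got$post_concordant, want$post_concordant)
      expect_equal(got$candidates, want$candidates)
    }
  }
})

test_that("post-concordant sets grow and the pre-exclusion filter shrinks with the threshold", {
  for (seed in 1:4) {
    stats <- random_stats(500, seed)
    fracs <- c(0.004, 0.01, 0.03, 0.08)
    prev <- NULL
    prev_keep <- NULL
    all_ids <- stats$site_id
    for (f in fracs) {
      sel <- run_outlier_pipeline(stats, f, numeric(0))
      if (!is.null(prev)) {
        expect_true(all(prev %in% sel$post_concordant))
        keep <- setdiff(all_ids, union(sel$sd_pre, sel$scor_pre))
        expect_true(all(keep %in% prev_keep))
      }
      prev <- sel$post_concordant
      prev_keep <- setdiff(all_ids, union(sel$sd_pre, sel$scor_pre))
    }
  }
})

test_that("a planted post-only signal site is the sole candidate", {
  stats <- random_stats(1000, 42)
  # plant: argmax of both post distributions, median pre
  i <- 17L
  stats$sd_post[i] <- 2; stats$scor_post[i] <- 2
  stats$sd_pre[i] <- stats::median(stats$sd_pre)
  stats$scor_pre[i] <- stats::median(stats$scor_pre)
  sid <- stats$site_id
  stats$rank_sd_pre <- rank_descending(stats$sd_pre, sid)
  stats$rank_sd_post <- rank_descending(stats$sd_post, sid)
  stats$rank_scor_pre <- rank_descending(stats$scor_pre, sid)
  stats$rank_scor_post <- rank_descending(stats$scor_post, sid)
  rep <- run_outlier_pipeline(stats, 0.001, c(0.005, 0.01))
  expect_equal(rep$candidates, sid[i])
  expect_equal(rep$threshold_fraction, 0.001)
  expect_false(rep$fallback_used)
  expect_true(rep$table_rows$bold[rep$table_rows$site_id == sid[i]])
})

test_that("fallback thresholds are tried in order and recorded", {
  stats <- random_stats(1000, 43)
  sid <- stats$site_id
  # two sites just below the 0.1% cut in one post distribution each, so the
  # 0.1% sets are disjoint, but a shared site enters both at 0.5%
  stats$sd_post <- seq(1, 0.001, length.out = 1000)
  stats$scor_post <- rev(stats$sd_post)
  shared <- 3L  # rank 3 in sd_post, rank 998 in scor_post
  stats$scor_post[shared] <- sort(stats$scor_post, decreasing = TRUE)[4] + 1e-4
  stats$sd_pre <- stats::median(stats$sd_pre)  # no pre outlier structure
  stats$rank_sd_pre <- rank_descending(stats$sd_pre, sid)
  stats$rank_sd_post <- rank_descending(stats$sd_post, sid)
  stats$rank_scor_pre <- rank_descending(stats$scor_pre, sid)
  stats$rank_scor_post <- rank_descending(stats$scor_post, sid)
  rep <- run_outlier_pipeline(stats, 0.001, c(0.005, 0.01))
  expect_true(rep$fallback_used)
  expect_equal(rep$threshold_fraction, 0.005)
  expect_true(sid[shared] %in% rep$candidates)

  # no signal anywhere: thresholds exhaust and the report says so
  none <- random_stats(200, 44)
  none$scor_post <- rev(sort(none$sd_post))  # force disjoint small sets
  none$rank_scor_post <- rank_descending(none$scor_post, none$site_id)
  rep2 <- run_outlier_pipeline(none, 0.005, numeric(0))
  if (length(rep2$candidates) == 0L) expect_true(rep2$exhausted)
})

test_that("the screen is deterministic and the report writer round-trips", {
  stats <- random_stats(300, 7)
  a <- run_outlier_pipeline(stats, 0.01)
  b <- run_outlier_pipeline(stats, 0.01)
  expect_identical(a, b)
  dir <- withr::local_tempdir()
  write_outlier_report(a, dir)
  expect_true(file.exists(file.path(dir, "outlier_summary.json")))
  summ <- jsonlite::read_json(file.path(dir, "outlier_summary.json"))
  expect_equal(summ$threshold_count, a$threshold_count)
  expect_equal(summ$set_sizes$candidates, length(a$candidates))
  tab <- data.table::fread(file.path(dir, "concordant_table.tsv"))
  expect_equal(nrow(tab), length(a$post_concordant))
})
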