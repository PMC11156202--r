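test_that("per-tumor profiles compute percent monosomy and chromosome 3 index", {
  p <- profile_tumor(rep(2L, 100), "t1", min_cells = 50)
  expect_equal(p$pct_monosomy, 0); expect_equal(p$chr3_index, 2)
  p2 <- profile_tumor(c(rep(1L, 50), rep(2L, 50)), "t2", min_cells = 50)
  expect_equal(p2$pct_monosomy, 50); expect_equal(p2$chr3_index, 1.5)
  expect_warning(profile_tumor(rep(2L, 88), "small"), "88 cells")
  expect_error(profile_tumor(integer(0), "empty"), "empty")
  # 0-signal nuclei stay in the denominators by default, can be dropped
  counts <- c(0L, 1L, 1L, 2L)
  expect_equal(profile_tumor(counts, min_cells = 1)$chr3_index, 1)
  expect_equal(profile_tumor(counts, min_cells = 1)$pct_monosomy, 50)
  d <- profile_tumor(counts, min_cells = 1, drop_zero_signal = TRUE)
  expect_equal(d$n_cells, 3); expect_equal(d$chr3_index, 4 / 3)
  # >=3 signals never count as monosomy but fully enter the index
  p3 <- profile_tumor(c(1L, 3L), min_cells = 1)
  expect_equal(p3$pct_monosomy, 50); expect_equal(p3$chr3_index, 2)
})

test_that("cohort binarisation applies the >=median / <=median rules per cohort", {
  prof <- data.frame(tumor_id = paste0("t", 1:3), cohort_id = "A",
                     pct_monosomy = c(10, 40, 60), chr3_index = c(1.5, 1.8, 1.9))
  sc <- cohort_binarize(prof)
  expect_equal(sc$score_pct, c(0L, 1L, 1L))     # median 40, ties score 1
  expect_equal(sc$score_index, c(1L, 1L, 0L))   # median 1.8, ties score 1
  expect_equal(sc$combined_state, c("mixed", "monosomy", "mixed"))
  expect_error(cohort_binarize(data.frame(tumor_id = "x", cohort_id = "B",
                                          pct_monosomy = 1, chr3_index = 2)),
               "single tumor")
})

test_that("medians are computed separately per cohort", {
  prof <- data.frame(tumor_id = paste0("t", 1:6),
                     cohort_id = rep(c("A", "B"), each = 3),
                     pct_monosomy = c(10, 20, 30, 60, 70, 80),
                     chr3_index = c(1.9, 1.8, 1.7, 1.3, 1.2, 1.1))
  sc <- cohort_binarize(prof)
  expect_equal(sc$median_pct, rep(c(20, 70), each = 3))
  # the same profile can receive different calls in different cohort contexts
  probe <- data.frame(tumor_id = "p", cohort_id = NA, pct_monosomy = 45, chr3_index = 1.55)
  low <- rbind(prof[1:3, ], transform(probe, cohort_id = "A"))
  high <- rbind(prof[4:6, ], transform(probe, cohort_id = "B"))
  s_low <- cohort_binarize(low); s_high <- cohort_binarize(high)
  expect_equal(s_low$combined_state[4], "monosomy")
  expect_equal(s_high$combined_state[4], "disomy")
})

test_that("mixed-case resolution follows the 40% and mean-minus-SD rules", {
  # pct > 40 (strict) rescues a mixed tumor
  r1 <- resolve_call("mixed", 45, 1.9, 1.8, 0.2)
  expect_equal(r1$final, "monosomy3"); expect_match(r1$reason, "pct>40")
  # neither rule met: defaults to disomy
  r2 <- resolve_call("mixed", 30, 1.9, 1.8, 0.2)
  expect_equal(r2$final, "disomy3"); expect_equal(r2$reason, "mixed-default-disomy")
  # index <= mean - SD (inclusive) rescues
  r3 <- resolve_call("mixed", 30, 1.55, 1.8, 0.2)
  expect_equal(r3$final, "monosomy3"); expect_equal(r3$reason, "index<=mean-sd")
  expect_equal(resolve_call("mixed", 30, 1.6, 1.8, 0.2)$final, "monosomy3") # exactly at mean-SD
  expect_equal(resolve_call("mixed", 40, 1.9, 1.8, 0.2)$final, "disomy3")  # 40 is not > 40
  # concordant scores decide directly
  expect_equal(resolve_call("monosomy", 0, 2, 1.8, 0.2)$final, "monosomy3")
  expect_equal(resolve_call("disomy", 99, 1, 1.8, 0.2)$final, "disomy3")
})

test_that("with frozen cohort statistics the final call is monotone in the profile", {
  mu <- 1.8; sdv <- 0.2
  set.seed(21)
  for (i in 1:50) {
    pct <- runif(1, 0, 100); idx <- runif(1, 0.8, 2.2)
    state <- sample(c("mixed", "monosomy", "disomy"), 1)
    base <- resolve_call(state, pct, idx, mu, sdv)$final
    worse <- resolve_call(state, min(pct + runif(1, 0, 30), 100),
                          max(idx - runif(1, 0, 0.5), 0), mu, sdv)$final
    if (base == "monosomy3") expect_equal(worse, "monosomy3")
  }
})

test_that("every tumor receives exactly one call and the median split covers half", {
  fish <- generate_fish_counts(12, runif(12, 0, 0.9), dropout_p = 0.02,
                               n_cells = 250, seed = 5)
  calls <- suppressWarnings(chr3_classify(fish, min_cells = 203))
  expect_equal(nrow(calls), 12)
  expect_true(all(calls$final_call %in% c("disomy3", "monosomy3")))
  expect_gte(mean(calls$score_pct), 0.5)
  expect_gte(mean(calls$score_index), 0.5)
})

test_that("the classifier recovers planted labels on a well-separated cohort", {
  k <- 4
  truth <- rep(c(0.8, 0.05), each = k)
  fish <- generate_fish_counts(2 * k, truth, dropout_p = 0.05, n_cells = 500,
                               cohort_id = "clinic", seed = 17)
  calls <- chr3_classify(fish, min_cells = 203)
  expected <- ifelse(truth > 0.5, "monosomy3", "disomy3")
  got <- calls$final_call[match(attr(fish, "truth")$tumor_id, calls$tumor_id)]
  expect_identical(got, expected)
})
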