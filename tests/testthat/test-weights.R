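two_sample_set <- function(a_allocs, b_allocs, tree = two_domain_tree()) {
  allocation_set(tree, dplyr::bind_rows(alloc_tbl("a", a_allocs),
                                        alloc_tbl("b", b_allocs)))
}

domain_points <- function(xs) {
  lapply(stats::setNames(xs, paste0("r", seq_along(xs))), function(x) {
    list(root = c(d1 = x, d2 = 100 - x))
  })
}

test_that("compare_samples reproduces hand-computed Welch and rank-sum results", {
  allocs <- two_sample_set(domain_points(c(10, 20, 30)),
                           domain_points(c(40, 50, 60)))
  res <- compare_samples(allocs, "d1", "a", "b")
  # Welch on {10,20,30} vs {40,50,60}: t = -30/sqrt(200/3), df = 4
  expect_equal(res$t_statistic, -30 / sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(res$t_df, 4, tolerance = 1e-12)
  expect_equal(res$t_p, 2 * stats::pt(-30 / sqrt(200 / 3), 4),
               tolerance = 1e-12)
  expect_equal(res$t_p, 0.021, tolerance = 0.03)
  expect_equal(res$mean_diff, -30)
  # fully separated samples: U = 0 for the lower sample
  allocs2 <- two_sample_set(domain_points(c(1, 2, 3)),
                            domain_points(c(4, 5, 6)))
  expect_equal(compare_samples(allocs2, "d1", "a", "b")$ranksum_statistic, 0)
})

test_that("identical samples give zero difference and p near 1", {
  allocs <- two_sample_set(domain_points(c(10, 20, 30)),
                           domain_points(c(10, 20, 30)))
  res <- compare_samples(allocs, "d1", "a", "b")
  expect_equal(res$mean_diff, 0)
  expect_equal(res$ranksum_p, 1, tolerance = 1e-9)
  expect_false(res$degenerate)
})

test_that("degenerate zero-variance input reports p = 1 with a flag", {
  allocs <- two_sample_set(domain_points(c(30, 30)),
                           domain_points(c(30, 30)))
  res <- compare_samples(allocs, "d1", "a", "b")
  expect_true(res$degenerate)
  expect_equal(res$t_p, 1)
  expect_equal(res$ranksum_p, 1)
  expect_error(compare_samples(two_sample_set(domain_points(30),
                                              domain_points(c(1, 2))),
                               "d1", "a", "b"), ">= 2 respondents")
})

test_that("tests agree with an independent reference on random samples", {
  set.seed(11)
  for (rep in 1:100) {
    x <- sample(0:50, sample(3:12, 1), replace = TRUE)  # integer ties likely
    y <- sample(0:50, sample(3:12, 1), replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    allocs <- two_sample_set(domain_points(x), domain_points(y))
    res <- compare_samples(allocs, "d1", "a", "b")
    w <- welch_oracle(x, y)
    r <- ranksum_oracle(x, y)
    expect_equal(res$t_statistic, w$t, tolerance = 1e-8)
    expect_equal(res$t_p, w$p, tolerance = 1e-8)
    expect_equal(res$ranksum_statistic, r$U, tolerance = 1e-8)
    expect_equal(res$ranksum_p, r$p, tolerance = 1e-8)
  }
})

test_that("pool_means averages the two sample means and is affine in lambda", {
  sa <- tibble::tibble(node_id = "d1", group_id = "root", mean = 28.1)
  sb <- tibble::tibble(node_id = "d1", group_id = "root", mean = 23.7)
  expect_equal(pool_means(sa, sb, 0.5)$pooled, 25.9, tolerance = 1e-9)
  expect_equal(pool_means(sa, sb, 1)$pooled, 28.1)
  expect_equal(pool_means(sa, sb, 0.3)$pooled,
               pool_means(sb, sa, 0.7)$pooled)
  # equal means are a fixed point for any lambda
  expect_equal(pool_means(sa, sa, 0.123)$pooled, 28.1)
  sb2 <- tibble::tibble(node_id = "dX", group_id = "root", mean = 1)
  expect_error(pool_means(sa, sb2, 0.5), "different nodes")
})

test_that("round_preserving_sum matches hand-worked largest-remainder cases", {
  expect_identical(round_preserving_sum(c(25.9, 23.85, 19.25, 16.5, 14.5)),
                   c(26L, 24L, 19L, 17L, 14L))  # .5/.5 tie -> earlier item
  expect_identical(round_preserving_sum(c(50, 50)), c(50L, 50L))
  expect_identical(round_preserving_sum(c(33.33, 33.33, 33.34)),
                   c(33L, 33L, 34L))
  expect_error(round_preserving_sum(c(-1, 101)), "non-negative")
  expect_error(round_preserving_sum(c(40, 40)), "sum to 80")
})

test_that("largest-remainder output attains the minimal total deviation", {
  set.seed(23)
  for (rep in 1:500) {
    v <- random_percents(sample(2:5, 1))
    out <- round_preserving_sum(v)
    expect_identical(sum(out), 100L)
    expect_equal(sum(abs(out - v)), min_deviation_oracle(v),
                 tolerance = 1e-9)
    expect_true(all(abs(out - v) < 1))  # never off by a whole unit
  }
})

test_that("build_weight_table composes summaries, pooling, rounding, normalization", {
  allocs <- two_sample_set(domain_points(c(30, 30)), domain_points(c(30, 30)))
  wt <- build_weight_table(allocs)
  expect_equal(wt$pooled, c(30, 70))
  expect_identical(wt$rounded, c(30L, 70L))
  expect_equal(wt$normalized, c(0.3, 0.7))
  expect_identical(attr(wt, "samples"), c("a", "b"))
})

test_that("every sibling group of a realistic weight table sums exactly to 100", {
  tree <- load_criteria_config(default_criteria_path())
  profiles <- default_survey_profiles(tree)
  profiles$professionals$n <- 25L
  profiles$general_population$n <- 40L
  allocs <- simulate_allocations(tree, profiles, seed = 5)
  wt <- build_weight_table(allocs)
  expect_true(all(tapply(wt$rounded, wt$group_id, sum) == 100))
  expect_true(all(abs(tapply(wt$pooled, wt$group_id, sum) - 100) < 1e-9))
  expect_true(all(abs(tapply(wt$normalized, wt$group_id, sum) - 1) < 1e-12))
  # single-child groups normalize to exactly 1
  singles <- names(which(table(wt$group_id) == 1))
  expect_true(all(wt$normalized[wt$group_id %in% singles] == 1))
  # normalized fractions regenerate the integer weights
  expect_equal(wt$normalized * 100,
               as.numeric(wt$rounded) * 100 /
                 as.numeric(tapply(wt$rounded, wt$group_id, sum)[wt$group_id]))
})

test_that("naive rounding can break the budget and says so", {
  tree3 <- new_criteria_tree("t3", "1", nodes_tbl(
    node_id = c("d1", "d1.c1", "d2", "d2.c1", "d3", "d3.c1"),
    level = rep(c("domain", "criterion"), 3),
    parent_id = c(NA, "d1", NA, "d2", NA, "d3")))
  pts <- list(root = c(d1 = 16.5, d2 = 16.5, d3 = 67))
  allocs <- two_sample_set(list(r1 = pts, r2 = pts),
                           list(r1 = pts, r2 = pts), tree = tree3)
  expect_message(wt <- build_weight_table(allocs, rounding = "naive"),
                 "broke the 100 budget")
  expect_identical(sum(wt$rounded), 99L)  # 16.5 rounds half-to-even twice
  expect_identical(attr(wt, "broken_groups"), "root")
})

test_that("a published integer weight table can be imported directly", {
  tree <- two_domain_tree()
  wt <- weight_table_from_weights(
    tree, c(d1 = 60, "d1.c1" = 100, d2 = 40, "d2.c1" = 100))
  expect_equal(wt$normalized, c(0.6, 1, 0.4, 1))
  expect_error(weight_table_from_weights(tree, c(d1 = 60)), "missing")
})
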