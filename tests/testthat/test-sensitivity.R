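two_tech_setup <- function() {
  tree <- two_domain_tree()
  wt <- weight_table_from_weights(
    tree, c(d1 = 50, "d1.c1" = 100, d2 = 50, "d2.c1" = 100))
  sheets <- list(
    A = score_sheet("A", c("d1.c1" = 1.0, "d2.c1" = 0.2), tree),
    B = score_sheet("B", c("d1.c1" = 0.2, "d2.c1" = 0.8), tree))
  list(tree = tree, wt = wt, sheets = sheets)
}

test_that("one-way curves pass through the baseline value exactly", {
  s <- two_tech_setup()
  base_A <- aggregate_value(s$wt, s$sheets$A)$value
  curve <- one_way_weight_sensitivity(s$wt, s$sheets, "d1",
                                      grid = c(0, 25, 50, 75, 100))
  at_base <- curve$values[curve$values$grid == 50 &
                          curve$values$technology_id == "A", ]
  expect_identical(at_base$value, base_A)  # bit-exact, not just close
  expect_equal(curve$baseline, 50)
})

test_that("budget collapse to one domain leaves only that subtree's score", {
  s <- two_tech_setup()
  curve <- one_way_weight_sensitivity(s$wt, s$sheets, "d1", grid = c(100, 0))
  vA <- curve$values[curve$values$technology_id == "A", ]
  expect_equal(vA$value[vA$grid == 100], 1.0)  # d1 subtree score alone
  expect_equal(vA$value[vA$grid == 0], 0.2)    # d2 subtree score alone
})

test_that("the crossover sits at the closed-form linear intersection", {
  s <- two_tech_setup()
  # V_A(w) = 0.2 + 0.8 w, V_B(w) = 0.8 - 0.6 w (w = d1 fraction);
  # equal at w = 3/7
  curve <- one_way_weight_sensitivity(s$wt, s$sheets, "d1",
                                      grid = seq(0, 100, by = 10))
  expect_identical(nrow(curve$crossovers), 1L)
  expect_equal(curve$crossovers$weight, 300 / 7, tolerance = 1e-9)
  expect_identical(curve$crossovers$from, "B")
  expect_identical(curve$crossovers$to, "A")
})

test_that("one-way curves are linear in the varied weight", {
  set.seed(19)
  tree <- load_criteria_config(default_criteria_path())
  profiles <- default_survey_profiles(tree)
  profiles$professionals$n <- 15L
  profiles$general_population$n <- 15L
  allocs <- simulate_allocations(tree, profiles, seed = 19)
  wt <- build_weight_table(allocs)
  sheets <- list(score_sheet("T", random_scores(tree), tree))
  curve <- one_way_weight_sensitivity(wt, sheets, "d2", grid = c(10, 20, 30))
  v <- curve$values$value
  expect_equal(v[2], (v[1] + v[3]) / 2, tolerance = 1e-12)  # collinear
})

test_that("varying a node without siblings cannot be rescaled", {
  tree <- chain_tree()
  wt <- weight_table_from_weights(tree, c(d1 = 100, "d1.c1" = 100))
  sheets <- list(score_sheet("T", c("d1.c1" = 0.5), tree))
  expect_error(one_way_weight_sensitivity(wt, sheets, "d1", grid = 40),
               "zero total weight")
  expect_error(one_way_weight_sensitivity(wt, sheets, "d1.c1.s9", grid = 40),
               "unknown")
})

psa_alloc_fixture <- function(n_a = 10, n_b = 12, jitter = TRUE, seed = 3) {
  tree <- two_domain_tree()
  set.seed(seed)
  mk <- function(n, centre) {
    lapply(stats::setNames(seq_len(n), paste0("r", seq_len(n))), function(i) {
      d1 <- if (jitter) max(0, min(100, centre + sample(-10:10, 1))) else centre
      list(root = c(d1 = d1, d2 = 100 - d1),
           d1 = c("d1.c1" = 100), d2 = c("d2.c1" = 100))
    })
  }
  allocation_set(tree, dplyr::bind_rows(
    alloc_tbl("a", mk(n_a, 60)), alloc_tbl("b", mk(n_b, 40))))
}

test_that("rank acceptability is doubly stochastic and seed-deterministic", {
  allocs <- psa_alloc_fixture()
  tree <- two_domain_tree()
  sheets <- list(score_sheet("A", c("d1.c1" = 0.9, "d2.c1" = 0.1), tree),
                 score_sheet("B", c("d1.c1" = 0.4, "d2.c1" = 0.6), tree),
                 score_sheet("C", c("d1.c1" = 0.5, "d2.c1" = 0.5), tree))
  psa <- probabilistic_sensitivity(allocs, sheets, n_draws = 200, seed = 42)
  expect_true(all(abs(rowSums(psa$acceptability) - 1) < 1e-9))
  expect_true(all(abs(colSums(psa$acceptability) - 1) < 1e-9))
  again <- probabilistic_sensitivity(allocs, sheets, n_draws = 200, seed = 42)
  expect_identical(psa, again)
  other <- probabilistic_sensitivity(allocs, sheets, n_draws = 200, seed = 43)
  expect_false(identical(psa$acceptability, other$acceptability))
})

test_that("a single technology always holds rank one", {
  allocs <- psa_alloc_fixture()
  tree <- two_domain_tree()
  sheets <- list(score_sheet("A", c("d1.c1" = 0.9, "d2.c1" = 0.1), tree))
  psa <- probabilistic_sensitivity(allocs, sheets, n_draws = 25, seed = 1)
  expect_equal(unname(psa$acceptability["A", "1"]), 1)
})

test_that("zero-variance allocations give a degenerate, zero-width interval", {
  allocs <- psa_alloc_fixture(jitter = FALSE)
  tree <- two_domain_tree()
  sheets <- list(score_sheet("A", c("d1.c1" = 0.9, "d2.c1" = 0.1), tree),
                 score_sheet("B", c("d1.c1" = 0.4, "d2.c1" = 0.6), tree))
  psa <- probabilistic_sensitivity(allocs, sheets, n_draws = 50, seed = 8)
  expect_equal(psa$value_summary$q025, psa$value_summary$q975)
  expect_true(all(psa$acceptability %in% c(0, 1)))
})

test_that("clearly separated technologies saturate top-rank acceptability", {
  allocs <- psa_alloc_fixture()
  tree <- two_domain_tree()
  sheets <- list(score_sheet("good", c("d1.c1" = 0.95, "d2.c1" = 0.9), tree),
                 score_sheet("poor", c("d1.c1" = 0.1, "d2.c1" = 0.15), tree))
  psa <- probabilistic_sensitivity(allocs, sheets, n_draws = 500, seed = 21)
  expect_equal(unname(psa$acceptability["good", "1"]), 1)
})

test_that("the Dirichlet route mirrors the bootstrap contract", {
  tree <- two_domain_tree()
  profs <- list(
    sample_profile("a", n = 30, targets = list(
      root = c(d1 = 60, d2 = 40), d1 = c("d1.c1" = 100),
      d2 = c("d2.c1" = 100)), concentration = 40),
    sample_profile("b", n = 50, targets = list(
      root = c(d1 = 40, d2 = 60), d1 = c("d1.c1" = 100),
      d2 = c("d2.c1" = 100)), concentration = 15))
  sheets <- list(score_sheet("A", c("d1.c1" = 0.9, "d2.c1" = 0.1), tree),
                 score_sheet("B", c("d1.c1" = 0.4, "d2.c1" = 0.6), tree))
  psa <- probabilistic_sensitivity(profs, sheets, n_draws = 150, seed = 11)
  expect_identical(psa$method, "dirichlet")
  expect_true(all(abs(rowSums(psa$acceptability) - 1) < 1e-9))
  expect_true(all(abs(colSums(psa$acceptability) - 1) < 1e-9))
  expect_identical(psa,
                   probabilistic_sensitivity(profs, sheets, 150, seed = 11))
  expect_error(probabilistic_sensitivity(psa_alloc_fixture(n_a = 1), sheets,
                                         10, 1), ">= 2 respondents")
})
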