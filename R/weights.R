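#' From survey allocations to the framework's weight table
#'
#' The final weights of the framework are the equal-weighted average of the
#' mean weights from the two respondent samples, rounded to integers that
#' still sum to 100 within every sibling group, and normalized to fractions
#' summing to one per group for use in the value function. The two samples'
#' weights are compared node-by-node with Welch's t-test and the
#' Mann-Whitney-Wilcoxon rank-sum test.
#'
#' @name weight_table
NULL

#' Compare two samples' allocations at one node
#'
#' Two-sided unequal-variance (Welch) t-test and Mann-Whitney-Wilcoxon
#' rank-sum test (normal approximation with tie correction, no continuity
#' correction) on the points the two samples allocated to one node.
#'
#' @param allocs An `allocation_set`.
#' @param node_id Node whose allocations are compared.
#' @param sample_a,sample_b The two sample ids; the mean difference is
#'   `sample_a - sample_b`.
#' @return One-row tibble: `node_id`, `n_a`, `n_b`, `mean_diff`,
#'   `t_statistic`, `t_df`, `t_p`, `ranksum_statistic` (the Mann-Whitney U
#'   of `sample_a`), `ranksum_p`, `degenerate` (both samples constant).
#' @export
compare_samples <- function(allocs, node_id, sample_a, sample_b) {
  rec <- allocs$records
  xa <- rec$points[rec$node_id == node_id & rec$sample_id == sample_a]
  xb <- rec$points[rec$node_id == node_id & rec$sample_id == sample_b]
  if (length(xa) < 2 || length(xb) < 2) {
    stop("compare_samples needs >= 2 respondents per sample at node ",
         node_id, call. = FALSE)
  }
  degenerate <- stats::sd(xa) == 0 && stats::sd(xb) == 0
  if (degenerate) {
    same <- mean(xa) == mean(xb)
    tt <- list(statistic = c(t = if (same) 0 else Inf * sign(mean(xa) - mean(xb))),
               parameter = c(df = NA_real_),
               p.value = if (same) 1 else 0)
  } else {
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(xa, xb, exact = FALSE, correct = FALSE))
  ranksum_p <- if (degenerate && mean(xa) == mean(xb)) 1 else
    if (is.nan(wt$p.value)) 1 else wt$p.value
  tibble::tibble(
    node_id = node_id, n_a = length(xa), n_b = length(xb),
    mean_diff = mean(xa) - mean(xb),
    t_statistic = unname(tt$statistic), t_df = unname(tt$parameter),
    t_p = tt$p.value,
    ranksum_statistic = unname(wt$statistic), ranksum_p = ranksum_p,
    degenerate = degenerate)
}

#' Compare two samples at every node of the tree
#'
#' @inheritParams compare_samples
#' @param p_adjust Multiple-testing adjustment applied to each family of
#'   p-values (`"none"` by default, matching the practice of reporting raw
#'   per-item p-values; `"holm"` available).
#' @return Tibble with one [compare_samples()] row per node answered in both
#'   samples, plus `label` and `level`.
#' @export
compare_all_nodes <- function(allocs, sample_a, sample_b,
                              p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  rec <- allocs$records
  ids <- intersect(allocs$tree$nodes$node_id,
                   intersect(rec$node_id[rec$sample_id == sample_a],
                             rec$node_id[rec$sample_id == sample_b]))
  out <- dplyr::bind_rows(lapply(ids, function(id) {
    compare_samples(allocs, id, sample_a, sample_b)
  }))
  if (p_adjust != "none") {
    out$t_p <- stats::p.adjust(out$t_p, method = p_adjust)
    out$ranksum_p <- stats::p.adjust(out$ranksum_p, method = p_adjust)
  }
  out$label <- node_label(allocs$tree, out$node_id)
  out$level <- node_level(allocs$tree, out$node_id)
  out
}

#' Pool the mean weights of two samples
#'
#' Equal-weighted (by default) convex combination of the two samples' mean
#' weights per node: `pooled = lambda * mean_a + (1 - lambda) * mean_b`.
#' Because each sample's sibling means sum to 100, so do the pooled values.
#'
#' @param summary_a,summary_b [summarize_sample()] outputs over the same
#'   node set.
#' @param lambda Weight on `summary_a`, in \[0, 1\]; 0.5 gives the
#'   equal-weighted average of the two sample means.
#' @return Tibble `node_id`, `group_id`, `pooled` in `summary_a`'s order.
#' @export
pool_means <- function(summary_a, summary_b, lambda = 0.5) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  only_a <- setdiff(summary_a$node_id, summary_b$node_id)
  only_b <- setdiff(summary_b$node_id, summary_a$node_id)
  if (length(only_a) || length(only_b)) {
    stop("pool_means: summaries cover different nodes; only in A: {",
         paste(only_a, collapse = ", "), "}; only in B: {",
         paste(only_b, collapse = ", "), "}", call. = FALSE)
  }
  mb <- summary_b$mean[match(summary_a$node_id, summary_b$node_id)]
  tibble::tibble(node_id = summary_a$node_id, group_id = summary_a$group_id,
                 pooled = lambda * summary_a$mean + (1 - lambda) * mb)
}

#' Round percentages to integers that keep their sum
#'
#' Largest-remainder (Hamilton) rounding: each value is floored, then the
#' leftover units are given to the values with the largest fractional parts,
#' ties broken by position. Among all integer vectors with the required sum,
#' the result minimizes the total absolute deviation from the input.
#'
#' @param values Non-negative numeric vector summing to `total` (tolerance
#'   1e-6).
#' @param total Target integer sum (default 100).
#' @return Integer vector of `length(values)` summing to exactly `total`.
#' @export
#' @examples
#' round_preserving_sum(c(25.9, 23.85, 19.25, 16.5, 14.5))
round_preserving_sum <- function(values, total = 100L) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("round_preserving_sum: values must be finite and non-negative",
         call. = FALSE)
  }
  if (abs(sum(values) - total) > 1e-6) {
    stop("round_preserving_sum: values sum to ", sum(values), ", not ",
         total, call. = FALSE)
  }
  lo <- floor(values + SUM_TOL)  # guard against 26 stored as 25.999...
  k <- as.integer(round(total - sum(lo)))
  rem <- values - lo
  out <- lo
  if (k > 0) {
    gets <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(k)]
    out[gets] <- out[gets] + 1
  }
  as.integer(out)
}

#' Build the framework weight table from a two-sample allocation set
#'
#' Composes the weighting pipeline: per-sample summaries, pooling of means
#' with weight `lambda` on `sample_a`, per-sibling-group integer rounding,
#' and normalization to fractions. With the default largest-remainder
#' rounding every sibling group's integers sum to exactly 100; `"naive"`
#' nearest-integer rounding may break that sum (groups where it does are
#' recorded in the `broken_groups` attribute and a message).
#'
#' @param allocs An `allocation_set` containing exactly two samples (or name
#'   them via `samples`).
#' @param lambda Weight on the first sample's means (default 0.5, the
#'   equal-weighted average).
#' @param rounding `"largest-remainder"` (default) or `"naive"`.
#' @param normalize Base of the normalized fractions: the `"rounded"`
#'   integer weights (default; the published presentation) or the unrounded
#'   `"pooled"` percents.
#' @param samples Optional length-2 character vector `(sample_a, sample_b)`;
#'   defaults to the set's samples in sorted order.
#' @return A `weight_table`: tibble with per-node columns `node_id`, `label`,
#'   `level`, `group_id`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `pooled`, `rounded`, `normalized`; attributes `tree`, `lambda`,
#'   `samples`, `rounding`, `normalize`.
#' @export
build_weight_table <- function(allocs, lambda = 0.5,
                               rounding = c("largest-remainder", "naive"),
                               normalize = c("rounded", "pooled"),
                               samples = NULL) {
  rounding <- match.arg(rounding)
  normalize <- match.arg(normalize)
  if (is.null(samples)) samples <- allocs$samples
  if (length(samples) != 2) {
    stop("build_weight_table needs exactly two samples, got: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  sa <- summarize_sample(allocs, samples[1])
  sb <- summarize_sample(allocs, samples[2])
  pooled <- pool_means(sa, sb, lambda)
  tab <- tibble::tibble(
    node_id = pooled$node_id,
    label = node_label(allocs$tree, pooled$node_id),
    level = node_level(allocs$tree, pooled$node_id),
    group_id = pooled$group_id,
    mean_a = sa$mean, sd_a = sa$sd, n_a = sa$n,
    mean_b = sb$mean[match(pooled$node_id, sb$node_id)],
    sd_b = sb$sd[match(pooled$node_id, sb$node_id)],
    n_b = sb$n[match(pooled$node_id, sb$node_id)],
    pooled = pooled$pooled)
  tab <- tab[order(match(tab$node_id, allocs$tree$nodes$node_id)), ]
  tab <- dplyr::group_by(tab, .data$group_id) |>
    dplyr::mutate(rounded = if (rounding == "largest-remainder")
      round_preserving_sum(.data$pooled) else as.integer(round(.data$pooled))) |>
    dplyr::ungroup()
  broken <- tab |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(s = sum(.data$rounded), .groups = "drop") |>
    dplyr::filter(.data$s != 100)
  if (nrow(broken) > 0) {
    message("naive rounding broke the 100 budget in group(s): ",
            paste0(broken$group_id, " (sum ", broken$s, ")",
                   collapse = ", "))
  }
  base <- if (normalize == "rounded") tab$rounded else tab$pooled
  tab$normalized <- stats::ave(as.numeric(base), tab$group_id,
                               FUN = function(v) v / sum(v))
  tab <- tab[order(match(tab$node_id, allocs$tree$nodes$node_id)), ]
  new_weight_table(tab, tree = allocs$tree, lambda = lambda,
                   samples = samples, rounding = rounding,
                   normalize = normalize,
                   broken_groups = broken$group_id)
}

new_weight_table <- function(tab, tree, lambda, samples, rounding,
                             normalize, broken_groups = character()) {
  structure(tab, tree = tree, lambda = lambda, samples = samples,
            rounding = rounding, normalize = normalize,
            broken_groups = broken_groups,
            class = c("weight_table", class(tab)))
}

#' Build a weight table directly from published integer weights
#'
#' For users who already have a published table of integer percent weights
#' and want to skip elicitation entirely.
#'
#' @param tree A valid `criteria_tree`.
#' @param weights Named numeric vector of percent weights, one entry per
#'   node of the tree; each sibling group should sum to 100.
#' @return A `weight_table` with `pooled = rounded = weights` and
#'   `normalized = weights / (group sum)`.
#' @export
weight_table_from_weights <- function(tree, weights) {
  ids <- tree$nodes$node_id
  missing <- setdiff(ids, names(weights))
  if (length(missing) > 0) {
    stop("weights missing for node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- as.numeric(weights[ids])
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  tab <- tibble::tibble(
    node_id = ids, label = tree$nodes$label, level = tree$nodes$level,
    group_id = node_group(tree, ids),
    mean_a = NA_real_, sd_a = NA_real_, n_a = NA_integer_,
    mean_b = NA_real_, sd_b = NA_real_, n_b = NA_integer_,
    pooled = w, rounded = as.integer(round(w)))
  tab$normalized <- stats::ave(w, tab$group_id, FUN = function(v) v / sum(v))
  new_weight_table(tab, tree = tree, lambda = NA_real_,
                   samples = character(), rounding = "as-given",
                   normalize = "pooled")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf(
    "<weight_table> %d nodes, lambda = %s, rounding = %s, normalize = %s\n",
    nrow(x), format(attr(x, "lambda")), attr(x, "rounding"),
    attr(x, "normalize")))
  NextMethod()
}
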