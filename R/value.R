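#' Additive multi-attribute value of a technology
#'
#' Once a technology has been scored on every leaf of the criteria tree,
#' its composite value is the nested weighted sum
#' \deqn{V = \sum_i \hat w_i \sum_j \hat w_{ij} \sum_k \hat w_{ijk}\, s_{ijk}}
#' where \eqn{i, j, k} index domains, criteria and subcriteria, the
#' \eqn{\hat w} are the sibling-normalized weights (summing to one within
#' each group) and \eqn{s} are the leaf scores; for a criterion without
#' subcriteria the inner sum collapses to the criterion's own score. Scores
#' are attached at leaves only -- a domain's or criterion's "score" is the
#' weighted sum of its descendants, the standard additive multi-attribute
#' value reading of the nested formula (scoring internal nodes independently
#' would double-count).
#'
#' @name value_function
NULL

#' Construct a score sheet for one technology
#'
#' @param technology_id Identifier of the technology scored.
#' @param scores Named numeric vector: one score per leaf node id of `tree`.
#' @param tree The `criteria_tree` the scores refer to.
#' @param scale Length-2 numeric, the declared score range (default
#'   `c(0, 1)`). No rescaling is applied; scores outside the range are an
#'   error.
#' @return A `score_sheet`.
#' @export
score_sheet <- function(technology_id, scores, tree, scale = c(0, 1)) {
  stopifnot(is.numeric(scale), length(scale) == 2, scale[1] < scale[2])
  leaves <- tree_leaves(tree)
  missing <- setdiff(leaves, names(scores))
  if (length(missing) > 0) {
    stop("score sheet '", technology_id, "' lacks scores for leaf/leaves: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- as.numeric(scores[leaves])
  if (any(!is.finite(s)) || any(s < scale[1]) || any(s > scale[2])) {
    stop("score sheet '", technology_id, "' has scores outside the declared ",
         "scale [", scale[1], ", ", scale[2], "]", call. = FALSE)
  }
  structure(list(technology_id = technology_id,
                 scores = stats::setNames(s, leaves), scale = scale),
            class = "score_sheet")
}

#' Read technology score sheets from CSV
#'
#' CSV columns `technology_id,node_id,score`; one row per (technology, leaf).
#'
#' @param path CSV file path.
#' @param tree The `criteria_tree` the scores refer to.
#' @param scale Declared score range applied to every sheet.
#' @return Named list of `score_sheet` objects, one per technology, in
#'   first-appearance order.
#' @export
read_score_sheets <- function(path, tree, scale = c(0, 1)) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           technology_id = readr::col_character(),
                           node_id = readr::col_character(),
                           score = readr::col_double()))
  techs <- unique(tab$technology_id)
  stats::setNames(lapply(techs, function(tid) {
    rows <- tab[tab$technology_id == tid, ]
    score_sheet(tid, stats::setNames(rows$score, rows$node_id), tree, scale)
  }), techs)
}

#' Effective weight of each leaf
#'
#' The effective weight of a leaf is the product of the normalized weights
#' along its path: domain x criterion (x subcriterion when present). A
#' criterion without subcriteria carries an implicit subcriterion weight of
#' one. Because the normalized weights sum to one within every sibling
#' group, the effective leaf weights sum to one over the whole tree.
#'
#' @param weights A `weight_table`.
#' @return Named numeric vector over leaf ids, in document order.
#' @export
effective_leaf_weights <- function(weights) {
  tree <- attr(weights, "tree")
  paths <- leaf_paths(tree)
  w <- stats::setNames(weights$normalized, weights$node_id)
  ew <- w[paths$domain_id] * w[paths$criterion_id]
  has_sub <- !is.na(paths$subcriterion_id)
  ew[has_sub] <- ew[has_sub] * w[paths$subcriterion_id[has_sub]]
  stats::setNames(as.numeric(ew), paths$leaf_id)
}

#' Composite value of a technology
#'
#' @param weights A `weight_table` over the same tree as `sheet`.
#' @param sheet A `score_sheet`.
#' @return A `value_result`: list with `technology_id`, `value` (on the
#'   sheet's score scale), `domain_contributions` (named; sums to `value`),
#'   `leaf_weights` (the effective weights used), `scale`.
#' @export
aggregate_value <- function(weights, sheet) {
  stopifnot(inherits(weights, "weight_table"), inherits(sheet, "score_sheet"))
  tree <- attr(weights, "tree")
  paths <- leaf_paths(tree)
  missing <- setdiff(paths$leaf_id, names(sheet$scores))
  if (length(missing) > 0) {
    stop("score sheet '", sheet$technology_id, "' lacks scores for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ew <- effective_leaf_weights(weights)
  s <- sheet$scores[names(ew)]
  contrib <- as.numeric(ew) * as.numeric(s)
  by_domain <- vapply(split(contrib, paths$domain_id)[unique(paths$domain_id)],
                      sum, numeric(1))
  structure(list(technology_id = sheet$technology_id, value = sum(contrib),
                 domain_contributions = by_domain, leaf_weights = ew,
                 scale = sheet$scale),
            class = "value_result")
}

#' @export
print.value_result <- function(x, ...) {
  cat(sprintf("<value_result> %s: V = %.4f on [%g, %g]\n", x$technology_id,
              x$value, x$scale[1], x$scale[2]))
  for (d in names(x$domain_contributions)) {
    cat(sprintf("  %-8s %.4f\n", d, x$domain_contributions[[d]]))
  }
  invisible(x)
}

#' Rank technologies by composite value
#'
#' Descending by value; ties share a rank (competition / "1224" ranking)
#' and are flagged.
#'
#' @param results List of `value_result` objects on the same scale.
#' @return Tibble `technology_id`, `value`, `rank`, `tied`, sorted by rank
#'   then input order.
#' @export
rank_technologies <- function(results) {
  stopifnot(length(results) >= 1)
  scales <- unique(lapply(results, function(r) r$scale))
  if (length(scales) != 1) {
    stop("rank_technologies: results are on mixed score scales",
         call. = FALSE)
  }
  v <- vapply(results, function(r) r$value, numeric(1))
  out <- tibble::tibble(
    technology_id = vapply(results, function(r) r$technology_id,
                           character(1)),
    value = v,
    rank = as.integer(rank(-v, ties.method = "min")))
  out$tied <- out$rank %in% out$rank[duplicated(out$rank)]
  out[order(out$rank), ]
}
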