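#' Sensitivity of values and rankings to weight uncertainty
#'
#' Two complementary analyses: deterministic \emph{one-way} reweighting,
#' where a single domain or criterion weight sweeps a grid while its
#' siblings are rescaled proportionally to keep the 100-point budget, and
#' \emph{probabilistic} analysis, where the whole weighting pipeline is
#' re-run over resampled respondents (stratified bootstrap) or over draws
#' from fitted Dirichlet profiles, yielding rank-acceptability fractions
#' and percentile intervals for each technology's composite value.
#'
#' @name sensitivity
NULL

#' One-way weight sensitivity
#'
#' Sweeps one domain's or criterion's percent weight over a grid. At each
#' grid value the varied node takes that percent of its sibling group and
#' the siblings keep their relative proportions, rescaled so the group
#' still sums to 100; the composite value of every technology is then
#' recomputed. The value curves are linear in the varied weight, so the
#' top-ranked technology can only change at crossover points, which are
#' located by linear interpolation between grid neighbours.
#'
#' @param weights A `weight_table`.
#' @param sheets List of `score_sheet`s on a common scale.
#' @param node_id A domain or criterion node to vary.
#' @param grid Numeric vector of percent weights in \[0, 100\].
#' @return A `sensitivity_curve`: list with `node_id`, `baseline` (the
#'   node's current percent weight), `values` (tibble `grid`,
#'   `technology_id`, `value`), and `crossovers` (tibble `weight`,
#'   `from`, `to`).
#' @export
one_way_weight_sensitivity <- function(weights, sheets, node_id, grid) {
  tree <- attr(weights, "tree")
  lev <- node_level(tree, node_id)
  if (is.na(lev) || !lev %in% c("domain", "criterion")) {
    stop("one-way sensitivity varies a domain or criterion; '", node_id,
         "' is ", if (is.na(lev)) "unknown" else paste0("a ", lev),
         call. = FALSE)
  }
  stopifnot(is.numeric(grid), length(grid) >= 1,
            all(grid >= 0), all(grid <= 100))
  w0 <- weights$normalized[weights$node_id == node_id]
  in_group <- weights$group_id == weights$group_id[weights$node_id == node_id]
  siblings <- in_group & weights$node_id != node_id
  sib_total <- sum(weights$normalized[siblings])
  rows <- lapply(grid, function(g) {
    wt <- weights
    if (g / 100 != w0) {  # baseline grid point: reuse the table bit-for-bit
      if (sib_total == 0) {
        stop("cannot rescale: node '", node_id,
             "' has siblings with zero total weight", call. = FALSE)
      }
      wt$normalized[siblings] <-
        wt$normalized[siblings] * (1 - g / 100) / sib_total
      wt$normalized[wt$node_id == node_id] <- g / 100
    }
    dplyr::bind_rows(lapply(sheets, function(sh) {
      tibble::tibble(grid = g, technology_id = sh$technology_id,
                     value = aggregate_value(wt, sh)$value)
    }))
  })
  values <- dplyr::bind_rows(rows)
  structure(list(node_id = node_id, baseline = w0 * 100, values = values,
                 crossovers = find_crossovers(values)),
            class = "sensitivity_curve")
}

# top-technology changes between adjacent grid points, located by linear
# interpolation of the two curves involved (valid because V is linear in g)
find_crossovers <- function(values) {
  grid <- sort(unique(values$grid))
  top_at <- function(g) {
    rows <- values[values$grid == g, ]
    rows$technology_id[which.max(rows$value)]
  }
  out <- list()
  for (i in seq_len(length(grid) - 1)) {
    g1 <- grid[i]; g2 <- grid[i + 1]
    t1 <- top_at(g1); t2 <- top_at(g2)
    if (t1 == t2) next
    v <- function(tech, g) values$value[values$grid == g &
                                        values$technology_id == tech]
    d1 <- v(t1, g1) - v(t2, g1)
    d2 <- v(t1, g2) - v(t2, g2)
    w <- if (d1 == d2) g1 else g1 + d1 / (d1 - d2) * (g2 - g1)
    out[[length(out) + 1L]] <- tibble::tibble(weight = w, from = t1, to = t2)
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(weight = numeric(), from = character(), to = character())
}

#' Probabilistic sensitivity analysis of values and rankings
#'
#' Re-runs the weighting pipeline under resampled weights and tabulates how
#' often each technology attains each rank. With an `allocation_set`, each
#' draw resamples respondents with replacement within each sample
#' (stratified bootstrap), recomputes per-node means, pools them with the
#' same `lambda`, and normalizes the \emph{unrounded} pooled weights
#' (integer rounding is a presentation step and its noise would swamp small
#' groups). With a list of `sample_profile`s (e.g. from
#' [moment_match_profiles()]), each draw samples each group's mean weight
#' vector from a Dirichlet whose concentration is scaled by the profile's
#' `n`, approximating the sampling distribution of a mean of `n`
#' respondents. Ranks within draws break ties by document order so that
#' rank fractions are doubly stochastic.
#'
#' @param x An `allocation_set` with two samples, or a list of two
#'   `sample_profile`s.
#' @param sheets List of `score_sheet`s on a common scale.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param lambda Pooling weight on the first sample (default 0.5).
#' @param samples Optional length-2 sample order; defaults to sorted.
#' @return A `rank_acceptability`: list with `n_draws`, `seed`, `lambda`,
#'   `method`, `acceptability` (matrix technology x rank of rank
#'   fractions), `value_summary` (tibble `technology_id`, `mean`, `q025`,
#'   `q975`).
#' @export
probabilistic_sensitivity <- function(x, sheets, n_draws, seed,
                                      lambda = 0.5, samples = NULL) {
  stopifnot(n_draws >= 1, length(sheets) >= 1)
  if (inherits(x, "allocation_set")) {
    psa_bootstrap(x, sheets, n_draws, seed, lambda, samples)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "sample_profile"))) {
    psa_dirichlet(x, sheets, n_draws, seed, lambda)
  } else {
    stop("x must be an allocation_set or a list of sample_profiles",
         call. = FALSE)
  }
}

psa_bootstrap <- function(allocs, sheets, n_draws, seed, lambda, samples) {
  if (is.null(samples)) samples <- allocs$samples
  if (length(samples) != 2) {
    stop("probabilistic sensitivity needs exactly two samples",
         call. = FALSE)
  }
  tree <- allocs$tree
  node_ids <- tree$nodes$node_id
  # per sample: respondent x node matrix of points (NA where unanswered)
  mats <- lapply(samples, function(sid) {
    rec <- allocs$records[allocs$records$sample_id == sid, ]
    resp <- unique(rec$respondent_id)
    if (length(resp) < 2) {
      stop("probabilistic sensitivity needs >= 2 respondents in sample '",
           sid, "'", call. = FALSE)
    }
    m <- matrix(NA_real_, nrow = length(resp), ncol = length(node_ids),
                dimnames = list(resp, node_ids))
    m[cbind(match(rec$respondent_id, resp),
            match(rec$node_id, node_ids))] <- rec$points
    m
  })
  group_of <- node_group(tree, node_ids)
  draw_means <- function() {
    pooled <- lambda *
      colMeans(mats[[1]][sample.int(nrow(mats[[1]]), replace = TRUE), ,
                         drop = FALSE], na.rm = TRUE) +
      (1 - lambda) *
      colMeans(mats[[2]][sample.int(nrow(mats[[2]]), replace = TRUE), ,
                         drop = FALSE], na.rm = TRUE)
    normalize_by_group(pooled, group_of)
  }
  psa_engine(tree, sheets, n_draws, seed, draw_means,
             method = "stratified-bootstrap", lambda = lambda)
}

psa_dirichlet <- function(profiles, sheets, n_draws, seed, lambda) {
  if (length(profiles) != 2) {
    stop("probabilistic sensitivity needs exactly two profiles",
         call. = FALSE)
  }
  draw_profile_means <- function(p) {
    unlist(lapply(names(p$targets), function(gid) {
      m <- profile_implied_means(p, gid) / 100
      alpha <- p$concentration[[gid]] * m * p$n
      stats::setNames(draw_dirichlet(alpha), names(m))
    }))
  }
  draw_means <- function() {
    w <- lambda * draw_profile_means(profiles[[1]]) +
      (1 - lambda) * draw_profile_means(profiles[[2]])
    w  # already normalized within groups (fractions summing to 1)
  }
  psa_engine(tree = NULL, sheets, n_draws, seed, draw_means,
             method = "dirichlet", lambda = lambda)
}

normalize_by_group <- function(x, group_of) {
  sums <- tapply(x, group_of, sum)
  x / as.numeric(sums[group_of])
}

# shared Monte-Carlo loop: draw normalized node weights, form effective
# leaf weights, score every sheet, rank with document-order tie-breaking
psa_engine <- function(tree, sheets, n_draws, seed, draw_means, method,
                       lambda) {
  scales <- unique(lapply(sheets, function(s) s$scale))
  if (length(scales) != 1) {
    stop("score sheets are on mixed scales", call. = FALSE)
  }
  paths <- if (!is.null(tree)) leaf_paths(tree) else NULL
  leaf_weights_from <- function(w) {
    if (is.null(paths)) {
      # profile route: leaves are whatever the sheets score; the product
      # structure is recovered from id nesting d / d.c / d.c.s
      leaves <- names(sheets[[1]]$scores)
      vapply(leaves, function(id) {
        parts <- strsplit(id, ".", fixed = TRUE)[[1]]
        anc <- vapply(seq_along(parts), function(k) {
          paste(parts[seq_len(k)], collapse = ".")
        }, character(1))
        prod(w[anc])
      }, numeric(1))
    } else {
      ew <- w[paths$domain_id] * w[paths$criterion_id]
      has_sub <- !is.na(paths$subcriterion_id)
      ew[has_sub] <- ew[has_sub] * w[paths$subcriterion_id[has_sub]]
      stats::setNames(as.numeric(ew), paths$leaf_id)
    }
  }
  techs <- vapply(sheets, function(s) s$technology_id, character(1))
  score_mat <- do.call(cbind, lapply(sheets, function(s) s$scores))
  n_tech <- length(techs)
  with_seed(seed, {
    vals <- matrix(NA_real_, n_draws, n_tech,
                   dimnames = list(NULL, techs))
    rank_counts <- matrix(0L, n_tech, n_tech,
                          dimnames = list(techs, seq_len(n_tech)))
    for (d in seq_len(n_draws)) {
      ew <- leaf_weights_from(draw_means())
      v <- as.numeric(ew %*% score_mat[names(ew), , drop = FALSE])
      vals[d, ] <- v
      rk <- rank(-v, ties.method = "first")
      rank_counts[cbind(seq_len(n_tech), rk)] <-
        rank_counts[cbind(seq_len(n_tech), rk)] + 1L
    }
    structure(list(
      n_draws = n_draws, seed = seed, lambda = lambda, method = method,
      acceptability = rank_counts / n_draws,
      value_summary = tibble::tibble(
        technology_id = techs,
        mean = colMeans(vals),
        q025 = apply(vals, 2, stats::quantile, 0.025),
        q975 = apply(vals, 2, stats::quantile, 0.975))),
      class = "rank_acceptability")
  })
}

#' @export
print.rank_acceptability <- function(x, ...) {
  cat(sprintf("<rank_acceptability> %s, %d draws, seed %d\n", x$method,
              x$n_draws, x$seed))
  print(round(x$acceptability, 3))
  invisible(x)
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve> node %s, baseline %.2f%%, %d grid points\n",
              x$node_id, x$baseline, length(unique(x$values$grid))))
  if (nrow(x$crossovers) > 0) {
    cat("crossovers:\n"); print(x$crossovers)
  }
  invisible(x)
}
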