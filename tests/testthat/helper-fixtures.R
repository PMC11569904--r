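# Fixtures and independent oracles shared across the test files.

nodes_tbl <- function(node_id, level, parent_id, label = node_id,
                      description = "") {
  tibble::tibble(node_id = node_id, label = label, level = level,
                 parent_id = parent_id, description = description)
}

# two domains: d1 {c1 {s1, s2}, c2}, d2 {c1}; leaves d1.c1.s1, d1.c1.s2,
# d1.c2, d2.c1
toy_tree <- function() {
  new_criteria_tree("toy", "1", nodes_tbl(
    node_id = c("d1", "d1.c1", "d1.c1.s1", "d1.c1.s2", "d1.c2",
                "d2", "d2.c1"),
    level = c("domain", "criterion", "subcriterion", "subcriterion",
              "criterion", "domain", "criterion"),
    parent_id = c(NA, "d1", "d1.c1", "d1.c1", "d1", NA, "d2")))
}

# one domain, one criterion, no subcriteria
chain_tree <- function() {
  new_criteria_tree("chain", "1", nodes_tbl(
    node_id = c("d1", "d1.c1"),
    level = c("domain", "criterion"),
    parent_id = c(NA, "d1")))
}

# flat two-domain tree: each domain one criterion leaf
two_domain_tree <- function() {
  new_criteria_tree("two", "1", nodes_tbl(
    node_id = c("d1", "d1.c1", "d2", "d2.c1"),
    level = c("domain", "criterion", "domain", "criterion"),
    parent_id = c(NA, "d1", NA, "d2")))
}

# random valid tree: <= 5 domains, <= 4 criteria each, 0..4 subcriteria each
random_tree <- function() {
  id <- character(); lv <- character(); pa <- character()
  for (i in seq_len(sample(1:5, 1))) {
    did <- paste0("d", i)
    id <- c(id, did); lv <- c(lv, "domain"); pa <- c(pa, NA)
    for (j in seq_len(sample(1:4, 1))) {
      cid <- paste0(did, ".c", j)
      id <- c(id, cid); lv <- c(lv, "criterion"); pa <- c(pa, did)
      for (k in seq_len(sample(0:4, 1))) {
        id <- c(id, paste0(cid, ".s", k))
        lv <- c(lv, "subcriterion"); pa <- c(pa, cid)
      }
    }
  }
  new_criteria_tree("random", "1", nodes_tbl(id, lv, pa))
}

# long-format allocation records from list(respondent -> list(group -> pts))
alloc_tbl <- function(sample_id, allocations) {
  dplyr::bind_rows(lapply(names(allocations), function(rid) {
    dplyr::bind_rows(lapply(names(allocations[[rid]]), function(gid) {
      pts <- allocations[[rid]][[gid]]
      tibble::tibble(respondent_id = rid, sample_id = sample_id,
                     group_id = gid, node_id = names(pts),
                     points = as.numeric(pts))
    }))
  }))
}

# weight table with random positive weights, normalized per sibling group
random_weight_table <- function(tree) {
  ids <- tree$nodes$node_id
  grp <- ifelse(is.na(tree$nodes$parent_id), "root", tree$nodes$parent_id)
  w <- stats::rgamma(length(ids), shape = 1) + 0.05
  w <- unlist(lapply(split(w, grp)[unique(grp)], function(v) 100 * v / sum(v)))
  names(w) <- unlist(split(ids, grp)[unique(grp)])
  weight_table_from_weights(tree, w[ids])
}

random_scores <- function(tree) {
  leaves <- tree_leaves(tree)
  stats::setNames(stats::runif(length(leaves)), leaves)
}

# independent value oracle: recursive descent over the tree, multiplying
# normalized sibling weights; never touches leaf_paths/effective_leaf_weights
brute_value <- function(wt, sheet) {
  tree <- attr(wt, "tree")
  wnorm <- stats::setNames(wt$normalized, wt$node_id)
  node_value <- function(id) {
    kids <- tree_children(tree, id)
    if (length(kids) == 0) return(sheet$scores[[id]])
    sum(vapply(kids, function(k) wnorm[[k]] * node_value(k), numeric(1)))
  }
  sum(vapply(tree_children(tree, "root"),
             function(d) wnorm[[d]] * node_value(d), numeric(1)))
}

# textbook Welch two-sample t-test with Welch-Satterthwaite df
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Mann-Whitney U via rank sums; normal approximation with tie correction,
# no continuity correction
ranksum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# brute-force minimal-total-deviation integer rounding: enumerate all
# floor/ceiling combinations (every optimum lies there) and return the
# minimal total absolute deviation among those summing to `total`
min_deviation_oracle <- function(values, total = 100) {
  lo <- floor(values)
  combos <- expand.grid(rep(list(0:1), length(values)))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    cand <- lo + as.numeric(combos[i, ])
    if (sum(cand) == total) {
      best <- min(best, sum(abs(cand - values)))
    }
  }
  best
}

# random percent vector of length k summing exactly to 100
random_percents <- function(k) {
  v <- stats::rgamma(k, 1)
  v <- v / sum(v) * 100
  v[k] <- 100 - sum(v[-k])
  v
}
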