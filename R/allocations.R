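#' 100-point allocation surveys
#'
#' Weights are elicited by budget allocation: each respondent distributes
#' 100 points among the domains, 100 points among the criteria within each
#' domain, and 100 points among the subcriteria within each criterion. One
#' \emph{record} is one respondent's allocation over one sibling group. An
#' `allocation_set` holds the validated records of one or more respondent
#' samples in long form against a fixed tree.
#'
#' @name allocation_set
NULL

SUM_TOL <- 1e-9

#' Validate one allocation record against a tree
#'
#' A record is valid iff its group exists, its point keys are exactly the
#' children of the group, all points are non-negative, and they sum to 100
#' exactly (to floating tolerance; the survey interface enforces the budget,
#' so any deviation in file data is an entry error).
#'
#' @param record List with `group_id` and `points` (named numeric over the
#'   group's children).
#' @param tree A valid `criteria_tree`.
#' @return Character vector of violation codes, empty iff valid. Codes:
#'   `"unknown-group"`, `"unknown-node: <id>"`, `"missing-sibling: <id>"`,
#'   `"negative-points"`, `"sum-not-100"`.
#' @export
validate_allocation <- function(record, tree) {
  out <- character()
  children <- tree_children(tree, record$group_id)
  if (length(children) == 0) {
    return(paste0("unknown-group: ", record$group_id))
  }
  pts <- record$points
  extra <- setdiff(names(pts), children)
  out <- c(out, if (length(extra)) paste0("unknown-node: ", extra))
  missing <- setdiff(children, names(pts))
  out <- c(out, if (length(missing)) paste0("missing-sibling: ", missing))
  known <- pts[names(pts) %in% children]
  if (any(!is.finite(known)) || any(known < 0)) {
    out <- c(out, "negative-points")
  } else if (length(missing) == 0 && length(extra) == 0 &&
             abs(sum(known) - 100) > SUM_TOL) {
    out <- c(out, "sum-not-100")
  }
  out
}

#' Build an allocation set from long-format records
#'
#' @param tree A valid `criteria_tree`.
#' @param records Tibble with columns `respondent_id`, `sample_id`,
#'   `group_id`, `node_id`, `points`; one row per (respondent, node).
#' @param repair `"none"` rejects any record whose points do not sum to
#'   exactly 100; `"proportional"` rescales off-budget (but otherwise valid)
#'   records to a 100 sum and re-rounds to integers by the largest-remainder
#'   method, marking them in the rejection report with reason
#'   `"repaired-proportional"`.
#' @return An `allocation_set`: list with `tree`, `records` (valid rows,
#'   long form), `samples`, and `rejections` (tibble `respondent_id`,
#'   `sample_id`, `group_id`, `reason`).
#' @export
allocation_set <- function(tree, records,
                           repair = c("none", "proportional")) {
  repair <- match.arg(repair)
  records <- tibble::as_tibble(records)
  needed <- c("respondent_id", "sample_id", "group_id", "node_id", "points")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("allocation table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- records[needed]
  records$points <- as.numeric(records$points)

  rid_v <- records$respondent_id; sid_v <- records$sample_id
  gid_v <- records$group_id; nid_v <- records$node_id
  pts_v <- records$points
  keep <- vector("list", 0)
  rej_rid <- character(); rej_sid <- character()
  rej_gid <- character(); rej_why <- character()
  keys <- split(seq_len(nrow(records)),
                paste(rid_v, sid_v, gid_v, sep = "\r"))
  # records kept in file order of each group's first row
  first_row <- vapply(keys, min, integer(1))
  for (idx in keys[order(first_row)]) {
    rid <- rid_v[idx[1]]; sid <- sid_v[idx[1]]; gid <- gid_v[idx[1]]
    nid <- nid_v[idx]
    reject <- function(reason) {
      rej_rid <<- c(rej_rid, rid); rej_sid <<- c(rej_sid, sid)
      rej_gid <<- c(rej_gid, gid); rej_why <<- c(rej_why, reason)
    }
    if (anyDuplicated(nid)) {
      reject("duplicate-node"); next
    }
    rec <- list(group_id = gid, points = stats::setNames(pts_v[idx], nid))
    bad <- validate_allocation(rec, tree)
    if (identical(bad, "sum-not-100") && repair == "proportional" &&
        sum(rec$points) > 0) {
      pts_v[idx] <- round_preserving_sum(
        rec$points * 100 / sum(rec$points), 100)
      reject("repaired-proportional")
      bad <- character()
    }
    if (length(bad) > 0) {
      for (b in bad) reject(b)
      next
    }
    # keep rows in the tree's document order of the group's children
    keep[[length(keep) + 1L]] <- idx[match(tree_children(tree, gid), nid)]
  }
  kept <- unlist(keep)
  out <- records[kept, ]
  out$points <- pts_v[kept]
  structure(list(
    tree = tree,
    records = out,
    samples = sort(unique(out$sample_id)),
    rejections = tibble::tibble(respondent_id = rej_rid,
                                sample_id = rej_sid, group_id = rej_gid,
                                reason = rej_why)
  ), class = "allocation_set")
}

#' Read allocation survey responses from CSV
#'
#' Long format, UTF-8, header row, columns
#' `respondent_id,sample_id,group_id,node_id,points`; one row per
#' (respondent, node). Invalid records are not dropped silently: they are
#' collected in the returned object's `rejections` tibble with a reason
#' code per violation.
#'
#' @inheritParams allocation_set
#' @param path CSV file path.
#' @return An `allocation_set`.
#' @export
read_allocations <- function(path, tree, repair = c("none", "proportional")) {
  records <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               respondent_id = readr::col_character(),
                               sample_id = readr::col_character(),
                               group_id = readr::col_character(),
                               node_id = readr::col_character(),
                               points = readr::col_double()))
  allocation_set(tree, records, repair = repair)
}

#' Write an allocation set to CSV
#' @param allocs An `allocation_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_allocations <- function(allocs, path) {
  readr::write_csv(allocs$records, path)
  invisible(path)
}

#' Per-sample summary statistics of allocated points
#'
#' For each node answered by the sample: number of respondents, mean,
#' standard deviation (n-1 denominator) and median of the allocated points.
#' When all respondents answered all siblings of a group, the node means in
#' that group sum to 100 by linearity.
#'
#' @param allocs An `allocation_set`.
#' @param sample_id Sample to summarise.
#' @return A `sample_summary`: tibble with columns `sample_id`, `node_id`,
#'   `group_id`, `n`, `mean`, `sd`, `median`, in tree document order.
#' @export
summarize_sample <- function(allocs, sample_id) {
  rec <- allocs$records[allocs$records$sample_id == sample_id, ]
  if (nrow(rec) == 0) {
    stop("no-records-for-sample: ", sample_id, call. = FALSE)
  }
  out <- rec |>
    dplyr::group_by(.data$group_id, .data$node_id) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$points),
                     sd = stats::sd(.data$points),
                     median = stats::median(.data$points),
                     .groups = "drop") |>
    dplyr::mutate(sample_id = sample_id, .before = 1)
  # single-respondent nodes get sd 0, not NA
  out$sd[out$n == 1] <- 0
  out <- out[order(match(out$node_id, allocs$tree$nodes$node_id)), ]
  class(out) <- c("sample_summary", class(out))
  out
}

#' @export
print.allocation_set <- function(x, ...) {
  n_resp <- length(unique(paste(x$records$sample_id, x$records$respondent_id)))
  cat(sprintf(
    "<allocation_set> %d samples (%s), %d respondents, %d valid records, %d rejections\n",
    length(x$samples), paste(x$samples, collapse = ", "), n_resp,
    nrow(unique(x$records[c("respondent_id", "sample_id", "group_id")])),
    nrow(x$rejections)))
  invisible(x)
}
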