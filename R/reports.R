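#' Distribution report of allocated points
#'
#' Per node at the requested level and per sample: respondent count,
#' median, quartiles, and histogram counts in bins of width 5 over
#' \[0, 100\] (the bin width exposes the round-number clustering typical of
#' point-allocation surveys; 100 falls in the last bin).
#'
#' @param allocs An `allocation_set` with at least one record.
#' @param level `"domain"`, `"criterion"` or `"subcriterion"`.
#' @param binwidth Histogram bin width in points (default 5).
#' @return List with `stats` (tibble `node_id`, `sample_id`, `n`, `median`,
#'   `q25`, `q75`) and `histogram` (tibble `node_id`, `sample_id`,
#'   `bin_lo`, `bin_hi`, `count`); per node and sample the bin counts sum
#'   to `n`.
#' @export
distribution_report <- function(allocs,
                                level = c("domain", "criterion",
                                          "subcriterion"),
                                binwidth = 5) {
  level <- match.arg(level)
  if (nrow(allocs$records) == 0) stop("allocation set is empty",
                                      call. = FALSE)
  ids <- allocs$tree$nodes$node_id[allocs$tree$nodes$level == level]
  rec <- allocs$records[allocs$records$node_id %in% ids, ]
  stats_tab <- rec |>
    dplyr::group_by(.data$node_id, .data$sample_id) |>
    dplyr::summarise(n = dplyr::n(), median = stats::median(.data$points),
                     q25 = stats::quantile(.data$points, 0.25),
                     q75 = stats::quantile(.data$points, 0.75),
                     .groups = "drop")
  breaks <- seq(0, 100, by = binwidth)
  hist_tab <- rec |>
    dplyr::mutate(bin = pmin(findInterval(.data$points, breaks),
                             length(breaks) - 1)) |>
    dplyr::count(.data$node_id, .data$sample_id, .data$bin,
                 name = "count") |>
    dplyr::mutate(bin_lo = breaks[.data$bin],
                  bin_hi = breaks[.data$bin + 1]) |>
    dplyr::select("node_id", "sample_id", "bin_lo", "bin_hi", "count")
  ord <- function(t) t[order(match(t$node_id, ids), t$sample_id), ]
  list(stats = ord(stats_tab), histogram = ord(hist_tab))
}

#' Configure a full pipeline run
#'
#' @param criteria Path to the criteria configuration file.
#' @param allocations Path to the allocation CSV.
#' @param scores Optional path to a technology score-sheet CSV.
#' @param lambda Pooling weight on the first sample (default 0.5).
#' @param rounding Rounding policy for the weight table.
#' @param scale Score scale for the score sheets.
#' @param seed Seed for the probabilistic sensitivity stage.
#' @param psa_draws Bootstrap draws for the sensitivity stage (0 skips it).
#' @param out_dir Output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(criteria, allocations, scores = NULL, lambda = 0.5,
                       rounding = "largest-remainder", scale = c(0, 1),
                       seed = 1L, psa_draws = 0L, out_dir = ".") {
  stopifnot(lambda >= 0, lambda <= 1)
  for (p in c(criteria, allocations, scores)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  structure(list(criteria = criteria, allocations = allocations,
                 scores = scores, lambda = lambda, rounding = rounding,
                 scale = scale, seed = as.integer(seed),
                 psa_draws = as.integer(psa_draws), out_dir = out_dir),
            class = "run_config")
}

#' Run the full MCDA pipeline
#'
#' Validate the tree, read and validate allocations, summarise each sample,
#' compare the samples, build the weight table, and -- when score sheets are
#' supplied -- compute composite values, rankings, and (when `psa_draws > 0`)
#' rank acceptability. All tables are written as CSV into `out_dir`
#' together with `run_log.json` recording package version, configuration
#' name/version, seed, lambda and rounding policy; a rerun with identical
#' inputs produces byte-identical tables. A failing stage aborts with the
#' stage name and removes the files written by this run.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a named list of the written file paths.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(tab, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_csv(tibble::as_tibble(tab), path)
    written[[length(written) + 1L]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tree <- stage("validate", load_criteria_config(cfg$criteria))
  allocs <- stage("read-allocations", read_allocations(cfg$allocations, tree))
  stage("summarize", {
    for (sid in allocs$samples) {
      emit(summarize_sample(allocs, sid), paste0("summary_", sid, ".csv"))
    }
    if (nrow(allocs$rejections) > 0) {
      emit(allocs$rejections, "rejections.csv")
    }
  })
  wt <- stage("weights", {
    wt <- build_weight_table(allocs, lambda = cfg$lambda,
                             rounding = cfg$rounding)
    emit(wt, "weights.csv")
    if (length(allocs$samples) == 2) {
      emit(compare_all_nodes(allocs, allocs$samples[1], allocs$samples[2]),
           "comparisons.csv")
    }
    wt
  })
  stage("report", {
    rep <- distribution_report(allocs, "domain")
    emit(rep$stats, "domain_distribution_stats.csv")
    emit(rep$histogram, "domain_histograms.csv")
  })
  if (!is.null(cfg$scores)) {
    sheets <- stage("score", read_score_sheets(cfg$scores, tree,
                                               scale = cfg$scale))
    stage("score", {
      results <- lapply(sheets, function(sh) aggregate_value(wt, sh))
      emit(dplyr::bind_rows(lapply(results, function(r) {
        tibble::tibble(technology_id = r$technology_id, value = r$value,
                       domain = names(r$domain_contributions),
                       contribution = as.numeric(r$domain_contributions))
      })), "values.csv")
      emit(rank_technologies(results), "ranking.csv")
    })
    if (cfg$psa_draws > 0) {
      stage("sensitivity", {
        psa <- probabilistic_sensitivity(allocs, sheets,
                                         n_draws = cfg$psa_draws,
                                         seed = cfg$seed,
                                         lambda = cfg$lambda)
        acc <- tibble::as_tibble(psa$acceptability, rownames = "technology_id")
        emit(acc, "rank_acceptability.csv")
        emit(psa$value_summary, "value_percentiles.csv")
      })
    }
  } else if (cfg$psa_draws > 0) {
    stop("stage 'score' failed: sensitivity requested without a score file",
         call. = FALSE)
  }
  log <- list(package = "mcdahta",
              version = as.character(utils::packageVersion("mcdahta")),
              config = list(name = tree$name, version = tree$version),
              seed = cfg$seed, lambda = cfg$lambda,
              rounding = cfg$rounding, psa_draws = cfg$psa_draws)
  log_path <- file.path(cfg$out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
  written[[length(written) + 1L]] <- log_path
  invisible(stats::setNames(as.list(written), basename(unlist(written))))
}
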