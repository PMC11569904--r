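#' Synthetic 100-point allocation surveys
#'
#' Respondent-level microdata behind published weight tables are rarely
#' available, so the package ships a seeded generator that emulates the
#' statistical structure of point-allocation surveys: compositional
#' allocations drawn from a Dirichlet distribution around target mean
#' weights, an \emph{equalizing bias} shrinking means toward the uniform
#' allocation, and a \emph{round-number bias} snapping allocations to
#' multiples of five -- both patterns documented for point-allocation
#' elicitation. Low Dirichlet concentration yields the dispersed,
#' right-skewed allocations typical of general-population samples; high
#' concentration the tight allocations of professional samples.
#'
#' @name synthetic_survey
NULL

#' Define a respondent-sample profile for the simulator
#'
#' @param sample_id Sample identifier (e.g. `"professionals"`).
#' @param n Number of respondents.
#' @param targets Named list: sibling-group id (`"root"` for the domain
#'   question) to named numeric vector of target mean percents over the
#'   group's children, each summing to 100.
#' @param concentration Dirichlet concentration (sum of the alpha
#'   parameters); a single positive number, or a named numeric vector with
#'   one entry per group in `targets`. Larger means less dispersion.
#' @param round_number_bias Probability, per respondent and group, that the
#'   allocation is snapped to multiples of five.
#' @param equalizing_bias Shrinkage fraction of the target means toward the
#'   uniform allocation; the generated mean is
#'   `(1 - bias) * target + bias * uniform`.
#' @return A `sample_profile`.
#' @export
sample_profile <- function(sample_id, n, targets, concentration,
                           round_number_bias = 0, equalizing_bias = 0) {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.numeric(n), length(n) == 1, n >= 1,
            is.list(targets), length(targets) >= 1)
  for (gid in names(targets)) {
    tg <- targets[[gid]]
    if (is.null(names(tg)) || any(!is.finite(tg)) || any(tg < 0)) {
      stop("profile '", sample_id, "', group '", gid,
           "': targets must be named, finite and non-negative",
           call. = FALSE)
    }
    if (abs(sum(tg) - 100) > 1e-6) {
      stop("profile '", sample_id, "', group '", gid,
           "': target means sum to ", sum(tg), ", not 100", call. = FALSE)
    }
  }
  if (length(concentration) == 1 && is.null(names(concentration))) {
    concentration <- stats::setNames(rep(concentration, length(targets)),
                                     names(targets))
  }
  missing <- setdiff(names(targets), names(concentration))
  if (length(missing) > 0) {
    stop("profile '", sample_id, "': no concentration for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(concentration <= 0)) {
    stop("concentration must be > 0", call. = FALSE)
  }
  stopifnot(round_number_bias >= 0, round_number_bias <= 1,
            equalizing_bias >= 0, equalizing_bias <= 1)
  structure(list(sample_id = sample_id, n = as.integer(n), targets = targets,
                 concentration = concentration,
                 round_number_bias = round_number_bias,
                 equalizing_bias = equalizing_bias),
            class = "sample_profile")
}

#' Mean allocation a profile generates
#'
#' The target means after equalizing-bias shrinkage:
#' `(1 - bias) * target + bias * uniform`. This -- not the raw target -- is
#' the vector the generated sample means converge to.
#'
#' @param profile A `sample_profile`.
#' @param group_id Sibling group id.
#' @return Named numeric percent vector summing to 100.
#' @export
profile_implied_means <- function(profile, group_id) {
  tg <- profile$targets[[group_id]]
  if (is.null(tg)) stop("profile has no targets for group ", group_id,
                        call. = FALSE)
  b <- profile$equalizing_bias
  (1 - b) * tg + b * 100 / length(tg)
}

#' Default two-sample survey profiles
#'
#' Emulates the study conditions of a regional weight-elicitation exercise:
#' a small, homogeneous sample of healthcare professionals (n = 35, high
#' Dirichlet concentration) and a large, dispersed, right-skewed
#' general-population sample (n = 494, low concentration). Domain-level
#' target means are set to the published per-sample values where printed
#' (professionals 23.7 / 23.1 / 19.5 / 18.5, general population
#' 28.1 / 24.6 / 19.0 / 14.5 on the feasibility domain), with the one
#' unprinted domain per sample taking the residual to 100; criterion- and
#' subcriterion-level targets default to uniform and can be overridden.
#' Concentrations (150 and 12) and bias parameters are calibration
#' defaults, not published values.
#'
#' @param tree A valid `criteria_tree`; domain targets are only meaningful
#'   for the packaged default tree (5 domains in its document order).
#' @return List of two `sample_profile`s: `professionals`,
#'   `general_population`.
#' @export
default_survey_profiles <- function(tree) {
  domains <- tree_children(tree, ROOT_GROUP)
  groups <- sibling_groups(tree)
  uniform_targets <- lapply(groups, function(kids) {
    stats::setNames(rep(100 / length(kids), length(kids)), kids)
  })
  root_target <- function(named) {
    if (length(domains) == length(named)) {
      resid <- 100 - sum(named, na.rm = TRUE)
      named[is.na(named)] <- resid
      stats::setNames(named, domains)
    } else {
      uniform_targets[[ROOT_GROUP]]
    }
  }
  pro <- uniform_targets
  pro[[ROOT_GROUP]] <- root_target(c(23.7, 23.1, 19.5, 18.5, NA))
  gen <- uniform_targets
  gen[[ROOT_GROUP]] <- root_target(c(28.1, 24.6, 19.0, NA, 14.5))
  list(
    professionals = sample_profile(
      "professionals", n = 35, targets = pro, concentration = 150,
      round_number_bias = 0.3, equalizing_bias = 0.10),
    general_population = sample_profile(
      "general_population", n = 494, targets = gen, concentration = 12,
      round_number_bias = 0.5, equalizing_bias = 0.15))
}

# snap to multiples of 5 by stochastic rounding (up with probability equal
# to the fractional distance, so the snap is mean-unbiased even for tight
# distributions), then repair the 100 budget in +/-5 steps applied to the
# components with the largest snapping residuals; stays on-grid
snap_to_fives <- function(pts) {
  lo <- 5 * floor(pts / 5)
  snapped <- lo + 5 * (stats::runif(length(pts)) < (pts - lo) / 5)
  resid <- pts - snapped
  deficit <- 100 - sum(snapped)
  while (deficit > 0) {
    i <- which.max(resid)
    snapped[i] <- snapped[i] + 5
    resid[i] <- resid[i] - 5
    deficit <- deficit - 5
  }
  while (deficit < 0) {
    ok <- snapped >= 5
    i <- which(ok)[which.min(resid[ok])]
    snapped[i] <- snapped[i] - 5
    resid[i] <- resid[i] + 5
    deficit <- deficit + 5
  }
  snapped
}

draw_dirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Simulate a seeded synthetic allocation survey
#'
#' For every respondent of every profile and every sibling group with
#' targets: proportions are drawn from a Dirichlet distribution whose mean
#' is the equalizing-bias-shrunk target and whose concentration is the
#' profile's, scaled to 100 points, snapped to multiples of five with
#' probability `round_number_bias`, and rounded to integers summing to
#' exactly 100 by the largest-remainder method. Every emitted record passes
#' [validate_allocation()]; the output is identical for identical seeds.
#'
#' @param tree A valid `criteria_tree`.
#' @param profiles List of `sample_profile`s (e.g.
#'   [default_survey_profiles()]).
#' @param seed Integer seed; all randomness derives from it.
#' @return An `allocation_set`.
#' @export
simulate_allocations <- function(tree, profiles, seed) {
  stopifnot(length(profiles) >= 1)
  groups <- sibling_groups(tree)
  for (p in profiles) {
    stopifnot(inherits(p, "sample_profile"))
    bad <- setdiff(names(p$targets), names(groups))
    if (length(bad) > 0) {
      stop("profile '", p$sample_id, "' targets unknown group(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (gid in names(p$targets)) {
      if (!setequal(names(p$targets[[gid]]), groups[[gid]])) {
        stop("profile '", p$sample_id, "', group '", gid,
             "': target names must be exactly the group's children",
             call. = FALSE)
      }
    }
  }
  with_seed(seed, {
    col_rid <- list(); col_sid <- list(); col_gid <- list()
    col_nid <- list(); col_pts <- list()
    k <- 0L
    for (p in profiles) {
      gids <- names(groups)[names(groups) %in% names(p$targets)]
      alphas <- lapply(gids, function(gid) {
        p$concentration[[gid]] *
          profile_implied_means(p, gid)[groups[[gid]]] / 100
      })
      names(alphas) <- gids
      for (r in seq_len(p$n)) {
        rid <- sprintf("%s_%04d", p$sample_id, r)
        for (gid in gids) {
          kids <- groups[[gid]]
          pts <- draw_dirichlet(alphas[[gid]]) * 100
          pts <- if (stats::runif(1) < p$round_number_bias) {
            snap_to_fives(pts)
          } else {
            round_preserving_sum(pts, 100)
          }
          k <- k + 1L
          col_rid[[k]] <- rep(rid, length(kids))
          col_sid[[k]] <- rep(p$sample_id, length(kids))
          col_gid[[k]] <- rep(gid, length(kids))
          col_nid[[k]] <- kids
          col_pts[[k]] <- as.numeric(pts)
        }
      }
    }
    allocation_set(tree, tibble::tibble(
      respondent_id = unlist(col_rid), sample_id = unlist(col_sid),
      group_id = unlist(col_gid), node_id = unlist(col_nid),
      points = unlist(col_pts)))
  })
}

#' Fit simulator profiles to an observed allocation set
#'
#' Moment matching per sample and sibling group: the target mean vector is
#' the sample mean, and the Dirichlet concentration is chosen so the model's
#' component variances match the observed ones on average
#' (`alpha0 = mean_i[m_i (1 - m_i) / v_i] - 1` on the proportion scale).
#' Useful for parametric sensitivity analysis when microdata exist, or for
#' generating look-alike data.
#'
#' @param allocs An `allocation_set`.
#' @return Named list of `sample_profile`s, one per sample in `allocs`.
#' @export
moment_match_profiles <- function(allocs) {
  groups <- sibling_groups(allocs$tree)
  stats::setNames(lapply(allocs$samples, function(sid) {
    sm <- summarize_sample(allocs, sid)
    gids <- intersect(names(groups), unique(sm$group_id))
    targets <- list(); conc <- numeric()
    for (gid in gids) {
      rows <- sm[sm$group_id == gid, ]
      targets[[gid]] <- stats::setNames(rows$mean, rows$node_id)
      m <- rows$mean / 100
      v <- (rows$sd / 100)^2
      usable <- v > 0 & m > 0 & m < 1
      conc[[gid]] <- if (any(usable)) {
        max(mean(m[usable] * (1 - m[usable]) / v[usable]) - 1, 1e-3)
      } else {
        1e6  # degenerate: observed allocations are constant
      }
    }
    n <- max(sm$n)
    sample_profile(sid, n = n, targets = targets, concentration = conc)
  }), allocs$samples)
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
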