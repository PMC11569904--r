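#' Hierarchical criteria trees
#'
#' An MCDA framework for health technology assessment organises its criteria
#' in a three-level hierarchy: \emph{domains} at the top, \emph{criteria}
#' within each domain, and optional \emph{subcriteria} within each criterion.
#' A `criteria_tree` holds that hierarchy as a node table in document order,
#' together with a name and version. The \emph{leaves} of the tree -- all
#' subcriteria plus any criterion without subcriteria -- are the units that
#' receive technology scores; every internal sibling group is a unit of
#' weight elicitation.
#'
#' @name criteria_tree
NULL

ROOT_GROUP <- "root"
LEVELS <- c("domain", "criterion", "subcriterion")

#' Construct a criteria tree from a node table
#'
#' Low-level constructor. `nodes` must have columns `node_id`, `label`,
#' `level`, `parent_id` (`NA` for domains) and `description`, in document
#' order. No validation is performed; see [validate_tree()].
#'
#' @param name Framework name.
#' @param version Framework version string.
#' @param nodes Tibble of nodes in document order.
#' @return A `criteria_tree` object.
#' @export
new_criteria_tree <- function(name, version, nodes) {
  nodes <- tibble::as_tibble(nodes)
  needed <- c("node_id", "label", "level", "parent_id", "description")
  missing <- setdiff(needed, names(nodes))
  if (length(missing) > 0) {
    stop("node table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(name = name, version = version, nodes = nodes[needed]),
    class = "criteria_tree"
  )
}

#' Load a criteria-tree configuration file
#'
#' Reads a YAML or JSON configuration (nested
#' `domains -> criteria -> subcriteria`, each node carrying `id`, `label` and
#' optional `description`) into a validated [criteria_tree]. The packaged
#' default lives at
#' `system.file("extdata", "criteria_default.yaml", package = "mcdahta")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `criteria_tree`; node order follows the file.
#' @seealso [write_criteria_config()], [validate_tree()]
#' @export
#' @examples
#' tree <- load_criteria_config(default_criteria_path())
#' tree
load_criteria_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- tryCatch(
    switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::fromJSON(path, simplifyVector = FALSE),
      stop("unsupported configuration format: .", ext, call. = FALSE)
    ),
    error = function(e) {
      stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  tree <- tree_from_config(cfg, path)
  report <- validate_tree(tree)
  if (!report$ok) {
    stop(format_validation_report(report, header = paste0(
      "invalid criteria configuration ", path, ":")), call. = FALSE)
  }
  tree
}

#' Path to the packaged default criteria configuration
#' @return File path of the default YAML configuration.
#' @export
default_criteria_path <- function() {
  system.file("extdata", "criteria_default.yaml", package = "mcdahta",
              mustWork = TRUE)
}

tree_from_config <- function(cfg, path = "<config>") {
  for (field in c("name", "version", "domains")) {
    if (is.null(cfg[[field]])) {
      stop("configuration ", path, " lacks required field '", field, "'",
           call. = FALSE)
    }
  }
  rows <- list()
  push <- function(node, level, parent_id) {
    if (is.null(node$id) || is.null(node$label)) {
      stop("configuration ", path, ": every node needs 'id' and 'label' (",
           level, " under ", parent_id %||% "root", ")", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      node_id = as.character(node$id),
      label = as.character(node$label),
      level = level,
      parent_id = parent_id %||% NA_character_,
      description = as.character(node$description %||% "")
    )
  }
  for (dom in cfg$domains) {
    push(dom, "domain", NULL)
    for (cri in dom$criteria %||% list()) {
      push(cri, "criterion", as.character(dom$id))
      for (sub in cri$subcriteria %||% list()) {
        push(sub, "subcriterion", as.character(cri$id))
      }
    }
  }
  new_criteria_tree(as.character(cfg$name), as.character(cfg$version),
                    dplyr::bind_rows(rows))
}

#' Write a criteria tree back to a configuration file
#'
#' Inverse of [load_criteria_config()]: the written file parses to a tree
#' equal field-by-field to the input.
#'
#' @param tree A `criteria_tree`.
#' @param path Output path; format chosen by extension (`.yaml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_criteria_config <- function(tree, path) {
  stopifnot(inherits(tree, "criteria_tree"))
  node_cfg <- function(row, children) {
    out <- list(id = row$node_id, label = row$label,
                description = row$description)
    if (length(children) > 0) out <- c(out, children)
    out
  }
  nodes <- tree$nodes
  cfg <- list(name = tree$name, version = tree$version, domains = lapply(
    which(nodes$level == "domain"), function(i) {
      dom <- nodes[i, ]
      crits <- lapply(which(nodes$parent_id %in% dom$node_id), function(j) {
        cri <- nodes[j, ]
        subs <- lapply(which(nodes$parent_id %in% cri$node_id), function(k) {
          node_cfg(nodes[k, ], list())
        })
        node_cfg(cri, if (length(subs)) list(subcriteria = subs) else list())
      })
      node_cfg(dom, if (length(crits)) list(criteria = crits) else list())
    }))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported configuration format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Validate a criteria tree
#'
#' Checks every structural invariant and reports \emph{all} violations, not
#' just the first: unique node ids (`unique-id`), valid levels
#' (`level-valid`), domains having no parent and non-domains exactly one
#' existing parent (`parent-exists`, `domain-parent`), parents one level up
#' (`parent-level`), subcriteria being childless (`leaf-level`), at least one
#' domain (`nonempty`) and a non-empty leaf set (`leaves-nonempty`).
#'
#' @param tree A `criteria_tree` (not necessarily valid).
#' @return A `validation_report`: list with `ok` (logical) and `violations`
#'   (tibble with columns `node`, `rule`, `message`); `ok` is `TRUE` iff
#'   `violations` has no rows.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "criteria_tree"))
  nodes <- tree$nodes
  v <- list()
  flag <- function(node, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(node = node, rule = rule,
                                           message = message)
  }
  dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
  for (id in dup) flag(id, "unique-id", paste0("node_id '", id, "' occurs ",
    sum(nodes$node_id == id), " times"))
  bad_level <- nodes$node_id[!nodes$level %in% LEVELS]
  for (id in bad_level) flag(id, "level-valid",
    paste0("level must be one of ", paste(LEVELS, collapse = "/")))
  if (!any(nodes$level == "domain")) {
    flag(NA_character_, "nonempty", "tree has no domains")
  }
  parent_level <- c(domain = NA, criterion = "domain",
                    subcriterion = "criterion")
  for (i in seq_len(nrow(nodes))) {
    row <- nodes[i, ]
    if (!row$level %in% LEVELS) next
    if (row$level == "domain") {
      if (!is.na(row$parent_id)) {
        flag(row$node_id, "domain-parent", "domains must not have a parent")
      }
      next
    }
    if (is.na(row$parent_id)) {
      flag(row$node_id, "parent-exists",
           paste0(row$level, " has no parent_id"))
      next
    }
    hit <- which(nodes$node_id == row$parent_id)
    if (length(hit) == 0) {
      flag(row$node_id, "parent-exists",
           paste0("parent '", row$parent_id, "' does not exist"))
    } else if (nodes$level[hit[1]] != parent_level[[row$level]]) {
      flag(row$node_id, "parent-level", paste0(
        row$level, " must sit under a ", parent_level[[row$level]],
        ", not a ", nodes$level[hit[1]]))
    }
  }
  sub_ids <- nodes$node_id[nodes$level == "subcriterion"]
  kids_of_sub <- nodes$node_id[!is.na(nodes$parent_id) &
                               nodes$parent_id %in% sub_ids]
  for (id in kids_of_sub) flag(id, "leaf-level",
    "subcriteria must not have children")
  if (length(v) == 0 && nrow(leaf_paths(tree)) == 0) {
    flag(NA_character_, "leaves-nonempty", "tree has no leaves")
  }
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(node = character(), rule = character(),
                   message = character())
  structure(list(ok = nrow(violations) == 0, violations = violations),
            class = "validation_report")
}

format_validation_report <- function(report, header = "validation report:") {
  if (report$ok) return(paste(header, "ok"))
  lines <- sprintf("  [%s] %s: %s", report$violations$rule,
                   ifelse(is.na(report$violations$node), "<tree>",
                          report$violations$node),
                   report$violations$message)
  paste(c(header, lines), collapse = "\n")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(format_validation_report(x), "\n")
  invisible(x)
}

# ---- traversal helpers -----------------------------------------------------

#' Children of a node, in document order
#' @param tree A `criteria_tree`.
#' @param node_id Parent node id, or the sentinel `"root"` for domains.
#' @return Character vector of child node ids.
#' @export
tree_children <- function(tree, node_id) {
  nodes <- tree$nodes
  if (identical(node_id, ROOT_GROUP)) {
    return(nodes$node_id[nodes$level == "domain"])
  }
  nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == node_id]
}

#' Sibling groups of a tree
#'
#' Each group is the set of children of one parent (the domains form the
#' `"root"` group). These are exactly the units over which a respondent
#' allocates 100 points.
#'
#' @param tree A `criteria_tree`.
#' @return Named list mapping group id (parent node id or `"root"`) to the
#'   character vector of member node ids, in document order.
#' @export
sibling_groups <- function(tree) {
  nodes <- tree$nodes
  parents <- c(ROOT_GROUP,
               nodes$node_id[nodes$node_id %in% nodes$parent_id])
  stats::setNames(lapply(parents, function(p) tree_children(tree, p)),
                  parents)
}

#' Leaf paths of a criteria tree
#'
#' One row per leaf in document order. A criterion without subcriteria is a
#' leaf itself and appears with `subcriterion_id = NA`.
#'
#' @param tree A valid `criteria_tree`.
#' @return Tibble with columns `domain_id`, `criterion_id`,
#'   `subcriterion_id`, `leaf_id`.
#' @export
leaf_paths <- function(tree) {
  nodes <- tree$nodes
  has_kids <- nodes$node_id %in% nodes$parent_id
  idx <- which((nodes$level == "criterion" & !has_kids) |
               nodes$level == "subcriterion")
  is_sub <- nodes$level[idx] == "subcriterion"
  crit <- ifelse(is_sub, nodes$parent_id[idx], nodes$node_id[idx])
  tibble::tibble(
    domain_id = nodes$parent_id[match(crit, nodes$node_id)],
    criterion_id = crit,
    subcriterion_id = ifelse(is_sub, nodes$node_id[idx], NA_character_),
    leaf_id = nodes$node_id[idx])
}

#' Leaf node ids of a tree
#' @param tree A valid `criteria_tree`.
#' @return Character vector of leaf ids in document order.
#' @export
tree_leaves <- function(tree) leaf_paths(tree)$leaf_id

node_level <- function(tree, node_id) {
  tree$nodes$level[match(node_id, tree$nodes$node_id)]
}

node_label <- function(tree, node_id) {
  tree$nodes$label[match(node_id, tree$nodes$node_id)]
}

# group id that a node is weighted in: its parent, or "root" for domains
node_group <- function(tree, node_id) {
  p <- tree$nodes$parent_id[match(node_id, tree$nodes$node_id)]
  ifelse(is.na(p), ROOT_GROUP, p)
}

#' @export
print.criteria_tree <- function(x, ...) {
  n <- table(factor(x$nodes$level, levels = LEVELS))
  cat(sprintf("<criteria_tree> %s v%s: %d domains, %d criteria, %d subcriteria (%d leaves)\n",
              x$name, x$version, n[["domain"]], n[["criterion"]],
              n[["subcriterion"]], nrow(leaf_paths(x))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
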