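#' Summarize a policy table as a yes-no decision tree
#'
#' The full policy is a large lookup table; for communication it is condensed
#' into a CART-style regression tree of yes-no threshold questions on the
#' abundance of adults (A) and young (Y, both thousands) and DAYS. Training
#' samples are the policy's grid states, with the (A, Y) split derived from
#' total abundance via [derive_age_split()] at a reference reproduction rate.
#' Splits are greedy variance-reduction splits (fit with \pkg{rpart}); leaf
#' quotas are snapped to the nearest action-grid value.
#'
#' @param policy An `ahm_policy` from [optimize_policy()].
#' @param reproduction_ref Reference young-per-adult rate used to express the
#'   grid abundances as (A, Y) pairs.
#' @param max_depth Maximum tree depth (>= 1).
#' @return An object of class `ahm_policy_tree` with a recursive `root` node;
#'   internal nodes hold `var` (one of `"A"`, `"Y"`, `"DAYS"`), `threshold`
#'   and the yes/no children (`yes` when the condition holds), leaves hold
#'   `quota`.
#' @export
fit_policy_tree <- function(policy, reproduction_ref, max_depth = 6L) {
  if (max_depth < 1L) stop("max_depth must be at least 1")
  split <- derive_age_split(rep(policy$N_grid, times = length(policy$days_grid)),
                            reproduction_ref)
  df <- data.frame(
    A = split$A, Y = split$Y,
    DAYS = rep(policy$days_grid, each = length(policy$N_grid)),
    quota = as.vector(policy$quota)
  )
  if (stats::var(df$quota) == 0) {
    root <- list(leaf = TRUE, quota = snap_to_grid(df$quota[1], policy$action_grid))
  } else {
    fit <- rpart::rpart(
      quota ~ A + Y + DAYS, data = df, method = "anova",
      control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                     minsplit = 2, minbucket = 1, xval = 0,
                                     maxcompete = 0, maxsurrogate = 0))
    root <- rpart_to_node(fit, node_id = 1L, action_grid = policy$action_grid)
  }
  structure(list(root = root, max_depth = max_depth,
                 action_grid = policy$action_grid),
            class = "ahm_policy_tree")
}

snap_to_grid <- function(x, grid) grid[which.min(abs(grid - x))]

# Convert an rpart fit into the package's recursive node representation.
# With maxcompete = maxsurrogate = 0 the splits matrix has exactly one row
# per internal node, in frame order.
rpart_to_node <- function(fit, node_id, action_grid) {
  frame <- fit$frame
  node_ids <- as.integer(rownames(frame))
  row <- match(node_id, node_ids)
  if (frame$var[row] == "<leaf>") {
    return(list(leaf = TRUE,
                quota = snap_to_grid(frame$yval[row], action_grid)))
  }
  internal_rows <- which(frame$var != "<leaf>")
  split_row <- fit$splits[match(row, internal_rows), , drop = TRUE]
  threshold <- unname(split_row["index"])
  # ncat -1: observations with var < threshold go left; +1: var >= threshold
  yes_is_lt <- split_row["ncat"] < 0
  left <- rpart_to_node(fit, 2L * node_id, action_grid)
  right <- rpart_to_node(fit, 2L * node_id + 1L, action_grid)
  list(leaf = FALSE, var = as.character(frame$var[row]),
       threshold = threshold,
       op = if (yes_is_lt) "<" else ">=",
       yes = left, no = right)
}

#' Predict quotas from a policy tree
#'
#' @param object An `ahm_policy_tree`.
#' @param newdata Data frame with columns `A`, `Y`, `DAYS` (thousands for A
#'   and Y).
#' @param ... Unused.
#' @return Numeric vector of quotas (thousands).
#' @export
predict.ahm_policy_tree <- function(object, newdata, ...) {
  one <- function(a, y, d) {
    node <- object$root
    while (!node$leaf) {
      x <- switch(node$var, A = a, Y = y, DAYS = d)
      cond <- if (node$op == "<") x < node$threshold else x >= node$threshold
      node <- if (cond) node$yes else node$no
    }
    node$quota
  }
  mapply(one, newdata$A, newdata$Y, newdata$DAYS)
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$yes), tree_depth(node$no))
}

tree_variables <- function(node) {
  if (node$leaf) return(character(0))
  c(node$var, tree_variables(node$yes), tree_variables(node$no))
}

tree_leaves <- function(node) {
  if (node$leaf) return(node$quota)
  c(tree_leaves(node$yes), tree_leaves(node$no))
}

format_node <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  if (node$leaf) return(sprintf("%squota = %.1f\n", pad, node$quota))
  paste0(
    sprintf("%s%s %s %.3g?\n", pad, node$var, node$op, node$threshold),
    sprintf("%syes:\n", pad), format_node(node$yes, indent + 1L),
    sprintf("%sno:\n", pad), format_node(node$no, indent + 1L)
  )
}

#' @exportS3Method base::format
format.ahm_policy_tree <- function(x, ...) format_node(x$root)

#' @exportS3Method base::print
print.ahm_policy_tree <- function(x, ...) {
  cat(sprintf("<ahm_policy_tree> depth %d, %d leaves\n",
              tree_depth(x$root), length(tree_leaves(x$root))))
  cat(format(x))
  invisible(x)
}

#' Export a policy tree as indented text and an optional DOT graph file
#'
#' @param tree An `ahm_policy_tree`.
#' @param path Path for the indented-text rendering.
#' @param dot_path Optional path for a Graphviz DOT description.
#' @return `path`, invisibly.
#' @export
write_policy_tree <- function(tree, path, dot_path = NULL) {
  writeLines(format(tree), path)
  if (!is.null(dot_path)) {
    edges <- character(0)
    labels <- character(0)
    walk <- function(node, id) {
      if (node$leaf) {
        labels <<- c(labels, sprintf('n%d [label="%.1f" shape=box];', id, node$quota))
        return(invisible())
      }
      labels <<- c(labels, sprintf('n%d [label="%s %s %.3g?"];',
                                   id, node$var, node$op, node$threshold))
      edges <<- c(edges,
                  sprintf('n%d -> n%d [label="yes"];', id, 2L * id),
                  sprintf('n%d -> n%d [label="no"];', id, 2L * id + 1L))
      walk(node$yes, 2L * id)
      walk(node$no, 2L * id + 1L)
    }
    walk(tree$root, 1L)
    writeLines(c("digraph policy_tree {", labels, edges, "}"), dot_path)
  }
  invisible(path)
}
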