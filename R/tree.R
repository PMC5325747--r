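#' Terminal node of a decision tree
#'
#' @param payoff finite numeric payoff (a utility or QALY total).
#' @param label node label; terminal labels identify the path outcome.
#' @return object of class `tn_terminal` (also `tn_node`).
#' @export
terminal_node <- function(payoff, label = "") {
  stopifnot(is.numeric(payoff), length(payoff) == 1L)
  structure(list(payoff = payoff, label = label),
            class = c("tn_terminal", "tn_node"))
}

#' Chance node of a decision tree
#'
#' Branch probabilities are stored as given; [validate_tree()] and
#' [rollback()] renormalize sums within `1e-6` of one silently and treat
#' larger deviations as violations (printed tables carry rounding, so tiny
#' deviations are expected; large ones are data errors).
#'
#' @param probs numeric vector of branch probabilities.
#' @param children list of `tn_node`s, same length as `probs`.
#' @param labels character vector of branch labels.
#' @param label node label.
#' @return object of class `tn_chance` (also `tn_node`).
#' @export
chance_node <- function(probs, children, labels = NULL, label = "") {
  stopifnot(is.numeric(probs), is.list(children),
            length(probs) == length(children), length(probs) >= 1L)
  for (ch in children) stopifnot(inherits(ch, "tn_node"))
  if (is.null(labels)) labels <- rep("", length(probs))
  stopifnot(length(labels) == length(probs))
  structure(list(probs = as.numeric(probs), children = children,
                 labels = as.character(labels), label = label),
            class = c("tn_chance", "tn_node"))
}

is_terminal <- function(node) inherits(node, "tn_terminal")

PROB_TOL <- 1e-6

#' Validate a decision tree
#'
#' Walks the tree and reports violations: negative or non-finite branch
#' probabilities, branch probabilities whose sum deviates from one by more
#' than `1e-6`, non-finite terminal payoffs, and nesting deeper than
#' `max_depth` (a finiteness guard).
#'
#' @param root a `tn_node`.
#' @param max_depth maximum allowed nesting depth.
#' @return list with elements `valid` (logical) and `violations` (character).
#' @export
validate_tree <- function(root, max_depth = 1000L) {
  violations <- character()
  walk <- function(node, depth, where) {
    if (depth > max_depth) {
      violations <<- c(violations,
                       sprintf("%s: depth exceeds %d (cycle or runaway recursion?)",
                               where, max_depth))
      return(invisible())
    }
    if (is_terminal(node)) {
      if (!is.finite(node$payoff)) {
        violations <<- c(violations,
                         sprintf("%s: non-finite payoff %s", where,
                                 format(node$payoff)))
      }
      return(invisible())
    }
    p <- node$probs
    if (any(!is.finite(p))) {
      violations <<- c(violations, sprintf("%s: non-finite probability", where))
    } else {
      if (any(p < 0)) {
        violations <<- c(violations,
                         sprintf("%s: negative probability %.4g", where, min(p)))
      }
      if (abs(sum(p) - 1) > PROB_TOL) {
        violations <<- c(violations,
                         sprintf("%s: probabilities sum to %.6g", where, sum(p)))
      }
    }
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], depth + 1L, paste0(where, "/", i))
    }
    invisible()
  }
  walk(root, 1L, "root")
  list(valid = length(violations) == 0L, violations = violations)
}

assert_valid_tree <- function(root) {
  rep <- validate_tree(root)
  if (!rep$valid) {
    stop("invalid decision tree:\n  ", paste(rep$violations, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Expected payoff of a decision tree by rollback
#'
#' Recursive expected-value evaluation from the leaves to the root: a
#' terminal returns its payoff, a chance node the probability-weighted mean
#' of its children.  Branch probabilities within `1e-6` of summing to one are
#' renormalized before weighting.
#'
#' @param root a `tn_node`; must pass [validate_tree()].
#' @return expected payoff (numeric scalar).
#' @export
rollback <- function(root) {
  assert_valid_tree(root)
  rollback_unchecked(root)
}

rollback_unchecked <- function(node) {
  if (is_terminal(node)) return(node$payoff)
  p <- node$probs / sum(node$probs)
  vals <- vapply(node$children, rollback_unchecked, 0)
  sum(p * vals)
}

#' Enumerate all root-to-terminal paths
#'
#' Brute-force oracle for [rollback()]: lists every path with its product
#' probability, terminal payoff and branch-label sequence.  The
#' probability-weighted payoff sum over all paths equals the rollback value,
#' and path probabilities sum to one.
#'
#' @param root a `tn_node`; must pass [validate_tree()].
#' @return data.frame with columns `prob`, `payoff`, and list-column
#'   `labels`.
#' @export
enumerate_paths <- function(root) {
  assert_valid_tree(root)
  acc <- list()
  walk <- function(node, prob, labels) {
    if (is_terminal(node)) {
      acc[[length(acc) + 1L]] <<- list(prob = prob, payoff = node$payoff,
                                       labels = c(labels, node$label))
      return(invisible())
    }
    p <- node$probs / sum(node$probs)
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], prob * p[i], c(labels, node$labels[i]))
    }
    invisible()
  }
  walk(root, 1, character())
  data.frame(
    prob = vapply(acc, `[[`, 0, "prob"),
    payoff = vapply(acc, `[[`, 0, "payoff"),
    labels = I(lapply(acc, `[[`, "labels")))
}

#' Expected payoff conditional on a path predicate
#'
#' Sub-tree expectations are taken by conditioning on a subset of paths:
#' the probability-weighted payoff over selected paths divided by their total
#' probability.
#'
#' @param root a `tn_node`.
#' @param predicate function taking one path's character vector of labels and
#'   returning `TRUE` to include the path.
#' @return conditional expected payoff.
#' @export
conditional_expectation <- function(root, predicate) {
  paths <- enumerate_paths(root)
  keep <- vapply(paths$labels, function(l) isTRUE(predicate(l)), NA)
  total <- sum(paths$prob[keep])
  if (!any(keep) || total <= 0) {
    stop("predicate selects paths of zero total probability")
  }
  sum(paths$prob[keep] * paths$payoff[keep]) / total
}

#' Serialize / deserialize a tree as JSON
#'
#' Nested-object JSON mirror of the node structure, for fixtures and
#' debugging.
#'
#' @param root a `tn_node`.
#' @param path file path.
#' @return `tree_to_json` returns the path invisibly; `tree_from_json`
#'   returns a `tn_node`.
#' @export
tree_to_json <- function(root, path) {
  to_list <- function(node) {
    if (is_terminal(node)) {
      list(kind = "terminal", payoff = node$payoff, label = node$label)
    } else {
      list(kind = "chance", label = node$label,
           branches = lapply(seq_along(node$children), function(i) {
             list(prob = node$probs[i], label = node$labels[i],
                  child = to_list(node$children[[i]]))
           }))
    }
  }
  jsonlite::write_json(to_list(root), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  from_list <- function(x) {
    if (identical(x$kind, "terminal")) {
      terminal_node(x$payoff, x$label)
    } else {
      chance_node(
        probs = vapply(x$branches, `[[`, 0, "prob"),
        children = lapply(x$branches, function(b) from_list(b$child)),
        labels = vapply(x$branches, `[[`, "", "label"),
        label = x$label)
    }
  }
  from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
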