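# Recursive tree growth, routing, rendering and serialisation.

#' Grow a signal detection tree
#'
#' Recursive binary partitioning of the registry: at each node the best
#' admissible split (maximum weighted kappa, see [best_split()]) divides the
#' subgroup, and both children are partitioned further with ALL candidate
#' variables still available (a variable may reappear deeper in either
#' branch). A node becomes a leaf when any of the three stopping rules
#' applies: (1) a child below `min_subgroup` subjects would result (a node
#' smaller than `2 * min_subgroup` cannot split at all), (2) no candidate
#' passes the chi-square gate `p < alpha`, (3) the lower limit of the
#' kappa confidence interval of the best candidate does not exceed zero.
#' The result is deterministic given the data, the variable order and the
#' control settings, and invariant to row order.
#'
#' @param data Registry data frame (one row per subject).
#' @param outcome Name of the binary severity column.
#' @param variables Candidate predictors, in tie-break priority order.
#' @param control An [sda_control()].
#' @return An object of class `sda_tree`. Leaves are labelled `S1`, `S2`,
#'   ... in top-down, positive-branch-first order.
#' @export
grow_sda <- function(data, outcome = "severity", variables = sda_variables(),
                     control = sda_control()) {
  if (nrow(data) == 0) stop_domain("`data` must be nonempty.")
  unknown <- setdiff(c(outcome, variables), names(data))
  if (length(unknown) > 0) {
    stop_domain(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  data <- as_tibble(data)

  build <- function(idx, depth) {
    sub <- data[idx, , drop = FALSE]
    ysev <- outcome_severe(sub[[outcome]])
    node <- list(node_id = NA_integer_, depth = as.integer(depth),
                 n = length(idx), n_severe = as.integer(sum(ysev)),
                 split = NULL, pos = NULL, neg = NULL, subgroup = NA_character_)
    can_try <- node$n >= 2L * control$min_subgroup &&
      (is.null(control$max_depth) || depth < control$max_depth)
    if (can_try) {
      sp <- best_split(sub, outcome = outcome, variables = variables,
                       control = control)
      if (!is.null(sp)) {
        take <- split_apply(sp, sub)
        node$split <- sp
        node$pos <- build(idx[take], depth + 1L)
        node$neg <- build(idx[!take], depth + 1L)
      }
    }
    node
  }

  root <- number_nodes(build(seq_len(nrow(data)), 0L))
  tree <- structure(
    list(root = root, outcome = outcome, variables = variables,
         control = control, n = nrow(data),
         n_severe = as.integer(sum(outcome_severe(data[[outcome]])))),
    class = "sda_tree")
  label_leaves(tree)
}

# Sequential pre-order node ids (root = 1, positive branch first).
number_nodes <- function(root) {
  counter <- 0L
  walk <- function(node) {
    counter <<- counter + 1L
    node$node_id <- counter
    if (!is.null(node$split)) {
      node$pos <- walk(node$pos)
      node$neg <- walk(node$neg)
    }
    node
  }
  walk(root)
}

# Pre-order (positive branch first) leaf labels S1, S2, ...
label_leaves <- function(tree) {
  counter <- 0L
  walk <- function(node) {
    if (is.null(node$split)) {
      counter <<- counter + 1L
      node$subgroup <- paste0("S", counter)
    } else {
      node$pos <- walk(node$pos)
      node$neg <- walk(node$neg)
    }
    node
  }
  tree$root <- walk(tree$root)
  tree
}

is_leaf <- function(node) is.null(node$split)

walk_nodes <- function(node, f) {
  out <- list(f(node))
  if (!is_leaf(node)) {
    out <- c(out, walk_nodes(node$pos, f), walk_nodes(node$neg, f))
  }
  out
}

#' Route records to their subgroup (leaf)
#'
#' Every record follows the split rules from the root to exactly one leaf.
#' A missing value in a variable the tree uses raises a routing error naming
#' that variable.
#'
#' @param data Registry data frame.
#' @param tree A fitted [grow_sda()] tree.
#' @return `data` with two added columns: `.subgroup` (factor over the leaf
#'   labels in tree order) and `.node_id` (the leaf's node id).
#' @export
assign_subgroup <- function(data, tree) {
  stopifnot(inherits(tree, "sda_tree"))
  n <- nrow(data)
  sub <- rep(NA_character_, n)
  nid <- rep(NA_integer_, n)
  route <- function(node, idx) {
    if (length(idx) == 0 && n > 0) return(invisible())
    if (is_leaf(node)) {
      sub[idx] <<- node$subgroup
      nid[idx] <<- node$node_id
      return(invisible())
    }
    take <- split_apply(node$split, data[idx, , drop = FALSE])
    route(node$pos, idx[take])
    route(node$neg, idx[!take])
  }
  route(tree$root, seq_len(n))
  labs <- leaf_labels(tree)
  data |>
    mutate(.subgroup = factor(sub, levels = labs), .node_id = nid)
}

leaf_labels <- function(tree) {
  unlist(walk_nodes(tree$root, function(nd) if (is_leaf(nd)) nd$subgroup else NULL))
}

# Per-leaf planted severe probability (synthetic truth trees); named by leaf.
leaf_probs <- function(tree) {
  out <- walk_nodes(tree$root, function(nd) {
    if (is_leaf(nd)) setNames(nd$p_severe %||% NA_real_, nd$subgroup) else NULL
  })
  unlist(out)
}

#' @export
#' @rdname grow_sda
#' @param x,... An `sda_tree` and further arguments (ignored).
print.sda_tree <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.sda_tree <- function(x, ...) {
  fmt1 <- function(p) sprintf("%.1f", round_half_up(p, 1))
  hdr <- function(nd) {
    extra <- if (!is.null(nd$p_severe)) sprintf(" [planted p=%.3f]", nd$p_severe) else ""
    sprintf("n=%d, severe=%d (%s%%)%s", nd$n, nd$n_severe,
            fmt1(100 * nd$n_severe / nd$n), extra)
  }
  lines <- character()
  walk <- function(nd, indent) {
    if (is_leaf(nd)) {
      lines <<- c(lines, sprintf("%s<%s> %s", indent, nd$subgroup, hdr(nd)))
    } else {
      sp <- nd$split
      stat <- if (is.na(sp$kappa)) "" else
        sprintf(" [kappa=%.3f (%.3f, %.3f), chi2=%.2f, p=%.3g]",
                sp$kappa, sp$kappa_lower, sp$kappa_upper, sp$chi2, sp$p_value)
      lines <<- c(lines, sprintf("%s|- %s%s", indent, split_label(sp), stat))
      walk(nd$pos, paste0(indent, "   "))
      lines <<- c(lines, sprintf("%s|- %s", indent, split_negate_label(sp)))
      walk(nd$neg, paste0(indent, "   "))
    }
  }
  lines <- c(sprintf("signal detection tree (outcome: %s)", x$outcome),
             sprintf("root %s", hdr(x$root)))
  if (is_leaf(x$root)) {
    lines <- c(lines, sprintf("<%s> %s", x$root$subgroup, hdr(x$root)))
  } else {
    walk(x$root, "")
  }
  lines
}

#' Tidy a signal detection tree into a node table
#'
#' One row per node with subgroup size, severe count and percentage, and for
#' internal nodes the split rule and its statistics.
#'
#' @param x An `sda_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node (root first, positive branch
#'   before negative).
#' @method tidy sda_tree
#' @export
tidy.sda_tree <- function(x, ...) {
  rows <- walk_nodes(x$root, function(nd) {
    sp <- nd$split
    tibble(
      node_id = nd$node_id,
      depth = nd$depth,
      is_leaf = is_leaf(nd),
      subgroup = nd$subgroup,
      n = nd$n,
      n_severe = nd$n_severe,
      severe_pct = round_half_up(100 * nd$n_severe / nd$n, 1),
      variable = if (is.null(sp)) NA_character_ else sp$variable,
      rule = if (is.null(sp)) NA_character_ else split_label(sp),
      op = if (is.null(sp)) NA_character_ else sp$op,
      cut = if (is.null(sp)) NA_real_ else sp$cut,
      kappa = if (is.null(sp)) NA_real_ else sp$kappa,
      kappa_lower = if (is.null(sp)) NA_real_ else sp$kappa_lower,
      kappa_upper = if (is.null(sp)) NA_real_ else sp$kappa_upper,
      chi2 = if (is.null(sp)) NA_real_ else sp$chi2,
      p_value = if (is.null(sp)) NA_real_ else sp$p_value
    )
  })
  bind_rows(rows)
}

#' @rdname tidy.sda_tree
#' @method glance sda_tree
#' @export
glance.sda_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble(
    n = x$n, n_severe = x$n_severe,
    n_nodes = nrow(nodes), n_leaves = sum(nodes$is_leaf),
    n_splits = sum(!nodes$is_leaf), depth = max(nodes$depth)
  )
}

node_to_list <- function(nd) {
  out <- list(node_id = nd$node_id, depth = nd$depth, n = nd$n,
              n_severe = nd$n_severe,
              severe_prop = nd$n_severe / nd$n)
  if (!is.null(nd$p_severe)) out$p_severe <- nd$p_severe
  if (is_leaf(nd)) {
    out$subgroup <- nd$subgroup
  } else {
    sp <- nd$split
    out$split <- list(
      variable = sp$variable, var_type = sp$var_type, op = sp$op,
      cut = sp$cut, set = as.list(sp$set), levels = as.list(sp$levels),
      kappa = sp$kappa, kappa_lower = sp$kappa_lower,
      kappa_upper = sp$kappa_upper, chi2 = sp$chi2, p_value = sp$p_value,
      n_pos = sp$n_pos, n_neg = sp$n_neg, label = split_label(sp)
    )
    out$pos <- node_to_list(nd$pos)
    out$neg <- node_to_list(nd$neg)
  }
  out
}

node_from_list <- function(l) {
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  int <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  nd <- list(node_id = as.integer(l$node_id), depth = as.integer(l$depth),
             n = as.integer(l$n), n_severe = as.integer(l$n_severe),
             split = NULL, pos = NULL, neg = NULL,
             subgroup = if (is.null(l$subgroup)) NA_character_ else l$subgroup)
  if (!is.null(l$p_severe)) nd$p_severe <- as.numeric(l$p_severe)
  if (!is.null(l$split)) {
    s <- l$split
    nd$split <- list(
      variable = s$variable, var_type = s$var_type, op = s$op,
      cut = num(s$cut),
      set = if (length(s$set)) as.character(unlist(s$set)) else NULL,
      levels = if (length(s$levels)) as.character(unlist(s$levels)) else NULL,
      kappa = num(s$kappa), kappa_lower = num(s$kappa_lower),
      kappa_upper = num(s$kappa_upper), chi2 = num(s$chi2),
      p_value = num(s$p_value), n_pos = int(s$n_pos),
      n_neg = int(s$n_neg))
    nd$pos <- node_from_list(l$pos)
    nd$neg <- node_from_list(l$neg)
  }
  nd
}

#' Serialise a signal detection tree to JSON
#'
#' The document carries every node (rules, kappa with its CI, chi-square,
#' p-value, sizes, severe counts and proportions) plus the fit settings, at
#' full numeric precision, and round-trips through [tree_from_json()] to an
#' identical tree.
#'
#' @param tree An `sda_tree`.
#' @return A JSON string (class `json`).
#' @export
tree_to_json <- function(tree) {
  ctl <- tree$control
  doc <- list(
    outcome = tree$outcome,
    variables = as.list(tree$variables),
    control = list(r = ctl$r, alpha = ctl$alpha, ci_level = ctl$ci_level,
                   min_subgroup = ctl$min_subgroup, max_depth = ctl$max_depth,
                   n_boot = ctl$n_boot, boot_seed = ctl$boot_seed),
    n = tree$n, n_severe = tree$n_severe,
    root = node_to_list(tree$root)
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

#' @rdname tree_to_json
#' @param json A JSON string or file path produced by [tree_to_json()].
#' @export
tree_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ctl <- doc$control
  tree <- structure(list(
    root = node_from_list(doc$root),
    outcome = doc$outcome,
    variables = as.character(unlist(doc$variables)),
    control = sda_control(r = ctl$r, alpha = ctl$alpha,
                          ci_level = ctl$ci_level,
                          min_subgroup = ctl$min_subgroup,
                          max_depth = ctl$max_depth,
                          n_boot = ctl$n_boot, boot_seed = ctl$boot_seed),
    n = as.integer(doc$n), n_severe = as.integer(doc$n_severe)
  ), class = "sda_tree")
  tree
}

#' Render a tree as JSON plus indented text
#'
#' @param tree An `sda_tree`.
#' @param json_path,text_path Optional output file paths.
#' @return Invisibly, `list(json = <json string>, text = <character lines>)`.
#' @export
render_tree <- function(tree, json_path = NULL, text_path = NULL) {
  js <- tree_to_json(tree)
  tx <- format(tree)
  if (!is.null(json_path)) writeLines(js, json_path)
  if (!is.null(text_path)) writeLines(tx, text_path)
  invisible(list(json = js, text = tx))
}

#' Plot a signal detection tree
#'
#' Dendrogram-style layout: leaves are evenly spaced, internal nodes sit at
#' the mean of their children, depth runs downward. Internal nodes are
#' labelled with their split rule, leaves with their subgroup label, size
#' and percentage severe.
#'
#' @param object An `sda_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sda_tree
#' @export
autoplot.sda_tree <- function(object, ...) {
  leaf_x <- 0
  layout <- function(nd) {
    if (is_leaf(nd)) {
      leaf_x <<- leaf_x + 1
      tibble(node_id = nd$node_id, x = leaf_x, y = -nd$depth,
             label = sprintf("%s\nn=%d\n%.1f%%", nd$subgroup, nd$n,
                             round_half_up(100 * nd$n_severe / nd$n, 1)),
             is_leaf = TRUE, parent = NA_integer_)
    } else {
      l <- layout(nd$pos)
      r <- layout(nd$neg)
      kids <- bind_rows(l, r)
      kids$parent[kids$node_id %in% c(nd$pos$node_id, nd$neg$node_id)] <- nd$node_id
      me <- tibble(node_id = nd$node_id,
                   x = mean(c(l$x[l$node_id == nd$pos$node_id],
                              r$x[r$node_id == nd$neg$node_id])),
                   y = -nd$depth,
                   label = split_label(nd$split), is_leaf = FALSE,
                   parent = NA_integer_)
      bind_rows(me, kids)
    }
  }
  nodes <- layout(object$root)
  seg <- nodes |>
    filter(!is.na(.data$parent)) |>
    left_join(nodes |> select("node_id", px = "x", py = "y"),
              by = c(parent = "node_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = .data$py,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey50") +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label,
                                     fill = .data$is_leaf),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#cfe8cf", `FALSE` = "white")) +
    ggplot2::theme_void()
}
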