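# Group-comparison and subgroup cross-validation tables.

default_table_variables <- function(data) {
  drop <- c("record_id", "injury_datetime", "residence_x", "residence_y",
            "injury_x", "injury_y", "road_width_m", "unreachable",
            ".subgroup", ".node_id")
  setdiff(names(data), drop)
}

# Shared engine: per-variable per-group summaries plus one comparison test
# per variable. Continuous variables get mean/SD and a two-sample t-test
# (pooled variance by default, Welch on request) for two groups or a one-way
# ANOVA F-test for more; categorical variables get counts with one-decimal
# percentages and a Pearson chi-square test of independence on the full RxC
# table (no continuity correction). Percentages round half up.
summarise_by_group <- function(data, grouping, variables, welch = FALSE,
                               force_anova = FALSE) {
  g <- data[[grouping]]
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  groups <- levels(g)
  rows <- purrr::map(variables, function(var) {
    x <- data[[var]]
    if (is.numeric(x)) {
      stats_tbl <- tibble(
        variable = var, type = "continuous", level = NA_character_,
        group = groups,
        n = as.integer(tapply(!is.na(x), g, sum)),
        pct = NA_real_,
        mean = as.numeric(tapply(x, g, mean, na.rm = TRUE)),
        sd = as.numeric(tapply(x, g, sd, na.rm = TRUE))
      )
      small <- any(tapply(!is.na(x), g, sum) < 2)
      if (length(groups) < 2 || small) {
        if (small) warn(paste0("`", var, "`: a group has fewer than 2 observations; test omitted."))
        stat <- NA_real_; p <- NA_real_
      } else if (length(groups) == 2 && !force_anova) {
        tt <- t.test(x ~ g, var.equal = !welch)
        stat <- unname(tt$statistic); p <- tt$p.value
      } else {
        fit <- anova(aov(x ~ g))
        stat <- fit$`F value`[1]; p <- fit$`Pr(>F)`[1]
      }
      stats_tbl$statistic <- stat
      stats_tbl$p_value <- p
      stats_tbl
    } else {
      f <- if (is.factor(x)) x else factor(x)
      tab <- table(f, g)
      if (length(groups) >= 2 && nrow(tab) >= 2 && all(colSums(tab) > 0)) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      } else {
        stat <- NA_real_; p <- NA_real_
      }
      cn <- colSums(tab)
      purrr::map_dfr(rownames(tab), function(lv) {
        tibble(variable = var, type = "categorical", level = lv,
               group = groups,
               n = as.integer(tab[lv, ]),
               pct = pct1(as.numeric(tab[lv, ]), as.numeric(cn)),
               mean = NA_real_, sd = NA_real_,
               statistic = stat, p_value = p)
      })
    }
  })
  out <- bind_rows(rows)
  out$group <- factor(out$group, levels = groups)
  attr(out, "grouping") <- grouping
  class(out) <- c("group_summary", class(out))
  out
}

#' Compare study variables between groups
#'
#' Builds the descriptive comparison table: for each study variable, counts
#' and one-decimal percentages (categorical) or mean and SD (continuous) per
#' group, with a two-sided two-sample t-test (pooled variance, or Welch via
#' `welch = TRUE`) for continuous variables and a Pearson chi-square test of
#' independence on the full RxC table for categorical ones. A group with
#' fewer than 2 observations of a continuous variable omits the test with a
#' warning.
#'
#' @param data Registry tibble.
#' @param grouping Name of the grouping column (e.g. `"age_group"`), which
#'   must yield at least two nonempty groups.
#' @param variables Variables to summarise; defaults to every study column.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return A `group_summary` tibble, one row per variable level and group.
#' @export
compare_groups <- function(data, grouping, variables = NULL, welch = FALSE) {
  g <- data[[grouping]]
  if (is.null(g)) stop_domain(paste0("unknown grouping column: ", grouping))
  k <- length(unique(g[!is.na(g)]))
  if (k < 2) stop_domain("`grouping` must yield at least two nonempty groups.")
  variables <- variables %||% setdiff(default_table_variables(data), grouping)
  summarise_by_group(data, grouping, variables, welch = welch)
}

#' Profile the subgroups of a fitted tree
#'
#' The cross-validation table: records are routed to the tree's leaves and
#' every study variable is compared across subgroups — one-way ANOVA for
#' continuous variables, chi-square tests of independence for categorical
#' ones — including the per-subgroup proportion severely injured (the
#' `severity` row). With a single leaf the summaries equal the whole-sample
#' values and tests are omitted.
#'
#' @param data Registry tibble (every record must be routable).
#' @param tree A fitted [grow_sda()] tree.
#' @param variables Variables to profile; defaults to the tree's candidate
#'   variables plus the outcome.
#' @return A `group_summary` tibble with one column block per subgroup.
#' @export
subgroup_profile <- function(data, tree, variables = NULL) {
  routed <- assign_subgroup(data, tree)
  variables <- variables %||% unique(c(intersect(tree$variables, names(data)),
                                       tree$outcome))
  summarise_by_group(routed, ".subgroup", variables, force_anova = TRUE)
}

#' Pool subgroup proportions back to a combined percentage
#'
#' Reconstructs each subgroup's event count as `round(n * prop / 100)`
#' (half-up), sums counts and sizes, and returns the pooled percentage to
#' one decimal. This is how combined severe-injury percentages are reported
#' across adjacent subgroups.
#'
#' @param subgroups Data frame with columns `n` (subgroup size) and `prop`
#'   (percentage, 0-100).
#' @return Pooled percentage (one decimal).
#' @export
#' @examples
#' pooled_proportion(data.frame(n = c(55, 74), prop = c(45.5, 27.0)))  # 34.9
pooled_proportion <- function(subgroups) {
  stopifnot(all(c("n", "prop") %in% names(subgroups)))
  n <- subgroups$n
  prop <- subgroups$prop
  if (any(n < 1) || any(prop < 0 | prop > 100)) {
    stop_domain("`n` must be >= 1 and `prop` in [0, 100].")
  }
  counts <- round_half_up(n * prop / 100, 0)
  pct1(sum(counts), sum(n))
}

#' Reconcile printed subgroup percentages against stratum totals
#'
#' Consistency checker for published subgroup tables: the severe count
#' implied by each subgroup's size and percentage (`round(n * prop / 100)`,
#' half-up) is computed, and the implied total is compared with the
#' stratum's severe count (and, when given, the subgroup sizes with the
#' stratum size). Useful for flagging internally inconsistent printed
#' values.
#'
#' @param subgroups Data frame with columns `n` and `prop` (and optionally a
#'   `subgroup` label column).
#' @param total_n Stratum size the subgroup sizes should sum to (optional).
#' @param total_severe Stratum severe count the implied counts should sum
#'   to (optional).
#' @return A `subgroup_reconciliation` list: the per-subgroup table with
#'   implied counts, the implied totals, and logical `consistent_n` /
#'   `consistent_severe` flags.
#' @export
reconcile_subgroups <- function(subgroups, total_n = NULL, total_severe = NULL) {
  tab <- as_tibble(subgroups) |>
    mutate(implied_severe = round_half_up(.data$n * .data$prop / 100, 0))
  out <- list(
    table = tab,
    n_total = sum(tab$n),
    implied_severe_total = sum(tab$implied_severe),
    pooled_pct = pct1(sum(tab$implied_severe), sum(tab$n)),
    expected_n = total_n,
    expected_severe = total_severe,
    consistent_n = if (is.null(total_n)) NA else sum(tab$n) == total_n,
    consistent_severe = if (is.null(total_severe)) NA else
      sum(tab$implied_severe) == total_severe
  )
  structure(out, class = "subgroup_reconciliation")
}

#' @export
print.subgroup_reconciliation <- function(x, ...) {
  print(x$table)
  cat(sprintf("sizes sum to %d%s; implied severe count %d%s; pooled %.1f%%\n",
              x$n_total,
              if (is.na(x$consistent_n)) "" else
                sprintf(" (expected %d: %s)", x$expected_n,
                        if (x$consistent_n) "consistent" else "INCONSISTENT"),
              x$implied_severe_total,
              if (is.na(x$consistent_severe)) "" else
                sprintf(" (expected %d: %s)", x$expected_severe,
                        if (x$consistent_severe) "consistent" else "INCONSISTENT"),
              x$pooled_pct))
  invisible(x)
}

# Aligned plain-text rendering of a group_summary, for the pipeline's .txt
# outputs.
group_summary_text <- function(gs) {
  grouping <- attr(gs, "grouping")
  groups <- levels(gs$group)
  key <- gs |>
    mutate(cell = ifelse(.data$type == "continuous",
                         sprintf("%.2f (%.2f)", .data$mean, .data$sd),
                         sprintf("%d (%.1f%%)", .data$n, .data$pct))) |>
    select("variable", "level", "group", "cell", "p_value") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
  hdr <- c("variable", "level", groups, "p")
  body <- key |>
    mutate(p = ifelse(is.na(.data$p_value), "",
                      formatC(.data$p_value, format = "g", digits = 3))) |>
    select(-"p_value") |>
    mutate(level = ifelse(is.na(.data$level), "", .data$level))
  mat <- rbind(hdr, as.matrix(body))
  widths <- apply(nchar(mat), 2, max)
  apply(mat, 1, function(r) {
    paste(mapply(function(s, w) formatC(s, width = w, flag = "-"), r, widths),
          collapse = "  ")
  })
}
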