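# Candidate split enumeration and the maximum-weighted-kappa split search.

#' Control parameters for the signal detection analysis
#'
#' @param r Kappa weight in `[0, 1]`; `0.5` (Cohen's kappa) weighs false
#'   positives and false negatives equally.
#' @param alpha Significance level of the chi-square gate (default `0.05`);
#'   stopping rule 2: no split is made when no candidate reaches `p < alpha`.
#' @param ci_level Coverage of the kappa confidence interval (default
#'   `0.95`); stopping rule 3: no split is made when the interval's lower
#'   limit is not above zero.
#' @param min_subgroup Minimum subgroup size (default `10`); stopping rule
#'   1: splits that would create a child below this size are inadmissible.
#' @param max_depth Optional cap on tree depth (`NULL` = unlimited).
#' @param n_boot,boot_seed Bootstrap settings for the kappa interval when
#'   `r != 0.5` (see [kappa_confidence_interval()]).
#' @return An `sda_control` list.
#' @export
sda_control <- function(r = 0.5, alpha = 0.05, ci_level = 0.95,
                        min_subgroup = 10, max_depth = NULL,
                        n_boot = 1000, boot_seed = 20170602) {
  stopifnot(r >= 0, r <= 1, alpha > 0, alpha < 1, ci_level > 0, ci_level < 1,
            min_subgroup >= 1, is.null(max_depth) || max_depth >= 0,
            n_boot >= 1000)
  structure(list(r = r, alpha = alpha, ci_level = ci_level,
                 min_subgroup = as.integer(min_subgroup),
                 max_depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
                 n_boot = as.integer(n_boot), boot_seed = as.integer(boot_seed)),
            class = "sda_control")
}

# How a column enters the split search.
sda_var_type <- function(x) {
  if (is.numeric(x)) return("continuous")
  if (is.ordered(x)) return("ordinal")
  if (is.logical(x)) return("binary")
  f <- as.factor(x)
  if (nlevels(droplevels(f)) <= 2) "binary" else "nominal"
}

#' Enumerate the candidate splits of one variable
#'
#' Continuous variables yield the midpoints between consecutive sorted
#' distinct values; ordinal variables the boundaries between consecutive
#' observed classes; binary variables the single two-group split; nominal
#' variables one one-vs-rest candidate per observed level. A constant
#' variable yields no candidates (empty tibble, not an error).
#'
#' @param data Data frame holding the variable.
#' @param variable Column name.
#' @return Tibble with columns `variable`, `type`, `cut` (threshold
#'   candidates; `NA` for category splits) and `level` (the ordinal class
#'   below the boundary, or the singled-out category).
#' @export
enumerate_cutpoints <- function(data, variable) {
  if (!variable %in% names(data)) {
    stop_domain(paste0("unknown variable: ", variable))
  }
  x <- data[[variable]]
  x <- x[!is.na(x)]
  type <- sda_var_type(x)
  empty <- tibble(variable = character(), type = character(),
                  cut = double(), level = character())
  if (type == "continuous") {
    u <- sort(unique(x))
    if (length(u) < 2) return(empty)
    cuts <- (u[-length(u)] + u[-1]) / 2
    return(tibble(variable = variable, type = type, cut = cuts, level = NA_character_))
  }
  if (type == "ordinal") {
    codes <- sort(unique(as.integer(x)))
    if (length(codes) < 2) return(empty)
    cuts <- (codes[-length(codes)] + codes[-1]) / 2
    return(tibble(variable = variable, type = type, cut = cuts,
                  level = levels(x)[floor(cuts)]))
  }
  lev <- if (is.logical(x)) as.character(sort(unique(x), decreasing = TRUE)) else levels(droplevels(as.factor(x)))
  if (length(lev) < 2) return(empty)
  if (type == "binary") {
    return(tibble(variable = variable, type = type, cut = NA_real_, level = lev[1]))
  }
  tibble(variable = variable, type = type, cut = NA_real_, level = lev)
}

# Score every admissible candidate of one variable, both orientations of
# threshold partitions (the severe-enriched side becomes the positive
# branch). Returns parallel vectors of oriented candidates with 2x2 counts
# (plain vectors: this is the hot path of the tree search).
score_variable <- function(x, ysev, variable, vi, r) {
  n <- length(ysev)
  S <- sum(ysev)
  type <- sda_var_type(x)

  orient <- function(a_le, b_le, c_le, d_le, cut, level) {
    k_le <- weighted_kappa(a_le, b_le, c_le, d_le, r)
    k_gt <- weighted_kappa(c_le, d_le, a_le, b_le, r)
    flip <- k_gt > k_le
    list(
      variable = rep(variable, length(cut)), vi = rep(vi, length(cut)),
      type = rep(type, length(cut)),
      op = ifelse(flip, ">", "<="), cut = cut, level = level,
      a = ifelse(flip, c_le, a_le), b = ifelse(flip, d_le, b_le),
      c = ifelse(flip, a_le, c_le), d = ifelse(flip, b_le, d_le),
      kappa = pmax(k_le, k_gt),
      chi2 = chi2_stat_2x2(a_le, b_le, c_le, d_le)
    )
  }

  if (type %in% c("continuous", "ordinal")) {
    v <- if (type == "ordinal") as.integer(x) else as.numeric(x)
    u <- sort(unique(v))
    m <- length(u)
    if (m < 2) return(NULL)
    grp <- match(v, u)
    nn <- tabulate(grp, m)
    ss <- as.vector(rowsum(as.numeric(ysev), grp, reorder = TRUE))
    cn <- cumsum(nn)
    cs <- cumsum(ss)
    a_le <- cs[-m]; n1 <- cn[-m]
    b_le <- n1 - a_le; c_le <- S - a_le; d_le <- (n - n1) - c_le
    cuts <- (u[-m] + u[-1]) / 2
    lev <- if (type == "ordinal") levels(x)[floor(cuts)] else rep(NA_character_, m - 1)
    return(orient(a_le, b_le, c_le, d_le, cuts, lev))
  }

  xc <- as.character(x)
  lev <- if (is.logical(x)) as.character(sort(unique(x), decreasing = TRUE)) else
    levels(droplevels(as.factor(x)))
  if (length(lev) < 2) return(NULL)
  pos_sev <- vapply(lev, function(L) sum(ysev[xc == L]), numeric(1))
  pos_n <- vapply(lev, function(L) sum(xc == L), numeric(1))
  a <- pos_sev; b <- pos_n - pos_sev; c <- S - a; d <- (n - pos_n) - c
  out <- list(
    variable = rep(variable, length(lev)), vi = rep(vi, length(lev)),
    type = rep(type, length(lev)), op = rep("in", length(lev)),
    cut = rep(NA_real_, length(lev)), level = lev,
    a = a, b = b, c = c, d = d,
    kappa = weighted_kappa(a, b, c, d, r),
    chi2 = chi2_stat_2x2(a, b, c, d)
  )
  if (type == "binary") {
    # one partition; keep the severe-enriched orientation
    keep <- which.max(out$kappa)
    out <- lapply(out, `[`, keep)
  }
  out
}

split_label <- function(sp) {
  if (sp$op == "in") {
    paste0(sp$variable, " in {", paste(sp$set, collapse = ", "), "}")
  } else if (sp$var_type == "ordinal") {
    bound <- sp$levels[floor(sp$cut)]
    paste0(sp$variable, " ", sp$op, " ", bound)
  } else {
    paste0(sp$variable, " ", sp$op, " ", format(sp$cut, digits = 6))
  }
}

split_negate_label <- function(sp) {
  if (sp$op == "in") {
    paste0(sp$variable, " not in {", paste(sp$set, collapse = ", "), "}")
  } else if (sp$var_type == "ordinal") {
    bound <- sp$levels[floor(sp$cut)]
    paste0(sp$variable, " ", if (sp$op == "<=") ">" else "<=", " ", bound)
  } else {
    paste0(sp$variable, " ", if (sp$op == "<=") ">" else "<=", " ",
           format(sp$cut, digits = 6))
  }
}

# Positive-branch indicator of a fitted split on a data frame.
split_apply <- function(sp, data) {
  if (!sp$variable %in% names(data)) {
    stop_domain(paste0("routing error: variable `", sp$variable, "` is missing."))
  }
  x <- data[[sp$variable]]
  if (anyNA(x)) {
    stop_domain(paste0("routing error: variable `", sp$variable, "` has missing values."))
  }
  if (sp$op == "in") {
    as.character(x) %in% sp$set
  } else {
    v <- if (identical(sp$var_type, "ordinal")) {
      as.numeric(match(as.character(x), sp$levels))
    } else {
      as.numeric(x)
    }
    if (sp$op == "<=") v <= sp$cut else v > sp$cut
  }
}

#' Find the best admissible split of a subgroup
#'
#' Scores every candidate split of every variable (all cut-points of
#' continuous and ordinal variables in both orientations, the single split
#' of binary variables, one-vs-rest for nominal variables) by the weighted
#' kappa between the split indicator and the severity outcome. Candidates
#' that would create a child smaller than `min_subgroup`, that miss the
#' chi-square gate `p < alpha`, or whose kappa confidence interval reaches
#' zero or below are inadmissible. Among the rest the maximum-kappa
#' candidate wins; ties break by smaller p-value, then by position in
#' `variables`, then by smaller cut value. Variables with missing values in
#' the subgroup are ineligible at that node (no surrogate splits).
#'
#' @param data Subgroup data frame.
#' @param outcome Name of the binary severity column (factor minor/severe or
#'   logical, `TRUE` = severe).
#' @param variables Character vector of candidate predictor names, in
#'   priority order for tie-breaking.
#' @param control An [sda_control()].
#' @return A split description (list with the rule, 2x2 counts, kappa and
#'   its CI, chi-square and p-value), or `NULL` when no admissible
#'   significant split exists.
#' @export
best_split <- function(data, outcome = "severity", variables = sda_variables(),
                       control = sda_control()) {
  unknown <- setdiff(c(outcome, variables), names(data))
  if (length(unknown) > 0) {
    stop_domain(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  ysev <- outcome_severe(data[[outcome]])
  n <- length(ysev)
  S <- sum(ysev)
  if (n == 0 || S == 0 || S == n) return(NULL)

  parts <- purrr::imap(variables, function(var, vi) {
    x <- data[[var]]
    if (anyNA(x)) return(NULL)  # missing values: variable ineligible here
    score_variable(x, ysev, var, vi, control$r)
  })
  parts <- compact(parts)
  if (length(parts) == 0) return(NULL)
  field <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
  cand <- list(variable = field("variable"), vi = field("vi"),
               type = field("type"), op = field("op"), cut = field("cut"),
               level = field("level"), a = field("a"), b = field("b"),
               c = field("c"), d = field("d"), kappa = field("kappa"),
               chi2 = field("chi2"))
  cand$n_pos <- cand$a + cand$b
  cand$n_neg <- cand$c + cand$d
  keep <- cand$n_pos >= control$min_subgroup & cand$n_neg >= control$min_subgroup
  if (!any(keep)) return(NULL)
  cand <- lapply(cand, `[`, keep)
  cand$p_value <- ifelse(cand$chi2 == 0, 1,
                         pchisq(cand$chi2, df = 1, lower.tail = FALSE))
  keep <- cand$p_value < control$alpha
  if (!any(keep)) return(NULL)
  cand <- lapply(cand, `[`, keep)
  ord <- order(-cand$kappa, cand$p_value, cand$vi,
               ifelse(is.na(cand$cut), Inf, cand$cut), cand$level,
               method = "radix")
  cand <- lapply(cand, `[`, ord)

  use_fce <- isTRUE(all.equal(control$r, 0.5))
  z <- qnorm(1 - (1 - control$ci_level) / 2)
  if (use_fce) {
    se <- kappa_se_fce(cand$a, cand$b, cand$c, cand$d)
    lower <- pmax(cand$kappa - z * se, -1)
    upper <- pmin(cand$kappa + z * se, 1)
    hit <- which(lower > 0)
    if (length(hit) == 0) return(NULL)
    i <- hit[1]
    ci <- c(lower[i], upper[i])
  } else {
    i <- NULL
    for (k in seq_along(cand$kappa)) {
      ci_k <- kappa_confidence_interval(cand$a[k], cand$b[k], cand$c[k],
                                        cand$d[k], r = control$r,
                                        level = control$ci_level,
                                        n_boot = control$n_boot,
                                        boot_seed = control$boot_seed)
      if (ci_k[1] > 0) {
        i <- k
        ci <- unname(ci_k)
        break
      }
    }
    if (is.null(i)) return(NULL)
  }
  x <- data[[cand$variable[i]]]
  list(
    variable = cand$variable[i],
    var_type = cand$type[i],
    op = cand$op[i],
    cut = cand$cut[i],
    set = if (cand$op[i] == "in") cand$level[i] else NULL,
    levels = if (cand$type[i] == "ordinal") levels(x) else NULL,
    kappa = cand$kappa[i],
    kappa_lower = ci[1],
    kappa_upper = ci[2],
    chi2 = cand$chi2[i],
    p_value = cand$p_value[i],
    n_pos = as.integer(cand$n_pos[i]),
    n_neg = as.integer(cand$n_neg[i])
  )
}

outcome_severe <- function(y) {
  if (is.logical(y)) return(y)
  yc <- as.character(y)
  ok <- yc %in% severity_levels
  if (!all(ok)) stop_domain("outcome must be minor/severe (or logical).")
  yc == "severe"
}
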