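make_two_group_registry <- function() {
  # severe counts 75/229 (older) and 31/316 (working-age)
  n_o <- 229; n_w <- 316
  tibble::tibble(
    age_group = factor(rep(c("older", "working_age"), c(n_o, n_w)),
                       levels = c("working_age", "older")),
    severity = factor(c(rep(c("severe", "minor"), c(75, n_o - 75)),
                        rep(c("severe", "minor"), c(31, n_w - 31))),
                      levels = c("minor", "severe"))
  )
}

test_that("group comparison reproduces printed proportions and tests", {
  gs <- compare_groups(make_two_group_registry(), "age_group",
                       variables = "severity")
  sev <- dplyr::filter(gs, level == "severe")
  expect_equal(sev$pct[sev$group == "older"], 32.8)
  expect_equal(sev$pct[sev$group == "working_age"], 9.8)
  expect_lt(sev$p_value[1], 0.0001)
})

test_that("identical groups give p = 1 for categorical rows", {
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 50),
    cat = factor(rep(rep(c("x", "y"), c(20, 30)), 2))
  )
  gs <- compare_groups(d, "g", variables = "cat")
  expect_equal(unique(gs$p_value), 1)
  expect_error(compare_groups(dplyr::filter(d, g == "a"), "g"),
               class = "pedsda_domain_error")
})

test_that("the pooled t statistic matches the closed form", {
  withr::with_seed(31, {
    d <- tibble::tibble(
      g = rep(c("a", "b"), c(40, 55)),
      x = c(rnorm(40, 10, 2), rnorm(55, 11.5, 2.5))
    )
  })
  gs <- compare_groups(d, "g", variables = "x")
  m <- tapply(d$x, d$g, mean)
  v <- tapply(d$x, d$g, var)
  n <- tapply(d$x, d$g, length)
  sp2 <- ((n[1] - 1) * v[1] + (n[2] - 1) * v[2]) / (sum(n) - 2)
  t_hand <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  expect_equal(unique(gs$statistic), unname(t_hand), tolerance = 1e-12)
  # a group with < 2 observations omits the test with a warning
  d1 <- tibble::tibble(g = c("a", "a", "b"), x = c(1, 2, 3))
  expect_warning(gs1 <- compare_groups(d1, "g", variables = "x"), "fewer than 2")
  expect_true(all(is.na(gs1$p_value)))
})

test_that("subgroup profiles: single leaf equals whole-sample; ANOVA matches direct summation", {
  d <- tibble::tibble(
    x = runif(30),
    network_distance_m = rnorm(30, 500, 50),
    severity = factor(rep(c("minor", "severe"), 15), levels = c("minor", "severe"))
  )
  tr1 <- grow_sda(d[1:15, ], variables = "x")  # single leaf
  prof <- subgroup_profile(d, tr1, variables = c("network_distance_m", "severity"))
  expect_true(all(is.na(prof$p_value)))
  sev <- dplyr::filter(prof, variable == "severity", level == "severe")
  expect_equal(sev$pct, 50.0)

  # planted three-subgroup structure with shifted distance means
  withr::with_seed(77, {
    d3 <- tibble::tibble(
      grp = rep(c("g1", "g2", "g3"), each = 40),
      network_distance_m = rnorm(120, rep(c(400, 900, 1600), each = 40), 150),
      low_ses_prop = runif(120, 30, 50)
    )
    d3$severity <- factor(
      ifelse(rbinom(120, 1, rep(c(0.6, 0.3, 0.05), each = 40)) == 1,
             "severe", "minor"), levels = c("minor", "severe"))
  })
  tr <- grow_sda(d3, variables = c("network_distance_m", "low_ses_prop"))
  prof3 <- subgroup_profile(d3, tr, variables = c("network_distance_m", "severity"))
  routed <- assign_subgroup(d3, tr)
  # direct between/within mean-square ratio
  g <- routed$.subgroup
  x <- d3$network_distance_m
  gm <- tapply(x, g, mean); gn <- tapply(x, g, length)
  ssb <- sum(gn * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  k <- length(unique(g))
  f_hand <- (ssb / (k - 1)) / (ssw / (length(x) - k))
  got <- dplyr::filter(prof3, variable == "network_distance_m")
  expect_equal(unique(got$statistic), unname(f_hand), tolerance = 1e-10)
  # subgroup columns partition the sample
  expect_equal(sum(got$n), nrow(d3))
})

test_that("pooled proportions reconstruct combined percentages", {
  expect_equal(pooled_proportion(data.frame(n = c(55, 74), prop = c(45.5, 27.0))), 34.9)
  expect_equal(pooled_proportion(data.frame(n = c(10, 10), prop = c(0, 0))), 0)
  expect_equal(pooled_proportion(data.frame(n = c(66, 219, 31),
                                            prop = c(19.7, 8.2, 0.0))), 9.8)
  # single subgroup returns (up to implied-count rounding) its own proportion
  expect_equal(pooled_proportion(data.frame(n = 200, prop = 12.5)), 12.5)
  expect_error(pooled_proportion(data.frame(n = 0, prop = 10)),
               class = "pedsda_domain_error")
})

test_that("percentages use half-up rounding to one decimal", {
  expect_equal(pedsda:::round_half_up(0.25, 1), 0.3)
  expect_equal(pedsda:::round_half_up(32.75, 1), 32.8)
  expect_equal(pedsda:::pct1(75, 229), 32.8)
  expect_equal(pedsda:::pct1(31, 316), 9.8)
})

test_that("subgroup reconciliation flags inconsistent printed values", {
  older <- readr::read_csv(system.file("extdata", "published_subgroups_older.csv",
                                       package = "pedsda"),
                           show_col_types = FALSE)
  rec <- reconcile_subgroups(older, total_n = 229, total_severe = 75)
  expect_equal(rec$table$implied_severe, c(18, 12, 25, 20))
  expect_equal(rec$implied_severe_total, 75)
  expect_true(rec$consistent_n)
  expect_true(rec$consistent_severe)
  # the alternative first-subgroup percentage printed elsewhere cannot be
  # reconciled with the stratum severe count
  alt <- dplyr::mutate(older, prop = prop_table)
  rec_alt <- reconcile_subgroups(alt, total_n = 229, total_severe = 75)
  expect_false(rec_alt$consistent_severe)
  expect_equal(rec_alt$implied_severe_total, 67)
})
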