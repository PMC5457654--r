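planted_one_split <- function(n = 400, seed = 17) {
  # severity depends only on low_ses_prop <= 35 vs > 35 (0.55 vs 0.20), with
  # a value gap around 35 so the recoverable cut is pinned down
  withr::with_seed(seed, {
    ses <- runif(n, 20, 50)
    ses[ses > 33 & ses < 37] <- ses[ses > 33 & ses < 37] + 10
    ses <- pmin(ses, 60)
    p <- ifelse(ses <= 35, 0.55, 0.20)
    tibble::tibble(
      low_ses_prop = ses,
      noise = rnorm(n),
      severity = factor(ifelse(rbinom(n, 1, p) == 1, "severe", "minor"),
                        levels = c("minor", "severe"))
    )
  })
}

test_that("too few records for any admissible split yield a single leaf", {
  d <- tibble::tibble(
    x = runif(15),
    severity = factor(rep(c("severe", "minor"), length.out = 15),
                      levels = c("minor", "severe"))
  )
  tr <- grow_sda(d, variables = "x")
  expect_equal(glance(tr)$n_leaves, 1)
  expect_equal(glance(tr)$n_nodes, 1)
})

test_that("planted single splits are recovered at the generating boundary", {
  # the maximum-kappa boundary estimate wanders by a few observations around
  # the generating cut (change-point behaviour), so recovery is scored by
  # the induced partition: the root must name the planted variable and its
  # partition must agree with the generating one for >= 95% of records, in
  # at least 90% of 50 replicates
  agree <- vapply(seq_len(50), function(i) {
    d <- planted_one_split(seed = 100 + i)
    tr <- grow_sda(d, variables = c("low_ses_prop", "noise"))
    sp <- tr$root$split
    if (is.null(sp) || sp$variable != "low_ses_prop") return(0)
    truth_pos <- d$low_ses_prop <= 35
    got_pos <- if (sp$op == "<=") d$low_ses_prop <= sp$cut else
      d$low_ses_prop > sp$cut
    max(mean(got_pos == truth_pos), mean(got_pos != truth_pos))
  }, numeric(1))
  expect_true(all(agree > 0))          # the variable itself is always found
  expect_gte(mean(agree >= 0.95), 0.90)
  # and the cut stays near the boundary on the value scale
  cuts <- vapply(seq_len(10), function(i) {
    grow_sda(planted_one_split(seed = 100 + i),
             variables = c("low_ses_prop", "noise"))$root$split$cut
  }, numeric(1))
  expect_true(all(abs(cuts - 35) < 6))
})

test_that("grown trees satisfy the three stopping rules structurally", {
  for (seed in c(4, 8, 15)) {
    cfg <- sim_config(seed = seed)
    reg <- simulate_registry(cfg, simulate_road_network(cfg))
    for (stratum in split(reg, reg$age_group)) {
      tr <- grow_sda(stratum)
      nodes <- tidy(tr)
      leaves <- dplyr::filter(nodes, is_leaf)
      internal <- dplyr::filter(nodes, !is_leaf)
      expect_gte(min(leaves$n), tr$control$min_subgroup)
      if (nrow(internal) > 0) {
        expect_lt(max(internal$p_value), tr$control$alpha)
        expect_gt(min(internal$kappa_lower), 0)
      }
      # leaves partition the stratum
      expect_equal(sum(leaves$n), nrow(stratum))
      expect_equal(sum(leaves$n_severe), sum(stratum$severity == "severe"))
    }
  }
})

test_that("tree growth is invariant to record order", {
  d <- planted_one_split(n = 300, seed = 5)
  tr1 <- grow_sda(d, variables = c("low_ses_prop", "noise"))
  tr2 <- grow_sda(d[sample.int(nrow(d)), ], variables = c("low_ses_prop", "noise"))
  expect_equal(tidy(tr1), tidy(tr2))
})

test_that("records route to exactly one leaf and sizes add up", {
  d <- planted_one_split(n = 300, seed = 9)
  tr <- grow_sda(d, variables = c("low_ses_prop", "noise"))
  routed <- assign_subgroup(d, tr)
  expect_false(anyNA(routed$.subgroup))
  counts <- table(routed$.subgroup)
  leaves <- dplyr::filter(tidy(tr), is_leaf)
  expect_equal(as.integer(counts[leaves$subgroup]), leaves$n)
  # single-leaf tree routes everything to that leaf
  tr1 <- grow_sda(d[1:15, ], variables = "noise")
  expect_equal(unique(as.character(assign_subgroup(d, tr1)$.subgroup)), "S1")
  # a missing value in a used variable is a routing error naming it
  d_na <- d
  d_na$low_ses_prop[3] <- NA
  expect_error(assign_subgroup(d_na, tr), "low_ses_prop")
})

test_that("the planted reference tree routes a high-SES older record to its first subgroup", {
  truth <- planted_truth(sim_config(), "older")
  rec <- make_mini_registry()[1, ]
  rec$low_ses_prop <- 30  # below the 35.21% threshold: higher-SES subgroup
  rec$network_distance_m <- 500
  expect_equal(as.character(assign_subgroup(rec, truth)$.subgroup), "S1")
  rec$low_ses_prop <- 40
  rec$road_width_class <- factor("lt3", levels = levels(rec$road_width_class),
                                 ordered = TRUE)
  expect_equal(as.character(assign_subgroup(rec, truth)$.subgroup), "S4")
})

test_that("JSON rendering round-trips and counts nodes correctly", {
  d <- planted_one_split(n = 300, seed = 13)
  tr <- grow_sda(d, variables = c("low_ses_prop", "noise"))
  back <- tree_from_json(tree_to_json(tr))
  expect_equal(tidy(back), tidy(tr))
  expect_equal(as.character(assign_subgroup(d, back)$.subgroup),
               as.character(assign_subgroup(d, tr)$.subgroup))
  g <- glance(tr)
  expect_equal(g$n_nodes, 2 * g$n_splits + 1)
})

test_that("text rendering shows subgroup percentages including 0.0%", {
  d <- tibble::tibble(
    x = runif(31),
    severity = factor(rep("minor", 31), levels = c("minor", "severe"))
  )
  tr <- grow_sda(d, variables = "x")
  txt <- format(tr)
  expect_true(any(grepl("0.0%", txt, fixed = TRUE)))
  expect_true(any(grepl("n=31", txt, fixed = TRUE)))
  out <- render_tree(tr)
  expect_s3_class(out$json, "json")
})

test_that("tidy, glance and autoplot expose the fitted tree", {
  d <- planted_one_split(n = 300, seed = 2)
  tr <- grow_sda(d, variables = c("low_ses_prop", "noise"))
  td <- tidy(tr)
  expect_true(all(c("node_id", "subgroup", "n", "kappa", "p_value") %in% names(td)))
  expect_equal(td$node_id, seq_len(nrow(td)))
  expect_s3_class(autoplot(tr), "ggplot")
})
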