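# Synthetic injury-registry generator: a jittered grid road network and a
# two-stratum cohort whose covariate marginals and planted subgroup tree
# reproduce the statistical structure the analysis assumes, so every
# pipeline stage is testable without external data.

# Per-stratum marginal parameters of the emulated registry (a mid-sized
# Japanese suburban EMS catchment, two adult age strata). Categorical
# weights are the published one-decimal percentages, which are internally
# consistent; continuous variables carry mean/SD.
sim_marginals_default <- function() {
  list(
    older = list(
      male = 0.332,
      time_bin = c(1.3, 14.4, 26.2, 14.8, 34.1, 9.2) / 100,
      season = c(31.0, 23.6, 16.2, 29.3) / 100,
      national_road = 0.189,
      road_width = c(3.5, 32.8, 46.7, 16.6) / 100,
      did = 0.742,
      aging_rate = c(mean = 19.64, sd = 5.17),
      low_ses_prop = c(mean = 40.80, sd = 6.50),
      distance_m = c(mean = 1128, sd = 1837),
      age = c(mean = 75, sd = 7, min = 65, max = 100)
    ),
    working = list(
      male = 0.505,
      time_bin = c(8.8, 8.2, 13.9, 9.1, 35.3, 24.6) / 100,
      season = c(27.1, 22.1, 24.0, 26.8) / 100,
      national_road = 0.188,
      road_width = c(5.0, 40.1, 30.3, 24.6) / 100,
      did = 0.808,
      aging_rate = c(mean = 17.80, sd = 4.93),
      low_ses_prop = c(mean = 41.51, sd = 7.53),
      distance_m = c(mean = 1939, sd = 2487),
      age = c(mean = 44, sd = 13, min = 18, max = 64)
    )
  )
}

planted_node <- function(id, depth, split = NULL, pos = NULL, neg = NULL,
                         p_severe = NULL) {
  nd <- list(node_id = as.integer(id), depth = as.integer(depth), n = 0L,
             n_severe = 0L, split = split, pos = pos, neg = neg,
             subgroup = NA_character_)
  if (!is.null(p_severe)) nd$p_severe <- p_severe
  nd
}

planted_split <- function(variable, var_type, op, cut = NA_real_,
                          set = NULL, levels = NULL) {
  list(variable = variable, var_type = var_type, op = op, cut = cut,
       set = set, levels = levels, kappa = NA_real_, kappa_lower = NA_real_,
       kappa_upper = NA_real_, chi2 = NA_real_, p_value = NA_real_,
       n_pos = NA_integer_, n_neg = NA_integer_)
}

as_planted_tree <- function(root, variables) {
  label_leaves(structure(
    list(root = root, outcome = "severity", variables = variables,
         control = sda_control(), n = 0L, n_severe = 0L),
    class = "sda_tree"))
}

# Older stratum: residence-area SES drives the root; on the lower-SES side
# road width, then aging rate, stratify risk. Leaf probabilities 0.563
# (higher SES), 0.455 (lower SES, wide road, aging rate > 20.3), 0.270
# (ditto, aging rate <= 20.3), 0.176 (lower SES, narrow road).
planted_tree_older <- function() {
  aging <- planted_node(
    8, 2, split = planted_split("aging_rate", "continuous", ">", cut = 20.3),
    pos = planted_node(16, 3, p_severe = 0.455),
    neg = planted_node(17, 3, p_severe = 0.270))
  width <- planted_node(
    3, 1,
    split = planted_split("road_width_class", "ordinal", ">", cut = 2.5,
                          levels = road_width_levels),
    pos = aging,
    neg = planted_node(9, 2, p_severe = 0.176))
  root <- planted_node(
    1, 0, split = planted_split("low_ses_prop", "continuous", "<=", cut = 35.21),
    pos = planted_node(2, 1, p_severe = 0.563),
    neg = width)
  as_planted_tree(root, sda_variables())
}

# Working-age stratum: network distance drives the root (>= 132.84 m), then
# aging rate (>= 21.05); injuries within ~133 m of home are never severe.
planted_tree_working <- function() {
  aging <- planted_node(
    2, 1, split = planted_split("aging_rate", "continuous", ">", cut = 21.05),
    pos = planted_node(4, 2, p_severe = 0.197),
    neg = planted_node(5, 2, p_severe = 0.082))
  root <- planted_node(
    1, 0,
    split = planted_split("network_distance_m", "continuous", ">", cut = 132.84),
    pos = aging,
    neg = planted_node(3, 1, p_severe = 0.0))
  as_planted_tree(root, sda_variables())
}

# Single-leaf truth: severity independent of every covariate (null model).
planted_tree_null <- function(p_severe) {
  as_planted_tree(planted_node(1, 0, p_severe = p_severe), sda_variables())
}

#' Configuration of the synthetic registry generator
#'
#' Defaults describe the emulated study conditions: 229 older and 316
#' working-age transported pedestrians, covariate marginals per stratum
#' (aging rate N(19.64, 5.17) / N(17.80, 4.93) and low-SES proportion
#' N(40.80, 6.50) / N(41.51, 7.53), truncated to [0, 100]; published
#' road-width, district, road-type, sex, time-bin and season frequencies),
#' residence-to-injury network distances lognormal with moments matched to
#' 1128 (1837) m and 1939 (2487) m, and the planted subgroup trees of
#' [planted_truth()] supplying each record's severe-injury probability. The
#' road network is a jittered rectangular grid.
#'
#' @param n_older,n_working Stratum sizes.
#' @param seed Integer seed; every generator draw derives from it.
#' @param grid_nx,grid_ny,spacing,jitter Grid dimensions (nodes per side),
#'   node spacing and coordinate jitter, meters.
#' @param coordinate_noise Noise added to residence/injury coordinates
#'   relative to their network node, meters (kept below half the node
#'   separation so snapping recovers the node).
#' @param marginals Per-stratum marginal parameters; see
#'   `pedsda:::sim_marginals_default()` for the structure.
#' @param planted Named list with elements `older` and `working`: planted
#'   `sda_tree`s whose leaves carry `p_severe`, or `NULL` to use the
#'   defaults. Pass single-leaf trees (e.g.
#'   `planted_truth(cfg, "older", null_rate = 0.328)`) for a null model.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_older = 229, n_working = 316, seed = 1L,
                       grid_nx = 30, grid_ny = 30, spacing = 100,
                       jitter = 10, coordinate_noise = 15,
                       marginals = sim_marginals_default(),
                       planted = NULL) {
  stopifnot(n_older >= 1, n_working >= 1, grid_nx >= 2, grid_ny >= 2,
            spacing > 0, jitter >= 0, jitter < spacing / 2,
            coordinate_noise >= 0)
  planted <- planted %||% list(older = planted_tree_older(),
                               working = planted_tree_working())
  structure(list(
    n_older = as.integer(n_older), n_working = as.integer(n_working),
    seed = as.integer(seed), grid_nx = as.integer(grid_nx),
    grid_ny = as.integer(grid_ny), spacing = spacing, jitter = jitter,
    coordinate_noise = coordinate_noise, marginals = marginals,
    planted = planted
  ), class = "sim_config")
}

#' The generating rule set of a synthetic registry
#'
#' Returns the planted tree used to assign severe-injury probabilities in a
#' stratum, as an `sda_tree` whose leaves carry `p_severe` — the reference
#' against which recovery by [grow_sda()] is scored.
#'
#' @param config A [sim_config()].
#' @param age_group `"older"` or `"working"`.
#' @param null_rate If given, returns a single-leaf truth with this constant
#'   severe probability instead (severity independent of all covariates).
#' @return An `sda_tree`.
#' @export
planted_truth <- function(config, age_group = c("older", "working"),
                          null_rate = NULL) {
  age_group <- match.arg(age_group)
  if (!is.null(null_rate)) return(planted_tree_null(null_rate))
  config$planted[[age_group]]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a jittered-grid road network
#'
#' A `grid_nx` by `grid_ny` rectangular lattice with node coordinates
#' jittered uniformly by up to `jitter` meters; each edge's length is the
#' Euclidean chord between its (jittered) endpoints, so the road-network
#' invariants hold by construction. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [road_network()].
#' @export
simulate_road_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nx <- config$grid_nx; ny <- config$grid_ny
  with_seed(config$seed + 101L, {
    grid <- expand.grid(col = seq_len(nx), row = seq_len(ny))
    nodes <- tibble(
      node_id = sprintf("n%03d_%03d", grid$row, grid$col),
      x = (grid$col - 1) * config$spacing +
        runif(nrow(grid), -config$jitter, config$jitter),
      y = (grid$row - 1) * config$spacing +
        runif(nrow(grid), -config$jitter, config$jitter)
    )
    idx <- function(r, c) (r - 1L) * nx + c
    horiz <- expand.grid(col = seq_len(nx - 1), row = seq_len(ny))
    vert <- expand.grid(col = seq_len(nx), row = seq_len(ny - 1))
    ei <- c(idx(horiz$row, horiz$col), idx(vert$row, vert$col))
    ej <- c(idx(horiz$row, horiz$col + 1L), idx(vert$row + 1L, vert$col))
    edges <- tibble(
      from = nodes$node_id[ei], to = nodes$node_id[ej],
      length_m = sqrt((nodes$x[ei] - nodes$x[ej])^2 +
                        (nodes$y[ei] - nodes$y[ej])^2)
    )
    road_network(nodes, edges)
  })
}

lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

sample_datetime <- function(n, time_bin, season) {
  season_months <- list(spring = 3:5, summer = 6:8, fall = 9:11, winter = c(12, 1, 2))
  month <- vapply(as.character(season), function(s) {
    ms <- season_months[[s]]
    ms[sample.int(3, 1)]
  }, numeric(1))
  bin0 <- (as.integer(time_bin) - 1L) * 4L
  hour <- bin0 + runif(n, 0, 4)
  year <- sample(2002:2008, n, replace = TRUE)
  day <- sample.int(28, n, replace = TRUE)
  as.POSIXct(sprintf("%d-%02d-%02d %02d:%02d:00", year, month, day,
                     floor(hour), floor((hour %% 1) * 60)), tz = "UTC")
}

simulate_stratum <- function(config, network, stratum, n, D, id_offset) {
  m <- config$marginals[[stratum]]
  nodes <- network$nodes
  nn <- nrow(nodes)
  noise <- config$coordinate_noise

  age_lo <- m$age[["min"]]; age_hi <- m$age[["max"]]
  age <- round(rtruncnorm01(n, m$age[["mean"]], m$age[["sd"]], age_lo, age_hi))
  gender <- factor(ifelse(runif(n) < m$male, "male", "female"),
                   levels = gender_levels)
  time_bin <- factor(time_bin_levels[sample.int(6, n, replace = TRUE,
                                                prob = m$time_bin)],
                     levels = time_bin_levels)
  season <- factor(season_levels[sample.int(4, n, replace = TRUE,
                                            prob = m$season)],
                   levels = season_levels)
  national_road <- runif(n) < m$national_road
  road_width_class <- factor(road_width_levels[sample.int(4, n, replace = TRUE,
                                                          prob = m$road_width)],
                             levels = road_width_levels, ordered = TRUE)
  did <- runif(n) < m$did
  aging_rate <- rtruncnorm01(n, m$aging_rate[["mean"]], m$aging_rate[["sd"]])
  low_ses_prop <- rtruncnorm01(n, m$low_ses_prop[["mean"]], m$low_ses_prop[["sd"]])

  lp <- lnorm_params(m$distance_m[["mean"]], m$distance_m[["sd"]])
  if (stats::qlnorm(0.5, lp[["meanlog"]], lp[["sdlog"]]) > max(D[is.finite(D)])) {
    stop_domain(paste0("the road network is too small for the target distance",
                       " distribution; increase grid_nx/grid_ny or spacing."))
  }
  res_idx <- sample.int(nn, n, replace = TRUE)
  target <- rlnorm(n, lp[["meanlog"]], lp[["sdlog"]])
  inj_idx <- vapply(seq_len(n), function(k) {
    which.min(abs(D[res_idx[k], ] - target[k]))
  }, integer(1))
  net_dist <- D[cbind(res_idx, inj_idx)]

  out <- tibble(
    record_id = sprintf("P%05d", id_offset + seq_len(n)),
    age = as.integer(age),
    gender = gender,
    injury_datetime = sample_datetime(n, time_bin, season),
    residence_x = nodes$x[res_idx] + runif(n, -noise, noise),
    residence_y = nodes$y[res_idx] + runif(n, -noise, noise),
    injury_x = nodes$x[inj_idx] + runif(n, -noise, noise),
    injury_y = nodes$y[inj_idx] + runif(n, -noise, noise),
    national_road = national_road,
    road_width_class = road_width_class,
    did = did,
    aging_rate = aging_rate,
    low_ses_prop = low_ses_prop,
    time_bin = time_bin,
    season = season,
    network_distance_m = net_dist
  )
  truth <- config$planted[[stratum]]
  routed <- assign_subgroup(out, truth)
  p <- leaf_probs(truth)[as.character(routed$.subgroup)]
  out$severity <- factor(ifelse(rbinom(n, 1, p) == 1, "severe", "minor"),
                         levels = severity_levels)
  out
}

#' Generate a synthetic injury registry
#'
#' Draws both age strata with the configured covariate marginals; each
#' record's residence node is uniform on the network, its injury node is
#' chosen so the network distance best matches a lognormal draw
#' (moment-matched to the configured mean/SD), and severity is Bernoulli
#' with the probability of the planted tree's leaf for that record. The true
#' node-to-node network distance used for severity generation is included as
#' `network_distance_m`; re-annotating from the (noised) coordinates via
#' [annotate_distances()] recovers it because snapping maps points back to
#' their nodes. Deterministic given `config$seed`: identical seeds give a
#' byte-identical registry CSV.
#'
#' @param config A [sim_config()].
#' @param network A [road_network()], typically [simulate_road_network()].
#' @return A validated registry tibble with both strata, severity and the
#'   derived columns `time_bin`, `season`, `network_distance_m`.
#' @export
simulate_registry <- function(config, network) {
  stopifnot(inherits(config, "sim_config"), inherits(network, "road_network"))
  D <- igraph::distances(network$graph,
                         weights = igraph::E(network$graph)$weight,
                         algorithm = "dijkstra")
  ord <- match(network$nodes$node_id, rownames(D))
  D <- D[ord, ord, drop = FALSE]
  out <- with_seed(config$seed + 202L, {
    bind_rows(
      simulate_stratum(config, network, "older", config$n_older, D, 0L),
      simulate_stratum(config, network, "working", config$n_working, D,
                       config$n_older)
    )
  })
  out <- mutate(out, age_group = derive_age_group(.data$age))
  validate_registry(out)
  out
}
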