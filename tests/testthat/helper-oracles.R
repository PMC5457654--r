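# Independent oracles used across the suite. These deliberately do NOT share
# code with the package: Cohen's kappa from the agreement/chance form,
# chi-square by direct summation over expected counts, shortest paths by
# exhaustive simple-path enumeration, and a plain-loop split search.

oracle_cohen_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  exp <- outer(rowSums(obs), colSums(obs)) / n
  if (any(exp == 0)) return(0)
  sum((obs - exp)^2 / exp)
}

# Large-sample variance of Cohen's kappa, coded independently in the
# marginal-proportion form.
oracle_kappa_var <- function(a, b, c, d) {
  n <- a + b + c + d
  p <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE) / n
  pr <- rowSums(p); pc <- colSums(p)
  po <- p[1, 1] + p[2, 2]
  pe <- sum(pr * pc)
  k <- (po - pe) / (1 - pe)
  t1 <- sum(vapply(1:2, function(i) p[i, i] * (1 - (pr[i] + pc[i]) * (1 - k))^2, 0))
  t2 <- (1 - k)^2 * (p[1, 2] * (pc[1] + pr[2])^2 + p[2, 1] * (pc[2] + pr[1])^2)
  t3 <- (k - pe * (1 - k))^2
  (t1 + t2 - t3) / (n * (1 - pe)^2)
}

# Exhaustive minimum-length simple path between two nodes of a small graph.
# edges: data frame with from, to, length_m (undirected).
oracle_shortest_path <- function(edges, origin, dest) {
  if (origin == dest) return(0)
  adj <- list()
  add <- function(u, v, w) {
    adj[[u]] <<- rbind(adj[[u]], data.frame(v = v, w = w))
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$from[i], edges$to[i], edges$length_m[i])
    add(edges$to[i], edges$from[i], edges$length_m[i])
  }
  best <- Inf
  dfs <- function(u, visited, len) {
    if (len >= best) return()
    if (u == dest) { best <<- len; return() }
    nb <- adj[[u]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      if (!(nb$v[i] %in% visited)) {
        dfs(nb$v[i], c(visited, nb$v[i]), len + nb$w[i])
      }
    }
  }
  dfs(origin, origin, 0)
  best
}

# Random connected road network (spanning tree plus extras); edge lengths
# exceed the chord so the constructor invariant holds.
random_road_network <- function(n_nodes, n_extra = 2) {
  ids <- sprintf("v%02d", seq_len(n_nodes))
  nodes <- tibble::tibble(node_id = ids,
                          x = runif(n_nodes, 0, 100),
                          y = runif(n_nodes, 0, 100))
  from <- ids[vapply(2:n_nodes, function(i) sample.int(i - 1, 1), 0L)]
  to <- ids[2:n_nodes]
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      pair <- sample(ids, 2)
      dup <- any((from == pair[1] & to == pair[2]) |
                   (from == pair[2] & to == pair[1]))
      if (!dup) { from <- c(from, pair[1]); to <- c(to, pair[2]) }
    }
  }
  i <- match(from, ids); j <- match(to, ids)
  chord <- sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2)
  edges <- tibble::tibble(from = from, to = to,
                          length_m = chord * (1 + runif(length(from), 0, 0.5)))
  road_network(nodes, edges)
}

random_2x2 <- function(max_cell = 60) {
  repeat {
    tab <- sample.int(max_cell + 1, 4, replace = TRUE) - 1
    if (sum(tab) >= 2) return(tab)
  }
}

# Plain-loop split search: every cut-point of numeric variables in both
# orientations, every one-vs-rest split of categorical ones; kappa by the
# Cohen oracle, p by stats::chisq.test, CI gate by the oracle variance.
oracle_best_split <- function(data, outcome, variables, min_n = 10,
                              alpha = 0.05) {
  ysev <- data[[outcome]] == "severe"
  best <- NULL
  consider <- function(pos, variable, cut) {
    a <- sum(pos & ysev); b <- sum(pos & !ysev)
    c <- sum(!pos & ysev); d <- sum(!pos & !ysev)
    if (a + b < min_n || c + d < min_n) return()
    k <- oracle_cohen_kappa(a, b, c, d)
    suppressWarnings(p <- chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                     correct = FALSE)$p.value)
    if (is.na(p) || p >= alpha) return()
    lo <- k - qnorm(0.975) * sqrt(max(oracle_kappa_var(a, b, c, d), 0))
    if (lo <= 0) return()
    if (is.null(best) || k > best$kappa + 1e-12) {
      best <<- list(variable = variable, cut = cut, kappa = k, p = p)
    }
  }
  for (variable in variables) {
    x <- data[[variable]]
    if (is.numeric(x)) {
      u <- sort(unique(x))
      if (length(u) < 2) next
      for (cut in (u[-length(u)] + u[-1]) / 2) {
        consider(x <= cut, variable, cut)
        consider(x > cut, variable, cut)
      }
    } else {
      for (lv in unique(as.character(x))) {
        consider(as.character(x) == lv, variable, NA_real_)
      }
    }
  }
  best
}

# Small handmade registry used by schema/round-trip tests.
make_mini_registry <- function() {
  tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    age = c(70L, 34L, 65L),
    gender = factor(c("male", "female", "female"), levels = c("male", "female")),
    injury_datetime = as.POSIXct(c("2004-04-10 08:30:00", "2006-12-01 21:10:00",
                                   "2002-07-15 02:45:00"), tz = "UTC"),
    residence_x = c(0, 100, 250),
    residence_y = c(0, 50, 75),
    injury_x = c(30, 100, 180),
    injury_y = c(40, 50, 75),
    national_road = c(TRUE, FALSE, FALSE),
    road_width_class = factor(c("gt13", "w3to5_5", "lt3"),
                              levels = c("lt3", "w3to5_5", "w5_5to13", "gt13"),
                              ordered = TRUE),
    did = c(TRUE, TRUE, FALSE),
    aging_rate = c(24.2, 18.3, 21.0),
    low_ses_prop = c(32.8, 42.1, 41.1),
    severity = factor(c("severe", "minor", "minor"), levels = c("minor", "severe"))
  )
}

make_square_network <- function() {
  road_network(
    nodes = tibble::tibble(node_id = c("a", "b", "c", "d"),
                           x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
    edges = tibble::tibble(from = c("a", "a", "b", "c"),
                           to = c("b", "c", "d", "d"),
                           length_m = c(1, 1, 1, 1))
  )
}
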