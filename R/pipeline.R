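# One-command reproduction of the analysis: registry -> distances -> strata
# -> comparison table -> signal detection trees -> subgroup tables.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_schema(paste0("config file not found: ", config))
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Run the full analysis pipeline
#'
#' Stages: read (or synthesise) the registry, excluding and counting under-18
#' records; annotate Euclidean and network distances (unreachable pairs are
#' flagged, counted and excluded from analysis); derive the age-group, time
#' bin and season variables; build the stratified group-comparison table;
#' grow one signal detection tree per age stratum (or one pooled tree with
#' `stratify = FALSE`); profile and reconcile the resulting subgroups; and
#' write every table, tree rendering and a run manifest to `out_dir`. Fully
#' deterministic given the seed: reruns produce byte-identical analysis
#' outputs.
#'
#' @param config A list, or path to a JSON/YAML file, with elements:
#'   `out_dir` (required); `seed` (default 1); either `simulate = TRUE` with
#'   an optional `sim` list of [sim_config()] arguments, or `registry` (CSV
#'   path) plus a `network` list (`nodes`/`edges` CSV paths, or `geojson`);
#'   optional `variables`, `control` (arguments to [sda_control()]),
#'   `stratify` (default `TRUE`), `welch`.
#' @return A `run_manifest`: input/output paths, seed, config hash,
#'   per-stage record counts (read = analyzed + excluded), per-stratum
#'   summaries and timestamps. Fitted objects are attached in
#'   `$results`.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  if (is.null(config[["out_dir"]])) stop_schema("config must name `out_dir`.")
  out_dir <- config[["out_dir"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config[["seed"]] %||% 1L)
  control <- do.call(sda_control, as.list(config[["control"]] %||% list()))
  stratify <- config[["stratify"]] %||% TRUE
  started <- Sys.time()

  # --- stage: input ---------------------------------------------------------
  if (isTRUE(config[["simulate"]])) {
    sim_args <- as.list(config[["sim"]] %||% list())
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    network <- simulate_road_network(scfg)
    registry <- simulate_registry(scfg, network)
    n_excluded_minors <- 0L
    input_label <- "synthetic"
  } else {
    if (is.null(config[["registry"]])) stop_schema("config must name `registry` or set simulate: true.")
    registry <- read_registry(config[["registry"]], exclude_minors = TRUE)
    n_excluded_minors <- attr(registry, "n_excluded_minors") %||% 0L
    nw <- config[["network"]]
    network <- if (!is.null(nw[["geojson"]])) {
      read_network_geojson(nw[["geojson"]])
    } else if (!is.null(nw[["nodes"]])) {
      read_road_network(nw[["nodes"]], nw[["edges"]])
    } else {
      NULL
    }
    input_label <- config[["registry"]]
  }
  n_read <- nrow(registry) + n_excluded_minors

  # --- stage: distances -----------------------------------------------------
  if (!is.null(network)) {
    registry <- annotate_distances(registry, network)
    n_unreachable <- attr(registry, "n_unreachable") %||% 0L
    if (n_unreachable > 0) {
      registry <- filter(registry, !.data$unreachable)
    }
  } else if (!"network_distance_m" %in% names(registry)) {
    stop_schema("no network given and the registry carries no network_distance_m column.")
  } else {
    n_unreachable <- 0L
  }

  # --- stage: derived variables --------------------------------------------
  registry <- augment_registry(registry)
  n_analyzed <- nrow(registry)

  # --- stage: group comparison ---------------------------------------------
  variables <- config[["variables"]] %||% sda_variables()
  table1 <- compare_groups(registry, "age_group",
                           variables = setdiff(c(variables, "severity"), "age"),
                           welch = isTRUE(config[["welch"]]))

  # --- stage: trees per stratum --------------------------------------------
  strata <- if (isTRUE(stratify)) split(registry, registry$age_group) else
    list(pooled = registry)
  strata <- strata[vapply(strata, nrow, 0L) > 0]
  fits <- purrr::imap(strata, function(dat, label) {
    tree <- grow_sda(dat, outcome = "severity", variables = variables,
                     control = control)
    profile <- subgroup_profile(dat, tree)
    severe_rows <- filter(profile, .data$variable == "severity",
                          .data$level == "severe")
    recon <- reconcile_subgroups(
      tibble(subgroup = as.character(severe_rows$group),
             n = as.integer(tapply(rep(1L, nrow(dat)),
                                   assign_subgroup(dat, tree)$.subgroup, sum)),
             prop = severe_rows$pct),
      total_n = nrow(dat),
      total_severe = sum(outcome_severe(dat$severity)))
    list(tree = tree, profile = profile, reconciliation = recon)
  })

  # --- stage: outputs -------------------------------------------------------
  paths <- list(registry = file.path(out_dir, "registry_annotated.csv"),
                table1_csv = file.path(out_dir, "table1.csv"),
                table1_txt = file.path(out_dir, "table1.txt"),
                manifest = file.path(out_dir, "manifest.json"))
  write_registry(registry |> select(-any_of(c(".subgroup", ".node_id"))),
                 paths$registry)
  readr::write_csv(as_tibble(table1), paths$table1_csv, progress = FALSE)
  writeLines(group_summary_text(table1), paths$table1_txt)
  for (label in names(fits)) {
    f <- fits[[label]]
    paths[[paste0("tree_", label, "_json")]] <-
      file.path(out_dir, paste0("tree_", label, ".json"))
    paths[[paste0("tree_", label, "_txt")]] <-
      file.path(out_dir, paste0("tree_", label, ".txt"))
    paths[[paste0("subgroups_", label)]] <-
      file.path(out_dir, paste0("subgroups_", label, ".csv"))
    render_tree(f$tree, paths[[paste0("tree_", label, "_json")]],
                paths[[paste0("tree_", label, "_txt")]])
    readr::write_csv(as_tibble(f$profile),
                     paths[[paste0("subgroups_", label)]], progress = FALSE)
  }

  counts <- list(read = n_read, excluded_minors = n_excluded_minors,
                 unreachable = n_unreachable, analyzed = n_analyzed)
  stopifnot(counts$read == counts$analyzed + counts$excluded_minors +
              counts$unreachable)
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- structure(list(
    input = input_label,
    seed = seed,
    config_hash = rlang::hash(cfg_for_hash),
    counts = counts,
    strata = purrr::imap(fits, function(f, label) {
      g <- glance(f$tree)
      list(n = g$n, n_severe = g$n_severe, n_leaves = g$n_leaves,
           severe_reconciled = isTRUE(f$reconciliation$consistent_severe))
    }),
    outputs = lapply(paths, normalizePath, mustWork = FALSE),
    started = format(started, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$results <- list(registry = registry, table1 = table1, fits = fits)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  input:    ", x$input, "\n", sep = "")
  cat("  seed:     ", x$seed, "\n", sep = "")
  cat(sprintf("  counts:   read=%d analyzed=%d excluded_minors=%d unreachable=%d\n",
              x$counts$read, x$counts$analyzed, x$counts$excluded_minors,
              x$counts$unreachable))
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    cat(sprintf("  %-8s n=%d severe=%d leaves=%d reconciled=%s\n", s,
                st$n, st$n_severe, st$n_leaves, st$severe_reconciled))
  }
  invisible(x)
}
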