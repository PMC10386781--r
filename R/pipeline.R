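#' Configuration for the end-to-end pipeline
#'
#' @param input path to a CSV/ARFF dataset, or the string `"synthetic"` to
#'   generate from `synthetic` (a [synthetic_spec()]).
#' @param format input dialect for files.
#' @param class_name,positive_label class column and positive value.
#' @param missing_sentinels named list of per-feature sentinel codes mapped
#'   to missing (e.g. `list(Cholesterol = 0)`).
#' @param synthetic a [synthetic_spec()] used when `input = "synthetic"`.
#' @param binary use binary (per-bin indicator) discretization.
#' @param select_k optional information-gain attribute selection: keep the
#'   class and the top-k discretized features before mining.
#' @param min_support,min_confidence,max_len mining parameters.
#' @param tau slope-of-interestingness acceptance threshold.
#' @param grid,folds,seed,prune,tie_policy,exclusion_training forest
#'   parameters (see [forest_config()]).
#' @param output_dir artifact directory, created if absent.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", format = "auto",
                            class_name = "Disease", positive_label = "Yes",
                            missing_sentinels = list(),
                            synthetic = synthetic_spec(),
                            binary = FALSE, select_k = NULL,
                            min_support = 0, min_confidence = 0,
                            max_len = 2L, tau = -1,
                            grid = default_grid(), folds = 10L, seed = 1L,
                            prune = TRUE, tie_policy = "negative",
                            exclusion_training = TRUE,
                            output_dir = "descforest-run") {
  if (!length(grid)) stop("sweep grid must be non-empty")
  if (!identical(input, "synthetic") && !file.exists(input))
    stop("input file does not exist: ", input)
  structure(list(input = input, format = format, class_name = class_name,
                 positive_label = positive_label,
                 missing_sentinels = missing_sentinels,
                 synthetic = synthetic, binary = binary, select_k = select_k,
                 min_support = min_support, min_confidence = min_confidence,
                 max_len = max_len, tau = tau, grid = grid, folds = folds,
                 seed = seed, prune = prune, tie_policy = tie_policy,
                 exclusion_training = exclusion_training,
                 output_dir = output_dir),
            class = "pipeline_config")
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " INFO  ", ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the full descriptive-forest pipeline
#'
#' Reads (or generates) the dataset, discretizes, mines class association
#' rules, grows the rule tree, extracts topics, builds the forest with
#' per-topic least-PTS sweeps, evaluates it against a single least-PTS tree
#' and writes every intermediate artifact (schema, discretization map, rule
#' list, rule tree, sweeps, forest, If--Then rules, evaluation report, run
#' log) to the output directory.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    log = file.path(config$output_dir, "run_log.txt"),
    schema = file.path(config$output_dir, "schema.json"),
    discretization = file.path(config$output_dir, "discretization.json"),
    cars = file.path(config$output_dir, "cars.csv"),
    rule_tree = file.path(config$output_dir, "rule_tree.json"),
    sweeps = file.path(config$output_dir, "sweeps.csv"),
    forest = file.path(config$output_dir, "forest.json"),
    rules = file.path(config$output_dir, "if_then_rules.txt"),
    evaluation = file.path(config$output_dir, "evaluation.csv"))
  cat("", file = paths$log)
  log_line(paths$log, "descforest ", as.character(utils::packageVersion("descforest")),
           ", R ", paste(R.version$major, R.version$minor, sep = "."),
           ", seed ", config$seed)

  if (identical(config$input, "synthetic")) {
    gen <- generate_synthetic(config$synthetic, seed = config$seed)
    table <- gen$table
    log_line(paths$log, "generated synthetic table: ", n_rows(table), " rows")
  } else {
    table <- read_table(config$input, format = config$format,
                        class_name = config$class_name,
                        positive_label = config$positive_label,
                        missing_sentinels = config$missing_sentinels)
    log_line(paths$log, "read ", config$input, ": ", n_rows(table), " rows")
  }
  schema_to_json(table$schema, paths$schema)

  map <- mdlp_map(table, binary_mode = config$binary)
  jsonlite::write_json(
    list(binary_mode = map$binary_mode, dropped = as.list(map$dropped),
         cuts = lapply(map$cuts, as.list)),
    paths$discretization, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(paths$log, "discretized ", length(map$cuts), " numeric features (",
           length(map$dropped), " dropped)")

  mine_table <- table
  mine_map <- map
  if (!is.null(config$select_k)) {
    disc <- apply_discretization(table, map)
    kept <- rank_and_select(disc, config$select_k)
    keep_cols <- unique(c(kept, table$schema$class_name))
    # selection is on derived columns; map indicators back to their source
    src <- unique(vapply(keep_cols, function(nm)
      sub("_[0-9]+$", "", nm), character(1)))
    keep_src <- intersect(names(table$schema$features), src)
    feats <- table$schema$features[keep_src]
    mine_table <- item_table(table$data[keep_src],
                             schema = feature_schema(feats,
                                                     table$schema$class_name,
                                                     table$schema$positive_label))
    log_line(paths$log, "attribute selection kept ", length(keep_src) - 1L,
             " features")
  }
  cars <- mine_cars(mine_table, map = mine_map,
                    min_support = config$min_support,
                    min_confidence = config$min_confidence,
                    max_len = config$max_len)
  write_cars(cars, paths$cars)
  n_pos_rules <- length(cars$antecedent)
  log_line(paths$log, "mined ", n_pos_rules, " positive-class rules")

  rt <- grow_rule_tree(cars, tau = config$tau)
  write_rule_tree(rt, paths$rule_tree)
  topics <- extract_topics(rt)
  log_line(paths$log, "rule tree accepted ", length(topics$topics),
           " main topics (", sum(topics$independent), " independent)")
  if (!length(topics$topics)) {
    log_line(paths$log, "no topics discovered; stopping after rule tree")
    return(invisible(list(table = table, map = map, cars = cars,
                          rule_tree = rt, topics = topics, paths = paths)))
  }

  fc <- forest_config(grid = config$grid, folds = config$folds,
                      seed = config$seed, prune = config$prune,
                      tie_policy = config$tie_policy,
                      exclusion_training = config$exclusion_training)
  forest <- build_forest(table, topics, fc)
  write_forest(forest, paths$forest)
  sweep_rows <- do.call(rbind, lapply(forest$trees, function(tt) {
    if (is.null(tt$sweep)) return(NULL)
    cbind(topic = tt$label, tt$sweep)
  }))
  if (!is.null(sweep_rows))
    utils::write.csv(sweep_rows, paths$sweeps, row.names = FALSE)
  writeLines(vapply(forest$trees, function(tt)
    to_rules(tt$tree, boundary = tt$topic, exclusions = tt$exclusions),
    character(1)), paths$rules)
  for (tt in forest$trees)
    log_line(paths$log, "tree ", tt$label, ": minNumObj ", tt$min_num_obj,
             ", ", tt$stats$n, " leaves / ", tt$stats$m, " nodes")

  ev <- evaluate_forest(forest, table)
  write_evaluation(ev, paths$evaluation)
  m <- metrics(ev$forest)
  log_line(paths$log, sprintf(
    "forest: accuracy %.4f precision %.4f recall %.4f", m$accuracy,
    m$precision, m$recall))
  invisible(list(table = table, map = map, cars = cars, rule_tree = rt,
                 topics = topics, forest = forest, evaluation = ev,
                 paths = paths))
}
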