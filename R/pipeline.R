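#' Configuration of the full stability-driven workflow
#'
#' @param estimation an [estimation_settings()].
#' @param bootstrap a [bootstrap_settings()].
#' @param item_threshold item-stability cutoff below which an item is
#'   flagged unstable (default 0.70).
#' @param dimension_threshold structural-consistency cutoff below which a
#'   dimension is flagged unstable (default 0.75).
#' @param removal_mode `"single_pass"` removes all flagged items at once
#'   (the standard workflow); `"iterative"` removes the single worst item
#'   and re-runs until none remain, for sensitivity analysis.
#' @param steps Walktrap random-walk length.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(estimation = estimation_settings(),
                            bootstrap = bootstrap_settings(),
                            item_threshold = 0.70,
                            dimension_threshold = 0.75,
                            removal_mode = c("single_pass", "iterative"),
                            steps = 4L) {
  removal_mode <- match.arg(removal_mode)
  if (item_threshold <= 0 || item_threshold >= 1 ||
      dimension_threshold <= 0 || dimension_threshold >= 1)
    stop("thresholds must be in (0, 1)")
  stopifnot(inherits(estimation, "estimation_settings"),
            inherits(bootstrap, "bootstrap_settings"))
  structure(list(estimation = estimation, bootstrap = bootstrap,
                 item_threshold = item_threshold,
                 dimension_threshold = dimension_threshold,
                 removal_mode = removal_mode, steps = as.integer(steps)),
            class = "pipeline_config")
}

# One EGA + bootEGA + stability stage on a correlation matrix.
run_stage <- function(corr, config, seed) {
  boot <- config$bootstrap
  boot$seed <- as.integer(seed)
  fit <- ega(corr, config$estimation, steps = config$steps)
  ensemble <- bootstrap_ega(corr, config$estimation, boot,
                            steps = config$steps)
  typical <- typical_network(ensemble, steps = config$steps)
  list(network = fit$network,
       solution = fit$solution,
       ensemble = ensemble,
       typical = typical,
       counts = dimension_count_summary(ensemble, boot$confidence),
       stability = stability_report(ensemble, fit$solution,
                                    config$item_threshold,
                                    config$dimension_threshold),
       seed = as.integer(seed))
}

# Distinct stream offset for the post-removal stage (a prime, so group
# streams seed + g * 10^6 and replicate streams seed + b never collide).
.final_stage_offset <- 104729L

#' Analyze one group: EGA, bootEGA, stability, unstable-item removal
#'
#' The full workflow for one correlation matrix: estimate the empirical
#' network and dimensions, bootstrap them, compute item stability and
#' structural consistency, remove unstable items (all at once under
#' `single_pass`, worst-first under `iterative`), and re-estimate everything
#' on the reduced matrix. Stability is always judged against each item's own
#' dimension in the *initial* empirical solution. If no item is unstable the
#' final stage is the initial stage.
#'
#' @param corr a [corr_matrix()] with known `n`.
#' @param config a [pipeline_config()].
#' @param label group label for reporting.
#' @return a `group_result`: list with `label`, `initial` and `final` stage
#'   results (each holding `network`, `solution`, `ensemble`, `typical`,
#'   `counts`, `stability`, `seed`) and `removed_items`.
#' @export
analyze_group <- function(corr, config = pipeline_config(), label = "group") {
  initial <- run_stage(corr, config, config$bootstrap$seed)
  removed <- character(0)
  final <- initial
  repeat {
    unstable <- final$stability$unstable_items
    if (length(unstable) == 0) break
    drop_now <- if (config$removal_mode == "single_pass") unstable else {
      own <- final$stability$item_stability$own
      names(which.min(own[unstable]))
    }
    keep <- setdiff(final$stability$alignment$ensemble$labels, drop_now)
    if (length(keep) < 3)
      stop("removing ", paste(drop_now, collapse = ", "),
           " would leave fewer than 3 items; aborting refinement")
    removed <- c(removed, drop_now)
    reduced <- corr_matrix(corr$values[keep, keep, drop = FALSE],
                           n = corr$n, labels = keep)
    final <- run_stage(reduced, config,
                       config$bootstrap$seed + .final_stage_offset)
    if (config$removal_mode == "single_pass") break
  }
  structure(list(label = label, initial = initial, final = final,
                 removed_items = removed),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("== Group:", x$label, "==\n")
  cat("Initial EGA:", n_dimensions(x$initial$solution), "dimensions\n")
  print(x$initial$solution)
  if (length(x$removed_items)) {
    cat("Removed unstable items:", paste(x$removed_items, collapse = ", "),
        "\n")
    cat("Final EGA:", n_dimensions(x$final$solution), "dimensions\n")
    print(x$final$solution)
  } else cat("No unstable items; final solution equals the initial one.\n")
  invisible(x)
}

#' Analyze several groups and a pooled sample
#'
#' Runs [analyze_group()] independently on each labeled correlation matrix,
#' with derived per-group seeds (`seed + (g-1) * 10^6`), and collects the
#' results. Groups that fail are recorded with their error message; the
#' remaining groups are still reported.
#'
#' @param inputs named list of [corr_matrix()] objects (names are group
#'   labels).
#' @param config a [pipeline_config()]; its bootstrap seed is the master
#'   seed.
#' @return a `multi_group_result`: list of `group_result` (or error records)
#'   plus the config.
#' @export
analyze_groups <- function(inputs, config = pipeline_config()) {
  if (length(inputs) < 1) stop("need at least one group")
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop("inputs must be a named list of correlation matrices")
  master <- config$bootstrap$seed
  results <- vector("list", length(inputs))
  names(results) <- names(inputs)
  for (g in seq_along(inputs)) {
    cfg <- config
    cfg$bootstrap$seed <- as.integer(master + (g - 1L) * 1000000L)
    results[[g]] <- tryCatch(
      analyze_group(inputs[[g]], cfg, label = names(inputs)[g]),
      error = function(e) structure(list(label = names(inputs)[g],
                                         error = conditionMessage(e)),
                                    class = "group_error"))
  }
  structure(list(groups = results, config = config, master_seed = master),
            class = "multi_group_result")
}

# Format a dimension solution as "1: A, B | 2: C, D".
format_clusters <- function(solution) {
  paste(vapply(seq_len(n_dimensions(solution)), function(d)
    paste0(d, ": ", paste(names(solution)[solution == d], collapse = ", ")),
    character(1)), collapse = " | ")
}

stage_payload <- function(stage) {
  list(
    n_dimensions = n_dimensions(stage$solution),
    solution = as.list(stats::setNames(as.integer(stage$solution),
                                       names(stage$solution))),
    edge_count = stage$network$edge_count,
    lambda = stage$network$lambda,
    ebic = stage$network$ebic,
    typical_n_dimensions = n_dimensions(stage$typical$solution),
    dimension_frequencies = as.list(stage$counts$frequencies),
    count_median = stage$counts$median,
    count_sd = stage$counts$sd,
    count_ci = as.list(stage$counts$ci),
    count_percentile_ci = as.list(stage$counts$percentile_ci),
    item_stability = as.list(stage$stability$item_stability$own),
    structural_consistency = as.list(stage$stability$structural_consistency),
    unstable_items = as.list(stage$stability$unstable_items),
    seed = stage$seed)
}

#' Serialize results as a JSON report
#'
#' The payload contains, per group, both stages (initial and final) with the
#' full numeric results: solutions, edge counts, dimension-count frequency
#' tables and CIs, item stabilities and structural consistencies. Output is
#' deterministic: two runs with the same inputs, config and seed produce
#' byte-identical files.
#'
#' @param result a `group_result` or `multi_group_result`.
#' @param path output file; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
report_json <- function(result, path = NULL) {
  payload <- if (inherits(result, "multi_group_result")) {
    list(master_seed = result$master_seed,
         groups = lapply(result$groups, group_payload))
  } else group_payload(result)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

group_payload <- function(result) {
  if (inherits(result, "group_error"))
    return(list(label = result$label, error = result$error))
  list(label = result$label,
       removed_items = as.list(result$removed_items),
       initial = stage_payload(result$initial),
       final = stage_payload(result$final))
}

#' Render a markdown summary table of one or more group analyses
#'
#' One row per group: the initial EGA clusters, the bootstrap typical
#' clusters, the removed items, and the final clusters after removal —
#' the standard reporting layout for multi-group dimensionality studies.
#'
#' @param result a `group_result` or `multi_group_result`.
#' @param path output file; `NULL` returns the text.
#' @return the path (or text), invisibly.
#' @export
report_markdown <- function(result, path = NULL) {
  groups <- if (inherits(result, "multi_group_result")) result$groups
            else list(result)
  lines <- c("| Group | EGA | bootEGA (typical) | Removed | Final |",
             "|---|---|---|---|---|")
  for (g in groups) {
    if (inherits(g, "group_error")) {
      lines <- c(lines, sprintf("| %s | ERROR: %s | | | |", g$label, g$error))
      next
    }
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s |",
      g$label,
      format_clusters(g$initial$solution),
      format_clusters(g$initial$typical$solution),
      if (length(g$removed_items)) paste(g$removed_items, collapse = ", ")
      else "none",
      format_clusters(g$final$solution)))
  }
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(invisible(text))
  writeLines(text, path)
  invisible(path)
}
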