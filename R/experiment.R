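# Scenario orchestration: replicate batches, parameter sweeps and the
# four-way scenario comparison.

# counter-based per-replicate seeds, kept inside 32-bit integer range
.replicate_seeds <- function(base_seed, replicates) {
  (as.numeric(base_seed) + 7919 * seq_len(replicates)) %% 2147483647
}

#' Run a batch of replicate simulations
#'
#' Runs `replicates` independent simulations of one scenario with
#' per-replicate seeds derived from `base_seed` by a counter scheme
#' (logged in the result), and aggregates the scalar metrics across
#' replicates as mean and standard error.
#'
#' @param scenario scenario id (`"i"` to `"iv"`) or a full
#'   [scenario_config()]; extra named arguments in `...` override config
#'   fields (e.g. `rounds`, `n_groups`).
#' @param base_seed integer seed of the batch.
#' @param replicates number of replicates; defaults to the config value (50).
#' @param ... overrides passed to [scenario_config()] when `scenario` is an
#'   id.
#' @param keep_results logical; keep the full `ratchetr_result` objects
#'   (memory heavy for large batches).
#' @return an object of class `ratchetr_batch`: list with `config`, `seeds`,
#'   `replicates` (data.frame of scalar metrics, one row per replicate) and
#'   `aggregate` (data.frame: `metric`, `mean`, `se`).
#' @examples
#' b <- run_batch("i", base_seed = 1, replicates = 2,
#'                n_groups = 2, group_size = 10, rounds = 10)
#' b$aggregate
#' @export
run_batch <- function(scenario, base_seed, replicates = NULL, ...,
                      keep_results = FALSE) {
  config <- if (inherits(scenario, "ratchetr_config")) scenario
            else scenario_config(scenario, ...)
  if (is.null(replicates)) replicates <- config$replicates
  seeds <- .replicate_seeds(base_seed, replicates)
  results <- vector("list", replicates)
  rows <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    res <- run_simulation(config, seeds[k])
    rows[[k]] <- c(replicate = k, seed = seeds[k], metrics_record(res)$summary)
    if (keep_results) results[[k]] <- res
  }
  reps <- as.data.frame(do.call(rbind, rows))
  metrics <- setdiff(names(reps), c("replicate", "seed"))
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reps[[m]]), numeric(1)),
    se = vapply(metrics, function(m) stats::sd(reps[[m]]) / sqrt(nrow(reps)),
                numeric(1)),
    row.names = NULL
  )
  structure(list(config = config, base_seed = base_seed, seeds = seeds,
                 replicates = reps, aggregate = aggregate,
                 results = if (keep_results) results else NULL),
            class = "ratchetr_batch")
}

#' @export
print.ratchetr_batch <- function(x, ...) {
  cat(sprintf("ratchetr batch: scenario %s, %d replicates (base seed %s)\n",
              x$config$scenario, nrow(x$replicates),
              format(x$base_seed)))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Sweep one structural parameter across batches
#'
#' Runs one replicate batch per value of the swept axis and returns a
#' long-format table of aggregated metrics.
#'
#' @param axis one of `"memory_cap"`, `"group_size"`, `"n_groups"`.
#' @param values vector of axis values (`Inf` allowed for `memory_cap`).
#' @param scenario scenario id providing the other settings.
#' @param base_seed integer; each batch uses `base_seed` plus an axis
#'   offset.
#' @param replicates replicates per batch.
#' @param ... further overrides passed to [scenario_config()].
#' @return data.frame with columns `axis`, `value`, `metric`, `mean`, `se`.
#' @export
run_sweep <- function(axis = c("memory_cap", "group_size", "n_groups"),
                      values, scenario, base_seed, replicates = NULL, ...) {
  axis <- match.arg(axis)
  if (length(values) == 0L) stop("'values' must be non-empty")
  out <- vector("list", length(values))
  for (v in seq_along(values)) {
    args <- c(list(scenario = scenario), stats::setNames(list(values[v]), axis),
              list(...))
    config <- do.call(scenario_config, args)
    batch <- run_batch(config, base_seed = base_seed + 131 * v,
                       replicates = replicates)
    out[[v]] <- cbind(data.frame(axis = axis, value = values[v]),
                      batch$aggregate)
  }
  do.call(rbind, out)
}

#' Side-by-side comparison of scenario batches
#'
#' Collates the aggregated metrics of several batches (typically the four
#' canonical scenarios) into one table and derives the between-group link
#' ratio of the limited-memory/transmission scenario to the largest mean
#' among the others, plus the ranking of scenarios by mean weighted agent
#' entropy.
#'
#' @param batches named list of `ratchetr_batch` objects; names are
#'   scenario ids.
#' @return list with `table` (data.frame: one row per scenario x metric,
#'   columns `scenario`, `metric`, `mean`, `se`), `link_ratio` (NA unless a
#'   batch named `"iv"` and at least one other are present) and
#'   `entropy_ranking` (scenario ids, most to least entropic).
#' @export
compare_scenarios <- function(batches) {
  stopifnot(is.list(batches), length(batches) >= 2L)
  if (is.null(names(batches)) || any(names(batches) == ""))
    stop("'batches' must be a named list")
  for (b in batches) stopifnot(inherits(b, "ratchetr_batch"))
  tab <- do.call(rbind, lapply(names(batches), function(nm) {
    cbind(data.frame(scenario = nm), batches[[nm]]$aggregate)
  }))
  get_mean <- function(b, m) b$aggregate$mean[b$aggregate$metric == m]
  link_ratio <- NA_real_
  if ("iv" %in% names(batches) && length(batches) > 1L) {
    others <- setdiff(names(batches), "iv")
    link_ratio <- get_mean(batches[["iv"]], "between_group_links") /
      max(vapply(others, function(nm) get_mean(batches[[nm]], "between_group_links"),
                 numeric(1)))
  }
  ent <- vapply(batches, get_mean, numeric(1), m = "mean_entropy_weighted")
  list(table = tab,
       link_ratio = link_ratio,
       entropy_ranking = names(sort(ent, decreasing = TRUE)))
}
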