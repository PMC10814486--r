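#' Configuration for the clonal artificial-selection simulator
#'
#' Parameters of the synthetic selection experiment: clone populations
#' are scored for FCM (frequency of cells with micronuclei, percent),
#' the top fraction of clones by FCM seeds the next stage, and clones
#' whose FCM reaches the apoptosis threshold stop proliferating.
#'
#' The defaults are calibrated to the published selection experiment:
#' stage 0 is an equilibrium population of 48 clones with FCM
#' mean 0.6% (observed range 0-2%), selection proceeds over 5 stages
#' (indices 0-4), and clones at or above 10% FCM undergo apoptosis.
#' The per-stage standard-deviation inflation (`dispersal`) makes the
#' maximum FCM grow faster than the mean, as observed.
#'
#' @param n_clones Clones sampled per stage (default 48).
#' @param init_mean,init_sd Stage-0 FCM mean and SD in percent
#'   (defaults 0.6 and 0.5).
#' @param floor Lower truncation for FCM draws (default 0%).
#' @param selection_fraction Top fraction of clones, ranked by FCM, that
#'   seeds the next stage (default 0.1).
#' @param response Weight of the selected-parent mean in the offspring
#'   mean, in \[0, 1\]: offspring mean =
#'   `(1 - response) * population mean + response * parent mean`
#'   (default 1, full heritability of the clone phenotype).
#' @param dispersal Per-stage multiplicative inflation of the draw SD
#'   (default 1.5), so stage `k` offspring are drawn with SD
#'   `init_sd * dispersal^k`.
#' @param apoptosis_threshold FCM (%) at or above which a clone is
#'   flagged apoptotic and excluded from further breeding (default 10).
#' @param n_stages Maximum number of stages, counting stage 0
#'   (default 5).
#' @param seed Optional integer seed making the whole experiment
#'   reproducible.
#' @return A `selection_config` object (named list).
#' @export
selection_config <- function(n_clones = 48,
                             init_mean = 0.6,
                             init_sd = 0.5,
                             floor = 0,
                             selection_fraction = 0.1,
                             response = 1,
                             dispersal = 1.5,
                             apoptosis_threshold = 10,
                             n_stages = 5,
                             seed = NULL) {
  if (n_clones < 2) abort_bad_arg("`n_clones` must be >= 2")
  if (init_sd < 0) abort_bad_arg("`init_sd` must be >= 0")
  if (selection_fraction <= 0 || selection_fraction > 1) {
    abort_bad_arg("`selection_fraction` must be in (0, 1]")
  }
  if (response < 0 || response > 1) abort_bad_arg("`response` must be in [0, 1]")
  if (dispersal <= 0) abort_bad_arg("`dispersal` must be > 0")
  if (apoptosis_threshold <= 0) abort_bad_arg("`apoptosis_threshold` must be > 0")
  if (n_stages < 1) abort_bad_arg("`n_stages` must be >= 1")
  structure(
    list(n_clones = as.integer(n_clones), init_mean = init_mean,
         init_sd = init_sd, floor = floor,
         selection_fraction = selection_fraction, response = response,
         dispersal = dispersal, apoptosis_threshold = apoptosis_threshold,
         n_stages = as.integer(n_stages), seed = seed),
    class = "selection_config"
  )
}

#' @export
print.selection_config <- function(x, ...) {
  cat("<selection_config>\n")
  for (k in setdiff(names(x), "seed")) cat(sprintf("  %s: %g\n", k, x[[k]]))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# floor-truncated normal draw (values clamped at the floor)
draw_clones <- function(n, mean, sd, floor, stage, prefix = "c") {
  fcm <- pmax(floor, rnorm(n, mean = mean, sd = sd))
  fcm <- pmin(fcm, 100)
  tibble(
    clone_id = sprintf("%s%d_%03d", prefix, stage, seq_len(n)),
    fcm_percent = fcm
  )
}

#' Sample the stage-0 (equilibrium) clone population
#'
#' Draws `n_clones` clone FCM values from a zero-floored normal
#' distribution with mean `init_mean` and SD `init_sd`.
#'
#' @param config A [selection_config()].
#' @return A tibble with columns `clone_id` and `fcm_percent`.
#' @examples
#' sample_initial_population(selection_config(seed = 1))
#' @export
sample_initial_population <- function(config) {
  stopifnot(inherits(config, "selection_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  draw_clones(config$n_clones, config$init_mean, config$init_sd,
              config$floor, stage = 0)
}

#' One round of truncation selection on clone FCM
#'
#' Ranks clones by FCM (ties broken by `clone_id`), takes the top
#' `selection_fraction` as parents, and redraws a full population of
#' `n_clones` offspring around the blended mean
#' `(1 - response) * population mean + response * parent mean`, with SD
#' `init_sd * dispersal^stage`, floored at `floor`.
#'
#' @param clones Tibble of the current population (`clone_id`,
#'   `fcm_percent`), at least 2 rows.
#' @param config A [selection_config()].
#' @param stage Index of the offspring stage (used for the dispersal
#'   scaling and clone labels).
#' @return The offspring tibble, with attributes `pop_mean`,
#'   `parent_mean` and `target_mean` recording the selection arithmetic.
#' @export
selection_step <- function(clones, config, stage = 1) {
  stopifnot(inherits(config, "selection_config"))
  if (!is.data.frame(clones) || nrow(clones) < 2L) {
    abort_bad_arg("`clones` must have at least 2 rows")
  }
  ord <- order(-clones$fcm_percent, clones$clone_id)
  n_par <- max(1L, ceiling(config$selection_fraction * nrow(clones)))
  parents <- clones[ord[seq_len(n_par)], , drop = FALSE]
  pop_mean <- mean(clones$fcm_percent)
  parent_mean <- mean(parents$fcm_percent)
  target <- (1 - config$response) * pop_mean + config$response * parent_mean
  off_sd <- config$init_sd * config$dispersal^stage
  offspring <- draw_clones(config$n_clones, target, off_sd, config$floor,
                           stage = stage)
  attr(offspring, "pop_mean") <- pop_mean
  attr(offspring, "parent_mean") <- parent_mean
  attr(offspring, "target_mean") <- target
  offspring
}

#' Partition clones at the apoptosis threshold
#'
#' Clones whose FCM is at or above the threshold stop proliferating and
#' are flagged apoptotic; the partition preserves counts.
#'
#' @param clones Clone tibble (`clone_id`, `fcm_percent`).
#' @param threshold FCM (%) threshold, > 0; the comparison is inclusive.
#' @return A list with tibbles `survivors` (`fcm < threshold`) and
#'   `apoptotic` (`fcm >= threshold`).
#' @export
apoptosis_filter <- function(clones, threshold) {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort_bad_arg("`threshold` must be > 0")
  }
  dead <- clones$fcm_percent >= threshold
  list(
    survivors = clones[!dead, , drop = FALSE],
    apoptotic = clones[dead, , drop = FALSE]
  )
}

#' Summarise one stage's clone population
#'
#' @param stage_index Stage label (0-based).
#' @param clones Non-empty clone tibble.
#' @return One-row tibble: `stage`, `n_clones`, `min_fcm`, `avg_fcm`,
#'   `max_fcm`.
#' @export
stage_summary <- function(stage_index, clones) {
  x <- clone_fcm(clones)
  tibble(
    stage = as.integer(stage_index), n_clones = length(x),
    min_fcm = min(x), avg_fcm = mean(x), max_fcm = max(x)
  )
}

#' Run a full artificial-selection experiment
#'
#' Iterates sample -> summarise -> apoptosis filter -> select over up to
#' `n_stages` stages. The run terminates early, with cause
#' `"apoptosis"`, if fewer than 2 clones survive the apoptosis filter —
#' the population can no longer be propagated; otherwise it completes
#' all stages with cause `"selection-complete"`.
#'
#' Selection ranks the full scored population, apoptotic clones
#' included. This mirrors the experimental protocol: each clone is cut
#' in half and one half seeds the next stage before the other half's
#' smear is scored, so clones destined to stop proliferating cannot be
#' excluded at selection time — it is precisely the selected high-FCM
#' clones that eventually undergo apoptosis and end the experiment.
#'
#' @param config A [selection_config()]. Set `config$seed` for full
#'   reproducibility.
#' @return A `selection_experiment` object: list with
#'   * `summaries` — tibble of per-stage [stage_summary()] rows;
#'   * `stages` — list of per-stage clone tibbles (each with a logical
#'     `apoptotic` column);
#'   * `transitions` — tibble of the selection arithmetic per stage
#'     transition (`stage_from`, `pop_mean`, `parent_mean`,
#'     `differential`, `next_mean`, `increment`), the raw material for
#'     [estimate_selection_response()];
#'   * `terminated`, `termination_stage`, `cause`, `config`.
#' @examples
#' res <- run_selection_experiment(selection_config(seed = 42))
#' tidy(res)
#' @export
run_selection_experiment <- function(config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- draw_clones(config$n_clones, config$init_mean, config$init_sd,
                     config$floor, stage = 0)
  summaries <- list()
  stages <- list()
  transitions <- list()
  cause <- "selection-complete"
  termination_stage <- config$n_stages - 1L
  for (stage in 0:(config$n_stages - 1L)) {
    smry <- stage_summary(stage, pop)
    part <- apoptosis_filter(pop, config$apoptosis_threshold)
    stages[[stage + 1L]] <- mutate(
      pop, apoptotic = .data$fcm_percent >= config$apoptosis_threshold
    )
    summaries[[stage + 1L]] <- smry
    if (length(transitions)) {
      k <- length(transitions)
      transitions[[k]]$next_mean <- smry$avg_fcm
      transitions[[k]]$increment <-
        smry$avg_fcm - transitions[[k]]$pop_mean
    }
    if (stage == config$n_stages - 1L) break
    if (nrow(part$survivors) < 2L) {
      cause <- "apoptosis"
      termination_stage <- stage
      break
    }
    pop <- selection_step(pop, config, stage = stage + 1L)
    transitions[[length(transitions) + 1L]] <- tibble(
      stage_from = stage,
      pop_mean = attr(pop, "pop_mean"),
      parent_mean = attr(pop, "parent_mean"),
      differential = attr(pop, "parent_mean") - attr(pop, "pop_mean"),
      next_mean = NA_real_, increment = NA_real_
    )
  }
  structure(
    list(
      summaries = bind_rows(summaries),
      stages = stages,
      transitions = bind_rows(transitions),
      terminated = TRUE,
      termination_stage = termination_stage,
      cause = cause,
      config = config
    ),
    class = "selection_experiment"
  )
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat(sprintf("<selection_experiment> %d stage(s), cause: %s\n",
              nrow(x$summaries), x$cause))
  print(x$summaries)
  invisible(x)
}

#' @describeIn run_selection_experiment Per-stage summary tibble.
#' @param x A `selection_experiment`.
#' @param ... Unused.
#' @method tidy selection_experiment
#' @export
tidy.selection_experiment <- function(x, ...) x$summaries

#' @describeIn run_selection_experiment One-row overview tibble
#'   (`n_stages_run`, `cause`, `termination_stage`, `final_avg_fcm`,
#'   `final_max_fcm`).
#' @method glance selection_experiment
#' @export
glance.selection_experiment <- function(x, ...) {
  last <- x$summaries[nrow(x$summaries), ]
  tibble(
    n_stages_run = nrow(x$summaries),
    cause = x$cause,
    termination_stage = x$termination_stage,
    final_avg_fcm = last$avg_fcm,
    final_max_fcm = last$max_fcm
  )
}

#' Recover the selection response from simulated experiments
#'
#' Under the blended-mean heredity model, the expected per-stage change
#' in mean FCM is `response` times the selection differential (parent
#' mean minus population mean), a breeder's-equation relationship. The
#' response is therefore recovered by regressing realised increments on
#' differentials through the origin, pooling transitions across
#' experiments.
#'
#' @param experiments A single `selection_experiment` or a list of them.
#' @return The estimated response (regression slope).
#' @examples
#' runs <- lapply(1:20, function(s)
#'   run_selection_experiment(selection_config(seed = s)))
#' estimate_selection_response(runs)
#' @export
estimate_selection_response <- function(experiments) {
  if (inherits(experiments, "selection_experiment")) {
    experiments <- list(experiments)
  }
  tr <- bind_rows(lapply(experiments, function(e) e$transitions))
  tr <- tr[!is.na(tr$increment) & tr$differential > 0, , drop = FALSE]
  if (!nrow(tr)) abort_bad_arg("no usable stage transitions")
  unname(coef(lm(increment ~ 0 + differential, data = tr))[1L])
}
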