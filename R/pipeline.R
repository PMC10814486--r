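#' Read a per-stage clone summary table
#'
#' Reads a CSV or TSV (delimiter auto-detected from the header line)
#' with columns `stage`, `n_clones`, `min_fcm`, `avg_fcm`, `max_fcm` and
#' validates it: stages must ascend strictly from 0, and every row must
#' satisfy `min_fcm <= avg_fcm <= max_fcm` with FCM in \[0, 100\].
#'
#' A fixture reproducing the published five-stage selection table ships
#' with the package; see the example.
#'
#' @param path Path to the table.
#' @return A validated tibble of stage summaries.
#' @examples
#' read_stage_table(system.file("extdata", "table1.csv",
#'                              package = "genomechaos"))
#' @export
read_stage_table <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("stage", "n_clones", "min_fcm", "avg_fcm", "max_fcm")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort_bad_arg(paste0("missing column(s): ",
                         paste(missing, collapse = ", ")))
  }
  tbl <- as_tibble(tbl[required])
  if (!nrow(tbl)) abort_bad_arg("stage table is empty")
  tbl$stage <- as.integer(tbl$stage)
  tbl$n_clones <- as.integer(tbl$n_clones)
  if (tbl$stage[1L] != 0 || any(diff(tbl$stage) != 1)) {
    abort_bad_arg("stages must ascend strictly from 0 in steps of 1")
  }
  fcm <- c(tbl$min_fcm, tbl$avg_fcm, tbl$max_fcm)
  if (any(!is.finite(fcm)) || any(fcm < 0) || any(fcm > 100)) {
    abort_bad_arg("FCM values must be finite and in [0, 100]")
  }
  bad <- which(tbl$min_fcm > tbl$avg_fcm | tbl$avg_fcm > tbl$max_fcm)
  if (length(bad)) {
    abort_bad_arg(sprintf(
      "row %d (stage %d) violates min_fcm <= avg_fcm <= max_fcm",
      bad[1L], tbl$stage[bad[1L]]
    ))
  }
  tbl
}

#' Analyse a stage table: effective rates, defects, mutation probability
#'
#' For each selection stage, converts the chosen FCM column to a
#' chromothripsis cell fraction (`f_c` = FCM / 100), evaluates the
#' mixture model [effective_mutation_rate()] under the chosen
#' [rate_preset()], and reports the rate both raw and in units of 1e-4
#' rounded (half-even) to two decimals. When per-stage clone-level data
#' are supplied, the [ergodicity_defect()] of each stage against the
#' stage-0 equilibrium distribution is added; it is omitted (`NA`), not
#' zero-filled, otherwise. The cumulative probability that a gene of
#' `gene_length` nucleotides acquires at least one mutation over
#' `generations_per_stage` divisions at each stage's effective rate is
#' reported per stage.
#'
#' @param table A stage tibble as returned by [read_stage_table()] or
#'   [tidy()] of a [run_selection_experiment()] result.
#' @param fc_source Which FCM column drives `f_c`: `"average"` (default,
#'   matching the published rate column) or `"max"`.
#' @param preset Rate preset, `"table"` (default) or `"text"`; see
#'   [rate_preset()].
#' @param gene_length Gene length in nucleotides (default 720, the BCL2
#'   stand-in).
#' @param generations_per_stage Divisions per stage for the cumulative
#'   mutation probability (default 86).
#' @param clone_data Optional list of per-stage clone tibbles
#'   (`clone_id`, `fcm_percent`), one per table row in stage order, for
#'   the ergodicity-defect column.
#' @param bin_edges Bin edges for the defect histograms; by default
#'   integer edges from 0 to just above the largest observation (at
#'   least 0..20).
#' @return A `chaos_analysis` tibble: the input columns plus `f_c`,
#'   `mu`, `mu_x1e4` (rounded report), `p_mutation` and
#'   `ergodicity_defect`, with the preset and parameters stored as
#'   attributes (see [glance()]).
#' @examples
#' tab <- read_stage_table(system.file("extdata", "table1.csv",
#'                                     package = "genomechaos"))
#' analyze_stage_table(tab)
#' @export
analyze_stage_table <- function(table,
                                fc_source = c("average", "max"),
                                preset = c("table", "text"),
                                gene_length = 720,
                                generations_per_stage = 86,
                                clone_data = NULL,
                                bin_edges = NULL) {
  fc_source <- match.arg(fc_source)
  preset <- match.arg(preset)
  if (!is.data.frame(table) || !nrow(table)) {
    abort_bad_arg("`table` must be a non-empty stage table")
  }
  col <- if (fc_source == "average") "avg_fcm" else "max_fcm"
  if (!col %in% names(table)) {
    abort_bad_arg(sprintf("`table` lacks column %s", col))
  }
  f_c <- table[[col]] / 100
  if (any(f_c < 0) || any(f_c > 1)) {
    abort_bad_arg("FCM/100 must lie in [0, 1] to serve as f_c")
  }
  rates <- rate_preset(preset)
  mu <- effective_mutation_rate(f_c, rates)$mu
  out <- mutate(
    as_tibble(table),
    f_c = f_c,
    mu = mu,
    mu_x1e4 = round(mu / 1e-4, 2),
    p_mutation = cumulative_mutation_probability(mu, gene_length,
                                                 generations_per_stage)
  )
  out$ergodicity_defect <- NA_real_
  if (!is.null(clone_data)) {
    if (length(clone_data) != nrow(out)) {
      abort_bad_arg("`clone_data` must supply one clone table per stage")
    }
    if (is.null(bin_edges)) {
      top <- max(vapply(clone_data, function(d) max(d$fcm_percent),
                        numeric(1)))
      bin_edges <- 0:max(20, floor(top) + 1)
    }
    hists <- lapply(clone_data, fcm_histogram, bin_edges = bin_edges)
    out$ergodicity_defect <- vapply(
      hists, function(h) ergodicity_defect(h, hists[[1L]])$D, numeric(1)
    )
  }
  structure(out,
            class = c("chaos_analysis", class(out)),
            preset = preset, fc_source = fc_source,
            gene_length = gene_length,
            generations_per_stage = generations_per_stage)
}

#' @describeIn analyze_stage_table One-row tibble of the analysis
#'   settings and headline outputs (final-stage rate and mutation
#'   probability).
#' @param x A `chaos_analysis` tibble.
#' @param ... Unused.
#' @method glance chaos_analysis
#' @export
glance.chaos_analysis <- function(x, ...) {
  last <- x[nrow(x), ]
  tibble(
    preset = attr(x, "preset"),
    fc_source = attr(x, "fc_source"),
    gene_length = attr(x, "gene_length"),
    generations_per_stage = attr(x, "generations_per_stage"),
    n_stages = nrow(x),
    final_mu = last$mu,
    final_p_mutation = last$p_mutation
  )
}
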