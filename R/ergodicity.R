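#' Bin clone micronucleus frequencies into a probability histogram
#'
#' Discretises a set of clone observations of FCM (frequency of cells
#' with micronuclei, in percent) into half-open bins
#' \eqn{[e_i, e_{i+1})} and normalises the counts to probability masses.
#' The default binning, integer edges 0..20%, covers the range observed
#' in the selection experiments (about 0.5-17%).
#'
#' @param clones A data frame with a numeric column `fcm_percent` (one
#'   row per clone). A `clone_id` column, if present, is ignored here.
#' @param bin_edges Strictly ascending numeric edges; observations must
#'   fall in \[first edge, last edge) — the right edge is exclusive.
#' @return An `fcm_distribution` object: list with `bin_edges` and
#'   `masses` (non-negative, summing to 1).
#' @examples
#' fcm_histogram(tibble::tibble(fcm_percent = c(0.5, 1.5)), bin_edges = 0:2)
#' @export
fcm_histogram <- function(clones, bin_edges = 0:20) {
  x <- clone_fcm(clones)
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      any(diff(bin_edges) <= 0)) {
    abort_bad_arg("`bin_edges` must be >= 2 strictly ascending numbers")
  }
  lo <- bin_edges[1L]
  hi <- bin_edges[length(bin_edges)]
  out <- which(x < lo | x >= hi)
  if (length(out)) {
    abort_bad_arg(sprintf(
      "observation %g outside binning range [%g, %g) (right edge exclusive)",
      x[out[1L]], lo, hi
    ))
  }
  idx <- findInterval(x, bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  structure(
    list(bin_edges = as.numeric(bin_edges), masses = counts / length(x)),
    class = "fcm_distribution"
  )
}

clone_fcm <- function(clones) {
  if (!is.data.frame(clones) || !"fcm_percent" %in% names(clones)) {
    abort_bad_arg("`clones` must be a data frame with column `fcm_percent`")
  }
  x <- clones$fcm_percent
  if (!length(x)) abort_bad_arg("`clones` is empty")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    abort_bad_arg("`fcm_percent` must be finite values in [0, 100]")
  }
  x
}

#' @export
print.fcm_distribution <- function(x, ...) {
  nb <- length(x$masses)
  cat(sprintf("<fcm_distribution> %d bins on [%g, %g)\n",
              nb, x$bin_edges[1L], x$bin_edges[nb + 1L]))
  invisible(x)
}

#' @describeIn fcm_histogram Tidy an `fcm_distribution` into a tibble with
#'   columns `bin_left`, `bin_right`, `mass`.
#' @param x An `fcm_distribution`.
#' @param ... Unused.
#' @method tidy fcm_distribution
#' @export
tidy.fcm_distribution <- function(x, ...) {
  nb <- length(x$masses)
  tibble(
    bin_left = x$bin_edges[seq_len(nb)],
    bin_right = x$bin_edges[seq_len(nb) + 1L],
    mass = x$masses
  )
}

#' Population (ensemble) average of clone FCM
#'
#' The arithmetic mean FCM across clones — the ensemble average whose
#' equality with the time average defines ergodic behaviour of the clone
#' population.
#'
#' @inheritParams fcm_histogram
#' @return Mean FCM in percent.
#' @export
population_average <- function(clones) {
  mean(clone_fcm(clones))
}

#' Time (generation) average of a lineage trajectory
#'
#' The arithmetic mean of an observable recorded per generation for one
#' lineage. In a stationary (ergodic) population this converges to the
#' population average.
#'
#' @param trajectory Numeric vector of per-generation values (>= 1).
#' @return Mean over generations.
#' @export
time_average <- function(trajectory) {
  if (!is.numeric(trajectory) || !length(trajectory)) {
    abort_bad_arg("`trajectory` must be a non-empty numeric vector")
  }
  mean(trajectory)
}

#' Discrete ergodicity defect between two FCM distributions
#'
#' Quantifies deviation from ergodic behaviour as the integrated squared
#' difference between a current (ensemble) distribution and a reference
#' (equilibrium / time-average) distribution, discretised on a shared
#' binning with proportionality constant 1:
#' \deqn{D = \sum_i (m^{cur}_i - m^{ref}_i)^2.}
#' D is symmetric in its arguments, zero iff the histograms coincide, and
#' bounded above by 2 (attained by disjoint point masses). The
#' pre-selection (stage-0) distribution is the natural reference, being
#' assumed to be the equilibrium distribution.
#'
#' @param current,reference `fcm_distribution` objects on identical
#'   `bin_edges` (see [fcm_histogram()]).
#' @return A one-row tibble with columns `D` and `n_bins`.
#' @examples
#' a <- fcm_histogram(tibble::tibble(fcm_percent = c(0.2, 0.4)), 0:3)
#' b <- fcm_histogram(tibble::tibble(fcm_percent = c(2.1, 2.9)), 0:3)
#' ergodicity_defect(a, b)  # D = 2, disjoint point masses
#' @export
ergodicity_defect <- function(current, reference) {
  if (!inherits(current, "fcm_distribution") ||
      !inherits(reference, "fcm_distribution")) {
    abort_bad_arg("inputs must be `fcm_distribution` objects")
  }
  if (length(current$bin_edges) != length(reference$bin_edges) ||
      any(current$bin_edges != reference$bin_edges)) {
    abort_bad_arg("distributions must share identical bin edges")
  }
  tibble(
    D = sum((current$masses - reference$masses)^2),
    n_bins = length(current$masses)
  )
}

#' Is a population ergodic at a given tolerance?
#'
#' @param result A result of [ergodicity_defect()] (or a bare numeric D).
#' @param tol Non-negative threshold; the comparison is inclusive
#'   (`D <= tol` is ergodic).
#' @return Logical flag.
#' @export
is_ergodic <- function(result, tol) {
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0) {
    abort_bad_arg("`tol` must be a single non-negative number")
  }
  d <- if (is.data.frame(result)) result$D else result
  if (!is.numeric(d) || any(d < 0)) abort_bad_arg("invalid defect value")
  d <= tol
}
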