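#' Somatic mutation-rate model
#'
#' Bundles the three per-nucleotide, per-division mutation rates used by
#' the chromothripsis mixture model: the spontaneous somatic rate `mu0`,
#' the rate in cancer cells without chromothripsis `mu_can`, and the rate
#' in chromothripsis-affected cells `mu_c`. Rates must satisfy
#' `mu0 <= mu_can <= mu_c`, each in (0, 1].
#'
#' @param mu0 Spontaneous somatic rate (default 1.4e-10).
#' @param mu_can Cancer-without-chromothripsis rate (default 1e-7).
#' @param mu_c Chromothripsis-cell rate (default 1e-4).
#' @return A `rate_model` object (named list).
#' @seealso [rate_preset()] for the two published parameterisations.
#' @export
rate_model <- function(mu0 = 1.4e-10, mu_can = 1e-7, mu_c = 1e-4) {
  vals <- c(mu0 = mu0, mu_can = mu_can, mu_c = mu_c)
  if (!all(is.finite(vals)) || any(vals <= 0) || any(vals > 1)) {
    abort_bad_arg("all rates must lie in (0, 1]")
  }
  if (!(mu0 <= mu_can && mu_can <= mu_c)) {
    abort_bad_arg("rates must satisfy mu0 <= mu_can <= mu_c")
  }
  structure(list(mu0 = mu0, mu_can = mu_can, mu_c = mu_c),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> mu0 = %g, mu_can = %g, mu_c = %g\n",
              x$mu0, x$mu_can, x$mu_c))
  invisible(x)
}

#' Named rate presets
#'
#' Two parameterisations of the mixture model ship as presets:
#'
#' * `"text"` — `mu_c = 1e-4`, `mu_can = 1e-7`: the narrative worked
#'   example (10% chromothripsis fraction gives an effective rate of
#'   1.009e-5).
#' * `"table"` — `mu_c = 1e-1`, `mu_can = 1e-4`: the parameterisation
#'   that reproduces, cell for cell, the published per-stage effective
#'   mutation rate column (in units of 1e-4, two decimals) of the
#'   selection-experiment summary table when the chromothripsis fraction
#'   is taken as average FCM / 100.
#'
#' The two differ by a factor of 1000 in both component rates; the source
#' material does not reconcile the units, so both are kept explicit.
#'
#' @param preset `"text"` or `"table"`.
#' @return A [rate_model()].
#' @examples
#' rate_preset("text")
#' @export
rate_preset <- function(preset = c("text", "table")) {
  preset <- match.arg(preset)
  switch(preset,
    text  = rate_model(mu0 = 1.4e-10, mu_can = 1e-7, mu_c = 1e-4),
    table = rate_model(mu0 = 1.4e-10, mu_can = 1e-4, mu_c = 1e-1)
  )
}

#' Effective population mutation rate under the chromothripsis mixture
#'
#' The effective rate in a population in which a fraction `f_c` of cells
#' carry chromothripsis is the linear mixture
#' \deqn{\mu = f_c \mu_c + (1 - f_c) \mu_{can}.}
#'
#' @param f_c Fraction of cells with chromothripsis, in \[0, 1\].
#'   Vectorised.
#' @param rates A [rate_model()]; defaults to the `"text"` preset.
#' @return A tibble with columns `f_c` and `mu`. `mu` always lies in
#'   \[`mu_can`, `mu_c`\] and is affine increasing in `f_c`.
#' @examples
#' effective_mutation_rate(0.1)  # mu = 1.009e-5
#' @export
effective_mutation_rate <- function(f_c, rates = rate_preset("text")) {
  if (!inherits(rates, "rate_model")) abort_bad_arg("`rates` must be a rate_model")
  if (!is.numeric(f_c) || any(!is.finite(f_c)) ||
      any(f_c < 0) || any(f_c > 1)) {
    abort_bad_arg("`f_c` must be in [0, 1]")
  }
  tibble(f_c = f_c, mu = f_c * rates$mu_c + (1 - f_c) * rates$mu_can)
}

#' Probability of at least one mutation over many divisions
#'
#' For a sequence of `length` nucleotides dividing for `generations`
#' divisions at per-nucleotide rate `rate`, the probability that at least
#' one substitution has occurred is
#' \eqn{p = 1 - (1 - rate)^{length \times generations}}.
#'
#' @param rate Per-nucleotide, per-division probability in \[0, 1\].
#' @param length Sequence length in nucleotides (>= 1).
#' @param generations Number of divisions (>= 0). Vectorised.
#' @return Probability in \[0, 1\], monotone non-decreasing in each
#'   argument.
#' @examples
#' cumulative_mutation_probability(1e-5, 720, 86)
#' @export
cumulative_mutation_probability <- function(rate, length, generations) {
  if (!is.numeric(rate) || any(rate < 0) || any(rate > 1)) {
    abort_bad_arg("`rate` must be in [0, 1]")
  }
  if (!is.numeric(length) || any(length < 1)) abort_bad_arg("`length` must be >= 1")
  if (!is.numeric(generations) || any(generations < 0)) {
    abort_bad_arg("`generations` must be >= 0")
  }
  ifelse(rate == 1 & length * generations > 0, 1,
         -expm1(length * generations * log1p(-rate)))
}

#' Barrier height from the spontaneous mutation rate
#'
#' The enthalpy-analogue resistance to phenotype switching is estimated as
#' the reciprocal of the spontaneous somatic mutation rate,
#' \eqn{\Delta h = 1/\mu_0}.
#'
#' @param mu0 Spontaneous rate, > 0.
#' @param signif_digits Optional: round the report to this many
#'   significant figures (the headline estimate uses one, giving 7e9 at
#'   `mu0 = 1.4e-10`).
#' @return `1 / mu0`, optionally rounded.
#' @examples
#' barrier_height(1.4e-10)
#' barrier_height(1.4e-10, signif_digits = 1)
#' @export
barrier_height <- function(mu0, signif_digits = NULL) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0) || mu0 <= 0) {
    abort_bad_arg("`mu0` must be a single positive number")
  }
  dh <- 1 / mu0
  if (!is.null(signif_digits)) dh <- signif(dh, signif_digits)
  dh
}

#' Exact number of chromosomal rearrangement variants
#'
#' `N` chromosomal segments shattered and rejoined in arbitrary order can
#' be rearranged in `N!` ways. The count is computed exactly: as a double
#' while exactly representable (N <= 18), and as an arbitrary-precision
#' decimal string beyond that.
#'
#' @param n Non-negative integer segment count.
#' @return Numeric `n!` for `n <= 18`; otherwise a character string giving
#'   the exact factorial.
#' @examples
#' rearrangement_count(5)   # 120
#' rearrangement_count(25)  # exact 26-digit string
#' @export
rearrangement_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n < 0 || n != round(n)) {
    abort_bad_arg("`n` must be a single non-negative integer")
  }
  n <- as.integer(n)
  if (n <= 18L) return(prod(seq_len(n)))  # prod(integer(0)) == 1
  big_factorial(n)
}

# schoolbook big-integer factorial in base 1e7, least-significant first
big_factorial <- function(n) {
  digits <- 1
  base <- 1e7
  for (k in 2:n) {
    digits <- digits * k
    carry <- 0
    for (i in seq_along(digits)) {
      v <- digits[i] + carry
      digits[i] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) {
      digits <- c(digits, carry %% base)
      carry <- carry %/% base
    }
  }
  paste0(
    format(digits[length(digits)], scientific = FALSE),
    paste(rev(sprintf("%07d", digits[-length(digits)])), collapse = "")
  )
}

#' Shannon entropy of chromosomal rearrangement
#'
#' Two conventions are provided. `"permutation"` (the default) returns
#' \eqn{\ln(N!)}, the Shannon entropy in nats of the uniform distribution
#' over the `N!` possible rearrangements of `N` segments — a proper,
#' non-negative mixing entropy. `"printed"` returns \eqn{-N \ln N}, the
#' literal closed form sometimes quoted for this quantity; it is negative
#' for `N > 1` and is retained only for fidelity to that convention.
#'
#' @param n Positive integer segment count. Vectorised.
#' @param mode `"permutation"` (default) or `"printed"`.
#' @return Entropy in nats.
#' @examples
#' rearrangement_entropy(4)                    # log(24)
#' rearrangement_entropy(10, mode = "printed") # -10 log(10)
#' @export
rearrangement_entropy <- function(n, mode = c("permutation", "printed")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1) ||
      any(n != round(n))) {
    abort_bad_arg("`n` must be integer >= 1")
  }
  switch(mode,
    permutation = lfactorial(n),
    printed     = -n * log(n)
  )
}

#' Gibbs-type stability criterion for genome integrity
#'
#' By analogy with phase-transition thermodynamics, genome stability under
#' mutagenic pressure is scored by a free-energy-like difference
#' \deqn{\Delta G = \Delta h - \theta \Delta S,}
#' where \eqn{\Delta h} is the barrier height (resistance to mutation),
#' \eqn{\theta} a dimensionless mutagenicity parameter, and
#' \eqn{\Delta S} the entropy change of rearrangement. The genome is
#' stable (chromothripsis prohibited) while \eqn{\Delta G > 0}, i.e.
#' strictly below the critical mutagenicity
#' \eqn{\theta_0 = \Delta h / \Delta S}.
#'
#' @param delta_h Enthalpic resistance term.
#' @param theta Dimensionless mutagenicity. Vectorised.
#' @param delta_s Entropy change, > 0.
#' @return A tibble with columns `theta`, `delta_g`, `stable` (logical,
#'   `delta_g > 0`) and `theta0`.
#' @examples
#' gibbs_free_energy(10, theta = c(1, 2, 3), delta_s = 5)
#' @export
gibbs_free_energy <- function(delta_h, theta, delta_s) {
  if (!is.numeric(delta_s) || any(delta_s <= 0)) {
    abort_bad_arg("`delta_s` must be > 0")
  }
  dg <- delta_h - theta * delta_s
  tibble(theta = theta, delta_g = dg, stable = dg > 0,
         theta0 = delta_h / delta_s)
}

#' Critical mutagenicity threshold
#'
#' The mutagenicity at which the Gibbs-type criterion
#' \eqn{\Delta G = \Delta h - \theta \Delta S} crosses zero:
#' \eqn{\theta_0 = \Delta h / \Delta S}.
#'
#' @inheritParams gibbs_free_energy
#' @return `delta_h / delta_s`.
#' @examples
#' critical_mutagenicity(7e9, 7e9)
#' @export
critical_mutagenicity <- function(delta_h, delta_s) {
  if (!is.numeric(delta_s) || any(delta_s <= 0)) {
    abort_bad_arg("`delta_s` must be > 0")
  }
  delta_h / delta_s
}

#' Difference of protein stability scores
#'
#' The stability change of a mutant relative to wild type is the simple
#' difference of their energy scores,
#' \eqn{\Delta ES = ES_{mut} - ES_{wt}} (in Rosetta energy units when the
#' scores come from a Rosetta protocol). Positive values indicate
#' destabilisation. This function only subtracts supplied numbers; it
#' does not compute scores.
#'
#' @param es_wt,es_mut Finite numeric scores. Vectorised.
#' @return `es_mut - es_wt`.
#' @examples
#' score_difference(es_wt = -282.11, es_mut = -278)  # 4.11
#' @export
score_difference <- function(es_wt, es_mut) {
  if (!is.numeric(es_wt) || !is.numeric(es_mut) ||
      any(!is.finite(es_wt)) || any(!is.finite(es_mut))) {
    abort_bad_arg("scores must be finite numbers")
  }
  es_mut - es_wt
}
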