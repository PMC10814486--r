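test_that("rate models validate their ordering and range invariants", {
  m <- rate_model()
  expect_s3_class(m, "rate_model")
  expect_error(rate_model(mu0 = 0), "\\(0, 1\\]")
  expect_error(rate_model(mu0 = 1e-4, mu_can = 1e-7), "mu0 <= mu_can")
  expect_error(rate_model(mu_can = 2), "\\(0, 1\\]")
})

test_that("the effective rate is the mixture of component rates", {
  text <- rate_preset("text")
  expect_equal(effective_mutation_rate(0.1, text)$mu, 1.009e-5)
  expect_identical(effective_mutation_rate(0, text)$mu, text$mu_can)
  expect_identical(effective_mutation_rate(1, text)$mu, text$mu_c)
  expect_error(effective_mutation_rate(1.2, text), "\\[0, 1\\]")

  # affine, monotone increasing, bounded by the component rates
  f <- seq(0, 1, by = 0.05)
  mu <- effective_mutation_rate(f, text)$mu
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu >= text$mu_can & mu <= text$mu_c))
  slopes <- diff(mu) / diff(f)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
})

test_that("the table preset reproduces the per-stage rate column by direct arithmetic", {
  tab <- rate_preset("table")
  fcm_avg <- c(0.6, 0.8, 1.7, 1.6, 4.7)
  # independent oracle: direct evaluation of the mixture
  oracle <- fcm_avg / 100 * 0.1 + (1 - fcm_avg / 100) * 1e-4
  got <- effective_mutation_rate(fcm_avg / 100, tab)$mu
  expect_equal(got, oracle)
  expect_identical(round(got / 1e-4, 2), c(6.99, 8.99, 17.98, 16.98, 47.95))
})

test_that("cumulative mutation probability is a closed-form saturation curve", {
  expect_identical(cumulative_mutation_probability(1e-5, 720, 0), 0)
  expect_identical(cumulative_mutation_probability(1, 10, 5), 1)
  expect_equal(cumulative_mutation_probability(1e-5, 720, 86),
               1 - (1 - 1e-5)^(720 * 86), tolerance = 1e-9)
  # monotone in each argument
  expect_true(all(diff(cumulative_mutation_probability(1e-5, 720, 0:200)) > 0))
  expect_lt(cumulative_mutation_probability(1e-6, 720, 86),
            cumulative_mutation_probability(1e-5, 720, 86))
  expect_lt(cumulative_mutation_probability(1e-5, 100, 86),
            cumulative_mutation_probability(1e-5, 720, 86))
})

test_that("cumulative probability agrees with a Monte Carlo built from mutate_gene", {
  # length 50, rate 1e-3, 20 generations, 1e4 replicates (3 SE band)
  L <- 50; mu <- 1e-3; gens <- 20; n_rep <- 1e4
  s <- gene_sequence(strrep("A", L))
  set.seed(123)
  hit <- vapply(seq_len(n_rep), function(i) {
    for (g in seq_len(gens)) {
      if (nrow(mutate_gene(s, mu)$mutations) > 0L) return(TRUE)
    }
    FALSE
  }, logical(1))
  p_hat <- mean(hit)
  p <- cumulative_mutation_probability(mu, L, gens)
  se <- sqrt(p * (1 - p) / n_rep)
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("barrier height is the reciprocal spontaneous rate", {
  expect_equal(barrier_height(1.4e-10), 1 / 1.4e-10)
  expect_identical(barrier_height(1.4e-10, signif_digits = 1), 7e9)
  expect_identical(barrier_height(1), 1)
  expect_identical(barrier_height(2e-10), 5e9)
  expect_error(barrier_height(0), "positive")
})

test_that("rearrangement counts are exact factorials, validated by enumeration", {
  expect_identical(rearrangement_count(0), 1)
  expect_identical(rearrangement_count(3), 6)
  expect_identical(rearrangement_count(5), 120)
  # brute-force permutation enumeration as the oracle
  for (n in 0:5) {
    expect_identical(rearrangement_count(n),
                     as.numeric(enumerate_permutations(n)))
  }
  # arbitrary precision beyond the double-exact range
  expect_identical(rearrangement_count(19), "121645100408832000")
  expect_identical(rearrangement_count(20), "2432902008176640000")
  expect_identical(nchar(rearrangement_count(25)), 26L)
  expect_error(rearrangement_count(-1), "non-negative")
  expect_error(rearrangement_count(2.5), "integer")
})

test_that("rearrangement entropy has both conventions, in nats", {
  expect_identical(rearrangement_entropy(1), 0)
  expect_identical(rearrangement_entropy(1, mode = "printed"), 0)
  # permutation mode: Shannon entropy of 24 equiprobable rearrangements
  p <- rep(1 / 24, 24)
  expect_equal(rearrangement_entropy(4), -sum(p * log(p)))
  expect_equal(rearrangement_entropy(10, mode = "printed"), -10 * log(10))
  # permutation entropy equals log of the exact count up to N = 12
  for (n in 1:12) {
    expect_equal(rearrangement_entropy(n), log(rearrangement_count(n)))
  }
  expect_error(rearrangement_entropy(0), ">= 1")
})

test_that("the Gibbs criterion flips stability exactly at the critical mutagenicity", {
  res <- gibbs_free_energy(10, theta = 1, delta_s = 5)
  expect_equal(res$delta_g, 5)
  expect_true(res$stable)
  expect_false(gibbs_free_energy(10, theta = 3, delta_s = 5)$stable)
  # boundary: theta = theta0 gives delta_g = 0, not stable (strict inequality)
  expect_false(gibbs_free_energy(10, theta = 2, delta_s = 5)$stable)
  expect_identical(critical_mutagenicity(10, 5), 2)
  expect_identical(critical_mutagenicity(7e9, 7e9), 1)
  expect_error(gibbs_free_energy(10, 1, 0), "> 0")
  expect_error(critical_mutagenicity(10, -1), "> 0")

  set.seed(3)
  for (i in 1:25) {
    dh <- runif(1, 0.1, 100); ds <- runif(1, 0.1, 10)
    t0 <- critical_mutagenicity(dh, ds)
    eps <- 1e-6 * t0
    expect_true(gibbs_free_energy(dh, t0 - eps, ds)$stable)
    expect_false(gibbs_free_energy(dh, t0 + eps, ds)$stable)
  }
})

test_that("score differences subtract mutant minus wild type", {
  expect_equal(score_difference(es_wt = -282.11, es_mut = -278), 4.11)
  expect_identical(score_difference(5, 5), 0)
  expect_identical(score_difference(0, -1), -1)
  expect_error(score_difference(NA_real_, 1), "finite")
  expect_error(score_difference(1, Inf), "finite")
})
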