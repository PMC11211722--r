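make_paired_data <- function(n = 6, shift_ms = 20, fs = 250, seed = 1,
                             lambda = 0.1) {
  syn <- generate_erp(synth_spec(n_participants = n, fs = fs,
                                 condition_shift_ms = shift_ms,
                                 noise_lambda = lambda),
                      seed = seed)
  list(a = syn$comp1$early, b = syn$comp1$late)
}

test_that("permutation test returns p = 1 and zero area for identical conditions", {
  d <- make_paired_data(n = 5, shift_ms = 0, seed = 3)
  # condition B literally equal to condition A for every participant
  res <- permutation_test(d$a, d$a, window = c(150, 400), n_perm = 50, seed = 7)
  expect_identical(res$observed_area, 0)
  expect_identical(res$p, 1)
  expect_true(all(res$null_areas == 0))
})

test_that("Monte-Carlo permutation p matches exhaustive flip enumeration at n = 3", {
  d <- make_paired_data(n = 3, shift_ms = 30, seed = 11, lambda = 0.2)
  exact <- exact_permutation_p(d$a, d$b, window = c(150, 400))
  mc <- permutation_test(d$a, d$b, window = c(150, 400),
                         n_perm = 4000, seed = 5)
  expect_equal(mc$observed_area, exact$observed)
  expect_lt(abs(mc$p - exact$p), 0.02)
})

test_that("larger injected shifts do not increase the expected permutation p", {
  p_small <- p_large <- numeric(5)
  for (s in 1:5) {
    d1 <- make_paired_data(n = 10, shift_ms = 8, seed = 100 + s, lambda = 0.3)
    d2 <- make_paired_data(n = 10, shift_ms = 60, seed = 100 + s, lambda = 0.3)
    p_small[s] <- permutation_test(d1$a, d1$b, c(150, 400), n_perm = 200,
                                   seed = s)$p
    p_large[s] <- permutation_test(d2$a, d2$b, c(150, 400), n_perm = 200,
                                   seed = s)$p
  }
  expect_lte(mean(p_large), mean(p_small))
})

test_that("bootstrap coupling of a component with itself is perfect", {
  syn <- generate_erp(synth_spec(n_participants = 8, fs = 250), seed = 2)
  cp <- bootstrap_coupling(syn$comp1$early, syn$comp1$early,
                           window1 = c(150, 400), window2 = c(150, 400),
                           n_boot = 100, seed = 9)
  expect_identical(cp$areas[, 1], cp$areas[, 2])
  expect_equal(cp$r_pearson, 1)
  expect_equal(cp$r_spearman, 1)
})

test_that("coupling correlations carry the shared-sample pairing, not the marginals", {
  syn <- generate_erp(synth_spec(n_participants = 12, fs = 250,
                                 coupling_b = 1, coupling_sd = 2,
                                 noise_lambda = 0.05),
                      seed = 4)
  cp <- bootstrap_coupling(syn$comp1$early, syn$comp2$early,
                           window1 = c(150, 400), window2 = c(250, 800),
                           n_boot = 400, seed = 6)
  expect_gt(cp$r_pearson, 0.3)

  # Pearson r is invariant to the z-scoring of the area distributions
  expect_equal(cp$r_pearson, cor(cp$areas[, 1], cp$areas[, 2]))

  # destroying the pairing destroys the correlation
  set.seed(8)
  shuffled <- cor(cp$z_areas[, 1], sample(cp$z_areas[, 2]))
  expect_lt(abs(shuffled), abs(cp$r_pearson) / 2)
  expect_lt(abs(shuffled), 0.15)
})

test_that("outlier-pair exclusion removes exactly the planted pairs", {
  set.seed(21)
  areas <- cbind(comp1 = rnorm(10000), comp2 = rnorm(10000))
  cp <- erpwarp:::build_coupling(areas, n_participants = 23,
                                 skipped = 0L, removed = 0L)

  # nothing beyond 5 SD: unchanged, removed count 0
  clean <- exclude_outlier_pairs(cp, k_sd = 5)
  expect_identical(clean$removed, 0L)
  expect_identical(clean$areas, cp$areas)
  expect_equal(clean$r_pearson, cp$r_pearson)

  # one extreme pair at +10 SD is removed from both marginals
  areas1 <- areas
  areas1[17, ] <- c(10 * sd(areas[, 1]), 0.2)
  cp1 <- erpwarp:::build_coupling(areas1, 23, 0L, 0L)
  ex1 <- exclude_outlier_pairs(cp1, k_sd = 5)
  expect_identical(ex1$removed, 1L)
  expect_identical(ex1$areas, areas1[-17, ])

  # 80 planted 6-SD values in one marginal -> removed count equals planted count
  areas2 <- areas
  planted <- sample(10000, 80)
  areas2[planted, 1] <- 6 * sample(c(-1, 1), 80, replace = TRUE)
  cp2 <- erpwarp:::build_coupling(areas2, 23, 0L, 0L)
  ex2 <- exclude_outlier_pairs(cp2, k_sd = 5)
  expect_identical(ex2$removed, 80L)
  expect_identical(ex2$areas, areas2[-planted, ])
})

test_that("Fisher-Z correlation comparison matches an independent computation", {
  # identical correlations: no difference
  same <- compare_correlations(0.4, 50, 0.4, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  # independently hand-coded oracle
  fisher_oracle <- function(r1, n1, r2, n2, k) {
    z1 <- 0.5 * log((1 + r1) / (1 - r1))
    z2 <- 0.5 * log((1 + r2) / (1 - r2))
    zs <- (z1 - z2) / sqrt(k / (n1 - 3) + k / (n2 - 3))
    list(z = zs, p = 2 * (1 - pnorm(abs(zs))))
  }
  got <- compare_correlations(0.33, 10000, 0.15, 10000, method = "pearson")
  want <- fisher_oracle(0.33, 10000, 0.15, 10000, k = 1)
  expect_equal(got$z, want$z)
  expect_equal(got$p, want$p)
  expect_lt(got$p, 0.0001)

  sp <- compare_correlations(0.4, 10000, 0.14, 10000, method = "spearman")
  want_sp <- fisher_oracle(0.4, 10000, 0.14, 10000, k = 1.06)
  expect_equal(sp$z, want_sp$z)

  # antisymmetry under argument swap
  a <- compare_correlations(0.5, 100, -0.5, 100)
  b <- compare_correlations(-0.5, 100, 0.5, 100)
  expect_equal(a$z, -b$z)

  expect_error(compare_correlations(1, 100, 0.2, 100), "inside")
  expect_error(compare_correlations(0.1, 3, 0.2, 100), "exceed 3")
})

test_that("marginal moments use the documented conventions", {
  x <- c(2.1, -0.3, 0.8, 1.4, -1.9, 0.05, 3.2, -0.6, 0.9, 1.1)
  m <- marginal_moments(x)
  # hand-computed oracle with explicit central moments
  mu <- sum(x) / 10
  m2 <- sum((x - mu)^2) / 10
  expect_equal(m$variance, sum((x - mu)^2) / 9)
  expect_equal(m$skewness, (sum((x - mu)^3) / 10) / m2^1.5)
  expect_equal(m$kurtosis, (sum((x - mu)^4) / 10) / m2^2 - 3)

  # cross-check against e1071's type-1 (biased moment) definitions
  expect_equal(m$skewness, e1071::skewness(x, type = 1))
  expect_equal(m$kurtosis, e1071::kurtosis(x, type = 1))

  # symmetric two-point sample has zero skewness
  expect_equal(marginal_moments(c(-1, 1, -1, 1))$skewness, 0)

  # standard normal sample, large n
  set.seed(33)
  big <- marginal_moments(rnorm(20000))
  expect_equal(big$variance, 1, tolerance = 0.05)
  expect_equal(big$skewness, 0, tolerance = 0.05)

  expect_error(marginal_moments(c(1, 2)), "at least 3")
})
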