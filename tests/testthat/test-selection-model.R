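slice_fixture <- function() {
  # 10 tumors: T1-T3 carry the focal variant, T4-T5 carry another variant
  # of the same gene, T6-T10 are untouched in that gene
  dplyr::bind_rows(
    make_variant(tumor_id = c("T1", "T2", "T3"), pos = 50L, gene = "NFE2L2"),
    make_variant(tumor_id = c("T4", "T5"), pos = 60L, gene = "NFE2L2"),
    make_variant(tumor_id = paste0("T", 6:10), pos = 500L, gene = "TP53"))
}

test_that("slice_cohort separates carriers from eligible non-carriers", {
  v <- slice_fixture()
  key <- variant_key(make_variant(pos = 50L))
  sl <- slice_cohort(v, key, tumor_ids = paste0("T", 1:10))
  expect_equal(sl$M, 3)
  expect_equal(sl$Z, 8)
  expect_setequal(sl$carriers, c("T1", "T2", "T3"))
  expect_false(any(c("T4", "T5") %in% sl$noncarriers))

  # absent variant: no carriers, everyone without same-gene variants eligible
  sl0 <- slice_cohort(v, "chrX:1:A>C", tumor_ids = paste0("T", 1:10))
  expect_equal(sl0$M, 0)
  expect_equal(sl0$Z, 10)

  # carrier status dominates: a carrier with a second same-gene variant stays
  v2 <- dplyr::bind_rows(v, make_variant(tumor_id = "T1", pos = 60L,
                                         gene = "NFE2L2"))
  sl2 <- slice_cohort(v2, key, tumor_ids = paste0("T", 1:10))
  expect_true("T1" %in% sl2$carriers)
  expect_equal(sl2$M, 3)
})

test_that("log-likelihood matches its closed expression", {
  # no carriers: monotone decreasing in gamma, maximized at 0
  ll <- loglik_gamma(c(0, 1, 5), numeric(0), c(0.3, 0.7))
  expect_equal(ll, c(0, -1, -5))
  # hand evaluation: M=1, Z=2, mu=(1,1), gamma=ln 2 -> -2 ln 2
  expect_equal(loglik_gamma(log(2), 1, 1), -2 * log(2))
  # gamma -> Inf with M=Z: approaches 0 from below, monotonically
  ll_inc <- loglik_gamma(c(1, 5, 20), c(0.5, 0.5), numeric(0))
  expect_true(all(diff(ll_inc) > 0))
  expect_true(all(ll_inc < 0))
  expect_gt(ll_inc[3], -1e-3)
})

test_that("homogeneous-rate MLE matches the closed form to 1e-6", {
  for (Z in c(5L, 20L, 100L)) {
    for (M in unique(pmin(c(1L, 2L, Z %/% 3L, Z - 1L), Z - 1L))) {
      if (M < 1) next
      for (mu in c(1e-6, 1e-3, 0.5)) {
        est <- mle_gamma(rep(mu, M), rep(mu, Z - M))
        closed <- -log(1 - M / Z) / mu
        expect_equal(est$gamma_hat, closed, tolerance = 1e-6)
        expect_false(est$unbounded)
        # score is zero and the likelihood is locally concave at the optimum
        mu_c <- rep(mu, M); mu_n <- rep(mu, Z - M)
        expect_lt(abs(sigfx:::score_gamma(est$gamma_hat, mu_c, mu_n)),
                  1e-5 * sum(mu_n))
        d <- est$gamma_hat * 1e-3
        expect_gt(est$loglik, loglik_gamma(est$gamma_hat - d, mu_c, mu_n))
        expect_gt(est$loglik, loglik_gamma(est$gamma_hat + d, mu_c, mu_n))
      }
    }
  }
})

test_that("a reference worked example evaluates correctly: M=3, Z=10, mu=1e-6", {
  est <- mle_gamma(rep(1e-6, 3), rep(1e-6, 7))
  expect_equal(est$gamma_hat, -log(0.7) * 1e6, tolerance = 1e-6)
  expect_equal(est$gamma_hat, 3.5667e5, tolerance = 1e-4)
})

test_that("heterogeneous-rate MLE matches a dense grid-search oracle", {
  set.seed(17)
  for (i in 1:5) {
    M <- sample(2:8, 1); Znon <- sample(5:30, 1)
    mu_c <- stats::runif(M, 1e-5, 1e-3)
    mu_n <- stats::runif(Znon, 1e-5, 1e-3)
    est <- mle_gamma(mu_c, mu_n)
    grid <- exp(seq(log(est$gamma_hat) - 3, log(est$gamma_hat) + 3,
                    length.out = 20001))
    ll <- loglik_gamma(grid, mu_c, mu_n)
    expect_equal(est$gamma_hat, grid[which.max(ll)], tolerance = 1e-3)
    expect_gte(est$loglik, max(ll) - 1e-9)
  }
})

test_that("degenerate slices behave as documented", {
  expect_equal(mle_gamma(numeric(0), c(0.1, 0.2))$gamma_hat, 0)
  capped <- mle_gamma(c(0.1, 0.2), numeric(0), gamma_max = 1e12)
  expect_true(capped$unbounded)
  expect_equal(capped$gamma_hat, 1e12)
  expect_error(mle_gamma(numeric(0), numeric(0)), "empty")
})

test_that("gamma_hat increases with M and is scale-equivariant in mu", {
  mu <- 2e-4
  Z <- 30L
  est <- vapply(1:20, function(M) {
    mle_gamma(rep(mu, M), rep(mu, Z - M))$gamma_hat
  }, numeric(1))
  expect_true(all(diff(est) > 0))

  set.seed(23)
  mu_c <- stats::runif(4, 1e-5, 1e-3); mu_n <- stats::runif(12, 1e-5, 1e-3)
  g1 <- mle_gamma(mu_c, mu_n)$gamma_hat
  g2 <- mle_gamma(10 * mu_c, 10 * mu_n)$gamma_hat
  expect_equal(g2, g1 / 10, tolerance = 1e-8)
})

test_that("profile-likelihood intervals cover the MLE and invert the LR drop", {
  mu_c <- rep(2e-4, 6); mu_n <- rep(2e-4, 24)
  ci <- profile_gamma_ci(mu_c, mu_n, level = 0.95)
  expect_lt(ci$lower, ci$gamma_hat)
  expect_gt(ci$upper, ci$gamma_hat)
  drop <- stats::qchisq(0.95, 1) / 2
  ll_max <- loglik_gamma(ci$gamma_hat, mu_c, mu_n)
  expect_equal(loglik_gamma(ci$lower, mu_c, mu_n), ll_max - drop,
               tolerance = 1e-5)
  expect_equal(loglik_gamma(ci$upper, mu_c, mu_n), ll_max - drop,
               tolerance = 1e-5)
  # boundary cases: no carriers (one-sided), all carriers (upper = Inf)
  ci0 <- profile_gamma_ci(numeric(0), rep(1e-3, 10))
  expect_equal(ci0$lower, 0)
  expect_gt(ci0$upper, 0)
  ciZ <- profile_gamma_ci(rep(1e-3, 5), numeric(0))
  expect_equal(ciZ$upper, Inf)
})

test_that("estimate_effect_sizes ties the pieces together on a tiny cohort", {
  cfg <- simulation_config(n_tumors = 40, seed = 77)
  sim <- simulate_cohort(cfg)
  fit <- fit_signatures(build_spectra(remove_recurrent(sim$variants),
                                      tumor_ids = unique(sim$variants$tumor_id)),
                        cfg$catalog)
  eff <- estimate_effect_sizes(sim$variants, fit, cfg$catalog, cfg$gene_rates,
                               sim$composition)
  est <- eff$estimates
  # every estimated variant is recurrent and satisfies the slice identities
  expect_true(all(est$M >= 2))
  expect_true(all(est$Z >= est$M))
  expect_true(all(est$gamma_hat >= 0))
  expect_true(all(vapply(est$carriers, length, integer(1)) == est$M))
  # the planted driver is present and carries a positive estimate
  key <- sim$truth$drivers$variant_key[1]
  if (key %in% est$variant_key) {
    expect_gt(est$gamma_hat[est$variant_key == key], 0)
  }
})
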