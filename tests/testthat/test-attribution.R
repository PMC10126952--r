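test_that("signature_posterior follows the weight-times-emission rule", {
  catS <- synthetic_signature_catalog()
  w <- stats::setNames(numeric(6), catS$names); w[2] <- 1
  post <- signature_posterior(w, catS, 30L)
  expect_equal(unname(post[2]), 1)
  expect_equal(sum(post), 1)

  # hand arithmetic: numerators (0.8*0.1, 0.2*0.4) = (0.08, 0.08)
  S <- matrix(0, 96, 2, dimnames = list(sbs96_channels(), c("P", "Q")))
  S[5, ] <- c(0.1, 0.4); S[6, ] <- 1 - S[5, ]
  cat2 <- signature_catalog(S)
  post2 <- signature_posterior(c(P = 0.8, Q = 0.2), cat2, 5L)
  expect_equal(unname(post2), c(0.5, 0.5))

  # posteriors sum to 1 for random weights and channels
  set.seed(4)
  for (i in 1:20) {
    w <- stats::runif(6); w <- w / sum(w); names(w) <- catS$names
    expect_equal(sum(signature_posterior(w, catS, sample(96, 1))), 1,
                 tolerance = 1e-12)
  }

  # a channel emitted by no active signature is an error
  S0 <- matrix(0, 96, 2, dimnames = list(sbs96_channels(), c("P", "Q")))
  S0[1, 1] <- 1; S0[2, 2] <- 1
  cat0 <- signature_catalog(S0)
  expect_error(signature_posterior(c(P = 1, Q = 0), cat0, 2L), "no active")
})

# a minimal effect_fit + signature_fit pair built by hand
attribution_fixture <- function(gammas = c(30, 10), w = c(SIG_A = 1, SIG_B = 0)) {
  cat2 <- toy_catalog()
  est <- tibble::tibble(
    gene = "G1", chrom = "chr1", pos = c(5L, 9L), ref = "C", alt = "T",
    variant_key = c("chr1:5:C>T", "chr1:9:C>T"), channel = c(1L, 2L),
    M = 1L, Z = 5L, gamma_hat = gammas, unbounded = FALSE, loglik = -1,
    carriers = list("T1", "T1"))
  eff <- structure(list(estimates = est, rates = tibble::tibble(),
                        min_carriers = 2L), class = "effect_fit")
  weights <- tibble::tibble(tumor_id = "T1", SIG_A = w[["SIG_A"]],
                            SIG_B = w[["SIG_B"]], sse = 0,
                            n_mutations_fit = 10L)
  fit <- structure(list(weights = weights, catalog = cat2,
                        dropped = tibble::tibble()), class = "signature_fit")
  list(eff = eff, fit = fit, cat = cat2)
}

test_that("attributed effects renormalize to per-tumor proportions", {
  fx <- attribution_fixture()
  rec <- attribute_effects(fx$eff, fx$fit, fx$cat)
  # single active signature: proportions are 30/40 and 10/40
  a <- rec[rec$signature == "SIG_A", ]
  expect_equal(sort(a$proportionate_effect), c(0.25, 0.75))
  expect_equal(sum(rec$proportionate_effect), 1)
  # posterior rows per (tumor, variant) sum to 1
  sums <- rec |>
    dplyr::group_by(variant_key) |>
    dplyr::summarise(s = sum(posterior))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("zero-weight signatures receive exactly zero attribution", {
  fx <- attribution_fixture()
  rec <- attribute_effects(fx$eff, fx$fit, fx$cat)
  expect_true(all(rec$attributed_effect[rec$signature == "SIG_B"] == 0))
})

test_that("double conservation holds to 1e-9 on simulated cohorts", {
  cfg <- simulation_config(n_tumors = 25, seed = 57)
  sim <- simulate_cohort(cfg)
  fit <- fit_signatures(build_spectra(remove_recurrent(sim$variants),
                                      tumor_ids = unique(sim$variants$tumor_id)),
                        cfg$catalog)
  eff <- estimate_effect_sizes(sim$variants, fit, cfg$catalog, cfg$gene_rates,
                               sim$composition)
  rec <- attribute_effects(eff, fit, cfg$catalog)
  post_sums <- rec |>
    dplyr::group_by(tumor_id, variant_key) |>
    dplyr::summarise(s = sum(posterior), .groups = "drop")
  expect_true(all(abs(post_sums$s - 1) < 1e-9))
  prop_sums <- rec |>
    dplyr::group_by(tumor_id) |>
    dplyr::summarise(s = sum(proportionate_effect), .groups = "drop")
  expect_true(all(abs(prop_sums$s - 1) < 1e-9))
})

test_that("merging identical catalog columns preserves total attributed effect", {
  # SIG_B duplicated: attribution splits between the twins but their sum
  # equals the single-column attribution
  base <- toy_catalog()
  S3 <- cbind(base$S, SIG_B2 = base$S[, "SIG_B"])
  cat3 <- signature_catalog(sweep(S3, 2, colSums(S3), "/"))
  est <- tibble::tibble(
    gene = "G1", chrom = "chr1", pos = 5L, ref = "C", alt = "T",
    variant_key = "chr1:5:C>T", channel = 42L, M = 1L, Z = 4L,
    gamma_hat = 12, unbounded = FALSE, loglik = -1, carriers = list("T1"))
  eff <- structure(list(estimates = est, rates = tibble::tibble(),
                        min_carriers = 2L), class = "effect_fit")
  w2 <- tibble::tibble(tumor_id = "T1", SIG_A = 0.4, SIG_B = 0.6,
                       sse = 0, n_mutations_fit = 5L)
  w3 <- tibble::tibble(tumor_id = "T1", SIG_A = 0.4, SIG_B = 0.3,
                       SIG_B2 = 0.3, sse = 0, n_mutations_fit = 5L)
  fit2 <- structure(list(weights = w2, catalog = base,
                         dropped = tibble::tibble()), class = "signature_fit")
  fit3 <- structure(list(weights = w3, catalog = cat3,
                         dropped = tibble::tibble()), class = "signature_fit")
  rec2 <- attribute_effects(eff, fit2, base)
  rec3 <- attribute_effects(eff, fit3, cat3)
  total_b2 <- sum(rec2$attributed_effect[rec2$signature == "SIG_B"])
  total_b3 <- sum(rec3$attributed_effect[rec3$signature %in% c("SIG_B", "SIG_B2")])
  expect_equal(total_b3, total_b2, tolerance = 1e-12)
  expect_equal(sum(rec3$attributed_effect), sum(rec2$attributed_effect),
               tolerance = 1e-12)
})

test_that("mean relative attributable effect averages per-tumor shares", {
  rec <- tibble::tibble(
    tumor_id = c("T1", "T2"), gene = "G", variant_key = "k",
    signature = c("S1", "S2"), posterior = 1,
    attributed_effect = c(5, 9), proportionate_effect = 1)
  m <- mean_relative_attributable_effect(rec)
  expect_equal(m$mean_relative_effect, c(0.5, 0.5))
  # single tumor, single signature
  m1 <- mean_relative_attributable_effect(rec[1, ], signatures = c("S1", "S2"))
  expect_equal(m1$mean_relative_effect[m1$signature == "S1"], 1)
  expect_equal(m1$mean_relative_effect[m1$signature == "S2"], 0)
})

test_that("variant_signature_table aggregates per-tumor effects", {
  rec <- tibble::tibble(
    tumor_id = c("T1", "T2", "T3", "T1"), gene = "G",
    variant_key = c("k1", "k1", "k1", "k2"),
    signature = "S1", posterior = 1,
    attributed_effect = c(4, 4, 4, 1),
    proportionate_effect = c(0.8, 1, 1, 0.2))
  tab <- variant_signature_table(rec)
  expect_equal(tab$n_tumors[tab$variant_key == "k1"], 3)
  expect_length(tab$effects[tab$variant_key == "k1"][[1]], 3)
  # sorted by descending median proportionate effect
  expect_equal(tab$variant_key, c("k1", "k2"))
})

test_that("unbounded estimates are excluded from attribution with a warning", {
  fx <- attribution_fixture()
  fx$eff$estimates$unbounded[1] <- TRUE
  expect_warning(rec <- attribute_effects(fx$eff, fx$fit, fx$cat),
                 "unbounded")
  expect_false("chr1:5:C>T" %in% rec$variant_key)
  expect_equal(sum(rec$proportionate_effect), 1)
})
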