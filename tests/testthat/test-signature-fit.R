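test_that("remove_recurrent drops variants shared by two or more tumors", {
  shared <- dplyr::bind_rows(make_variant(tumor_id = "T1", pos = 5L),
                             make_variant(tumor_id = "T2", pos = 5L))
  unique_v <- make_variant(tumor_id = "T3", pos = 9L)
  out <- remove_recurrent(dplyr::bind_rows(shared, unique_v))
  expect_equal(out$pos, 9L)

  # all unique: unchanged
  v <- dplyr::bind_rows(make_variant(pos = 1L), make_variant(pos = 2L))
  expect_equal(remove_recurrent(v), v)

  # same position, different alt alleles: different variants, both kept
  diff_alt <- dplyr::bind_rows(
    make_variant(tumor_id = "T1", pos = 5L, alt = "T"),
    make_variant(tumor_id = "T2", pos = 5L, alt = "G"))
  expect_equal(nrow(remove_recurrent(diff_alt)), 2)

  # same substitution twice in ONE tumor is not recurrent across tumors
  same_tumor <- dplyr::bind_rows(make_variant(pos = 5L), make_variant(pos = 5L))
  expect_equal(nrow(remove_recurrent(same_tumor)), 2)
})

test_that("build_spectrum counts channels and conserves totals", {
  v <- dplyr::bind_rows(
    make_variant(pos = 1L, channel = 10L),
    make_variant(pos = 2L, channel = 10L),
    make_variant(pos = 3L, channel = 45L))
  counts <- build_spectrum(v, "T1")
  expect_equal(unname(counts[10]), 2)
  expect_equal(unname(counts[45]), 1)
  expect_equal(sum(counts), 3)

  # zero-variant tumor named in the universe gets an all-zero row
  sp <- build_spectra(v, tumor_ids = c("T1", "T9"))
  expect_equal(sp$total, c(3L, 0L))
  # absent tumor is an error in the strict single-tumor form
  expect_error(build_spectrum(v, "T9"), "T9")
  # conservation across tumors
  expect_equal(sum(sp$total), sum(v$is_snv & !is.na(v$channel)))
})

test_that("noise-free two-signature mixtures are recovered near-exactly", {
  cat2 <- toy_catalog()
  mix <- 0.7 * cat2$S[, 1] + 0.3 * cat2$S[, 2]
  sp <- spectra_from_matrix(matrix(mix * 1e6, nrow = 1,
                                   dimnames = list("T1", NULL)))
  fit <- fit_signatures(sp, cat2)
  w <- weights_matrix(fit)["T1", ]
  expect_equal(unname(w["SIG_A"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(w["SIG_B"]), 0.3, tolerance = 1e-6)
  expect_lt(fit$weights$sse, 1e-12)
})

test_that("a single-signature catalog yields weight 1", {
  S <- matrix(synthetic_signature_catalog()$S[, 1], ncol = 1,
              dimnames = list(sbs96_channels(), "ONLY"))
  cat1 <- signature_catalog(S)
  sp <- spectra_from_matrix(matrix(S[, 1] * 5000, nrow = 1))
  fit <- fit_signatures(sp, cat1)
  expect_equal(unname(weights_matrix(fit)[1, "ONLY"]), 1)
})

test_that("weights below min_weight are zeroed before renormalization", {
  cat2 <- toy_catalog()
  mix <- 0.97 * cat2$S[, 1] + 0.03 * cat2$S[, 2]
  sp <- spectra_from_matrix(matrix(mix * 1e6, nrow = 1))
  fit <- fit_signatures(sp, cat2, min_weight = 0.06)
  w <- weights_matrix(fit)[1, ]
  expect_equal(unname(w["SIG_B"]), 0)
  expect_equal(unname(w["SIG_A"]), 1)
})

test_that("normalize_weights removes artifacts and renormalizes", {
  S <- synthetic_signature_catalog()$S[, 1:3]
  colnames(S) <- c("S1", "S2", "S3")
  cat3 <- signature_catalog(sweep(S, 2, colSums(S), "/"), artifacts = "S3")
  out <- normalize_weights(c(S1 = 0.5, S2 = 0.3, S3 = 0.2), cat3)
  expect_equal(unname(out), c(0.625, 0.375, 0))
  # no artifacts, already normalized: unchanged
  cat_na <- signature_catalog(sweep(S, 2, colSums(S), "/"))
  expect_equal(unname(normalize_weights(c(S1 = 0.6, S2 = 0.4, S3 = 0), cat_na)),
               c(0.6, 0.4, 0))
  # all weight on an artifact: unfittable
  expect_error(normalize_weights(c(S1 = 0, S2 = 0, S3 = 0.4), cat3),
               "unfittable")
})

test_that("SSE is non-increasing across forward-selection steps", {
  catS <- synthetic_signature_catalog()
  set.seed(3)
  for (i in 1:5) {
    t_norm <- stats::runif(96); t_norm <- t_norm / sum(t_norm)
    trace <- sigfx:::fit_weights_one(t_norm, catS$S)$sse_trace
    expect_true(all(diff(trace) <= 0))
  }
})

test_that("fitted weights are invariant to permuting catalog columns", {
  catS <- synthetic_signature_catalog()
  set.seed(5)
  mix <- catS$S %*% c(0.5, 0.2, 0, 0.3, 0, 0)
  sp <- spectra_from_matrix(matrix(mix * 1e5, nrow = 1))
  fit1 <- fit_signatures(sp, catS)
  perm <- sample(ncol(catS$S))
  catP <- signature_catalog(catS$S[, perm], artifacts = catS$artifacts)
  fit2 <- fit_signatures(sp, catP)
  w1 <- weights_matrix(fit1)[1, ]
  w2 <- weights_matrix(fit2)[1, names(w1)]
  expect_equal(w1, w2, tolerance = 1e-8)
})

test_that("noise-free mixtures of up to 3 signatures are recovered within 1e-4", {
  catS <- synthetic_signature_catalog()
  nonartifact <- setdiff(catS$names, catS$artifacts)
  set.seed(9)
  for (i in 1:10) {
    k <- sample(1:3, 1)
    sigs <- sample(nonartifact, k)
    w_true <- stats::setNames(numeric(length(catS$names)), catS$names)
    raw <- stats::runif(k, 0.2, 1)
    w_true[sigs] <- raw / sum(raw)
    if (any(w_true[sigs] < 0.06)) next  # below the reporting floor by design
    mix <- catS$S %*% w_true
    sp <- spectra_from_matrix(matrix(mix * 1e6, nrow = 1))
    fit <- fit_signatures(sp, catS)
    w_hat <- weights_matrix(fit)[1, names(w_true)]
    expect_lt(max(abs(w_hat - w_true)), 1e-4)
  }
})

test_that("normalized weights sum to 1 for every fitted tumor", {
  cfg <- simulation_config(n_tumors = 8, seed = 21)
  sim <- simulate_cohort(cfg)
  fit <- fit_signatures(build_spectra(sim$variants), cfg$catalog)
  sums <- rowSums(weights_matrix(fit))
  expect_true(all(abs(sums - 1) < 1e-9))
  # artifact signature is exactly zero after normalization
  expect_true(all(weights_matrix(fit)[, "SYN_ARTIFACT"] == 0))
})

test_that("mean_signature_weights averages and ranks with name tie-break", {
  w <- tibble::tibble(
    tumor_id = c("T1", "T1", "T2", "T2"),
    signature = c("B_SIG", "A_SIG", "B_SIG", "A_SIG"),
    weight = c(1, 0, 0, 1))
  m <- mean_signature_weights(w)
  expect_equal(m$mean_weight, c(0.5, 0.5))
  expect_equal(m$signature, c("A_SIG", "B_SIG"))
  # single tumor: means equal its weights
  single <- w[w$tumor_id == "T1", ]
  expect_equal(mean_signature_weights(single)$mean_weight, c(1, 0))
})

test_that("zero-mutation tumors are dropped with a warning", {
  sp <- spectra_from_matrix(matrix(0, nrow = 1, ncol = 96,
                                   dimnames = list("T0", NULL)))
  expect_warning(fit <- fit_signatures(sp, toy_catalog()), "could not be fit")
  expect_equal(nrow(fit$weights), 0)
  expect_equal(fit$dropped$tumor_id, "T0")
})
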