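test_that("each filter rule fires on a hand-built violating record", {
  cfg <- filter_config()
  cases <- list(
    gnomad_af = make_variant(gnomad_max_subpop_af = 0.001),
    tumor_vaf = make_variant(t_alt_count = 3L, t_ref_count = 97L),
    normal_vaf = make_variant(n_alt_count = 10L, n_ref_count = 90L),
    tumor_alt_reads = make_variant(t_alt_count = 4L, t_ref_count = 16L),
    normal_alt_reads = make_variant(n_alt_count = 5L, n_ref_count = 995L),
    offtarget = make_variant(variant_classification = "Intron"),
    blacklist_gene = make_variant(gene = "MUC4"))
  for (rule in names(cases)) {
    res <- apply_filters(cases[[rule]], cfg)
    expect_equal(nrow(res$variants), 0)
    expect_equal(res$report$n_removed[res$report$rule == rule], 1,
                 info = rule)
  }
  # panel of normals keys on chrom:pos:ref>alt
  pon <- make_variant(pos = 99L)
  res <- apply_filters(pon, filter_config(panel_of_normals = variant_key(pon)))
  expect_equal(res$report$n_removed[res$report$rule == "panel_of_normals"], 1)
})

test_that("thresholds use the literal operator directions", {
  cfg <- filter_config()
  # exactly at the boundary: gnomAD 0.04% not removed (strictly over)
  at_gnomad <- make_variant(gnomad_max_subpop_af = 0.0004)
  expect_equal(nrow(apply_filters(at_gnomad, cfg)$variants), 1)
  # tumor VAF exactly 5% kept (strictly below removes)
  at_vaf <- make_variant(t_alt_count = 5L, t_ref_count = 95L)
  expect_equal(nrow(apply_filters(at_vaf, cfg)$variants), 1)
  # normal VAF exactly 5% removed (at or above)
  nv <- make_variant(n_alt_count = 5L, n_ref_count = 95L)
  expect_equal(nrow(apply_filters(nv, cfg)$variants), 0)
  # normal ALT exactly 5 removed, 4 kept
  expect_equal(nrow(apply_filters(
    make_variant(n_alt_count = 5L, n_ref_count = 995L), cfg)$variants), 0)
  expect_equal(nrow(apply_filters(
    make_variant(n_alt_count = 4L, n_ref_count = 996L), cfg)$variants), 1)
})

test_that("a clean variant passes all rules", {
  v <- make_variant(t_alt_count = 20L, t_ref_count = 80L,
                    n_alt_count = 0L, n_ref_count = 100L,
                    gnomad_max_subpop_af = 0, gene = "TP53")
  res <- apply_filters(v)
  expect_equal(nrow(res$variants), 1)
  expect_true(all(res$report$n_removed == 0))
})

test_that("a variant failing several rules is counted once, under the first", {
  v <- make_variant(gnomad_max_subpop_af = 0.01,
                    t_alt_count = 1L, t_ref_count = 99L, gene = "MUC4")
  res <- apply_filters(v)
  expect_equal(res$report$n_removed[res$report$rule == "gnomad_af"], 1)
  expect_equal(sum(res$report$n_removed), 1)
})

test_that("missing annotations skip the rule, not the variant", {
  v <- make_variant(gnomad_max_subpop_af = NA_real_,
                    t_alt_count = NA_integer_, t_ref_count = NA_integer_,
                    n_alt_count = NA_integer_, n_ref_count = NA_integer_)
  res <- apply_filters(v)
  expect_equal(nrow(res$variants), 1)
})

test_that("filter accounting is exact and filtering is idempotent on random cohorts", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 80
    v <- make_variant(
      tumor_id = sample(paste0("T", 1:6), n, replace = TRUE),
      pos = sample.int(5000, n),
      gene = sample(c("TP53", "MUC4", "KEAP1", "PDE4DIP"), n, replace = TRUE),
      variant_classification = sample(c("Missense_Mutation", "Intron", "IGR"),
                                      n, replace = TRUE),
      t_alt_count = sample(0:40, n, replace = TRUE),
      t_ref_count = sample(30:100, n, replace = TRUE),
      n_alt_count = sample(0:8, n, replace = TRUE),
      n_ref_count = 100L,
      gnomad_max_subpop_af = sample(c(0, 0.0002, 0.002, NA), n, replace = TRUE))
    res <- apply_filters(v)
    expect_equal(nrow(res$variants) + sum(res$report$n_removed), n)
    res2 <- apply_filters(res$variants)
    expect_equal(res2$variants, res$variants)
    expect_true(all(res2$report$n_removed == 0))
  }
})

test_that("Fisher filter drops non-significant non-COSMIC variants only", {
  # identical tumor and normal tables: P = 1
  expect_false(fisher_af_filter(5L, 95L, 5L, 95L, in_cosmic = FALSE))
  expect_true(fisher_af_filter(5L, 95L, 5L, 95L, in_cosmic = TRUE))
  # strongly different allele fractions: kept
  expect_true(fisher_af_filter(30L, 70L, 0L, 100L, in_cosmic = FALSE))
  # zero reads in one sample: kept with a warning
  expect_warning(keep <- fisher_af_filter(0L, 0L, 5L, 95L, in_cosmic = FALSE),
                 "zero reads")
  expect_true(keep)
})

test_that("Fisher P-values match brute-force hypergeometric enumeration", {
  set.seed(11)
  for (i in 1:200) {
    total <- sample(4:50, 1)
    a <- sample(0:total, 1); rest <- total - a
    b <- sample(0:rest, 1); rest <- rest - b
    c <- sample(0:rest, 1); d <- rest - c
    if (a + b == 0 || c + d == 0) next
    p_pkg <- fisher_af_test(a, b, c, d)
    expect_equal(p_pkg, fisher_oracle(a, b, c, d), tolerance = 1e-10,
                 info = paste(a, b, c, d))
  }
})

test_that("enabling the Fisher rule folds it into the report accounting", {
  v <- dplyr::bind_rows(
    make_variant(pos = 1L, t_alt_count = 5L, t_ref_count = 95L,
                 n_alt_count = 5L, n_ref_count = 95L),
    make_variant(pos = 2L, t_alt_count = 30L, t_ref_count = 70L,
                 n_alt_count = 0L, n_ref_count = 100L))
  res <- apply_filters(v, filter_config(fisher_enabled = TRUE,
                                        max_normal_vaf = 0.5,
                                        max_normal_alt = 10L))
  expect_equal(res$report$n_removed[res$report$rule == "fisher_af"], 1)
  expect_equal(nrow(res$variants) + sum(res$report$n_removed), 2)
})
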