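#' Split the cohort into carriers and eligible non-carriers for a variant
#'
#' Carriers are tumors bearing the exact variant. Eligible non-carriers are
#' tumors with no variant anywhere in the same gene: tumors carrying a
#' *different* variant of that gene are excluded from both groups, because
#' selection on subsequent same-gene mutations is likely reduced once one is
#' present. A tumor carrying the focal variant and another same-gene variant
#' is still a carrier.
#'
#' @param variants Canonical variant tibble (gene-annotated).
#' @param key Focal variant key (`"chrom:pos:ref>alt"`, see
#'   [variant_key()]).
#' @param tumor_ids Tumor universe; defaults to tumors present in
#'   `variants`. Tumors with no variants at all are eligible non-carriers.
#' @return List with `key`, `gene`, `carriers`, `noncarriers` (character
#'   vectors of tumor ids), `M`, `Z`.
#' @export
slice_cohort <- function(variants, key, tumor_ids = NULL) {
  if (is.null(tumor_ids)) tumor_ids <- sort(unique(variants$tumor_id))
  keys <- variant_key(variants)
  hit <- keys == key
  gene <- unique(variants$gene[hit])
  if (!length(gene)) {
    # variant absent from the table: gene unknown, all tumors non-carriers
    gene <- NA_character_
  }
  if (length(gene) > 1L) {
    stop(sprintf("variant %s maps to several genes: %s", key,
                 paste(gene, collapse = ", ")), call. = FALSE)
  }
  carriers <- sort(unique(variants$tumor_id[hit]))
  same_gene <- if (is.na(gene)) character() else
    unique(variants$tumor_id[!is.na(variants$gene) & variants$gene == gene])
  noncarriers <- sort(setdiff(tumor_ids, same_gene))
  list(key = key, gene = gene, carriers = carriers, noncarriers = noncarriers,
       M = length(carriers), Z = length(carriers) + length(noncarriers))
}

#' Log-likelihood of a cancer effect size
#'
#' Under the fixation model, a tumor with mutation rate `mu_i` to the
#' variant carries it with probability `1 - exp(-mu_i * gamma)`, so
#' `logL(gamma) = sum_carriers log(1 - exp(-mu_i gamma))
#'              - gamma * sum_noncarriers mu_i`.
#' At `gamma = 0` with at least one carrier the log-likelihood is `-Inf`.
#'
#' @param gamma Non-negative effect size (vectorized).
#' @param mu_carriers,mu_noncarriers Positive per-tumor mutation rates for
#'   the carrier and eligible non-carrier tumors.
#' @return Log-likelihood value(s).
#' @export
loglik_gamma <- function(gamma, mu_carriers, mu_noncarriers) {
  stopifnot(all(gamma >= 0), all(mu_carriers > 0), all(mu_noncarriers > 0) ||
              length(mu_noncarriers) == 0L)
  s_non <- sum(mu_noncarriers)
  vapply(gamma, function(g) {
    if (g == 0 && length(mu_carriers)) return(-Inf)
    # log(1 - exp(-x)) computed stably via expm1
    sum(log(-expm1(-mu_carriers * g))) - g * s_non
  }, numeric(1))
}

score_gamma <- function(gamma, mu_carriers, mu_noncarriers) {
  # d logL / d gamma; strictly decreasing in gamma (logL is concave)
  x <- mu_carriers * gamma
  sum(mu_carriers * exp(-x) / (-expm1(-x))) - sum(mu_noncarriers)
}

#' Maximum-likelihood cancer effect size for one variant
#'
#' Maximizes [loglik_gamma()] over `gamma >= 0`. For `0 < M < Z` the
#' log-likelihood is strictly concave with a unique interior maximum, found
#' as the root of the score function (bracketed and solved to relative
#' tolerance `tol`). With no carriers the maximizer is `gamma = 0`; when
#' every eligible tumor is a carrier (`M = Z`) the likelihood increases
#' monotonically and the estimate is capped at `gamma_max` and flagged
#' `unbounded`. When all rates are equal to `mu` the estimator has the
#' closed form `-log(1 - M/Z) / mu`.
#'
#' @param mu_carriers,mu_noncarriers Positive per-tumor rates (lengths `M`
#'   and `Z - M`).
#' @param gamma_max Cap used when no finite maximizer exists (default
#'   1e12).
#' @param tol Relative tolerance of the estimate (default 1e-8).
#' @return One-row tibble: `gamma_hat`, `loglik`, `unbounded`, `M`, `Z`.
#' @export
mle_gamma <- function(mu_carriers, mu_noncarriers, gamma_max = 1e12,
                      tol = 1e-8) {
  M <- length(mu_carriers)
  Z <- M + length(mu_noncarriers)
  if (Z == 0L) stop("empty cohort slice (Z = 0)", call. = FALSE)
  if (M == 0L) {
    return(tibble::tibble(gamma_hat = 0, loglik = 0, unbounded = FALSE,
                          M = M, Z = Z))
  }
  if (M == Z) {
    return(tibble::tibble(gamma_hat = gamma_max,
                          loglik = loglik_gamma(gamma_max, mu_carriers,
                                                mu_noncarriers),
                          unbounded = TRUE, M = M, Z = Z))
  }
  # center the bracket on the homogeneous-rate closed form
  mu_bar <- mean(c(mu_carriers, mu_noncarriers))
  gamma0 <- -log(1 - M / Z) / mu_bar
  lo <- gamma0 * 1e-9
  hi <- min(gamma0 * 1e9, gamma_max)
  # widen until the score changes sign (it is strictly decreasing)
  while (score_gamma(lo, mu_carriers, mu_noncarriers) <= 0 && lo > gamma0 * 1e-30) {
    lo <- lo / 1e3
  }
  while (score_gamma(hi, mu_carriers, mu_noncarriers) >= 0 && hi < gamma_max) {
    hi <- min(hi * 1e3, gamma_max)
  }
  if (score_gamma(hi, mu_carriers, mu_noncarriers) >= 0) {
    return(tibble::tibble(gamma_hat = gamma_max,
                          loglik = loglik_gamma(gamma_max, mu_carriers,
                                                mu_noncarriers),
                          unbounded = TRUE, M = M, Z = Z))
  }
  root <- stats::uniroot(score_gamma, interval = c(lo, hi),
                         mu_carriers = mu_carriers,
                         mu_noncarriers = mu_noncarriers,
                         tol = tol * gamma0, maxiter = 2000L)
  gamma_hat <- root$root
  tibble::tibble(gamma_hat = gamma_hat,
                 loglik = loglik_gamma(gamma_hat, mu_carriers, mu_noncarriers),
                 unbounded = FALSE, M = M, Z = Z)
}

#' Profile-likelihood confidence interval for an effect size
#'
#' Inverts the likelihood-ratio statistic: the interval contains every
#' `gamma` whose log-likelihood is within `qchisq(level, 1) / 2` of the
#' maximum. Off the default reporting path (estimates are reported as
#' points); provided as a hook for users who want uncertainty.
#'
#' @inheritParams mle_gamma
#' @param level Coverage level (default 0.95).
#' @return One-row tibble: `gamma_hat`, `lower`, `upper`, `level`. The
#'   upper bound is `Inf` when every eligible tumor is a carrier.
#' @export
profile_gamma_ci <- function(mu_carriers, mu_noncarriers, level = 0.95,
                             gamma_max = 1e12, tol = 1e-8) {
  est <- mle_gamma(mu_carriers, mu_noncarriers, gamma_max = gamma_max,
                   tol = tol)
  drop <- stats::qchisq(level, df = 1) / 2
  if (est$M == 0L) {
    # maximum at the boundary gamma = 0: one-sided interval
    f <- function(g) loglik_gamma(g, mu_carriers, mu_noncarriers) -
      (est$loglik - drop)
    hi <- 1 / sum(mu_noncarriers)
    while (f(hi) > 0) hi <- hi * 2
    return(tibble::tibble(gamma_hat = 0, lower = 0,
                          upper = stats::uniroot(f, c(0, hi), tol = tol * hi)$root,
                          level = level))
  }
  target <- est$loglik - drop
  f <- function(g) loglik_gamma(g, mu_carriers, mu_noncarriers) - target
  lo_bracket <- est$gamma_hat * 1e-12
  lower <- stats::uniroot(f, c(lo_bracket, est$gamma_hat),
                          tol = tol * est$gamma_hat)$root
  upper <- if (est$unbounded || est$M == est$Z) Inf else {
    hi <- est$gamma_hat * 2
    while (f(hi) > 0 && hi < gamma_max) hi <- hi * 2
    if (f(hi) > 0) Inf else
      stats::uniroot(f, c(est$gamma_hat, hi), tol = tol * est$gamma_hat)$root
  }
  tibble::tibble(gamma_hat = est$gamma_hat, lower = lower, upper = upper,
                 level = level)
}

#' Estimate cancer effect sizes for recurrent variants
#'
#' For every variant carried by at least `min_carriers` distinct tumors:
#' slice the cohort into carriers and eligible non-carriers
#' ([slice_cohort()]), compute each tumor's mutation rate to the variant
#' from its signature weights and the gene's baseline rate
#' ([variant_rates()]), and maximize the fixation likelihood
#' ([mle_gamma()]). Tumors without fitted weights are left out of both
#' groups.
#'
#' @param variants Canonical, context-annotated variant tibble (the full
#'   filtered cohort, *including* recurrent variants).
#' @param fit A `signature_fit`, or a weights tibble as written by
#'   [write_weights()].
#' @param catalog A [signature_catalog()].
#' @param gene_rates Gene-rate tibble (see [read_gene_rates()]).
#' @param composition Gene composition tibble
#'   ([gene_context_composition()]).
#' @param tumor_ids Tumor universe; defaults to fitted tumors.
#' @param min_carriers Recurrence threshold: variants in fewer distinct
#'   tumors get no estimate (default 2).
#' @param gamma_max,tol Passed to [mle_gamma()].
#' @return Object of class `effect_fit`: `$estimates` (tibble `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_key`, `channel`, `M`, `Z`,
#'   `gamma_hat`, `unbounded`, `loglik`, list-column `carriers`), plus
#'   `$rates` (the per-tumor `mu` table used).
#' @seealso [tidy.effect_fit()], [attribute_effects()]
#' @export
estimate_effect_sizes <- function(variants, fit, catalog, gene_rates,
                                  composition, tumor_ids = NULL,
                                  min_carriers = 2L, gamma_max = 1e12,
                                  tol = 1e-8) {
  fitted_tumors <- if (inherits(fit, "signature_fit")) fit$weights$tumor_id
    else fit$tumor_id
  if (is.null(tumor_ids)) tumor_ids <- fitted_tumors
  tumor_ids <- intersect(tumor_ids, fitted_tumors)

  snv <- variants[variants$is_snv & !is.na(variants$channel) &
                    variants$tumor_id %in% tumor_ids, , drop = FALSE]
  keys <- variant_key(snv)
  carriers_per_key <- tapply(snv$tumor_id, keys,
                             function(x) length(unique(x)))
  focal_keys <- names(carriers_per_key)[carriers_per_key >= min_carriers]
  if (!length(focal_keys)) {
    return(structure(list(estimates = tibble::tibble(), rates = tibble::tibble(),
                          min_carriers = min_carriers),
                     class = "effect_fit"))
  }
  focal <- snv[match(focal_keys, keys), , drop = FALSE]
  rates <- variant_rates(focal, fit, catalog, gene_rates, composition)

  rows <- lapply(seq_len(nrow(focal)), function(i) {
    key <- focal_keys[i]
    sl <- slice_cohort(snv, key, tumor_ids = tumor_ids)
    mu <- rates[rates$variant_key == key, , drop = FALSE]
    mu_lookup <- stats::setNames(mu$mu, mu$tumor_id)
    est <- mle_gamma(mu_lookup[sl$carriers],
                     mu_lookup[sl$noncarriers],
                     gamma_max = gamma_max, tol = tol)
    tibble::tibble(gene = focal$gene[i], chrom = focal$chrom[i],
                   pos = focal$pos[i], ref = focal$ref[i], alt = focal$alt[i],
                   variant_key = key, channel = focal$channel[i],
                   M = est$M, Z = est$Z, gamma_hat = est$gamma_hat,
                   unbounded = est$unbounded, loglik = est$loglik,
                   carriers = list(sl$carriers))
  })
  estimates <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$gamma_hat))
  structure(list(estimates = estimates, rates = rates,
                 min_carriers = min_carriers),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("<effect_fit> %d recurrent variant(s) (>= %d carriers)\n",
              nrow(x$estimates), x$min_carriers))
  if (nrow(x$estimates)) {
    show <- utils::head(x$estimates[, c("gene", "variant_key", "M", "Z",
                                        "gamma_hat", "unbounded")], 10L)
    print(show)
  }
  invisible(x)
}

#' Write effect estimates as TSV
#' @param fit An `effect_fit`.
#' @param path Output path.
#' @export
write_effects <- function(fit, path) {
  out <- dplyr::select(fit$estimates, -"carriers")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
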