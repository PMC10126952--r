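#' Posterior probability that each signature generated a variant
#'
#' Given a tumor's signature weights and a variant's channel, the
#' probability that signature `s` produced the variant is proportional to
#' the weight times the signature's emission in that channel:
#' `posterior[s] = w[s] S[c, s] / sum_s' w[s'] S[c, s']`.
#'
#' @param w Named weight vector over catalog signatures, summing to 1.
#' @param catalog A [signature_catalog()].
#' @param channel Channel index (1..96).
#' @return Named numeric vector over signatures, summing to 1.
#' @export
signature_posterior <- function(w, catalog, channel) {
  stopifnot(inherits(catalog, "signature_catalog"),
            channel >= 1L, channel <= 96L)
  if (is.null(names(w))) {
    stopifnot(length(w) == length(catalog$names))
    names(w) <- catalog$names
  }
  full <- stats::setNames(numeric(length(catalog$names)), catalog$names)
  full[names(w)] <- w
  num <- full * catalog$S[channel, ]
  denom <- sum(num)
  if (denom <= 0) {
    stop(sprintf("no active signature emits channel %d (%s); posterior undefined",
                 channel, sbs96_channels()[channel]), call. = FALSE)
  }
  num / denom
}

#' Attribute effect sizes to signatures per tumor
#'
#' For every carrier tumor of every estimated variant, the variant's effect
#' size is multiplied by the posterior probability that each signature
#' generated it ([signature_posterior()]), giving the attributed effect.
#' Within each tumor, attributed effects are then renormalized across all
#' of the tumor's (variant, signature) pairs to sum to 1, giving the
#' proportionate attributable effect size.
#'
#' Variants flagged `unbounded` (no finite likelihood maximizer) are
#' excluded with a warning unless `include_unbounded = TRUE`; tumors whose
#' attributed effects are all zero are excluded from the proportional
#' output with a warning.
#'
#' @param effects An `effect_fit` from [estimate_effect_sizes()].
#' @param fit The `signature_fit` used for estimation (or its weights
#'   tibble).
#' @param catalog A [signature_catalog()].
#' @param include_unbounded Keep unbounded estimates at their cap.
#' @return Tibble with `tumor_id`, `gene`, `variant_key`, `signature`,
#'   `posterior`, `attributed_effect`, `proportionate_effect`.
#' @seealso [mean_relative_attributable_effect()],
#'   [variant_signature_table()]
#' @export
attribute_effects <- function(effects, fit, catalog,
                              include_unbounded = FALSE) {
  stopifnot(inherits(effects, "effect_fit"))
  est <- effects$estimates
  if (!nrow(est)) return(tibble::tibble())
  if (!include_unbounded && any(est$unbounded)) {
    warning(sprintf("%d unbounded estimate(s) excluded from attribution",
                    sum(est$unbounded)), call. = FALSE)
    est <- est[!est$unbounded, , drop = FALSE]
  }
  W <- weights_matrix(fit)
  rows <- lapply(seq_len(nrow(est)), function(i) {
    carriers <- est$carriers[[i]]
    if (!length(carriers)) return(NULL)
    recs <- lapply(carriers, function(tid) {
      post <- signature_posterior(W[tid, ], catalog, est$channel[i])
      tibble::tibble(tumor_id = tid, gene = est$gene[i],
                     variant_key = est$variant_key[i],
                     signature = names(post),
                     posterior = as.numeric(post),
                     attributed_effect = est$gamma_hat[i] * as.numeric(post))
    })
    dplyr::bind_rows(recs)
  })
  records <- dplyr::bind_rows(rows)
  if (!nrow(records)) return(records)
  totals <- records |>
    dplyr::group_by(.data$tumor_id) |>
    dplyr::summarise(total = sum(.data$attributed_effect), .groups = "drop")
  zero <- totals$tumor_id[totals$total == 0]
  if (length(zero)) {
    warning(sprintf("%d tumor(s) with zero total attributed effect excluded: %s",
                    length(zero), paste(utils::head(zero, 5L), collapse = ", ")),
            call. = FALSE)
    records <- records[!records$tumor_id %in% zero, , drop = FALSE]
    totals <- totals[!totals$tumor_id %in% zero, , drop = FALSE]
  }
  records |>
    dplyr::left_join(totals, by = "tumor_id") |>
    dplyr::mutate(proportionate_effect = .data$attributed_effect / .data$total) |>
    dplyr::select(-"total")
}

#' Mean relative attributable effect size per signature
#'
#' For each tumor with at least one attributed recurrent variant, sums the
#' proportionate effects over variants per signature (a per-tumor share
#' vector summing to 1), then averages those shares across tumors.
#' Signatures never attributed in a tumor contribute a zero share for that
#' tumor. Sorted descending; ties broken by signature name.
#'
#' @param records Attribution tibble from [attribute_effects()].
#' @param signatures Signature universe; defaults to those appearing in
#'   `records`.
#' @return Tibble with `signature`, `mean_relative_effect`, descending.
#' @export
mean_relative_attributable_effect <- function(records, signatures = NULL) {
  stopifnot(nrow(records) > 0)
  if (is.null(signatures)) signatures <- sort(unique(records$signature))
  per_tumor <- records |>
    dplyr::group_by(.data$tumor_id, .data$signature) |>
    dplyr::summarise(share = sum(.data$proportionate_effect), .groups = "drop") |>
    tidyr::complete(tumor_id = unique(records$tumor_id),
                    signature = signatures,
                    fill = list(share = 0))
  per_tumor |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(mean_relative_effect = mean(.data$share), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_relative_effect), .data$signature)
}

#' Per-variant, per-signature attribution summary
#'
#' Aggregates attribution records by (variant, signature): the number of
#' carrier tumors contributing records, the per-tumor proportionate effects
#' (as a list-column, for plotting), and their median and mean. Sorted by
#' descending median proportionate effect.
#'
#' @param records Attribution tibble from [attribute_effects()].
#' @return Tibble with `gene`, `variant_key`, `signature`, `n_tumors`,
#'   `median_proportionate`, `mean_proportionate`, list-column `effects`.
#' @export
variant_signature_table <- function(records) {
  stopifnot(nrow(records) > 0)
  records |>
    dplyr::group_by(.data$gene, .data$variant_key, .data$signature) |>
    dplyr::summarise(n_tumors = dplyr::n_distinct(.data$tumor_id),
                     median_proportionate = stats::median(.data$proportionate_effect),
                     mean_proportionate = mean(.data$proportionate_effect),
                     effects = list(.data$proportionate_effect),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$median_proportionate), .data$variant_key,
                   .data$signature)
}

#' Write attribution records as TSV
#' @param records Attribution tibble.
#' @param path Output path.
#' @export
write_attribution <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
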