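#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signature fit into long format
#'
#' @param x A `signature_fit` from [fit_signatures()].
#' @param ... Unused.
#' @return Tibble with `tumor_id`, `signature`, `weight` (one row per
#'   tumor-signature pair, weights summing to 1 within tumor).
#' @method tidy signature_fit
#' @export
tidy.signature_fit <- function(x, ...) {
  tidyr::pivot_longer(x$weights,
                      cols = dplyr::all_of(x$catalog$names),
                      names_to = "signature", values_to = "weight") |>
    dplyr::select("tumor_id", "signature", "weight")
}

#' One-row summary of a signature fit
#'
#' @param x A `signature_fit`.
#' @param ... Unused.
#' @return Tibble with `n_tumors`, `n_dropped`, `n_signatures`,
#'   `mean_sse`, `median_mutations`.
#' @method glance signature_fit
#' @export
glance.signature_fit <- function(x, ...) {
  tibble::tibble(n_tumors = nrow(x$weights),
                 n_dropped = nrow(x$dropped),
                 n_signatures = length(x$catalog$names),
                 mean_sse = if (nrow(x$weights)) mean(x$weights$sse) else NA_real_,
                 median_mutations = if (nrow(x$weights))
                   stats::median(x$weights$n_mutations_fit) else NA_real_)
}

#' Tidy effect-size estimates
#'
#' @param x An `effect_fit` from [estimate_effect_sizes()].
#' @param ... Unused.
#' @return The estimates tibble without the carrier list-column.
#' @method tidy effect_fit
#' @export
tidy.effect_fit <- function(x, ...) {
  if (!nrow(x$estimates)) return(x$estimates)
  dplyr::select(x$estimates, -"carriers")
}

#' One-row summary of effect-size estimation
#'
#' @param x An `effect_fit`.
#' @param ... Unused.
#' @return Tibble with `n_variants`, `n_unbounded`, `median_gamma`,
#'   `max_gamma`.
#' @method glance effect_fit
#' @export
glance.effect_fit <- function(x, ...) {
  est <- x$estimates
  bounded <- est$gamma_hat[!est$unbounded]
  tibble::tibble(n_variants = nrow(est),
                 n_unbounded = sum(est$unbounded),
                 median_gamma = if (length(bounded)) stats::median(bounded) else NA_real_,
                 max_gamma = if (length(bounded)) max(bounded) else NA_real_)
}
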