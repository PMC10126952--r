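#' Remove variants recurrently substituted among tumors
#'
#' Variants seen in two or more distinct tumors are under positive selection
#' more often than chance, so their trinucleotide contexts bias the
#' passenger spectrum used for signature deconvolution. This drops every
#' occurrence of any variant (same chromosome, position, ref and alt)
#' carried by at least `min_tumors` distinct tumors. Use the filtered
#' result only for spectrum building and weight fitting; keep the full
#' cohort for effect-size estimation.
#'
#' @param variants Canonical variant tibble.
#' @param min_tumors Recurrence threshold (default 2).
#' @return The tibble without recurrent variants.
#' @export
remove_recurrent <- function(variants, min_tumors = 2L) {
  key <- variant_key(variants)
  carriers <- tapply(variants$tumor_id, key, function(x) length(unique(x)))
  recurrent <- names(carriers)[carriers >= min_tumors]
  variants[!key %in% recurrent, , drop = FALSE]
}

#' Build per-tumor 96-channel mutation spectra
#'
#' Counts each tumor's context-annotated SNVs per SBS-96 channel.
#' `build_spectra()` returns one row per tumor in wide form (one column per
#' channel label); tumors named in `tumor_ids` but absent from the variant
#' table get all-zero rows. `build_spectrum()` is the strict single-tumor
#' form and errors when the tumor has no variants in the table.
#'
#' @param variants Context-annotated variant tibble (see
#'   [annotate_contexts()]); non-SNVs and unannotated variants are ignored.
#' @param tumor_ids Tumor universe; defaults to the tumors present.
#' @return `build_spectra()`: tibble with `tumor_id`, 96 channel count
#'   columns, and `total`. `build_spectrum()`: named integer 96-vector.
#' @export
build_spectra <- function(variants, tumor_ids = NULL) {
  if (is.null(tumor_ids)) tumor_ids <- sort(unique(variants$tumor_id))
  usable <- variants$is_snv & !is.na(variants$channel)
  v <- variants[usable, , drop = FALSE]
  mat <- matrix(0L, nrow = length(tumor_ids), ncol = 96L,
                dimnames = list(tumor_ids, sbs96_channels()))
  if (nrow(v)) {
    tab <- table(factor(v$tumor_id, levels = tumor_ids),
                 factor(v$channel, levels = 1:96))
    mat[] <- as.integer(tab)
  }
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(tumor_id = tumor_ids), out)
  out$total <- as.integer(rowSums(mat))
  out
}

#' @rdname build_spectra
#' @param tumor_id A single tumor identifier.
#' @export
build_spectrum <- function(variants, tumor_id) {
  if (!tumor_id %in% variants$tumor_id) {
    stop(sprintf("tumor '%s' not present in cohort", tumor_id), call. = FALSE)
  }
  sp <- build_spectra(variants, tumor_ids = tumor_id)
  counts <- as.integer(sp[1, sbs96_channels()])
  names(counts) <- sbs96_channels()
  counts
}

spectra_matrix <- function(spectra) {
  mat <- as.matrix(spectra[, sbs96_channels(), drop = FALSE])
  rownames(mat) <- spectra$tumor_id
  mat
}

# Forward-selection NNLS deconvolution of one normalized spectrum.
# Returns weights over all catalog signatures (zeros for unselected),
# the final sum-squared reconstruction error, and the SSE trace.
fit_weights_one <- function(t_norm, S, stop_tol = 1e-3) {
  K <- ncol(S)
  selected <- integer(0)
  w <- stats::setNames(numeric(K), colnames(S))
  sse <- sum(t_norm^2)          # reconstruction error of the empty model
  sse_trace <- sse
  repeat {
    remaining <- setdiff(seq_len(K), selected)
    if (!length(remaining)) break
    best_j <- NA_integer_; best_sse <- Inf; best_x <- NULL
    for (j in remaining) {
      cols <- c(selected, j)
      fit <- pracma::lsqnonneg(S[, cols, drop = FALSE], t_norm)
      rss <- sum((t_norm - S[, cols, drop = FALSE] %*% fit$x)^2)
      if (rss < best_sse) {
        best_sse <- rss; best_j <- j; best_x <- fit$x
      }
    }
    if ((sse - best_sse) / sse < stop_tol) break
    selected <- c(selected, best_j)
    w[] <- 0
    w[selected] <- best_x
    sse <- best_sse
    sse_trace <- c(sse_trace, sse)
  }
  list(w = w, sse = sse, sse_trace = sse_trace)
}

#' Deconvolve per-tumor signature weights by forward selection
#'
#' For each tumor, the spectrum is normalized to channel proportions and
#' approximated as a non-negative mixture of catalog signatures. Signatures
#' enter one at a time: at each step the candidate whose inclusion (with
#' all weights refit by non-negative least squares over the selected set)
#' most reduces the sum-squared reconstruction error is added, until the
#' best relative improvement falls below `stop_tol`. Fitted weights below
#' `min_weight` are zeroed, artifact-signature weights are removed, and the
#' remainder renormalized to sum to 1 ([normalize_weights()]).
#'
#' Tumors with no mutations, and tumors whose weight lands entirely on
#' artifact signatures, cannot be fit; they are dropped from the result
#' with a warning and listed in `$dropped`.
#'
#' @param spectra Wide spectra tibble from [build_spectra()].
#' @param catalog A [signature_catalog()].
#' @param min_weight Weights below this are zeroed before renormalization
#'   (default 0.06, the usual deconvolution reporting floor).
#' @param stop_tol Relative SSE improvement below which selection stops
#'   (default 1e-3).
#' @param context_scaling Optional positive 96-vector by which each
#'   normalized spectrum is multiplied (then renormalized) before fitting,
#'   e.g. to correct for trinucleotide abundance differences between an
#'   exome and the catalog's reference. Default none.
#' @return An object of class `signature_fit`: `$weights` (tibble
#'   `tumor_id`, one column per signature, `sse`, `n_mutations_fit`),
#'   `$catalog`, `$dropped` (tibble `tumor_id`, `reason`).
#' @seealso [tidy.signature_fit()], [mean_signature_weights()],
#'   [autoplot.signature_fit()]
#' @export
fit_signatures <- function(spectra, catalog, min_weight = 0.06,
                           stop_tol = 1e-3, context_scaling = NULL) {
  stopifnot(inherits(catalog, "signature_catalog"))
  mat <- spectra_matrix(spectra)
  totals <- rowSums(mat)
  if (!is.null(context_scaling)) {
    stopifnot(length(context_scaling) == 96L, all(context_scaling > 0))
  }
  rows <- vector("list", nrow(mat))
  dropped <- list()
  for (i in seq_len(nrow(mat))) {
    id <- rownames(mat)[i]
    if (totals[i] == 0) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        tumor_id = id, reason = "no mutations to fit")
      next
    }
    t_norm <- mat[i, ] / totals[i]
    if (!is.null(context_scaling)) {
      t_norm <- t_norm * context_scaling
      t_norm <- t_norm / sum(t_norm)
    }
    fit <- fit_weights_one(t_norm, catalog$S, stop_tol = stop_tol)
    w <- fit$w
    w[w < min_weight] <- 0
    norm <- tryCatch(normalize_weights(w, catalog), error = function(e) NULL)
    if (is.null(norm)) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        tumor_id = id, reason = "all non-artifact weights zero")
      next
    }
    rows[[i]] <- tibble::tibble(tumor_id = id, !!!as.list(norm),
                                sse = fit$sse,
                                n_mutations_fit = as.integer(totals[i]))
  }
  weights <- dplyr::bind_rows(rows)
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(tumor_id = character(), reason = character())
  if (nrow(dropped)) {
    warning(sprintf("%d tumor(s) could not be fit: %s", nrow(dropped),
                    paste(utils::head(dropped$tumor_id, 5L), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(weights = weights, catalog = catalog, dropped = dropped,
                 min_weight = min_weight, stop_tol = stop_tol),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("<signature_fit> %d tumor(s), %d signature(s); mean SSE %.3g\n",
              nrow(x$weights), length(x$catalog$names),
              if (nrow(x$weights)) mean(x$weights$sse) else NA_real_))
  if (nrow(x$dropped)) cat(sprintf("dropped: %d tumor(s)\n", nrow(x$dropped)))
  invisible(x)
}

#' Zero artifact signatures and renormalize weights
#'
#' Sets the weight of every signature flagged as a sequencing artifact to
#' zero and divides the remaining weights by their sum, so they express the
#' proportion of total detected (non-artifact) weight in the tumor.
#'
#' @param w Named non-negative numeric vector over (a subset of) the
#'   catalog's signatures.
#' @param catalog A [signature_catalog()].
#' @return Named numeric vector over all catalog signatures, summing to 1.
#' @export
normalize_weights <- function(w, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  full <- stats::setNames(numeric(length(catalog$names)), catalog$names)
  if (is.null(names(w))) {
    stopifnot(length(w) == length(full))
    names(w) <- catalog$names
  }
  stopifnot(all(names(w) %in% catalog$names), all(w >= 0))
  full[names(w)] <- w
  full[catalog$artifacts] <- 0
  s <- sum(full)
  if (s == 0) stop("all non-artifact weights are zero; tumor unfittable",
                   call. = FALSE)
  full / s
}

#' Mean signature weight across fitted tumors
#'
#' Arithmetic mean of each signature's normalized weight over all fitted
#' tumors, sorted in descending order (ties broken by signature name).
#'
#' @param fit A `signature_fit`, or a tidy long tibble with columns
#'   `tumor_id`, `signature`, `weight`.
#' @return Tibble with `signature`, `mean_weight`, sorted descending.
#' @export
mean_signature_weights <- function(fit) {
  long <- if (inherits(fit, "signature_fit")) tidy(fit) else tibble::as_tibble(fit)
  stopifnot(all(c("signature", "weight") %in% names(long)))
  long |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(mean_weight = mean(.data$weight), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_weight), .data$signature)
}

#' Extract per-tumor weights as a tumors-by-signatures matrix
#' @param fit A `signature_fit` or its `$weights` tibble.
#' @return Numeric matrix, rownames tumor ids, colnames signatures.
#' @export
weights_matrix <- function(fit) {
  if (inherits(fit, "signature_fit")) {
    sigs <- fit$catalog$names
    tbl <- fit$weights
  } else {
    tbl <- tibble::as_tibble(fit)
    sigs <- setdiff(names(tbl), c("tumor_id", "sse", "n_mutations_fit"))
  }
  mat <- as.matrix(tbl[, sigs, drop = FALSE])
  rownames(mat) <- tbl$tumor_id
  mat
}

#' Write fitted weights as TSV
#' @param fit A `signature_fit`.
#' @param path Output path.
#' @export
write_weights <- function(fit, path) {
  readr::write_tsv(fit$weights, path, progress = FALSE)
  invisible(path)
}
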