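#' Construct a mutational-signature catalog
#'
#' A catalog holds the matrix S of 96 channel probabilities per signature
#' (columns), in the row order of [sbs96_channels()], together with the set
#' of signatures flagged as sequencing artifacts. Artifact signatures may be
#' selected during deconvolution but their weights are zeroed and the
#' remainder renormalized before any downstream use.
#'
#' @param S Numeric matrix, 96 rows by K signatures. Columns must be named
#'   and each must sum to 1 (tolerance 1e-6). Rows may be named with channel
#'   labels; if so they are checked (and reordered) against
#'   [sbs96_channels()].
#' @param artifacts Character vector of signature names flagged as
#'   sequencing artifacts. Must be a subset of `colnames(S)`.
#' @return An object of class `signature_catalog` with elements `S`,
#'   `names`, `artifacts`.
#' @export
signature_catalog <- function(S, artifacts = character()) {
  S <- as.matrix(S)
  if (nrow(S) != 96L) stop("S must have 96 rows (one per channel)", call. = FALSE)
  if (is.null(colnames(S))) stop("S must have signature names as colnames", call. = FALSE)
  if (!is.null(rownames(S))) {
    if (!setequal(rownames(S), sbs96_channels())) {
      stop("rownames(S) must be the 96 channel labels", call. = FALSE)
    }
    S <- S[sbs96_channels(), , drop = FALSE]
  } else {
    rownames(S) <- sbs96_channels()
  }
  if (any(S < 0)) stop("signature probabilities must be non-negative", call. = FALSE)
  csums <- colSums(S)
  if (any(abs(csums - 1) > 1e-6)) {
    stop(sprintf("each signature column must sum to 1 (worst deviation %.3g)",
                 max(abs(csums - 1))), call. = FALSE)
  }
  if (!all(artifacts %in% colnames(S))) {
    stop("artifacts must name columns of S", call. = FALSE)
  }
  structure(list(S = S, names = colnames(S), artifacts = unique(artifacts)),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("<signature_catalog> %d signatures x 96 channels\n", length(x$names)))
  cat("signatures:", paste(x$names, collapse = ", "), "\n")
  if (length(x$artifacts)) {
    cat("artifacts: ", paste(x$artifacts, collapse = ", "), "\n")
  }
  invisible(x)
}

parse_channel_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", labels))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop(sprintf("malformed channel label '%s'", labels[which(bad)[1]]), call. = FALSE)
  }
  f5 <- vapply(m, `[`, character(1), 2L)
  ref <- vapply(m, `[`, character(1), 3L)
  alt <- vapply(m, `[`, character(1), 4L)
  f3 <- vapply(m, `[`, character(1), 5L)
  channel_index(ref, alt, paste0(f5, ref, f3))
}

#' Read and write signature catalogs in COSMIC SBS layout
#'
#' The file is tab-delimited with the 96 channel labels (e.g. `"A[C>A]A"`)
#' in the first column and one column per signature. Rows may appear in any
#' order; they are mapped to the canonical order of [sbs96_channels()].
#'
#' @param path File path.
#' @param artifacts Character vector of signature names to flag as
#'   sequencing artifacts (an annotation, not part of the COSMIC layout).
#' @return `read_signature_catalog()` returns a `signature_catalog`;
#'   `write_signature_catalog()` returns `path` invisibly.
#' @export
read_signature_catalog <- function(path, artifacts = character()) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) stop("catalog file needs a label column plus >=1 signature", call. = FALSE)
  labels <- as.character(tbl[[1]])
  if (nrow(tbl) != 96L) stop("catalog file must have 96 rows", call. = FALSE)
  idx <- parse_channel_labels(labels)
  if (anyDuplicated(idx)) stop("duplicate channel labels in catalog file", call. = FALSE)
  S <- as.matrix(tbl[, -1, drop = FALSE])
  S <- S[order(idx), , drop = FALSE]
  rownames(S) <- sbs96_channels()
  signature_catalog(S, artifacts = artifacts)
}

#' @rdname read_signature_catalog
#' @param catalog A `signature_catalog`.
#' @export
write_signature_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "signature_catalog"))
  tbl <- tibble::as_tibble(catalog$S)
  tbl <- dplyr::bind_cols(tibble::tibble(Type = sbs96_channels()), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

# smooth a structured emission pattern with a small uniform floor so every
# channel has non-zero probability, then normalize to 1
smooth_signature <- function(raw, floor = 1e-4) {
  p <- raw / sum(raw)
  p <- p * (1 - 96 * floor) + floor
  p / sum(p)
}

#' A small synthetic signature catalog for simulation and testing
#'
#' Six deterministically constructed signatures over the 96 channels,
#' loosely modelled on processes seen in squamous lung tumors but with
#' simplified, clearly separated emission patterns (every pattern carries a
#' small uniform floor so no channel has probability zero):
#'
#' * `SYN_APOBEC_CT` - C>T concentrated at TpC dinucleotides (the APOBEC
#'   deamination-then-replication route).
#' * `SYN_APOBEC_CG` - C>G concentrated at TpC (the APOBEC
#'   abasic-site route).
#' * `SYN_SMOKE` - broad C>A transversions, heavier at 5' purine flanks.
#' * `SYN_CLOCK` - C>T at NpCpG contexts (spontaneous CpG deamination).
#' * `SYN_FLAT` - near-uniform background.
#' * `SYN_ARTIFACT` - T>A spike, flagged as a sequencing artifact.
#'
#' This catalog is synthetic: it is not a copy of any published signature
#' set, and its only purpose is to give simulations and tests a ground
#' truth with recognizable APOBEC-like components.
#'
#' @return A `signature_catalog` with 6 signatures; `SYN_ARTIFACT` is listed
#'   in `artifacts`.
#' @export
synthetic_signature_catalog <- function() {
  ch <- sbs96_channels()
  cls <- rep(sbs96_classes(), each = 16L)
  f5 <- substr(ch, 1L, 1L)
  f3 <- substr(ch, 7L, 7L)

  apobec_ct <- ifelse(cls == "C>T" & f5 == "T", c(A = 5, C = 1, G = 3, T = 4)[f3], 0)
  apobec_cg <- ifelse(cls == "C>G" & f5 == "T", c(A = 4, C = 2, G = 1, T = 5)[f3], 0)
  smoke     <- ifelse(cls == "C>A", c(A = 3, C = 2, G = 2, T = 1)[f5] *
                                    c(A = 1, C = 2, G = 1, T = 1)[f3], 0)
  clock     <- ifelse(cls == "C>T" & f3 == "G", c(A = 3, C = 2, G = 2, T = 3)[f5], 0)
  flat      <- rep(1, 96L)
  artifact  <- ifelse(cls == "T>A" & f5 == "G" & f3 == "G", 10,
                      ifelse(cls == "T>A", 0.5, 0))

  S <- cbind(
    SYN_APOBEC_CT = smooth_signature(apobec_ct),
    SYN_APOBEC_CG = smooth_signature(apobec_cg),
    SYN_SMOKE     = smooth_signature(smoke),
    SYN_CLOCK     = smooth_signature(clock),
    SYN_FLAT      = smooth_signature(flat),
    SYN_ARTIFACT  = smooth_signature(artifact)
  )
  rownames(S) <- ch
  signature_catalog(S, artifacts = "SYN_ARTIFACT")
}
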