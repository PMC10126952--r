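#' Tumor-specific trinucleotide context profile
#'
#' Mixes the catalog columns by the tumor's signature weights to give the
#' probability that a mutation in this tumor falls in each of the 96
#' channels: `p[k] = sum_s w[s] * S[k, s]`.
#'
#' @param w Named weight vector over catalog signatures, summing to 1.
#' @param catalog A [signature_catalog()].
#' @return Named numeric 96-vector summing to 1.
#' @export
context_profile <- function(w, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  if (is.null(names(w))) {
    stopifnot(length(w) == length(catalog$names))
    names(w) <- catalog$names
  }
  stopifnot(all(names(w) %in% catalog$names))
  full <- stats::setNames(numeric(length(catalog$names)), catalog$names)
  full[names(w)] <- w
  stopifnot(abs(sum(full) - 1) < 1e-6)
  p <- as.numeric(catalog$S %*% full)
  names(p) <- sbs96_channels()
  p
}

# context profiles for many tumors at once: tumors x 96 matrix
context_profile_matrix <- function(W, catalog) {
  stopifnot(ncol(W) == length(catalog$names))
  P <- W[, catalog$names, drop = FALSE] %*% t(catalog$S)
  colnames(P) <- sbs96_channels()
  P
}

#' Read gene intervals from BED
#'
#' BED is 0-based, half-open; intervals are converted to the 1-based fully
#' closed convention used everywhere else in the package.
#'
#' @param path BED file path (columns chrom, start, end, name).
#' @return Tibble with `chrom`, `start`, `end` (1-based closed), `gene`.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                         show_col_types = FALSE, progress = FALSE)
  tibble::tibble(chrom = as.character(tbl$chrom),
                 start = as.integer(tbl$start) + 1L,
                 end = as.integer(tbl$end),
                 gene = as.character(tbl$gene))
}

#' @rdname read_bed
#' @param intervals Interval tibble (1-based closed).
#' @export
write_bed <- function(intervals, path) {
  out <- tibble::tibble(chrom = intervals$chrom,
                        start = intervals$start - 1L,
                        end = intervals$end,
                        gene = intervals$gene)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Per-gene channel composition from the reference
#'
#' For each gene interval, counts at how many of its positions each of the
#' 96 substitution channels is possible. A position whose (collapsed)
#' trinucleotide context is, say, TCG contributes one possibility to each
#' of the three channels T\[C>A\]G, T\[C>G\]G, T\[C>T\]G, so each usable
#' position contributes exactly 3 possibilities. Positions at contig edges
#' (no flanking base) are skipped.
#'
#' @param genome Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param intervals Gene interval tibble (1-based closed; see [read_bed()]).
#' @return Tibble with `gene` plus one count column per channel label.
#' @export
gene_context_composition <- function(genome, intervals) {
  genome <- as_genome(genome)
  ctx_channels <- context_to_channels()
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    chrom <- intervals$chrom[i]
    if (!chrom %in% names(genome)) {
      stop(sprintf("contig '%s' not in reference", chrom), call. = FALSE)
    }
    len <- nchar(genome[[chrom]])
    pos <- seq(max(intervals$start[i], 2L), min(intervals$end[i], len - 1L))
    ctx <- substring(genome[[chrom]], pos - 1L, pos + 1L)
    idx <- collapse_context_index(ctx)
    idx <- idx[!is.na(idx)]
    counts <- integer(96L)
    tab <- tabulate(idx, nbins = 32L)
    for (ci in which(tab > 0L)) {
      counts[ctx_channels[[ci]]] <- counts[ctx_channels[[ci]]] + tab[ci]
    }
    counts
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- sbs96_channels()
  dplyr::bind_cols(tibble::tibble(gene = intervals$gene), tibble::as_tibble(mat))
}

composition_matrix <- function(composition) {
  mat <- as.matrix(composition[, sbs96_channels(), drop = FALSE])
  rownames(mat) <- composition$gene
  mat
}

#' Read/write per-gene baseline mutation rates
#'
#' Rates are expected mutation counts per gene per tumor, either one
#' cohort-level rate per gene (columns `gene`, `rate`) or per-tumor rates
#' (columns `gene`, `tumor_id`, `rate`).
#'
#' @param path TSV path.
#' @return Tibble with `gene`, optionally `tumor_id`, and `rate`.
#' @export
read_gene_rates <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene", "rate") %in% names(tbl)))
  tbl
}

#' @rdname read_gene_rates
#' @param gene_rates Gene-rate tibble.
#' @export
write_gene_rates <- function(gene_rates, path) {
  readr::write_tsv(gene_rates, path, progress = FALSE)
  invisible(path)
}

gene_rate_lookup <- function(gene_rates, gene, tumor_ids) {
  sub <- gene_rates[gene_rates$gene == gene, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("gene '%s' absent from rate table", gene),
                       call. = FALSE)
  if ("tumor_id" %in% names(sub) && !all(is.na(sub$tumor_id))) {
    r <- sub$rate[match(tumor_ids, sub$tumor_id)]
    if (anyNA(r)) {
      stop(sprintf("gene '%s': missing per-tumor rate for %s", gene,
                   tumor_ids[which(is.na(r))[1]]), call. = FALSE)
    }
    r
  } else {
    rep(sub$rate[1], length(tumor_ids))
  }
}

#' Per-variant, per-tumor mutation rate
#'
#' Distributes a gene's expected mutation count over its possible variants
#' in proportion to the tumor's context profile:
#' `mu = R_g * p[c] / sum_k n_g[k] * p[k]`,
#' where `R_g` is the gene's expected mutation count for the tumor, `p` the
#' tumor's context profile ([context_profile()]), `c` the variant's channel
#' and `n_g` the gene's channel composition
#' ([gene_context_composition()]). Summing `mu` over every possible variant
#' of the gene recovers `R_g` exactly, and `mu` is invariant to rescaling
#' `p` by a positive constant.
#'
#' `variant_mu()` computes the rate for one variant in one tumor;
#' [variant_rates()] vectorizes over variants and tumors.
#'
#' @param gene Gene symbol (must be present in `gene_rates` and
#'   `composition`).
#' @param channel Variant channel index (1..96).
#' @param p Tumor context profile (96-vector).
#' @param gene_rates Gene-rate tibble (see [read_gene_rates()]).
#' @param composition Gene composition tibble
#'   ([gene_context_composition()]).
#' @param tumor_id Tumor identifier (used for per-tumor rate tables).
#' @return Positive scalar rate.
#' @export
variant_mu <- function(gene, channel, p, gene_rates, composition,
                       tumor_id = NA_character_) {
  ng <- composition_matrix(composition)
  if (!gene %in% rownames(ng)) {
    stop(sprintf("gene '%s' absent from composition table", gene), call. = FALSE)
  }
  denom <- sum(ng[gene, ] * p)
  if (denom <= 0) stop(sprintf("gene '%s': degenerate composition (denominator 0)",
                               gene), call. = FALSE)
  R <- gene_rate_lookup(gene_rates, gene, tumor_id)
  mu <- R * p[channel] / denom
  unname(mu)
}

#' Mutation rates for a set of variants across all tumors
#'
#' Applies the rate equation of [variant_mu()] to every (variant, tumor)
#' pair: for each distinct variant (gene and channel) the rate is computed
#' in every fitted tumor from that tumor's context profile.
#'
#' @param variants Tibble of distinct variants with `gene`, `channel`, and
#'   the key columns `chrom`, `pos`, `ref`, `alt`.
#' @param fit A `signature_fit` (or weights tibble accepted by
#'   [weights_matrix()]).
#' @param catalog A [signature_catalog()].
#' @param gene_rates Gene-rate tibble.
#' @param composition Gene composition tibble.
#' @return Long tibble with `variant_key`, `gene`, `tumor_id`, `mu`.
#' @export
variant_rates <- function(variants, fit, catalog, gene_rates, composition) {
  variants <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref,
                              .data$alt, .data$gene, .data$channel)
  stopifnot(!anyNA(variants$channel))
  W <- weights_matrix(fit)
  P <- context_profile_matrix(W, catalog)     # tumors x 96
  ng <- composition_matrix(composition)       # genes x 96
  genes <- unique(variants$gene)
  missing <- setdiff(genes, rownames(ng))
  if (length(missing)) {
    stop(sprintf("gene(s) absent from composition table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  denom <- P %*% t(ng[genes, , drop = FALSE])  # tumors x genes
  if (any(denom <= 0)) stop("degenerate composition (denominator 0)", call. = FALSE)
  tumor_ids <- rownames(W)
  keys <- variant_key(variants)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    g <- variants$gene[i]
    R <- gene_rate_lookup(gene_rates, g, tumor_ids)
    tibble::tibble(variant_key = keys[i], gene = g, tumor_id = tumor_ids,
                   mu = unname(R * P[, variants$channel[i]] / denom[, g]))
  })
  dplyr::bind_rows(rows)
}
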