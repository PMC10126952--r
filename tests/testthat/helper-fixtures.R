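# Shared fixtures: all built in code at test time.

# one canonical variant row with sensible defaults, overridable per field
make_variant <- function(tumor_id = "T1", chrom = "chr1", pos = 10L,
                         ref = "C", alt = "T", gene = "TP53",
                         variant_classification = "Missense_Mutation",
                         t_alt_count = 20L, t_ref_count = 80L,
                         n_alt_count = 0L, n_ref_count = 100L,
                         gnomad_max_subpop_af = 0,
                         in_cosmic = FALSE, is_snv = TRUE,
                         context = NA_character_, channel = NA_integer_) {
  tibble::tibble(tumor_id = tumor_id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, gene = gene,
                 variant_classification = variant_classification,
                 t_alt_count = t_alt_count, t_ref_count = t_ref_count,
                 n_alt_count = n_alt_count, n_ref_count = n_ref_count,
                 gnomad_max_subpop_af = gnomad_max_subpop_af,
                 in_cosmic = in_cosmic, is_snv = is_snv, context = context,
                 channel = channel)
}

# a tiny two-signature catalog with analytically convenient emissions
toy_catalog <- function(artifacts = character()) {
  S <- matrix(1e-4, nrow = 96, ncol = 2,
              dimnames = list(sbs96_channels(), c("SIG_A", "SIG_B")))
  # SIG_A concentrated on channels 1..8, SIG_B on 41..48
  S[1:8, 1] <- S[1:8, 1] + (1 - 96e-4) / 8
  S[41:48, 2] <- S[41:48, 2] + (1 - 96e-4) / 8
  signature_catalog(S, artifacts = artifacts)
}

# wide spectra tibble from a plain tumors x 96 matrix (fractional ok)
spectra_from_matrix <- function(mat) {
  colnames(mat) <- sbs96_channels()
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(
    tibble::tibble(tumor_id = rownames(mat) %||% paste0("T", seq_len(nrow(mat)))),
    out)
  out$total <- rowSums(mat)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a minimal MAF file and return its path
write_toy_maf <- function(rows, path = tempfile(fileext = ".maf.tsv")) {
  write_maf(rows, path)
  path
}

# independent two-sided Fisher oracle: enumerate the conditional
# hypergeometric distribution of the top-left cell with choose()
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
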