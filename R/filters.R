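#' Post-calling filter configuration
#'
#' Thresholds for the post-calling somatic variant filters. Defaults follow
#' common exome QC practice for matched tumor/normal calls: population
#' variants above 0.04% in any gnomAD subpopulation, low tumor VAF, normal
#' contamination, read-support minima, a panel of normals, off-target
#' classes, and a small set of genes with known alignment problems in hg19.
#' Operator directions are literal: gnomAD strictly greater than
#' `max_gnomad_af`; tumor VAF strictly below `min_tumor_vaf`; normal VAF at
#' or above `max_normal_vaf`; tumor ALT reads below `min_tumor_alt`; normal
#' ALT reads above `max_normal_alt` (i.e. removal at `max_normal_alt + 1`).
#'
#' The optional Fisher allele-frequency filter (off by default) drops
#' variants whose tumor and matched-normal allele counts do not differ
#' significantly (two-sided Fisher exact P > `fisher_alpha`), unless the
#' variant is reported in COSMIC. The gnomAD filter carries no COSMIC
#' exemption unless `gnomad_cosmic_exempt = TRUE`.
#'
#' @param max_gnomad_af,min_tumor_vaf,max_normal_vaf Fractions in \[0, 1\].
#' @param min_tumor_alt,max_normal_alt Non-negative integer read counts.
#' @param blacklist_genes Genes removed outright.
#' @param offtarget_classes Variant classifications treated as off-target.
#' @param panel_of_normals Character vector of variant keys
#'   (`"chrom:pos:ref>alt"`, see [variant_key()]) to remove.
#' @param fisher_enabled,fisher_alpha Enable/parametrize the Fisher filter.
#' @param gnomad_cosmic_exempt Exempt COSMIC variants from the gnomAD rule.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_gnomad_af = 0.0004,
                          min_tumor_vaf = 0.05,
                          max_normal_vaf = 0.05,
                          min_tumor_alt = 5L,
                          max_normal_alt = 4L,
                          blacklist_genes = c("PDE4DIP", "CDC27", "MUC4",
                                              "DUX4", "HYDIN", "PRIM2"),
                          offtarget_classes = c("Intron", "3'Flank",
                                                "5'Flank", "IGR"),
                          panel_of_normals = character(),
                          fisher_enabled = FALSE,
                          fisher_alpha = 0.05,
                          gnomad_cosmic_exempt = FALSE) {
  stopifnot(max_gnomad_af >= 0, max_gnomad_af <= 1,
            min_tumor_vaf >= 0, min_tumor_vaf <= 1,
            max_normal_vaf >= 0, max_normal_vaf <= 1,
            min_tumor_alt >= 0, max_normal_alt >= 0,
            fisher_alpha > 0, fisher_alpha < 1)
  structure(list(max_gnomad_af = max_gnomad_af,
                 min_tumor_vaf = min_tumor_vaf,
                 max_normal_vaf = max_normal_vaf,
                 min_tumor_alt = as.integer(min_tumor_alt),
                 max_normal_alt = as.integer(max_normal_alt),
                 blacklist_genes = blacklist_genes,
                 offtarget_classes = offtarget_classes,
                 panel_of_normals = panel_of_normals,
                 fisher_enabled = isTRUE(fisher_enabled),
                 fisher_alpha = fisher_alpha,
                 gnomad_cosmic_exempt = isTRUE(gnomad_cosmic_exempt)),
            class = "filter_config")
}

vaf <- function(alt, ref) {
  total <- alt + ref
  ifelse(!is.na(total) & total > 0, alt / total, NA_real_)
}

#' Fisher exact tumor-vs-normal allele-frequency test
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[t_alt, t_ref], [n_alt, n_ref]]`. Used to drop calls whose allele
#' frequency does not differ between tumor and matched normal (likely
#' germline or systematic error): a variant is dropped when P >
#' `alpha` and it is not reported in COSMIC. Variants with zero total reads
#' in either sample are kept with a warning (the test is undefined).
#'
#' @param t_alt,t_ref,n_alt,n_ref Read counts (vectorized).
#' @param in_cosmic Logical; COSMIC-reported variants are exempt from
#'   dropping.
#' @param alpha Significance level (default 0.05).
#' @return `fisher_af_test()` returns the vector of two-sided P-values
#'   (`NA` where undefined); `fisher_af_filter()` returns a logical vector,
#'   `TRUE` = keep.
#' @export
fisher_af_test <- function(t_alt, t_ref, n_alt, n_ref) {
  n <- length(t_alt)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cnt <- c(t_alt[i], t_ref[i], n_alt[i], n_ref[i])
    if (anyNA(cnt)) next
    if (t_alt[i] + t_ref[i] == 0L || n_alt[i] + n_ref[i] == 0L) next
    tab <- matrix(cnt, nrow = 2L, byrow = TRUE)
    p[i] <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  p
}

#' @rdname fisher_af_test
#' @export
fisher_af_filter <- function(t_alt, t_ref, n_alt, n_ref,
                             in_cosmic = FALSE, alpha = 0.05) {
  n <- max(length(t_alt), length(n_alt))
  in_cosmic <- rep_len(in_cosmic, n)
  p <- fisher_af_test(t_alt, t_ref, n_alt, n_ref)
  undefined <- is.na(p) & !(is.na(t_alt) | is.na(t_ref) | is.na(n_alt) | is.na(n_ref))
  if (any(undefined)) {
    warning(sprintf("Fisher test skipped for %d variant(s) with zero reads; kept",
                    sum(undefined)), call. = FALSE)
  }
  # drop only when the test ran, was non-significant, and no COSMIC exemption
  !(!is.na(p) & p > alpha & !in_cosmic)
}

filter_rule_names <- function(config) {
  rules <- c("gnomad_af", "tumor_vaf", "normal_vaf", "tumor_alt_reads",
             "normal_alt_reads", "panel_of_normals", "offtarget", "blacklist_gene")
  if (config$fisher_enabled) rules <- c(rules, "fisher_af")
  rules
}

#' Apply post-calling variant filters
#'
#' Applies the filter rules of [filter_config()] in a fixed order (gnomAD
#' population frequency, tumor VAF, normal VAF, tumor ALT reads, normal ALT
#' reads, panel of normals, off-target class, blacklisted gene, then the
#' optional Fisher allele-frequency test). A variant failing several rules
#' is counted once, under the first failing rule, so surviving count plus
#' per-rule removals always equals the input count. A rule whose required
#' annotation is missing for a variant (e.g. no gnomAD frequency, no read
#' counts) is skipped for that variant.
#'
#' @param variants Canonical variant tibble.
#' @param config A [filter_config()].
#' @return A list with `variants` (survivors, same columns) and `report`
#'   (tibble with `rule`, `n_removed`, in rule order).
#' @export
apply_filters <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(variants)
  rules <- filter_rule_names(config)
  if (n == 0L) {
    return(list(variants = variants,
                report = tibble::tibble(rule = rules,
                                        n_removed = integer(length(rules)))))
  }
  tv <- vaf(variants$t_alt_count, variants$t_ref_count)
  nv <- vaf(variants$n_alt_count, variants$n_ref_count)
  gaf <- variants$gnomad_max_subpop_af

  fails <- list(
    gnomad_af = !is.na(gaf) & gaf > config$max_gnomad_af &
      !(config$gnomad_cosmic_exempt & variants$in_cosmic),
    tumor_vaf = !is.na(tv) & tv < config$min_tumor_vaf,
    normal_vaf = !is.na(nv) & nv >= config$max_normal_vaf,
    tumor_alt_reads = !is.na(variants$t_alt_count) &
      variants$t_alt_count < config$min_tumor_alt,
    normal_alt_reads = !is.na(variants$n_alt_count) &
      variants$n_alt_count > config$max_normal_alt,
    panel_of_normals = variant_key(variants) %in% config$panel_of_normals,
    offtarget = !is.na(variants$variant_classification) &
      normalize_primes(variants$variant_classification) %in%
        normalize_primes(config$offtarget_classes),
    blacklist_gene = !is.na(variants$gene) & variants$gene %in% config$blacklist_genes
  )
  if (config$fisher_enabled) {
    keep_f <- fisher_af_filter(variants$t_alt_count, variants$t_ref_count,
                               variants$n_alt_count, variants$n_ref_count,
                               in_cosmic = variants$in_cosmic,
                               alpha = config$fisher_alpha)
    fails$fisher_af <- !keep_f
  }
  fail_mat <- do.call(cbind, fails)
  first_fail <- apply(fail_mat, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  removed <- !is.na(first_fail)
  report <- tibble::tibble(
    rule = rules,
    n_removed = vapply(seq_along(rules),
                       function(j) sum(first_fail == j, na.rm = TRUE), integer(1))
  )
  list(variants = variants[!removed, , drop = FALSE], report = report)
}

# unify ASCII apostrophe and typographic prime in flank class names
normalize_primes <- function(x) gsub("′", "'", x)

#' @rdname apply_filters
#' @param report A filter report tibble.
#' @param path Output TSV path.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
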