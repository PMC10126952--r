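#' Study cohort sizes for the squamous-lung analysis
#'
#' Sizes of the four tumor cohorts combined in the motivating
#' squamous-cell lung carcinoma analysis: two institutional whole-exome
#' cohorts (a SPORE biorepository and a VA medical center series) and two
#' public sources. Their total is the cohort size over which per-tumor
#' signature weights were summarized.
#'
#' @return Tibble with `cohort`, `source`, `n_tumors`.
#' @examples
#' sum(lusc_study_cohorts()$n_tumors)
#' @export
lusc_study_cohorts <- function() {
  tibble::tibble(
    cohort = c("YCCLSB", "VAMC", "GDC", "Yale-Gilead"),
    source = c("institutional biorepository (WES)",
               "VA medical center (WES)",
               "public: NCI Genomic Data Commons",
               "public: Yale-Gilead collaboration"),
    n_tumors = c(59L, 22L, 492L, 108L))
}

#' NFE2L2 deamination substrate oligonucleotides
#'
#' The two single-stranded oligonucleotide substrates spanning the NFE2L2
#' mutational hotspot around codon R34 (amino acids 31-38) used to assay
#' APOBEC3B cytidine deamination in vitro: a 25-mer on the coding strand
#' (one TC target cytosine) and a 22-mer on the noncoding strand (three TC
#' target cytosines). Sequences are written 5' to 3'.
#'
#' @return Tibble with `strand`, `length`, `sequence`.
#' @examples
#' oligos <- nfe2l2_substrates()
#' find_tc_sites(oligos$sequence[oligos$strand == "coding"])
#' @export
nfe2l2_substrates <- function() {
  tibble::tibble(
    strand = c("coding", "noncoding"),
    length = c(25L, 22L),
    sequence = c("TTGGAGTAAGTCGAGAAGTATTTGA",
                 "AATACTTCTCGACTTACTCCAA"))
}
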