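check_sequence <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters other than A, C, G, T", call. = FALSE)
  }
  seq
}

#' Find APOBEC TC recognition sites in a sequence
#'
#' APOBEC cytidine deaminases prefer cytidines immediately preceded by
#' thymidine, so TC is the minimal recognition dinucleotide. This scans the
#' supplied strand 5'->3' and reports one site per C preceded by T, with
#' its NTCN 4-mer context (truncated at sequence edges) and the resulting
#' C>T change. Sites are labelled with sequential-product names
#' ([label_sequential_products()]).
#'
#' @param seq Nucleotide string over A, C, G, T (length >= 2).
#' @param strand Label recorded in the output: `"coding"` or
#'   `"noncoding"` (metadata only; the scan always runs on `seq` as
#'   given).
#' @return Tibble with `strand`, `position` (1-based index of the target
#'   C), `motif` (NTCN 4-mer, edge-truncated), `change`, `product`.
#' @examples
#' find_tc_sites("AATACTTCTCGACTTACTCCAA", strand = "noncoding")
#' @export
find_tc_sites <- function(seq, strand = c("coding", "noncoding")) {
  strand <- match.arg(strand)
  seq <- check_sequence(seq)
  if (nchar(seq) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- which(chars == "C" & c("", chars[-length(chars)]) == "T")
  motif <- substr(rep(seq, length(pos)), pmax(pos - 2L, 1L),
                  pmin(pos + 1L, nchar(seq)))
  tibble::tibble(strand = strand,
                 position = as.integer(pos),
                 motif = motif,
                 change = "C>T",
                 product = label_sequential_products(pos))
}

#' Sequential deamination product labels
#'
#' Multi-site substrates are deaminated sequentially; chromatographic
#' products are conventionally labelled P1, P2, ... For a strand with
#' exactly three target sites, P1 is the central site, P2 the 5'-most and
#' P3 the 3'-most. For any other number of sites, labels are assigned in
#' 5'->3' order. Labels are reporting metadata only.
#'
#' @param positions Integer vector of site positions on one strand.
#' @return Character vector of labels, same order as `positions`.
#' @export
label_sequential_products <- function(positions) {
  n <- length(positions)
  if (n == 0L) return(character())
  ord <- order(positions)
  labels <- character(n)
  if (n == 3L) {
    labels[ord[2]] <- "P1"
    labels[ord[1]] <- "P2"
    labels[ord[3]] <- "P3"
  } else {
    labels[ord] <- paste0("P", seq_len(n))
  }
  labels
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Amino-acid consequence of a deamination site
#'
#' Maps a C->U deamination (read as C>T after replication) to its codon
#' change. For a coding-strand site the substitution is applied directly;
#' for a noncoding-strand site the deamination corresponds to a G>A change
#' on the coding sense, so the scanned strand is reverse-complemented and
#' the mirrored position mutated before translation. `frame_offset` gives
#' the 0-based offset of the first complete codon on the *coding* sense.
#'
#' @param seq The scanned strand (the sequence passed to
#'   [find_tc_sites()]).
#' @param position 1-based position of the target C on `seq`.
#' @param frame_offset 0-based offset of the reading frame on the coding
#'   sense (0, 1 or 2).
#' @param strand `"coding"` or `"noncoding"`: which strand `seq` is.
#' @return One-row tibble with `codon_index`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `consequence` (`"missense"`, `"synonymous"`,
#'   `"nonsense"`); all `NA` with a warning when the site falls in an
#'   incomplete codon.
#' @examples
#' codon_effect("TTGGAGTAAGTCGAGAAGTATTTGA", position = 12, frame_offset = 0)
#' @export
codon_effect <- function(seq, position, frame_offset = 0L,
                         strand = c("coding", "noncoding")) {
  strand <- match.arg(strand)
  seq <- check_sequence(seq)
  stopifnot(position >= 1L, position <= nchar(seq),
            frame_offset %in% 0:2)
  if (strand == "coding") {
    coding <- seq
    cpos <- position
    ref_base <- "C"; alt_base <- "T"
  } else {
    coding <- revcomp(seq)
    cpos <- nchar(seq) - position + 1L
    ref_base <- "G"; alt_base <- "A"
  }
  if (substr(coding, cpos, cpos) != ref_base) {
    stop(sprintf("position %d is not a %s on the %s sense", position,
                 ref_base, "coding"), call. = FALSE)
  }
  empty <- tibble::tibble(codon_index = NA_integer_, ref_codon = NA_character_,
                          alt_codon = NA_character_, ref_aa = NA_character_,
                          alt_aa = NA_character_, consequence = NA_character_)
  rel <- cpos - frame_offset
  if (rel < 1L) {
    warning("site lies 5' of the reading frame; no codon effect", call. = FALSE)
    return(empty)
  }
  codon_index <- (rel - 1L) %/% 3L + 1L
  codon_start <- frame_offset + (codon_index - 1L) * 3L + 1L
  if (codon_start + 2L > nchar(coding)) {
    warning("incomplete codon at sequence edge; no codon effect", call. = FALSE)
    return(empty)
  }
  ref_codon <- substr(coding, codon_start, codon_start + 2L)
  within <- cpos - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  consequence <- if (ref_aa == alt_aa) "synonymous" else
    if (alt_aa == "*") "nonsense" else "missense"
  tibble::tibble(codon_index = codon_index, ref_codon = ref_codon,
                 alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
                 consequence = consequence)
}

#' Scan a substrate and annotate codon effects
#'
#' Convenience wrapper combining [find_tc_sites()] with [codon_effect()]
#' for every site when a reading frame is supplied.
#'
#' @inheritParams find_tc_sites
#' @param frame_offset 0-based reading-frame offset on the coding sense,
#'   or `NULL` to skip codon annotation.
#' @return The [find_tc_sites()] tibble, with codon-effect columns appended
#'   when `frame_offset` is given.
#' @export
scan_substrate <- function(seq, strand = c("coding", "noncoding"),
                           frame_offset = NULL) {
  strand <- match.arg(strand)
  sites <- find_tc_sites(seq, strand = strand)
  if (is.null(frame_offset) || !nrow(sites)) return(sites)
  eff <- dplyr::bind_rows(lapply(sites$position, function(p) {
    codon_effect(seq, p, frame_offset = frame_offset, strand = strand)
  }))
  dplyr::bind_cols(sites, eff)
}
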