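#' @importFrom rlang .data
NULL

# canonical column -> accepted MAF synonyms (first match wins)
maf_synonyms <- list(
  tumor_id               = c("tumor_id", "Tumor_Sample_Barcode"),
  chrom                  = c("chrom", "Chromosome"),
  pos                    = c("pos", "Start_Position"),
  ref                    = c("ref", "Reference_Allele"),
  alt                    = c("alt", "Tumor_Seq_Allele2"),
  gene                   = c("gene", "Hugo_Symbol"),
  variant_classification = c("variant_classification", "Variant_Classification"),
  t_alt_count            = c("t_alt_count", "tumor_alt_reads"),
  t_ref_count            = c("t_ref_count", "tumor_ref_reads"),
  n_alt_count            = c("n_alt_count", "normal_alt_reads"),
  n_ref_count            = c("n_ref_count", "normal_ref_reads"),
  gnomad_max_subpop_af   = c("gnomad_max_subpop_af", "gnomAD_max_subpop_AF"),
  in_cosmic              = c("in_cosmic", "COSMIC")
)

maf_mandatory <- c("tumor_id", "chrom", "pos", "ref", "alt")

#' Read a MAF-style somatic variant table
#'
#' Reads a tab-delimited variant table (one row per called substitution) and
#' returns a tibble with canonical column names. Standard MAF column names
#' (`Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Tumor_Sample_Barcode`, `Variant_Classification`,
#' `t_alt_count`, `t_ref_count`, `n_alt_count`, `n_ref_count`) are accepted
#' as synonyms; extra columns are ignored. Coordinates stay 1-based.
#'
#' Indels and multi-nucleotide variants are parsed but flagged with
#' `is_snv = FALSE`; downstream spectrum and effect-size computations use
#' SNVs only. Rows with a missing or non-numeric position are rejected with
#' a warning reporting their row numbers.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A tibble with columns `tumor_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `variant_classification`, `t_alt_count`, `t_ref_count`,
#'   `n_alt_count`, `n_ref_count`, `gnomad_max_subpop_af`, `in_cosmic`,
#'   `is_snv`, `context`, `channel` (the last two `NA` until
#'   [annotate_contexts()] is applied). Missing optional columns are filled
#'   with `NA` (`in_cosmic` with `FALSE`).
#' @seealso [write_maf()], [annotate_contexts()], [apply_filters()]
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  as_variant_table(raw, source = path)
}

#' Coerce a data frame of variant calls to the canonical variant table
#'
#' @param x A data frame with canonical or MAF-synonym column names.
#' @param source Label used in error messages.
#' @return A canonical variant tibble (see [read_maf()]).
#' @export
as_variant_table <- function(x, source = "variant table") {
  x <- tibble::as_tibble(x)
  out <- list()
  for (canon in names(maf_synonyms)) {
    hit <- intersect(maf_synonyms[[canon]], names(x))
    out[[canon]] <- if (length(hit)) x[[hit[1]]] else NA
  }
  missing <- maf_mandatory[vapply(out[maf_mandatory],
                                  function(v) all(is.na(v)) && length(v) == 1L,
                                  logical(1))]
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(x)
  out <- lapply(out, function(v) if (length(v) == 1L && n != 1L) rep(v, n) else v)
  tbl <- tibble::as_tibble(out)

  tbl$pos <- suppressWarnings(as.numeric(tbl$pos))
  bad <- which(is.na(tbl$pos) | is.na(tbl$tumor_id) | is.na(tbl$ref) | is.na(tbl$alt))
  if (length(bad)) {
    warning(sprintf("%s: rejected %d malformed row(s): %s", source, length(bad),
                    paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
    tbl <- tbl[-bad, , drop = FALSE]
  }
  for (col in c("t_alt_count", "t_ref_count", "n_alt_count", "n_ref_count")) {
    tbl[[col]] <- suppressWarnings(as.integer(tbl[[col]]))
  }
  tbl$pos <- as.integer(tbl$pos)
  tbl$gnomad_max_subpop_af <- suppressWarnings(as.numeric(tbl$gnomad_max_subpop_af))
  tbl$in_cosmic <- !is.na(tbl$in_cosmic) & tolower(as.character(tbl$in_cosmic)) %in%
    c("true", "t", "1", "yes")
  tbl$ref <- toupper(tbl$ref)
  tbl$alt <- toupper(tbl$alt)
  tbl$is_snv <- tbl$ref %in% c("A", "C", "G", "T") &
    tbl$alt %in% c("A", "C", "G", "T") & tbl$ref != tbl$alt
  tbl$context <- NA_character_
  tbl$channel <- NA_integer_
  tbl
}

#' @rdname read_maf
#' @param variants A canonical variant tibble.
#' @export
write_maf <- function(variants, path) {
  out <- tibble::tibble(
    Hugo_Symbol = variants$gene,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Tumor_Sample_Barcode = variants$tumor_id,
    Variant_Classification = variants$variant_classification,
    t_alt_count = variants$t_alt_count,
    t_ref_count = variants$t_ref_count,
    n_alt_count = variants$n_alt_count,
    n_ref_count = variants$n_ref_count,
    gnomad_max_subpop_af = variants$gnomad_max_subpop_af,
    in_cosmic = variants$in_cosmic
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load a reference sequence set from FASTA
#'
#' @param path FASTA file path (plain text).
#' @return Named character vector of upper-case contig sequences.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_reference
#' @param genome Named character vector of contig sequences.
#' @export
write_reference <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

as_genome <- function(genome) {
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(read_reference(genome))
  }
  if (inherits(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  stop("genome must be a named character vector, DNAStringSet, or FASTA path",
       call. = FALSE)
}

#' Variant identity key
#'
#' Two calls are the same variant when chromosome, position, reference and
#' alternate allele all agree; tumors sharing a key carry the same variant.
#'
#' @param variants A variant tibble (or any data frame with `chrom`, `pos`,
#'   `ref`, `alt`).
#' @return Character vector `"chrom:pos:ref>alt"`.
#' @export
variant_key <- function(variants) {
  paste0(variants$chrom, ":", variants$pos, ":", variants$ref, ">", variants$alt)
}

#' Annotate variants with trinucleotide context and SBS-96 channel
#'
#' Looks up the reference base either side of each SNV and assigns the
#' pyrimidine-collapsed channel via [channel_index()]. The reference base at
#' the variant position must equal the recorded `ref` allele; a mismatch is
#' a coordinate-system error and aborts. SNVs at a contig edge (no flanking
#' base on one side) are flagged by leaving `channel` as `NA` and are
#' excluded from spectra; a warning reports how many.
#'
#' @param variants Canonical variant tibble (see [read_maf()]).
#' @param genome Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @return The input tibble with `context` and `channel` filled for SNVs.
#' @export
annotate_contexts <- function(variants, genome) {
  genome <- as_genome(genome)
  snv <- which(variants$is_snv)
  if (!length(snv)) return(variants)
  chrom <- variants$chrom[snv]
  missing_contig <- !chrom %in% names(genome)
  if (any(missing_contig)) {
    stop(sprintf("contig '%s' not in reference", chrom[which(missing_contig)[1]]),
         call. = FALSE)
  }
  pos <- variants$pos[snv]
  len <- nchar(genome)[chrom]
  at_edge <- pos <= 1L | pos >= len
  inb <- !at_edge

  ctx <- rep(NA_character_, length(snv))
  if (any(inb)) {
    ctx[inb] <- substr(genome[chrom[inb]], pos[inb] - 1L, pos[inb] + 1L)
    ref_seen <- substr(ctx[inb], 2L, 2L)
    mism <- ref_seen != variants$ref[snv][inb]
    if (any(mism)) {
      i <- snv[inb][which(mism)[1]]
      stop(sprintf(
        "reference mismatch at %s:%d: MAF says %s, FASTA has %s (coordinate-system error?)",
        variants$chrom[i], variants$pos[i], variants$ref[i],
        ref_seen[which(mism)[1]]), call. = FALSE)
    }
  }
  if (any(at_edge)) {
    warning(sprintf("%d variant(s) at contig edges excluded from context annotation",
                    sum(at_edge)), call. = FALSE)
  }
  variants$context[snv] <- ctx
  ok <- snv[inb]
  variants$channel[ok] <- channel_index(variants$ref[ok], variants$alt[ok],
                                        variants$context[ok])
  variants
}
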