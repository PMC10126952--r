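#' The six pyrimidine-central substitution classes
#'
#' Single-base substitutions are conventionally collapsed so that the mutated
#' base is a pyrimidine (C or T); a G>A change is recorded as C>T on the
#' opposite strand. The six classes, in catalog order, are
#' C>A, C>G, C>T, T>A, T>C, T>G.
#'
#' @return Character vector of length 6.
#' @export
sbs96_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' SBS-96 channel labels in catalog order
#'
#' Returns the 96 trinucleotide-context substitution channels in the order
#' used throughout the package: substitution class first (C>A, C>G, C>T,
#' T>A, T>C, T>G), then the 5' flanking base (A, C, G, T), then the 3'
#' flanking base (A, C, G, T). Labels follow the COSMIC convention, e.g.
#' `"A[C>A]A"`. Signature catalogs and tumor spectra both use this row
#' order, so the two align by index.
#'
#' @return Character vector of length 96.
#' @examples
#' head(sbs96_channels())
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  f5 <- rep(bases, each = 4L)
  f3 <- rep(bases, times = 4L)
  unlist(lapply(sbs96_classes(), function(cls) {
    paste0(f5, "[", cls, "]", f3)
  }), use.names = FALSE)
}

#' The 32 pyrimidine-central trinucleotide contexts
#'
#' Contexts in the order induced by [sbs96_channels()]: central base C
#' (contexts 1-16) then T (17-32), each block ordered by 5' then 3' flank.
#'
#' @return Character vector of length 32 (e.g. `"ACA"`, `"ACC"`, ...).
#' @export
sbs96_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  f5 <- rep(bases, each = 4L)
  f3 <- rep(bases, times = 4L)
  unlist(lapply(c("C", "T"), function(ctr) {
    paste0(f5, ctr, f3)
  }), use.names = FALSE)
}

base_complement <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector over the alphabet A, C, G, T.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ATGCA")
#' @export
revcomp <- function(x) {
  comp <- base_complement(x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

assert_bases <- function(x, what) {
  bad <- !x %in% c("A", "C", "G", "T")
  if (any(bad)) {
    stop(sprintf("%s must be one of A, C, G, T (got '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
}

#' Map a substitution in context to its SBS-96 channel
#'
#' Computes the 1-based channel index (1..96, ordered as in
#' [sbs96_channels()]) for a single-base substitution given its
#' trinucleotide context as read from the reference. Substitutions with a
#' purine reference base are reverse-complemented so the central base is a
#' pyrimidine, the standard strand-collapse rule.
#'
#' @param ref,alt Single reference and alternate bases (vectorized).
#' @param context Trinucleotide context as read from the reference strand;
#'   its central base must equal `ref`.
#' @return Integer vector of channel indices in 1..96.
#' @examples
#' channel_index("C", "T", "TCG")            # T[C>T]G
#' channel_index("G", "A", "TGA")            # collapses to T[C>T]A
#' @export
channel_index <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); context <- rep_len(context, n)
  assert_bases(ref, "ref"); assert_bases(alt, "alt")
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  if (any(nchar(context) != 3L)) {
    stop("context must be a trinucleotide", call. = FALSE)
  }
  ctr <- substr(context, 2L, 2L)
  if (any(ctr != ref)) {
    stop("central base of context must equal ref", call. = FALSE)
  }
  f5 <- substr(context, 1L, 1L)
  f3 <- substr(context, 3L, 3L)
  assert_bases(f5, "5' flank"); assert_bases(f3, "3' flank")

  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, base_complement(ref), ref)
  a <- ifelse(purine, base_complement(alt), alt)
  new_f5 <- ifelse(purine, base_complement(f3), f5)
  new_f3 <- ifelse(purine, base_complement(f5), f3)

  cls <- match(paste0(r, ">", a), sbs96_classes())
  bases <- c("A", "C", "G", "T")
  i5 <- match(new_f5, bases)
  i3 <- match(new_f3, bases)
  as.integer((cls - 1L) * 16L + (i5 - 1L) * 4L + i3)
}

#' @rdname channel_index
#' @export
channel_label <- function(ref, alt, context) {
  sbs96_channels()[channel_index(ref, alt, context)]
}

# channel k -> index of its pyrimidine-central context in sbs96_contexts()
channel_to_context <- function() {
  cls <- rep(1:6, each = 16L)           # 1..3 central C, 4..6 central T
  within_cls <- rep(1:16, times = 6L)
  ifelse(cls <= 3L, within_cls, 16L + within_cls)
}

# context index (1..32) -> the 3 channel indices with that context
context_to_channels <- function() {
  ctx_of <- channel_to_context()
  lapply(1:32, function(i) which(ctx_of == i))
}

# collapse an as-read trinucleotide to its pyrimidine-central context index,
# NA when the 3-mer contains a non-ACGT character
collapse_context_index <- function(context) {
  ctx <- toupper(context)
  ctr <- substr(ctx, 2L, 2L)
  flip <- ctr %in% c("A", "G")
  ctx[flip] <- revcomp(ctx[flip])
  idx <- match(ctx, sbs96_contexts())
  idx
}
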