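#' Configuration for synthetic cohort simulation
#'
#' Bundles everything the generator needs: a signature catalog, per-tumor
#' signature-weight Dirichlet concentrations, a log-normal passenger-count
#' distribution, a synthetic gene set, per-gene baseline mutation rates,
#' and planted driver variants with known effect sizes. The defaults
#' emulate a squamous-lung-like exome panel at desk scale: a handful of
#' driver genes, tens of passenger substitutions per tumor, APOBEC-like
#' signatures prominent, and one planted APOBEC-context driver whose
#' per-tumor fixation probability `1 - exp(-mu * gamma)` sits near 0.3.
#'
#' @param n_tumors Number of tumors.
#' @param catalog A [signature_catalog()].
#' @param dirichlet_alpha Named Dirichlet concentrations over catalog
#'   signatures. Signatures with zero (or omitted) concentration get
#'   exactly zero weight; artifact signatures should normally be zero
#'   (artifacts do not generate real somatic mutations).
#' @param mutation_meanlog,mutation_sdlog Log-normal parameters of the
#'   per-tumor passenger substitution count.
#' @param genes Tibble with `gene` and `length` (and optionally `start`,
#'   explicit 1-based positions on the synthetic contig).
#' @param gene_rates Tibble with `gene`, `rate`: expected mutation count
#'   per gene per tumor used both to place drivers and as the baseline
#'   rate table handed to the estimation pipeline.
#' @param drivers Tibble with `gene`, `offset` (1-based position within
#'   the gene), `ref`, `alt`, `context` (trinucleotide written into the
#'   reference, central base = `ref`), `true_gamma`.
#' @param seed Integer seed governing every draw.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_tumors = 100L,
                              catalog = synthetic_signature_catalog(),
                              dirichlet_alpha = c(SYN_APOBEC_CT = 2,
                                                  SYN_APOBEC_CG = 2,
                                                  SYN_SMOKE = 4,
                                                  SYN_CLOCK = 3,
                                                  SYN_FLAT = 4),
                              mutation_meanlog = log(60),
                              mutation_sdlog = 0.5,
                              genes = default_gene_panel(),
                              gene_rates = tibble::tibble(
                                gene = default_gene_panel()$gene,
                                rate = 0.12),
                              drivers = tibble::tibble(
                                gene = "NFE2L2", offset = 100L,
                                ref = "C", alt = "T", context = "TCA",
                                true_gamma = 1000),
                              seed = 1L) {
  stopifnot(n_tumors >= 1, inherits(catalog, "signature_catalog"),
            all(names(dirichlet_alpha) %in% catalog$names),
            all(dirichlet_alpha >= 0), any(dirichlet_alpha > 0),
            all(genes$length >= 3L), all(gene_rates$rate > 0),
            mutation_sdlog >= 0)
  if (nrow(drivers)) {
    stopifnot(all(drivers$gene %in% genes$gene),
              all(drivers$offset >= 2L),
              all(drivers$offset <= genes$length[match(drivers$gene, genes$gene)] - 1L),
              all(nchar(drivers$context) == 3L),
              all(substr(drivers$context, 2L, 2L) == drivers$ref),
              all(drivers$true_gamma >= 0))
  }
  structure(list(n_tumors = as.integer(n_tumors), catalog = catalog,
                 dirichlet_alpha = dirichlet_alpha,
                 mutation_meanlog = mutation_meanlog,
                 mutation_sdlog = mutation_sdlog,
                 genes = genes, gene_rates = gene_rates, drivers = drivers,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default synthetic gene panel
#'
#' Forty 450-nt genes: the four named driver genes of the squamous-lung
#' setting plus 36 numbered background genes. A panel this wide keeps
#' per-gene passenger hits sparse (as in a whole exome), so for a typical
#' variant a sizeable fraction of tumors carries no same-gene variant and
#' remains an eligible non-carrier.
#'
#' @return Tibble with `gene` and `length`.
#' @export
default_gene_panel <- function() {
  tibble::tibble(
    gene = c("TP53", "NFE2L2", "PIK3CA", "KEAP1",
             sprintf("GENE%02d", 5:40)),
    length = 450L)
}

#' Build the synthetic reference for a simulation
#'
#' Generates one contig (`chr1` by default) containing every configured
#' gene, separated and flanked by short random spacers so every gene
#' position has both neighbours. Planted driver trinucleotide contexts are
#' written into the sequence at their configured sites. The same seed
#' always yields the same sequence.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @param chrom Contig name.
#' @return List with `genome` (named character vector) and `intervals`
#'   (tibble `chrom`, `start`, `end`, `gene`, 1-based closed).
#' @export
simulate_reference <- function(config, seed = config$seed, chrom = "chr1") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  genes <- config$genes
  spacer <- 6L
  if ("start" %in% names(genes)) {
    starts <- as.integer(genes$start)
    ends <- starts + genes$length - 1L
    ord <- order(starts)
    if (any(starts[ord][-1] <= ends[ord][-length(ord)])) {
      stop("overlapping gene intervals", call. = FALSE)
    }
    total_len <- max(ends) + spacer
  } else {
    starts <- spacer + 1L +
      cumsum(c(0L, utils::head(genes$length + spacer, -1L)))
    ends <- starts + genes$length - 1L
    total_len <- max(ends) + spacer
  }
  seq_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  drv <- config$drivers
  for (i in seq_len(nrow(drv))) {
    g <- match(drv$gene[i], genes$gene)
    p <- starts[g] + drv$offset[i] - 1L
    seq_chars[(p - 1L):(p + 1L)] <- strsplit(drv$context[i], "")[[1]]
  }
  genome <- stats::setNames(paste(seq_chars, collapse = ""), chrom)
  intervals <- tibble::tibble(chrom = chrom, start = starts, end = ends,
                              gene = genes$gene)
  list(genome = genome, intervals = intervals)
}

draw_dirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(0, n, K, dimnames = list(NULL, names(alpha)))
  pos <- alpha > 0
  g[, pos] <- matrix(stats::rgamma(n * sum(pos), shape = rep(alpha[pos],
                                                             each = n)),
                     n, sum(pos))
  g / rowSums(g)
}

# per-gene channel positions on the reference, for passenger placement
reference_site_index <- function(reference, intervals) {
  genome <- reference$genome
  chrom <- names(genome)[1]
  chars <- strsplit(genome[[1]], "")[[1]]
  len <- length(chars)
  gene_at <- rep(NA_character_, len)
  for (i in seq_len(nrow(intervals))) {
    gene_at[intervals$start[i]:intervals$end[i]] <- intervals$gene[i]
  }
  pos <- which(!is.na(gene_at))
  pos <- pos[pos > 1L & pos < len]
  ctx <- paste0(chars[pos - 1L], chars[pos], chars[pos + 1L])
  ctx_idx <- collapse_context_index(ctx)
  list(chrom = chrom, pos = pos, base = chars[pos], gene = gene_at[pos],
       ctx_idx = ctx_idx,
       by_ctx = split(seq_along(pos), factor(ctx_idx, levels = 1:32)))
}

#' Simulate a synthetic tumor cohort with known ground truth
#'
#' Per tumor: signature weights are drawn from the configured Dirichlet;
#' a passenger count from the log-normal; passenger substitutions are
#' placed channel-first (channels sampled from the tumor's mixed context
#' profile `S w`, restricted to channels with at least one matching
#' reference position) and then uniformly among matching gene positions.
#' Each planted driver's per-tumor mutation rate `mu` is computed with the
#' same rate equation the estimation pipeline uses ([variant_mu()]), and
#' the tumor carries the driver with probability `1 - exp(-mu * gamma*)`.
#' Read counts and annotations are drawn so the default [apply_filters()]
#' rules pass.
#'
#' @param config A [simulation_config()].
#' @param reference Output of [simulate_reference()]; built on the fly if
#'   `NULL`.
#' @param seed Seed (defaults to `config$seed`).
#' @return List of class `simulated_cohort` with `variants` (canonical
#'   variant tibble, contexts and channels filled), `reference`,
#'   `composition` (gene channel composition), and `truth`: `weights`
#'   (wide tibble of the generating weights), `passengers` (`tumor_id`,
#'   `n_passengers`), `drivers` (`tumor_id`, `gene`, `variant_key`, `mu`,
#'   `carrier`, `true_gamma`), and `seed`.
#' @export
simulate_cohort <- function(config, reference = NULL, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(reference)) reference <- simulate_reference(config, seed = seed)
  set.seed(seed)
  catalog <- config$catalog
  n <- config$n_tumors
  tumor_ids <- sprintf("T%03d", seq_len(n))

  alpha <- stats::setNames(numeric(length(catalog$names)), catalog$names)
  alpha[names(config$dirichlet_alpha)] <- config$dirichlet_alpha
  W <- draw_dirichlet(n, alpha)
  rownames(W) <- tumor_ids

  N <- pmax(1L, as.integer(round(stats::rlnorm(n, config$mutation_meanlog,
                                               config$mutation_sdlog))))

  sites <- reference_site_index(reference, reference$intervals)
  ctx_avail <- vapply(sites$by_ctx, length, integer(1)) > 0L
  ch_ctx <- channel_to_context()
  ch_avail <- ctx_avail[ch_ctx]

  P <- context_profile_matrix(W, catalog)        # tumors x 96
  P_eff <- P
  P_eff[, !ch_avail] <- 0
  lost <- 1 - rowSums(P_eff)
  if (any(lost > 0.05)) {
    warning(sprintf("up to %.1f%% of channel mass had no matching reference position; renormalized",
                    100 * max(lost)), call. = FALSE)
  }
  P_eff <- P_eff / rowSums(P_eff)

  counts <- vapply(seq_len(n),
                   function(i) stats::rmultinom(1L, N[i], P_eff[i, ])[, 1],
                   integer(96L))                 # 96 x tumors

  nz <- which(counts > 0L, arr.ind = TRUE)
  channel_v <- rep(nz[, 1L], counts[nz])
  tumor_v <- rep(nz[, 2L], counts[nz])
  site_v <- integer(length(channel_v))
  ctx_v <- ch_ctx[channel_v]
  for (ci in unique(ctx_v)) {
    idx <- which(ctx_v == ci)
    pool <- sites$by_ctx[[ci]]
    site_v[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }

  base_v <- sites$base[site_v]
  pyrim <- base_v %in% c("C", "T")
  cls <- rep(sbs96_classes(), each = 16L)[channel_v]
  alt_pyr <- substr(cls, 3L, 3L)
  ref_v <- base_v
  alt_v <- ifelse(pyrim, alt_pyr, base_complement(alt_pyr))

  passengers <- tibble::tibble(
    tumor_id = tumor_ids[tumor_v],
    chrom = sites$chrom,
    pos = sites$pos[site_v],
    ref = ref_v,
    alt = alt_v,
    gene = sites$gene[site_v],
    in_cosmic = FALSE,
    channel = as.integer(channel_v))
  passengers <- dplyr::distinct(passengers, .data$tumor_id, .data$chrom,
                                .data$pos, .data$ref, .data$alt,
                                .keep_all = TRUE)

  # planted drivers: mu from the pipeline's own rate equation, then a
  # Bernoulli fixation draw at probability 1 - exp(-mu * gamma*)
  composition <- gene_context_composition(reference$genome,
                                          reference$intervals)
  ngmat <- composition_matrix(composition)
  drv <- config$drivers
  driver_rows <- list()
  truth_driver <- list()
  for (i in seq_len(nrow(drv))) {
    g <- drv$gene[i]
    gstart <- reference$intervals$start[match(g, reference$intervals$gene)]
    p_abs <- gstart + drv$offset[i] - 1L
    ch <- channel_index(drv$ref[i], drv$alt[i], drv$context[i])
    R <- gene_rate_lookup(config$gene_rates, g, tumor_ids)
    denom <- as.numeric(P %*% ngmat[g, ])
    mu <- R * P[, ch] / denom
    # selection for a second same-gene mutation is assumed negligible, so
    # drivers fix only in tumors without another variant of the gene -- the
    # generative converse of the estimator's same-gene exclusion rule
    eligible <- !tumor_ids %in% passengers$tumor_id[passengers$gene == g]
    carrier <- eligible & stats::runif(n) < -expm1(-mu * drv$true_gamma[i])
    key <- paste0(sites$chrom, ":", p_abs, ":", drv$ref[i], ">", drv$alt[i])
    truth_driver[[i]] <- tibble::tibble(
      tumor_id = tumor_ids, gene = g, variant_key = key, mu = mu,
      carrier = carrier, true_gamma = drv$true_gamma[i])
    if (any(carrier)) {
      driver_rows[[i]] <- tibble::tibble(
        tumor_id = tumor_ids[carrier], chrom = sites$chrom, pos = p_abs,
        ref = drv$ref[i], alt = drv$alt[i], gene = g, in_cosmic = TRUE,
        channel = as.integer(ch))
    }
  }

  # keep planted driver sites out of the passenger pool so the truth table's
  # carrier flags match the MAF rows exactly
  driver_keys <- unique(unlist(lapply(truth_driver, function(t) t$variant_key)))
  if (length(driver_keys)) {
    passengers <- passengers[!variant_key(passengers) %in% driver_keys, ,
                             drop = FALSE]
  }
  all_rows <- dplyr::bind_rows(passengers, dplyr::bind_rows(driver_rows))
  m <- nrow(all_rows)
  depth <- 120L
  t_alt <- pmax(6L, stats::rbinom(m, depth, stats::runif(m, 0.25, 0.55)))
  chars <- strsplit(reference$genome[[1]], "")[[1]]
  ctx_all <- paste0(chars[all_rows$pos - 1L], chars[all_rows$pos],
                    chars[all_rows$pos + 1L])

  variants <- tibble::tibble(
    tumor_id = all_rows$tumor_id,
    chrom = all_rows$chrom,
    pos = all_rows$pos,
    ref = all_rows$ref,
    alt = all_rows$alt,
    gene = all_rows$gene,
    variant_classification = "Missense_Mutation",
    t_alt_count = t_alt,
    t_ref_count = depth - t_alt,
    n_alt_count = 0L,
    n_ref_count = depth,
    gnomad_max_subpop_af = 0,
    in_cosmic = all_rows$in_cosmic,
    is_snv = TRUE,
    context = ctx_all,
    channel = all_rows$channel) |>
    dplyr::arrange(.data$tumor_id, .data$chrom, .data$pos)

  truth <- list(
    weights = dplyr::bind_cols(tibble::tibble(tumor_id = tumor_ids),
                               tibble::as_tibble(W)),
    passengers = tibble::tibble(tumor_id = tumor_ids, n_passengers = N),
    drivers = if (length(truth_driver)) dplyr::bind_rows(truth_driver) else
      tibble::tibble(),
    seed = seed)

  structure(list(variants = variants, reference = reference,
                 composition = composition, truth = truth,
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d tumor(s), %d variant row(s), seed %d\n",
              x$config$n_tumors, nrow(x$variants), x$truth$seed))
  invisible(x)
}

#' Write a simulated cohort to disk as pipeline inputs
#'
#' Writes exactly the files the estimation pipeline consumes: the MAF
#' (`cohort.maf.tsv`), reference FASTA (`reference.fa`), gene intervals
#' BED (`genes.bed`), baseline rate table (`gene_rates.tsv`), and the
#' machine-readable ground truth (`truth.json`).
#'
#' @param sim A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(maf = file.path(dir, "cohort.maf.tsv"),
             fasta = file.path(dir, "reference.fa"),
             bed = file.path(dir, "genes.bed"),
             gene_rates = file.path(dir, "gene_rates.tsv"),
             truth = file.path(dir, "truth.json"))
  write_maf(sim$variants, paths["maf"])
  write_reference(sim$reference$genome, paths["fasta"])
  write_bed(sim$reference$intervals, paths["bed"])
  write_gene_rates(sim$config$gene_rates, paths["gene_rates"])
  write_truth(sim$truth, paths["truth"])
  invisible(paths)
}

#' Write simulation ground truth as JSON
#'
#' Schema: `weights` (rows: tumor_id plus one weight per signature),
#' `passengers` (tumor_id, n_passengers), `drivers` (tumor_id, gene,
#' variant_key, mu, carrier, true_gamma), `seed`.
#'
#' @param truth The `$truth` element of a `simulated_cohort`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$weights <- tibble::as_tibble(raw$weights)
  raw$passengers <- tibble::as_tibble(raw$passengers)
  raw$drivers <- tibble::as_tibble(raw$drivers)
  raw
}
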