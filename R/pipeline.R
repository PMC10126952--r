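pipeline_stages <- c("simulate", "filter", "spectra", "fit-signatures",
                     "effects", "attribute", "scan-motifs", "report", "all")

need_file <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("stage '%s': missing expected input file '%s'", stage,
                 path %||% "<unset>"), call. = FALSE)
  }
  path
}

#' Assemble a pipeline run configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. Any
#' field can also be supplied through a YAML or JSON file via
#' [read_run_config()]. When `simulate = TRUE` the input paths are
#' produced by the synthetic generator instead of being read.
#'
#' @param maf,fasta,bed,catalog_file,gene_rates_file Input paths. The
#'   catalog file is optional; by default the bundled synthetic catalog is
#'   used.
#' @param artifacts Signature names flagged as artifacts when reading
#'   `catalog_file`.
#' @param filter A [filter_config()].
#' @param min_weight,stop_tol Signature-fit parameters
#'   ([fit_signatures()]).
#' @param min_carriers,gamma_max,tol Effect-size parameters
#'   ([estimate_effect_sizes()]).
#' @param apobec Signature names tagged APOBEC for reporting.
#' @param simulate Generate inputs with [simulate_cohort()] first.
#' @param simulation A [simulation_config()] (used when `simulate`).
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(maf = NULL, fasta = NULL, bed = NULL,
                       catalog_file = NULL, gene_rates_file = NULL,
                       artifacts = character(),
                       filter = filter_config(),
                       min_weight = 0.06, stop_tol = 1e-3,
                       min_carriers = 2L, gamma_max = 1e12, tol = 1e-8,
                       apobec = NULL, simulate = FALSE,
                       simulation = simulation_config(), seed = 1L) {
  structure(list(maf = maf, fasta = fasta, bed = bed,
                 catalog_file = catalog_file,
                 gene_rates_file = gene_rates_file, artifacts = artifacts,
                 filter = filter, min_weight = min_weight,
                 stop_tol = stop_tol, min_carriers = as.integer(min_carriers),
                 gamma_max = gamma_max, tol = tol, apobec = apobec,
                 simulate = isTRUE(simulate), simulation = simulation,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file. Fields
#'   mirror the arguments of `run_config()`; `filter` may be a mapping of
#'   [filter_config()] arguments.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_config, raw$filter)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  do.call(run_config, raw)
}

load_pipeline_catalog <- function(config) {
  if (is.null(config$catalog_file)) return(synthetic_signature_catalog())
  read_signature_catalog(config$catalog_file, artifacts = config$artifacts)
}

# reconstruct an effect_fit (with carrier lists) from its TSV plus the
# filtered variant table, for stage-wise runs
rebuild_effect_fit <- function(estimates, variants, tumor_ids, min_carriers) {
  keys <- variant_key(variants)
  estimates$carriers <- lapply(estimates$variant_key, function(k) {
    sort(unique(variants$tumor_id[keys == k & variants$tumor_id %in% tumor_ids]))
  })
  structure(list(estimates = estimates, rates = tibble::tibble(),
                 min_carriers = min_carriers),
            class = "effect_fit")
}

#' Run the estimation pipeline
#'
#' Chains the package's stages behind one entry point. Each stage reads
#' its predecessors' outputs from `output_dir` and writes its own, so
#' stages can be run one at a time or all at once (`stage = "all"`). A
#' manifest (`manifest.json`) with the package version, seed and a
#' configuration hash is written at the end; outputs are pure functions of
#' (inputs, configuration, seed).
#'
#' Stages: `simulate` (synthetic inputs), `filter` (context annotation and
#' post-calling filters), `spectra` (recurrent-variant removal and
#' 96-channel spectra), `fit-signatures` (weight deconvolution), `effects`
#' (per-variant effect-size MLE), `attribute` (signature attribution and
#' summaries), `scan-motifs` (TC-site scan of the bundled substrates),
#' `report` (ranked summary tables).
#'
#' @param config A [run_config()] (or a path readable by
#'   [read_run_config()]).
#' @param stage One of `"simulate"`, `"filter"`, `"spectra"`,
#'   `"fit-signatures"`, `"effects"`, `"attribute"`, `"scan-motifs"`,
#'   `"report"`, `"all"`.
#' @param output_dir Directory for stage outputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config, stage = "all", output_dir = "sigfx_out",
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage, pipeline_stages)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- function(name) file.path(output_dir, name)
  written <- list()

  stages <- if (stage == "all") {
    c(if (config$simulate) "simulate", "filter", "spectra", "fit-signatures",
      "effects", "attribute", "scan-motifs", "report")
  } else stage

  catalog <- load_pipeline_catalog(config)

  if ("simulate" %in% stages) {
    say("simulate: generating synthetic cohort (seed %d)", config$seed)
    sim <- simulate_cohort(config$simulation, seed = config$seed)
    paths <- write_cohort(sim, output_dir)
    config$maf <- paths[["maf"]]; config$fasta <- paths[["fasta"]]
    config$bed <- paths[["bed"]]; config$gene_rates_file <- paths[["gene_rates"]]
    catalog <- config$simulation$catalog
    written <- c(written, as.list(paths))
  } else if (config$simulate || is.null(config$maf)) {
    # stage-wise runs after an earlier simulate stage pick inputs up from disk
    config$maf <- config$maf %||% out("cohort.maf.tsv")
    config$fasta <- config$fasta %||% out("reference.fa")
    config$bed <- config$bed %||% out("genes.bed")
    config$gene_rates_file <- config$gene_rates_file %||% out("gene_rates.tsv")
    if (config$simulate) catalog <- config$simulation$catalog
  }

  if ("filter" %in% stages) {
    variants <- read_maf(need_file(config$maf, "filter"))
    genome <- read_reference(need_file(config$fasta, "filter"))
    variants <- annotate_contexts(variants, genome)
    res <- apply_filters(variants, config$filter)
    say("filter: %d of %d variant row(s) retained", nrow(res$variants),
        nrow(variants))
    readr::write_tsv(res$variants, out("filtered_variants.tsv"), progress = FALSE)
    write_filter_report(res$report, out("filter_report.tsv"))
    written$filtered <- out("filtered_variants.tsv")
    written$filter_report <- out("filter_report.tsv")
  }

  read_filtered <- function(stage) {
    path <- need_file(out("filtered_variants.tsv"), stage)
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }

  if ("spectra" %in% stages) {
    variants <- read_filtered("spectra")
    passengers <- remove_recurrent(variants)
    spectra <- build_spectra(passengers,
                             tumor_ids = sort(unique(variants$tumor_id)))
    say("spectra: %d tumor(s), %d passenger substitution(s)",
        nrow(spectra), sum(spectra$total))
    readr::write_tsv(spectra, out("spectra.tsv"), progress = FALSE)
    written$spectra <- out("spectra.tsv")
  }

  if ("fit-signatures" %in% stages) {
    spectra <- readr::read_tsv(need_file(out("spectra.tsv"), "fit-signatures"),
                               show_col_types = FALSE, progress = FALSE)
    fit <- fit_signatures(spectra, catalog, min_weight = config$min_weight,
                          stop_tol = config$stop_tol)
    say("fit-signatures: fitted %d tumor(s), dropped %d", nrow(fit$weights),
        nrow(fit$dropped))
    write_weights(fit, out("weights.tsv"))
    written$weights <- out("weights.tsv")
  }

  if ("effects" %in% stages) {
    variants <- read_filtered("effects")
    weights <- readr::read_tsv(need_file(out("weights.tsv"), "effects"),
                               show_col_types = FALSE, progress = FALSE)
    genome <- read_reference(need_file(config$fasta, "effects"))
    intervals <- read_bed(need_file(config$bed, "effects"))
    gene_rates <- read_gene_rates(need_file(config$gene_rates_file, "effects"))
    composition <- gene_context_composition(genome, intervals)
    effects <- estimate_effect_sizes(variants, weights, catalog, gene_rates,
                                     composition,
                                     min_carriers = config$min_carriers,
                                     gamma_max = config$gamma_max,
                                     tol = config$tol)
    say("effects: %d recurrent variant(s) estimated", nrow(effects$estimates))
    write_effects(effects, out("effects.tsv"))
    written$effects <- out("effects.tsv")
  }

  if ("attribute" %in% stages) {
    variants <- read_filtered("attribute")
    weights <- readr::read_tsv(need_file(out("weights.tsv"), "attribute"),
                               show_col_types = FALSE, progress = FALSE)
    estimates <- readr::read_tsv(need_file(out("effects.tsv"), "attribute"),
                                 show_col_types = FALSE, progress = FALSE)
    effects <- rebuild_effect_fit(estimates, variants, weights$tumor_id,
                                  config$min_carriers)
    records <- attribute_effects(effects, weights, catalog)
    say("attribute: %d attribution record(s)", nrow(records))
    write_attribution(records, out("attribution.tsv"))
    written$attribution <- out("attribution.tsv")
    if (nrow(records)) {
      readr::write_tsv(mean_relative_attributable_effect(records),
                       out("attributable_effect_summary.tsv"), progress = FALSE)
      vst <- variant_signature_table(records) |>
        dplyr::select(-"effects")
      readr::write_tsv(vst, out("variant_signature_summary.tsv"),
                       progress = FALSE)
      written$effect_summary <- out("attributable_effect_summary.tsv")
      written$variant_summary <- out("variant_signature_summary.tsv")
    }
  }

  if ("scan-motifs" %in% stages) {
    oligos <- nfe2l2_substrates()
    sites <- dplyr::bind_rows(lapply(seq_len(nrow(oligos)), function(i) {
      find_tc_sites(oligos$sequence[i], strand = oligos$strand[i])
    }))
    say("scan-motifs: %d TC site(s) across %d substrate(s)", nrow(sites),
        nrow(oligos))
    readr::write_tsv(sites, out("motif_sites.tsv"), progress = FALSE)
    written$motif_sites <- out("motif_sites.tsv")
  }

  if ("report" %in% stages) {
    weights_path <- out("weights.tsv")
    if (file.exists(weights_path)) {
      weights <- readr::read_tsv(weights_path, show_col_types = FALSE,
                                 progress = FALSE)
      long <- tidyr::pivot_longer(
        weights, cols = dplyr::all_of(intersect(catalog$names, names(weights))),
        names_to = "signature", values_to = "weight")
      readr::write_tsv(mean_signature_weights(long),
                       out("signature_weight_summary.tsv"), progress = FALSE)
      written$weight_summary <- out("signature_weight_summary.tsv")
    }
    manifest <- list(package = "sigfx",
                     version = as.character(utils::packageVersion("sigfx")),
                     seed = config$seed,
                     stage = stage,
                     config_hash = rlang::hash(config))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    written$manifest <- out("manifest.json")
  }

  invisible(written)
}
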