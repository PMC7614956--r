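#' Pipeline configuration
#'
#' One flat document collecting every tunable of the design-to-statistics
#' workflow. Defaults are the screen's published operating point: a
#' 400/100 bp TSS window with six 50-bp promoter bins, a minimum off-target
#' distance of 3 mismatches, four guides per 190-bp oligo, droplet loading
#' mean 0.4, and enrichment gates log2FC > 3 at FDR < 0.05. Unknown keys are
#' rejected.
#'
#' @param ... Overrides of the defaults listed by `pipeline_config()`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    window_upstream = 400, window_downstream = 100,
    bin_region = 300, bin_width = 50, max_per_feature = 6,
    pam = "NGG", protospacer_len = 20,
    min_mm = 3,
    guides_per_oligo = 4L,
    lam = 0.4,
    lfc_threshold = 3, fdr_threshold = 0.05,
    gene_fdr_threshold = 0.3,
    min_cpm = 1, min_samples = 0.5,
    flank = "GTTTAAGAGCTAAGCTG",
    genome = NULL, features = NULL, out_dir = ".",
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

config_design_params <- function(config) {
  design_params(window_upstream = config$window_upstream,
                window_downstream = config$window_downstream,
                bin_region = config$bin_region,
                bin_width = config$bin_width,
                max_per_feature = config$max_per_feature,
                pam = config$pam,
                protospacer_len = config$protospacer_len)
}

#' Run the design-to-statistics pipeline
#'
#' Wires the modules into the screen workflow: guide design with off-target
#' filtering, oligo packing with a digest check, then (when a count table or
#' FASTQ + sample sheet are supplied, or under [demo_pipeline()]'s
#' simulation) guide counting and enrichment testing. All outputs are
#' written under `config$out_dir` together with a provenance manifest
#' (package version, parameters, input checksums). Deterministic for a
#' given configuration, including the seed.
#'
#' @param config A [pipeline_config()].
#' @param genome Optional preloaded `genome` (else `config$genome` is read).
#' @param features Optional preloaded feature `data.frame`.
#' @param counts Optional `count_table` to test; if `NULL` and `simulate`
#'   is `TRUE`, a spiked screen is simulated over the designed library.
#' @param simulate Simulate reads/counts for a demo run (default `FALSE`).
#' @return Invisible list of the main artifacts: `library`, `pool`,
#'   `released`, and when statistics ran `test` plus `genes`.
#' @export
run_pipeline <- function(config = pipeline_config(), genome = NULL,
                         features = NULL, counts = NULL, simulate = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- character(0)
  if (is.null(genome)) {
    if (is.null(config$genome))
      stop("stage design: no genome given (set config$genome); ",
           "pass --genome or supply a genome object")
    if (!file.exists(config$genome))
      stop("stage design: genome path not found: ", config$genome)
    checksums["genome"] <- unname(tools::md5sum(config$genome))
    genome <- read_genome(config$genome)
  }
  if (is.null(features)) {
    if (is.null(config$features))
      stop("stage design: no feature annotation given (set config$features)")
    if (!file.exists(config$features))
      stop("stage design: feature path not found: ", config$features)
    checksums["features"] <- unname(tools::md5sum(config$features))
    features <- read_features(config$features)
  }
  params <- config_design_params(config)
  library <- design_library(genome, features, params, min_mm = config$min_mm)
  lib_path <- file.path(config$out_dir, "library.tsv")
  write_guide_library(library, lib_path)
  write_guide_fasta(library, file.path(config$out_dir, "library.fa"))

  layout <- cassette_layout(guides_per_oligo = config$guides_per_oligo)
  pool <- pack_oligos(library, layout)
  write_oligo_pool(pool, file.path(config$out_dir, "pool.fa"),
                   file.path(config$out_dir, "pool_manifest.tsv"))
  released <- digest_pool(pool, layout$recognition,
                          library = unique(pool$guide_seq))
  if (!setequal(intersect(released, library$protospacer),
                library$protospacer))
    stop("stage pack: digest failed to release every packed guide")

  test <- NULL; genes <- NULL
  if (simulate && is.null(counts)) {
    sim <- simulate_screen_counts(screen_sim_params(
      n_guides = nrow(library), spike_fraction = 0.05, seed = config$seed))
    rownames(sim$table$counts) <- library$guide_id
    names(sim$truth) <- library$guide_id
    reads <- simulate_reads(sim$table, library, flank = config$flank,
                            seed = config$seed)
    demux <- demultiplex(reads, sim$table$samples)
    counts <- count_guides(demux, library, config$flank, sim$table$samples)
    write_count_table(counts, file.path(config$out_dir, "counts.tsv"))
  }
  if (!is.null(counts)) {
    test <- screen_test(counts, lfc_threshold = config$lfc_threshold,
                        fdr_threshold = config$fdr_threshold,
                        min_cpm = config$min_cpm,
                        min_samples = config$min_samples)
    write_results(test, file.path(config$out_dir, "results.tsv"))
    map <- sub("_g[0-9]+$", "", test$results$guide_id)
    names(map) <- test$results$guide_id
    genes <- summarize_genes(test$results, map,
                             lfc_threshold = config$lfc_threshold,
                             fdr_threshold = config$gene_fdr_threshold)
    utils::write.table(genes, file.path(config$out_dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "crisprscreen",
    version = as.character(utils::packageVersion("crisprscreen")),
    parameters = unclass(config)[!vapply(config, is.null, logical(1))],
    input_md5 = as.list(checksums),
    n_features = nrow(features),
    n_guides = nrow(library),
    n_oligos = length(oligo_sequences(pool))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(library = library, pool = pool, released = released,
                 test = test, genes = genes))
}

#' Run the full pipeline end-to-end on simulated data
#'
#' Generates a toy genome with plantable promoter PAM sites, designs and
#' packs a library, simulates a spiked screen read-out, and runs the
#' enrichment statistics — a smoke test of every stage that needs no
#' external data.
#'
#' @param seed Integer seed driving all randomness.
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param n_features Number of simulated features (default 12).
#' @return Invisible artifact list as in [run_pipeline()].
#' @export
demo_pipeline <- function(seed = 1, out_dir = tempfile("crisprscreen_demo_"),
                          n_features = 12) {
  sim <- simulate_genome(n_features = n_features, promoter_pam_min = 6,
                         length = max(20000, n_features * 750 + 500),
                         seed = seed)
  config <- pipeline_config(out_dir = out_dir, seed = as.integer(seed))
  run_pipeline(config, genome = sim$genome, features = sim$features,
               simulate = TRUE)
}
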