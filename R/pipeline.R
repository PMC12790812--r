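# End-to-end orchestration: abundance -> amplicons -> templates -> read
# simulation -> consolidation, from one validated config.

#' Simulation run configuration
#'
#' @param n_samples Number of samples (must match the barcode table).
#' @param reads_per_sample Sequencing depth per sample.
#' @param abundance_dist One of `"uniform"`, `"lognormal"`, `"powerlaw"`,
#'   `"empirical"`.
#' @param abundance_params Named list of distribution parameters (see
#'   [sample_genome_molarity()]).
#' @param subread_accuracy Per-base no-error probability of a single pass
#'   (default 0.65).
#' @param error_ratio Substitution:insertion:deletion weights (default
#'   `c(6, 55, 39)`).
#' @param np_source `"lognormal"` or `"empirical"`.
#' @param np_min,np_max Pass-number range (defaults 2 and 59).
#' @param np_meanlog,np_sdlog Lognormal pass-number parameters (defaults
#'   2.3 and 0.5, giving a mode around 8-10 passes).
#' @param np_table Histogram tibble (`np`, `count`) or TSV path, required
#'   when `np_source = "empirical"`.
#' @param seed Integer run seed; drives every random stage.
#' @param primer_fwd,primer_rev IUPAC primers (defaults: the 27F/1492R
#'   full-length 16S pair).
#' @param max_primer_mismatch Per-primer mismatch budget for extraction.
#' @param min_amplicon_len,max_amplicon_len Product length window applied
#'   at extraction (defaults: no filter).
#' @param primer_mode `"oligo"` or `"genomic"` (see [assign_templates()]).
#' @param variability A [variability_model()].
#' @param variability_per `"cell"` or `"feature"`.
#' @return A validated `hifisim_config` object.
#' @export
run_config <- function(n_samples = 2L,
                       reads_per_sample = 100L,
                       abundance_dist = "uniform",
                       abundance_params = list(),
                       subread_accuracy = 0.65,
                       error_ratio = c(6, 55, 39),
                       np_source = c("lognormal", "empirical"),
                       np_min = 2L, np_max = 59L,
                       np_meanlog = 2.3, np_sdlog = 0.5,
                       np_table = NULL,
                       seed = 1L,
                       primer_fwd = "AGRGTTYGATYMTGGCTCAG",
                       primer_rev = "RGYTACCTTGTTACGACTT",
                       max_primer_mismatch = 2L,
                       min_amplicon_len = 0,
                       max_amplicon_len = Inf,
                       primer_mode = c("oligo", "genomic"),
                       variability = variability_model(),
                       variability_per = c("cell", "feature")) {
  np_source <- match.arg(np_source)
  primer_mode <- match.arg(primer_mode)
  variability_per <- match.arg(variability_per)
  if (!inherits(variability, "hifisim_variability")) {
    # e.g. a plain list deserialized from a YAML/JSON config
    variability <- do.call(variability_model, as.list(variability))
  }
  if (!is.null(np_table) && !is.character(np_table)) {
    np_table <- tibble::as_tibble(as.list(np_table))
  }
  stopifnot(
    n_samples >= 1, reads_per_sample > 0,
    subread_accuracy > 0, subread_accuracy <= 1,
    length(error_ratio) == 3, all(error_ratio >= 0), sum(error_ratio) > 0,
    np_min >= 1, np_max >= np_min,
    max_primer_mismatch >= 0, min_amplicon_len <= max_amplicon_len
  )
  .check_iupac(c(toupper(primer_fwd), toupper(primer_rev)), "primer")
  if (np_source == "empirical" && is.null(np_table)) {
    stop("np_source = 'empirical' requires np_table", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         reads_per_sample = as.integer(reads_per_sample),
         abundance_dist = abundance_dist,
         abundance_params = abundance_params,
         subread_accuracy = subread_accuracy,
         error_ratio = as.numeric(error_ratio),
         np_source = np_source,
         np_min = as.integer(np_min), np_max = as.integer(np_max),
         np_meanlog = np_meanlog, np_sdlog = np_sdlog,
         np_table = np_table,
         seed = as.integer(seed),
         primer_fwd = toupper(primer_fwd),
         primer_rev = toupper(primer_rev),
         max_primer_mismatch = as.integer(max_primer_mismatch),
         min_amplicon_len = min_amplicon_len,
         max_amplicon_len = max_amplicon_len,
         primer_mode = primer_mode,
         variability = variability,
         variability_per = variability_per),
    class = "hifisim_config"
  )
}

#' @export
print.hifisim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<hifisim run config: %d samples x %d reads, %s abundances, ",
           "accuracy %.2f, np %s [%d, %d], seed %d>\n"),
    x$n_samples, x$reads_per_sample, x$abundance_dist, x$subread_accuracy,
    x$np_source, x$np_min, x$np_max, x$seed))
  invisible(x)
}

#' Pass-number distribution implied by a config
#'
#' @param config A `hifisim_config`.
#' @return A `hifisim_np` object.
#' @export
as_np_distribution <- function(config) {
  stopifnot(inherits(config, "hifisim_config"))
  if (config$np_source == "empirical") {
    tbl <- config$np_table
    if (is.character(tbl)) tbl <- read_np_table(tbl)
    np_empirical(tbl, np_min = config$np_min, np_max = config$np_max)
  } else {
    np_lognormal(meanlog = config$np_meanlog, sdlog = config$np_sdlog,
                 np_min = config$np_min, np_max = config$np_max)
  }
}

#' Run the full simulation pipeline
#'
#' Executes abundance simulation, in-silico PCR, template assignment,
#' subread + consensus simulation, and consolidation. With an `out_dir`,
#' writes `reads.fastq`, `ground_truth.tsv`, `asv_catalog.tsv`,
#' `counts.tsv` and `manifest.json`. The run is fully determined by
#' (config, genomes, barcodes): a fixed seed gives byte-identical output
#' for any worker count.
#'
#' @param config A [run_config()].
#' @param genomes Genome tibble (`id`, `seq`), e.g. from [read_fasta()].
#' @param barcodes Barcode tibble (`sample_id`, `fwd_barcode`,
#'   `rev_barcode`) with `n_samples` rows.
#' @param out_dir Optional output directory (created if missing).
#' @param workers Parallel workers for the per-ZMW stage.
#' @return A `hifisim_manifest` list: per-stage counts and timings, the
#'   config, and the in-memory tables (`amplicons`, `catalog`, `counts`,
#'   `templates`, `reads`).
#' @export
run_pipeline <- function(config, genomes, barcodes, out_dir = NULL,
                         workers = 1L) {
  stopifnot(inherits(config, "hifisim_config"))
  barcodes <- validate_barcodes(barcodes)
  if (nrow(barcodes) != config$n_samples) {
    stop(sprintf("barcode table has %d samples but config says %d",
                 nrow(barcodes), config$n_samples), call. = FALSE)
  }
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  amplicons <- stage("amplicons", extract_amplicons(
    genomes, config$primer_fwd, config$primer_rev,
    max_mismatch = config$max_primer_mismatch,
    min_len = config$min_amplicon_len, max_len = config$max_amplicon_len))
  if (nrow(amplicons) == 0) {
    stop("no extractable amplicons in any genome; check primers and length window",
         call. = FALSE)
  }
  catalog <- asv_catalog(amplicons)

  abundance <- stage("abundance", {
    ab <- build_abundance_matrix(
      genomes$id, barcodes$sample_id,
      dist = config$abundance_dist, params = config$abundance_params,
      model = config$variability, variability_per = config$variability_per,
      seed = .substream(config$seed, "abundance"))
    expand_to_asv(ab, catalog)
  })
  counts <- stage("counts", simulate_counts(
    abundance, depth = config$reads_per_sample,
    seed = .substream(config$seed, "counts")))

  templates <- stage("templates", assign_templates(
    counts, catalog, barcodes, config$primer_fwd, config$primer_rev,
    primer_mode = config$primer_mode,
    seed = .substream(config$seed, "templates")))

  reads <- stage("reads", simulate_reads(
    templates, np_dist = as_np_distribution(config),
    model = error_model(config$subread_accuracy, config$error_ratio),
    seed = .substream(config$seed, "readsim"), workers = workers))
  reads <- dplyr::arrange(reads, .data$read_id)

  manifest <- structure(
    list(
      config = config, seed = config$seed,
      n_genomes = nrow(genomes), n_samples = nrow(barcodes),
      n_amplicons = nrow(amplicons), n_asvs = nrow(catalog),
      n_templates = nrow(templates),
      n_zmws = sum(templates$copies), n_reads = nrow(reads),
      timings = timings,
      amplicons = amplicons, catalog = catalog, counts = counts,
      templates = templates, reads = reads,
      files = NULL
    ),
    class = "hifisim_manifest"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      fastq = file.path(out_dir, "reads.fastq"),
      ground_truth = file.path(out_dir, "ground_truth.tsv"),
      asv_catalog = file.path(out_dir, "asv_catalog.tsv"),
      counts = file.path(out_dir, "counts.tsv"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_fastq(reads, files$fastq)
    write_ground_truth(reads, files$ground_truth)
    readr::write_tsv(catalog, files$asv_catalog)
    readr::write_tsv(counts, files$counts)
    jsonlite::write_json(
      list(seed = config$seed, n_genomes = manifest$n_genomes,
           n_samples = manifest$n_samples, n_amplicons = manifest$n_amplicons,
           n_asvs = manifest$n_asvs, n_templates = manifest$n_templates,
           n_zmws = manifest$n_zmws, n_reads = manifest$n_reads,
           timings = as.list(timings)),
      files$manifest, auto_unbox = TRUE, digits = NA)
    manifest$files <- files
  }
  manifest
}

#' @export
print.hifisim_manifest <- function(x, ...) {
  cat(sprintf(
    paste0("<hifisim run: %d genomes, %d samples, %d ASVs, %d templates, ",
           "%d ZMWs -> %d reads>\n"),
    x$n_genomes, x$n_samples, x$n_asvs, x$n_templates, x$n_zmws, x$n_reads))
  invisible(x)
}

#' @method glance hifisim_manifest
#' @export
glance.hifisim_manifest <- function(x, ...) {
  tibble::tibble(
    n_genomes = x$n_genomes, n_samples = x$n_samples,
    n_amplicons = x$n_amplicons, n_asvs = x$n_asvs,
    n_templates = x$n_templates, n_zmws = x$n_zmws, n_reads = x$n_reads,
    elapsed_s = sum(unlist(x$timings))
  )
}
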