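#' Assemble a pipeline run configuration
#'
#' Collects every stage parameter with the package defaults (capture flank
#' cap 4500 bp; 120-nt probes with 17-nt overlap; strict >10-hit
#' specificity filter; pseudocount 1; untreated wild type as the reference
#' condition; 3 x 3 clustering) plus input/output paths. Values given in
#' `...` override the defaults; a YAML file read with [read_config()]
#' round-trips through this constructor.
#'
#' @param ... Named overrides of any default parameter or path.
#' @return A named list of class `quantcap_config`.
#' @export
quantcap_config <- function(...) {
  defaults <- list(
    # inputs
    genome = NULL, gff = NULL, repeats = NULL, genes = NULL,
    sample_sheet = NULL, counts = NULL,
    out_dir = "quantcap_out",
    # design
    flank_cap = 4500L, bait_len = 120L, overlap = 17L, max_hits = 10L,
    mask_policy = "exclude",
    # quantification
    negative_controls = character(0),
    # normalization / profiling
    control_genes = character(0), gof_k = NULL, gof_threshold = NULL,
    reference = "wt_un", pseudocount = 1,
    # clustering / correlation
    k_genes = 3L, k_conditions = 3L, gene_distance = "pearson",
    condition_distance = "euclidean", linkage = "average",
    cor_method = "pearson",
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  # YAML round trip: empty character vectors come back as lists
  for (key in c("negative_controls", "control_genes")) {
    config[[key]] <- as.character(unlist(config[[key]]))
  }
  structure(config, class = "quantcap_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of config keys (flat key-value mapping).
#' @return A `quantcap_config`; unknown keys are an error, so a written
#'   config echoes back identically.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(quantcap_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `quantcap_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the capture-seq pipeline
#'
#' Executes the requested stages in dependency order over the configured
#' inputs, writing every artifact plus a JSON run manifest (package
#' version, every effective parameter, input checksums, output files) into
#' `config$out_dir`. Numeric outputs are identical across reruns with the
#' same config and inputs.
#'
#' Stages and artifacts: `design` (regions BED/FASTA, bait FASTA/BED/
#' report), `count` (counts and coverage TSV, needs a sample sheet CSV
#' with alignment paths), `normalize` (normalized TSV + scale factors),
#' `profile` (log-ratio TSV), `cluster` (z-score and cluster TSVs),
#' `correlate` (correlation TSV).
#'
#' @param config A [quantcap_config()].
#' @param stages Character vector of stages to run.
#' @return Named list of produced artifact paths (and in-memory results),
#'   invisibly.
#' @export
run_pipeline <- function(config = quantcap_config(),
                         stages = c("design", "count", "normalize",
                                    "profile", "cluster", "correlate")) {
  stopifnot(inherits(config, "quantcap_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  results <- list()
  inputs <- character(0)
  need <- function(key) {
    if (is.null(config[[key]])) {
      stop("config$", key, " required for requested stages", call. = FALSE)
    }
    if (!file.exists(config[[key]])) {
      stop("input not found: ", config[[key]], call. = FALSE)
    }
    inputs[[key]] <<- config[[key]]
    config[[key]]
  }
  out <- function(name) file.path(config$out_dir, name)

  regions <- NULL
  if ("design" %in% stages) {
    genome <- read_genome(need("genome"))
    models <- read_gene_models(need("gff"), genome)
    targets <- if (!is.null(config$genes)) readLines(need("genes")) else NULL
    regions <- build_target_regions(models, targets = targets,
                                    flank_cap = config$flank_cap)
    masks <- if (!is.null(config$repeats)) read_bed(need("repeats")) else NULL
    write_target_regions(regions, genome, bed_path = out("regions.bed"),
                         fasta_path = out("regions.fa"))
    lib <- design_baits(regions, genome, masks = masks,
                        params = bait_params(config$bait_len, config$overlap,
                                             config$max_hits,
                                             config$mask_policy))
    write_bait_library(lib, fasta_path = out("baits.fa"),
                       bed_path = out("baits.bed"),
                       report_path = out("baits_report.tsv"))
    artifacts <- c(artifacts, list(
      regions_bed = out("regions.bed"), regions_fasta = out("regions.fa"),
      baits_fasta = out("baits.fa"), baits_bed = out("baits.bed"),
      baits_report = out("baits_report.tsv")
    ))
    results$regions <- regions
    results$baits <- lib
  }

  sheet <- NULL
  counts <- NULL
  if ("count" %in% stages) {
    sheet <- readr::read_csv(need("sample_sheet"), show_col_types = FALSE)
    if (is.null(regions)) {
      bed <- read_bed(out("regions.bed"))
      regions <- tibble::tibble(gene_id = bed$name, chrom = bed$chrom,
                                start = bed$start, end = bed$end,
                                strand = bed$strand %||% "+")
    }
    quant <- assemble_matrix(sheet, regions,
                             negative_controls = config$negative_controls)
    readr::write_tsv(quant$counts, out("counts.tsv"))
    readr::write_tsv(quant$coverage, out("coverage.tsv"))
    artifacts <- c(artifacts, list(counts = out("counts.tsv"),
                                   coverage = out("coverage.tsv")))
    counts <- quant$counts
    results$quant <- quant
  }

  norm <- NULL
  if ("normalize" %in% stages) {
    if (is.null(counts)) {
      counts <- readr::read_tsv(need("counts"), show_col_types = FALSE)
    }
    controls <- if (length(config$control_genes)) config$control_genes else counts$gene_id
    norm <- normalize_counts(counts, controls, k = config$gof_k,
                             threshold = config$gof_threshold)
    readr::write_tsv(norm$normalized, out("normalized.tsv"))
    readr::write_tsv(
      tibble::tibble(sample_id = names(norm$scale_factors),
                     scale_factor = unname(norm$scale_factors)),
      out("scale_factors.tsv"))
    readr::write_tsv(norm$gof, out("gof.tsv"))
    artifacts <- c(artifacts, list(normalized = out("normalized.tsv"),
                                   scale_factors = out("scale_factors.tsv"),
                                   gof = out("gof.tsv")))
    results$norm <- norm
  }

  profile <- NULL
  if ("profile" %in% stages) {
    if (is.null(norm)) stop("profile stage needs the normalize stage", call. = FALSE)
    if (is.null(sheet)) sheet <- readr::read_csv(need("sample_sheet"),
                                                 show_col_types = FALSE)
    profile <- log_ratio_profile(norm, sheet, reference = config$reference,
                                 pseudocount = config$pseudocount)
    readr::write_tsv(tibble::as_tibble(profile), out("log_ratios.tsv"))
    artifacts <- c(artifacts, list(log_ratios = out("log_ratios.tsv")))
    results$profile <- profile
  }

  if ("cluster" %in% stages) {
    if (is.null(profile)) stop("cluster stage needs the profile stage", call. = FALSE)
    z <- zscore_rows(profile)
    cl <- cluster_profiles(z, k_genes = config$k_genes,
                           k_conditions = config$k_conditions,
                           gene_distance = config$gene_distance,
                           condition_distance = config$condition_distance,
                           linkage = config$linkage)
    readr::write_tsv(z, out("zscores.tsv"))
    readr::write_tsv(cl$gene_labels, out("gene_clusters.tsv"))
    readr::write_tsv(cl$condition_labels, out("condition_clusters.tsv"))
    artifacts <- c(artifacts, list(zscores = out("zscores.tsv"),
                                   gene_clusters = out("gene_clusters.tsv"),
                                   condition_clusters = out("condition_clusters.tsv")))
    results$clusters <- cl
  }

  if ("correlate" %in% stages) {
    basis <- profile %||% norm$normalized %||% counts
    if (is.null(basis)) stop("correlate stage needs counts, normalize or profile",
                             call. = FALSE)
    cm <- correlate_columns(basis, method = config$cor_method)
    readr::write_tsv(tibble::as_tibble(cm), out("correlation.tsv"))
    artifacts <- c(artifacts, list(correlation = out("correlation.tsv")))
    results$correlation <- cm
  }

  manifest <- list(
    package = "quantcap",
    version = as.character(utils::packageVersion("quantcap")),
    stages = stages,
    parameters = unclass(config),
    input_md5 = as.list(tools::md5sum(unname(unlist(inputs)))),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  results$artifacts <- c(artifacts, list(manifest = out("manifest.json")))
  invisible(results)
}
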