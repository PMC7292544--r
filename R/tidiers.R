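#' Tidy a bait library
#'
#' @param x A `bait_library` from [design_baits()].
#' @param ... Unused.
#' @return The bait tibble (one row per designed probe, with status).
#' @method tidy bait_library
#' @export
tidy.bait_library <- function(x, ...) x$baits

#' One-row summary of a bait library
#'
#' @param x A `bait_library`.
#' @param ... Unused.
#' @return One-row tibble with design parameters and status totals.
#' @method glance bait_library
#' @export
glance.bait_library <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$baits$source_gene)),
    n_baits = nrow(x$baits),
    n_kept = sum(x$baits$status == "kept"),
    n_removed_repeat = sum(x$baits$status == "removed_repeat"),
    n_removed_multihit = sum(x$baits$status == "removed_multihit"),
    n_removed_duplicate = sum(x$baits$status == "removed_duplicate"),
    bait_len = x$params$bait_len,
    overlap = x$params$overlap,
    max_hits = x$params$max_hits
  )
}

#' Tidy quantification results
#'
#' @param x A `capture_quant` from [assemble_matrix()].
#' @param ... Unused.
#' @return Long tibble `sample_id`, `material`, `gene_id`, `read_count`,
#'   `covered_bases`, `breadth`, `mean_depth`.
#' @method tidy capture_quant
#' @export
tidy.capture_quant <- function(x, ...) x$coverage

#' One-row summary of quantification results
#'
#' @param x A `capture_quant`.
#' @param ... Unused.
#' @return One-row tibble with sample/region totals and QC flags.
#' @method glance capture_quant
#' @export
glance.capture_quant <- function(x, ...) {
  gdna <- dplyr::filter(x$coverage, .data$material == "gDNA")
  tibble::tibble(
    n_regions = nrow(x$counts),
    n_cdna = sum(x$samples$material == "cDNA"),
    n_gdna = sum(x$samples$material == "gDNA"),
    min_gdna_breadth = if (nrow(gdna)) min(gdna$breadth) else NA_real_,
    contamination_flags = sum(!x$contamination$pass)
  )
}

#' Tidy a normalization fit
#'
#' @param x A `quantcap_norm` from [normalize_counts()].
#' @param ... Unused.
#' @return Long tibble `gene_id`, `sample_id`, `normalized`.
#' @method tidy quantcap_norm
#' @export
tidy.quantcap_norm <- function(x, ...) {
  tidyr::pivot_longer(x$normalized, -"gene_id",
                      names_to = "sample_id", values_to = "normalized")
}

#' One-row summary of a normalization fit
#'
#' @param x A `quantcap_norm`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, number of controls, scale-factor
#'   spread.
#' @method glance quantcap_norm
#' @export
glance.quantcap_norm <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$normalized),
    n_samples = length(x$scale_factors),
    n_controls = length(x$controls),
    sf_min = min(x$scale_factors),
    sf_max = max(x$scale_factors),
    sf_geomean = geo_mean(x$scale_factors)
  )
}

#' Tidy a condition profile
#'
#' @param x A `condition_profile` from [log_ratio_profile()].
#' @param ... Unused.
#' @return Long tibble `gene_id`, `condition`, `log2_ratio`.
#' @method tidy condition_profile
#' @export
tidy.condition_profile <- function(x, ...) {
  out <- tidyr::pivot_longer(tibble::as_tibble(x), -"gene_id",
                             names_to = "condition", values_to = "log2_ratio")
  out
}

#' Tidy a clustering result
#'
#' @param x A `quantcap_clusters` from [cluster_profiles()].
#' @param margin `"genes"` for gene labels, `"conditions"` for condition
#'   groups.
#' @param ... Unused.
#' @return Tibble of item/label assignments.
#' @method tidy quantcap_clusters
#' @export
tidy.quantcap_clusters <- function(x, margin = c("genes", "conditions"), ...) {
  margin <- match.arg(margin)
  if (margin == "genes") x$gene_labels else x$condition_labels
}

#' One-row summary of a clustering result
#'
#' @param x A `quantcap_clusters`.
#' @param ... Unused.
#' @return One-row tibble with cluster counts and settings.
#' @method glance quantcap_clusters
#' @export
glance.quantcap_clusters <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$gene_labels),
    n_conditions = nrow(x$condition_labels),
    k_genes = x$params$k_genes,
    k_conditions = x$params$k_conditions,
    gene_distance = x$params$gene_distance,
    condition_distance = x$params$condition_distance,
    linkage = x$params$linkage
  )
}

#' Tidy a correlation matrix
#'
#' @param x A `quantcap_cor` from [correlate_columns()].
#' @param ... Unused.
#' @return Long tibble `item1`, `item2`, `r` (all ordered pairs).
#' @method tidy quantcap_cor
#' @export
tidy.quantcap_cor <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"item",
                      names_to = "item2", values_to = "r") |>
    dplyr::rename(item1 = "item")
}
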