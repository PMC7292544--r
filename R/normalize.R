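#' Goodness-of-fit scores for control-gene candidates
#'
#' Scores how well each gene's counts track library size across samples,
#' as a Pearson chi-square statistic of the observed row against expected
#' counts proportional to library size:
#' `X^2 = sum_j (O_j - E_j)^2 / E_j` with
#' `E_j = rowSum * libSize_j / sum(libSize)`. A perfectly stable control --
#' counts exactly proportional to library sizes -- scores 0; highly
#' variable genes score large and are poor normalization anchors.
#'
#' @param counts Wide counts tibble (`gene_id` + one column per sample).
#' @param library_sizes Optional named vector of per-sample library sizes;
#'   defaults to the column sums of `counts`.
#' @return Tibble `gene_id`, `gof`, in increasing `gof` order. All-zero
#'   rows score 0 with a warning; negative counts are an error.
#' @export
gof_scores <- function(counts, library_sizes = NULL) {
  m <- counts_to_matrix(counts)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  lib <- library_sizes %||% colSums(m)
  lib <- lib[colnames(m)]
  if (any(lib <= 0)) stop("library sizes must be positive", call. = FALSE)
  row_tot <- rowSums(m)
  # single division so exactly proportional rows give E == O in floating
  # point (and hence a statistic of exactly zero)
  expected <- outer(row_tot, lib) / sum(lib)
  gof <- rowSums((m - expected)^2 / expected)
  zero <- row_tot == 0
  if (any(zero)) {
    warning("all-zero count row(s) score 0: ",
            paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
    gof[zero] <- 0
  }
  tibble::tibble(gene_id = rownames(m), gof = unname(gof)) |>
    dplyr::arrange(.data$gof, .data$gene_id)
}

#' Select control genes by goodness of fit
#'
#' Ranks candidates by increasing goodness-of-fit score (ties broken by
#' gene ID) and keeps either the `k` most stable or all scoring strictly
#' below `threshold`.
#'
#' @param gof Tibble from [gof_scores()] (columns `gene_id`, `gof`).
#' @param k Number of controls to keep.
#' @param threshold Alternative to `k`: keep all with `gof < threshold`.
#' @return The `gof` tibble with a logical `selected` column, ranked.
#'   An empty selection is an error (advising a different threshold).
#' @export
select_controls <- function(gof, k = NULL, threshold = NULL) {
  if (nrow(gof) < 2L) stop("need at least 2 control candidates", call. = FALSE)
  gof <- dplyr::arrange(gof, .data$gof, .data$gene_id)
  if (!is.null(k)) {
    if (k < 1L || k > nrow(gof)) stop("k out of range", call. = FALSE)
    gof$selected <- seq_len(nrow(gof)) <= k
  } else if (!is.null(threshold)) {
    gof$selected <- gof$gof < threshold
  } else {
    gof$selected <- TRUE
  }
  if (!any(gof$selected)) {
    stop("no control gene selected; raise the goodness-of-fit threshold",
         call. = FALSE)
  }
  gof
}

#' Median-of-ratios scale factors from control genes
#'
#' Per control gene, a reference level is its geometric mean across samples
#' (zeros excluded); each sample's factor is the median over controls of
#' `count / reference`, rescaled so the factors have geometric mean 1.
#' Robust to a minority of unstable controls.
#'
#' @param counts Wide counts tibble.
#' @param controls Character vector of control gene IDs (each must be
#'   nonzero in at least one sample).
#' @return Named numeric vector of per-sample scale factors (geometric
#'   mean 1).
#' @export
control_scale_factors <- function(counts, controls) {
  m <- counts_to_matrix(counts)
  missing <- setdiff(controls, rownames(m))
  if (length(missing)) {
    stop("control gene(s) not in counts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cm <- m[controls, , drop = FALSE]
  if (any(rowSums(cm) == 0)) {
    stop("control gene(s) zero in all samples: ",
         paste(controls[rowSums(cm) == 0], collapse = ", "), call. = FALSE)
  }
  ref <- apply(cm, 1L, function(x) geo_mean(x[x > 0]))
  ratios <- cm / ref
  ratios[cm == 0] <- NA # zero in a sample: gene skipped for that median
  factors <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  if (anyNA(factors)) {
    stop("all controls zero in sample(s): ",
         paste(colnames(m)[is.na(factors)], collapse = ", "), call. = FALSE)
  }
  factors / geo_mean(factors)
}

#' Normalize a count matrix on control genes
#'
#' Divides each sample's counts by a control-gene median-of-ratios scale
#' factor. Control candidates may be pre-filtered by goodness of fit with
#' `k` or `threshold` (see [select_controls()]); with neither, all
#' candidates are used.
#'
#' @param counts Wide counts tibble.
#' @param controls Character vector of control-candidate gene IDs.
#' @param k,threshold Optional goodness-of-fit selection among the
#'   candidates.
#' @param library_sizes Optional library sizes for the goodness-of-fit
#'   scores (defaults to full-matrix column sums).
#' @return An object of class `quantcap_norm`: list with `normalized` (wide
#'   tibble), `scale_factors` (named, geometric mean 1), `controls` (those
#'   used), `gof` (scores over the candidates, with `selected`), and `raw`.
#' @export
normalize_counts <- function(counts, controls, k = NULL, threshold = NULL,
                             library_sizes = NULL) {
  gof_all <- gof_scores(counts, library_sizes)
  gof <- dplyr::filter(gof_all, .data$gene_id %in% controls)
  if (!is.null(k) || !is.null(threshold)) {
    gof <- select_controls(gof, k = k, threshold = threshold)
  } else {
    gof$selected <- TRUE
  }
  use <- gof$gene_id[gof$selected]
  factors <- control_scale_factors(counts, use)
  m <- counts_to_matrix(counts)
  norm <- sweep(m, 2L, factors[colnames(m)], `/`)
  structure(
    list(normalized = matrix_to_counts(norm), scale_factors = factors,
         controls = use, gof = gof, raw = counts),
    class = "quantcap_norm"
  )
}

#' @export
print.quantcap_norm <- function(x, ...) {
  cat("<quantcap_norm> ", nrow(x$normalized), " genes x ",
      length(x$scale_factors), " samples; ", length(x$controls),
      " control gene(s); scale factors in [",
      sprintf("%.3f", min(x$scale_factors)), ", ",
      sprintf("%.3f", max(x$scale_factors)), "]\n", sep = "")
  invisible(x)
}

#' Log-ratio condition profiles
#'
#' Averages normalized counts over replicates within each condition
#' (`genotype_treatment`) and expresses every condition as a per-gene log2
#' ratio to the reference condition, with a pseudocount guarding zeros:
#' `log2((mean_cond + pc) / (mean_ref + pc))`. The reference column is
#' identically zero.
#'
#' @param norm A `quantcap_norm` object or wide normalized counts tibble.
#' @param samples Sample sheet tibble (`sample_id`, `genotype`,
#'   `treatment`, `replicate`, `material`); only cDNA samples are used.
#' @param reference Reference condition id (default `"wt_un"`, untreated
#'   wild type).
#' @param pseudocount Pseudocount added to both means.
#' @return An object of class `condition_profile`: wide tibble `gene_id` x
#'   conditions of log2 ratios, with `reference` and `pseudocount`
#'   attributes.
#' @export
log_ratio_profile <- function(norm, samples, reference = "wt_un",
                              pseudocount = 1) {
  counts <- if (inherits(norm, "quantcap_norm")) norm$normalized else norm
  m <- counts_to_matrix(counts)
  sheet <- samples
  if ("material" %in% names(sheet)) sheet <- sheet[sheet$material == "cDNA", ]
  sheet <- sheet[sheet$sample_id %in% colnames(m), , drop = FALSE]
  sheet$condition <- paste(sheet$genotype, sheet$treatment, sep = "_")
  if (!reference %in% sheet$condition) {
    stop("reference condition absent from sample sheet: ", reference,
         call. = FALSE)
  }
  conds <- unique(sheet$condition)
  means <- vapply(conds, function(cc) {
    rowMeans(m[, sheet$sample_id[sheet$condition == cc], drop = FALSE])
  }, numeric(nrow(m)))
  ratios <- log2((means + pseudocount) / (means[, reference] + pseudocount))
  out <- matrix_to_counts(ratios)
  attr(out, "reference") <- reference
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("condition_profile", class(out))
  out
}

#' Row-wise z-scores
#'
#' Standardizes each gene's profile to mean 0 and (sample, `n - 1`
#' denominator) standard deviation 1 across conditions. Constant rows map
#' to all-zeros with a warning.
#'
#' @param profile Wide tibble (`gene_id` + numeric condition columns), e.g.
#'   a [log_ratio_profile()].
#' @return Wide tibble of the same shape with standardized rows.
#' @export
zscore_rows <- function(profile) {
  m <- counts_to_matrix(profile)
  if (ncol(m) < 2L) stop("need at least 2 conditions", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  flat <- sdv == 0 | is.na(sdv)
  if (any(flat)) {
    warning("constant row(s) mapped to zero z-scores: ",
            paste(rownames(m)[flat], collapse = ", "), call. = FALSE)
  }
  z <- (m - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  matrix_to_counts(z)
}

#' Cluster genes and conditions
#'
#' Agglomerative clustering of a z-score matrix along both axes: genes by
#' correlation distance (`1 - Pearson`, the shape of a profile mattering
#' more than its amplitude) and conditions by Euclidean distance, both with
#' average linkage by default; trees are cut at `k_genes` / `k_conditions`.
#' Deterministic given inputs and settings. Rows with undefined
#' correlations (constant rows) sit at the maximum correlation distance, 2.
#'
#' @param z Wide tibble (`gene_id` + numeric condition columns), typically
#'   from [zscore_rows()].
#' @param k_genes,k_conditions Number of clusters per axis (must not exceed
#'   the number of items).
#' @param gene_distance,condition_distance `"pearson"` (1 - r) or
#'   `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `quantcap_clusters`: list with `gene_labels`
#'   and `condition_labels` tibbles, the two `hclust` trees, the z matrix
#'   and the settings.
#' @export
cluster_profiles <- function(z, k_genes = 3L, k_conditions = 3L,
                             gene_distance = c("pearson", "euclidean"),
                             condition_distance = c("euclidean", "pearson"),
                             linkage = "average") {
  gene_distance <- match.arg(gene_distance)
  condition_distance <- match.arg(condition_distance)
  m <- counts_to_matrix(z)
  if (!all(is.finite(m))) stop("z matrix must be finite", call. = FALSE)
  if (k_genes > nrow(m)) stop("k_genes exceeds number of genes", call. = FALSE)
  if (k_conditions > ncol(m)) stop("k_conditions exceeds number of conditions",
                                   call. = FALSE)

  dist_of <- function(mat, how) {
    if (how == "pearson") {
      r <- suppressWarnings(stats::cor(t(mat)))
      d <- 1 - r
      d[is.na(d)] <- 2
      diag(d) <- 0
      stats::as.dist(d)
    } else {
      stats::dist(mat)
    }
  }
  gene_tree <- stats::hclust(dist_of(m, gene_distance), method = linkage)
  cond_tree <- stats::hclust(dist_of(t(m), condition_distance), method = linkage)
  structure(
    list(
      gene_labels = tibble::tibble(
        gene_id = rownames(m),
        cluster = unname(stats::cutree(gene_tree, k = k_genes))
      ),
      condition_labels = tibble::tibble(
        condition = colnames(m),
        group = unname(stats::cutree(cond_tree, k = k_conditions))
      ),
      gene_tree = gene_tree, condition_tree = cond_tree,
      z = z,
      params = list(k_genes = k_genes, k_conditions = k_conditions,
                    gene_distance = gene_distance,
                    condition_distance = condition_distance, linkage = linkage)
    ),
    class = "quantcap_clusters"
  )
}

#' @export
print.quantcap_clusters <- function(x, ...) {
  cat("<quantcap_clusters> ", nrow(x$gene_labels), " genes in ",
      x$params$k_genes, " clusters; ", nrow(x$condition_labels),
      " conditions in ", x$params$k_conditions, " groups\n", sep = "")
  invisible(x)
}

#' Correlation matrix over columns or rows
#'
#' Pairwise Pearson or Spearman correlations over the numeric columns of a
#' wide tibble (samples or conditions), or over its rows (genes) with
#' `margin = "rows"`. Zero-variance vectors give undefined correlations,
#' reported as `NA` with a warning.
#'
#' @param x Wide tibble (`gene_id` + numeric columns).
#' @param method `"pearson"` or `"spearman"`.
#' @param margin Correlate `"columns"` (default) or `"rows"`.
#' @return An object of class `quantcap_cor`: wide tibble with an `item`
#'   column and one column per item, with the method attached as an
#'   attribute.
#' @export
correlate_columns <- function(x, method = c("pearson", "spearman"),
                              margin = c("columns", "rows")) {
  method <- match.arg(method)
  margin <- match.arg(margin)
  m <- counts_to_matrix(x)
  if (margin == "rows") m <- t(m)
  if (ncol(m) < 2L) stop("need at least 2 vectors to correlate", call. = FALSE)
  degenerate <- apply(m, 2L, function(v) stats::sd(v) == 0 || is.na(stats::sd(v)))
  if (any(degenerate)) {
    warning("zero-variance vector(s), correlations undefined (NA): ",
            paste(colnames(m)[degenerate], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, method = method))
  out <- dplyr::bind_cols(tibble::tibble(item = colnames(r)), tibble::as_tibble(r))
  attr(out, "method") <- method
  class(out) <- c("quantcap_cor", class(out))
  out
}

#' Correlation between two condition profiles
#'
#' Pairwise comparison of two columns (e.g. two treatments' log-ratio
#' profiles), reporting r and r-squared alongside the paired values for a
#' scatter plot.
#'
#' @param x Wide tibble (`gene_id` + numeric columns).
#' @param cond_x,cond_y Column names to compare.
#' @param method Correlation method.
#' @return List with `r`, `r_squared`, `n` and `data` (tibble `gene_id`,
#'   `x`, `y`).
#' @export
cor_pair <- function(x, cond_x, cond_y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c(cond_x, cond_y) %in% names(x)))
  vx <- x[[cond_x]]
  vy <- x[[cond_y]]
  r <- stats::cor(vx, vy, method = method)
  list(
    r = r, r_squared = r^2, n = nrow(x),
    data = tibble::tibble(gene_id = x$gene_id, x = vx, y = vy)
  )
}
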