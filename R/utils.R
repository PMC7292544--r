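# Internal helpers shared across modules.

# Geometric mean; zeros/NAs dropped by callers where the method requires it.
geo_mean <- function(x) exp(mean(log(x)))

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Convert a tibble with chrom/start/end (0-based half-open) and optional
# strand into a GRanges (1-based closed, the Bioconductor convention).
regions_to_granges <- function(x, chrom_sizes = NULL) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  }
  if ("gene_id" %in% names(x)) names(gr) <- x$gene_id
  gr
}

# Wide counts tibble (gene_id + one numeric column per sample) -> matrix.
counts_to_matrix <- function(counts) {
  stopifnot("gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# Reverse complement for plain character vectors (delegates to Biostrings).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
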