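#' Load capture-seq alignments
#'
#' Reads primary, mapped alignments from a BAM or SAM file. SAM input is
#' converted and coordinate-sorted internally; BAM input must already be
#' coordinate-sorted (`SO:coordinate` in the header), otherwise an error is
#' raised. Secondary and supplementary alignments are dropped at load time,
#' matching the counting contract.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A [GenomicAlignments::GAlignments] object of primary, mapped
#'   alignments.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
    so <- hdr[["@HD"]] %||% character(0)
    if (!any(grepl("^SO:coordinate$", so))) {
      stop("BAM file is not coordinate-sorted: ", path, call. = FALSE)
    }
    bam <- path
    if (!file.exists(paste0(path, ".bai"))) Rsamtools::indexBam(path)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  GenomicAlignments::readGAlignments(bam, param = Rsamtools::ScanBamParam(flag = flags))
}

# Regions whose chromosome is absent from the alignment header count 0 with
# a warning; returns a logical mask of usable regions.
check_region_chroms <- function(alignments, regions) {
  present <- regions$chrom %in% GenomeInfoDb::seqlevels(alignments)
  if (!all(present)) {
    warning("region chromosome(s) absent from alignments, counting 0: ",
            paste(unique(regions$chrom[!present]), collapse = ", "),
            call. = FALSE)
  }
  present
}

#' Count reads per target region
#'
#' Number of primary, mapped reads whose alignment span (clipping excluded,
#' spliced reads taken as their full reference span) overlaps each region
#' by at least 1 bp. A read is counted once per region it touches.
#'
#' @param alignments `GAlignments` from [read_alignments()].
#' @param regions Target-region tibble.
#' @return Tibble `gene_id`, `read_count`.
#' @export
count_reads <- function(alignments, regions) {
  present <- check_region_chroms(alignments, regions)
  counts <- integer(nrow(regions))
  if (any(present)) {
    gr <- regions_to_granges(regions[present, , drop = FALSE])
    GenomicRanges::strand(gr) <- "*"
    counts[present] <- GenomicRanges::countOverlaps(
      gr, GenomicRanges::granges(alignments), minoverlap = 1L
    )
  }
  tibble::tibble(gene_id = regions$gene_id, read_count = counts)
}

#' Per-region coverage summary
#'
#' For each region: the primary-read count, the number of positions covered
#' by at least one read, the breadth of coverage (covered / region length)
#' and the mean depth. Breadth uses the full reference span of each read (a
#' capture-QC measure of whether baits pulled the locus down); mean depth
#' uses the aligned blocks of spliced reads (a quantification measure).
#'
#' @param alignments `GAlignments` from [read_alignments()].
#' @param regions Target-region tibble.
#' @return Tibble `gene_id`, `read_count`, `covered_bases`, `breadth`,
#'   `mean_depth`.
#' @export
region_coverage <- function(alignments, regions) {
  present <- check_region_chroms(alignments, regions)
  counts <- count_reads(alignments, regions)
  covered <- integer(nrow(regions))
  depth_sum <- numeric(nrow(regions))
  if (any(present)) {
    span_cov <- GenomicRanges::coverage(GenomicRanges::granges(alignments))
    block_cov <- GenomicRanges::coverage(alignments)
    for (i in which(present)) {
      window <- IRanges::IRanges(regions$start[i] + 1L, regions$end[i])
      v_span <- IRanges::Views(span_cov[[regions$chrom[i]]], window)[[1]]
      v_block <- IRanges::Views(block_cov[[regions$chrom[i]]], window)[[1]]
      covered[i] <- sum(v_span > 0)
      depth_sum[i] <- sum(as.numeric(v_block))
    }
  }
  len <- regions$end - regions$start
  tibble::tibble(
    gene_id = regions$gene_id,
    read_count = counts$read_count,
    covered_bases = covered,
    breadth = covered / len,
    mean_depth = depth_sum / len
  )
}

#' Breadth of coverage per region
#'
#' Fraction of region positions covered by at least one primary read.
#'
#' @inheritParams region_coverage
#' @return Tibble `gene_id`, `breadth`.
#' @export
region_breadth <- function(alignments, regions) {
  dplyr::select(region_coverage(alignments, regions), "gene_id", "breadth")
}

#' Assemble a count matrix and coverage report from a sample sheet
#'
#' Quantifies every sample's alignments over the target regions. cDNA
#' samples populate the count matrix; gDNA spike-in samples contribute only
#' to the coverage report (the capture-QC channel). Designated
#' negative-control regions (loci not expressed in the sampled tissue) are
#' checked for cDNA contamination: any cDNA reads there raise a warning.
#'
#' @param sample_sheet Tibble with columns `sample_id`, `genotype`,
#'   `treatment`, `replicate`, `material` (`"cDNA"` or `"gDNA"`) and `path`
#'   (SAM/BAM file per sample).
#' @param regions Target-region tibble.
#' @param negative_controls Character vector of gene IDs serving as
#'   contamination negative controls (default none).
#' @return An object of class `capture_quant`: a list with `counts` (wide
#'   tibble, `gene_id` x cDNA samples), `coverage` (long tibble over all
#'   samples), `samples` (the sheet) and `contamination` (per negative
#'   control x cDNA sample check with a `pass` flag).
#' @export
assemble_matrix <- function(sample_sheet, regions, negative_controls = NULL) {
  required <- c("sample_id", "material", "path")
  missing_cols <- setdiff(required, names(sample_sheet))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  absent <- !file.exists(sample_sheet$path)
  if (any(absent)) {
    stop("alignment file missing for sample(s): ",
         paste(sample_sheet$sample_id[absent], collapse = ", "), call. = FALSE)
  }

  per_sample <- purrr::map(seq_len(nrow(sample_sheet)), function(i) {
    aln <- read_alignments(sample_sheet$path[i])
    cov <- region_coverage(aln, regions)
    cov$sample_id <- sample_sheet$sample_id[i]
    cov$material <- sample_sheet$material[i]
    cov
  })
  coverage <- purrr::list_rbind(per_sample) |>
    dplyr::select("sample_id", "material", "gene_id", "read_count",
                  "covered_bases", "breadth", "mean_depth")

  cdna_ids <- sample_sheet$sample_id[sample_sheet$material == "cDNA"]
  counts <- tibble::tibble(gene_id = regions$gene_id)
  for (sid in cdna_ids) {
    counts[[sid]] <- coverage$read_count[match(
      paste(sid, regions$gene_id),
      paste(coverage$sample_id, coverage$gene_id)
    )]
  }

  contamination <- tibble::tibble(
    gene_id = character(), sample_id = character(),
    read_count = integer(), pass = logical()
  )
  if (length(negative_controls) && length(cdna_ids)) {
    contamination <- coverage |>
      dplyr::filter(.data$material == "cDNA",
                    .data$gene_id %in% negative_controls) |>
      dplyr::mutate(pass = .data$read_count == 0L) |>
      dplyr::select("gene_id", "sample_id", "read_count", "pass")
    if (any(!contamination$pass)) {
      bad <- contamination[!contamination$pass, ]
      warning("possible contamination: cDNA reads on negative-control region(s) ",
              paste(unique(bad$gene_id), collapse = ", "), " in sample(s) ",
              paste(unique(bad$sample_id), collapse = ", "), call. = FALSE)
    }
  }

  structure(
    list(counts = counts, coverage = coverage, samples = sample_sheet,
         contamination = contamination),
    class = "capture_quant"
  )
}

#' @export
print.capture_quant <- function(x, ...) {
  cat("<capture_quant> ", nrow(x$counts), " regions x ",
      ncol(x$counts) - 1L, " cDNA samples (",
      sum(x$samples$material == "gDNA"), " gDNA spike-ins in coverage QC)\n",
      sep = "")
  invisible(x)
}
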