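#' Read a genome FASTA
#'
#' Loads a genome as a named `DNAStringSet`. Sequence names are truncated at
#' the first whitespace, matching the identifiers used in GFF3/BED files.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

chrom_sizes <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Cheap structural validation so that a malformed line is reported with its
# line number before the typed parser runs.
validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields, got ",
           length(fields), call. = FALSE)
    }
    if (anyNA(suppressWarnings(as.integer(fields[4:5])))) {
      stop("malformed GFF3 line ", i, ": non-numeric start/end", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Parse a GFF3 annotation into gene models
#'
#' Builds one gene model per gene feature: strand, gene span, CDS span and
#' the union of exons across isoforms. Coordinates are converted from the
#' GFF3 1-based inclusive convention to the package-internal 0-based
#' half-open convention. Genes are sorted by chromosome and start.
#'
#' @param gff_path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome A `DNAStringSet` from [read_genome()]. Every chromosome
#'   referenced by the annotation must be present, otherwise an error is
#'   raised.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `cds_start`, `cds_end` and a list-column `exons` of
#'   start/end tibbles, with the chromosome sizes attached as the
#'   `chrom_sizes` attribute. Genes lacking an annotated CDS use their gene
#'   boundaries as a CDS proxy (with a warning).
#' @export
read_gene_models <- function(gff_path, genome) {
  validate_gff_lines(gff_path)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  sizes <- chrom_sizes(genome)

  feat <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gff)),
    # internal 0-based half-open
    start = GenomicRanges::start(gff) - 1L,
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = as.character(gff$type),
    id = as.character(gff$ID %||% rep(NA_character_, length(gff))),
    parent = purrr::map_chr(as.list(gff$Parent %||% vector("list", length(gff))),
                            ~ if (length(.x)) .x[[1]] else NA_character_)
  )

  missing_chrom <- setdiff(unique(feat$chrom), names(sizes))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }

  genes <- dplyr::filter(feat, .data$type == "gene")
  if (nrow(genes) == 0L) stop("no gene features found in ", gff_path, call. = FALSE)

  # Map every feature id to its owning gene (mRNA -> gene, exon/CDS -> mRNA).
  parent_of <- stats::setNames(feat$parent, feat$id)
  owner_gene <- function(parent) {
    while (!is.na(parent) && !parent %in% genes$id) parent <- parent_of[[parent]] %||% NA_character_
    parent
  }
  sub <- dplyr::filter(feat, .data$type %in% c("exon", "CDS"))
  sub$gene_id <- purrr::map_chr(sub$parent, owner_gene)

  models <- genes |>
    dplyr::rename(gene_id = "id") |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end")

  cds <- sub |>
    dplyr::filter(.data$type == "CDS", !is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(cds_start = min(.data$start), cds_end = max(.data$end))

  exon_union <- function(gid, gstart, gend) {
    ex <- dplyr::filter(sub, .data$type == "exon", .data$gene_id == gid)
    if (nrow(ex) == 0L) return(tibble::tibble(start = gstart, end = gend))
    ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }

  models <- models |>
    dplyr::left_join(cds, by = "gene_id") |>
    dplyr::mutate(exons = purrr::pmap(list(.data$gene_id, .data$start, .data$end), exon_union))

  no_cds <- is.na(models$cds_start)
  if (any(no_cds)) {
    warning("gene(s) without CDS, using gene boundaries as CDS proxy: ",
            paste(models$gene_id[no_cds], collapse = ", "), call. = FALSE)
    models$cds_start[no_cds] <- models$start[no_cds]
    models$cds_end[no_cds] <- models$end[no_cds]
  }

  models <- dplyr::arrange(models, .data$chrom, .data$start)
  attr(models, "chrom_sizes") <- sizes
  models
}

#' Resolve intergenic bounds for each gene
#'
#' For every gene, finds the CDS end of the nearest gene to its genomic left
#' and the CDS start of the nearest gene to its genomic right (either
#' strand). Where no neighbour exists the chromosome start (0) or end is
#' used. A neighbour whose CDS overlaps the target CDS clamps the bound to
#' the target CDS boundary (zero-length gap) with a warning.
#'
#' @param models Gene-model tibble from [read_gene_models()].
#' @param chrom_sizes Named integer vector of chromosome lengths; defaults
#'   to the attribute attached by [read_gene_models()].
#' @return `models` with columns `upstream_limit`, `downstream_limit`
#'   (genomic left/right bounds) and `upstream_gap`, `downstream_gap`
#'   (CDS-to-CDS distances) appended.
#' @export
neighbor_bounds <- function(models, chrom_sizes = attr(models, "chrom_sizes")) {
  if (is.null(chrom_sizes)) stop("chrom_sizes required", call. = FALSE)
  clamped <- character(0)
  res <- models |>
    dplyr::mutate(upstream_limit = NA_real_, downstream_limit = NA_real_)
  for (i in seq_len(nrow(res))) {
    g <- res[i, ]
    others <- models[models$chrom == g$chrom & models$gene_id != g$gene_id, ]
    left <- others[others$cds_start < g$cds_start, ]
    up <- if (nrow(left)) max(left$cds_end) else 0
    right <- others[others$cds_end > g$cds_end, ]
    down <- if (nrow(right)) min(right$cds_start) else unname(chrom_sizes[[g$chrom]])
    if (up > g$cds_start) { up <- g$cds_start; clamped <- c(clamped, g$gene_id) }
    if (down < g$cds_end) { down <- g$cds_end; clamped <- c(clamped, g$gene_id) }
    res$upstream_limit[i] <- up
    res$downstream_limit[i] <- down
  }
  if (length(clamped)) {
    warning("overlapping neighbour CDS, flank clamped to zero for: ",
            paste(unique(clamped), collapse = ", "), call. = FALSE)
  }
  res <- dplyr::mutate(res,
    upstream_gap = .data$cds_start - .data$upstream_limit,
    downstream_gap = .data$downstream_limit - .data$cds_end
  )
  attr(res, "chrom_sizes") <- chrom_sizes
  res
}

#' Build capture target regions
#'
#' Turns gene models into capture windows spanning putative promoter, gene
#' body (introns included) and putative terminator. Flank lengths are the
#' CDS-to-CDS intergenic gaps capped at `flank_cap` (default 4500 bp) and
#' are laid outward from the CDS; the window always contains the full gene,
#' so annotated UTRs are absorbed into the flank. "Promoter" and
#' "terminator" are resolved in transcription orientation: for a minus-
#' strand gene the promoter lies genomically right of the gene.
#'
#' @param models Gene-model tibble; if it lacks neighbour bounds,
#'   [neighbor_bounds()] is applied first.
#' @param targets Optional character vector of gene IDs to design for
#'   (default: all genes in `models`). Non-target genes still bound flanks.
#' @param flank_cap Maximum promoter/terminator length in bp.
#' @param chrom_sizes Named chromosome lengths (defaults to the attribute).
#' @return A tibble of target regions: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open span), `promoter_len`,
#'   `terminator_len` (extent of the flanks beyond the gene boundaries) and
#'   `flank_cap`.
#' @export
build_target_regions <- function(models, targets = NULL, flank_cap = 4500,
                                 chrom_sizes = attr(models, "chrom_sizes")) {
  if (!all(c("upstream_limit", "downstream_limit") %in% names(models))) {
    models <- neighbor_bounds(models, chrom_sizes)
  }
  if (is.null(chrom_sizes)) stop("chrom_sizes required", call. = FALSE)
  regions <- models
  if (!is.null(targets)) {
    missing <- setdiff(targets, models$gene_id)
    if (length(missing)) {
      stop("target gene(s) not in annotation: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    regions <- regions[regions$gene_id %in% targets, ]
  }
  regions <- regions |>
    dplyr::mutate(
      left_flank = pmin(.data$upstream_gap, flank_cap),
      right_flank = pmin(.data$downstream_gap, flank_cap),
      span_start = pmin(.data$start, .data$cds_start - .data$left_flank),
      span_end = pmax(.data$end, .data$cds_end + .data$right_flank),
      span_start = pmax(.data$span_start, 0),
      span_end = pmin(.data$span_end, unname(chrom_sizes[.data$chrom])),
      left_len = .data$start - .data$span_start,
      right_len = .data$span_end - .data$end,
      promoter_len = ifelse(.data$strand == "-", .data$right_len, .data$left_len),
      terminator_len = ifelse(.data$strand == "-", .data$left_len, .data$right_len)
    )
  out <- tibble::tibble(
    gene_id = regions$gene_id,
    chrom = regions$chrom,
    strand = regions$strand,
    start = as.integer(regions$span_start),
    end = as.integer(regions$span_end),
    promoter_len = as.integer(regions$promoter_len),
    terminator_len = as.integer(regions$terminator_len),
    flank_cap = as.integer(flank_cap)
  )
  attr(out, "chrom_sizes") <- chrom_sizes
  out
}

#' Extract coding-strand capture templates
#'
#' Returns the template sequence of each target region on the gene's coding
#' strand: the genomic slice for plus-strand genes, its reverse complement
#' for minus-strand genes. Sequences are uppercased; IUPAC ambiguity codes
#' are preserved.
#'
#' @param regions Target-region tibble from [build_target_regions()].
#' @param genome `DNAStringSet` from [read_genome()].
#' @return `regions` with a `template` character column appended
#'   (`nchar(template) == end - start`).
#' @export
region_templates <- function(regions, genome) {
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sizes <- chrom_sizes(genome)
  bad <- regions$start < 0 | regions$end > sizes[regions$chrom]
  if (any(bad)) {
    stop("region span outside chromosome for: ",
         paste(regions$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(purrr::pmap_chr(
    list(regions$chrom, regions$start, regions$end),
    function(chrom, start, end) as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  ))
  minus <- regions$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  dplyr::mutate(regions, template = toupper(as.character(seqs)))
}

#' Write target regions to BED6 and FASTA
#'
#' @param regions Target-region tibble (templates are computed if absent).
#' @param genome Genome `DNAStringSet` (only needed when `regions` has no
#'   `template` column).
#' @param bed_path,fasta_path Output paths; either may be `NULL` to skip.
#' @return `regions` (with templates), invisibly.
#' @export
write_target_regions <- function(regions, genome = NULL, bed_path = NULL,
                                 fasta_path = NULL) {
  if (!is.null(fasta_path) && !"template" %in% names(regions)) {
    if (is.null(genome)) stop("genome required to extract templates", call. = FALSE)
    regions <- region_templates(regions, genome)
  }
  if (!is.null(bed_path)) {
    gr <- regions_to_granges(regions)
    gr$name <- regions$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(regions$template)
    names(seqs) <- sprintf("%s|%s:%d-%d|%s", regions$gene_id, regions$chrom,
                           regions$start, regions$end, regions$strand)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(regions)
}
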