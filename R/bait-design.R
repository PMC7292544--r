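#' Bait design parameters
#'
#' @param bait_len Probe length in nt (fixed-length chemistry).
#' @param overlap Tiling overlap between successive probes in nt; the tiling
#'   step is `bait_len - overlap`.
#' @param max_hits Maximum tolerated number of exact genome occurrences; a
#'   bait with strictly more hits is removed by the specificity filter.
#' @param mask_policy `"exclude"` subtracts repeat intervals before tiling
#'   (no bait can overlap a mask); `"ignore"` tiles across masks.
#' @return A validated list of class `bait_params`.
#' @export
bait_params <- function(bait_len = 120L, overlap = 17L, max_hits = 10L,
                        mask_policy = c("exclude", "ignore")) {
  bait_len <- as.integer(bait_len); overlap <- as.integer(overlap)
  max_hits <- as.integer(max_hits)
  mask_policy <- match.arg(mask_policy)
  if (!(overlap >= 0L && overlap < bait_len)) {
    stop("need 0 <= overlap < bait_len", call. = FALSE)
  }
  if (max_hits < 1L) stop("max_hits must be >= 1", call. = FALSE)
  structure(
    list(bait_len = bait_len, overlap = overlap, step = bait_len - overlap,
         max_hits = max_hits, mask_policy = mask_policy),
    class = "bait_params"
  )
}

#' Subtract repeat masks from regions
#'
#' Removes repeat intervals from each target region, returning the ordered,
#' disjoint unmasked sub-intervals. A fully masked region yields no rows.
#'
#' @param regions Region tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param masks Tibble of repeat intervals (`chrom`, `start`, `end`, 0-based
#'   half-open, e.g. from [read_bed()]), or `NULL` for no masking.
#' @return Tibble with one row per unmasked sub-interval: `gene_id`,
#'   `chrom`, `start`, `end`, sorted within each region.
#' @export
subtract_masks <- function(regions, masks = NULL) {
  pieces <- purrr::pmap(
    list(regions$gene_id, regions$chrom, regions$start, regions$end),
    function(gene_id, chrom, start, end) {
      ir <- IRanges::IRanges(start + 1L, end)
      if (!is.null(masks) && nrow(masks)) {
        m <- masks[masks$chrom == chrom, , drop = FALSE]
        if (nrow(m)) {
          ir <- IRanges::setdiff(ir, IRanges::IRanges(m$start + 1L, m$end))
        }
      }
      tibble::tibble(
        gene_id = gene_id, chrom = chrom,
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir)
      )
    }
  )
  purrr::list_rbind(pieces)
}

#' Tiling offsets for one interval
#'
#' Start offsets (0-based, relative to the interval) of fixed-length probes
#' tiled with a constant step, plus an end-anchored final probe whenever the
#' regular tiling would leave the tail uncovered. Every base of an interval
#' of length `>= bait_len` is covered, and the probe count obeys
#' `1 + ceiling((L - bait_len) / step)`. Intervals shorter than `bait_len`
#' yield no probes.
#'
#' @param L Interval length in bp.
#' @param bait_len,overlap Probe length and tiling overlap in nt.
#' @return Integer vector of start offsets (possibly empty).
#' @export
tile_offsets <- function(L, bait_len = 120L, overlap = 17L) {
  L <- as.integer(L); bait_len <- as.integer(bait_len)
  step <- bait_len - as.integer(overlap)
  stopifnot(step >= 1L)
  if (L < bait_len) return(integer(0))
  starts <- seq.int(0L, L - bait_len, by = step)
  if (starts[length(starts)] + bait_len < L) starts <- c(starts, L - bait_len)
  starts
}

# Tile the unmasked sub-intervals of one region in template (coding-strand)
# orientation and return genomic bait intervals with template sequences.
tile_region <- function(region, pieces, genome, params) {
  tmpl_len <- region$end - region$start
  # genomic sub-interval -> template-space [a, b)
  if (region$strand == "-") {
    a <- region$end - pieces$end
    b <- region$end - pieces$start
  } else {
    a <- pieces$start - region$start
    b <- pieces$end - region$start
  }
  ord <- order(a)
  a <- a[ord]; b <- b[ord]
  template <- as.character(Biostrings::subseq(genome[[region$chrom]],
                                              region$start + 1L, region$end))
  if (region$strand == "-") template <- revcomp_chr(template)
  template <- toupper(template)

  out <- vector("list", length(a))
  for (k in seq_along(a)) {
    offs <- tile_offsets(b[k] - a[k], params$bait_len, params$overlap)
    if (!length(offs)) { out[[k]] <- NULL; next }
    tstart <- a[k] + offs
    tend <- tstart + params$bait_len
    gstart <- if (region$strand == "-") region$end - tend else region$start + tstart
    out[[k]] <- tibble::tibble(
      source_gene = region$gene_id,
      chrom = region$chrom,
      start = as.integer(gstart),
      end = as.integer(gstart + params$bait_len),
      strand = region$strand,
      seq = substring(template, tstart + 1L, tend)
    )
  }
  list(
    baits = purrr::list_rbind(out[!vapply(out, is.null, logical(1))]),
    n_short = sum((b - a) < params$bait_len)
  )
}

#' Count exact genome occurrences of probe sequences
#'
#' Counts exact matches of each sequence on both strands of the genome;
#' overlapping occurrences count separately, so a palindromic probe present
#' at one locus counts twice (once per strand). Probes containing IUPAC
#' ambiguity codes are matched with the ambiguous positions acting as
#' wildcards (the genome letters stay fixed).
#'
#' @param seqs Character vector of probe sequences.
#' @param genome `DNAStringSet` from [read_genome()].
#' @return Integer vector of hit counts, one per sequence. Any probe taken
#'   from the genome itself counts at least 1.
#' @export
count_genome_hits <- function(seqs, genome) {
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  hits <- integer(n)
  plain <- grepl("^[ACGT]+$", seqs)
  widths <- nchar(seqs)

  count_exact <- function(ss) {
    ss <- unname(ss)
    # both strands via the forward genome and the reverse-complement pattern
    pd_f <- Biostrings::PDict(Biostrings::DNAStringSet(ss))
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(Biostrings::DNAStringSet(ss)))
    tot <- integer(length(ss))
    for (chr in seq_along(genome)) {
      tot <- tot + Biostrings::countPDict(pd_f, genome[[chr]]) +
        Biostrings::countPDict(pd_r, genome[[chr]])
    }
    tot
  }

  for (w in unique(widths[plain])) {
    idx <- which(plain & widths == w)
    hits[idx] <- count_exact(seqs[idx])
  }
  for (i in which(!plain)) {
    pat <- Biostrings::DNAString(seqs[i])
    tot <- 0L
    for (chr in seq_along(genome)) {
      tot <- tot + Biostrings::countPattern(pat, genome[[chr]], fixed = "subject") +
        Biostrings::countPattern(Biostrings::reverseComplement(pat), genome[[chr]],
                                 fixed = "subject")
    }
    hits[i] <- tot
  }
  hits
}

#' Mark redundant baits
#'
#' Among baits identical in genomic interval (`chrom`, `start`, `end`) or
#' identical in sequence -- as arises in the shared intergenic span between
#' two adjacent target genes -- the first in (`chrom`, `start`, `gene_id`)
#' order keeps its status and the rest are marked `removed_duplicate`.
#' Deterministic for identical input.
#'
#' @param baits Bait tibble (pooled across genes) with a `status` column.
#' @return The bait tibble with duplicate statuses updated, in
#'   (`chrom`, `start`, `source_gene`) order.
#' @export
deduplicate_baits <- function(baits) {
  baits <- dplyr::arrange(baits, .data$chrom, .data$start, .data$source_gene)
  key <- paste(baits$chrom, baits$start, baits$end)
  dup <- duplicated(key) | duplicated(baits$seq)
  baits$status[dup & baits$status == "kept"] <- "removed_duplicate"
  baits
}

#' Remove promiscuous baits
#'
#' Marks baits whose exact-match genome hit count strictly exceeds
#' `max_hits` as `removed_multihit` (a bait with exactly `max_hits` hits is
#' kept). Hit counts are computed where absent.
#'
#' @param baits Bait tibble with `seq` and `status` columns.
#' @param genome Genome `DNAStringSet`.
#' @param max_hits Strict threshold on the hit count.
#' @return The bait tibble with `hit_count` filled and statuses updated.
#' @export
specificity_filter <- function(baits, genome, max_hits = 10L) {
  if (nrow(baits) == 0L) return(baits)
  if (!"hit_count" %in% names(baits) || anyNA(baits$hit_count)) {
    need <- if ("hit_count" %in% names(baits)) is.na(baits$hit_count) else rep(TRUE, nrow(baits))
    counted <- count_genome_hits(unique(baits$seq[need]), genome)
    lut <- stats::setNames(counted, unique(baits$seq[need]))
    baits$hit_count[need] <- unname(lut[baits$seq[need]])
  }
  hot <- baits$status == "kept" & baits$hit_count > max_hits
  baits$status[hot] <- "removed_multihit"
  baits
}

#' Flag already-tiled baits overlapping repeat intervals
#'
#' Marks kept baits overlapping any repeat interval by at least 1 bp as
#' `removed_repeat`. Only relevant when tiling was done with
#' `mask_policy = "ignore"`; under `"exclude"` no bait can touch a mask.
#'
#' @param baits Bait tibble.
#' @param masks Repeat-interval tibble (`chrom`, `start`, `end`).
#' @return The bait tibble with statuses updated.
#' @export
flag_masked_baits <- function(baits, masks) {
  if (is.null(masks) || nrow(masks) == 0L || nrow(baits) == 0L) return(baits)
  bgr <- regions_to_granges(baits)
  mgr <- regions_to_granges(masks)
  hit <- IRanges::overlapsAny(bgr, mgr, minoverlap = 1L)
  baits$status[hit & baits$status == "kept"] <- "removed_repeat"
  baits
}

#' Design a tiled bait library
#'
#' Full probe-design pipeline: repeat subtraction, per-sub-interval tiling
#' with end anchoring (guaranteeing 100% breadth over every unmasked
#' stretch of length `>= bait_len`), pooling across genes, deduplication of
#' redundant baits, and the exact-match genome specificity filter. Bait
#' sequences are emitted in coding-strand template orientation.
#'
#' @param regions Target-region tibble from [build_target_regions()].
#' @param genome Genome `DNAStringSet`.
#' @param masks Optional repeat-interval tibble (BED-derived).
#' @param params [bait_params()] list.
#' @return An object of class `bait_library`: a list with `baits` (tibble
#'   with `bait_id`, `source_gene`, `chrom`, `start`, `end`, `strand`,
#'   `seq`, `hit_count`, `status`), `params`, and `report` (per-gene counts
#'   by status plus short-sub-interval warnings).
#' @export
design_baits <- function(regions, genome, masks = NULL, params = bait_params()) {
  stopifnot(inherits(params, "bait_params"))
  use_masks <- if (identical(params$mask_policy, "exclude")) masks else NULL
  pieces_all <- subtract_masks(regions, use_masks)

  per_gene <- vector("list", nrow(regions))
  n_short <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    pieces <- pieces_all[pieces_all$gene_id == region$gene_id, , drop = FALSE]
    tiled <- tile_region(region, pieces, genome, params)
    per_gene[[i]] <- tiled$baits
    n_short[i] <- tiled$n_short
  }
  if (any(n_short > 0L)) {
    warning("sub-interval(s) shorter than bait_len yielded no baits for: ",
            paste(regions$gene_id[n_short > 0L], collapse = ", "), call. = FALSE)
  }

  baits <- purrr::list_rbind(per_gene[!vapply(per_gene, is.null, logical(1))])
  if (is.null(baits) || nrow(baits) == 0L) {
    baits <- tibble::tibble(
      source_gene = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), seq = character()
    )
  }
  baits$status <- rep("kept", nrow(baits))
  baits$hit_count <- rep(NA_integer_, nrow(baits))
  baits <- deduplicate_baits(baits)
  baits <- specificity_filter(baits, genome, params$max_hits)
  baits <- baits |>
    dplyr::group_by(.data$source_gene) |>
    dplyr::mutate(bait_id = sprintf("%s_b%04d", .data$source_gene, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("bait_id", "source_gene", "chrom", "start", "end", "strand",
                  "seq", "hit_count", "status")

  report <- baits |>
    dplyr::group_by(.data$source_gene) |>
    dplyr::summarise(
      emitted = dplyr::n(),
      kept = sum(.data$status == "kept"),
      removed_repeat = sum(.data$status == "removed_repeat"),
      removed_multihit = sum(.data$status == "removed_multihit"),
      removed_duplicate = sum(.data$status == "removed_duplicate")
    ) |>
    dplyr::left_join(tibble::tibble(source_gene = regions$gene_id,
                                    short_subintervals = n_short),
                     by = "source_gene")

  structure(list(baits = baits, params = params, report = report),
            class = "bait_library")
}

#' @export
print.bait_library <- function(x, ...) {
  cat("<bait_library> ", nrow(x$baits), " baits (",
      sum(x$baits$status == "kept"), " kept) over ",
      length(unique(x$baits$source_gene)), " genes; ",
      x$params$bait_len, "-nt probes, ", x$params$overlap, "-nt overlap\n",
      sep = "")
  invisible(x)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) and, when
#'   present, `name` and `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) out$strand <- s
  out
}

#' Write a bait library to FASTA, BED6 and a design report
#'
#' Kept baits go to FASTA (header `bait_id|gene_id|chrom:start-end`) and
#' BED6; the full library with statuses is written as a TSV design report.
#'
#' @param library A `bait_library` from [design_baits()].
#' @param fasta_path,bed_path,report_path Output paths (`NULL` to skip).
#' @return `library`, invisibly.
#' @export
write_bait_library <- function(library, fasta_path = NULL, bed_path = NULL,
                               report_path = NULL) {
  baits <- library$baits
  kept <- baits[baits$status == "kept", , drop = FALSE]
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(kept$seq)
    names(seqs) <- sprintf("%s|%s|%s:%d-%d", kept$bait_id, kept$source_gene,
                           kept$chrom, kept$start, kept$end)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(bed_path)) {
    gr <- regions_to_granges(kept)
    gr$name <- kept$bait_id
    gr$score <- 0L
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  if (!is.null(report_path)) {
    readr::write_tsv(baits, report_path)
  }
  invisible(library)
}
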