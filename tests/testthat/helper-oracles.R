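# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the code paths they check:
# plain substring scans and per-base pileups instead of Biostrings /
# GenomicRanges machinery.

# Exact-occurrence count of `seq` on both strands of a genome given as a
# named character vector, by scanning every position.
oracle_hits <- function(seq, genome_chr) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  w <- nchar(seq)
  total <- 0L
  for (chrom in genome_chr) {
    n <- nchar(chrom) - w + 1L
    if (n < 1L) next
    subs <- substring(chrom, seq_len(n), seq_len(n) + w - 1L)
    total <- total + sum(subs == seq) + sum(subs == rc(seq))
  }
  total
}

# Per-base pileup over a region (0-based half-open) from read start
# positions (0-based) and a fixed read length.
oracle_pileup <- function(read_starts0, read_len, region_start0, region_end0) {
  len <- region_end0 - region_start0
  depth <- integer(len)
  count <- 0L
  for (s in read_starts0) {
    e <- s + read_len # half-open read interval
    if (e <= region_start0 || s >= region_end0) next
    count <- count + 1L
    lo <- max(s, region_start0) - region_start0 + 1L
    hi <- min(e, region_end0) - region_start0
    depth[lo:hi] <- depth[lo:hi] + 1L
  }
  list(
    read_count = count,
    covered_bases = sum(depth > 0L),
    breadth = sum(depth > 0L) / len,
    mean_depth = sum(depth) / len
  )
}

# Hand-built gene-model tibble (0-based half-open) with chromosome sizes
# attached, for geometry tests that need no GFF round trip.
make_models <- function(df, chrom_sizes) {
  models <- tibble::as_tibble(df)
  if (!"cds_start" %in% names(models)) models$cds_start <- models$start
  if (!"cds_end" %in% names(models)) models$cds_end <- models$end
  if (!"exons" %in% names(models)) {
    models$exons <- purrr::map2(models$start, models$end,
                                ~ tibble::tibble(start = .x, end = .y))
  }
  attr(models, "chrom_sizes") <- chrom_sizes
  models
}

# Write a SAM file from explicit records (pos1 is 1-based, as in SAM).
write_sam <- function(path, chrom_sizes, qname = character(0),
                      flag = integer(0), chrom = character(0),
                      pos1 = integer(0), cigar = character(0),
                      seq = NULL, sorted = TRUE) {
  so <- if (sorted) "coordinate" else "unsorted"
  lines <- c(
    paste0("@HD\tVN:1.6\tSO:", so),
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes)
  )
  if (length(qname)) {
    n <- length(qname)
    flag <- rep_len(flag, n); chrom <- rep_len(chrom, n)
    pos1 <- rep_len(pos1, n); cigar <- rep_len(cigar, n)
    seq <- rep_len(seq %||% "*", n)
    ord <- if (sorted) order(chrom, pos1) else seq_along(qname)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                              qname[ord], flag[ord], chrom[ord], pos1[ord],
                              cigar[ord], seq[ord]))
  }
  writeLines(lines, path)
  path
}

# Random DNA string (independent of the package generator).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A cached small synthetic study shared by alignment-level tests.
mini_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        simulate_study(fixture_spec(seed = 11, preset = "mini"),
                       dir = file.path(tempdir(), "quantcap-mini-study"))
      )
    }
    cache
  }
})
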