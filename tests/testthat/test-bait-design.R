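# Tiling, masking, deduplication and the specificity filter.

test_that("mask subtraction returns ordered disjoint sub-intervals", {
  region <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 0L, end = 1000L)
  mask <- tibble::tibble(chrom = "chr1", start = 400L, end = 600L)
  out <- subtract_masks(region, mask)
  expect_equal(out$start, c(0L, 600L))
  expect_equal(out$end, c(400L, 1000L))

  expect_equal(subtract_masks(region, NULL)[, c("start", "end")],
               tibble::tibble(start = 0L, end = 1000L))
  all_mask <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(nrow(subtract_masks(region, all_mask)), 0L)
  # mask on another chromosome is irrelevant
  other <- tibble::tibble(chrom = "chr2", start = 0L, end = 1000L)
  expect_equal(nrow(subtract_masks(region, other)), 1L)
})

test_that("tiling starts at multiples of the step and end-anchors the tail", {
  expect_equal(tile_offsets(120), 0L)
  expect_equal(tile_offsets(223), c(0L, 103L))
  expect_equal(tile_offsets(300), c(0L, 103L, 180L))
  expect_equal(tile_offsets(119), integer(0))
})

test_that("tiling obeys the count law and covers every base", {
  set.seed(42)
  lens <- sample(120:5000, 200)
  for (L in lens) {
    offs <- tile_offsets(L)
    expect_equal(length(offs), 1 + ceiling((L - 120) / 103))
    covered <- logical(L)
    for (o in offs) covered[(o + 1):(o + 120)] <- TRUE
    expect_true(all(covered))
    expect_true(all(offs + 120 <= L))
  }
})

test_that("deduplication keeps the first bait by position order", {
  baits <- tibble::tibble(
    source_gene = c("gB", "gA", "gC"),
    chrom = "chr1",
    start = c(100L, 100L, 900L),
    end = c(220L, 220L, 1020L),
    strand = "+",
    seq = c(strrep("A", 120), strrep("A", 120), strrep("C", 120)),
    status = "kept"
  )
  out <- deduplicate_baits(baits)
  # same interval: gA wins by gene order; gB marked duplicate
  expect_equal(out$status[out$source_gene == "gA"], "kept")
  expect_equal(out$status[out$source_gene == "gB"], "removed_duplicate")
  expect_equal(out$status[out$source_gene == "gC"], "kept")

  # identical sequence at a different locus: second-by-position removed
  seqdup <- tibble::tibble(
    source_gene = c("gA", "gB"),
    chrom = "chr1",
    start = c(0L, 5000L), end = c(120L, 5120L),
    strand = "+",
    seq = strrep("G", 120),
    status = "kept"
  )
  out2 <- deduplicate_baits(seqdup)
  expect_equal(out2$status, c("kept", "removed_duplicate"))

  # all-unique input is untouched
  uniq <- dplyr::mutate(baits[c(1, 3), ], seq = c(strrep("A", 120), strrep("C", 120)))
  expect_true(all(deduplicate_baits(uniq)$status == "kept"))
})

test_that("hit counting matches a brute-force both-strand scan", {
  set.seed(7)
  genome_chr <- c(chr1 = random_dna(30000), chr2 = random_dna(20000))
  genome <- Biostrings::DNAStringSet(genome_chr)
  # probes straight off the genome, from both chromosomes
  probes <- c(
    substring(genome_chr["chr1"], 101, 220),
    substring(genome_chr["chr1"], 15001, 15120),
    substring(genome_chr["chr2"], 501, 620)
  )
  hits <- count_genome_hits(probes, genome)
  expect_equal(hits, vapply(probes, oracle_hits, integer(1), genome_chr,
                            USE.NAMES = FALSE))
  expect_true(all(hits >= 1L))
})

test_that("palindromic probes count once per strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTTTTGAATTCTTTTT"))
  expect_equal(count_genome_hits("GAATTC", genome), 2L)
  expect_equal(oracle_hits("GAATTC", c(chr1 = "TTTTTGAATTCTTTTT")), 2L)
})

test_that("ambiguity codes act as wildcards and still return a count", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTAAAA"))
  expect_equal(count_genome_hits("ACNT", genome), 2L) # ACGT fwd + rev
  expect_equal(count_genome_hits("AANGTA", genome), 1L)
})

test_that("the specificity filter removes strictly above max_hits", {
  baits <- tibble::tibble(
    bait_id = c("b1", "b2", "b3"),
    source_gene = "g", chrom = "chr1",
    start = c(0L, 130L, 260L), end = c(120L, 250L, 380L), strand = "+",
    seq = c("AAA", "CCC", "GGG"),
    hit_count = c(11L, 10L, 1L),
    status = "kept"
  )
  out <- specificity_filter(baits, genome = NULL, max_hits = 10L)
  expect_equal(out$status, c("removed_multihit", "kept", "kept"))
  empty <- baits[0, ]
  expect_equal(nrow(specificity_filter(empty, NULL, 10L)), 0L)
})

test_that("planted multicopy probes are filtered exactly at the threshold", {
  study <- mini_study()
  lib <- design_baits(study$regions, study$ref$genome,
                      masks = study$ref$repeats)
  b <- lib$baits
  mc <- study$ref$multicopy
  removed <- b[b$seq == mc$seq[mc$seq_id == "mc_removed"], ]
  kept <- b[b$seq == mc$seq[mc$seq_id == "mc_kept"], ]
  expect_equal(removed$hit_count, 11L)
  expect_equal(removed$status, "removed_multihit")
  expect_equal(kept$hit_count, 10L)
  expect_equal(kept$status, "kept")
  # oracle agreement on the planted sequences
  genome_chr <- as.character(study$ref$genome)
  expect_equal(oracle_hits(mc$seq[1], genome_chr), 11L)
  expect_equal(oracle_hits(mc$seq[2], genome_chr), 10L)
})

test_that("design conserves baits across statuses and keeps unique probes", {
  study <- mini_study()
  lib <- design_baits(study$regions, study$ref$genome,
                      masks = study$ref$repeats)
  g <- glance(lib)
  expect_equal(g$n_kept + g$n_removed_repeat + g$n_removed_multihit +
                 g$n_removed_duplicate, g$n_baits)
  expect_equal(sum(lib$report$emitted), nrow(lib$baits))
  kept <- lib$baits[lib$baits$status == "kept", ]
  expect_false(any(duplicated(paste(kept$chrom, kept$start, kept$end))))
  expect_false(any(duplicated(kept$seq)))
  expect_true(all(nchar(lib$baits$seq) == 120L))
  expect_true(all(lib$baits$end - lib$baits$start == 120L))
  # adjacent target genes share an intergenic span: duplicates were condensed
  expect_gt(g$n_removed_duplicate, 0L)
})

test_that("no bait overlaps a mask under the exclude policy, and tiling covers sub-intervals", {
  study <- mini_study()
  masks <- study$ref$repeats
  lib <- design_baits(study$regions, study$ref$genome, masks = masks)
  b <- lib$baits
  for (i in seq_len(nrow(masks))) {
    hit <- b$chrom == masks$chrom[i] & b$start < masks$end[i] &
      b$end > masks$start[i]
    expect_false(any(hit))
  }
  # every unmasked sub-interval of length >= 120 is fully covered by the
  # emitted tiling of its own gene
  pieces <- subtract_masks(study$regions, masks)
  pieces <- pieces[pieces$end - pieces$start >= 120L, ]
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    own <- b[b$source_gene == p$gene_id & b$chrom == p$chrom, ]
    covered <- rep(FALSE, p$end - p$start)
    for (j in seq_len(nrow(own))) {
      lo <- max(own$start[j], p$start) - p$start
      hi <- min(own$end[j], p$end) - p$start
      if (hi > lo) covered[(lo + 1):hi] <- TRUE
    }
    expect_true(all(covered))
  }
})

test_that("mask policy 'ignore' tiles across masks; flagging then marks them", {
  study <- mini_study()
  masks <- study$ref$repeats
  lib <- design_baits(study$regions, study$ref$genome, masks = masks,
                      params = bait_params(mask_policy = "ignore"))
  flagged <- flag_masked_baits(lib$baits, masks)
  over <- flagged$chrom == masks$chrom[1] & flagged$start < masks$end[1] &
    flagged$end > masks$start[1]
  expect_true(any(over))
  expect_true(all(flagged$status[over] %in%
                    c("removed_repeat", "removed_duplicate", "removed_multihit")))
})

test_that("bait output files round-trip and are byte-identical across runs", {
  dir <- withr::local_tempdir()
  study <- mini_study()
  lib <- design_baits(study$regions, study$ref$genome,
                      masks = study$ref$repeats)
  p1 <- file.path(dir, "a"); p2 <- file.path(dir, "b")
  for (p in c(p1, p2)) {
    write_bait_library(lib, fasta_path = paste0(p, ".fa"),
                       bed_path = paste0(p, ".bed"),
                       report_path = paste0(p, ".tsv"))
  }
  expect_identical(readLines(paste0(p1, ".fa")), readLines(paste0(p2, ".fa")))
  expect_identical(readLines(paste0(p1, ".bed")), readLines(paste0(p2, ".bed")))

  kept <- lib$baits[lib$baits$status == "kept", ]
  bed <- read_bed(paste0(p1, ".bed"))
  expect_equal(bed$start, kept$start)
  expect_equal(bed$end, kept$end)
  fa <- Biostrings::readDNAStringSet(paste0(p1, ".fa"))
  expect_equal(length(fa), nrow(kept))
  report <- readr::read_tsv(paste0(p1, ".tsv"), show_col_types = FALSE)
  expect_equal(nrow(report), nrow(lib$baits))

  lib2 <- design_baits(study$regions, study$ref$genome,
                       masks = study$ref$repeats)
  expect_identical(lib$baits, lib2$baits)
})

test_that("invalid tiling parameters are rejected", {
  expect_error(bait_params(overlap = 120), "overlap")
  expect_error(bait_params(overlap = -1), "overlap")
  expect_error(bait_params(max_hits = 0), "max_hits")
})
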