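# Annotation parsing and capture-window geometry.

write_fasta <- function(path, seqs) {
  lines <- unlist(purrr::imap(seqs, ~ c(paste0(">", .y), .x)))
  writeLines(lines, path)
  path
}

test_that("GFF3 coordinates convert to 0-based half-open and exons sort", {
  dir <- withr::local_tempdir()
  set.seed(1)
  fa <- write_fasta(file.path(dir, "g.fa"), list(chr1 = random_dna(3000)))
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tx\texon\t1501\t2000\t.\t+\t.\tParent=gA.1",
    "chr1\tx\texon\t1001\t1200\t.\t+\t.\tParent=gA.1",
    "chr1\tx\tCDS\t1051\t1900\t.\t+\t0\tParent=gA.1"
  ), gff)
  models <- read_gene_models(gff, read_genome(fa))
  expect_equal(models$start, 1000L)
  expect_equal(models$end, 2000L)
  expect_equal(models$cds_start, 1050L)
  expect_equal(models$cds_end, 1900L)
  ex <- models$exons[[1]]
  expect_equal(nrow(ex), 2L)
  expect_true(all(diff(ex$start) > 0)) # sorted
  expect_true(all(ex$start >= models$start & ex$end <= models$end))
})

test_that("annotation errors are specific: malformed line, missing chromosome, no CDS", {
  dir <- withr::local_tempdir()
  set.seed(2)
  fa <- write_fasta(file.path(dir, "g.fa"), list(chr1 = random_dna(500)))
  genome <- read_genome(fa)

  bad <- file.path(dir, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=gA",
    "chr1\tx\tgene\t1\t100\t.\t+" # 7 fields
  ), bad)
  expect_error(read_gene_models(bad, genome), "line 3")

  off <- file.path(dir, "off.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr9\tx\tgene\t1\t100\t.\t+\t.\tID=gA"
  ), off)
  expect_error(read_gene_models(off, genome), "chr9")

  nocds <- file.path(dir, "nocds.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=gA",
    "chr1\tx\tgene\t301\t400\t.\t+\t.\tID=gB",
    "chr1\tx\tmRNA\t301\t400\t.\t+\t.\tID=gB.1;Parent=gB",
    "chr1\tx\tCDS\t301\t400\t.\t+\t0\tParent=gB.1"
  ), nocds)
  expect_warning(models <- read_gene_models(nocds, genome), "gA")
  expect_equal(models$cds_start[models$gene_id == "gA"], 100L)
  expect_equal(models$cds_end[models$gene_id == "gA"], 200L)
})

test_that("neighbour bounds use nearest CDS, chromosome ends, and clamp overlaps", {
  models <- make_models(tibble::tibble(
    gene_id = c("left", "mid", "right"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 5000L, 12000L),
    end = c(3000L, 6000L, 13000L)
  ), c(chr1 = 20000L))
  b <- neighbor_bounds(models)
  mid <- b[b$gene_id == "mid", ]
  expect_equal(mid$upstream_limit, 3000) # CDS end of left neighbour
  expect_equal(mid$upstream_gap, 2000)
  expect_equal(mid$downstream_limit, 12000)
  expect_equal(mid$downstream_gap, 6000)
  # chromosome ends where no neighbour exists
  expect_equal(b$upstream_limit[b$gene_id == "left"], 0)
  expect_equal(b$downstream_limit[b$gene_id == "right"], 20000)

  overlapping <- make_models(tibble::tibble(
    gene_id = c("a", "b"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 1800L),
    end = c(2000L, 2600L)
  ), c(chr1 = 10000L))
  expect_warning(bo <- neighbor_bounds(overlapping), "clamped")
  expect_equal(bo$downstream_gap[bo$gene_id == "a"], 0)
  expect_equal(bo$upstream_gap[bo$gene_id == "b"], 0)
})

test_that("flank rule: intergenic gap below the cap wins, otherwise the cap", {
  models <- make_models(tibble::tibble(
    gene_id = c("left", "mid", "right"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 4000L, 15000L),
    end = c(3000L, 9000L, 16000L)
  ), c(chr1 = 40000L))
  r <- build_target_regions(models, targets = "mid")
  expect_equal(r$promoter_len, 1000L) # gap 1000 < 4500
  expect_equal(r$terminator_len, 4500L) # gap 6000 capped
  expect_equal(r$end - r$start, r$promoter_len + 5000L + r$terminator_len)
})

test_that("an isolated gene gets the cap on both sides", {
  models <- make_models(tibble::tibble(
    gene_id = "solo", chrom = "chr1", strand = "+",
    start = 10000L, end = 12000L
  ), c(chr1 = 40000L))
  r <- build_target_regions(models)
  expect_equal(r$end - r$start, 2000L + 9000L)
  expect_equal(r$promoter_len, 4500L)
  expect_equal(r$terminator_len, 4500L)
})

test_that("strand symmetry: a minus-strand gene mirrors the plus-strand geometry", {
  base <- tibble::tibble(
    gene_id = c("left", "mid", "right"),
    chrom = "chr1",
    start = c(1000L, 4000L, 15000L),
    end = c(3000L, 9000L, 16000L)
  )
  plus <- make_models(dplyr::mutate(base, strand = "+"), c(chr1 = 40000L))
  minus <- make_models(dplyr::mutate(base, strand = "-"), c(chr1 = 40000L))
  rp <- build_target_regions(plus, targets = "mid")
  rm_ <- build_target_regions(minus, targets = "mid")
  # same genomic span, promoter/terminator swapped
  expect_equal(rp$start, rm_$start)
  expect_equal(rp$end, rm_$end)
  expect_equal(rp$promoter_len, rm_$terminator_len)
  expect_equal(rp$terminator_len, rm_$promoter_len)
})

test_that("spans clip to the chromosome", {
  models <- make_models(tibble::tibble(
    gene_id = "edge", chrom = "chr1", strand = "+",
    start = 1200L, end = 2200L
  ), c(chr1 = 3000L))
  r <- build_target_regions(models)
  expect_equal(r$start, 0L)
  expect_equal(r$promoter_len, 1200L)
  expect_equal(r$end, 3000L)
  expect_equal(r$terminator_len, 800L)
})

test_that("templates are the coding strand: slice for +, reverse complement for -", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGAAACGG", chr2 = "GGACGTGG"))
  regions <- tibble::tibble(
    gene_id = c("p", "m", "pal"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "-"),
    start = c(2L, 2L, 2L),
    end = c(6L, 6L, 6L)
  )
  out <- region_templates(regions, genome)
  expect_equal(out$template[1], "AAAC")
  expect_equal(out$template[2], "GTTT")
  expect_equal(out$template[3], "ACGT") # its own reverse complement
  # involution: reverse-complementing a minus template recovers the slice
  expect_equal(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(out$template[2]))),
    out$template[1]
  )
  expect_error(
    region_templates(tibble::tibble(gene_id = "x", chrom = "chr1",
                                    strand = "+", start = 5L, end = 50L),
                     genome),
    "outside"
  )
})

test_that("parsing and design are deterministic and BED/FASTA round-trip", {
  dir <- withr::local_tempdir()
  ref <- simulate_reference(fixture_spec(seed = 3))
  paths <- write_reference(ref, file.path(dir, "ref"))
  genome <- read_genome(paths$genome)
  m1 <- suppressWarnings(read_gene_models(paths$gff, genome))
  m2 <- suppressWarnings(read_gene_models(paths$gff, genome))
  expect_identical(m1, m2)

  regions <- suppressWarnings(
    build_target_regions(m1, targets = readLines(paths$targets)))
  bed <- file.path(dir, "r.bed"); fa <- file.path(dir, "r.fa")
  write_target_regions(regions, genome, bed_path = bed, fasta_path = fa)
  back <- read_bed(bed)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  expect_equal(back$name, regions$gene_id)
  expect_equal(back$strand, regions$strand)
  seqs <- read_genome(fa) # generic FASTA reader
  expect_equal(length(seqs), nrow(regions))
  expect_equal(unname(Biostrings::width(seqs)), regions$end - regions$start)
})
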