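#' Specification of a synthetic capture-seq study
#'
#' Collects every knob of the synthetic-data generator: the condition
#' design (genotypes x treatments x replicates, mirroring an immune-
#' activation survey of wild type plus signalling mutants under mock and
#' effector treatments), replicate noise, per-sample library-size factors,
#' and the geometry constants of the planted reference.
#'
#' The `"full"` preset is the default study design: 8 genotypes
#' (`wt, eds1, r1ab, sid2, gh, myc234, tplr14, peds`) x 4 treatments
#' (`mk, kv, a4, a2`) plus untreated wild type (`wt_un`), 3 biological
#' replicates each (99 cDNA samples), with gDNA spike-in libraries for
#' capture QC. The `"mini"` preset is a small design (2 genotypes x 2
#' treatments + `wt_un`, 2 replicates) for alignment-level work.
#'
#' @param seed Integer seed; the whole fixture chain is deterministic
#'   given the seed.
#' @param preset `"full"` (the complete study design) or `"mini"`.
#' @param genotypes,treatments,replicates,gdna_replicates Condition design
#'   overrides.
#' @param dispersion Negative-binomial dispersion of replicate noise
#'   (variance `mu + dispersion * mu^2`); 0 gives exact expected values.
#' @param libsize_log2sd Log2-sd of random per-sample library-size factors
#'   (rescaled to geometric mean 1).
#' @param libsize_factors Optional explicit per-sample factors (recycled to
#'   the number of cDNA samples, then rescaled to geometric mean 1);
#'   overrides `libsize_log2sd`.
#' @param base_range Range of per-gene baseline expression levels (counts
#'   in the reference condition), sampled log-uniformly.
#' @param multicopy_n,multicopy_kept_n Copy numbers of the two planted
#'   120-mers exercising the specificity filter (default 11 = removed under
#'   `max_hits = 10`, and 10 = kept).
#' @param read_len Simulated read length (single-end).
#' @param gdna_step Tiling step of gDNA spike-in reads over each region
#'   (must be `<= read_len` so breadth reaches 1).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         preset = c("full", "mini"),
                         genotypes = NULL, treatments = NULL,
                         replicates = NULL, gdna_replicates = NULL,
                         dispersion = 0.1,
                         libsize_log2sd = 0.25, libsize_factors = NULL,
                         base_range = c(100, 2000),
                         multicopy_n = 11L, multicopy_kept_n = 10L,
                         read_len = 74L, gdna_step = 37L) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(genotypes = c("wt", "eds1", "r1ab", "sid2", "gh", "myc234",
                       "tplr14", "peds"),
         treatments = c("mk", "kv", "a4", "a2"),
         replicates = 3L, gdna_replicates = 2L)
  } else {
    list(genotypes = c("wt", "eds1"), treatments = c("mk", "a4"),
         replicates = 2L, gdna_replicates = 2L)
  }
  structure(
    list(
      seed = as.integer(seed), preset = preset,
      genotypes = genotypes %||% def$genotypes,
      treatments = treatments %||% def$treatments,
      replicates = as.integer(replicates %||% def$replicates),
      gdna_replicates = as.integer(gdna_replicates %||% def$gdna_replicates),
      dispersion = dispersion,
      libsize_log2sd = libsize_log2sd,
      libsize_factors = libsize_factors,
      base_range = base_range,
      multicopy_n = as.integer(multicopy_n),
      multicopy_kept_n = as.integer(multicopy_kept_n),
      read_len = as.integer(read_len),
      gdna_step = as.integer(gdna_step)
    ),
    class = "fixture_spec"
  )
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic gene layout of the toy reference. Gaps are CDS-to-CDS and
# exercise every geometric branch: chromosome-edge gene, sub-cap and
# super-cap gaps, a minus-strand target, an overlapping-CDS pair, an
# adjacent target pair whose tiling frames coincide in the shared
# intergenic span (planting duplicate baits), two isolated genes hosting
# the planted multicopy 120-mers at their capture-window starts, a
# repeat-masked gene and a tissue-specific negative control.
fixture_layout <- function() {
  tibble::tribble(
    ~gene_id, ~role,        ~archetype,   ~strand, ~gap, ~len,
    "t01",    "target",     "control",    "+",     1200, 1000,
    "n01",    "neighbor",   NA,           "+",     1000,  800,
    "t02",    "target",     "control",    "+",      600, 1500,
    "n02",    "neighbor",   NA,           "-",     6000,  700,
    "t03",    "target",     "repressed",  "-",     5000, 1200,
    "n03",    "neighbor",   NA,           "+",     -200,  600,
    "t04",    "target",     "induced",    "+",     5000, 3019,
    "t05",    "target",     "genotype",   "+",      800, 1400,
    "n04",    "neighbor",   NA,           "+",     2000,  600,
    "t06",    "target",     "induced",    "+",     6000, 1500,
    "t07",    "target",     "repressed",  "+",     7000, 1300,
    "t08",    "target",     "genotype",   "+",     5000, 2000,
    "t09",    "target",     "negcontrol", "+",     5000, 1500,
    "n05",    "neighbor",   NA,           "+",     1500,  600
  )
}

#' Generate a synthetic reference: genome, annotation, repeats, truth
#'
#' Builds a two-chromosome toy genome with an annotated gene set covering
#' the geometric edge cases of capture design (see Details), planted
#' repeat intervals, and two planted multicopy 120-mers (`multicopy_n` and
#' `multicopy_kept_n` exact copies) positioned so that each becomes a bait
#' of its host gene's capture window. Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture_reference`: `genome` (`DNAStringSet`),
#'   `genes` (truth layout with coordinates, roles and archetypes),
#'   `repeats` (mask tibble), `multicopy` (planted-sequence truth),
#'   `chrom_sizes`.
#' @export
simulate_reference <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  layout <- fixture_layout()

  # resolve gaps to absolute coordinates (0-based half-open)
  cursor <- 0
  start <- integer(nrow(layout)); end <- integer(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    start[i] <- cursor + layout$gap[i]
    end[i] <- start[i] + layout$len[i]
    cursor <- end[i]
  }
  genes <- layout |>
    dplyr::mutate(chrom = "chr1", start = start, end = end)
  chr1_len <- max(genes$end) + 6000

  mc11_pos <- genes$start[genes$gene_id == "t06"] - 4500
  mc10_pos <- genes$start[genes$gene_id == "t07"] - 4500
  t08_start <- genes$start[genes$gene_id == "t08"]
  t09_start <- genes$start[genes$gene_id == "t09"]
  repeats <- tibble::tibble(
    chrom = "chr1",
    start = c(t08_start + 800, t09_start - 1000),
    end = c(t08_start + 1100, t09_start - 700)
  )

  n_extra11 <- spec$multicopy_n - 1L
  n_extra10 <- spec$multicopy_kept_n - 1L
  extra11_pos <- 1000 + (seq_len(n_extra11) - 1L) * 500
  extra10_pos <- max(extra11_pos) + 1000 + (seq_len(n_extra10) - 1L) * 500
  chr2_len <- max(extra10_pos) + 1000

  with_seed(spec$seed, {
    chr1 <- rand_dna(chr1_len)
    chr2 <- rand_dna(chr2_len)
    mc11 <- rand_dna(120)
    mc10 <- rand_dna(120)
  })

  plant <- function(seq, insert, pos0) {
    # pos0 is 0-based
    paste0(substring(seq, 1, pos0), insert,
           substring(seq, pos0 + nchar(insert) + 1))
  }
  chr1 <- plant(chr1, mc11, mc11_pos)
  chr1 <- plant(chr1, mc10, mc10_pos)
  low_complexity <- function(n) substring(strrep("TA", ceiling(n / 2)), 1, n)
  for (i in seq_len(nrow(repeats))) {
    chr1 <- plant(chr1, low_complexity(repeats$end[i] - repeats$start[i]),
                  repeats$start[i])
  }
  for (p in extra11_pos) chr2 <- plant(chr2, mc11, p)
  for (p in extra10_pos) chr2 <- plant(chr2, mc10, p)

  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  multicopy <- tibble::tibble(
    seq_id = c("mc_removed", "mc_kept"),
    seq = c(mc11, mc10),
    n_copies = c(spec$multicopy_n, spec$multicopy_kept_n),
    host_gene = c("t06", "t07"),
    host_pos = c(mc11_pos, mc10_pos)
  )

  structure(
    list(genome = genome, genes = genes, repeats = repeats,
         multicopy = multicopy,
         chrom_sizes = stats::setNames(c(chr1_len, chr2_len), c("chr1", "chr2"))),
    class = "fixture_reference"
  )
}

# GFF3 emission for the fixture annotation (1-based inclusive on disk).
# Gene "t02" carries a two-exon structure; all other genes are single-exon
# with CDS spanning the gene.
fixture_gff_lines <- function(genes) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s1 <- g$start + 1L; e1 <- g$end
    gid <- g$gene_id; mid <- paste0(gid, ".1")
    lines <- c(lines,
      sprintf("chr1\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s", s1, e1, g$strand, gid),
      sprintf("chr1\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              s1, e1, g$strand, mid, gid))
    if (gid == "t02") {
      ex <- rbind(c(0, 600), c(900, g$len))
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines,
          sprintf("chr1\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                  g$start + ex[k, 1] + 1L, g$start + ex[k, 2], g$strand, mid),
          sprintf("chr1\tfixture\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                  g$start + ex[k, 1] + 1L, g$start + ex[k, 2], g$strand, mid))
      }
    } else {
      lines <- c(lines,
        sprintf("chr1\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s", s1, e1, g$strand, mid),
        sprintf("chr1\tfixture\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s", s1, e1, g$strand, mid))
    }
  }
  lines
}

#' Write a synthetic reference to disk
#'
#' Emits genome FASTA, GFF3 annotation, repeat BED, target gene list and
#' truth tables into a directory. Byte-identical across runs for the same
#' reference object.
#'
#' @param ref A `fixture_reference` from [simulate_reference()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "annotation.gff3"),
    repeats = file.path(dir, "repeats.bed"),
    targets = file.path(dir, "target_genes.txt"),
    gene_truth = file.path(dir, "truth_genes.tsv"),
    multicopy_truth = file.path(dir, "truth_multicopy.tsv")
  )
  Biostrings::writeXStringSet(ref$genome, paths$genome)
  writeLines(fixture_gff_lines(ref$genes), paths$gff)
  readr::write_tsv(
    dplyr::mutate(ref$repeats, name = paste0("repeat_", dplyr::row_number())),
    paths$repeats, col_names = FALSE)
  writeLines(ref$genes$gene_id[ref$genes$role == "target"], paths$targets)
  readr::write_tsv(ref$genes, paths$gene_truth)
  readr::write_tsv(ref$multicopy, paths$multicopy_truth)
  invisible(paths)
}

# Condition table of a fixture spec: every genotype x treatment plus
# untreated wild type (the reference condition).
fixture_conditions <- function(spec) {
  dplyr::bind_rows(
    tibble::tibble(genotype = "wt", treatment = "un"),
    tidyr::expand_grid(genotype = spec$genotypes, treatment = spec$treatments)
  ) |>
    dplyr::mutate(condition = paste(.data$genotype, .data$treatment, sep = "_"))
}

#' Sample sheet of a synthetic study
#'
#' @param spec A [fixture_spec()].
#' @return Tibble `sample_id`, `genotype`, `treatment`, `replicate`,
#'   `material` (cDNA rows for every condition x replicate, plus gDNA
#'   spike-ins).
#' @export
fixture_samples <- function(spec) {
  cdna <- fixture_conditions(spec) |>
    tidyr::expand_grid(replicate = seq_len(spec$replicates)) |>
    dplyr::mutate(
      sample_id = paste(.data$condition, paste0("r", .data$replicate), sep = "_"),
      material = "cDNA"
    ) |>
    dplyr::select("sample_id", "genotype", "treatment", "replicate", "material")
  gdna <- tibble::tibble(
    sample_id = paste0("gdna_r", seq_len(spec$gdna_replicates)),
    genotype = "wt", treatment = "un",
    replicate = seq_len(spec$gdna_replicates),
    material = "gDNA"
  )
  dplyr::bind_rows(cdna, gdna)
}

# Planted expression multiplier for one gene archetype under one condition.
# "induced": immune-response genes up under effector treatments, with
#   genotype-dependent attenuation (eds1/r1ab lose the AvrRps4-triggered
#   response; sid2/gh/peds attenuate all responses).
# "repressed": growth/JA-side genes down under all effector treatments.
# "genotype": co-repressor targets derepressed in myc234/tplr14 regardless
#   of treatment.
# "control": stable; "negcontrol": never expressed in the sampled tissue.
fixture_multiplier <- function(archetype, genotype, treatment) {
  base_eff <- c(un = 1, mk = 1, kv = 4, a4 = 8, a2 = 8)
  atten <- function(genotype, treatment) {
    if (genotype %in% c("sid2", "gh", "peds")) return(0.4)
    if (genotype %in% c("eds1") && treatment %in% c("kv", "a4")) return(0.3)
    if (genotype %in% c("r1ab") && treatment == "a4") return(0.3)
    1
  }
  switch(archetype,
    induced = unname(base_eff[treatment])^atten(genotype, treatment),
    repressed = if (treatment %in% c("kv", "a4", "a2")) 0.4 else 1,
    genotype = if (genotype %in% c("myc234", "tplr14")) 4 else 1,
    control = 1,
    negcontrol = 0,
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
}

# Default count-level gene panel: a scaled study panel with three
# structured archetypes plus stable controls and one tissue negative
# control. Baselines are drawn log-uniformly from spec$base_range.
fixture_gene_panel <- function(spec) {
  ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  panel <- tibble::tibble(
    gene_id = c(ids("erg", 8), ids("jag", 8), ids("cor", 8), ids("ctl", 11), "neg01"),
    archetype = c(rep("induced", 8), rep("repressed", 8), rep("genotype", 8),
                  rep("control", 11), "negcontrol")
  )
  with_seed(spec$seed + 1000L, {
    lr <- runif(nrow(panel), log(spec$base_range[1]), log(spec$base_range[2]))
  })
  # baselines at a resolution of 10 counts: expected counts stay integral
  # under the dyadic library-size factors and rational effect sizes used in
  # exactness checks
  panel$base <- pmax(10, round(exp(lr) / 10) * 10)
  panel
}

#' Simulate a capture-seq count matrix with known truth
#'
#' Draws per-gene, per-sample counts around
#' `libsize_factor * base * multiplier(gene, condition)` with
#' negative-binomial replicate noise of the given dispersion. At
#' `dispersion = 0` the exact (real-valued) expected products are returned.
#' The tissue negative-control gene is 0 in every cDNA sample.
#'
#' @param spec A [fixture_spec()].
#' @param genes Optional gene panel tibble (`gene_id`, `archetype`,
#'   `base`); defaults to a built-in panel of 8 induced + 8 repressed + 8
#'   genotype-driven genes, 11 stable controls and 1 negative control.
#' @return List of class `fixture_counts`: `counts` (wide tibble),
#'   `samples` (cDNA sample sheet), and `truth` (list with the multiplier
#'   matrix per condition, library-size factors, baselines and archetypes).
#' @export
simulate_counts <- function(spec = fixture_spec(), genes = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- genes %||% fixture_gene_panel(spec)
  stopifnot(all(c("gene_id", "archetype", "base") %in% names(genes)))
  samples <- dplyr::filter(fixture_samples(spec), .data$material == "cDNA")
  conds <- fixture_conditions(spec)

  mult <- sapply(seq_len(nrow(conds)), function(j) {
    vapply(seq_len(nrow(genes)), function(i) {
      fixture_multiplier(genes$archetype[i], conds$genotype[j], conds$treatment[j])
    }, numeric(1))
  })
  dimnames(mult) <- list(genes$gene_id, conds$condition)

  n_s <- nrow(samples)
  if (!is.null(spec$libsize_factors)) {
    f <- rep_len(spec$libsize_factors, n_s)
    f <- f / geo_mean(f)
  } else {
    with_seed(spec$seed + 2000L, {
      f <- 2^stats::rnorm(n_s, 0, spec$libsize_log2sd)
    })
    f <- f / geo_mean(f)
  }
  names(f) <- samples$sample_id

  cond_of <- paste(samples$genotype, samples$treatment, sep = "_")
  mu <- mult[, cond_of, drop = FALSE] *
    outer(genes$base, unname(f))
  colnames(mu) <- samples$sample_id

  if (spec$dispersion == 0) {
    counts <- mu
  } else {
    with_seed(spec$seed + 3000L, {
      counts <- matrix(
        stats::rnbinom(length(mu), mu = as.numeric(mu), size = 1 / spec$dispersion),
        nrow = nrow(mu), dimnames = dimnames(mu)
      )
    })
  }
  structure(
    list(
      counts = matrix_to_counts(counts),
      samples = samples,
      truth = list(multipliers = matrix_to_counts(mult), lib_factors = f,
                   genes = genes)
    ),
    class = "fixture_counts"
  )
}

# One SAM alignment block per read; reads are emitted coordinate-sorted.
sam_lines <- function(qname, chrom, pos0, seqs, read_len) {
  ord <- order(pos0)
  sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
          qname[ord], chrom[ord], pos0[ord] + 1L, read_len, seqs[ord])
}

#' Simulate aligned capture-seq reads
#'
#' Emits per-sample SAM files of single-end reads (74 nt by default).
#' cDNA reads are placed uniformly within the expressed gene bodies, one
#' read per simulated count; the tissue negative control gets none. gDNA
#' spike-in samples tile every capture region at a fixed step not
#' exceeding the read length, so every region reaches breadth 1.
#'
#' @param ref A `fixture_reference`.
#' @param regions Target-region tibble (from [build_target_regions()] on
#'   the fixture annotation) -- used for gDNA tiling.
#' @param counts A `fixture_counts` whose gene panel matches the reference
#'   target genes (see [simulate_study()]).
#' @param spec The [fixture_spec()] used throughout.
#' @param dir Output directory for the SAM files.
#' @return The full sample sheet with a `path` column appended.
#' @export
simulate_alignments <- function(ref, regions, counts, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- fixture_samples(spec)
  rl <- spec$read_len
  genome_chr <- stats::setNames(as.character(ref$genome), names(ref$genome))
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref$chrom_sizes), ref$chrom_sizes)
  )
  bodies <- ref$genes[ref$genes$role == "target", c("gene_id", "chrom", "start", "end")]
  cmat <- counts_to_matrix(counts$counts)

  paths <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    path <- file.path(dir, paste0(s$sample_id, ".sam"))
    if (s$material == "gDNA") {
      recs <- purrr::pmap(
        list(regions$gene_id, regions$chrom, regions$start, regions$end),
        function(gene_id, chrom, start, end) {
          starts <- unique(c(seq(start, end - rl, by = spec$gdna_step), end - rl))
          tibble::tibble(
            qname = sprintf("%s_%s_g%04d", s$sample_id, gene_id, seq_along(starts)),
            chrom = chrom, pos0 = as.integer(starts)
          )
        }
      ) |> purrr::list_rbind()
    } else {
      recs <- with_seed(spec$seed + 4000L + i, {
        purrr::pmap(
          list(bodies$gene_id, bodies$chrom, bodies$start, bodies$end),
          function(gene_id, chrom, start, end) {
            n <- round(cmat[gene_id, s$sample_id])
            if (n <= 0) return(NULL)
            starts <- start + floor(runif(n, 0, end - start - rl + 1))
            tibble::tibble(
              qname = sprintf("%s_%s_c%05d", s$sample_id, gene_id, seq_len(n)),
              chrom = chrom, pos0 = as.integer(starts)
            )
          }
        ) |> purrr::list_rbind()
      })
    }
    lines <- header
    if (!is.null(recs) && nrow(recs)) {
      recs <- dplyr::arrange(recs, .data$chrom, .data$pos0)
      seqs <- substring(genome_chr[recs$chrom], recs$pos0 + 1L, recs$pos0 + rl)
      lines <- c(header, sam_lines(recs$qname, recs$chrom, recs$pos0, seqs, rl))
    }
    writeLines(lines, path)
    paths[i] <- path
  }
  samples$path <- paths
  samples
}

#' Simulate a complete capture-seq study
#'
#' Convenience wrapper chaining the whole fixture pipeline: reference
#' genome/annotation/repeats, target regions, count simulation restricted
#' to the reference target genes, and per-sample aligned reads. The count
#' panel maps the reference targets onto the planted archetypes with
#' seeded baselines.
#'
#' @param spec A [fixture_spec()] (the `"mini"` preset is recommended for
#'   alignment-level work).
#' @param dir Directory receiving reference files and SAM files.
#' @return List with `ref`, `models`, `regions`, `counts`
#'   (a `fixture_counts`), `samples` (sheet with paths) and `paths` (the
#'   reference file paths).
#' @export
simulate_study <- function(spec = fixture_spec(preset = "mini"), dir = tempfile()) {
  ref <- simulate_reference(spec)
  paths <- write_reference(ref, dir)
  genome <- read_genome(paths$genome)
  models <- suppressWarnings(read_gene_models(paths$gff, genome))
  targets <- ref$genes$gene_id[ref$genes$role == "target"]
  regions <- suppressWarnings(build_target_regions(models, targets = targets))

  panel <- ref$genes |>
    dplyr::filter(.data$role == "target") |>
    dplyr::select("gene_id", "archetype")
  with_seed(spec$seed + 5000L, {
    lr <- runif(nrow(panel), log(spec$base_range[1]), log(spec$base_range[2]))
  })
  panel$base <- pmax(10, round(exp(lr) / 10) * 10)
  counts <- simulate_counts(spec, genes = panel)

  samples <- simulate_alignments(ref, regions, counts, spec, file.path(dir, "alignments"))
  list(ref = ref, models = models, regions = regions, counts = counts,
       samples = samples, paths = paths)
}
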