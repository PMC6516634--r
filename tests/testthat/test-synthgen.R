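# synthetic genome, read, Hi-C, fiber and qPCR generators

test_that("build_genome plants the island where the blocks say", {
  b <- build_genome(example_spec(seed = 5))
  expect_equal(b$truth$island_spans,
               data.frame(contig = "c1", start = 10000L, end = 15000L))
  expect_equal(nchar(b$genome[["c1"]]), 25000L)
  # truth intervals tile the contig exactly
  iv <- b$truth$intervals
  expect_equal(iv$start[1], 0)
  expect_equal(iv$start[-1], head(iv$end, -1))
  expect_equal(tail(iv$end, 1), 25000)
  # satellite arrays are pure unit repeats
  expect_equal(substr(b$genome[["c1"]], 1, 10), "AATATAATAT")
})

test_that("the same seed reproduces the genome byte for byte", {
  b1 <- build_genome(default_genome_spec(9))
  b2 <- build_genome(default_genome_spec(9))
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$truth, b2$truth)
  b3 <- build_genome(default_genome_spec(10))
  expect_false(identical(b1$genome, b3$genome))
})

test_that("forced truncation shortens every element copy", {
  spec <- example_spec(seed = 2, truncation_prob = 1)
  b <- build_genome(spec)
  el <- b$truth$intervals[b$truth$intervals$class == "element", ]
  expect_true(all(el$end - el$start < 3000))
  expect_true(all(!el$full_length))
})

test_that("spec validation rejects malformed designs", {
  expect_error(genome_spec(
    contigs = list(list(name = "c", blocks = list(
      list(kind = "island", elements = "elX")))),
    satellite_defs = c(satA = "AATAT"), element_defs = c(el1 = 1000L),
    shared_element = "el1"), "shared element|unknown")
  # control satellite must not share a contig with an island
  expect_error(genome_spec(
    contigs = list(list(name = "c", blocks = list(
      list(kind = "satellite", family = "satA", length = 1000L),
      list(kind = "island", elements = "el1")))),
    satellite_defs = c(satA = "AATAT"), element_defs = c(el1 = 1000L),
    shared_element = "el1", control_satellite = "satA"),
    "control satellite")
  # explicitly positioned blocks must not overlap
  expect_error(genome_spec(
    contigs = list(list(name = "c", blocks = list(
      list(kind = "satellite", family = "satA", length = 1000L, start = 500L),
      list(kind = "satellite", family = "satA", length = 1000L, start = 100L)))),
    satellite_defs = c(satA = "AATAT"), element_defs = c(el1 = 1000L),
    shared_element = "el1"), "overlap")
})

test_that("read simulation hits the requested coverage and is seeded", {
  spec <- genome_spec(
    contigs = list(list(name = "c1", blocks = list(
      list(kind = "unique", length = 100000L)))),
    satellite_defs = c(satA = "AATAT"), element_defs = c(el1 = 1000L),
    shared_element = "el1", seed = 3)
  b <- build_genome(spec)
  p <- chip_sim_params(coverage = 30, n_replicates = 1, read_length = 150,
                       fragment_length = 300, seed = 4)
  rs <- simulate_chip_reads(b$genome, b$truth, p)
  chip <- rs$chip_1
  # 30x over 100 kb paired 150 bp -> 3.0 Mb per channel, within one pair
  expect_equal(chip$n_fragments * 2 * 150, 3e6, tolerance = 300 / 3e6)
  expect_equal(sum(nchar(chip$seq1)) + sum(nchar(chip$seq2)), 3e6)
  # reads really come from where the placements say
  i <- c(1L, 77L, chip$n_fragments)
  expect_equal(chip$seq1[i],
               substring(b$genome[["c1"]], chip$start[i] + 1,
                         chip$start[i] + 150))
  expect_equal(chip$seq2[i],
               revcomp(substring(b$genome[["c1"]], chip$start[i] + 300 - 149,
                                 chip$start[i] + 300)))
  rs2 <- simulate_chip_reads(b$genome, b$truth, p)
  expect_identical(rs2$chip_1$seq1, chip$seq1)
  expect_error(simulate_chip_reads(b$genome, b$truth,
                                   chip_sim_params(read_length = 150000,
                                                   fragment_length = 150000)),
               "shortest contig")
  p0 <- chip_sim_params(coverage = 0, n_replicates = 1)
  expect_equal(simulate_chip_reads(b$genome, b$truth, p0)$chip_1$n_fragments, 0)
})

test_that("uniform enrichment gives per-region ratios near 1, planted 10x near 10", {
  spec <- example_spec(seed = 12)
  b <- build_genome(spec)
  p_null <- chip_sim_params(coverage = 15, n_replicates = 1,
                            enrichment = c(island = 1 + 1e-9,
                                           flank_satellite = 1,
                                           background = 1,
                                           control_satellite = 1),
                            seed = 21)
  rs <- simulate_chip_reads(b$genome, b$truth, p_null)
  span <- b$truth$island_spans
  in_island <- function(r) mean(r$start >= span$start & r$start < span$end)
  f_chip <- in_island(rs$chip_1); f_input <- in_island(rs$input_1)
  # binomial sampling bound on the island fraction at n fragments
  pexp <- (span$end - span$start) / nchar(b$genome[["c1"]])
  se <- sqrt(pexp * (1 - pexp) / rs$chip_1$n_fragments)
  expect_lt(abs(f_chip - pexp), 4 * se)
  expect_lt(abs(f_chip / f_input - 1), 0.1)

  p_enr <- chip_sim_params(coverage = 15, n_replicates = 1, seed = 22)
  rs <- simulate_chip_reads(b$genome, b$truth, p_enr,
                            control_satellite = NULL)
  f_chip <- in_island(rs$chip_1); f_input <- in_island(rs$input_1)
  # island weight 10 over 5 kb, flanking satellite weight 3 over 20 kb:
  # expected chip island fraction 10*5 / (10*5 + 3*20) = 5/11, input 1/5;
  # the per-base sampling-rate ratio island/flank is (10/3) * exactly
  expect_equal(f_chip, 5 / 11, tolerance = 0.03)
  expect_equal(f_input, 1 / 5, tolerance = 0.05)
  rate_ratio <- (f_chip / 5000) / ((1 - f_chip) / 20000)
  expect_equal(rate_ratio, 10 / 3, tolerance = 0.05)
})

test_that("Hi-C pair sampling follows size products and rate weights", {
  cm <- data.frame(contig = c("a", "b"), start = 0L,
                   end = c(60000L, 20000L),
                   category = c("centromere", "euchromatin"),
                   unit = c("cenA", NA))
  expect_equal(nrow(simulate_hic_pairs(cm, hic_sim_params(n_pairs = 0))), 0)

  pr <- simulate_hic_pairs(cm, hic_sim_params(n_pairs = 40000, seed = 5))
  cat_of <- function(ctg) ifelse(ctg == "a", "centromere", "euchromatin")
  key <- paste(pmin(cat_of(pr$chrA), cat_of(pr$chrB)),
               pmax(cat_of(pr$chrA), cat_of(pr$chrB)))
  obs <- table(key) / nrow(pr)
  # uniform rates: P(cc) = 9/16, P(ce) = 2*3/16, P(ee) = 1/16
  expect_equal(unname(obs["centromere centromere"]), 9 / 16, tolerance = 0.03)
  expect_equal(unname(obs["centromere euchromatin"]), 6 / 16, tolerance = 0.03)
  expect_equal(unname(obs["euchromatin euchromatin"]), 1 / 16, tolerance = 0.05)

  rate <- matrix(1, 2, 2, dimnames = list(c("centromere", "euchromatin"),
                                          c("centromere", "euchromatin")))
  rate["centromere", "centromere"] <- 5
  pr5 <- simulate_hic_pairs(cm, hic_sim_params(n_pairs = 40000,
                                               rate_matrix = rate, seed = 6))
  key5 <- paste(cat_of(pr5$chrA), cat_of(pr5$chrB))
  f5 <- mean(key5 == "centromere centromere")
  f1 <- mean(key == "centromere centromere")
  expect_equal(f5 / (1 - f5) / (f1 / (1 - f1)), 5, tolerance = 0.1)
})

test_that("fiber measurements are exact at cv = 0 and unbiased with noise", {
  m <- simulate_fiber_measurements(c(p1 = 100), kb_per_um = 10, cv = 0, n = 5)
  expect_true(all(m$um == 10))
  set.seed(1)
  m <- simulate_fiber_measurements(c(p1 = 100), kb_per_um = 10, cv = 0.1,
                                   n = 30, seed = 8)
  expect_lt(abs(mean(m$um) - 10) / 10, 0.05)
})

test_that("simulated qPCR cycles round-trip through the fold formula", {
  expect_equal(simulate_qpcr(100, efficiency = 2, ct_input = 20), 20)
  ct <- simulate_qpcr(800, efficiency = 2, ct_input = 20)
  expect_equal(20 - ct, 3)  # log2(8)
  expect_equal(simulate_qpcr(100, efficiency = 1.5, ct_input = 18), 18)
  for (fold in c(3, 100, 800, 12345)) {
    ct_ip <- simulate_qpcr(fold, efficiency = 1.8, ct_input = 22)
    expect_equal(qpcr_fold(22, ct_ip, efficiency = 1.8), fold)
  }
})

test_that("FASTA/FASTQ/BED/validPairs writers round-trip", {
  dir <- withr::local_tempdir()
  b <- build_genome(example_spec(seed = 31))
  fa <- file.path(dir, "g.fa")
  write_fasta(b$genome, fa)
  expect_identical(read_fasta(fa), b$genome)

  p <- chip_sim_params(coverage = 0.2, n_replicates = 1, seed = 2)
  rs <- simulate_chip_reads(b$genome, b$truth, p)
  write_readset_fastq(rs$chip_1, file.path(dir, "chip"))
  r1 <- read_fastq(file.path(dir, "chip_1.fastq"))
  expect_identical(unname(r1), rs$chip_1$seq1)
  expect_match(names(r1)[1], "^c1:\\d+:1$")

  write_bed(b$truth$intervals, file.path(dir, "truth.bed"))
  bed <- read.table(file.path(dir, "truth.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(b$truth$intervals))
  expect_match(bed$V4[1], "^satellite:")

  cm <- data.frame(contig = "c1", start = 0L, end = 25000L,
                   category = "euchromatin")
  pr <- simulate_hic_pairs(cm, hic_sim_params(n_pairs = 50, seed = 3))
  vp <- file.path(dir, "pairs.tsv")
  write_valid_pairs(pr, vp)
  back <- read_valid_pairs(vp)
  expect_equal(back$posA, pr$posA)
  expect_equal(back$chrB, pr$chrB)
})

test_that("a YAML spec file builds the same genome as the in-code spec", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "spec.yaml")
  writeLines(c(
    "seed: 5",
    "shared_element: el1",
    "truncation_prob: 0",
    "divergence: 0.05",
    "satellite_defs: {satA: AATAT, satB: AAGAG}",
    "element_defs: {el1: 3000}",
    "contigs:",
    "  - name: c1",
    "    blocks:",
    "      - {kind: satellite, family: satA, length: 10000}",
    "      - {kind: island, elements: [el1, el1], spacer: 100, length: 5000}",
    "      - {kind: satellite, family: satB, length: 10000}"), path)
  spec <- genome_spec_from_yaml(path)
  expect_identical(build_genome(spec)$genome,
                   build_genome(example_spec(seed = 5))$genome)
})
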