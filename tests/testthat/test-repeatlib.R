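# read assignment to a repeat library, family enrichment, consensus
# profiles

mklib <- function(...) {
  cons <- c(...)
  list(consensus = cons,
       class = setNames(rep("element", length(cons)), names(cons)))
}

test_that("assign_reads places exact, mismatched and tied reads correctly", {
  set.seed(5)
  consA <- rand_seq(1000); consB <- rand_seq(1000)
  lib <- mklib(famA = consA, famB = consB)

  read <- substr(consA, 101, 250)
  a <- assign_reads(read, lib, details = TRUE)
  expect_equal(unname(a$counts), c(1, 0))
  expect_equal(a$per_read$tstart, 100)  # 0-based
  expect_equal(a$per_read$strand, 1L)

  # reverse-complement read assigns to the same family
  a2 <- assign_reads(r_revcomp(read), lib, details = TRUE)
  expect_equal(unname(a2$counts), c(1, 0))
  expect_equal(a2$per_read$strand, -1L)

  # two mismatches are inside the 4% tolerance for a 150-mer (6 allowed)
  mm <- read
  substr(mm, 10, 10) <- if (substr(mm, 10, 10) == "A") "C" else "A"
  substr(mm, 90, 90) <- if (substr(mm, 90, 90) == "G") "T" else "G"
  expect_equal(unname(assign_reads(mm, lib)$counts), c(1, 0))

  # seven mismatches exceed the tolerance
  mm7 <- read
  for (p in seq(5, 145, length.out = 7)) {
    p <- round(p)
    substr(mm7, p, p) <- chartr("ACGT", "CATG", substr(mm7, p, p))
  }
  mm7 <- vapply(strsplit(mm7, ""), function(ch) {
    paste(ch, collapse = "")
  }, character(1))
  a7 <- assign_reads(mm7, lib)
  expect_equal(a7$unassigned + a7$ambiguous + sum(a7$counts), 1)

  # a read matching two families equally well is ambiguous
  libdup <- mklib(famA = consA, famB = consA)
  ad <- assign_reads(read, libdup)
  expect_equal(ad$ambiguous, 1)
  expect_equal(sum(ad$counts), 0)

  expect_error(assign_reads(read, mklib()), "empty")
})

test_that("assignment partitions the read set and is strand-symmetric", {
  set.seed(6)
  consA <- rand_seq(800); consB <- rand_seq(800)
  lib <- mklib(famA = consA, famB = consB)
  reads <- c(
    vapply(sample(1:600, 30), function(s) substr(consA, s, s + 99), ""),
    vapply(sample(1:600, 30), function(s) substr(consB, s, s + 99), ""),
    vapply(1:30, function(i) rand_seq(100), ""))
  a <- assign_reads(reads, lib)
  expect_equal(sum(a$counts) + a$ambiguous + a$unassigned, length(reads))
  rc <- vapply(reads, r_revcomp, character(1), USE.NAMES = FALSE)
  arc <- assign_reads(rc, lib)
  expect_equal(a$counts, arc$counts)
  expect_equal(a$unassigned, arc$unassigned)
})

test_that("satellite families match reads in any repeat phase", {
  lib <- list(consensus = c(sat = "AATAT", el = rand_seq(500)),
              class = c(sat = "satellite", el = "element"))
  phases <- vapply(0:4, function(o)
    substr(strrep("AATAT", 40), o + 1, o + 120), character(1))
  a <- assign_reads(phases, lib)
  expect_equal(unname(a$counts["sat"]), 5)
})

test_that("family_enrichment implements the strict top-percentile rule", {
  fams <- paste0("f", 1:10)
  mkasg <- function(counts) {
    structure(list(counts = setNames(counts, fams), ambiguous = 0L,
                   unassigned = 0L, n_reads = sum(counts)),
              class = "FamilyAssignment")
  }
  base <- rep(100, 10)
  ratios <- c(3, 4, 3, 5)
  chip <- lapply(ratios, function(r) mkasg(replace(base, 1, 100 * r)))
  input <- rep(list(mkasg(base)), 4)
  tab <- family_enrichment(chip, input, rep(1e5, 4), rep(1e5, 4))
  expect_true(tab$enriched[tab$family == "f1"])
  expect_false(any(tab$enriched[-1]))

  # percentile must exceed 80 in every replicate: 80th-percentile-exact
  # and a single bad replicate both fail
  chip2 <- c(lapply(c(3, 3, 3), function(r) mkasg(replace(base, 1, 100 * r))),
             list(mkasg(base)))  # replicate 4: ratio 1, mid-rank
  tab2 <- family_enrichment(chip2, input, rep(1e5, 4), rep(1e5, 4))
  expect_false(tab2$enriched[tab2$family == "f1"])

  # all families identical: mean-rank ties leave nobody above the 80th
  tab3 <- family_enrichment(rep(list(mkasg(base)), 4), input,
                            rep(1e5, 4), rep(1e5, 4))
  expect_equal(unique(tab3$percentile_1), 55)
  expect_false(any(tab3$enriched))

  expect_error(family_enrichment(chip[1:2], input, rep(1e5, 4), rep(1e5, 4)),
               "paired")
})

test_that("consensus_profile reports unique-read depth ratios with masking", {
  set.seed(9)
  cons <- rand_seq(400)
  lib <- mklib(fam = cons)
  starts <- seq(1, 301, by = 10)
  reads <- vapply(starts, function(s) substr(cons, s, s + 99), character(1))
  chip <- assign_reads(reads, lib, details = TRUE)
  input <- assign_reads(reads, lib, details = TRUE)
  pr <- consensus_profile(chip, input, "fam", chip_total = 1000,
                          input_total = 1000, floor = 1)
  expect_true(all(pr$ratio[!pr$masked] == 1))
  expect_true(any(!pr$masked))
  # chip reads duplicated, totals equal -> ratio 2
  chip2 <- assign_reads(c(reads, reads), lib, details = TRUE)
  pr2 <- consensus_profile(chip2, input, "fam", 1000, 1000, floor = 1)
  expect_true(all(pr2$ratio[!pr2$masked] == 2))
  # masking: sites below the input floor carry no ratio
  pr5 <- consensus_profile(chip, input, "fam", 1000, 1000, floor = 5)
  expect_true(all(is.na(pr5$ratio[pr5$masked])))
  expect_true(all(pr5$masked[pr5$input_depth < 5]))

  # a position covered only by ambiguous reads stays masked
  lib2 <- mklib(famA = cons, famB = cons)
  chip3 <- assign_reads(reads, lib2, details = TRUE)
  pr3 <- consensus_profile(chip3, chip3, "famA", 1000, 1000, floor = 1)
  expect_true(all(pr3$masked))
  expect_error(consensus_profile(assign_reads(reads, lib), chip, "fam", 1, 1),
               "details")
})
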