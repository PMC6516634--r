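# coverage tracks, Poisson peak calling, QC cross-correlation,
# reproducibility, island detection and candidate classification

# coverage track built directly from per-contig pileups
mktrack <- function(pileups, total, fl = 300L) {
  structure(list(pileup = pileups, total_used = total, fragment_length = fl),
            class = "CoverageTrack")
}

mkreads <- function(contig, start, fl = 300L, rl = 150L, orient = NULL) {
  structure(list(channel = "chip", replicate = 1L, read_length = rl,
                 fragment_length = fl, contig = contig,
                 start = as.integer(start),
                 orient = orient %||% rep(1L, length(start)),
                 seq1 = character(length(start)),
                 seq2 = character(length(start)),
                 n_fragments = length(start),
                 total_reads = 2L * length(start)), class = "ReadSet")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("build_coverage masks duplicates and non-unique placements", {
  genome <- c(c1 = strrep("A", 5000))
  truth <- list(intervals = data.frame(
    contig = "c1", start = c(0L, 2000L), end = c(2000L, 5000L),
    class = c("unique", "satellite"), family = c("unique", "satA"),
    full_length = TRUE))
  # two identical fragments count once
  cov <- build_coverage(mkreads("c1", c(100, 100)), genome, truth)
  expect_equal(cov$total_used, 1)
  expect_equal(sum(cov$pileup$c1), 300)
  # a fragment wholly inside the satellite is dropped
  cov2 <- build_coverage(mkreads("c1", c(100, 3000)), genome, truth)
  expect_equal(cov2$total_used, 1)
  # a fragment overlapping >= 20 bp of complex sequence survives
  cov3 <- build_coverage(mkreads("c1", c(100, 1980, 1990)), genome, truth)
  expect_equal(cov3$total_used, 2)
  # n disjoint fragments of length L pile up n * L in total
  starts <- seq(0, 1500, by = 310)
  cov4 <- build_coverage(mkreads("c1", starts), genome, truth)
  expect_equal(sum(cov4$pileup$c1), length(starts) * 300)
})

test_that("call_peaks is null on identical tracks and finds planted windows", {
  set.seed(31)
  L <- 100000L
  base <- rpois(L, 5)
  chip <- mktrack(list(c1 = base), total = sum(base) / 300)
  input <- mktrack(list(c1 = base), total = sum(base) / 300)
  expect_equal(nrow(call_peaks(chip, input)), 0)

  # one 1-kb window at 10x over a flat background
  x <- rpois(L, 5); x[40001:41000] <- rpois(1000, 50)
  pk <- call_peaks(mktrack(list(c1 = x), sum(x) / 300),
                   mktrack(list(c1 = base), sum(base) / 300))
  expect_equal(nrow(pk), 1)
  expect_lte(pk$start, 40000)
  expect_gte(pk$end, 41000)
  expect_gt(pk$fold_enrichment, 5)

  # two windows 10 kb apart give two peaks
  y <- rpois(L, 5)
  y[30001:31000] <- rpois(1000, 50); y[41001:42000] <- rpois(1000, 50)
  pk2 <- call_peaks(mktrack(list(c1 = y), sum(y) / 300),
                    mktrack(list(c1 = base), sum(base) / 300))
  expect_equal(nrow(pk2), 2)
})

test_that("peak p-values equal the direct Poisson survival computation", {
  set.seed(77)
  L <- 20000L
  lam <- 4
  input <- rep(lam, L)  # flat input; every window mean equals lam
  x <- rpois(L, lam)
  spikes <- sample(seq(500, L - 500), 20)
  x[spikes] <- x[spikes] + sample(30:60, 20, TRUE)
  chip <- mktrack(list(c1 = x), total = 1000)
  inp <- mktrack(list(c1 = input), total = 1000)
  pk <- call_peaks(chip, inp, q_threshold = 0.01, merge_gap = 10L,
                   min_width = 1L)
  expect_gt(nrow(pk), 10)
  for (i in seq_len(nrow(pk))) {
    smt <- pk$summit[i] + 1L
    expect_equal(pk$p_value[i],
                 ppois(max(x[(pk$start[i] + 1):pk$end[i]]) - 1, lam,
                       lower.tail = FALSE))
  }
})

test_that("raising the q threshold only grows the peak set (nesting)", {
  set.seed(12)
  L <- 50000L
  base <- rpois(L, 3)
  x <- rpois(L, 3.4)
  x[10001:10400] <- rpois(400, 30)
  chip <- mktrack(list(c1 = x), sum(x) / 300)
  input <- mktrack(list(c1 = base), sum(base) / 300)
  p1 <- call_peaks(chip, input, q_threshold = 0.001)
  p2 <- call_peaks(chip, input, q_threshold = 0.05)
  # every strict peak lies inside some lenient peak
  for (i in seq_len(nrow(p1))) {
    expect_true(any(p2$start <= p1$start[i] & p2$end >= p1$end[i]))
  }
  expect_gte(nrow(p2), nrow(p1))
})

test_that("top_peaks sorts by fold with q and coordinate tie-breaks", {
  pk <- data.frame(contig = "c", start = c(30, 10, 20), end = c(31, 11, 21),
                   summit = 1, fold_enrichment = c(5, 5, 9),
                   p_value = 1e-9, q_value = c(1e-4, 1e-6, 1e-6),
                   replicate = 1)
  out <- top_peaks(pk, 2)
  expect_equal(out$start, c(20, 10))  # fold first, then q
  expect_equal(nrow(top_peaks(pk, 100)), 3)
  tie <- pk; tie$fold_enrichment <- 5; tie$q_value <- 1e-6
  expect_equal(top_peaks(tie, 3)$start, c(10, 20, 30))  # coordinate order
})

test_that("reproducible_peaks matches across replicates and reports rho", {
  mkpk <- function(starts, folds, rep = 1) data.frame(
    contig = "c1", start = starts, end = starts + 100, summit = starts + 50,
    fold_enrichment = folds, p_value = 1e-8, q_value = 1e-6, replicate = rep)
  a <- mkpk(c(100, 1000, 5000), c(10, 8, 3))
  rp <- reproducible_peaks(list(a, a))
  expect_true(all(rp$peaks$reproducible))
  expect_equal(rp$pair_rho$rho, 1)

  b <- mkpk(c(20000, 30000, 40000), c(4, 5, 6))
  rp2 <- reproducible_peaks(list(a, b))
  expect_false(any(rp2$peaks$reproducible))
  expect_equal(nrow(rp2$intervals), 0)

  # half-overlapping lists: only shared peaks survive; Spearman computed
  # on the matched pairs equals the hand rank correlation
  a3 <- mkpk(c(100, 1000, 5000, 9000), c(10, 8, 6, 2))
  b3 <- mkpk(c(150, 1050, 20000, 30000), c(9, 7, 5, 1), rep = 2)
  rp3 <- reproducible_peaks(list(a3, b3))
  rep_a <- rp3$peaks[rp3$peaks$replicate == 1 & rp3$peaks$reproducible, ]
  expect_equal(rep_a$start, c(100, 1000))
  expect_error(reproducible_peaks(list(a)), "2 replicates")
})

test_that("detect_islands applies length and interruption rules", {
  ann <- function(starts, ends, classes, fams) data.frame(
    contig = "c", start = starts, end = ends, class = classes, family = fams)
  # satellite | 5 kb complex | satellite
  a <- ann(c(0, 10000, 15000), c(10000, 15000, 25000),
           c("satellite", "element", "satellite"), c("satA", "el", "satB"))
  isl <- detect_islands(a, min_island = 1000)
  expect_equal(isl[, c("start", "end")], data.frame(start = 10000, end = 15000))
  expect_equal(isl$left_flank, "satA")
  expect_equal(isl$right_flank, "satB")
  # a 0.5 kb complex run is below the threshold
  b <- ann(c(0, 10000, 10500), c(10000, 10500, 20000),
           c("satellite", "element", "satellite"), c("satA", "el", "satB"))
  expect_equal(nrow(detect_islands(b, min_island = 1000)), 0)
  # complex | 200 bp satellite | complex merges into one island
  cc <- ann(c(0, 5000, 6000, 6200, 11200),
            c(5000, 6000, 6200, 11200, 16200),
            c("satellite", "element", "satellite", "element", "satellite"),
            c("satA", "el", "satA", "el", "satB"))
  isl3 <- detect_islands(cc, min_island = 1000, max_interruption = 500)
  expect_equal(isl3[, c("start", "end")], data.frame(start = 5000, end = 11200))
  # with a tighter tolerance it splits
  isl4 <- detect_islands(cc, min_island = 1000, max_interruption = 100)
  expect_equal(nrow(isl4), 2)
})

test_that("classify_candidates ranks by reproducible peak coverage", {
  islands <- data.frame(contig = c("c1", "c2"), start = c(0, 0),
                        end = c(10000, 10000),
                        left_flank = c("satA", "edge"),
                        right_flank = c("satB", "edge"))
  cover <- data.frame(contig = c("c1", "c2"), start = c(0, 0),
                      end = c(9000, 3000))
  rep <- classify_candidates(islands, cover)
  expect_equal(rep$contig, c("c1", "c2"))
  expect_equal(rep$peak_coverage, c(0.9, 0.3))
  expect_true(all(rep$candidate))
  rep2 <- classify_candidates(islands, cover[0, ])
  expect_false(any(rep2$candidate))
  # all-satellite contig produces no island hence no candidate
  sat_only <- data.frame(contig = "c3", start = 0, end = 50000,
                         class = "satellite", family = "satA")
  expect_equal(nrow(detect_islands(sat_only)), 0)
  # flank enrichment flag consults the k-mer table canonically
  kt <- data.frame(unit = c("AATAT", "AAGAG"), enriched = c(TRUE, FALSE))
  rep3 <- classify_candidates(islands, cover, kmer_table = kt,
                              satellite_units = c(satA = "ATAAT", satB = "GAGAA"))
  expect_true(rep3$flank_enriched[rep3$contig == "c1"])
  expect_false(rep3$flank_enriched[rep3$contig == "c2"])
})

test_that("cross-correlation recovers the fragment length from clustered reads", {
  set.seed(88)
  L <- 200000L
  genome <- c(c1 = strrep("A", L))
  fl <- 200L; rl <- 100L
  sites <- sample(seq(1000, L - 1000), 300)
  n <- 40000L
  start <- sample(rep(sites, length.out = n)) + sample(-25:25, n, TRUE)
  rs <- mkreads("c1", start, fl = fl, rl = rl,
                orient = sample(c(1L, -1L), n, TRUE))
  cp <- cross_correlation(rs, genome, max_shift = 400)
  expect_lt(abs(cp$est_fragment_length - (fl - 1)), 20)
  expect_gt(cp$nsc, 2)

  # uniform reads: profile near 1 everywhere, NSC near 1
  ru <- mkreads("c1", sample.int(L - fl, n, TRUE),
                fl = fl, rl = rl, orient = sample(c(1L, -1L), n, TRUE))
  cpu <- cross_correlation(ru, genome, max_shift = 400)
  expect_lt(cpu$nsc, 1.3)
  expect_gt(min(cpu$cc), 0.8)

  # single-strand degenerate input flags rsc as undefined
  r1 <- mkreads("c1", sample.int(L - fl, 100, TRUE), fl = fl, rl = rl,
                orient = rep(1L, 100))
  cp1 <- cross_correlation(r1, genome)
  expect_true(is.na(cp1$rsc))
  expect_error(cross_correlation(mkreads("c1", integer(0)), genome), "2 strand")
})
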