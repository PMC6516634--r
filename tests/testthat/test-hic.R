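# Hi-C interaction counting, per-100-kb normalisation, consensus tests

toy_map <- function() data.frame(
  contig = c("cen1", "cen2", "het", "euc"),
  start = 0L, end = c(50000L, 50000L, 100000L, 200000L),
  category = c("centromere", "centromere", "distal_het", "euchromatin"),
  unit = c("cen1", "cen2", NA, NA))

mkpairs <- function(chrA, posA, chrB, posB) data.frame(
  readID = sprintf("p%d", seq_along(chrA)), chrA = chrA, posA = posA,
  strandA = rep("+", length(chrA)), chrB = chrB, posB = posB,
  strandB = rep("-", length(chrA)))

test_that("assign_pairs partitions pairs and credits centromere units", {
  s0 <- assign_pairs(mkpairs(character(0), integer(0), character(0),
                             integer(0)), toy_map())
  expect_equal(sum(s0$global$count), 0)

  # one cen1-cen2 pair: global cen|cen cell gets 1, both units credited
  s1 <- assign_pairs(mkpairs("cen1", 100, "cen2", 200), toy_map())
  expect_equal(s1$global$count[s1$global$class_pair ==
                               "centromere|centromere"], 1)
  pu <- s1$per_unit
  expect_equal(pu$count[pu$unit == "cen1" & pu$partner_category == "centromere"], 1)
  expect_equal(pu$count[pu$unit == "cen2" & pu$partner_category == "centromere"], 1)

  # symmetric collapse and conservation; off-map ends are dropped
  pr <- mkpairs(c("euc", "cen1", "nowhere"), c(1, 1, 1),
                c("cen1", "euc", "euc"), c(1, 1, 1))
  s2 <- assign_pairs(pr, toy_map())
  expect_equal(s2$n_assigned, 2)
  expect_equal(s2$n_dropped, 1)
  expect_equal(sum(s2$global$count), s2$n_assigned)
  expect_equal(s2$global$count[s2$global$class_pair ==
                               "centromere|euchromatin"], 2)
})

test_that("normalisation follows N x (1e5)^2 / (LA x LB) and its scaling law", {
  cm <- data.frame(contig = c("a", "b"), start = 0L,
                   end = c(200000L, 100000L),
                   category = c("centromere", "euchromatin"),
                   unit = c("a", NA))
  sm <- assign_pairs(mkpairs(rep("a", 50), seq(0, 49) * 100,
                             rep("b", 50), seq(0, 49) * 100), cm)
  nm <- normalize_interactions(sm)
  g <- nm$global
  expect_equal(g$normalized[g$class_pair == "centromere|euchromatin"], 25)

  # doubling both lengths divides the value by 4
  cm2 <- transform(cm, end = end * 2L)
  nm2 <- normalize_interactions(assign_pairs(
    mkpairs(rep("a", 50), seq(0, 49) * 100, rep("b", 50), seq(0, 49) * 100),
    cm2))
  expect_equal(nm2$global$normalized, nm$global$normalized / 4)

  # zero counts normalise to zero (absent cells simply do not appear)
  s0 <- assign_pairs(mkpairs("a", 1, "a", 2), cm)
  n0 <- normalize_interactions(s0)
  expect_false("centromere|euchromatin" %in% n0$global$class_pair)

  # the per-length alternative divides by the sum instead
  nsum <- normalize_interactions(sm, mode = "sum")
  expect_equal(nsum$global$normalized[
    nsum$global$class_pair == "centromere|euchromatin"],
    50 * 1e5 / (3e5))
})

test_that("dunn_test matches the explicit rank formula", {
  # groups {1,2} vs {3,4}: mean ranks 1.5 and 3.5, sigma2 = N(N+1)/12
  d <- dunn_test(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  z_expected <- (1.5 - 3.5) / sqrt((4 * 5 / 12) * (1 / 2 + 1 / 2))
  expect_equal(d$z, z_expected)
  expect_equal(d$p_value, 2 * pnorm(-abs(z_expected)))
  # tie correction reduces the variance term
  dt <- dunn_test(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  ties_T <- 2 * (2^3 - 2)
  sigma2 <- 4 * 5 / 12 - ties_T / (12 * 3)
  expect_equal(dt$z, (1.5 - 3.5) / sqrt(sigma2 * (1 / 2 + 1 / 2)))
})

test_that("the consensus rule requires both tests to agree", {
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(11, 12, 13, 14, 15); g3 <- c(1, 2, 3, 4, 5)
  res <- test_category_differences(c(g1, g2, g3),
                                   rep(c("a", "b", "c"), each = 5))
  pr <- res$pairs
  expect_true(pr$significant[pr$group1 == "a" & pr$group2 == "b"])
  expect_false(pr$significant[pr$group1 == "a" & pr$group2 == "c"])
  # the flag is exactly the conjunction of the two adjusted tests
  expect_equal(pr$significant,
               !is.na(pr$p_adj) & !is.na(pr$wilcox_p_adj) &
                 pr$p_adj < 0.05 & pr$wilcox_p_adj < 0.05)
  # independent cross-checks of the two ingredient tests
  expect_lt(kruskal.test(list(g1, g2, g3))$p.value, 0.05)
  expect_lt(wilcox.test(g1, g2, exact = FALSE)$p.value, 0.05)

  expect_error(test_category_differences(1:4, rep("a", 4)), "2 non-empty")
  expect_error(test_category_differences(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 observations")
  expect_warning(
    test_category_differences(c(g1, g2), factor(rep(c("a", "b"), each = 5),
                                                levels = c("a", "b", "z"))),
    "empty")
})

test_that("identically distributed groups are rarely declared significant", {
  set.seed(14)
  hits <- 0L
  for (i in 1:20) {
    v <- rnorm(20)
    res <- test_category_differences(v, rep(letters[1:4], each = 5))
    hits <- hits + any(res$pairs$significant)
  }
  expect_lte(hits, 1L)
})

test_that("a planted centromere contact excess is recovered through the stack", {
  cats <- c("centromere", "proximal_het", "distal_het", "euchromatin")
  cm <- data.frame(
    contig = c(paste0("cen", 1:5), "ph", "dh", "eu"),
    start = 0L,
    end = c(rep(20000L, 5), 150000L, 150000L, 400000L),
    category = c(rep("centromere", 5), "proximal_het", "distal_het",
                 "euchromatin"),
    unit = c(paste0("cen", 1:5), NA, NA, NA))
  rate <- matrix(1, 4, 4, dimnames = list(cats, cats))
  rate["centromere", "centromere"] <- 5
  pairs <- simulate_hic_pairs(cm, hic_sim_params(n_pairs = 2e4,
                                                 rate_matrix = rate, seed = 3))
  sm <- normalize_interactions(assign_pairs(pairs, cm))
  pu <- sm$per_unit[grepl("^cen", sm$per_unit$unit), ]
  res <- test_category_differences(pu$normalized, pu$partner_category)
  pr <- res$pairs
  expect_true(pr$significant[pr$group1 == "centromere" &
                             pr$group2 == "euchromatin"])
})
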