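# Hi-C validation: assign valid pairs to genome-category bins, normalise
# interaction counts per 100 kb, and apply the two-test consensus
# significance rule.

# locate positions in a category map; returns row index or NA
locate_in_map <- function(contig, pos, category_map) {
  idx <- rep(NA_integer_, length(contig))
  for (cg in unique(contig)) {
    sel <- which(contig == cg)
    iv <- category_map[category_map$contig == cg, , drop = FALSE]
    if (nrow(iv) == 0) next
    ord <- order(iv$start)
    iv <- iv[ord, , drop = FALSE]
    j <- findInterval(pos[sel], iv$start)
    inside <- j >= 1 & pos[sel] < iv$end[pmax(j, 1)]
    idx[sel[inside]] <- as.integer(rownames(iv))[j[inside]]
  }
  idx
}

#' Assign Hi-C valid pairs to category pairs
#'
#' Each valid pair increments one symmetric category-pair cell
#' ((A,B) and (B,A) are collapsed); pairs with an end outside the
#' annotated map are dropped and reported.  In addition, every pair with
#' at least one end in a centromere unit is credited to that unit's
#' (unit, category-pair) cell -- a centromere-centromere pair credits
#' both participating units, so each unit's distribution describes its
#' own interactions.
#'
#' @param pairs validPairs-style data.frame (`chrA`, `posA`, `chrB`,
#'   `posB`, ...).
#' @param category_map data.frame with `contig`, `start`, `end`,
#'   `category` and optionally `unit` (unit names for centromere
#'   intervals).
#' @param unit_category category whose intervals carry units (default
#'   `"centromere"`).
#' @return an `InteractionSummary`: list with `global` (category-pair
#'   counts partitioning the assigned pairs), `per_unit` (unit-credited
#'   counts per partner category), `per_unit_pair` (finer replication:
#'   one cell per unit and partner map row, with the partner row's
#'   length), `n_pairs`, `n_assigned`, `n_dropped`.
#' @export
assign_pairs <- function(pairs, category_map, unit_category = "centromere") {
  category_map <- category_map[order(category_map$contig, category_map$start), ,
                               drop = FALSE]
  rownames(category_map) <- seq_len(nrow(category_map))
  ia <- locate_in_map(pairs$chrA, pairs$posA, category_map)
  ib <- locate_in_map(pairs$chrB, pairs$posB, category_map)
  keep <- !is.na(ia) & !is.na(ib)
  catA <- category_map$category[ia[keep]]
  catB <- category_map$category[ib[keep]]
  key <- ifelse(catA <= catB, paste0(catA, "|", catB), paste0(catB, "|", catA))
  global <- if (length(key)) {
    g <- as.data.frame(table(key), stringsAsFactors = FALSE)
    names(g) <- c("class_pair", "count")
    g
  } else data.frame(class_pair = character(0), count = integer(0))

  per_unit <- NULL
  has_unit <- "unit" %in% names(category_map)
  if (has_unit) {
    ua <- category_map$unit[ia[keep]]
    ub <- category_map$unit[ib[keep]]
    ua[category_map$category[ia[keep]] != unit_category] <- NA
    ub[category_map$category[ib[keep]] != unit_category] <- NA
    credits <- rbind(
      data.frame(unit = ua, partner = catB, stringsAsFactors = FALSE),
      data.frame(unit = ub, partner = catA, stringsAsFactors = FALSE))
    credits <- credits[!is.na(credits$unit), , drop = FALSE]
    per_unit <- if (nrow(credits)) {
      pu <- as.data.frame(table(unit = credits$unit,
                                partner = credits$partner),
                          stringsAsFactors = FALSE)
      names(pu) <- c("unit", "partner_category", "count")
      pu
    } else data.frame(unit = character(0), partner_category = character(0),
                      count = integer(0))
    # finer replication unit: one cell per (unit, partner map row)
    rcred <- rbind(
      data.frame(unit = ua, row = ib[keep], stringsAsFactors = FALSE),
      data.frame(unit = ub, row = ia[keep], stringsAsFactors = FALSE))
    rcred <- rcred[!is.na(rcred$unit), , drop = FALSE]
    units_all <- sort(unique(category_map$unit[
      category_map$category == unit_category & !is.na(category_map$unit)]))
    grid <- expand.grid(unit = units_all,
                        row = seq_len(nrow(category_map)),
                        stringsAsFactors = FALSE)
    cnts <- table(factor(rcred$unit, levels = units_all),
                  factor(rcred$row, levels = seq_len(nrow(category_map))))
    grid$count <- as.vector(cnts[cbind(grid$unit,
                                       as.character(grid$row))])
    grid$partner_category <- category_map$category[grid$row]
    grid$partner_unit <- category_map$unit[grid$row]
    grid$partner_length <- category_map$end[grid$row] -
      category_map$start[grid$row]
    # mirrored unit-unit cells (u, u') and (u', u) count the same pairs;
    # flag one of each mirror pair so analyses can deduplicate
    grid$mirror <- !is.na(grid$partner_unit) &
      grid$partner_unit < grid$unit
    per_unit_pair <- grid[, c("unit", "row", "partner_category",
                              "partner_unit", "partner_length", "count",
                              "mirror")]
  } else per_unit_pair <- NULL
  structure(list(global = global, per_unit = per_unit,
                 per_unit_pair = per_unit_pair,
                 n_pairs = nrow(pairs), n_assigned = sum(keep),
                 n_dropped = sum(!keep), category_map = category_map),
            class = "InteractionSummary")
}

#' Normalise interaction counts to region sizes (per 100 kb)
#'
#' The default normalisation divides each raw count by the product of the
#' participating region lengths in units of 100 kb:
#' `N * 1e5^2 / (L_A * L_B)`.  An additive per-length alternative
#' `N * 1e5 / (L_A + L_B)` is selectable.  Per-unit cells use the unit's
#' own length against the partner category's total length; the partner
#' length includes the unit itself when the partner is its own
#' category, which matches the end-crediting rule (a within-unit pair
#' credits both ends), so per-unit values are unbiased across partner
#' categories under uniform contacts.  `per_unit_pair` cells are
#' normalised by the unit length times the partner row's own length.
#'
#' @param summary an `InteractionSummary` from [assign_pairs()].
#' @param mode `"product"` (default) or `"sum"`.
#' @param unit_category category whose intervals carry units.
#' @return the summary with `normalized` columns added to `global` and
#'   `per_unit`.
#' @export
normalize_interactions <- function(summary, mode = c("product", "sum"),
                                   unit_category = "centromere") {
  mode <- match.arg(mode)
  cm <- summary$category_map
  L <- tapply(as.numeric(cm$end - cm$start), cm$category, sum)
  norm2 <- function(N, La, Lb) {
    if (mode == "product") N * 1e10 / (La * Lb) else N * 1e5 / (La + Lb)
  }
  g <- summary$global
  if (nrow(g)) {
    ab <- strsplit(g$class_pair, "|", fixed = TRUE)
    g$normalized <- vapply(seq_len(nrow(g)), function(i) {
      a <- ab[[i]][1]; b <- ab[[i]][2]
      norm2(g$count[i], L[[a]], L[[b]])
    }, numeric(1))
  }
  summary$global <- g
  pu <- summary$per_unit
  if (!is.null(pu) && nrow(pu)) {
    uL <- tapply(as.numeric(cm$end - cm$start), cm$unit, sum)
    pu$normalized <- vapply(seq_len(nrow(pu)), function(i) {
      norm2(pu$count[i], uL[[pu$unit[i]]], L[[pu$partner_category[i]]])
    }, numeric(1))
    summary$per_unit <- pu
    pup <- summary$per_unit_pair
    if (!is.null(pup) && nrow(pup)) {
      pup$normalized <- norm2(pup$count, as.numeric(uL[pup$unit]),
                              as.numeric(pup$partner_length))
      summary$per_unit_pair <- pup
    }
  }
  summary
}

#' Dunn's post hoc test from Kruskal-Wallis ranks
#'
#' Pairwise z statistics on mean ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups; two-sided normal p-values.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor.
#' @return data.frame with `group1`, `group2`, `z`, `p_value`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  gl <- levels(groups)
  out <- list()
  for (i in seq_along(gl)) for (j in seq_along(gl)) {
    if (j <= i) next
    z <- (rbar[[gl[i]]] - rbar[[gl[j]]]) /
      sqrt(sigma2 * (1 / n[[gl[i]]] + 1 / n[[gl[j]]]))
    out[[length(out) + 1L]] <- data.frame(
      group1 = gl[i], group2 = gl[j], z = z,
      p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consensus significance of category differences
#'
#' Kruskal-Wallis across groups, Dunn's post hoc z tests and pairwise
#' Wilcoxon rank-sum tests, both FDR-corrected (Benjamini-Hochberg).  A
#' pair of categories is declared significant only when the omnibus
#' Kruskal-Wallis test rejects (Dunn's test is a post hoc procedure)
#' and the Dunn-adjusted AND the Wilcoxon-adjusted p-values are below
#' `alpha` -- a result counts only if both tests agree.
#'
#' @param values numeric observations (e.g. per-centromere normalised
#'   interaction values).
#' @param groups grouping factor (e.g. partner category).
#' @param alpha significance level.
#' @return list with `kruskal` (statistic and p), `pairs` (per-pair Dunn
#'   and Wilcoxon adjusted p-values plus the consensus `significant`
#'   flag) and `group_medians`.
#' @export
test_category_differences <- function(values, groups, alpha = 0.05) {
  if (!is.factor(groups)) groups <- factor(groups)
  tab <- table(groups)
  empty <- names(tab)[tab == 0]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 observations")
  kw <- kruskal.test(values, groups)
  dn <- dunn_test(values, groups)
  dn$p_adj <- p.adjust(dn$p_value, method = "BH")
  wx <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = "BH",
                         exact = FALSE))
  wx_p <- function(a, b) {
    m <- wx$p.value
    if (a %in% rownames(m) && b %in% colnames(m) && !is.na(m[a, b]))
      return(m[a, b])
    if (b %in% rownames(m) && a %in% colnames(m) && !is.na(m[b, a]))
      return(m[b, a])
    NA_real_
  }
  dn$wilcox_p_adj <- mapply(wx_p, dn$group1, dn$group2)
  dn$significant <- kw$p.value < alpha &
    !is.na(dn$p_adj) & !is.na(dn$wilcox_p_adj) &
    dn$p_adj < alpha & dn$wilcox_p_adj < alpha
  med <- tapply(values, groups, median)
  list(kruskal = list(statistic = unname(kw$statistic), p_value = kw$p.value),
       pairs = dn, group_medians = med, alpha = alpha)
}

#' Derive a Hi-C category map from a planted-genome truth annotation
#'
#' Island spans become `centromere` intervals (unit = contig name);
#' satellite intervals on island contigs become `proximal_het`,
#' satellite intervals elsewhere `distal_het`; all remaining
#' (non-satellite, non-island) intervals are `euchromatin`.  Adjacent
#' intervals of the same category are merged, so the map is
#' non-overlapping and exhausts the annotated genome.
#'
#' @param truth truth annotation from [build_genome()] (list with
#'   `intervals` and `island_spans`).
#' @return category-map data.frame (`contig`, `start`, `end`,
#'   `category`, `unit`) suitable for [simulate_hic_pairs()] and
#'   [assign_pairs()].
#' @export
category_map_from_truth <- function(truth) {
  iv <- truth$intervals
  spans <- truth$island_spans
  cen_contigs <- unique(spans$contig)
  in_island <- rep(FALSE, nrow(iv))
  for (i in seq_len(nrow(spans)))
    in_island <- in_island | (iv$contig == spans$contig[i] &
                              iv$start >= spans$start[i] &
                              iv$end <= spans$end[i])
  cat_of <- ifelse(in_island, "centromere",
            ifelse(iv$class == "satellite" & iv$contig %in% cen_contigs,
                   "proximal_het",
            ifelse(iv$class == "satellite", "distal_het", "euchromatin")))
  out <- data.frame(contig = iv$contig, start = iv$start, end = iv$end,
                    category = cat_of, stringsAsFactors = FALSE)
  # merge runs of equal category within each contig
  merged <- list()
  for (cg in unique(out$contig)) {
    d <- out[out$contig == cg, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    r <- rle(d$category)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    merged[[cg]] <- data.frame(
      contig = cg, start = d$start[starts], end = d$end[ends],
      category = r$values, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, merged)
  res$unit <- ifelse(res$category == "centromere", res$contig, NA)
  rownames(res) <- NULL
  res
}
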