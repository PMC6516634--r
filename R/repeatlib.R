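# Approach (2): read assignment to a consensus repeat library, family
# enrichment with the top-percentile rule, and per-position consensus
# profiles.

# satellite units are expanded into tandem arrays long enough that any
# read phase aligns fully; element consensi are used as-is
expand_library <- function(library, read_length) {
  cons <- library$consensus
  cls <- library$class[names(cons)]
  out <- cons
  for (f in names(cons)) {
    if (identical(cls[[f]], "satellite")) {
      unit <- cons[[f]]
      target <- read_length + 2L * nchar(unit)
      out[[f]] <- satellite_array(unit, max(target, nchar(unit) * 3L))
    }
  }
  out
}

#' Assign reads to repeat families by seeded ungapped matching
#'
#' Each read is scored against every family consensus (both strands) by
#' its best ungapped alignment over exact-seed candidate offsets.  A read
#' is assigned to the unique best family when its mismatch count (bases
#' off the consensus end count as mismatches) is within
#' `max_mismatch_frac` of the read length; an equal best score across two
#' or more families makes the read ambiguous; no candidate at all leaves
#' it unassigned.  Satellite family units are internally expanded into
#' tandem arrays so that all repeat phases are alignable.
#'
#' @param reads a `ReadSet` or character vector of sequences.
#' @param library repeat library as returned by [build_genome()]: a list
#'   with named `consensus` and `class` ("satellite" or "element")
#'   vectors.
#' @param max_mismatch_frac mismatch tolerance as a fraction of read
#'   length.
#' @param seed_len,seed_step exact seed length and query stride.
#' @param details keep the per-read best alignment (needed by
#'   [consensus_profile()]).
#' @return a `FamilyAssignment`: list with `counts` (named, one entry per
#'   family), `ambiguous`, `unassigned`, `n_reads` and optionally
#'   `per_read`.
#' @export
assign_reads <- function(reads, library, max_mismatch_frac = 0.04,
                         seed_len = 20L, seed_step = 4L, details = FALSE) {
  seqs <- if (inherits(reads, "ReadSet")) c(reads$seq1, reads$seq2)
          else as.character(reads)
  fams <- names(library$consensus)
  if (length(fams) == 0) stop("empty repeat library")
  rl <- if (length(seqs)) max(nchar(seqs)) else 0L
  targets <- expand_library(library, rl)
  m <- seed_match_cpp(seqs, unname(targets), as.integer(seed_len),
                      as.integer(seed_step), 16L, 32L)
  qlen <- m$qlen
  mism <- qlen - m$score
  hit <- !is.na(m$target)
  ok <- hit & mism <= floor(max_mismatch_frac * qlen)
  tie <- hit & m$second_target_score == m$score
  family <- rep(NA_character_, length(seqs))
  family[hit] <- fams[m$target[hit]]
  status <- ifelse(!hit | !ok, "unassigned", ifelse(tie, "ambiguous", "assigned"))
  counts <- table(factor(family[status == "assigned"], levels = fams))
  out <- list(counts = setNames(as.numeric(counts), fams),
              ambiguous = sum(status == "ambiguous"),
              unassigned = sum(status == "unassigned"),
              n_reads = length(seqs))
  if (details) {
    out$per_read <- data.frame(
      family = family, status = status, tstart = m$tstart,
      overlap = m$overlap, strand = m$strand, qlen = qlen,
      stringsAsFactors = FALSE)
    out$target_lengths <- setNames(nchar(targets), fams)
  }
  class(out) <- "FamilyAssignment"
  out
}

#' Family-level enrichment with the top-percentile rule
#'
#' Normalised ratios are computed as in [kmer_enrichment()], then each
#' family's percentile rank among all families is taken within every
#' replicate (tied ratios share the mean rank).  A family is called
#' enriched when its rank is strictly above the 80th percentile in every
#' replicate; boundary ties are conservatively not enriched.
#'
#' @param chip_assignments,input_assignments lists (per replicate) of
#'   `FamilyAssignment` objects sharing the same family universe.
#' @param chip_totals,input_totals mapped-read totals per replicate.
#' @param percentile percentile boundary (default 80).
#' @param universe optional subset of families to rank (default: all
#'   families in the assignments).
#' @return data.frame with per-replicate ratios and percentile ranks,
#'   and the `enriched` call.
#' @export
family_enrichment <- function(chip_assignments, input_assignments,
                              chip_totals, input_totals, percentile = 80,
                              universe = NULL) {
  n_rep <- length(chip_assignments)
  if (length(input_assignments) != n_rep)
    stop("chip and input replicates must be paired")
  fams <- names(chip_assignments[[1]]$counts)
  for (a in c(chip_assignments, input_assignments))
    if (!identical(names(a$counts), fams))
      stop("family universe differs between replicates")
  if (!is.null(universe)) fams <- intersect(fams, universe)
  ratio <- sapply(seq_len(n_rep), function(r) {
    chip <- chip_assignments[[r]]$counts[fams] / chip_totals[r]
    input <- input_assignments[[r]]$counts[fams] / input_totals[r]
    ifelse(input > 0, chip / input, NA_real_)
  })
  ratio <- matrix(ratio, ncol = n_rep, dimnames = list(fams, NULL))
  pct <- apply(ratio, 2, function(x) 100 * rank(x, ties.method = "average",
                                                na.last = FALSE) / length(x))
  pct <- matrix(pct, ncol = n_rep, dimnames = list(fams, NULL))
  enriched <- apply(pct, 1, function(p) all(p > percentile))
  out <- data.frame(family = fams, stringsAsFactors = FALSE)
  for (r in seq_len(n_rep)) {
    out[[paste0("ratio_", r)]] <- ratio[, r]
    out[[paste0("percentile_", r)]] <- pct[, r]
  }
  out$enriched <- enriched
  rownames(out) <- NULL
  out
}

#' Per-position ChIP/input profile along a family consensus
#'
#' Only unambiguously assigned reads contribute depth (the analog of a
#' mapping-quality filter).  The per-site ratio is
#' `(chip depth / chip total) / (input depth / input total)`; sites whose
#' input depth falls below `floor` are masked and carry no ratio.
#'
#' @param chip_assignment,input_assignment `FamilyAssignment` objects
#'   created with `details = TRUE`.
#' @param family family whose consensus is profiled.
#' @param chip_total,input_total mapped-read totals.
#' @param floor minimum input depth for a site to be reported.
#' @return data.frame with `position` (0-based), `chip_depth`,
#'   `input_depth`, `ratio` and `masked`.
#' @export
consensus_profile <- function(chip_assignment, input_assignment, family,
                              chip_total, input_total, floor = 5) {
  for (a in list(chip_assignment, input_assignment))
    if (is.null(a$per_read))
      stop("assignments must be created with details = TRUE")
  L <- chip_assignment$target_lengths[[family]]
  depth_of <- function(a) {
    pr <- a$per_read
    sel <- pr$status == "assigned" & pr$family == family & !is.na(pr$family)
    d <- numeric(L)
    if (any(sel)) {
      s <- pmax(0, pr$tstart[sel]) + 1
      e <- pmin(L, pr$tstart[sel] + pr$overlap[sel])
      add <- numeric(L + 1)
      for (i in seq_along(s)) {
        add[s[i]] <- add[s[i]] + 1
        add[e[i] + 1] <- add[e[i] + 1] - 1
      }
      d <- cumsum(add[seq_len(L)])
    }
    d
  }
  chip_d <- depth_of(chip_assignment)
  input_d <- depth_of(input_assignment)
  masked <- input_d < floor
  ratio <- ifelse(masked, NA_real_,
                  (chip_d / chip_total) / (input_d / input_total))
  data.frame(position = seq_len(L) - 1L, chip_depth = chip_d,
             input_depth = input_d, ratio = ratio, masked = masked)
}
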