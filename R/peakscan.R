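# Approach (4): assembly-space coverage, Poisson local-background peak
# calling, strand cross-correlation QC, replicate reproducibility,
# island detection and candidate classification.

#' Fragment coverage track with duplicate masking and unique-placement
#' filtering
#'
#' Fragments with identical coordinates (contig, start) are duplicates
#' and counted once.  In synthetic space the mapping-quality filter maps
#' to a unique-placement rule: a fragment is considered uniquely
#' placeable when it overlaps at least `min_unique_overlap` bp of
#' non-satellite sequence (fragments wholly inside a satellite array fit
#' the array at every period and are dropped).  Remaining fragments add 1
#' over `[start, start + fragment_length)`.
#'
#' @param readset a `ReadSet` with placements.
#' @param genome named character vector of contigs.
#' @param truth optional truth annotation (list with `intervals`); when
#'   supplied, the unique-placement rule is applied.
#' @param min_unique_overlap bp of non-satellite overlap required for a
#'   fragment to count as uniquely placed.
#' @return a `CoverageTrack`: list with `pileup` (per-contig numeric
#'   vectors), `total_used` fragments, and `fragment_length`.
#' @export
build_coverage <- function(readset, genome, truth = NULL,
                           min_unique_overlap = 20L) {
  fl <- readset$fragment_length
  ctg <- readset$contig; start <- readset$start
  keep <- !duplicated(paste0(ctg, ":", start))
  if (!is.null(truth)) {
    iv <- truth$intervals
    sat_ok <- logical(length(ctg))
    for (cg in unique(ctg)) {
      sel <- which(ctg == cg & keep)
      if (!length(sel)) next
      L <- nchar(genome[[cg]])
      sat <- iv[iv$contig == cg & iv$class == "satellite", , drop = FALSE]
      satmask <- integer(L)
      if (nrow(sat) > 0) {
        for (i in seq_len(nrow(sat)))
          satmask[(sat$start[i] + 1):sat$end[i]] <- 1L
      }
      cs <- c(0L, cumsum(satmask))
      s <- start[sel]; e <- pmin(s + fl, L)
      nonsat <- (e - s) - (cs[e + 1] - cs[s + 1])
      sat_ok[sel] <- nonsat >= min_unique_overlap
    }
    keep <- keep & sat_ok
  }
  pileup <- list()
  for (cg in names(genome)) {
    L <- nchar(genome[[cg]])
    sel <- which(ctg == cg & keep)
    add <- numeric(L + 1)
    if (length(sel)) {
      s <- start[sel] + 1
      e <- pmin(start[sel] + fl, L)
      for (i in seq_along(s)) {
        add[s[i]] <- add[s[i]] + 1
        add[e[i] + 1] <- add[e[i] + 1] - 1
      }
    }
    pileup[[cg]] <- cumsum(add[seq_len(L)])
  }
  structure(list(pileup = pileup, total_used = sum(keep),
                 fragment_length = fl),
            class = "CoverageTrack")
}

# truncated-window running mean of x with half-width h (window clipped at
# the sequence ends)
running_mean <- function(x, w) {
  L <- length(x)
  h <- floor(w / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - h, 1)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Strand cross-correlation profile with NSC and RSC
#'
#' One read per fragment is taken (the sequenced mate orientation), and
#' the 5' end counts of plus- and minus-strand reads are compared at
#' shifts 0..`max_shift`.  The profile value at shift d is the
#' observed/expected coincidence ratio of plus ends at x with minus ends
#' at x + d, a monotone transform of the Pearson correlation of the two
#' count vectors; under uniform (unenriched) sampling it fluctuates
#' around 1 at every shift.  The fragment-length estimate is the argmax
#' of the profile outside a +/- `exclude_halfwidth` window around the
#' read length (the phantom-peak neighbourhood).  NSC is the
#' fragment-length peak divided by the background (the profile minimum);
#' RSC is the fragment-length peak divided by the read-length value.
#'
#' @param readset a `ReadSet`.
#' @param genome named character vector of contigs.
#' @param max_shift largest shift examined (bp).
#' @param exclude_halfwidth half-width of the excluded neighbourhood
#'   around the read length.
#' @param smooth width (in shifts) of the running mean applied to the
#'   profile before locating the peak and the background minimum; the
#'   raw profile is returned.
#' @return a `CrossCorrProfile`: list with `shift`, `cc`,
#'   `est_fragment_length`, `nsc`, `rsc`.
#' @export
cross_correlation <- function(readset, genome, max_shift = 400L,
                              exclude_halfwidth = 10L, smooth = 15L) {
  rl <- readset$read_length; fl <- readset$fragment_length
  plus_sel <- readset$orient == 1L
  pos <- ifelse(plus_sel, readset$start, readset$start + fl - 1L)
  n_plus <- sum(plus_sel); n_minus <- sum(!plus_sel)
  if (n_plus + n_minus < 2) stop("need at least 2 strand-assigned reads")
  shifts <- 0:max_shift
  num <- numeric(length(shifts)); expd <- numeric(length(shifts))
  for (cg in names(genome)) {
    L <- nchar(genome[[cg]])
    sel <- readset$contig == cg
    p <- tabulate(pos[sel & plus_sel] + 1L, nbins = L)
    m <- tabulate(pos[sel & !plus_sel] + 1L, nbins = L)
    np <- sum(p); nm <- sum(m)
    for (i in seq_along(shifts)) {
      d <- shifts[i]
      if (d >= L) next
      num[i] <- num[i] + sum(as.numeric(p[seq_len(L - d)]) * m[(1 + d):L])
      expd[i] <- expd[i] + as.numeric(np) * nm * (L - d) / L^2
    }
  }
  if (n_plus == 0 || n_minus == 0) {
    return(structure(list(shift = shifts, cc = rep(0, length(shifts)),
                          est_fragment_length = NA_integer_, nsc = NA_real_,
                          rsc = NA_real_), class = "CrossCorrProfile"))
  }
  cc <- ifelse(expd > 0, num / expd, 0)
  cs <- if (smooth > 1) running_mean(cc, smooth) else cc
  excluded <- abs(shifts - rl) <= exclude_halfwidth
  cand <- which(!excluded)
  est <- shifts[cand[which.max(cs[cand])]]
  background <- min(cs)
  nsc <- if (background > 0) cs[shifts == est] / background else NA_real_
  rl_cc <- if (rl <= max_shift) cs[shifts == rl] else NA_real_
  rsc <- if (!is.na(rl_cc) && rl_cc > 0) cs[shifts == est] / rl_cc else NA_real_
  structure(list(shift = shifts, cc = cc, est_fragment_length = est,
                 nsc = nsc, rsc = rsc), class = "CrossCorrProfile")
}

#' Poisson local-background peak calling
#'
#' The input track is scaled to the ChIP fragment total; the local
#' background rate at each base is the maximum of the scaled input mean
#' over centred windows (default 1 kb, 5 kb, 10 kb), the whole-contig
#' mean and (by default) the collection-wide mean, so short contigs with
#' sparse input cannot inflate fold enrichments.  Per-base upper-tail
#' Poisson p-values of the ChIP pileup are
#' corrected by Benjamini-Hochberg over all bases whose pileup exceeds
#' the local background, significant bases closer than `merge_gap` are
#' merged into peaks, and each peak reports its summit (pileup argmax),
#' fold enrichment over the local background at the summit (with a
#' pseudocount) and its best p and q value.
#'
#' @param chip,input `CoverageTrack` objects on the same genome.
#' @param q_threshold Benjamini-Hochberg q-value cutoff.
#' @param windows local background window sizes (bp).
#' @param merge_gap maximum gap (bp) between significant bases merged
#'   into one peak; defaults to the fragment length.
#' @param min_width minimum peak width (bp); merged regions narrower than
#'   this are discarded (isolated single-base spikes are not fragment
#'   pileups).  Defaults to `merge_gap`.
#' @param pseudocount added to numerator and denominator of the fold
#'   enrichment.
#' @param global_floor include the collection-wide scaled input mean as
#'   a lower bound on the local background.
#' @param replicate replicate label attached to the peaks.
#' @return data.frame of peaks: `contig`, `start`, `end` (0-based
#'   half-open), `summit` (absolute position), `fold_enrichment`,
#'   `p_value`, `q_value`, `replicate`.
#' @export
call_peaks <- function(chip, input, q_threshold = 0.01,
                       windows = c(1000L, 5000L, 10000L), merge_gap = NULL,
                       pseudocount = 0.1, global_floor = TRUE,
                       min_width = NULL, replicate = 1L) {
  stopifnot(inherits(chip, "CoverageTrack"), inherits(input, "CoverageTrack"),
            identical(names(chip$pileup), names(input$pileup)))
  if (chip$total_used == 0 || input$total_used == 0)
    stop("both tracks need nonzero totals")
  if (is.null(merge_gap)) merge_gap <- chip$fragment_length
  if (is.null(min_width)) min_width <- merge_gap
  scale <- chip$total_used / input$total_used
  lam_bg <- if (global_floor)
    scale * sum(vapply(input$pileup, sum, numeric(1))) /
      max(1, sum(lengths(input$pileup))) else 0
  test_p <- list(); lambdas <- list()
  for (cg in names(chip$pileup)) {
    x <- chip$pileup[[cg]]
    L <- length(x)
    if (L == 0) next
    y <- input$pileup[[cg]] * scale
    lam <- rep(max(mean(y), lam_bg), L)
    for (w in windows) if (w < L) lam <- pmax(lam, running_mean(y, w))
    sel <- which(x > lam)
    p <- rep(NA_real_, L)
    if (length(sel)) p[sel] <- ppois(x[sel] - 1, lam[sel], lower.tail = FALSE)
    test_p[[cg]] <- p
    lambdas[[cg]] <- lam
  }
  all_p <- unlist(lapply(test_p, function(p) p[!is.na(p)]))
  if (length(all_p) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), replicate = integer(0)))
  }
  all_q <- p.adjust(all_p, method = "BH")
  out <- list()
  offset <- 0L
  for (cg in names(test_p)) {
    p <- test_p[[cg]]
    idx <- which(!is.na(p))
    if (!length(idx)) next
    q <- all_q[offset + seq_along(idx)]
    offset <- offset + length(idx)
    sig <- idx[q < q_threshold]
    qsig <- q[q < q_threshold]
    psig <- p[sig]
    if (!length(sig)) next
    brk <- c(0, which(diff(sig) > merge_gap), length(sig))
    x <- chip$pileup[[cg]]; lam <- lambdas[[cg]]
    for (b in seq_len(length(brk) - 1)) {
      span <- sig[(brk[b] + 1):brk[b + 1]]
      s <- min(span) - 1L; e <- max(span)  # 0-based half-open
      if (e - s < min_width) next
      summit_rel <- span[which.max(x[span])]
      fold <- (x[summit_rel] + pseudocount) / (lam[summit_rel] + pseudocount)
      out[[length(out) + 1L]] <- data.frame(
        contig = cg, start = s, end = e, summit = summit_rel - 1L,
        fold_enrichment = fold,
        p_value = min(psig[(brk[b] + 1):brk[b + 1]]),
        q_value = min(qsig[(brk[b] + 1):brk[b + 1]]),
        replicate = replicate, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), replicate = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strongest peaks by fold enrichment
#'
#' @param peaks data.frame from [call_peaks()].
#' @param n number of peaks to keep.
#' @return the `n` peaks with the largest fold enrichment (ties broken by
#'   smaller q value, then by coordinate).
#' @export
top_peaks <- function(peaks, n = 100L) {
  if (is.null(peaks) || nrow(peaks) == 0) return(peaks)
  ord <- order(-peaks$fold_enrichment, peaks$q_value, peaks$contig, peaks$start)
  head(peaks[ord, , drop = FALSE], n)
}

#' Reproducible peaks across replicates
#'
#' A peak is reproducible when it overlaps (by at least `min_overlap` bp)
#' a peak in every other replicate, the role played by an irreproducible
#' discovery rate filter on ranked peak lists.  For every replicate pair
#' the Spearman correlation of log fold enrichment over matched peaks is
#' reported.
#'
#' @param peak_lists list of peak data.frames, one per replicate (>= 2).
#' @param min_overlap minimum overlap in bp.
#' @return list with `peaks` (all peaks with a `reproducible` flag),
#'   `intervals` (merged union of reproducible peaks) and `pair_rho`
#'   (per-pair Spearman correlations).
#' @export
reproducible_peaks <- function(peak_lists, min_overlap = 1L) {
  n_rep <- length(peak_lists)
  if (n_rep < 2) stop("need at least 2 replicates")
  ov_len <- function(a, b) {
    # for each row of a: max overlap with any row of b, and best partner
    best <- integer(nrow(a)); bl <- integer(nrow(a))
    for (i in seq_len(nrow(a))) {
      same <- b$contig == a$contig[i]
      if (!any(same)) { best[i] <- NA_integer_; next }
      o <- pmin(b$end[same], a$end[i]) - pmax(b$start[same], a$start[i])
      j <- which.max(o)
      bl[i] <- o[j]
      best[i] <- which(same)[j]
      if (o[j] < min_overlap) best[i] <- NA_integer_
    }
    list(partner = best, overlap = bl)
  }
  flags <- list(); rho <- list()
  for (r in seq_len(n_rep)) {
    a <- peak_lists[[r]]
    ok <- rep(TRUE, nrow(a))
    for (s in seq_len(n_rep)) {
      if (s == r) next
      mt <- ov_len(a, peak_lists[[s]])
      ok <- ok & !is.na(mt$partner)
      if (s > r) {
        sel <- !is.na(mt$partner)
        if (sum(sel) >= 3) {
          x <- log(a$fold_enrichment[sel])
          y <- log(peak_lists[[s]]$fold_enrichment[mt$partner[sel]])
          rho[[paste0(r, "_", s)]] <- data.frame(
            rep_a = r, rep_b = s, n_matched = sum(sel),
            rho = suppressWarnings(cor(x, y, method = "spearman")))
        } else {
          rho[[paste0(r, "_", s)]] <- data.frame(
            rep_a = r, rep_b = s, n_matched = sum(sel), rho = NA_real_)
        }
      }
    }
    a$reproducible <- ok
    flags[[r]] <- a
  }
  allp <- do.call(rbind, flags)
  rep_iv <- allp[allp$reproducible, c("contig", "start", "end"), drop = FALSE]
  intervals <- if (nrow(rep_iv)) merge_intervals(rep_iv) else
    data.frame(contig = character(0), start = integer(0), end = integer(0))
  list(peaks = allp, intervals = intervals,
       pair_rho = if (length(rho)) do.call(rbind, rho) else NULL)
}

#' Detect islands of complex DNA flanked by satellites
#'
#' Maximal runs of non-satellite annotation at least `min_island` bp
#' long, allowing internal satellite interruptions up to
#' `max_interruption` bp, with the flanking satellite family (or the
#' contig edge) recorded on each side.
#'
#' @param annotation truth-style interval data.frame (`contig`, `start`,
#'   `end`, `class`, `family`), 0-based half-open, tiling each contig.
#' @param min_island minimum island length (bp).
#' @param max_interruption longest satellite interval tolerated inside an
#'   island (bp).
#' @return data.frame of islands with `left_flank` and `right_flank`.
#' @export
detect_islands <- function(annotation, min_island = 1000L,
                           max_interruption = 2000L) {
  out <- list()
  for (cg in unique(annotation$contig)) {
    iv <- annotation[annotation$contig == cg, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    is_sat <- iv$class == "satellite"
    # absorb short satellite interruptions between complex blocks
    blockish <- !is_sat | (iv$end - iv$start <= max_interruption &
                           c(FALSE, !is_sat[-nrow(iv)]) &
                           c(!is_sat[-1], FALSE))
    r <- rle(blockish)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      i0 <- starts[k]; i1 <- ends[k]
      # trim absorbed satellites at the run edges (they are flanks, not body)
      while (i0 <= i1 && is_sat[i0]) i0 <- i0 + 1
      while (i1 >= i0 && is_sat[i1]) i1 <- i1 - 1
      if (i1 < i0) next
      s <- iv$start[i0]; e <- iv$end[i1]
      if (e - s < min_island) next
      left <- if (i0 > 1 && is_sat[i0 - 1]) iv$family[i0 - 1] else "edge"
      right <- if (i1 < nrow(iv) && is_sat[i1 + 1]) iv$family[i1 + 1] else "edge"
      out[[length(out) + 1L]] <- data.frame(
        contig = cg, start = s, end = e, left_flank = left,
        right_flank = right, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               left_flank = character(0), right_flank = character(0))
  rownames(res) <- NULL
  res
}

#' Rank islands into candidate centromeres
#'
#' Each island is scored by the fraction of its bases covered by
#' reproducible peaks; islands whose coverage exceeds
#' `coverage_threshold` are candidates, ranked by coverage.  When a
#' satellite enrichment table is supplied, the report flags whether at
#' least one flanking satellite family was itself called enriched.
#'
#' @param islands data.frame from [detect_islands()].
#' @param reproducible_intervals merged reproducible-peak intervals
#'   (`intervals` element of [reproducible_peaks()]).
#' @param kmer_table optional [kmer_enrichment()] table used to flag
#'   enriched flanking satellites.
#' @param satellite_units optional named vector mapping satellite family
#'   to its tandem unit (needed to look flank families up in the k-mer
#'   table).
#' @param coverage_threshold minimum peak-coverage fraction for candidacy.
#' @return `CandidateReport` data.frame sorted by rank score.
#' @export
classify_candidates <- function(islands, reproducible_intervals,
                                kmer_table = NULL, satellite_units = NULL,
                                coverage_threshold = 0.25) {
  if (nrow(islands) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), peak_coverage = numeric(0),
                      flank_enriched = logical(0), rank_score = numeric(0),
                      candidate = logical(0)))
  }
  cov <- numeric(nrow(islands))
  for (i in seq_len(nrow(islands))) {
    ri <- reproducible_intervals[
      reproducible_intervals$contig == islands$contig[i], , drop = FALSE]
    cov[i] <- interval_overlap_len(islands$start[i], islands$end[i],
                                   ri$start, ri$end) /
      (islands$end[i] - islands$start[i])
  }
  flank_enr <- rep(NA, nrow(islands))
  if (!is.null(kmer_table) && !is.null(satellite_units)) {
    enriched_units <- kmer_table$unit[kmer_table$enriched]
    flank_enr <- vapply(seq_len(nrow(islands)), function(i) {
      fams <- setdiff(c(islands$left_flank[i], islands$right_flank[i]), "edge")
      if (!length(fams)) return(FALSE)
      units <- canonical_unit(unname(satellite_units[fams]))
      any(units %in% enriched_units)
    }, logical(1))
  }
  out <- data.frame(islands, peak_coverage = cov, flank_enriched = flank_enr,
                    rank_score = cov, candidate = cov > coverage_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$contig), , drop = FALSE]
  rownames(out) <- NULL
  out
}
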