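# Approach (3): reference-free detection.  ChIP reads are assembled de
# novo into contigs (ChIPtigs), enrichment is computed post hoc by
# mapping ChIP and input reads back to the ChIPtigs, and significant
# ChIPtigs are projected onto the assembly.

#' Assemble ChIP reads into ChIPtigs
#'
#' A de Bruijn graph is built on canonical k-mers with count at least
#' `min_count`; maximal non-branching paths are emitted as contigs and
#' tips shorter than `2k` with a single dead end are clipped.  Reads may
#' optionally be subsampled deterministically first (the role coverage
#' normalisation plays on real libraries).
#'
#' @param reads a `ReadSet` or character vector of sequences.
#' @param k odd k-mer size, smaller than the read length.
#' @param min_count minimum k-mer multiplicity retained in the graph.
#' @param subsample optionally, the number of reads to keep (seeded,
#'   without replacement).
#' @param seed seed for the subsample.
#' @param replicate replicate label.
#' @return data.frame of ChIPtigs: `id`, `sequence`, `length`,
#'   `mean_cov`, `replicate`, sorted by decreasing length.
#' @export
assemble_chiptigs <- function(reads, k = 31L, min_count = 3L,
                              subsample = NULL, seed = 1L, replicate = 1L) {
  seqs <- if (inherits(reads, "ReadSet")) c(reads$seq1, reads$seq2)
          else as.character(reads)
  if (length(seqs) && k >= min(nchar(seqs)))
    stop("k must be smaller than the read length")
  if (!is.null(subsample) && subsample < length(seqs)) {
    seqs <- with_seed(seed, seqs[sample.int(length(seqs), subsample)])
  }
  if (length(seqs) == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      length = integer(0), mean_cov = numeric(0),
                      replicate = integer(0), stringsAsFactors = FALSE))
  }
  res <- assemble_debruijn_cpp(seqs, as.integer(k), as.integer(min_count))
  seq <- res$sequence
  ord <- order(-nchar(seq), seq)
  seq <- seq[ord]; cov <- res$mean_cov[ord]
  data.frame(id = sprintf("chiptig_%d_%05d", replicate, seq_along(seq)),
             sequence = seq, length = nchar(seq), mean_cov = cov,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Post hoc ChIP enrichment of ChIPtigs
#'
#' ChIP and input reads are assigned to the ChIPtigs by seeded ungapped
#' matching; uniquely assigned reads form per-ChIPtig coverage tracks and
#' the Poisson local-background peak caller ([call_peaks()]) is applied
#' with each ChIPtig as a contig.
#'
#' @param chiptigs data.frame from [assemble_chiptigs()].
#' @param chip_reads,input_reads `ReadSet`s or character vectors.
#' @param q_threshold q-value cutoff for a significant region.
#' @param max_mismatch_frac assignment mismatch tolerance.
#' @return list with `chiptigs` (the input table plus `n_assigned_chip`,
#'   `n_assigned_input`, `min_q`, `significant`) and `regions`
#'   (significant peak regions on the ChIPtigs).
#' @export
chiptig_enrichment <- function(chiptigs, chip_reads, input_reads,
                               q_threshold = 0.01, max_mismatch_frac = 0.04) {
  if (nrow(chiptigs) == 0) stop("no ChIPtigs to score")
  get_seqs <- function(r) if (inherits(r, "ReadSet")) c(r$seq1, r$seq2)
                          else as.character(r)
  chip_seqs <- get_seqs(chip_reads); input_seqs <- get_seqs(input_reads)
  if (length(input_seqs) == 0) stop("input channel is empty")
  lib <- list(consensus = setNames(chiptigs$sequence, chiptigs$id),
              class = setNames(rep("element", nrow(chiptigs)), chiptigs$id))
  asg_c <- assign_reads(chip_seqs, lib, max_mismatch_frac, details = TRUE)
  asg_i <- assign_reads(input_seqs, lib, max_mismatch_frac, details = TRUE)
  track_of <- function(a, read_len_src) {
    pr <- a$per_read
    pile <- list()
    for (j in seq_len(nrow(chiptigs))) {
      id <- chiptigs$id[j]; L <- chiptigs$length[j]
      sel <- which(pr$status == "assigned" & pr$family == id)
      add <- numeric(L + 1)
      if (length(sel)) {
        s <- pmax(0, pr$tstart[sel]) + 1
        e <- pmin(L, pr$tstart[sel] + pr$overlap[sel])
        for (i in seq_along(s)) {
          add[s[i]] <- add[s[i]] + 1
          add[e[i] + 1] <- add[e[i] + 1] - 1
        }
      }
      pile[[id]] <- cumsum(add[seq_len(L)])
    }
    structure(list(pileup = pile,
                   total_used = sum(pr$status == "assigned"),
                   fragment_length = max(nchar(read_len_src[1]), 1L)),
              class = "CoverageTrack")
  }
  chip_track <- track_of(asg_c, chip_seqs)
  input_track <- track_of(asg_i, input_seqs)
  peaks <- call_peaks(chip_track, input_track, q_threshold = q_threshold,
                      merge_gap = max(nchar(chip_seqs[1]), 1L))
  minq <- setNames(rep(NA_real_, nrow(chiptigs)), chiptigs$id)
  maxfold <- setNames(rep(NA_real_, nrow(chiptigs)), chiptigs$id)
  if (!is.null(peaks) && nrow(peaks)) {
    agg <- tapply(peaks$q_value, peaks$contig, min)
    minq[names(agg)] <- agg
    aggf <- tapply(peaks$fold_enrichment, peaks$contig, max)
    maxfold[names(aggf)] <- aggf
  }
  chiptigs$n_assigned_chip <- asg_c$counts[chiptigs$id]
  chiptigs$n_assigned_input <- asg_i$counts[chiptigs$id]
  chiptigs$min_q <- unname(minq)
  chiptigs$fold_enrichment <- unname(maxfold)
  chiptigs$significant <- !is.na(minq) & minq < q_threshold
  list(chiptigs = chiptigs,
       regions = if (is.null(peaks)) peaks else
         peaks[order(peaks$q_value), , drop = FALSE])
}

#' Project ChIPtigs onto a genome assembly
#'
#' Seed-and-extend placement on both strands; the best-scoring location
#' is chosen, a placement is unique when its score strictly exceeds the
#' best score at any other locus, and placements below the identity or
#' coverage floors are discarded (the analog of removing potentially
#' misassembled contigs).
#'
#' @param chiptigs data.frame from [assemble_chiptigs()].
#' @param genome named character vector of contigs.
#' @param identity_floor minimum identity of the aligned part.
#' @param coverage_floor minimum aligned fraction of the ChIPtig length.
#' @param seed_len,seed_step seed parameters.
#' @return data.frame of placements: `id`, `contig`, `start`, `end`,
#'   `strand`, `identity`, `coverage`, `unique`, `placed`.
#' @export
place_chiptigs <- function(chiptigs, genome, identity_floor = 0.95,
                           coverage_floor = 0.9, seed_len = 20L,
                           seed_step = 5L) {
  if (nrow(chiptigs) == 0) {
    return(data.frame(id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), unique = logical(0),
                      placed = logical(0), stringsAsFactors = FALSE))
  }
  m <- seed_match_cpp(chiptigs$sequence, unname(genome),
                      as.integer(seed_len), as.integer(seed_step), 64L, 64L)
  hit <- !is.na(m$target)
  identity <- ifelse(m$overlap > 0, m$score / m$overlap, 0)
  coverage <- m$overlap / m$qlen
  placed <- hit & identity >= identity_floor & coverage >= coverage_floor
  uniq <- placed & m$second_locus_score < m$score
  data.frame(id = chiptigs$id,
             contig = ifelse(hit, names(genome)[m$target], NA_character_),
             start = ifelse(hit, as.integer(m$tstart), NA_integer_),
             end = ifelse(hit, as.integer(m$tstart + m$overlap), NA_integer_),
             strand = ifelse(hit, ifelse(m$strand == 1, "+", "-"),
                             NA_character_),
             identity = identity, coverage = coverage,
             unique = uniq, placed = placed, stringsAsFactors = FALSE)
}

#' Fraction of top enriched ChIPtigs placing on candidate contigs
#'
#' Takes the `n` significant ChIPtigs with the strongest signal (largest
#' fold enrichment, ties by smaller q then larger assigned ChIP count)
#' and counts how many place uniquely within the candidate contigs (or
#' within supplied candidate regions); non-uniquely placed ChIPtigs
#' never count towards the numerator.
#'
#' @param placements data.frame from [place_chiptigs()].
#' @param scored ChIPtig table from [chiptig_enrichment()].
#' @param candidate_contigs character vector of candidate contig names.
#' @param n number of top ChIPtigs to summarise.
#' @param regions optional data.frame (`contig`, `start`, `end`): when
#'   given, the numerator requires overlap with these intervals rather
#'   than mere contig membership.
#' @return list with `n_top`, `n_unique_on_candidates`, `fraction`.
#' @export
summarize_on_candidates <- function(placements, scored, candidate_contigs,
                                    n = 30L, regions = NULL) {
  sig <- scored[scored$significant, , drop = FALSE]
  sig <- sig[order(-sig$fold_enrichment, sig$min_q, -sig$n_assigned_chip), ,
             drop = FALSE]
  top <- head(sig, n)
  pl <- placements[match(top$id, placements$id), , drop = FALSE]
  on_cand <- !is.na(pl$contig) & pl$unique & pl$contig %in% candidate_contigs
  if (!is.null(regions)) {
    hit_region <- vapply(seq_len(nrow(pl)), function(i) {
      if (is.na(pl$contig[i])) return(FALSE)
      rr <- regions[regions$contig == pl$contig[i], , drop = FALSE]
      interval_overlap_len(pl$start[i], pl$end[i], rr$start, rr$end) > 0
    }, logical(1))
    on_cand <- on_cand & hit_region
  }
  list(n_top = nrow(top), n_unique_on_candidates = sum(on_cand),
       fraction = if (nrow(top)) sum(on_cand) / nrow(top) else NA_real_)
}
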