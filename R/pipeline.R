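# End-to-end driver: generate a planted genome, simulate replicated
# ChIP/input read sets, run the four enrichment approaches and classify
# candidate centromeres against the planted truth.

#' Run the planted-centromere analysis end to end
#'
#' Builds (or accepts) a synthetic genome with planted centromere
#' islands, simulates `n_replicates` paired ChIP/input read sets, and
#' runs all four discovery approaches: tandem k-mer enrichment, repeat
#' library assignment with the top-percentile rule, de novo ChIPtig
#' assembly with post hoc enrichment and projection, and Poisson peak
#' calling with reproducibility filtering, island detection and
#' candidate classification.  Replicates are processed one at a time so
#' only summaries are retained.
#'
#' @param seed master seed; the genome and every read set derive their
#'   seeds from it.
#' @param spec optional [genome_spec()]; default [default_genome_spec()].
#' @param params optional [chip_sim_params()].
#' @param chiptig_subsample reads per replicate used for de novo
#'   assembly and ChIPtig enrichment (deterministic subsample).
#' @param top_n_chiptigs top enriched ChIPtigs summarised on candidates.
#' @param verbose print progress.
#' @return list with the genome truth, per-stage tables
#'   (`kmer_table`, `family_table`, `peaks`, `reproducible`, `islands`,
#'   `candidates`, `chiptig_summary`) and a `recovery` summary comparing
#'   candidates against planted islands.
#' @export
run_planted_analysis <- function(seed = 1L, spec = NULL, params = NULL,
                                 chiptig_subsample = 120000L,
                                 top_n_chiptigs = 30L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(spec)) spec <- default_genome_spec(seed)
  if (is.null(params)) params <- chip_sim_params(seed = seed + 17L)
  say("building genome")
  built <- build_genome(spec)
  genome <- built$genome; truth <- built$truth; lib <- built$library

  n_rep <- params$n_replicates
  kmer_chip <- list(); kmer_input <- list()
  fam_chip <- list(); fam_input <- list()
  totals_chip <- numeric(n_rep); totals_input <- numeric(n_rep)
  peak_lists <- list()
  chiptig_tops <- list()

  sat_units <- spec$satellite_defs

  for (r in seq_len(n_rep)) {
    say("replicate %d: simulating reads", r)
    rs <- simulate_chip_reads(genome, truth, params,
                              control_satellite = spec$control_satellite,
                              replicates = r)
    chip <- rs[[paste0("chip_", r)]]
    input <- rs[[paste0("input_", r)]]
    totals_chip[r] <- chip$total_reads
    totals_input[r] <- input$total_reads

    say("replicate %d: tandem k-mer counts", r)
    kmer_chip[[r]] <- count_kmers(chip)
    kmer_input[[r]] <- count_kmers(input)

    say("replicate %d: repeat-library assignment", r)
    fam_chip[[r]] <- assign_reads(chip, lib)
    fam_input[[r]] <- assign_reads(input, lib)

    say("replicate %d: coverage and peaks", r)
    cov_chip <- build_coverage(chip, genome, truth)
    cov_input <- build_coverage(input, genome, truth)
    peak_lists[[r]] <- call_peaks(cov_chip, cov_input, replicate = r)

    say("replicate %d: ChIPtigs", r)
    ss <- function(x, n, sd) with_seed(sd, x[sample.int(length(x), min(n, length(x)))])
    chip_sub <- ss(c(chip$seq1, chip$seq2), chiptig_subsample, seed + 31L * r)
    input_sub <- ss(c(input$seq1, input$seq2), chiptig_subsample, seed + 31L * r + 1L)
    tig <- assemble_chiptigs(chip_sub, replicate = r)
    if (nrow(tig)) {
      enr <- chiptig_enrichment(tig, chip_sub, input_sub)
      plc <- place_chiptigs(enr$chiptigs, genome)
      chiptig_tops[[r]] <- list(scored = enr$chiptigs, placements = plc)
    }
    rm(rs, chip, input, cov_chip, cov_input, chip_sub, input_sub)
    gc(FALSE)
  }

  say("aggregating calls")
  kmer_table <- kmer_enrichment(kmer_chip, kmer_input, totals_chip,
                                totals_input)
  family_table <- family_enrichment(fam_chip, fam_input, totals_chip,
                                    totals_input)
  repro <- reproducible_peaks(peak_lists)
  islands <- detect_islands(truth$intervals)
  candidates <- classify_candidates(islands, repro$intervals, kmer_table,
                                    satellite_units = sat_units)

  cand_contigs <- unique(candidates$contig[candidates$candidate])
  chiptig_summary <- lapply(seq_along(chiptig_tops), function(r) {
    ct <- chiptig_tops[[r]]
    if (is.null(ct)) return(NULL)
    sm <- summarize_on_candidates(ct$placements, ct$scored, cand_contigs,
                                  n = top_n_chiptigs,
                                  regions = truth$island_spans)
    data.frame(replicate = r, n_top = sm$n_top,
               n_unique_on_candidates = sm$n_unique_on_candidates,
               fraction = sm$fraction)
  })
  chiptig_summary <- do.call(rbind, chiptig_summary)

  planted <- truth$island_spans
  cand <- candidates[candidates$candidate, , drop = FALSE]
  hit_planted <- vapply(seq_len(nrow(cand)), function(i) {
    pp <- planted[planted$contig == cand$contig[i], , drop = FALSE]
    interval_overlap_len(cand$start[i], cand$end[i], pp$start, pp$end) > 0
  }, logical(1))
  recovery <- list(
    n_planted = nrow(planted),
    n_candidates = nrow(cand),
    n_candidates_on_planted = sum(hit_planted),
    n_decoy_candidates = sum(!hit_planted),
    shared_element_enriched =
      family_table$enriched[family_table$family == spec$shared_element],
    control_satellite_enriched = {
      cu <- canonical_unit(sat_units[[spec$control_satellite]])
      any(kmer_table$enriched[kmer_table$unit == cu])
    })

  list(spec = spec, params = params, truth = truth, library = lib,
       totals_chip = totals_chip, totals_input = totals_input,
       kmer_table = kmer_table, family_table = family_table,
       peaks = peak_lists, reproducible = repro, islands = islands,
       candidates = candidates, chiptig_summary = chiptig_summary,
       recovery = recovery)
}
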