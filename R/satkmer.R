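# Approach (1): tandem k-mer (satellite) detection in reads and the
# satellite enrichment decision rule.

#' Canonical representative of a tandem-repeat unit
#'
#' Tandem units are equivalent under rotation and reverse complement
#' (a read through an `AAGAG` array can enter the repeat in any phase and
#' on either strand), so counts are aggregated under the lexicographic
#' minimum over all rotations of the unit and of its reverse complement.
#' The map is idempotent.
#'
#' @param unit character vector of units over A/C/G/T.
#' @return character vector of canonical units.
#' @examples
#' canonical_unit("GAGAA")  # "AAGAG"
#' @export
canonical_unit <- function(unit) {
  canonical_unit_cpp(toupper(as.character(unit)))
}

#' Detect maximal tandem runs in reads
#'
#' Scans each read for maximal stretches that equal themselves shifted by
#' the unit length, for every unit length up to `max_unit`.  Runs are
#' attributed to their primitive unit (an `AAAA...` stretch is an `A` run,
#' never an `AA` run), require at least `min_copies` whole copies, and
#' overlapping runs of different units are resolved longest-span-first
#' (ties: shorter unit, then leftmost).  The copy count is the whole
#' number of unit copies in the run (`floor(span / unit length)`).
#'
#' @param reads character vector of read sequences.
#' @param max_unit maximum unit length (bp).
#' @param min_copies minimum whole unit copies for a run to be reported.
#' @return data.frame with `read` (index), canonical `unit`, `copies`,
#'   `start` (0-based) and `span`.
#' @export
detect_tandem_runs <- function(reads, max_unit = 20L, min_copies = 3L) {
  stopifnot(max_unit >= 1, min_copies >= 2)
  tandem_runs_cpp(toupper(as.character(reads)), as.integer(max_unit),
                  as.integer(min_copies))
}

#' Count tandem-unit copies across a read set
#'
#' Sums the tandem-run copy counts of [detect_tandem_runs()] over all
#' reads, aggregated by canonical unit.  Order of reads does not matter.
#'
#' @param reads a `ReadSet` (both mates are scanned) or a character
#'   vector of sequences.
#' @inheritParams detect_tandem_runs
#' @return named numeric vector, canonical unit -> total copies.
#' @export
count_kmers <- function(reads, max_unit = 20L, min_copies = 3L) {
  seqs <- if (inherits(reads, "ReadSet")) c(reads$seq1, reads$seq2)
          else as.character(reads)
  if (length(seqs) == 0) return(setNames(numeric(0), character(0)))
  out <- tandem_count_cpp(toupper(seqs), as.integer(max_unit),
                          as.integer(min_copies))
  out[order(names(out))]
}

#' Satellite enrichment from tandem-unit counts
#'
#' For each canonical unit and replicate, the normalised ratio is
#' `(chip count / chip mapped total) / (input count / input mapped
#' total)`.  A unit is called enriched when the input count is at least
#' `min_input` in every replicate and the median ratio across replicates
#' exceeds 1 (the median of an even number of replicates is the mean of
#' the two middle values).  Units with a zero input count in any
#' replicate have an undefined ratio there and are never enriched.
#'
#' @param chip_counts,input_counts lists (one element per replicate) of
#'   named count vectors as returned by [count_kmers()].
#' @param chip_totals,input_totals numeric vectors of mapped-read totals
#'   per replicate (all > 0).
#' @param min_input minimum input count required in every replicate.
#' @return data.frame with one row per unit: per-replicate ratios,
#'   `median_ratio`, `min_input_count` and the `enriched` call.
#' @export
kmer_enrichment <- function(chip_counts, input_counts, chip_totals,
                            input_totals, min_input = 10) {
  n_rep <- length(chip_counts)
  if (length(input_counts) != n_rep || length(chip_totals) != n_rep ||
      length(input_totals) != n_rep)
    stop("chip and input replicates must be paired")
  stopifnot(all(chip_totals > 0), all(input_totals > 0))
  units <- sort(unique(c(unlist(lapply(chip_counts, names)),
                         unlist(lapply(input_counts, names)))))
  if (length(units) == 0) {
    return(data.frame(unit = character(0)))
  }
  get0s <- function(v, u) ifelse(u %in% names(v), v[u], 0)
  chip_m <- sapply(seq_len(n_rep), function(r) get0s(chip_counts[[r]], units))
  input_m <- sapply(seq_len(n_rep), function(r) get0s(input_counts[[r]], units))
  chip_m <- matrix(chip_m, ncol = n_rep); input_m <- matrix(input_m, ncol = n_rep)
  ratio <- sapply(seq_len(n_rep), function(r) {
    num <- chip_m[, r] / chip_totals[r]
    den <- input_m[, r] / input_totals[r]
    ifelse(input_m[, r] > 0, num / den, NA_real_)
  })
  ratio <- matrix(ratio, ncol = n_rep)
  med <- apply(ratio, 1, function(x) if (anyNA(x)) NA_real_ else median(x))
  min_inp <- apply(input_m, 1, min)
  enriched <- !is.na(med) & min_inp >= min_input & med > 1
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  for (r in seq_len(n_rep)) {
    out[[paste0("chip_", r)]] <- chip_m[, r]
    out[[paste0("input_", r)]] <- input_m[, r]
    out[[paste0("ratio_", r)]] <- ratio[, r]
  }
  out$median_ratio <- med
  out$min_input_count <- min_inp
  out$enriched <- enriched
  rownames(out) <- NULL
  out
}
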