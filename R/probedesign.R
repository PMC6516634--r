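# Repeat-tolerant oligo probe design: overlap-mode tiling with a melting
# temperature window and a genome-wide 18-mer occurrence filter instead
# of alignment-based uniqueness (so probes inside repeats survive as
# long as no 18-mer in them is too common).

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Duplex Tm under the unified nearest-neighbor thermodynamic parameter
#' set, with a monovalent-salt entropy correction
#' (`0.368 (N-1) ln[Na+]`) and a linear formamide depression of
#' 0.65 degC per percent.  Defaults describe an Oligopaint-style
#' hybridisation: 25 nM of each strand, 390 mM Na+, 50% formamide.  The
#' Tm of a sequence equals that of its reverse complement.
#'
#' @param seq character vector of oligo sequences (10-60 nt, ACGT).
#' @param dnac1_nM,dnac2_nM strand concentrations (nM).
#' @param na_mM monovalent sodium concentration (mM).
#' @param formamide_pct percent formamide.
#' @return numeric vector of Tm in degrees Celsius.
#' @export
tm_nn <- function(seq, dnac1_nM = 25, dnac2_nM = 25, na_mM = 390,
                  formamide_pct = 50) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (any(n < 10 | n > 60)) stop("oligo length must be in 10..60 nt")
  if (any(grepl("[^ACGT]", seq))) stop("sequences must be ACGT only")
  tm_nn_cpp(seq, dnac1_nM, dnac2_nM, na_mM, formamide_pct)
}

#' Genome k-mer occurrence counter
#'
#' Counts every canonical (strand-collapsed) k-mer of the genome; used to
#' reject probe candidates containing k-mers that occur too often.
#'
#' @param genome named character vector of contig sequences.
#' @param k k-mer length (default 18).
#' @return a `kmer_counter` object.
#' @export
genome_kmer_counter <- function(genome, k = 18L) {
  ptr <- build_kmer_counter_cpp(unname(as.character(genome)), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 n_distinct = kmer_counter_size_cpp(ptr)),
            class = "kmer_counter")
}

#' Occurrence counts of specific k-mers
#'
#' @param counter a [genome_kmer_counter()].
#' @param kmers character vector of k-mers (length k).
#' @return integer vector of genome-wide canonical occurrence counts.
#' @export
kmer_hits <- function(counter, kmers) {
  stopifnot(inherits(counter, "kmer_counter"))
  kmer_hits_cpp(counter$ptr, toupper(as.character(kmers)))
}

#' Maximum k-mer occurrence within each sequence
#'
#' @param counter a [genome_kmer_counter()].
#' @param seqs character vector of sequences.
#' @return for each sequence, the maximum genome-wide occurrence count
#'   over all its k-mers.
#' @export
max_kmer_hits <- function(counter, seqs) {
  stopifnot(inherits(counter, "kmer_counter"))
  max_window_kmer_hits_cpp(counter$ptr, toupper(as.character(seqs)))
}

#' Overlap-mode probe tiling with Tm and occurrence filters
#'
#' Every start offset and length in `lengths` within the region is a
#' candidate (overlap mode: accepted probes may overlap).  A candidate is
#' accepted when its melting temperature falls inside `tm_window` and no
#' 18-mer (or `counter$k`-mer) it contains occurs more than `max_hits`
#' times in the genome -- a hit cap of 5 rejects anything matching 6 or
#' more times.
#'
#' @param genome named character vector of contigs.
#' @param contig,start,end target region (0-based half-open).
#' @param counter optional precomputed [genome_kmer_counter()]; built
#'   from the genome when missing.
#' @param lengths candidate probe lengths (nt).
#' @param tm_window acceptance window for Tm (degC, inclusive).
#' @param max_hits maximum tolerated genome-wide occurrence of any
#'   contained k-mer.
#' @param ... forwarded to [tm_nn()].
#' @return data.frame of `ProbeCandidate`s sorted by start: `contig`,
#'   `start`, `end`, `sequence`, `tm`, `max_kmer_hits`, `accepted`.
#' @export
tile_and_filter <- function(genome, contig, start, end, counter = NULL,
                            lengths = 35:41, tm_window = c(42, 47),
                            max_hits = 5L, ...) {
  stopifnot(contig %in% names(genome))
  L <- nchar(genome[[contig]])
  stopifnot(start >= 0, end <= L, start < end)
  if (is.null(counter)) counter <- genome_kmer_counter(genome)
  region_len <- end - start
  cand <- list()
  for (len in lengths) {
    if (len > region_len) next
    s <- start + 0:(region_len - len)
    cand[[length(cand) + 1L]] <- data.frame(start = s, end = s + len)
  }
  if (!length(cand)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      tm = numeric(0), max_kmer_hits = integer(0),
                      accepted = logical(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, cand)
  df$sequence <- substring(genome[[contig]], df$start + 1, df$end)
  df$tm <- tm_nn(df$sequence, ...)
  df$max_kmer_hits <- max_kmer_hits(counter, df$sequence)
  df$accepted <- df$tm >= tm_window[1] & df$tm <= tm_window[2] &
    df$max_kmer_hits <= max_hits
  out <- data.frame(contig = contig, df[, c("start", "end", "sequence", "tm",
                                            "max_kmer_hits", "accepted")],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Probe coverage/density report for a region
#'
#' @param probes output of [tile_and_filter()].
#' @param start,end region bounds.
#' @return list with accepted probe count, bases covered by accepted
#'   probes, coverage fraction and mean probes per kb.
#' @export
probe_density <- function(probes, start, end) {
  acc <- probes[probes$accepted, , drop = FALSE]
  covered <- 0L
  if (nrow(acc)) {
    iv <- merge_intervals(data.frame(contig = "r", start = acc$start,
                                     end = acc$end))
    covered <- sum(iv$end - iv$start)
  }
  list(n_accepted = nrow(acc), bases_covered = covered,
       coverage_fraction = covered / (end - start),
       probes_per_kb = nrow(acc) / ((end - start) / 1000))
}
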