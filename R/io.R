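# Readers/writers for the standard interchange formats: FASTA, paired
# FASTQ, BED (0-based half-open), validPairs TSV.

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a paired read set as _1/_2 FASTQ files
#'
#' Read names encode the fragment placement as `contig:start:mate`,
#' making truth lookups possible from the files alone.
#'
#' @param readset a `ReadSet`.
#' @param prefix path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_readset_fastq <- function(readset, prefix) {
  for (mate in 1:2) {
    seqs <- if (mate == 1) readset$seq1 else readset$seq2
    nm <- paste0("@", readset$contig, ":", readset$start, ":", mate)
    qual <- strrep("I", nchar(seqs))
    out <- as.vector(rbind(nm, seqs, "+", qual))
    writeLines(out, sprintf("%s_%d.fastq", prefix, mate))
  }
  invisible(prefix)
}

#' Read a FASTQ file (4-line records) as a character vector of sequences
#'
#' @param path FASTQ file.
#' @return character vector of sequences named by read id.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) stop("malformed FASTQ (not 4-line records)")
  seqs <- ln[seq(2, length(ln), by = 4)]
  setNames(seqs, sub("^@", "", ln[seq(1, length(ln), by = 4)]))
}

#' Write truth or island intervals as BED
#'
#' Interval names are `class:family` when those columns exist.
#'
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optional `class`/`family`.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  name <- if (all(c("class", "family") %in% names(intervals)))
    paste0(intervals$class, ":", intervals$family) else "."
  df <- data.frame(intervals$contig, intervals$start, intervals$end, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write Hi-C valid pairs in validPairs column order
#'
#' @param pairs data.frame from [simulate_hic_pairs()].
#' @param path output file.
#' @export
write_valid_pairs <- function(pairs, path) {
  write.table(pairs[, c("readID", "chrA", "posA", "strandA",
                        "chrB", "posB", "strandB")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a validPairs TSV
#'
#' @param path file with columns readID, chrA, posA, strandA, chrB,
#'   posB, strandB.
#' @export
read_valid_pairs <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("readID", "chrA", "posA", "strandA", "chrB", "posB",
                 "strandB")[seq_len(ncol(df))]
  df
}

#' Read a genome specification from a YAML file
#'
#' The YAML mirrors the arguments of [genome_spec()]: top-level keys
#' `seed`, `shared_element`, `truncation_prob`, `control_satellite`,
#' `divergence`, maps `satellite_defs` and `element_defs`, and a
#' `contigs` list whose entries have `name` and `blocks` (each block a
#' map with `kind` and its fields).
#'
#' @param path YAML file.
#' @return a [genome_spec()].
#' @export
genome_spec_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read spec files")
  y <- yaml::read_yaml(path)
  genome_spec(
    contigs = y$contigs,
    satellite_defs = unlist(y$satellite_defs),
    element_defs = unlist(y$element_defs),
    shared_element = y$shared_element,
    truncation_prob = y$truncation_prob %||% 0.4,
    control_satellite = y$control_satellite,
    divergence = y$divergence %||% 0.05,
    seed = y$seed %||% 1L)
}
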