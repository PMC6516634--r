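# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulations compose deterministically
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random ACGT string(s); uses the current RNG stream
random_dna <- function(n_bases) {
  vapply(n_bases, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# apply a uniform substitution rate to a single sequence
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  chars[pos] <- vapply(chars[pos], function(b) sample(alt[[b]], 1), character(1))
  paste(chars, collapse = "")
}

# tandem array of `unit` trimmed to exactly `len` bases
satellite_array <- function(unit, len) {
  full <- strrep(unit, ceiling(len / nchar(unit)))
  substr(full, 1, len)
}

# total length of the intersection of interval [s, e) with a set of
# intervals given as sorted non-overlapping (starts, ends); all 0-based
# half-open
interval_overlap_len <- function(s, e, starts, ends) {
  if (length(starts) == 0) return(0)
  lo <- pmax(s, starts)
  hi <- pmin(e, ends)
  sum(pmax(0, hi - lo))
}

# merge a sorted set of intervals (data.frame with start/end), returning
# non-overlapping union intervals
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- list()
  for (ctg in unique(df$contig)) {
    d <- df[df$contig == ctg, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]
    res_s <- c(); res_e <- c()
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (d$start[i] <= e) e <- max(e, d$end[i])
        else { res_s <- c(res_s, s); res_e <- c(res_e, e); s <- d$start[i]; e <- d$end[i] }
      }
    }
    res_s <- c(res_s, s); res_e <- c(res_e, e)
    out[[ctg]] <- data.frame(contig = ctg, start = res_s, end = res_e,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
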