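# Independent reference implementations used as oracles.  These are
# written in plain R against the documented semantics and share no code
# with the package internals.

r_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# canonical tandem unit: lexicographic min over rotations of the unit and
# of its reverse complement
r_canonical_unit <- function(u) {
  rots <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
      paste0(substr(s, i, n), substr(s, 1, i - 1)), character(1))
  }
  min(c(rots(u), rots(r_revcomp(u))))
}

r_is_primitive <- function(u) {
  n <- nchar(u)
  if (n == 1) return(TRUE)
  for (d in seq_len(n - 1)) {
    if (n %% d != 0) next
    if (identical(strrep(substr(u, 1, d), n / d), u)) return(FALSE)
  }
  TRUE
}

# brute-force tandem-run detector: every unit length at every offset,
# maximal runs, primitive units, >= min_copies whole copies, overlaps
# resolved longest-span-first (ties: shorter unit, then leftmost)
naive_tandem_runs <- function(read, max_unit = 20L, min_copies = 3L) {
  s <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(s)
  cand <- list()
  for (u in seq_len(min(max_unit, max(L - 1, 0)))) {
    i <- 1
    while (i + u <= L) {
      if (s[i] == s[i + u]) {
        j <- i
        while (j + u <= L && s[j] == s[j + u]) j <- j + 1
        span <- (j - i) + u
        copies <- span %/% u
        unit <- paste(s[i:(i + u - 1)], collapse = "")
        run <- paste(s[i:(i + span - 1)], collapse = "")
        if (copies >= min_copies && r_is_primitive(unit) &&
            !grepl("[^ACGT]", run)) {
          cand[[length(cand) + 1L]] <- data.frame(
            unit = r_canonical_unit(unit), copies = copies,
            start = i - 1L, span = span, ulen = u,
            stringsAsFactors = FALSE)
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (!length(cand)) {
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), span = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$span, cand$ulen, cand$start), , drop = FALSE]
  occupied <- rep(FALSE, L)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    span_idx <- (cand$start[k] + 1):(cand$start[k] + cand$span[k])
    if (!any(occupied[span_idx])) {
      occupied[span_idx] <- TRUE
      keep[k] <- TRUE
    }
  }
  out <- cand[keep, c("unit", "copies", "start", "span"), drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random reads: a mixture of random sequence and planted tandem arrays
random_test_reads <- function(n, len = 150L, p_tandem = 0.4) {
  units <- c("A", "AT", "AATAT", "AAGAG", "TTCG", "AGTCCTGGAATC", "ACG")
  vapply(seq_len(n), function(i) {
    if (runif(1) < p_tandem) {
      u <- sample(units, 1)
      k <- sample(0:len, 1)
      arr <- substr(strrep(u, ceiling(k / nchar(u)) + 1), 1, k)
      rest <- paste(sample(c("A", "C", "G", "T"), len - k, TRUE), collapse = "")
      at <- sample(0:(len - k), 1)
      paste0(substr(rest, 1, at), arr, substr(rest, at + 1, len - k))
    } else {
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    }
  }, character(1))
}

# a one-contig spec matching the canonical construction example:
# 10 kb satellite | 5 kb island with two shared-element copies | 10 kb satellite
example_spec <- function(seed = 1L, truncation_prob = 0) {
  genome_spec(
    contigs = list(list(name = "c1", blocks = list(
      list(kind = "satellite", family = "satA", length = 10000L),
      list(kind = "island", elements = c("el1", "el1"), spacer = 100L,
           length = 5000L),
      list(kind = "satellite", family = "satB", length = 10000L)))),
    satellite_defs = c(satA = "AATAT", satB = "AAGAG"),
    element_defs = c(el1 = 3000L),
    shared_element = "el1", truncation_prob = truncation_prob,
    divergence = 0.05, seed = seed)
}

# error-free reads tiling a source sequence at roughly `cov` fold; each
# start is emitted `copies` times so that terminal k-mers also reach the
# assembler's multiplicity threshold
tiling_reads <- function(source, read_len = 100L, cov = 30L, copies = 3L) {
  L <- nchar(source)
  step <- max(1L, round(copies * read_len / cov))
  starts <- unique(c(seq(1L, L - read_len + 1L, by = step), L - read_len + 1L))
  rep(substring(source, starts, starts + read_len - 1L), each = copies)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
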