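#' Specify a synthetic genome with planted centromere islands
#'
#' A genome specification lists contigs as ordered blocks of sequence:
#' satellite arrays (short tandem units), centromere islands (runs of
#' retroelement copies separated by unique spacers), standalone element
#' copies and unique filler.  One element family (`shared_element`) must be
#' present in every island, mirroring the organisation of real centromere
#' islands in which a single retroelement family recurs at all
#' centromeres.  A control satellite family is planted only outside
#' islands and receives no ChIP enrichment, providing a negative control
#' for the k-mer analysis.
#'
#' Blocks are lists with a `kind` field:
#' \describe{
#'   \item{`satellite`}{`family`, `length` (bp).}
#'   \item{`island`}{`elements`: character vector of element families in
#'     order; optional `spacer` (bp of unique DNA between copies, default
#'     200) and `length` (trim/pad the island to an exact size).}
#'   \item{`element`}{`family`: one standalone element copy.}
#'   \item{`unique`}{`length` bp of random unique sequence.}
#' }
#'
#' @param contigs list of `list(name =, blocks = list(...))`.
#' @param satellite_defs named character vector, family -> tandem unit.
#' @param element_defs named integer vector, family -> consensus length (bp).
#' @param shared_element family name required in every island block.
#' @param truncation_prob probability that an element copy is 5'-truncated.
#' @param control_satellite satellite family that must never occur inside
#'   or adjacent to an island.
#' @param divergence per-copy substitution rate applied to element copies
#'   so that individual insertions are distinguishable, as real
#'   retroelement copies are.
#' @param seed integer seed; the same spec and seed give a byte-identical
#'   genome.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(contigs, satellite_defs, element_defs,
                        shared_element, truncation_prob = 0.4,
                        control_satellite = NULL, divergence = 0.05,
                        seed = 1L) {
  stopifnot(length(contigs) > 0, length(satellite_defs) > 0,
            length(element_defs) > 0)
  if (!shared_element %in% names(element_defs))
    stop("shared_element must be an element family")
  if (!is.null(control_satellite) &&
      !control_satellite %in% names(satellite_defs))
    stop("control_satellite must be a satellite family")
  for (ctg in contigs) {
    if (is.null(ctg$name) || is.null(ctg$blocks))
      stop("each contig needs a name and a block list")
    last_end <- NULL
    for (b in ctg$blocks) {
      if (!b$kind %in% c("satellite", "island", "element", "unique"))
        stop("unknown block kind: ", b$kind)
      if (!is.null(b$start)) {
        if (!is.null(last_end) && b$start < last_end)
          stop("overlapping blocks in contig ", ctg$name)
        last_end <- b$start + (b$length %||% 0L)
      }
      if (b$kind == "island") {
        if (!shared_element %in% b$elements)
          stop("island in contig ", ctg$name,
               " lacks the shared element family '", shared_element, "'")
        if (!all(b$elements %in% names(element_defs)))
          stop("unknown element family in island of contig ", ctg$name)
      }
      if (b$kind == "satellite" && !b$family %in% names(satellite_defs))
        stop("unknown satellite family: ", b$family)
      if (b$kind == "element" && !b$family %in% names(element_defs))
        stop("unknown element family: ", b$family)
      if (!is.null(control_satellite) && b$kind == "island" &&
          control_satellite %in% b$elements)
        stop("control satellite cannot occur inside an island")
    }
    is_island <- vapply(ctg$blocks, function(b) b$kind == "island", logical(1))
    is_ctrl <- vapply(ctg$blocks, function(b)
      b$kind == "satellite" && identical(b$family, control_satellite), logical(1))
    if (any(is_island) && any(is_ctrl))
      stop("control satellite must not share a contig with an island")
  }
  structure(list(contigs = contigs, satellite_defs = satellite_defs,
                 element_defs = element_defs, shared_element = shared_element,
                 truncation_prob = truncation_prob,
                 control_satellite = control_satellite,
                 divergence = divergence, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Default planted-centromere study design
#'
#' Five island contigs (an island of retroelement copies flanked on both
#' sides by satellite arrays) plus twenty decoy contigs that contain
#' satellites and element copies but never a satellite-flanked island.
#' The shared element family (`retroA`) has roughly two thirds of its
#' copies inside islands, the analog of a retroelement family concentrated
#' at centromeres; other families are mostly non-centromeric.  The
#' control satellite (`AATAC`) occurs only on decoys.  Total genome size
#' is about 2.4 Mb.
#'
#' @param seed integer seed forwarded to [genome_spec()].
#' @return a `genome_spec`.
#' @export
default_genome_spec <- function(seed = 1L) {
  sat <- c(AATAT = "AATAT", AAGAG = "AAGAG", AAGAT = "AAGAT",
           AATAG = "AATAG", satXII = "AGTCCTGGAATC", AATAC = "AATAC")
  elem <- c(retroA = 3000L, retroB = 4500L, retroC = 2200L,
            retroD = 1600L, retroE = 1200L)
  sat_block <- function(f, l) list(kind = "satellite", family = f, length = l)
  isl <- function(...) list(kind = "island", elements = c(...), spacer = 250L)
  el <- function(f) list(kind = "element", family = f)
  uq <- function(l) list(kind = "unique", length = l)

  cen <- list(
    list(name = "cenA", blocks = list(sat_block("AAGAG", 14000L),
      isl("retroA", "retroA", "retroB", "retroA"), sat_block("AAGAT", 12000L))),
    list(name = "cenB", blocks = list(sat_block("AAGAT", 12000L),
      isl("retroA", "retroC", "retroA", "retroC"), sat_block("AAGAT", 14000L))),
    list(name = "cenC", blocks = list(sat_block("AATAG", 13000L),
      isl("retroA", "retroD", "retroA", "retroA"), sat_block("AAGAG", 12000L))),
    list(name = "cenD", blocks = list(sat_block("satXII", 14004L),
      isl("retroA", "retroB", "retroA", "retroE"), sat_block("satXII", 12000L))),
    list(name = "cenE", blocks = list(sat_block("AATAT", 14000L),
      isl("retroA", "retroC", "retroE", "retroA"), sat_block("AAGAG", 14000L)))
  )

  # decoy satellite amounts keep each flanking family predominantly
  # island-flanking (roughly 30-40% of its genomic copies at flanks);
  # the control satellite absorbs the remaining satellite mass
  decoys <- list()
  # pure-satellite decoys carrying the control satellite
  decoys[[1]] <- list(name = "decoy01", blocks = list(
    sat_block("AATAC", 40000L), sat_block("AATAT", 20000L), sat_block("AAGAG", 40000L)))
  decoys[[2]] <- list(name = "decoy02", blocks = list(
    sat_block("AAGAT", 35000L), sat_block("AATAC", 35000L), sat_block("AAGAG", 30000L)))
  decoys[[3]] <- list(name = "decoy03", blocks = list(
    sat_block("AATAC", 40000L), sat_block("AATAG", 20000L), sat_block("satXII", 25008L),
    sat_block("AATAC", 15000L)))
  decoys[[4]] <- list(name = "decoy04", blocks = list(
    sat_block("satXII", 20004L), sat_block("AATAC", 45000L), sat_block("AAGAT", 30000L)))
  # unique decoys with scattered element copies (no satellite flanks)
  scatter <- list(
    c("retroB", "retroB", "retroC"), c("retroB", "retroD", "retroD"),
    c("retroC", "retroC", "retroE"), c("retroB", "retroC", "retroA"),
    c("retroD", "retroE", "retroB"), c("retroC", "retroD", "retroA"),
    c("retroE", "retroE", "retroB"), c("retroB", "retroC", "retroD"))
  for (i in seq_along(scatter)) {
    blocks <- list(uq(25000L))
    for (f in scatter[[i]]) blocks <- c(blocks, list(el(f), uq(20000L)))
    decoys[[4 + i]] <- list(name = sprintf("decoy%02d", 4 + i), blocks = blocks)
  }
  # one-sided decoys: satellite on a single side of complex DNA
  onesided <- list(
    c("retroB", "retroA"), c("retroC", "retroB"),
    c("retroD", "retroC"), c("retroA", "retroB"))
  for (i in seq_along(onesided)) {
    blocks <- list(sat_block(c("AAGAG", "AATAC", "AATAC", "AAGAT")[i], 20000L),
                   uq(30000L))
    for (f in onesided[[i]]) blocks <- c(blocks, list(el(f), uq(22000L)))
    decoys[[12 + i]] <- list(name = sprintf("decoy%02d", 12 + i), blocks = blocks)
  }
  # control satellite embedded in complex DNA (never island-adjacent)
  for (i in 1:4) {
    decoys[[16 + i]] <- list(name = sprintf("decoy%02d", 16 + i), blocks = list(
      uq(30000L), sat_block("AATAC", 20000L), uq(25000L),
      el(c("retroB", "retroC", "retroD", "retroE")[i]), uq(20000L)))
  }

  genome_spec(contigs = c(cen, decoys), satellite_defs = sat,
              element_defs = elem, shared_element = "retroA",
              truncation_prob = 0.4, control_satellite = "AATAC",
              divergence = 0.05, seed = seed)
}

#' Build a synthetic genome from a specification
#'
#' Realises the contigs of a [genome_spec()] into sequence, producing the
#' genome, a ground-truth annotation that exactly tiles every contig, and
#' a consensus repeat library.  Element copies are drawn from a per-family
#' consensus with per-copy substitution divergence; a fraction
#' (`truncation_prob`) of copies is 5'-truncated, keeping the 3' end as
#' non-LTR retroelement insertions do.  Island spans are the spans of the
#' island blocks as built.
#'
#' @param spec a `genome_spec`.
#' @return list with `genome` (named character vector of contig
#'   sequences), `truth` (list of `intervals` and `island_spans`
#'   data.frames, 0-based half-open) and `library` (list with `consensus`
#'   and `class`, one entry per family).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    consensus <- vapply(spec$element_defs, function(L) random_dna(L), character(1))
    names(consensus) <- names(spec$element_defs)

    make_copy <- function(family) {
      cons <- consensus[[family]]
      L <- nchar(cons)
      truncated <- runif(1) < spec$truncation_prob
      s <- if (truncated) {
        keep <- floor(L * runif(1, 0.3, 0.9))
        substr(cons, L - keep + 1, L)  # 5' truncation keeps the 3' end
      } else cons
      list(seq = mutate_seq(s, spec$divergence), full_length = !truncated)
    }

    genome <- character(0)
    iv <- list(); spans <- list()
    for (ctg in spec$contigs) {
      parts <- character(0)
      pos <- 0L
      civ <- list()
      cspan <- list()
      for (b in ctg$blocks) {
        if (b$kind == "satellite") {
          seq <- satellite_array(spec$satellite_defs[[b$family]], b$length)
          civ[[length(civ) + 1L]] <- data.frame(
            contig = ctg$name, start = pos, end = pos + b$length,
            class = "satellite", family = b$family, full_length = TRUE,
            stringsAsFactors = FALSE)
          parts <- c(parts, seq); pos <- pos + b$length
        } else if (b$kind == "unique") {
          seq <- random_dna(b$length)
          civ[[length(civ) + 1L]] <- data.frame(
            contig = ctg$name, start = pos, end = pos + b$length,
            class = "unique", family = "unique", full_length = TRUE,
            stringsAsFactors = FALSE)
          parts <- c(parts, seq); pos <- pos + b$length
        } else if (b$kind == "element") {
          cp <- make_copy(b$family)
          L <- nchar(cp$seq)
          civ[[length(civ) + 1L]] <- data.frame(
            contig = ctg$name, start = pos, end = pos + L,
            class = "element", family = b$family, full_length = cp$full_length,
            stringsAsFactors = FALSE)
          parts <- c(parts, cp$seq); pos <- pos + L
        } else { # island
          spacer <- as.integer(b$spacer %||% 200L)
          isl_start <- pos
          isl_parts <- character(0)
          isl_iv <- list()
          ipos <- pos
          for (j in seq_along(b$elements)) {
            if (j > 1 && spacer > 0) {
              sp <- random_dna(spacer)
              isl_iv[[length(isl_iv) + 1L]] <- data.frame(
                contig = ctg$name, start = ipos, end = ipos + spacer,
                class = "unique", family = "unique", full_length = TRUE,
                stringsAsFactors = FALSE)
              isl_parts <- c(isl_parts, sp); ipos <- ipos + spacer
            }
            cp <- make_copy(b$elements[j])
            L <- nchar(cp$seq)
            isl_iv[[length(isl_iv) + 1L]] <- data.frame(
              contig = ctg$name, start = ipos, end = ipos + L,
              class = "element", family = b$elements[j],
              full_length = cp$full_length, stringsAsFactors = FALSE)
            isl_parts <- c(isl_parts, cp$seq); ipos <- ipos + L
          }
          isl_seq <- paste(isl_parts, collapse = "")
          isl_df <- do.call(rbind, isl_iv)
          if (!is.null(b$length)) {
            target <- as.integer(b$length)
            built <- nchar(isl_seq)
            if (built > target) {
              isl_seq <- substr(isl_seq, 1, target)
              isl_df <- isl_df[isl_df$start < isl_start + target, , drop = FALSE]
              trimmed <- isl_df$end > isl_start + target
              isl_df$end <- pmin(isl_df$end, isl_start + target)
              isl_df$full_length[trimmed & isl_df$class == "element"] <- FALSE
            } else if (built < target) {
              pad <- target - built
              isl_seq <- paste0(isl_seq, random_dna(pad))
              isl_df <- rbind(isl_df, data.frame(
                contig = ctg$name, start = isl_start + built,
                end = isl_start + target, class = "unique", family = "unique",
                full_length = TRUE, stringsAsFactors = FALSE))
            }
            ipos <- isl_start + nchar(isl_seq)
          }
          civ <- c(civ, list(isl_df))
          cspan[[length(cspan) + 1L]] <- data.frame(
            contig = ctg$name, start = isl_start, end = ipos,
            stringsAsFactors = FALSE)
          parts <- c(parts, isl_seq); pos <- ipos
        }
      }
      genome[[ctg$name]] <- paste(parts, collapse = "")
      iv[[ctg$name]] <- do.call(rbind, civ)
      if (length(cspan)) spans[[ctg$name]] <- do.call(rbind, cspan)
    }
    intervals <- do.call(rbind, iv); rownames(intervals) <- NULL
    island_spans <- if (length(spans)) do.call(rbind, spans) else
      data.frame(contig = character(0), start = integer(0), end = integer(0))
    rownames(island_spans) <- NULL

    lib_cons <- c(as.list(spec$satellite_defs), as.list(consensus))
    lib_class <- c(setNames(rep("satellite", length(spec$satellite_defs)),
                            names(spec$satellite_defs)),
                   setNames(rep("element", length(consensus)), names(consensus)))
    list(genome = genome,
         truth = list(intervals = intervals, island_spans = island_spans),
         library = list(consensus = unlist(lib_cons), class = lib_class))
  })
}

#' Parameters for ChIP/input read simulation
#'
#' @param read_length read length in bp.
#' @param fragment_length insert size in bp; mates are the two fragment
#'   ends.
#' @param n_replicates number of ChIP/input replicate pairs.
#' @param coverage per-channel fold coverage of the genome.
#' @param enrichment named weights of relative CENP-A occupancy by region
#'   class: `island`, `flank_satellite` (satellite arrays on island
#'   contigs), `background` and `control_satellite`.  Island weight must
#'   exceed background; the control satellite stays at background level.
#' @param error_rate uniform substitution rate applied to reads (0 =
#'   error-free).
#' @param seed integer seed.
#' @export
chip_sim_params <- function(read_length = 150L, fragment_length = 300L,
                            n_replicates = 4L, coverage = 30,
                            enrichment = c(island = 10, flank_satellite = 3,
                                           background = 1,
                                           control_satellite = 1),
                            error_rate = 0, seed = 1L) {
  stopifnot(all(enrichment > 0),
            enrichment[["island"]] > enrichment[["background"]],
            read_length > 0, fragment_length >= read_length, coverage >= 0)
  structure(list(read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 n_replicates = as.integer(n_replicates),
                 coverage = coverage, enrichment = enrichment,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "chip_sim_params")
}

# region-class weight for each truth interval under an enrichment map
interval_weights <- function(truth, spec_control, enrichment) {
  iv <- truth$intervals
  w <- rep(enrichment[["background"]], nrow(iv))
  spans <- truth$island_spans
  island_contigs <- unique(spans$contig)
  if (nrow(spans) > 0) {
    for (i in seq_len(nrow(spans))) {
      inside <- iv$contig == spans$contig[i] & iv$start >= spans$start[i] &
        iv$end <= spans$end[i]
      w[inside] <- enrichment[["island"]]
    }
  }
  flank <- iv$class == "satellite" & iv$contig %in% island_contigs
  w[flank] <- enrichment[["flank_satellite"]]
  if (!is.null(spec_control)) {
    ctrl <- iv$class == "satellite" & iv$family == spec_control
    w[ctrl] <- enrichment[["control_satellite"]]
  }
  w
}

# simulate one channel of paired-end fragments
simulate_channel <- function(genome, truth, params, weights, n_fragments,
                             seed) {
  rl <- params$read_length; fl <- params$fragment_length
  clen <- nchar(genome)
  if (rl > min(clen)) stop("read_length exceeds the shortest contig")
  if (fl > min(clen)) stop("fragment_length exceeds the shortest contig")
  iv <- truth$intervals
  with_seed(seed, {
    if (n_fragments == 0) {
      return(list(contig = character(0), start = integer(0),
                  orient = integer(0), seq1 = character(0),
                  seq2 = character(0)))
    }
    p <- weights * (iv$end - iv$start)
    idx <- sample.int(nrow(iv), n_fragments, replace = TRUE, prob = p)
    off <- floor(runif(n_fragments) * (iv$end[idx] - iv$start[idx]))
    start <- iv$start[idx] + off
    ctg <- iv$contig[idx]
    start <- pmin(start, clen[ctg] - fl)  # keep the fragment on the contig
    start <- pmax(start, 0L)
    orient <- ifelse(runif(n_fragments) < 0.5, 1L, -1L)
    seq1 <- character(n_fragments); seq2 <- character(n_fragments)
    for (cg in unique(ctg)) {
      sel <- which(ctg == cg)
      s <- start[sel]
      seq1[sel] <- substring(genome[[cg]], s + 1, s + rl)
      seq2[sel] <- substring(genome[[cg]], s + fl - rl + 1, s + fl)
    }
    seq2 <- revcomp(seq2)
    if (params$error_rate > 0) {
      seq1 <- vapply(seq1, mutate_seq, character(1), rate = params$error_rate,
                     USE.NAMES = FALSE)
      seq2 <- vapply(seq2, mutate_seq, character(1), rate = params$error_rate,
                     USE.NAMES = FALSE)
    }
    list(contig = ctg, start = as.integer(start), orient = orient,
         seq1 = seq1, seq2 = seq2)
  })
}

new_readset <- function(ch, channel, replicate, params) {
  structure(list(channel = channel, replicate = replicate,
                 read_length = params$read_length,
                 fragment_length = params$fragment_length,
                 contig = ch$contig, start = ch$start, orient = ch$orient,
                 seq1 = ch$seq1, seq2 = ch$seq2,
                 n_fragments = length(ch$start),
                 total_reads = 2L * length(ch$start)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %s replicate %d, %d fragments (%d bp reads, %d bp inserts)\n",
              x$channel, x$replicate, x$n_fragments, x$read_length,
              x$fragment_length))
  invisible(x)
}

#' Simulate paired-end ChIP and input read sets
#'
#' Input fragments are sampled uniformly over the genome; ChIP fragment
#' start probabilities are proportional to the per-base occupancy weight
#' of the region class they fall in (islands strongly enriched, flanking
#' satellites partially, the control satellite and everything else at
#' background).  Mates are the two ends of each fragment; read names are
#' recoverable as `contig:start:mate` via the stored placements, enabling
#' oracle lookups in tests.  Duplicate fragment coordinates are allowed;
#' downstream duplicate masking removes them.
#'
#' @param genome,truth output of [build_genome()].
#' @param params a [chip_sim_params()] object.
#' @param control_satellite family planted as unenriched control (taken
#'   from the genome spec in [run_planted_analysis()]).
#' @param replicates which replicates to simulate (default all).
#' @return list of `ReadSet` objects: for each replicate one ChIP and one
#'   input set.
#' @export
simulate_chip_reads <- function(genome, truth, params,
                                control_satellite = NULL,
                                replicates = seq_len(params$n_replicates)) {
  stopifnot(inherits(params, "chip_sim_params"))
  glen <- sum(nchar(genome))
  n_frag <- as.integer(round(params$coverage * glen / (2 * params$read_length)))
  w_chip <- interval_weights(truth, control_satellite, params$enrichment)
  w_input <- rep(1, nrow(truth$intervals))
  out <- list()
  for (r in replicates) {
    chip <- simulate_channel(genome, truth, params, w_chip, n_frag,
                             seed = params$seed + 1000L * r + 1L)
    out[[paste0("chip_", r)]] <- new_readset(chip, "chip", r, params)
    inp <- simulate_channel(genome, truth, params, w_input, n_frag,
                            seed = params$seed + 1000L * r + 2L)
    out[[paste0("input_", r)]] <- new_readset(inp, "input", r, params)
  }
  out
}

#' Parameters for Hi-C valid-pair simulation
#'
#' @param n_pairs number of valid pairs to draw.
#' @param bin_size bin size (bp) used to derive bin counts per category.
#' @param rate_matrix symmetric named matrix of relative contact weights
#'   between categories; sampling probabilities are proportional to
#'   `rate[a, b] * L_a * L_b`.
#' @param seed integer seed.
#' @export
hic_sim_params <- function(n_pairs = 1e5, bin_size = 10000L,
                           rate_matrix = NULL, seed = 1L) {
  stopifnot(n_pairs >= 0)
  if (!is.null(rate_matrix)) stopifnot(all(rate_matrix >= 0))
  structure(list(n_pairs = as.integer(n_pairs), bin_size = as.integer(bin_size),
                 rate_matrix = rate_matrix, seed = as.integer(seed)),
            class = "hic_sim_params")
}

#' Simulate Hi-C valid pairs over a category map
#'
#' Category-pair frequencies are proportional to the product of category
#' lengths times the relative contact weight, so a uniform rate matrix
#' reproduces the size-product null and an elevated centromere-centromere
#' weight plants excess centromere contacts.  Positions are uniform
#' within each category.
#'
#' @param category_map data.frame with `contig`, `start`, `end`,
#'   `category` (0-based half-open intervals covering the annotated
#'   genome) and optionally `unit`.
#' @param params a [hic_sim_params()] object.
#' @return data.frame in validPairs column order: `readID`, `chrA`,
#'   `posA`, `strandA`, `chrB`, `posB`, `strandB`.
#' @export
simulate_hic_pairs <- function(category_map, params) {
  stopifnot(inherits(params, "hic_sim_params"))
  cats <- sort(unique(category_map$category))
  L <- vapply(cats, function(cc)
    sum(category_map$end[category_map$category == cc] -
        category_map$start[category_map$category == cc]), numeric(1))
  names(L) <- cats
  rate <- params$rate_matrix
  if (is.null(rate)) {
    rate <- matrix(1, length(cats), length(cats), dimnames = list(cats, cats))
  }
  stopifnot(all(cats %in% rownames(rate)), all(cats %in% colnames(rate)))
  with_seed(params$seed, {
    n <- params$n_pairs
    if (n == 0) {
      return(data.frame(readID = character(0), chrA = character(0),
                        posA = integer(0), strandA = character(0),
                        chrB = character(0), posB = integer(0),
                        strandB = character(0), stringsAsFactors = FALSE))
    }
    combos <- expand.grid(a = cats, b = cats, stringsAsFactors = FALSE)
    wt <- mapply(function(a, b) rate[a, b] * L[[a]] * L[[b]], combos$a, combos$b)
    pick <- sample.int(nrow(combos), n, replace = TRUE, prob = wt)
    sample_pos <- function(cat_names) {
      ctg <- character(length(cat_names)); pos <- integer(length(cat_names))
      for (cc in unique(cat_names)) {
        sel <- which(cat_names == cc)
        ivs <- category_map[category_map$category == cc, , drop = FALSE]
        lens <- ivs$end - ivs$start
        i <- sample.int(nrow(ivs), length(sel), replace = TRUE, prob = lens)
        ctg[sel] <- ivs$contig[i]
        pos[sel] <- ivs$start[i] + floor(runif(length(sel)) * lens[i])
      }
      list(contig = ctg, pos = pos)
    }
    a <- sample_pos(combos$a[pick])
    b <- sample_pos(combos$b[pick])
    data.frame(readID = sprintf("pair%07d", seq_len(n)),
               chrA = a$contig, posA = a$pos,
               strandA = sample(c("+", "-"), n, replace = TRUE),
               chrB = b$contig, posB = b$pos,
               strandB = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate chromatin-fiber length measurements
#'
#' Fibre stretching is multiplicative, so measured lengths are the true
#' physical length divided by the stretching factor times unit-mean
#' lognormal noise with coefficient of variation `cv`.
#'
#' @param true_sizes_kb named numeric vector, probe -> true size (kb).
#' @param kb_per_um stretching factor (kb per micrometre), > 0.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param n measurements per probe.
#' @param seed integer seed.
#' @return data.frame with `probe` and `um`.
#' @export
simulate_fiber_measurements <- function(true_sizes_kb, kb_per_um, cv = 0.1,
                                        n = 20L, seed = 1L) {
  stopifnot(kb_per_um > 0, cv >= 0, n >= 1)
  with_seed(seed, {
    out <- lapply(names(true_sizes_kb), function(p) {
      base_um <- true_sizes_kb[[p]] / kb_per_um
      noise <- if (cv == 0) rep(1, n) else {
        sdlog <- sqrt(log(1 + cv^2))
        rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      data.frame(probe = p, um = base_um * noise, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a ChIP-qPCR threshold cycle from a true fold enrichment
#'
#' Inverts the fold-enrichment readout `100 * E^(Ct_input - Ct_ip)`:
#' given the true fold, the IP threshold cycle is
#' `Ct_input - log_E(fold / 100)`, so measuring the simulated value
#' recovers the planted fold exactly.
#'
#' @param true_fold true fold enrichment (> 0), on the percent scale where
#'   100 means parity with input.
#' @param efficiency amplification efficiency per cycle, in (1, 2].
#' @param ct_input input threshold cycle.
#' @return `ct_ip`, the simulated IP threshold cycle.
#' @export
simulate_qpcr <- function(true_fold, efficiency = 2, ct_input = 20) {
  stopifnot(all(true_fold > 0), all(efficiency > 1), all(efficiency <= 2))
  ct_input - log(true_fold / 100) / log(efficiency)
}
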