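# Fiber-FISH calibration and domain sizing, percent-overlap statistics,
# and the ChIP-qPCR / expression formulas.

#' Calibrate chromatin-fiber stretching (kb per micrometre)
#'
#' Each calibration probe of known genomic size yields a per-probe factor
#' `true kb / mean(um)`; the global stretching factor is the unweighted
#' mean of the per-probe factors (probes of equal weight, as when pooling
#' a few 100-kb locations), optionally weighted by the number of fibers.
#' Between-probe equality of the per-fiber implied factors is tested by
#' Welch's one-way test and the p-value reported.
#'
#' @param measurements data.frame with `probe` and `um` (one row per
#'   measured fiber; >= 2 per probe).
#' @param true_kb named numeric vector, probe -> true size in kb.
#' @param weighted weight the global mean by fibers per probe.
#' @return a `Calibration`: list with `kb_per_um`, `per_probe`
#'   (probe, n, mean_um, factor) and `equality_p`.
#' @export
calibrate <- function(measurements, true_kb, weighted = FALSE) {
  probes <- unique(measurements$probe)
  if (length(probes) < 1) stop("need at least one probe")
  if (!all(probes %in% names(true_kb)))
    stop("true_kb missing for some probes")
  per <- do.call(rbind, lapply(probes, function(p) {
    um <- measurements$um[measurements$probe == p]
    if (length(um) < 2) stop("probe ", p, " needs >= 2 measurements")
    data.frame(probe = p, n = length(um), mean_um = mean(um),
               factor = true_kb[[p]] / mean(um), stringsAsFactors = FALSE)
  }))
  kb_per_um <- if (weighted) sum(per$factor * per$n) / sum(per$n)
               else mean(per$factor)
  eq_p <- NA_real_
  if (length(probes) >= 2) {
    f <- true_kb[measurements$probe] / measurements$um
    eq_p <- tryCatch(
      oneway.test(f ~ factor(measurements$probe))$p.value,
      error = function(e) NA_real_)
  }
  structure(list(kb_per_um = kb_per_um, per_probe = per, equality_p = eq_p),
            class = "Calibration")
}

#' Convert micrometres to kilobases under a calibration
#'
#' @param um numeric micrometre lengths.
#' @param cal a `Calibration` or a bare kb-per-um factor.
#' @return lengths in kb.
#' @export
um_to_kb <- function(um, cal) {
  f <- if (inherits(cal, "Calibration")) cal$kb_per_um else cal
  um * f
}

#' Size CENP-A domains on extended chromatin fibers
#'
#' Per centromere, paired per-fiber measurements of the CENP-A
#' immunofluorescence signal and of the island probe (FISH) signal are
#' converted to kb; means and across-fiber SDs are reported together with
#' the percent overlap, defined as mean CENP-A domain length divided by
#' mean probe signal length times 100 (a per-fiber mode averages the
#' per-fiber ratios instead).
#'
#' @param fibers data.frame with `centromere`, `cenpa_um`, `probe_um`
#'   (one row per fiber).
#' @param cal a `Calibration` (or kb-per-um factor).
#' @param per_fiber use the mean of per-fiber ratios for the overlap.
#' @return data.frame of `DomainEstimate`s.
#' @export
size_domains <- function(fibers, cal, per_fiber = FALSE) {
  if (nrow(fibers) == 0) stop("no fiber measurements")
  cens <- unique(fibers$centromere)
  out <- lapply(cens, function(cen) {
    d <- fibers[fibers$centromere == cen, , drop = FALSE]
    ck <- um_to_kb(d$cenpa_um, cal)
    pk <- um_to_kb(d$probe_um, cal)
    pct <- if (per_fiber) mean(ck / pk) * 100 else mean(ck) / mean(pk) * 100
    data.frame(centromere = cen, n_fibers = nrow(d),
               cenpa_kb_mean = mean(ck), cenpa_kb_sd = sd(ck),
               probe_kb_mean = mean(pk), probe_kb_sd = sd(pk),
               percent_overlap = pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare CENP-A domain sizes between two centromeres
#'
#' Welch's unpaired t test on per-fiber kb lengths.
#'
#' @param kb_a,kb_b numeric vectors of per-fiber lengths (kb), each with
#'   at least 2 values.
#' @return list with `p_value`, `estimate` (group means) and `t`.
#' @export
compare_domains <- function(kb_a, kb_b) {
  if (length(kb_a) < 2 || length(kb_b) < 2)
    stop("each group needs at least 2 fibers")
  tt <- t.test(kb_a, kb_b, var.equal = FALSE)
  list(p_value = tt$p.value, estimate = unname(tt$estimate),
       t = unname(tt$statistic))
}

#' ChIP-qPCR fold enrichment
#'
#' Fold enrichment of the immunoprecipitated DNA over bulk input,
#' `100 * E^(Ct_input - Ct_ip)`, where `E` is the primer-set
#' amplification efficiency (2 = perfect doubling).  When a control
#' measurement is supplied (a non-centromeric locus), the fold is
#' normalised by the control's fold.
#'
#' @param ct_input,ct_ip threshold cycles of input and IP reactions.
#' @param efficiency amplification efficiency per cycle, in (1, 2].
#' @param control optional list/data.frame with `ct_input`, `ct_ip` and
#'   optionally `efficiency` for the normalising control locus.
#' @return fold enrichment (normalised if a control is given).
#' @export
qpcr_fold <- function(ct_input, ct_ip, efficiency = 2, control = NULL) {
  stopifnot(all(efficiency > 1), all(efficiency <= 2))
  fold <- 100 * efficiency^(ct_input - ct_ip)
  if (is.null(control)) return(fold)
  eC <- control$efficiency %||% efficiency
  fold / qpcr_fold(control$ct_input, control$ct_ip, eC)
}

#' Relative expression by the 2^-dCt method
#'
#' `2^-(Ct_target - Ct_reference)` per replicate, averaged.
#'
#' @param ct_target,ct_reference paired threshold cycles (vectors over
#'   replicates).
#' @return mean relative expression across replicates.
#' @export
expression_ddct <- function(ct_target, ct_reference) {
  stopifnot(length(ct_target) == length(ct_reference))
  mean(2^(-(ct_target - ct_reference)))
}
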