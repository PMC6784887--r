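## CoMPP (comprehensive microarray polymer profiling) normalization and
## polymer/monomer concordance.

#' Normalize raw CoMPP spot signals
#'
#' Within each data set (one extraction of one sample): replicate signals are
#' averaged per probe, the maximal mean spot signal is set to 100 and all
#' other values adjusted accordingly, and means scaling below the 5-signal
#' floor are set to 0.  Scaled data sets are then averaged across samples per
#' extraction, and the floor is re-applied so no reported value lies in the
#' open interval (0, 5).
#'
#' @param raw data.frame of raw signals (columns probe, substrate,
#'   extraction, sample, replicate, signal), as from \code{\link{readCoMPP}}.
#' @param floor minimum reportable mean spot signal (default 5).
#' @return list with \code{perSample} (probe x extraction x sample scaled
#'   means) and \code{values} (probe x extraction cross-sample averages),
#'   both data.frames with a \code{signal} column in [0, 100].
#' @export
normalizeCoMPP <- function(raw, floor = 5) {
  need <- c("probe", "substrate", "extraction", "sample", "replicate",
            "signal")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("raw CoMPP table missing column(s): ", paste(miss, collapse = ", "))

  key <- interaction(raw$probe, raw$substrate, raw$extraction, raw$sample,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(raw, key), function(d) {
    data.frame(probe = d$probe[1], substrate = d$substrate[1],
               extraction = d$extraction[1], sample = d$sample[1],
               mean_signal = mean(d$signal), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  dsKey <- interaction(agg$extraction, agg$sample, drop = TRUE)
  perSample <- do.call(rbind, lapply(split(agg, dsKey), function(d) {
    mx <- max(d$mean_signal)
    if (mx <= 0) {
      warning("all-zero CoMPP data set (extraction ", d$extraction[1],
              ", sample ", d$sample[1], ")")
      d$signal <- 0
    } else {
      d$signal <- 100 * d$mean_signal / mx
      d$signal[d$signal < floor] <- 0
    }
    d$mean_signal <- NULL
    d
  }))
  rownames(perSample) <- NULL
  perSample <- perSample[order(perSample$extraction, perSample$sample,
                               perSample$probe), , drop = FALSE]

  avgKey <- interaction(perSample$probe, perSample$substrate,
                        perSample$extraction, drop = TRUE)
  values <- do.call(rbind, lapply(split(perSample, avgKey), function(d) {
    data.frame(probe = d$probe[1], substrate = d$substrate[1],
               extraction = d$extraction[1], signal = mean(d$signal),
               stringsAsFactors = FALSE)
  }))
  values$signal[values$signal < floor] <- 0
  values <- values[order(values$extraction, values$probe), , drop = FALSE]
  rownames(values) <- NULL
  list(perSample = perSample, values = values)
}

#' Polymer/monomer concordance ("selfish uptake" screen)
#'
#' Joins normalized polymer signals against the concentrations of their
#' monomeric sugar units.  A polymer whose signal is in the top tertile of
#' the panel while its monomer sits below the median sugar concentration is
#' flagged \code{selfish-candidate}: its degraders are plausibly importing
#' oligosaccharides rather than releasing monomers to the environment.  The
#' flag is advisory; thresholds are configurable.
#'
#' @param panel output of \code{\link{normalizeCoMPP}}.
#' @param sugarPanel data.frame from \code{\link{readSugarPanel}}.
#' @param monomerMap named character: polymer substrate -> monomer sugar.
#' @param signalQuantile polymer-signal quantile for "high" (default 2/3).
#' @param concThreshold monomer concentration below which the monomer counts
#'   as depleted; default the median of the sugar panel.
#' @return data.frame (polymer, polymer_signal, monomer, monomer_conc, flag)
#'   where flag is \code{selfish-candidate}, \code{unmapped} or empty.
#' @export
polymerSugarConcordance <- function(panel, sugarPanel, monomerMap,
                                    signalQuantile = 2 / 3,
                                    concThreshold = NULL) {
  values <- panel$values
  if (nrow(values) == 0 || nrow(sugarPanel) == 0) {
    return(data.frame(polymer = character(0), polymer_signal = numeric(0),
                      monomer = character(0), monomer_conc = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE))
  }
  ## per-substrate signal: maximum over extractions and probes
  sig <- vapply(split(values$signal, values$substrate), max, numeric(1))
  hi <- quantile(sig, signalQuantile, names = FALSE)
  concThreshold <- concThreshold %||% median(sugarPanel$concentration)
  rows <- lapply(names(sig), function(poly) {
    mono <- if (poly %in% names(monomerMap)) monomerMap[[poly]] else NA
    if (is.null(mono) || is.na(mono)) {
      return(data.frame(polymer = poly, polymer_signal = sig[[poly]],
                        monomer = NA_character_, monomer_conc = NA_real_,
                        flag = "unmapped", stringsAsFactors = FALSE))
    }
    conc <- sugarPanel$concentration[sugarPanel$sugar == mono]
    conc <- if (length(conc)) conc[1] else NA_real_
    flag <- if (!is.na(conc) && sig[[poly]] >= hi && conc < concThreshold) {
      "selfish-candidate"
    } else ""
    data.frame(polymer = poly, polymer_signal = sig[[poly]], monomer = mono,
               monomer_conc = conc, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$polymer), , drop = FALSE]
}
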