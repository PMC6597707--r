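#' Default pump-probe delay binning
#'
#' 50 fs bins from -1000 to +1000 fs; delays inside the pulse-overlap
#' exclusion window |t| < 30 fs are flagged (the two 9 fs pulses interfere
#' there) and treated separately by downstream fits.
#'
#' @return list: `breaks_fs`, `overlap_fs`.
#' @export
delay_binning_defaults <- function() {
  list(breaks_fs = seq(-1000, 1000, by = 50), overlap_fs = 30)
}

.event_fields <- function(events) {
  data.frame(
    delay_fs = vapply(events, function(e) e$delay_fs, 0),
    ker_eV = vapply(events, ker, 0)
  )
}

#' KER versus pump-probe delay map
#'
#' 2D histogram of (delay, KER) for one channel's events.
#'
#' @param events list of `cei_event`s (already channel-assigned).
#' @param delay_breaks_fs,ker_breaks_eV bin edges.
#' @return list of class `cei_kermap`: `delay_breaks_fs`, `ker_breaks_eV`,
#'   `counts` (delay bins x KER bins).
#' @export
ker_delay_map <- function(events,
                          delay_breaks_fs = delay_binning_defaults()$breaks_fs,
                          ker_breaks_eV = seq(0, 15, by = 0.25)) {
  nd <- length(delay_breaks_fs) - 1
  nk <- length(ker_breaks_eV) - 1
  counts <- matrix(0L, nd, nk)
  if (length(events)) {
    ef <- .event_fields(events)
    keep <- ef$delay_fs >= delay_breaks_fs[1] &
      ef$delay_fs < delay_breaks_fs[nd + 1] &
      ef$ker_eV >= ker_breaks_eV[1] & ef$ker_eV < ker_breaks_eV[nk + 1]
    i <- findInterval(ef$delay_fs[keep], delay_breaks_fs)
    j <- findInterval(ef$ker_eV[keep], ker_breaks_eV)
    for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  }
  structure(list(delay_breaks_fs = delay_breaks_fs,
                 ker_breaks_eV = ker_breaks_eV, counts = counts),
            class = "cei_kermap")
}

#' Normalized channel yield versus pump-probe delay
#'
#' Per delay bin: the number of the channel's events with KER inside the
#' (half-open) gate, divided by the number of pulse pairs recorded in that
#' bin. Bins with zero pulse pairs are dropped; bins inside the
#' pulse-overlap window are flagged.
#'
#' @param events list of `cei_event`s of one channel.
#' @param ker_gate_eV `c(low, high)` KER gate, `[low, high)` eV.
#' @param pulse_pairs integer vector of pulse-pair counts, one per delay bin.
#' @param delay_breaks_fs delay bin edges (fs).
#' @param overlap_fs pulse-overlap exclusion half-width (fs).
#' @return data.frame of class `cei_delayscan`: `delay_fs` (bin centre),
#'   `n_events`, `pulse_pairs`, `yield`, `overlap` (logical flag).
#' @export
yield_vs_delay <- function(events, ker_gate_eV, pulse_pairs,
                           delay_breaks_fs = delay_binning_defaults()$breaks_fs,
                           overlap_fs = delay_binning_defaults()$overlap_fs) {
  nd <- length(delay_breaks_fs) - 1
  stopifnot(length(pulse_pairs) == nd)
  centres <- (delay_breaks_fs[-1] + delay_breaks_fs[-(nd + 1)]) / 2
  n <- integer(nd)
  if (length(events)) {
    ef <- .event_fields(events)
    gated <- ef$ker_eV >= ker_gate_eV[1] & ef$ker_eV < ker_gate_eV[2] &
      ef$delay_fs >= delay_breaks_fs[1] & ef$delay_fs < delay_breaks_fs[nd + 1]
    i <- findInterval(ef$delay_fs[gated], delay_breaks_fs)
    tab <- tabulate(i, nbins = nd)
    n <- tab
  }
  out <- data.frame(delay_fs = centres, n_events = n,
                    pulse_pairs = pulse_pairs,
                    yield = ifelse(pulse_pairs > 0, n / pulse_pairs, NA_real_),
                    overlap = abs(centres) < overlap_fs)
  out <- out[pulse_pairs > 0, ]
  class(out) <- c("cei_delayscan", "data.frame")
  out
}

#' Ratio of two delay scans with counting uncertainty
#'
#' Per-bin yield ratio a/b over the bins where b has events, with the
#' uncertainty propagated from Poisson counting errors of both channels:
#' sigma = ratio * sqrt(1/Na + 1/Nb).
#'
#' @param a,b `cei_delayscan`s on identical delay binning.
#' @return data.frame: `delay_fs`, `ratio`, `sigma`, `overlap`.
#' @export
channel_ratio <- function(a, b) {
  if (!isTRUE(all.equal(a$delay_fs, b$delay_fs))) {
    stop("delay binnings differ between the two scans")
  }
  keep <- b$n_events > 0 & a$n_events > 0
  r <- (a$yield / b$yield)[keep]
  data.frame(delay_fs = a$delay_fs[keep], ratio = r,
             sigma = r * sqrt(1 / a$n_events[keep] + 1 / b$n_events[keep]),
             overlap = a$overlap[keep])
}

#' Weighted linear slope of a ratio curve versus delay
#'
#' Flatness test for channel ratios: fits ratio ~ delay by weighted least
#' squares (weights 1/sigma^2), excluding pulse-overlap bins, and reports
#' the slope, its standard error and the z-score slope/se. |z| < 2 is
#' consistent with a delay-independent (competing-reaction) branching.
#'
#' @param ratio output of [channel_ratio()].
#' @return list: `slope`, `se`, `z`, `n`.
#' @export
ratio_flatness <- function(ratio) {
  d <- ratio[!ratio$overlap & is.finite(ratio$ratio) & ratio$sigma > 0, ]
  if (nrow(d) < 3) stop("fewer than 3 usable ratio bins")
  fit <- stats::lm(ratio ~ delay_fs, data = d, weights = 1 / d$sigma^2)
  co <- summary(fit)$coefficients
  list(slope = co[2, 1], se = co[2, 2], z = co[2, 1] / co[2, 2], n = nrow(d))
}

#' Fit a saturating-exponential yield curve
#'
#' Least-squares fit of A * (1 - exp(-(t - t0)/tau)) for t > t0 (0 before)
#' to a positive-delay yield curve; the onset t0 absorbs the lag between
#' migration completion and the KER gate being entered as the fragments
#' separate, so tau estimates the migration time constant. Overlap-flagged
#' and negative-delay bins are excluded. This fit is an analysis-side
#' convenience for parameter recovery; it is not itself a physical model of
#' the experiment.
#'
#' @param scan a `cei_delayscan`.
#' @param fit_t0 fit the onset (default) or fix it at 0.
#' @param weights `"poisson"` (default) weights residuals by the inverse
#'   Poisson standard error of each bin's count; `"none"` for ordinary
#'   least squares.
#' @return list: `A`, `tau_fs`, `t0_fs`, `fitted` (data.frame `delay_fs`,
#'   `yield`).
#' @export
fit_saturating_yield <- function(scan, fit_t0 = TRUE,
                                 weights = c("poisson", "none")) {
  weights <- match.arg(weights)
  d <- scan[!scan$overlap & scan$delay_fs > 0 & is.finite(scan$yield), ]
  if (nrow(d) < 5) stop("too few positive-delay bins to fit")
  w <- if (weights == "poisson") {
    1 / (sqrt(pmax(d$n_events, 1)) / d$pulse_pairs)
  } else {
    rep(1, nrow(d))
  }
  model <- function(p) {
    tt <- pmax(d$delay_fs - p["t0"], 0)
    p["A"] * (1 - exp(-tt / p["tau"]))
  }
  start <- c(A = max(d$yield), tau = 300, t0 = if (fit_t0) 50 else 0)
  resid_fn <- function(par) {
    p <- c(A = par[1], tau = par[2],
           t0 = if (fit_t0) par[3] else 0)
    w * (d$yield - model(p))
  }
  par0 <- unname(start[if (fit_t0) 1:3 else 1:2])
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            lower = c(0, 1, if (fit_t0) -200),
                            upper = c(Inf, 1e5, if (fit_t0) 500))
  p <- fit$par
  pars <- c(A = p[1], tau = p[2], t0 = if (fit_t0) p[3] else 0)
  list(A = unname(pars["A"]), tau_fs = unname(pars["tau"]),
       t0_fs = unname(pars["t0"]),
       fitted = data.frame(delay_fs = d$delay_fs,
                           yield = model(c(A = pars[["A"]], tau = pars[["tau"]],
                                           t0 = pars[["t0"]]))))
}
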