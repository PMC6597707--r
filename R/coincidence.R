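#' Per-species time-of-flight acceptance windows
#'
#' Window = TOF at momentum +/- `p_max_au` along the spectrometer axis;
#' every ion with axial momentum inside that range arrives inside the
#' window. Windows of neighbouring masses may overlap -- final channel
#' assignment is decided by momentum conservation, the windows only
#' prefilter candidate hits.
#'
#' @param species character vector of labels.
#' @param config a `cei_spectrometer`.
#' @param p_max_au maximum expected momentum magnitude (a.u.).
#' @return data.frame: `species`, `tof_lo_ns`, `tof_hi_ns`.
#' @export
tof_windows <- function(species, config = spectrometer_config(),
                        p_max_au = 400) {
  lo <- forward_model(cbind(0, 0, rep(p_max_au, length(species))),
                      species, config)$tof_ns
  hi <- forward_model(cbind(0, 0, rep(-p_max_au, length(species))),
                      species, config)$tof_ns
  data.frame(species = species, tof_lo_ns = lo, tof_hi_ns = hi,
             stringsAsFactors = FALSE)
}

#' Photoion-photoion coincidence (PIPICO) map
#'
#' 2D histogram of (first ion TOF, second ion TOF) over all ordered hit
#' pairs within each laser shot; two-ion fragmentation channels appear as
#' islands at the TOF pair of their fragments.
#'
#' @param hits data.frame with columns `shot_id` and `tof_ns`.
#' @param tof_breaks_ns bin edges (ns) applied to both axes.
#' @return list of class `cei_pipico`: `tof_breaks_ns`, `counts` (matrix,
#'   rows = first-ion TOF bin, cols = second-ion TOF bin), `n_pairs`.
#' @export
build_pipico_map <- function(hits, tof_breaks_ns) {
  t1 <- numeric(0); t2 <- numeric(0)
  for (tofs in split(hits$tof_ns, hits$shot_id)) {
    k <- length(tofs)
    if (k < 2) next
    tofs <- sort(tofs)
    pairs <- utils::combn(k, 2)
    t1 <- c(t1, tofs[pairs[1, ]])
    t2 <- c(t2, tofs[pairs[2, ]])
  }
  nb <- length(tof_breaks_ns) - 1
  counts <- matrix(0L, nb, nb)
  keep <- t1 >= tof_breaks_ns[1] & t1 < tof_breaks_ns[nb + 1] &
    t2 >= tof_breaks_ns[1] & t2 < tof_breaks_ns[nb + 1]
  i <- findInterval(t1[keep], tof_breaks_ns, rightmost.closed = FALSE)
  j <- findInterval(t2[keep], tof_breaks_ns, rightmost.closed = FALSE)
  for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  structure(list(tof_breaks_ns = tof_breaks_ns, counts = counts,
                 n_pairs = length(t1)),
            class = "cei_pipico")
}

#' Assign one shot's hits to a fragmentation channel
#'
#' Hits are matched to a channel's species by TOF windows; for every
#' complete, distinct matching the momenta are reconstructed under the
#' species hypotheses, and the matching with the smallest total momentum is
#' kept. Among all channels whose best matching passes the
#' momentum-conservation gate, the one conserving momentum best (smallest
#' |sum p|) is returned -- a wrong-mass hypothesis of a neighbouring
#' channel (e.g. OH+ + C2H5+ read as H2O+ + C2H4+) shifts the axial
#' momentum sum by a few a.u. and can slip inside the gate, but it can
#' never conserve momentum better than the true species hypothesis. The
#' number of additionally matching channels is reported as `n_ambiguous`.
#'
#' @param shot_hits data.frame for one shot: `tof_ns`, `x_mm`, `y_mm`, and
#'   optionally `delay_fs`, `shot_id`.
#' @param channels list of channel definitions ([channel_defs()]).
#' @param config a `cei_spectrometer`.
#' @param p_max_au TOF-window half-width parameter (see [tof_windows()]).
#' @param windows optional precomputed list of [tof_windows()] tables,
#'   one per channel (computed on the fly if `NULL`).
#' @return list: `channel` (name or `NA`), `event` (a `cei_event` or
#'   `NULL`), `p_sum_au`, `n_ambiguous`.
#' @export
assign_channel <- function(shot_hits, channels = channel_defs(),
                           config = spectrometer_config(), p_max_au = 400,
                           windows = NULL) {
  matches <- list()
  for (j in seq_along(channels)) {
    res <- .match_channel(shot_hits, channels[[j]], config, p_max_au,
                          windows[[j]])
    if (!is.null(res)) matches[[length(matches) + 1L]] <- res
  }
  if (length(matches) == 0) {
    return(list(channel = NA_character_, event = NULL,
                p_sum_au = NA_real_, n_ambiguous = 0L))
  }
  best <- matches[[which.min(vapply(matches, function(m) m$p_sum_au, 0))]]
  list(channel = best$channel, event = best$event,
       p_sum_au = best$p_sum_au, n_ambiguous = length(matches) - 1L)
}

.match_channel <- function(shot_hits, ch, config, p_max_au, win = NULL) {
  k <- length(ch$species)
  n <- nrow(shot_hits)
  if (n < k) return(NULL)
  if (is.null(win)) win <- tof_windows(ch$species, config, p_max_au)
  cand <- lapply(seq_len(k), function(j) {
    which(shot_hits$tof_ns >= win$tof_lo_ns[j] &
            shot_hits$tof_ns <= win$tof_hi_ns[j])
  })
  if (any(vapply(cand, length, 0L) == 0)) return(NULL)
  combos <- .distinct_assignments(cand)
  if (length(combos) == 0) return(NULL)
  best <- NULL
  for (idx in combos) {
    p <- reconstruct_momentum(shot_hits$tof_ns[idx], shot_hits$x_mm[idx],
                              shot_hits$y_mm[idx], ch$species, config)
    psum <- sqrt(sum(colSums(p)^2))
    if (is.null(best) || psum < best$p_sum_au) {
      best <- list(p = p, p_sum_au = psum, idx = idx)
    }
  }
  if (best$p_sum_au >= ch$momentum_sum_threshold) return(NULL)
  delay <- if ("delay_fs" %in% names(shot_hits)) shot_hits$delay_fs[1] else NA_real_
  shot <- if ("shot_id" %in% names(shot_hits)) shot_hits$shot_id[1] else NA_integer_
  ev <- coincidence_event(ch$species, best$p, delay_fs = delay,
                          shot_id = shot, source = "pump_probe")
  attr(ev, "channel") <- ch$name
  list(channel = ch$name, event = ev, p_sum_au = best$p_sum_au)
}

# all ways to pick one distinct hit index per species slot
.distinct_assignments <- function(cand) {
  out <- list()
  rec <- function(j, used, acc) {
    if (j > length(cand)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (h in cand[[j]]) {
      if (!(h %in% used)) rec(j + 1L, c(used, h), c(acc, h))
    }
  }
  rec(1L, integer(0), integer(0))
  out
}

#' Assign every shot in a hit table to a channel
#'
#' @param hits data.frame: `shot_id`, `tof_ns`, `x_mm`, `y_mm`, and
#'   optionally `delay_fs`.
#' @inheritParams assign_channel
#' @return list: `events` (list of channel-tagged `cei_event`s), `channel`
#'   (character vector per shot, `NA` = unassigned), `shot_id`,
#'   `n_ambiguous` (total), `counts` (table of assigned channels).
#' @export
assign_channels <- function(hits, channels = channel_defs(),
                            config = spectrometer_config(), p_max_au = 400) {
  windows <- lapply(channels, function(ch)
    tof_windows(ch$species, config, p_max_au))
  by_shot <- split(hits, hits$shot_id)
  res <- lapply(by_shot, assign_channel, channels = channels,
                config = config, p_max_au = p_max_au, windows = windows)
  chan <- vapply(res, function(r) r$channel, "")
  events <- lapply(res[!is.na(chan)], function(r) r$event)
  list(events = unname(events), channel = unname(chan),
       shot_id = as.integer(names(by_shot)),
       n_ambiguous = sum(vapply(res, function(r) r$n_ambiguous, 0L)),
       counts = table(factor(chan[!is.na(chan)], levels = names(channels))))
}
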