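#' Cumulative trajectory-count yield curve
#'
#' Number of trajectories of one channel whose channel-defining event time
#' (migration completing the species, or the C-O break for NHM) lies at or
#' below each grid time.
#'
#' @param records migration-record table (see [migration_records()]).
#' @param channel channel label.
#' @param times_fs time grid (fs).
#' @return data.frame of class `cei_yield`: `t_fs`, `value`; attribute
#'   `scale_factor` (1 for raw counts).
#' @export
cumulative_yield <- function(records, channel, times_fs) {
  tt <- records$t_event_fs[records$channel == channel &
                             !is.na(records$t_event_fs)]
  out <- data.frame(t_fs = times_fs,
                    value = vapply(times_fs, function(t) sum(tt <= t), 0))
  attr(out, "scale_factor") <- 1
  class(out) <- c("cei_yield", "data.frame")
  out
}

#' Scale a theory yield curve onto an experimental one
#'
#' Multiplies the theory curve by experiment(t_ref)/theory(t_ref), with both
#' curves evaluated at the grid point nearest `t_ref_fs` -- by 1 ps the
#' cumulative migration yields have essentially saturated, so this anchors
#' the trajectory counts to the measured normalized yield scale.
#'
#' @param theory,experiment `cei_yield`-style data.frames (`t_fs`, `value`).
#' @param t_ref_fs reference time (fs).
#' @return the scaled theory curve; attribute `scale_factor` records the
#'   applied factor.
#' @export
scale_to_experiment <- function(theory, experiment, t_ref_fs = 1000) {
  th_ref <- theory$value[which.min(abs(theory$t_fs - t_ref_fs))]
  ex_ref <- experiment$value[which.min(abs(experiment$t_fs - t_ref_fs))]
  if (th_ref == 0) stop("theory curve is zero at the reference time")
  sf <- ex_ref / th_ref
  out <- theory
  out$value <- theory$value * sf
  attr(out, "scale_factor") <- sf
  out
}

.pearson_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(present = FALSE, n = n, r = NA_real_, slope = NA_real_,
                intercept = NA_real_, slope_se = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  list(present = TRUE, n = n, r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = summary(fit)$coefficients[2, 2])
}

#' Correlation analyses of migration and bond-break times
#'
#' For trajectories with the relevant times present: Pearson r and
#' least-squares slope/intercept of (a) the second versus first migration
#' time and (b) the C-O bond-break versus second migration time, plus the
#' origin split (alpha vs beta counts) of the second migrating hydrogen.
#' A correlation with fewer than 3 complete pairs, or zero variance, is
#' reported absent.
#'
#' @param records migration-record table.
#' @return list: `t2_vs_t1`, `tco_vs_t2` (each: `present`, `n`, `r`,
#'   `slope`, `intercept`, `slope_se`), `origin_counts` (named integer:
#'   alpha/beta of the second migration).
#' @export
migration_correlations <- function(records) {
  list(
    t2_vs_t1 = .pearson_fit(records$t_mig1_fs, records$t_mig2_fs),
    tco_vs_t2 = .pearson_fit(records$t_mig2_fs, records$t_co_break_fs),
    origin_counts = c(
      alpha = sum(records$origin2 == "alpha", na.rm = TRUE),
      beta = sum(records$origin2 == "beta", na.rm = TRUE))
  )
}
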