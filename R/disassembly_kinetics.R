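#' pH schedules for disassembly simulations
#'
#' A schedule is piecewise-constant pH versus time: `breaks` (ascending,
#' starting at 0, minutes) and `ph` values, one per segment.
#' `ph_constant()` and `ph_step()` are exact; `ph_exp()` discretizes an
#' exponential approach (as when a photoacid lowers the pH) onto a fine
#' piecewise-constant grid.
#'
#' @param ph,ph_before,ph_after,ph_start,ph_end pH values in (0, 14).
#' @param switch_time time of the pH change, minutes.
#' @param tau approach time constant, minutes.
#' @param dt discretization step for the exponential approach, minutes.
#' @return object of class `"ph_schedule"`.
#' @export
ph_constant <- function(ph) new_ph_schedule(0, ph)

#' @rdname ph_constant
#' @export
ph_step <- function(ph_before, ph_after, switch_time) {
  if (switch_time <= 0) return(ph_constant(ph_after))
  new_ph_schedule(c(0, switch_time), c(ph_before, ph_after))
}

#' @rdname ph_constant
#' @export
ph_exp <- function(ph_start, ph_end, switch_time = 0, tau = 1, dt = 0.05) {
  t_tail <- switch_time + seq(0, 8 * tau, by = dt)
  ph_tail <- ph_end + (ph_start - ph_end) * exp(-(t_tail - switch_time) / tau)
  if (switch_time > 0) {
    new_ph_schedule(c(0, t_tail), c(ph_start, ph_tail))
  } else new_ph_schedule(t_tail, ph_tail)
}

new_ph_schedule <- function(breaks, ph) {
  if (any(ph <= 0 | ph >= 14)) stopf("pH values must lie in (0, 14)")
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 0)
    stopf("breaks must be strictly ascending and start at 0")
  structure(list(breaks = breaks, ph = ph), class = "ph_schedule")
}

ph_at <- function(schedule, t) {
  schedule$ph[findInterval(t, schedule$breaks)]
}

#' Kinetic parameters for fibre disassembly
#'
#' @param k_end per-end subunit removal rate (subunits/min per active end)
#'   at full pH activation. A scalar applies to both ends of every
#'   fragment; a length-2 vector gives (left, right) end rates, realising a
#'   one-end-immobilized fibre.
#' @param k_frag fragmentation rate per subunit junction (/min) at full
#'   activation.
#' @param ph_coupling list describing the pH coupling law: `n_sites`,
#'   `pKa_eff`, and `law` (`"linkage"`, the disassembled-state Boltzmann
#'   weight, or `"exponential"`). `NULL` disables coupling (multiplier 1).
#' @param rise_nm axial rise per subunit in nm (default 0.84, i.e. 8.4
#'   Angstrom).
#' @return object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k_end, k_frag = 0, ph_coupling = NULL,
                           rise_nm = 0.84) {
  k_end <- rep_len(as.numeric(k_end), 2)
  if (any(k_end < 0) || k_frag < 0) stopf("rates must be non-negative")
  if (rise_nm <= 0) stopf("rise_nm must be positive")
  structure(list(k_end = k_end, k_frag = k_frag, ph_coupling = ph_coupling,
                 rise_nm = rise_nm),
            class = "kinetic_params")
}

#' pH coupling multiplier for disassembly rates
#'
#' Default ("linkage") law: the disassembled-state Boltzmann weight of the
#' equilibrium protonation-linkage model,
#' `10^x / (1 + 10^x)` with `x = n_sites * (pKa_eff - ph)` -- saturating at
#' 1 far below the transition and ~0 above it, so fibres that are stable
#' 0.3 pH units above the effective midpoint disassemble rapidly just
#' below it. The `"exponential"` law returns the bare weight `10^x`
#' (unbounded).
#'
#' @param ph solution pH (vectorized).
#' @param law list with `n_sites`, `pKa_eff`, and optionally `law`;
#'   `NULL` gives multiplier 1.
#' @return non-negative multiplier.
#' @export
coupling <- function(ph, law) {
  if (is.null(law)) return(rep(1, length(ph)))
  x <- law$n_sites * (law$pKa_eff - ph)
  if (identical(law$law %||% "linkage", "exponential")) return(10^x)
  w <- 10^x
  ifelse(is.infinite(w), 1, w / (1 + w))
}

#' Simulate stochastic disassembly of a single fibre
#'
#' Exact event-driven (Gillespie) simulation of a fibre of initial length
#' `L0` nm under a pH schedule. Each active fragment end removes subunits
#' as a Poisson process at `k_end * coupling(pH(t))`; each subunit junction
#' fragments at `k_frag * coupling(pH(t))`; after fragmentation both new
#' ends are active. Within a schedule segment rates are constant and
#' waiting times are sampled exactly (memoryless restart at segment
#' boundaries). The trace is recorded on a separate regular grid.
#'
#' Recorded series: total remaining length, length of the longest remaining
#' fragment (the single-fibre length convention used in time-lapse
#' analyses), and the recession of the two original fibre ends. When the
#' fibre has fully disassembled both recessions are capped at half the
#' initial length (each end is deemed to have receded to the centre).
#'
#' @param L0 initial fibre length, nm.
#' @param params a [kinetic_params].
#' @param schedule a `ph_schedule` (default: constant pH far below the
#'   transition, full activation).
#' @param t_end simulated time, minutes.
#' @param dt_record recording interval, minutes.
#' @param seed integer seed; traces are bit-identical per seed.
#' @return object of class `"fibre_trace"`: data.frame with columns
#'   `time_min`, `length_total_nm`, `length_longest_nm`, `end1_nm`,
#'   `end2_nm`, plus attributes `L0`, `rise_nm`, `seed`.
#' @export
simulate_fibre <- function(L0, params, schedule = ph_constant(3),
                           t_end = 10, dt_record = 0.5, seed = 1) {
  if (L0 <= 0) stopf("L0 must be positive")
  if (t_end <= 0) stopf("t_end must be positive")
  rise <- params$rise_nm
  n0 <- max(1L, as.integer(round(L0 / rise)))
  rec_times <- seq(0, t_end, by = dt_record)
  nrec <- length(rec_times)
  out <- matrix(NA_real_, nrec, 4)

  with_seed(seed, {
    frags <- matrix(c(0L, n0), 1, 2)   # [lo, hi) in subunit units
    t <- 0
    seg <- findInterval(t, schedule$breaks)
    ri <- 1L
    record <- function(row) {
      lens <- (frags[, 2] - frags[, 1])
      tot <- sum(lens) * rise
      lng <- if (nrow(frags)) max(lens) * rise else 0
      half <- n0 * rise / 2      # each end is measured toward the centre
      if (nrow(frags)) {
        e1 <- min(half, min(frags[, 1]) * rise)
        e2 <- min(half, (n0 - max(frags[, 2])) * rise)
      } else e1 <- e2 <- half
      out[row, ] <<- c(tot, lng, e1, e2)
    }
    repeat {
      lens <- frags[, 2] - frags[, 1]
      n_junc <- sum(pmax(0L, lens - 1L))
      base_rate <- nrow(frags) * sum(params$k_end) + params$k_frag * n_junc
      cpl <- coupling(ph_at(schedule, t), params$ph_coupling)
      rate <- base_rate * cpl
      seg_end <- if (seg < length(schedule$breaks))
        schedule$breaks[seg + 1] else Inf
      dt <- if (rate > 0) stats::rexp(1, rate) else Inf
      t_next <- t + dt
      # flush the recording grid up to the next event / boundary / end
      t_stop <- min(t_next, seg_end, t_end)
      while (ri <= nrec && rec_times[ri] <= t_stop + 1e-12) {
        record(ri); ri <- ri + 1L
      }
      if (t_stop >= t_end) break
      if (t_next > seg_end) {          # pH segment boundary: resample
        t <- seg_end; seg <- seg + 1L
        next
      }
      t <- t_next
      if (nrow(frags) == 0L) next
      # choose event category
      u <- stats::runif(1) * base_rate
      kL <- params$k_end[1]; kR <- params$k_end[2]
      if (u < nrow(frags) * kL) {                       # left-end removal
        fi <- 1L + floor(u / max(kL, 1e-300))
        fi <- min(nrow(frags), as.integer(fi))
        frags[fi, 1] <- frags[fi, 1] + 1L
      } else if (u < nrow(frags) * (kL + kR)) {         # right-end removal
        u2 <- u - nrow(frags) * kL
        fi <- 1L + floor(u2 / max(kR, 1e-300))
        fi <- min(nrow(frags), as.integer(fi))
        frags[fi, 2] <- frags[fi, 2] - 1L
      } else {                                          # fragmentation
        juncs <- pmax(0L, frags[, 2] - frags[, 1] - 1L)
        pick <- sample.int(sum(juncs), 1)
        fi <- which(cumsum(juncs) >= pick)[1]
        prev <- if (fi > 1) sum(juncs[seq_len(fi - 1)]) else 0L
        cut <- frags[fi, 1] + (pick - prev)             # break after this index
        frags <- rbind(frags, c(cut, frags[fi, 2]))
        frags[fi, 2] <- cut
      }
      frags <- frags[frags[, 2] - frags[, 1] > 0L, , drop = FALSE]
    }
    while (ri <= nrec) { record(ri); ri <- ri + 1L }
  })

  tr <- data.frame(time_min = rec_times,
                   length_total_nm = out[, 1],
                   length_longest_nm = out[, 2],
                   end1_nm = out[, 3], end2_nm = out[, 4])
  attr(tr, "L0") <- L0
  attr(tr, "rise_nm") <- rise
  attr(tr, "seed") <- seed
  class(tr) <- c("fibre_trace", "data.frame")
  tr
}

# OLS slope with standard error; returns se = 0 for a perfect fit.
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stopf("degenerate time window (no spread in time)")
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  res <- y - (a + b * x)
  sigma2 <- if (n > 2) sum(res^2) / (n - 2) else 0
  list(slope = b, se = sqrt(sigma2 / sxx))
}

#' Estimate a disassembly rate from a fibre trace
#'
#' Ordinary least-squares slope of the longest-fragment length versus time
#' over a window, sign-flipped so a shrinking fibre reports a positive rate
#' (nm/min), with the residual-based standard error.
#'
#' @param trace a `fibre_trace`.
#' @param window length-2 time interval (minutes); default: whole trace.
#' @return list with `rate` (nm/min), `se`, and `n` points used.
#' @export
estimate_rate <- function(trace, window = range(trace$time_min)) {
  sel <- trace$time_min >= window[1] & trace$time_min <= window[2]
  if (sum(sel) < 3) stopf("need >= 3 recorded points in the window")
  fit <- ols_slope(trace$time_min[sel], trace$length_longest_nm[sel])
  list(rate = -fit$slope, se = fit$se, n = sum(sel))
}

#' Per-end recession rates
#'
#' Recession rate of each original fibre end (nm/min), by OLS on the
#' recorded end-recession series: the analysis convention assigns the fibre
#' centre (half the initial length) as the far limit of each end. A fibre
#' that fully disassembles inside the window has no defined per-end rates
#' and is returned flagged with `vanished = TRUE`.
#'
#' @param trace a `fibre_trace`.
#' @param window length-2 time interval (minutes).
#' @return list with `end1`, `end2` (rates, nm/min), `se1`, `se2`, and
#'   `vanished`.
#' @export
per_end_recession <- function(trace, window = range(trace$time_min)) {
  sel <- trace$time_min >= window[1] & trace$time_min <= window[2]
  if (sum(sel) < 3) stopf("need >= 3 recorded points in the window")
  if (any(trace$length_total_nm[sel] == 0))
    return(list(end1 = NA_real_, end2 = NA_real_, se1 = NA_real_,
                se2 = NA_real_, vanished = TRUE))
  f1 <- ols_slope(trace$time_min[sel], trace$end1_nm[sel])
  f2 <- ols_slope(trace$time_min[sel], trace$end2_nm[sel])
  list(end1 = f1$slope, end2 = f2$slope, se1 = f1$se, se2 = f2$se,
       vanished = FALSE)
}

#' Cross-sectional ensemble summary at a time point
#'
#' Mean and standard deviation of the longest-fragment length across traces
#' at the recorded time nearest `t`. Fully disassembled fibres (length 0)
#' are excluded by default, mirroring the declining object counts of
#' ensemble imaging analyses; set `include_vanished = TRUE` to count them
#' as zeros.
#'
#' @param traces list of `fibre_trace` objects.
#' @param t time, minutes.
#' @param include_vanished count vanished fibres as length 0.
#' @return list with `mean`, `sd`, `n`, and `t_used`.
#' @export
ensemble_summary <- function(traces, t, include_vanished = FALSE) {
  if (!length(traces)) stopf("need >= 1 trace")
  vals <- vapply(traces, function(tr) {
    i <- which.min(abs(tr$time_min - t))
    tr$length_longest_nm[i]
  }, numeric(1))
  t_used <- traces[[1]]$time_min[which.min(abs(traces[[1]]$time_min - t))]
  if (!include_vanished) vals <- vals[vals > 0]
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) stats::sd(vals) else if (length(vals)) 0 else NA_real_,
       n = length(vals), t_used = t_used)
}
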