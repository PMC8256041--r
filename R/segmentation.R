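#' Detection parameters for trace segmentation and step finding
#'
#' @param smooth_window Running-median window in samples (odd; default 9 for
#'   SM traces; SMSC traces, which relax more slowly, get 21 unless
#'   overridden).
#' @param baseline_tol nm. A post-step level within this of 0 nm (the trap
#'   center) is the ruptured baseline.
#' @param min_step Minimum step magnitude in nm for a conformational
#'   transition (default 3).
#' @param level_window Samples used for pre/post step level medians
#'   (default 50).
#' @param ramp_slope_frac Fraction of the peak loading slope below which the
#'   ramp is considered ended (used only as a fallback; default 0.1).
#' @return List of class `detect_params`.
#' @export
detect_params <- function(smooth_window = 9, baseline_tol = 3, min_step = 3,
                          level_window = 50, ramp_slope_frac = 0.1) {
  stopifnot(smooth_window >= 1, baseline_tol > 0, min_step > 0)
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  structure(list(smooth_window = smooth_window, baseline_tol = baseline_tol,
                 min_step = min_step, level_window = level_window,
                 ramp_slope_frac = ramp_slope_frac), class = "detect_params")
}

default_params_for <- function(trace, params) {
  if (!is.null(params)) return(params)
  if ((attr(trace, "assay") %||% "SM") == "SMSC") detect_params(smooth_window = 21)
  else detect_params()
}

smooth_sep <- function(y, k) {
  if (length(y) < 2 * k) abort("Trace shorter than twice the smoothing window")
  if (k <= 1) y else as.numeric(stats::runmed(y, k, endrule = "median"))
}

# index (in the raw series) of the first post-step sample for each detected
# downward step of at least min_step in the smoothed series
find_down_steps <- function(y_s, y_raw, min_step, h) {
  n <- length(y_s)
  post <- y_s[pmin(n, seq_len(n) + h)]
  pre <- y_s[pmax(1, seq_len(n) - h)]
  d <- post - pre
  cand <- which(d < -min_step)
  if (length(cand) == 0) return(integer())
  # cluster consecutive candidates, refine each to the steepest raw drop
  brk <- c(0, which(diff(cand) > h), length(cand))
  steps <- integer()
  for (b in seq_len(length(brk) - 1)) {
    cl <- cand[(brk[b] + 1):brk[b + 1]]
    lo <- max(1, min(cl) - h)
    hi <- min(n - 1, max(cl) + h)
    dd <- y_raw[(lo + 1):(hi + 1)] - y_raw[lo:hi]
    steps <- c(steps, lo + which.min(dd))   # first sample of post level
  }
  steps
}

level_before <- function(y, i, w) median(y[max(1, i - w):(i - 1)])
level_after <- function(y, i, w) median(y[i:min(length(y), i + w - 1)])

#' Segment a trace into loading, dwell and rupture phases
#'
#' The loading ramp ends (`t_clamp`) at the first sample where the smoothed
#' separation reaches the clamp level (the pre-rupture maximum of the
#' smoothed trace) within `baseline_tol`. Rupture is the first downward step
#' whose post-step median level lies within `baseline_tol` of 0 nm — the
#' bead snapping back to the trap center. A trace that ends mid-dwell is
#' censored.
#'
#' @param trace A `trap_trace`.
#' @param params [detect_params()] (default chosen by assay).
#' @return List of class `phase_segmentation`: `t_start`, `t_clamp`,
#'   `rupture_time` (NA if censored), `censored`, `baseline`, and the sample
#'   indices `clamp_idx`, `rupture_idx`.
#' @export
segment_trace <- function(trace, params = NULL) {
  params <- default_params_for(trace, params)
  y <- trace$separation_nm
  t <- trace$time_s
  k <- params$smooth_window
  ys <- smooth_sep(y, k)
  h <- max(3L, (k - 1L) %/% 2L)

  steps <- find_down_steps(ys, y, params$min_step, h)
  rupture_idx <- NA_integer_
  steps <- steps[steps > max(5L, h)]  # a pre-step level needs real samples
  for (i in steps) {
    pre_ok <- level_before(y, i, params$level_window) >
      params$baseline_tol + params$min_step
    if (pre_ok && level_after(y, i, params$level_window) <= params$baseline_tol) {
      rupture_idx <- i
      break
    }
  }
  censored <- is.na(rupture_idx)
  last_bonded <- if (censored) length(y) else rupture_idx - 1L

  clamp_level <- max(ys[seq_len(last_bonded)])
  if (clamp_level <= params$baseline_tol) {
    abort("No loading ramp found: trace never leaves the trap-center baseline")
  }
  # rough plateau onset: first sample within the noise floor of the
  # pre-rupture maximum; refined below by intersecting the fitted loading
  # ramp with the measured plateau level (unbiased under bead noise)
  sigma_hat <- stats::mad(diff(y)) / sqrt(2)
  tol <- max(3 * sigma_hat, 1e-9)
  cross <- which(ys[seq_len(last_bonded)] >= clamp_level - tol)[1]
  clamp_idx <- cross
  dwell_steps <- steps[steps > cross & steps <= last_bonded]
  n_w <- max(params$level_window, round(0.2 / max(median(diff(t)), 1e-9)))
  lvl_end <- min(last_bonded, cross + n_w,
                 if (length(dwell_steps) > 0) max(dwell_steps[1] - h, cross + 1)
                 else last_bonded)
  ramp_pts <- which(ys[seq_len(cross)] >= 0.2 * clamp_level &
                      ys[seq_len(cross)] <= 0.8 * clamp_level)
  if (length(ramp_pts) >= 2) {
    cf <- stats::coef(stats::lm(y[ramp_pts] ~ t[ramp_pts]))
    if (is.finite(cf[2]) && cf[2] > 0) {
      # intersect the ramp line with the plateau level; iterate so ramp
      # samples below the onset stop deflating the plateau median
      lo_i <- cross
      for (pass in 1:3) {
        plateau <- median(y[lo_i:lvl_end])
        t_hat <- (plateau - cf[1]) / cf[2]
        if (!is.finite(t_hat) || t_hat < t[1] || t_hat > t[lvl_end]) break
        lo_i <- min(lvl_end, which.min(abs(t - t_hat)) + 2L)
      }
      if (is.finite(t_hat) && t_hat >= t[1] && t_hat <= t[min(lvl_end, last_bonded)]) {
        clamp_idx <- which.min(abs(t - t_hat))
      }
    }
  }

  res <- list(t_start = t[1], t_clamp = t[clamp_idx],
              rupture_time = if (censored) NA_real_ else t[rupture_idx],
              censored = censored, baseline = 0,
              clamp_idx = clamp_idx, rupture_idx = rupture_idx)
  class(res) <- "phase_segmentation"
  res
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> clamp at %.4g s, %s\n", x$t_clamp,
              if (x$censored) "censored (no rupture)"
              else sprintf("rupture at %.4g s", x$rupture_time)))
  invisible(x)
}

#' Detect conformational-transition steps during the bond dwell
#'
#' Transitions are downward separation steps during the dwell whose magnitude
#' (difference of pre/post running medians) is at least `min_step` and whose
#' post-step level stays above the ruptured baseline — smaller displacements
#' of the bead toward the trap center, as opposed to the full snap-back of
#' rupture.
#'
#' @param trace A `trap_trace`.
#' @param segmentation From [segment_trace()].
#' @param params [detect_params()].
#' @return Tibble: `time` (s), `distance` (nm), `post_dwell` (s, time to the
#'   next transition or rupture).
#' @export
detect_transitions <- function(trace, segmentation, params = NULL) {
  params <- default_params_for(trace, params)
  y <- trace$separation_nm
  t <- trace$time_s
  k <- params$smooth_window
  h <- max(3L, (k - 1L) %/% 2L)
  lo <- segmentation$clamp_idx
  hi <- if (segmentation$censored) length(y) else segmentation$rupture_idx - 1L
  empty <- tibble::tibble(time = numeric(), distance = numeric(), post_dwell = numeric())
  if (hi - lo < 2 * k) return(empty)
  yd <- y[lo:hi]
  ysd <- smooth_sep(yd, k)
  steps <- find_down_steps(ysd, yd, params$min_step, h)
  # candidates within the smoothing support of either segment edge are the
  # loading kink or the rupture's own partial drop, not resolvable transitions
  steps <- steps[steps > max(5L, h) & steps <= length(yd) - max(5L, h)]
  if (length(steps) == 0) return(empty)
  ev <- purrr::map_dfr(steps, function(i) {
    pre <- level_before(yd, i, params$level_window)
    post <- level_after(yd, i, params$level_window)
    tibble::tibble(idx = lo + i - 1L, time = t[lo + i - 1L],
                   distance = pre - post, post_level = post)
  }) |>
    dplyr::filter(.data$distance >= params$min_step,
                  .data$post_level > params$baseline_tol)
  if (nrow(ev) == 0) return(empty)
  # merge detections closer than one level window (noise can split one step
  # into adjacent candidate clusters); keep the largest step of each group
  gap <- params$level_window * median(diff(t))
  ev <- ev |>
    dplyr::arrange(.data$time) |>
    dplyr::mutate(group = cumsum(c(1, diff(.data$time) > gap))) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  end_time <- if (segmentation$censored) t[length(t)] else segmentation$rupture_time
  ev |>
    dplyr::mutate(post_dwell = c(.data$time[-1], end_time) - .data$time) |>
    dplyr::select("time", "distance", "post_dwell")
}

#' Extract a bond event from a segmented trace
#'
#' The clamp force is the mean recorded force over the dwell; the lifetime
#' runs from the end of loading to rupture (total dwell, including any
#' post-transition dwell, which is recorded separately per transition).
#'
#' @param trace A `trap_trace`.
#' @param segmentation From [segment_trace()].
#' @param transitions From [detect_transitions()] (optional; computed if
#'   missing).
#' @param params [detect_params()].
#' @return One-row tibble of class `bond_event`: `label`, `clamp_force_pN`,
#'   `lifetime_s`, `n_transitions`, `censored`, plus a `transitions`
#'   list-column.
#' @export
extract_bond_event <- function(trace, segmentation = NULL, transitions = NULL,
                               params = NULL) {
  if (is.null(segmentation)) segmentation <- segment_trace(trace, params)
  if (is.null(transitions)) transitions <- detect_transitions(trace, segmentation, params)
  lo <- segmentation$clamp_idx
  hi <- if (segmentation$censored) length(trace$time_s) else segmentation$rupture_idx - 1L
  clamp_force <- mean(trace$force_pN[lo:hi])
  lifetime <- if (segmentation$censored) {
    trace$time_s[length(trace$time_s)] - segmentation$t_clamp
  } else {
    segmentation$rupture_time - segmentation$t_clamp
  }
  out <- tibble::tibble(label = attr(trace, "label") %||% "",
                        clamp_force_pN = clamp_force,
                        lifetime_s = lifetime,
                        n_transitions = nrow(transitions),
                        censored = segmentation$censored,
                        transitions = list(transitions))
  class(out) <- c("bond_event", class(out))
  out
}

#' Analyze a batch of traces into a bond-event table
#'
#' @param traces List of `trap_trace` objects.
#' @param params [detect_params()].
#' @return Tibble with one row per usable trace (events from traces that fail
#'   segmentation are dropped with a message).
#' @export
analyze_traces <- function(traces, params = NULL) {
  purrr::imap_dfr(traces, function(tr, i) {
    ev <- tryCatch(extract_bond_event(tr, params = params), error = function(e) {
      inform(sprintf("Trace %s rejected: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(ev) && ev$label == "") ev$label <- as.character(i)
    ev
  })
}
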