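#' Force-binned lifetime curve
#'
#' Bins uncensored bond events by clamp force and reports the mean lifetime,
#' its standard error (sample SD / sqrt(n)) and the event count per bin.
#' Empty bins are kept with `n = 0` and `NA` means so that two curves built
#' on shared edges stay aligned.
#'
#' @param events Bond-event tibble (`clamp_force_pN`, `lifetime_s`,
#'   optionally `censored`).
#' @param breaks Bin edges in pN (default 2.5-pN bins from 5 to 30).
#' @param include_censored If TRUE, censored lifetimes are included as
#'   observed values (default FALSE: censored events are excluded from
#'   means).
#' @return Tibble of class `lifetime_curve`: `bin_lo`, `bin_hi`, `force_mid`,
#'   `mean_s`, `sem_s`, `n`.
#' @export
lifetime_curve <- function(events, breaks = seq(5, 30, by = 2.5),
                           include_censored = FALSE) {
  ev <- events
  if (!"censored" %in% names(ev)) ev$censored <- FALSE
  if (!include_censored) ev <- dplyr::filter(ev, !.data$censored)
  if (nrow(ev) == 0) abort("All events are censored: no lifetimes to bin")
  bins <- tibble::tibble(bin = seq_len(length(breaks) - 1),
                         bin_lo = breaks[-length(breaks)],
                         bin_hi = breaks[-1])
  ev$bin <- findInterval(ev$clamp_force_pN, breaks,
                         rightmost.closed = TRUE, all.inside = FALSE)
  ev <- dplyr::filter(ev, .data$bin >= 1, .data$bin <= nrow(bins))
  out <- ev |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_s = mean(.data$lifetime_s),
                     sem_s = if (dplyr::n() > 1)
                       sd(.data$lifetime_s) / sqrt(dplyr::n()) else NA_real_,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(bins, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  force_mid = (.data$bin_lo + .data$bin_hi) / 2) |>
    dplyr::arrange(.data$bin) |>
    dplyr::select("bin_lo", "bin_hi", "force_mid", "mean_s", "sem_s", "n")
  structure(out, class = c("lifetime_curve", class(tibble::tibble())),
            breaks = breaks)
}

#' Sensitivity index: specific vs nonspecific lifetime ratio per force bin
#'
#' The ratio of the mean bond lifetime for the specific ligand to that for
#' the nonspecific ligand, computed per shared force bin, with a standard
#' error from first-order error propagation:
#' `SE = ratio * sqrt((sem_s/mean_s)^2 + (sem_n/mean_n)^2)`.
#' Bins empty on either side (or with a zero nonspecific mean) are omitted.
#'
#' @param curve_specific,curve_nonspecific `lifetime_curve` objects built on
#'   the same bin edges.
#' @param warn_zero Warn when a bin is dropped for a zero nonspecific mean.
#' @return Tibble of class `sensitivity_index`: `bin_lo`, `bin_hi`,
#'   `force_mid`, `ratio`, `se`, `n_specific`, `n_nonspecific`.
#' @export
sensitivity_index <- function(curve_specific, curve_nonspecific,
                              warn_zero = TRUE) {
  if (!isTRUE(all.equal(attr(curve_specific, "breaks"),
                        attr(curve_nonspecific, "breaks")))) {
    abort("Sensitivity index requires curves on shared bin edges")
  }
  j <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(curve_specific),
                  mean_sp = "mean_s", sem_sp = "sem_s", n_sp = "n"),
    dplyr::rename(tibble::as_tibble(curve_nonspecific),
                  mean_ns = "mean_s", sem_ns = "sem_s", n_ns = "n"),
    by = c("bin_lo", "bin_hi", "force_mid"))
  zero <- j$n_sp > 0 & j$n_ns > 0 & j$mean_ns == 0
  if (any(zero) && warn_zero) {
    warn(sprintf("%d bin(s) dropped: nonspecific mean lifetime is 0", sum(zero)))
  }
  out <- j |>
    dplyr::filter(.data$n_sp > 0, .data$n_ns > 0, .data$mean_ns > 0) |>
    dplyr::mutate(ratio = .data$mean_sp / .data$mean_ns,
                  se = .data$ratio * sqrt(
                    dplyr::coalesce(.data$sem_sp / .data$mean_sp, 0)^2 +
                      dplyr::coalesce(.data$sem_ns / .data$mean_ns, 0)^2)) |>
    dplyr::select("bin_lo", "bin_hi", "force_mid", "ratio", "se",
                  n_specific = "n_sp", n_nonspecific = "n_ns")
  structure(out, class = c("sensitivity_index", class(tibble::tibble())))
}
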