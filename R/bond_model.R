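#' Dual-pathway bond dissociation rate and lifetime
#'
#' The force-dependent off-rate is the sum of a catch pathway, suppressed by
#' force, and a slip pathway, accelerated by force:
#' `k(F) = k_c * exp(-F * x_c / kBT) + k_s * exp(F * x_s / kBT)`, with the
#' mean bond lifetime `tau(F) = 1 / k(F)`. With `k_c = 0` this reduces to a
#' single-pathway Bell slip bond.
#'
#' @param force Force(s) in pN.
#' @param k_c,x_c Catch-pathway zero-force rate (1/s) and distance (nm).
#' @param k_s,x_s Slip-pathway zero-force rate (1/s) and distance (nm).
#' @param kBT Thermal energy in pN nm (default 4.114, T = 298 K).
#' @return Numeric vector of rates (1/s) or lifetimes (s).
#' @export
dual_pathway_rate <- function(force, k_c, x_c, k_s, x_s, kBT = 4.114) {
  k_c * exp(-force * x_c / kBT) + k_s * exp(force * x_s / kBT)
}

#' @rdname dual_pathway_rate
#' @export
dual_pathway_lifetime <- function(force, k_c, x_c, k_s, x_s, kBT = 4.114) {
  1 / dual_pathway_rate(force, k_c, x_c, k_s, x_s, kBT)
}

#' Closed-form peak force of the dual-pathway lifetime curve
#'
#' `tau(F)` has an interior maximum at
#' `F* = kBT * log(k_c * x_c / (k_s * x_s)) / (x_c + x_s)` whenever all four
#' parameters are positive and `k_c * x_c > k_s * x_s`; otherwise `NA`.
#'
#' @inheritParams dual_pathway_rate
#' @return Peak force in pN, or `NA_real_` when no interior peak exists.
#' @export
dual_pathway_peak_force <- function(k_c, x_c, k_s, x_s, kBT = 4.114) {
  if (k_c <= 0 || k_s <= 0 || x_c <= 0 || x_s <= 0) return(NA_real_)
  r <- k_c * x_c / (k_s * x_s)
  if (r <= 1) return(NA_real_)
  kBT * log(r) / (x_c + x_s)
}

# negative log-likelihood of exponential lifetimes with force-dependent rate;
# censored observations contribute the survival term only
nll_dual <- function(theta, force, lifetime, censored, kBT, slip_only = FALSE) {
  if (slip_only) {
    k <- exp(theta[1]) * exp(force * exp(theta[2]) / kBT)
  } else {
    k <- exp(theta[1]) * exp(-force * exp(theta[2]) / kBT) +
      exp(theta[3]) * exp(force * exp(theta[4]) / kBT)
  }
  ll <- ifelse(censored, -k * lifetime, log(k) - k * lifetime)
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

fit_slip_only <- function(force, lifetime, censored, kBT) {
  # moment start: log(mean lifetime) regressed on force gives x_s/kBT
  ok <- !censored
  fit0 <- tryCatch({
    agg <- tapply(lifetime[ok], round(force[ok]), mean)
    f <- as.numeric(names(agg))
    cf <- stats::coef(stats::lm(log(pmax(agg, 1e-6)) ~ f))
    c(-cf[1], log(max(-cf[2] * kBT, 1e-3)))  # log k_s, log x_s
  }, error = function(e) c(0, log(0.5)))
  starts <- list(fit0, c(0, log(0.5)), c(log(2), log(0.3)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, nll_dual, force = force, lifetime = lifetime,
                        censored = censored, kBT = kBT, slip_only = TRUE,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  best
}

#' Fit the dual-pathway bond model to bond events
#'
#' Maximum-likelihood fit of exponentially distributed lifetimes with rate
#' `k(F) = k_c exp(-F x_c / kBT) + k_s exp(F x_s / kBT)` to per-event
#' (force, lifetime) pairs. Censored events contribute survival terms.
#'
#' The bond is classified as a catch bond when (i) the fitted lifetime curve
#' has an interior maximum within the sampled force range, (ii) the peak
#' lifetime exceeds the lifetime at the lowest sampled force by at least
#' `min_peak_ratio`, and (iii) a likelihood-ratio test against the nested
#' slip-only model (`k_c = 0`, 2 fewer parameters) is significant at `alpha`.
#' Otherwise it is a slip bond. If the full fit fails to converge the
#' slip-only fit is returned with `converged = FALSE`.
#'
#' @param events Bond-event tibble with columns `clamp_force_pN`,
#'   `lifetime_s` and optionally `censored` (censored events are used via
#'   their survival contribution; set `use_censored = FALSE` to drop them).
#' @param kBT Thermal energy, pN nm.
#' @param alpha Likelihood-ratio test level for the catch pathway.
#' @param min_peak_ratio Required `tau_peak / tau(F_min)` for a catch call.
#' @param use_censored Include censored events via survival terms (default
#'   TRUE; they are never treated as observed lifetimes).
#' @return Object of class `dual_pathway_fit` with elements `k_c`, `x_c`,
#'   `k_s`, `x_s`, `kBT`, `classification`, `peak_force`, `logLik`,
#'   `logLik_slip`, `lrt_stat`, `lrt_p`, `n`, `converged`, `force_range`.
#' @export
fit_bond_model <- function(events, kBT = 4.114, alpha = 0.05,
                           min_peak_ratio = 1.5, use_censored = TRUE) {
  ev <- events
  if (!"censored" %in% names(ev)) ev$censored <- FALSE
  if (!use_censored) ev <- ev[!ev$censored, , drop = FALSE]
  if (sum(!ev$censored) < 3) abort("Need at least 3 uncensored events to fit")
  force <- ev$clamp_force_pN
  lt <- ev$lifetime_s
  cens <- ev$censored
  if (length(unique(round(force[!cens] / 2.5))) < 3) {
    abort("Events must span at least 3 distinct force bins")
  }

  slip <- fit_slip_only(force, lt, cens, kBT)
  if (is.null(slip)) abort("Slip-only fit failed")
  ks0 <- exp(slip$par[1]); xs0 <- exp(slip$par[2])

  frange <- range(force)
  # profile initialisation: for fixed barrier distances the log-likelihood is
  # concave in (k_c, k_s), so a coarse grid over (x_c, x_s) with an inner 2-D
  # optimisation finds the right basin before the full 4-D refinement
  nll_rates <- function(logk, xc, xs) {
    nll_dual(c(logk[1], log(xc), logk[2], log(xs)), force, lt, cens, kBT)
  }
  grid <- expand.grid(xc = c(0.3, 0.6, 1, 1.5, 2.2, 3.2),
                      xs = c(0.1, 0.25, 0.5, 0.8, 1.3, 2))
  grid_best <- NULL
  for (g in seq_len(nrow(grid))) {
    o2 <- tryCatch(
      optim(c(slip$par[1], slip$par[1]), nll_rates,
            xc = grid$xc[g], xs = grid$xs[g], method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(o2) && (is.null(grid_best) || o2$value < grid_best$value)) {
      grid_best <- list(value = o2$value,
                        par = c(o2$par[1], log(grid$xc[g]),
                                o2$par[2], log(grid$xs[g])))
    }
  }
  starts <- purrr::compact(list(
    grid_best$par,
    c(log(1e-4), log(1.0), slip$par[1], slip$par[2])
  ))
  best <- NULL
  for (s in starts) {
    o <- tryCatch({
      o1 <- optim(s, nll_dual, force = force, lifetime = lt, censored = cens,
                  kBT = kBT, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
      optim(o1$par, nll_dual, force = force, lifetime = lt, censored = cens,
            kBT = kBT, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }

  converged <- !is.null(best) && best$value <= slip$value + 1e-6
  if (!converged) {
    # slip-only fallback
    fit <- structure(list(k_c = 0, x_c = 0, k_s = ks0, x_s = xs0, kBT = kBT,
                          classification = "slip", peak_force = NA_real_,
                          logLik = -slip$value, logLik_slip = -slip$value,
                          lrt_stat = 0, lrt_p = 1, n = nrow(ev),
                          converged = FALSE, force_range = frange),
                     class = "dual_pathway_fit")
    return(fit)
  }

  p <- exp(best$par)
  lrt <- max(0, 2 * (slip$value - best$value))
  lrt_p <- pchisq(lrt, df = 2, lower.tail = FALSE)
  pk <- dual_pathway_peak_force(p[1], p[2], p[3], p[4], kBT)
  is_interior <- is.finite(pk) && pk > frange[1] && pk < frange[2]
  peak_ratio <- if (is_interior) {
    dual_pathway_lifetime(pk, p[1], p[2], p[3], p[4], kBT) /
      dual_pathway_lifetime(frange[1], p[1], p[2], p[3], p[4], kBT)
  } else NA_real_
  is_catch <- is_interior && !is.na(peak_ratio) && peak_ratio >= min_peak_ratio &&
    lrt_p < alpha

  structure(list(k_c = p[1], x_c = p[2], k_s = p[3], x_s = p[4], kBT = kBT,
                 classification = if (is_catch) "catch" else "slip",
                 peak_force = if (is_catch) pk else if (is_interior) pk else NA_real_,
                 logLik = -best$value, logLik_slip = -slip$value,
                 lrt_stat = lrt, lrt_p = lrt_p, n = nrow(ev),
                 converged = TRUE, force_range = frange),
            class = "dual_pathway_fit")
}

#' @export
print.dual_pathway_fit <- function(x, ...) {
  cat(sprintf("<dual_pathway_fit> %s bond (n = %d)\n", x$classification, x$n))
  cat(sprintf("  k_c = %.4g 1/s, x_c = %.4g nm, k_s = %.4g 1/s, x_s = %.4g nm\n",
              x$k_c, x$x_c, x$k_s, x$x_s))
  if (is.finite(x$peak_force %||% NA)) {
    cat(sprintf("  peak force %.2f pN, peak lifetime %.3g s\n", x$peak_force,
                dual_pathway_lifetime(x$peak_force, x$k_c, x$x_c, x$k_s, x$x_s, x$kBT)))
  }
  cat(sprintf("  LRT vs slip-only: stat %.3g, p = %.3g\n", x$lrt_stat, x$lrt_p))
  invisible(x)
}

#' Tidy a dual-pathway fit into a parameter table
#'
#' @param x A `dual_pathway_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.dual_pathway_fit <- function(x, ...) {
  tibble::tibble(term = c("k_c", "x_c", "k_s", "x_s"),
                 estimate = c(x$k_c, x$x_c, x$k_s, x$x_s),
                 unit = c("1/s", "nm", "1/s", "nm"))
}

#' One-row summary of a dual-pathway fit
#'
#' @param x A `dual_pathway_fit`.
#' @param ... Unused.
#' @return One-row tibble: `classification`, `peak_force_pN`,
#'   `peak_lifetime_s`, `logLik`, `lrt_stat`, `lrt_p`, `n`, `converged`.
#' @export
glance.dual_pathway_fit <- function(x, ...) {
  pk <- x$peak_force %||% NA_real_
  tibble::tibble(classification = x$classification,
                 peak_force_pN = pk,
                 peak_lifetime_s = if (is.finite(pk))
                   dual_pathway_lifetime(pk, x$k_c, x$x_c, x$k_s, x$x_s, x$kBT)
                 else NA_real_,
                 logLik = x$logLik, lrt_stat = x$lrt_stat, lrt_p = x$lrt_p,
                 n = x$n, converged = x$converged)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
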