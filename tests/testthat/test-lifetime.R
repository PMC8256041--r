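events_tbl <- function(force, lifetime, censored = FALSE) {
  tibble::tibble(label = as.character(seq_along(force)),
                 clamp_force_pN = force, lifetime_s = lifetime,
                 n_transitions = 0L,
                 censored = rep_len(censored, length(force)))
}

test_that("lifetime bins report hand-computed mean and SEM", {
  ev <- events_tbl(rep(10, 3), c(1, 2, 3))
  lc <- lifetime_curve(ev, breaks = c(5, 10, 15))
  row <- dplyr::filter(tibble::as_tibble(lc), n == 3)
  expect_equal(row$mean_s, 2)
  expect_equal(row$sem_s, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(round(row$sem_s, 4), 0.5774)
  empty <- dplyr::filter(tibble::as_tibble(lc), n == 0)
  expect_true(all(is.na(empty$mean_s)))
})

test_that("censored events are excluded from bin means by default", {
  ev <- events_tbl(rep(10, 4), c(1, 2, 3, 50), censored = c(FALSE, FALSE, FALSE, TRUE))
  lc <- lifetime_curve(ev, breaks = c(5, 15))
  expect_equal(lc$mean_s[1], 2)
  expect_equal(lc$n[1], 3)
  expect_error(lifetime_curve(events_tbl(10, 5, censored = TRUE)), "censored")
})

test_that("simulated Bell slip kinetics match the closed-form lifetime", {
  # k0 = 2 1/s, x = 0.5 nm, kBT = 4.114: tau(10 pN) = 1/(2 e^{5/4.114}) = 0.1483 s
  p <- trace_sim_params(k_c = 0, k_s = 2, x_s = 0.5, kBT = 4.114)
  ev <- simulate_bond_events(10, 1000, p, seed = 99)
  tau <- 1 / (2 * exp(10 * 0.5 / 4.114))
  expect_equal(tau, 0.1483, tolerance = 1e-3)
  lc <- lifetime_curve(ev, breaks = c(8.75, 11.25))
  expect_lt(abs(lc$mean_s[1] - tau), 3 * lc$sem_s[1])
})

test_that("bin means of a simulated slip experiment track 1/k(F) within 3 SEM", {
  p <- trace_sim_params(k_c = 0, k_s = 2, x_s = 0.5)
  forces <- seq(5, 20, by = 2.5)
  ev <- simulate_bond_events(forces, 70, p, seed = 5)
  lc <- lifetime_curve(ev, breaks = seq(3.75, 21.25, by = 2.5))
  lc <- dplyr::filter(tibble::as_tibble(lc), n > 0)
  expected <- 1 / (2 * exp(lc$force_mid * 0.5 / 4.114))
  expect_true(all(abs(lc$mean_s - expected) < 3 * lc$sem_s))
})

test_that("lifetime estimator is nearly unbiased at n = 500 per bin", {
  p <- trace_sim_params(k_c = 0, k_s = 2, x_s = 0.5)
  ev <- simulate_bond_events(10, 500, p, seed = 123)
  tau <- 1 / dual_pathway_rate(10, 0, 0, 2, 0.5)
  expect_lt(abs(mean(ev$lifetime_s) - tau) / tau, 0.06)  # 3 sigma ~ 3/sqrt(500)
})

test_that("peak force matches the closed form to machine precision", {
  p <- demo_params("chimera")
  pk <- dual_pathway_peak_force(p$k_c, p$x_c, p$k_s, p$x_s, p$kBT)
  expect_equal(pk, p$kBT * log(p$k_c * p$x_c / (p$k_s * p$x_s)) / (p$x_c + p$x_s),
               tolerance = 1e-12)
  expect_equal(pk, 15, tolerance = 1e-9)
  expect_equal(dual_pathway_lifetime(pk, p$k_c, p$x_c, p$k_s, p$x_s, p$kBT), 5,
               tolerance = 1e-9)
  expect_true(is.na(dual_pathway_peak_force(0, 0, 2, 0.5)))
})

test_that("the fit recovers dual-pathway parameters and classifies a catch bond", {
  p <- demo_params("chimera")
  forces <- seq(5, 25, by = 2.5)
  # amplitude parameters trade off against their distances on any single
  # draw, so parameter accuracy is judged on the median over replicates while
  # classification and peak location must hold in every one; the zero-force
  # slip amplitude k_s is extrapolated far outside the sampled force range
  # (Cramer-Rao sigma(log k_s) = 0.29 for this design), so it is held to 1.5x
  # its information-limited median while the identifiable quantities get 15%
  errs <- sapply(1:10, function(s) {
    ev <- simulate_bond_events(forces, 200, p, seed = s)
    fit <- fit_bond_model(ev)
    expect_equal(fit$classification, "catch")
    expect_lt(abs(fit$peak_force - 15), 2.5)
    ff <- seq(5, 25, 0.5)
    curve_err <- max(abs(
      dual_pathway_lifetime(ff, fit$k_c, fit$x_c, fit$k_s, fit$x_s, fit$kBT) /
        dual_pathway_lifetime(ff, p$k_c, p$x_c, p$k_s, p$x_s, p$kBT) - 1))
    c(kc = abs(fit$k_c - p$k_c) / p$k_c, xc = abs(fit$x_c - p$x_c) / p$x_c,
      ks = abs(fit$k_s - p$k_s) / p$k_s, xs = abs(fit$x_s - p$x_s) / p$x_s,
      curve = curve_err)
  })
  med <- apply(errs, 1, median)
  expect_lt(med["kc"], 0.15)
  expect_lt(med["xc"], 0.15)
  expect_lt(med["xs"], 0.15)
  expect_lt(med["ks"], 1.5 * 0.675 * 0.29)
  # the fitted lifetime curve itself is accurate over the sampled forces
  expect_lt(med["curve"], 0.15)
})

test_that("slip-only data are classified slip and the fit recovers Bell parameters", {
  p <- demo_params("wt")
  forces <- seq(5, 25, by = 2.5)
  ev <- simulate_bond_events(forces, 200, p, seed = 8)
  fit <- fit_bond_model(ev)
  expect_equal(fit$classification, "slip")
  expect_lt(abs(fit$k_s - 2) / 2, 0.15)
  expect_lt(abs(fit$x_s - 0.5) / 0.5, 0.15)
})

test_that("tidy and glance summarise a fit", {
  p <- demo_params("chimera")
  ev <- simulate_bond_events(seq(5, 25, 2.5), 60, p, seed = 21)
  fit <- fit_bond_model(ev)
  td <- tidy(fit)
  expect_equal(td$term, c("k_c", "x_c", "k_s", "x_s"))
  expect_true(all(td$estimate >= 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$classification %in% c("catch", "slip"))
  expect_true(gl$lrt_p >= 0 && gl$lrt_p <= 1)
})

test_that("identical curves give a sensitivity index of exactly 1", {
  ev <- events_tbl(rep(c(7, 12, 17), each = 5),
                   rep(c(1, 0.8, 0.5), each = 5) * rep(c(1, 1.2, 0.9, 1.1, 0.8), 3))
  lc <- lifetime_curve(ev, breaks = seq(5, 20, 2.5))
  si <- sensitivity_index(lc, lc)
  expect_true(all(si$ratio == 1))
})

test_that("hand-arithmetic sensitivity bins are exact", {
  sp <- events_tbl(rep(10, 4), rep(5, 4))
  ns <- events_tbl(rep(10, 4), rep(0.5, 4))
  csp <- lifetime_curve(sp, breaks = c(7.5, 12.5))
  cns <- lifetime_curve(ns, breaks = c(7.5, 12.5))
  si <- sensitivity_index(csp, cns)
  expect_equal(si$ratio, 10)
  expect_equal(si$se, 0)   # zero spread on both sides
})

test_that("the index peaks near the catch peak for catch vs slip data", {
  forces <- seq(5, 25, by = 2.5)
  sp <- simulate_bond_events(forces, 150, demo_params("chimera"), seed = 31)
  ns <- simulate_bond_events(forces, 150, demo_params("wt"), seed = 32)
  breaks <- seq(3.75, 26.25, by = 2.5)
  si <- sensitivity_index(lifetime_curve(sp, breaks), lifetime_curve(ns, breaks))
  peak_bin <- si$force_mid[which.max(si$ratio)]
  expect_gte(peak_bin, 12.5)
  expect_lte(peak_bin, 20)
  # exact per-bin arithmetic against the two curves
  cs <- dplyr::filter(tibble::as_tibble(lifetime_curve(sp, breaks)), n > 0)
  cn <- dplyr::filter(tibble::as_tibble(lifetime_curve(ns, breaks)), n > 0)
  j <- dplyr::inner_join(cs, cn, by = "force_mid")
  expect_equal(si$ratio, j$mean_s.x / j$mean_s.y)
})

test_that("mismatched bin edges are refused", {
  ev <- events_tbl(rep(10, 3), c(1, 2, 3))
  c1 <- lifetime_curve(ev, breaks = c(5, 15))
  c2 <- lifetime_curve(ev, breaks = c(5, 10, 15))
  expect_error(sensitivity_index(c1, c2), "shared bin edges")
})
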