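test_that("hydrogen-bond detection applies the strict distance cutoff", {
  topo <- make_topology(2, chain_id = c("A", "B"), residue_number = c(1, 2),
                        element = c("H", "O"),
                        is_donor_hydrogen = c(TRUE, FALSE),
                        is_acceptor = c(FALSE, TRUE))
  just_under <- rbind(c(0, 0, 0), c(2.39, 0, 0))
  just_over <- rbind(c(0, 0, 0), c(2.41, 0, 0))
  expect_equal(nrow(detect_hbond_contacts(just_under, topo, 1, 2)), 1)
  expect_equal(nrow(suppressMessages(detect_hbond_contacts(just_over, topo, 1, 2))), 0)
})

test_that("nonpolar detection gates on charge and aggregates per residue pair", {
  topo <- make_topology(3, chain_id = c("A", "B", "B"),
                        residue_number = c(1, 2, 2),
                        element = c("C", "C", "N"),
                        partial_charge = c(-0.18, -0.12, 0.35))
  frame <- rbind(c(0, 0, 0), c(2.9, 0, 0), c(2.5, 0, 0))
  got <- detect_nonpolar_contacts(frame, topo, 1, c(2, 3))
  expect_equal(nrow(got), 1)     # one residue pair, charge-gated atom excluded
  expect_equal(got$kind, "NP")

  # the |q| = 0.35 atom alone cannot form the contact
  topo2 <- topo
  topo2$partial_charge[2] <- 0.5
  expect_equal(nrow(detect_nonpolar_contacts(frame, topo2, 1, c(2, 3))), 0)
})

test_that("detection equals the all-pairs brute-force oracle on random fixtures", {
  params <- contact_params()
  for (seed in 1:100) {
    fx <- random_fixture(n = sample(20:100, 1), seed = seed)
    hb <- suppressMessages(
      detect_hbond_contacts(fx$frame, fx$topology, fx$set_a, fx$set_b, params))
    expect_equal(sort(hb$key),
                 oracle_hbond_keys(fx$frame, fx$topology, fx$set_a, fx$set_b,
                                   params$hbond_cutoff),
                 info = paste("HB seed", seed))
    np <- suppressWarnings(
      detect_nonpolar_contacts(fx$frame, fx$topology, fx$set_a, fx$set_b, params))
    expect_equal(sort(np$key),
                 oracle_np_keys(fx$frame, fx$topology, fx$set_a, fx$set_b,
                                params$nonpolar_cutoff, params$charge_threshold),
                 info = paste("NP seed", seed))
  }
})

test_that("count-form windows tile the interval with half-width overlap", {
  w <- make_windows(100, 300, count = 10)
  expect_equal(nrow(w), 10)
  width <- 2 * 200 / 11
  expect_equal(w$end - w$start, rep(width, 10))
  expect_equal(w$start[1], 100)
  expect_equal(w$end[10], 300, tolerance = 1e-9)
  expect_equal(w$start[2], 100 + width / 2)             # prints as 118.2
  expect_equal(round(w$end[1], 1), 136.4)
  expect_equal(round(w$start[2], 1), 118.2)
  # adjacent windows overlap by exactly width/2
  expect_equal(w$end[-10] - w$start[-1], rep(width / 2, 9))
})

test_that("width-form windows follow the step rule and clamp the last end", {
  w1 <- make_windows(0, 10, width = 10)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 10))

  w2 <- make_windows(0, 30, width = 10, overlap = 0.5)
  expect_equal(w2$start, c(0, 5, 10, 15, 20))
  expect_equal(w2$end, c(10, 15, 20, 25, 30))

  expect_warning(w3 <- make_windows(0, 5, width = 10), "single window")
  expect_equal(c(w3$start, w3$end), c(0, 5))
})

planted_two_atom_traj <- function(p, n_frames, seed = 1) {
  topo <- make_topology(4, chain_id = c("A", "A", "B", "B"),
                        residue_number = c(1, 1, 2, 2),
                        element = c("H", "C", "O", "C"),
                        is_donor_hydrogen = c(TRUE, FALSE, FALSE, FALSE),
                        is_acceptor = c(FALSE, FALSE, TRUE, FALSE))
  template <- rbind(c(0, 0, 0), c(0, 5, 0), c(3, 0, 0), c(3, 5, 0))
  simulate_trajectory(topo, template,
                      list(planted_contact("HB", 1, 3, occupancy = p)),
                      n_frames = n_frames, seed = seed)
}

test_that("occupancy is exact for always-present and never-present contacts", {
  traj1 <- planted_two_atom_traj(1, 200)
  w <- make_windows(0, max(traj1$times), count = 4)
  occ1 <- contact_occupancy(traj1, c(1, 2), c(3, 4), windows = w, kinds = "HB")
  expect_equal(occ1$occupancy, rep(1, 4))

  traj0 <- planted_two_atom_traj(0, 200)
  occ0 <- contact_occupancy(traj0, c(1, 2), c(3, 4), windows = w, kinds = "HB")
  expect_equal(nrow(occ0), 0)
})

test_that("planted Bernoulli occupancy is recovered within the binomial bound", {
  p <- 0.85
  traj <- planted_two_atom_traj(p, 2000, seed = 11)
  w <- make_windows(0, max(traj$times), count = 1)
  n_in <- sum(traj$times >= w$start & traj$times <= w$end)
  occ <- contact_occupancy(traj, c(1, 2), c(3, 4), windows = w, kinds = "HB")
  expect_lt(abs(occ$occupancy - p), 3 * sqrt(p * (1 - p) / n_in))
})

test_that("frames outside all windows are ignored", {
  traj <- planted_two_atom_traj(1, 300)
  w <- make_windows(3, max(traj$times), count = 2)   # excludes t < 3 ns
  occ <- contact_occupancy(traj, c(1, 2), c(3, 4), windows = w, kinds = "HB")
  expect_equal(occ$occupancy, rep(1, 2))
  expect_error(
    contact_occupancy(traj, c(1, 2), c(3, 4),
                      windows = tibble::tibble(window = 1, start = 100, end = 120),
                      kinds = "HB"),
    "zero frames")
})

test_that("high-occupancy counting is strict and splits by kind", {
  w <- tibble::tibble(window = 1:2, start = c(0, 1), end = c(2, 3))
  occ <- structure(
    tibble::tibble(kind = rep("HB", 4), key = rep(c("HB:1-2", "HB:3-4"), 2),
                   res_a = "A1", res_b = "B1",
                   window = rep(1:2, each = 2),
                   occupancy = c(0.95, 0.79, 0.80, 0.95)),
    class = c("occupancy_table", "tbl_df", "tbl", "data.frame"), windows = w)
  s <- count_high_occupancy(occ, contact_params(), interface = "test")
  hb <- dplyr::filter(s$per_window, kind == "HB")
  # window 1: only 0.95 counts; window 2: occupancy exactly 0.80 is excluded
  expect_equal(hb$count, c(1L, 1L))
  expect_equal(dplyr::filter(s$stats, kind == "HB")$mean_count, 1)
})

test_that("a contact present in every window gives SD exactly zero", {
  traj <- planted_two_atom_traj(1, 500)
  w <- make_windows(0, max(traj$times), count = 10)
  occ <- contact_occupancy(traj, c(1, 2), c(3, 4), windows = w, kinds = "HB")
  s <- count_high_occupancy(occ, contact_params(), interface = "always")
  hb <- dplyr::filter(s$stats, kind == "HB")
  expect_equal(dplyr::filter(s$per_window, kind == "HB")$count, rep(1L, 10))
  expect_identical(hb$sd_count, 0)
  expect_equal(hb$mean_count, 1)
})

test_that("raising the occupancy threshold never increases any window count", {
  traj <- planted_two_atom_traj(0.6, 1000, seed = 3)
  w <- make_windows(0, max(traj$times), count = 5)
  occ <- contact_occupancy(traj, c(1, 2), c(3, 4), windows = w, kinds = "HB")
  thresholds <- c(0.2, 0.4, 0.6, 0.8, 0.9)
  counts <- sapply(thresholds, function(th) {
    s <- count_high_occupancy(occ, contact_params(occupancy_threshold = th))
    dplyr::filter(s$per_window, kind == "HB")$count
  })
  for (i in seq_len(nrow(counts))) {
    expect_true(all(diff(counts[i, ]) <= 0))
  }
})

fake_summary <- function(counts, interface = "x") {
  pw <- tibble::tibble(kind = "HB", window = seq_along(counts), count = counts) |>
    dplyr::bind_rows(tibble::tibble(kind = "NP", window = seq_along(counts),
                                    count = 0L))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(interface = interface, per_window = pw,
                 stats = tibble::tibble(kind = c("HB", "NP"),
                                        mean_count = c(mean(counts), 0),
                                        sd_count = c(pop_sd(counts), 0),
                                        n_windows = length(counts))),
            class = "interface_summary")
}

test_that("Welch comparison reproduces a hand-computed t-test and is symmetric", {
  a <- c(10, 10, 10, 10, 9, 10, 10, 10, 10, 10)
  b <- c(2, 2, 2, 3, 2, 2, 2, 2, 2, 2)
  got <- compare_interfaces(fake_summary(a, "A"), fake_summary(b, "B"), kind = "HB")
  ref <- t.test(a, b)       # independent oracle
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_lt(got$p_value, 1e-5)
  rev <- compare_interfaces(fake_summary(b, "B"), fake_summary(a, "A"), kind = "HB")
  expect_equal(abs(rev$statistic), abs(got$statistic))
  expect_equal(rev$p_value, got$p_value)
})

test_that("degenerate comparisons are handled explicitly", {
  same <- compare_interfaces(fake_summary(rep(2, 10)), fake_summary(rep(2, 10)),
                             kind = "HB")
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)
  diff_ <- compare_interfaces(fake_summary(rep(2, 10)), fake_summary(rep(5, 10)),
                              kind = "HB")
  expect_true(diff_$degenerate)
  expect_lt(diff_$p_value, 1e-300)
})
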