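#' Contact-detection parameters
#'
#' Defaults follow the interdomain contact criteria used for TCR ectodomain
#' trajectories: a hydrogen bond is a donor hydrogen within 2.4 Angstrom of an
#' acceptor; a nonpolar contact is any pair of atoms with |partial charge| <
#' 0.3 e within 3.0 Angstrom, aggregated to the residue pair; a contact is
#' "high occupancy" when its per-window occupancy is strictly greater than
#' 0.8.
#'
#' @param hbond_cutoff H-to-acceptor distance cutoff, Angstrom.
#' @param nonpolar_cutoff Atom-atom distance cutoff for nonpolar contacts,
#'   Angstrom.
#' @param charge_threshold Absolute partial-charge bound (fraction of e) for
#'   an atom to count as nonpolar; strict less-than.
#' @param occupancy_threshold High-occupancy threshold, in (0,1); strict
#'   greater-than.
#' @param hbond_angle_min Optional donor-H...acceptor angle gate in degrees;
#'   `NULL` (default) disables it, matching the distance-only criterion.
#' @param np_granularity `"residue"` (default) aggregates nonpolar contacts
#'   per residue pair; `"atom"` keeps atom pairs.
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(hbond_cutoff = 2.4, nonpolar_cutoff = 3.0,
                           charge_threshold = 0.3, occupancy_threshold = 0.8,
                           hbond_angle_min = NULL,
                           np_granularity = c("residue", "atom")) {
  np_granularity <- match.arg(np_granularity)
  stopifnot(hbond_cutoff > 0, nonpolar_cutoff > 0, charge_threshold > 0,
            occupancy_threshold > 0, occupancy_threshold < 1)
  structure(list(hbond_cutoff = hbond_cutoff, nonpolar_cutoff = nonpolar_cutoff,
                 charge_threshold = charge_threshold,
                 occupancy_threshold = occupancy_threshold,
                 hbond_angle_min = hbond_angle_min,
                 np_granularity = np_granularity),
            class = "contact_params")
}

residue_label <- function(topology, atom_ids) {
  i <- match(atom_ids, topology$atom_id)
  paste0(topology$chain_id[i], topology$residue_number[i], topology$insert[i])
}

#' Detect hydrogen-bond contacts across an interface in one frame
#'
#' A cross-interface (donor-hydrogen, acceptor) atom pair is a hydrogen bond
#' when the H-acceptor Euclidean distance is strictly below
#' `params$hbond_cutoff`. The criterion is distance-only by default; the
#' optional angle gate requires the donor-H...acceptor angle to exceed
#' `hbond_angle_min` (donor = nearest N/O/S heavy atom to the hydrogen).
#'
#' @param frame Coordinates `n_atoms x 3` (Angstrom).
#' @param topology Annotated topology tibble.
#' @param set_a,set_b Disjoint atom-id vectors defining the interface sides.
#' @param params [contact_params()].
#' @return Tibble with one row per contact: `kind` ("HB"), `key`
#'   (canonicalized), `atom_a`, `atom_b` (donor-H and acceptor atom ids),
#'   `res_a`, `res_b`.
#' @export
detect_hbond_contacts <- function(frame, topology, set_a, set_b,
                                  params = contact_params()) {
  if (length(intersect(set_a, set_b)) > 0) abort("Interface atom sets must be disjoint")
  hits <- rbind(
    hb_one_direction(frame, topology, set_a, set_b, params),
    hb_one_direction(frame, topology, set_b, set_a, params)
  )
  if (nrow(hits) == 0) {
    inform("No donor-hydrogen/acceptor pairs within cutoff across this interface")
    return(empty_contacts())
  }
  canonicalize_contacts(hits, topology, kind = "HB")
}

hb_one_direction <- function(frame, topology, donors_side, acceptors_side, params) {
  dh <- intersect(donors_side, topology$atom_id[topology$is_donor_hydrogen])
  ac <- intersect(acceptors_side, topology$atom_id[topology$is_acceptor])
  if (length(dh) == 0 || length(ac) == 0) {
    return(data.frame(atom_a = integer(), atom_b = integer()))
  }
  d2 <- cross_dist2(frame[dh, , drop = FALSE], frame[ac, , drop = FALSE])
  hit <- which(d2 < params$hbond_cutoff^2, arr.ind = TRUE)
  out <- data.frame(atom_a = dh[hit[, 1]], atom_b = ac[hit[, 2]])
  if (!is.null(params$hbond_angle_min) && nrow(out) > 0) {
    keep <- vapply(seq_len(nrow(out)), function(k) {
      hpos <- frame[out$atom_a[k], ]
      apos <- frame[out$atom_b[k], ]
      heavy <- which(topology$element %in% c("N", "O", "S"))
      heavy <- heavy[heavy != out$atom_a[k]]
      if (length(heavy) == 0) return(TRUE)
      dpos <- frame[heavy[which.min(rowSums(sweep(frame[heavy, , drop = FALSE], 2, hpos)^2))], ]
      v1 <- dpos - hpos; v2 <- apos - hpos
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      ang >= params$hbond_angle_min
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Detect nonpolar contacts across an interface in one frame
#'
#' A cross-interface residue pair is a nonpolar (NP) contact when at least one
#' atom pair — both atoms with |partial charge| strictly below
#' `params$charge_threshold` — lies within `params$nonpolar_cutoff`.
#'
#' @inheritParams detect_hbond_contacts
#' @return Tibble as in [detect_hbond_contacts()] with `kind = "NP"`. At
#'   residue granularity `atom_a`/`atom_b` hold one witnessing atom pair.
#' @export
detect_nonpolar_contacts <- function(frame, topology, set_a, set_b,
                                     params = contact_params()) {
  if (length(intersect(set_a, set_b)) > 0) abort("Interface atom sets must be disjoint")
  if (all(topology$partial_charge == 0)) {
    warn("All partial charges are zero (no charge table applied?): every atom passes the nonpolar charge gate")
  }
  qok <- abs(topology$partial_charge) < params$charge_threshold
  aa <- intersect(set_a, topology$atom_id[qok])
  bb <- intersect(set_b, topology$atom_id[qok])
  if (length(aa) == 0 || length(bb) == 0) return(empty_contacts())
  d2 <- cross_dist2(frame[aa, , drop = FALSE], frame[bb, , drop = FALSE])
  hit <- which(d2 < params$nonpolar_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_contacts())
  out <- data.frame(atom_a = aa[hit[, 1]], atom_b = bb[hit[, 2]])
  out <- canonicalize_contacts(out, topology, kind = "NP")
  if (params$np_granularity == "residue") {
    out <- out |>
      dplyr::group_by(.data$key) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  out
}

empty_contacts <- function() {
  tibble::tibble(kind = character(), key = character(),
                 atom_a = integer(), atom_b = integer(),
                 res_a = character(), res_b = character())
}

# canonical key: HB keyed by the (donor-H, acceptor) atom-id pair, NP by the
# residue pair; both sorted so (a,b) == (b,a)
canonicalize_contacts <- function(df, topology, kind) {
  if (nrow(df) == 0) return(empty_contacts())
  ra <- residue_label(topology, df$atom_a)
  rb <- residue_label(topology, df$atom_b)
  if (kind == "HB") {
    p1 <- pmin(df$atom_a, df$atom_b)
    p2 <- pmax(df$atom_a, df$atom_b)
    key <- paste0("HB:", p1, "-", p2)
  } else {
    key <- paste0("NP:", pmin(ra, rb), "-", pmax(ra, rb))
  }
  tibble::tibble(kind = kind, key = key,
                 atom_a = df$atom_a, atom_b = df$atom_b,
                 res_a = ra, res_b = rb) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
}

#' Build overlapping analysis windows over a time interval
#'
#' Either `count` or `width` must be given. With `count`, windows tile
#' `[t0, t1]` exactly: width = 2(t1 - t0)/(count + 1) and step = width/2, so
#' 10 windows over 100-300 ns are 36.36-ns windows starting every 18.18 ns
#' (printed as "36.4-ns windows", "100.0 to 136.4", "118.2 to 154.5"). With
#' `width`, step = width * (1 - overlap); windows are added while their start
#' is below `t1 - step` and the final window end is clamped to `t1`.
#'
#' @param t0,t1 Interval bounds in ns.
#' @param count Number of windows (preferred form).
#' @param width Window width in ns (alternative form).
#' @param overlap Fractional overlap between consecutive windows (default
#'   0.5).
#' @return Tibble with columns `window` (1..n), `start`, `end` (ns).
#' @export
make_windows <- function(t0, t1, count = NULL, width = NULL, overlap = 0.5) {
  if (t1 <= t0) abort("Window interval requires t1 > t0")
  span <- t1 - t0
  if (!is.null(count)) {
    stopifnot(count >= 1)
    w <- 2 * span / (count + 1)
    starts <- t0 + (seq_len(count) - 1) * w / 2
    return(tibble::tibble(window = seq_len(count), start = starts, end = starts + w))
  }
  if (is.null(width)) abort("Provide count or width")
  if (width > span) {
    warn("Window width exceeds interval span: returning a single window")
    return(tibble::tibble(window = 1L, start = t0, end = t1))
  }
  step <- width * (1 - overlap)
  if (step <= 0) abort("overlap must be < 1")
  starts <- seq(t0, t1, by = step)
  starts <- starts[starts < t1 - step]
  if (length(starts) == 0) starts <- t0
  ends <- pmin(starts + width, t1)
  tibble::tibble(window = seq_along(starts), start = starts, end = ends)
}

#' Windowed contact occupancy over a trajectory
#'
#' Runs hydrogen-bond and nonpolar contact detection on every frame that falls
#' inside at least one window and reports, for each contact ever observed, the
#' fraction of frames in each window in which it is present. Frames in
#' overlapping windows count in each window they belong to.
#'
#' @param trajectory An `md_trajectory` with annotated topology.
#' @param set_a,set_b Atom-id sets for the two interface sides.
#' @param params [contact_params()].
#' @param windows Window tibble from [make_windows()].
#' @param kinds Which contact kinds to detect (default both).
#' @return A long tibble of class `occupancy_table`: `kind`, `key`, `res_a`,
#'   `res_b`, `window`, `occupancy`.
#' @export
contact_occupancy <- function(trajectory, set_a, set_b,
                              params = contact_params(),
                              windows, kinds = c("HB", "NP")) {
  times <- trajectory$times
  in_any <- rep(FALSE, length(times))
  frames_per_window <- integer(nrow(windows))
  member <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    m <- times >= windows$start[w] & times <= windows$end[w]
    frames_per_window[w] <- sum(m)
    if (frames_per_window[w] == 0) {
      abort(sprintf("Window %d [%g, %g] ns contains zero frames",
                    windows$window[w], windows$start[w], windows$end[w]))
    }
    member[[w]] <- which(m)
    in_any <- in_any | m
  }
  use_frames <- which(in_any)

  per_frame <- vector("list", length(use_frames))
  for (k in seq_along(use_frames)) {
    f <- use_frames[k]
    co <- frame_coords(trajectory, f)
    found <- list()
    if ("HB" %in% kinds) {
      found$hb <- suppressMessages(
        detect_hbond_contacts(co, trajectory$topology, set_a, set_b, params))
    }
    if ("NP" %in% kinds) {
      found$np <- suppressWarnings(
        detect_nonpolar_contacts(co, trajectory$topology, set_a, set_b, params))
    }
    per_frame[[k]] <- dplyr::bind_rows(found)
  }
  all_hits <- dplyr::bind_rows(per_frame, .id = "frame_pos")
  if (nrow(all_hits) == 0) {
    return(structure(tibble::tibble(kind = character(), key = character(),
                                    res_a = character(), res_b = character(),
                                    window = integer(), occupancy = numeric()),
                     class = c("occupancy_table", "tbl_df", "tbl", "data.frame"),
                     windows = windows))
  }
  all_hits$frame <- use_frames[as.integer(all_hits$frame_pos)]
  keys <- dplyr::distinct(all_hits, .data$kind, .data$key, .data$res_a, .data$res_b)

  # presence matrix: contacts x frames (sparse via match on key+frame pairs)
  occ <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    fr <- member[[w]]
    counts <- all_hits |>
      dplyr::filter(.data$frame %in% fr) |>
      dplyr::count(.data$key, name = "n_present")
    keys |>
      dplyr::left_join(counts, by = "key") |>
      dplyr::mutate(window = windows$window[w],
                    occupancy = dplyr::coalesce(.data$n_present, 0L) / frames_per_window[w]) |>
      dplyr::select(-"n_present")
  })
  structure(occ, class = c("occupancy_table", class(tibble::tibble())),
            windows = windows)
}

#' Count high-occupancy contacts per window and summarise an interface
#'
#' Counts, in each window and separately for hydrogen bonds and nonpolar
#' contacts, the contacts whose occupancy is strictly greater than
#' `params$occupancy_threshold`, then reports the mean and the SD over
#' windows. A contact counted in every window at occupancy 1 contributes
#' identical counts, so the SD is exactly zero (the "no error bar" case).
#'
#' @param occupancy An `occupancy_table` from [contact_occupancy()].
#' @param params [contact_params()].
#' @param interface Name attached to the summary.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return A list of class `interface_summary`: `interface`, `per_window`
#'   (tibble kind x window x count) and `stats` (tibble kind, mean_count,
#'   sd_count, n_windows).
#' @export
count_high_occupancy <- function(occupancy, params = contact_params(),
                                 interface = "interface",
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  windows <- attr(occupancy, "windows")
  grid <- tidyr::expand_grid(kind = c("HB", "NP"), window = windows$window)
  per_window <- occupancy |>
    dplyr::filter(.data$occupancy > params$occupancy_threshold) |>
    dplyr::count(.data$kind, .data$window, name = "count") |>
    dplyr::right_join(grid, by = c("kind", "window")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$kind, .data$window)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  stats <- per_window |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(mean_count = mean(.data$count),
                     sd_count = if (sd_type == "population") pop_sd(.data$count) else sd(.data$count),
                     n_windows = dplyr::n(), .groups = "drop")
  structure(list(interface = interface, per_window = per_window, stats = stats),
            class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  cat("<interface_summary>", x$interface, "\n")
  print(x$stats)
  invisible(x)
}

#' Compare high-occupancy contact counts between two interfaces
#'
#' Two-sided Welch two-sample t-test on the per-window high-occupancy counts
#' of one contact kind. Symmetric in its arguments. With zero variance in
#' both groups the p-value is 1 for equal means and reported at the machine
#' floor with `degenerate = TRUE` for unequal means.
#'
#' @param summary_a,summary_b `interface_summary` objects.
#' @param kind `"HB"`, `"NP"`, or `"all"` (counts summed over kinds).
#' @return Tibble: `interface_a`, `interface_b`, `kind`, `test`, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
compare_interfaces <- function(summary_a, summary_b, kind = "all") {
  counts_of <- function(s) {
    pw <- s$per_window
    if (kind != "all") pw <- dplyr::filter(pw, .data$kind == !!kind)
    pw |> dplyr::group_by(.data$window) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::pull(.data$count)
  }
  a <- counts_of(summary_a)
  b <- counts_of(summary_b)
  if (length(a) < 2 || length(b) < 2) abort("Need at least 2 windows per interface")
  degenerate <- FALSE
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(a) - mean(b)) * Inf
      p <- .Machine$double.xmin
      degenerate <- TRUE
    }
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(interface_a = summary_a$interface, interface_b = summary_b$interface,
                 kind = kind, test = "Welch two-sample t-test",
                 statistic = stat, p_value = p, degenerate = degenerate)
}
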