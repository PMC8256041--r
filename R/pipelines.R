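read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("Config must be a list or a YAML file path")
  config
}

collect_errors <- function(checks) {
  msgs <- purrr::compact(checks)
  if (length(msgs) > 0) {
    abort(paste0("Invalid config:\n", paste0("  - ", unlist(msgs), collapse = "\n")))
  }
}

# hash over the analysis-defining fields only: where outputs are written is
# not part of the result's identity
config_hash <- function(config) {
  config$out_dir <- NULL
  rlang::hash(config)
}

provenance_header <- function(config, seed) {
  c(sprintf("# generated_by: tcrmech %s",
            as.character(utils::packageVersion("tcrmech"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", format(seed)))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  close(con)
  on.exit()
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the contact-occupancy pipeline from a config
#'
#' Loads a trajectory (multi-model PDB or DCD plus topology source) and
#' charge table, resolves the configured domains, computes windowed contact
#' occupancy for every configured interface, writes per-interface occupancy
#' and summary tables and all pairwise Welch comparisons. Every output file
#' carries a provenance header (package version, config hash, seed).
#'
#' Config fields: `structure` (PDB path), `trajectory` (optional trajectory
#' path; defaults to `structure`), `charges` (optional TSV), `domains`
#' (named list of `chain` + `residues = c(lo, hi)`), `interfaces` (list of
#' `c(domainA, domainB)` pairs), `t0`, `t1` (ns), `windows` (count), `params`
#' (overrides for [contact_params()]), `frame_interval`, `seed`, `out_dir`.
#'
#' @param config List or YAML file path.
#' @return Invisibly, a list with `summaries`, `comparisons` and the output
#'   file paths.
#' @export
run_contact_pipeline <- function(config) {
  cfg <- read_config(config)
  collect_errors(list(
    if (is.null(cfg$structure)) "missing 'structure' (PDB path)",
    if (!is.null(cfg$structure) && !file.exists(cfg$structure))
      paste0("structure file not found: ", cfg$structure),
    if (!is.null(cfg$trajectory) && !file.exists(cfg$trajectory))
      paste0("trajectory file not found: ", cfg$trajectory),
    if (!is.null(cfg$charges) && !file.exists(cfg$charges))
      paste0("charge table not found: ", cfg$charges),
    if (is.null(cfg$domains) || length(cfg$domains) < 2)
      "need at least two 'domains'",
    if (is.null(cfg$interfaces)) "missing 'interfaces'",
    if (is.null(cfg$out_dir)) "missing 'out_dir'"
  ))
  seed <- cfg$seed %||% 1
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  st <- read_structure(cfg$structure)
  topo <- st$topology
  traj_path <- cfg$trajectory %||% cfg$structure
  traj <- read_trajectory(topo, traj_path,
                          frame_interval = cfg$frame_interval %||% 0.02)
  if (!is.null(cfg$charges)) {
    topo <- apply_charge_table(topo, read_charge_table(cfg$charges))
  }
  if (!any(topo$is_donor_hydrogen) && !any(topo$is_acceptor)) {
    topo <- infer_donors_acceptors(topo, frame_coords(traj, 1))
  }
  traj$topology <- topo

  params <- do.call(contact_params, cfg$params %||% list())
  t0 <- cfg$t0 %||% min(traj$times)
  t1 <- cfg$t1 %||% max(traj$times)
  windows <- make_windows(t0, t1, count = cfg$windows %||% 10)

  specs <- purrr::imap(cfg$domains, function(d, nm) {
    domain_spec(nm, d$chain, residue_range = unlist(d$residues))
  })
  hdr <- provenance_header(cfg, seed)
  summaries <- list()
  paths <- character()
  for (iface in cfg$interfaces) {
    nm <- paste(iface[[1]], iface[[2]], sep = "-")
    a <- resolve_domain(specs[[iface[[1]]]], topo)
    b <- resolve_domain(specs[[iface[[2]]]], topo)
    occ <- contact_occupancy(traj, a, b, params, windows)
    summ <- count_high_occupancy(occ, params, interface = nm)
    summaries[[nm]] <- summ
    p1 <- file.path(cfg$out_dir, paste0("occupancy_", nm, ".tsv"))
    write_tsv_with_header(tibble::as_tibble(occ), p1, hdr)
    paths <- c(paths, p1)
  }
  summary_tbl <- purrr::imap_dfr(summaries, function(s, nm) {
    dplyr::mutate(s$stats, interface = nm, .before = 1)
  })
  counts_tbl <- purrr::imap_dfr(summaries, function(s, nm) {
    dplyr::mutate(s$per_window, interface = nm, .before = 1)
  })
  p_sum <- file.path(cfg$out_dir, "summary.tsv")
  write_tsv_with_header(summary_tbl, p_sum, hdr)
  p_cnt <- file.path(cfg$out_dir, "window_counts.tsv")
  write_tsv_with_header(counts_tbl, p_cnt, hdr)

  comparisons <- NULL
  if (length(summaries) >= 2) {
    pairs <- utils::combn(names(summaries), 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      compare_interfaces(summaries[[pr[1]]], summaries[[pr[2]]])
    })
    p_cmp <- file.path(cfg$out_dir, "comparisons.json")
    jsonlite::write_json(list(provenance = list(config_hash = config_hash(cfg),
                                                seed = seed),
                              comparisons = comparisons),
                         p_cmp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_cmp)
  }
  invisible(list(summaries = summaries, comparisons = comparisons,
                 files = c(paths, p_sum, p_cnt)))
}

#' Run the trace-analysis pipeline from a config
#'
#' Reads one or two trace TSV files (conditions `specific` and optionally
#' `nonspecific`), segments every trace, extracts bond events, builds
#' force-binned lifetime curves, fits the dual-pathway bond model with
#' catch/slip classification, and — when both conditions are given —
#' computes the sensitivity index. Outputs: `events_<cond>.tsv`,
#' `curve_<cond>.tsv`, `fit_<cond>.json`, `sensitivity_index.tsv`, all with
#' provenance headers.
#'
#' Config fields: `specific` (trace TSV path), `nonspecific` (optional),
#' `bins` (edges, pN; default `seq(5, 30, 2.5)`), `kbt`, `detect` (overrides
#' for [detect_params()]), `seed`, `out_dir`.
#'
#' @param config List or YAML file path.
#' @return Invisibly, list with `events`, `curves`, `fits`, `index`, `files`.
#' @export
run_trace_pipeline <- function(config) {
  cfg <- read_config(config)
  collect_errors(list(
    if (is.null(cfg$specific)) "missing 'specific' (trace TSV path)",
    if (!is.null(cfg$specific) && !file.exists(cfg$specific))
      paste0("trace file not found: ", cfg$specific),
    if (!is.null(cfg$nonspecific) && !file.exists(cfg$nonspecific))
      paste0("trace file not found: ", cfg$nonspecific),
    if (is.null(cfg$out_dir)) "missing 'out_dir'"
  ))
  seed <- cfg$seed %||% 1
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(cfg, seed)
  breaks <- unlist(cfg$bins) %||% seq(5, 30, by = 2.5)
  kbt <- cfg$kbt %||% 4.114
  dpar <- if (is.null(cfg$detect)) NULL else do.call(detect_params, cfg$detect)

  conds <- purrr::compact(list(specific = cfg$specific,
                               nonspecific = cfg$nonspecific))
  events <- list(); curves <- list(); fits <- list(); paths <- character()
  for (nm in names(conds)) {
    traces <- read_traces(conds[[nm]])
    ev <- analyze_traces(traces, params = dpar)
    if (nrow(ev) == 0 || all(ev$censored)) {
      abort(paste0("Zero usable (uncensored) traces in condition '", nm, "'"))
    }
    events[[nm]] <- ev
    curves[[nm]] <- lifetime_curve(ev, breaks = breaks)
    fits[[nm]] <- fit_bond_model(ev, kBT = kbt)
    pe <- file.path(cfg$out_dir, paste0("events_", nm, ".tsv"))
    write_tsv_with_header(dplyr::select(ev, -"transitions"), pe, hdr)
    pc <- file.path(cfg$out_dir, paste0("curve_", nm, ".tsv"))
    write_tsv_with_header(tibble::as_tibble(curves[[nm]]), pc, hdr)
    pf <- file.path(cfg$out_dir, paste0("fit_", nm, ".json"))
    jsonlite::write_json(
      list(provenance = list(config_hash = config_hash(cfg), seed = seed),
           parameters = tidy(fits[[nm]]), summary = glance(fits[[nm]])),
      pf, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pe, pc, pf)
  }
  index <- NULL
  if (length(conds) == 2) {
    index <- sensitivity_index(curves$specific, curves$nonspecific)
    pi_ <- file.path(cfg$out_dir, "sensitivity_index.tsv")
    write_tsv_with_header(tibble::as_tibble(index), pi_, hdr)
    paths <- c(paths, pi_)
  }
  invisible(list(events = events, curves = curves, fits = fits, index = index,
                 files = paths))
}
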