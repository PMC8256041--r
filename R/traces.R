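#' Construct an optical-trap trace
#'
#' A trace is a tibble of time-stamped bead-trap separation (nm) and force
#' (pN), with trap metadata attached as attributes. When force is omitted it
#' is synthesized as `trap_stiffness * separation`.
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param separation_nm Bead-trap separation in nm (0 = trap center).
#' @param force_pN Optional force in pN.
#' @param trap_stiffness Trap spring constant, pN/nm.
#' @param sampling_rate Sampling rate, Hz.
#' @param assay `"SM"` (single molecule) or `"SMSC"` (single molecule on a
#'   single cell).
#' @param label Free-text label.
#' @return Tibble of class `trap_trace` with columns `time_s`,
#'   `separation_nm`, `force_pN`.
#' @export
trap_trace <- function(time_s, separation_nm, force_pN = NULL,
                       trap_stiffness = 0.25, sampling_rate = NULL,
                       assay = c("SM", "SMSC"), label = "") {
  assay <- match.arg(assay)
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort(paste0("Trace times must be strictly increasing (first violation at row ",
                 which(diff(time_s) <= 0)[1] + 1, ")"))
  }
  if (is.null(force_pN)) force_pN <- trap_stiffness * separation_nm
  if (is.null(sampling_rate)) {
    sampling_rate <- if (length(time_s) > 1) 1 / median(diff(time_s)) else NA_real_
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        separation_nm = as.numeric(separation_nm),
                        force_pN = as.numeric(force_pN))
  structure(out, class = c("trap_trace", class(out)),
            trap_stiffness = trap_stiffness, sampling_rate = sampling_rate,
            assay = assay, label = label)
}

trace_meta <- function(trace) {
  list(trap_stiffness = attr(trace, "trap_stiffness"),
       sampling_rate = attr(trace, "sampling_rate"),
       assay = attr(trace, "assay") %||% "SM",
       label = attr(trace, "label") %||% "")
}

#' Read optical-trap traces from a TSV file
#'
#' The file starts with `#`-prefixed metadata lines
#' (`# trap_stiffness_pN_per_nm: 0.25`, `# sampling_rate_hz: 1000`,
#' `# assay: SM`, `# label: ...`) followed by a tab-separated table with
#' columns `time_s`, `separation_nm` and optionally `force_pN` and `trace`
#' (a block id; one `trap_trace` is returned per block). Without a force
#' column, force is synthesized from the trap stiffness; with one, a
#' discrepancy of more than 5% against `stiffness * separation` raises a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return A list of `trap_trace` objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(paste0("Trace file not found: ", path))
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(trap_stiffness = NA_real_, sampling_rate = NA_real_,
               assay = "SM", label = "")
  for (ml in meta_lines) {
    kv <- stringr::str_match(ml, "^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$")
    if (is.na(kv[1, 1])) next
    key <- kv[1, 2]; val <- kv[1, 3]
    if (key == "trap_stiffness_pN_per_nm") meta$trap_stiffness <- as.numeric(val)
    if (key == "sampling_rate_hz") meta$sampling_rate <- as.numeric(val)
    if (key == "assay") meta$assay <- val
    if (key == "label") meta$label <- val
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("time_s", "separation_nm")
  if (!all(need %in% names(tab))) {
    abort("Trace TSV needs columns time_s and separation_nm")
  }
  if (!"trace" %in% names(tab)) tab$trace <- "1"
  blocks <- split(tab, factor(tab$trace, levels = unique(tab$trace)))
  purrr::imap(blocks, function(b, id) {
    bad <- which(diff(b$time_s) <= 0)
    if (length(bad) > 0) {
      abort(sprintf("Non-monotone time in trace '%s' at row %d", id, bad[1] + 1))
    }
    force <- if ("force_pN" %in% names(b)) b$force_pN else NULL
    if (!is.null(force) && is.finite(meta$trap_stiffness)) {
      expected <- meta$trap_stiffness * b$separation_nm
      big <- abs(b$separation_nm) > 1
      if (any(big) && median(abs(force[big] - expected[big]) /
                               pmax(abs(expected[big]), 1e-9)) > 0.05) {
        warn(sprintf("Trace '%s': force column inconsistent with trap_stiffness * separation by >5%%", id))
      }
    }
    stiff <- if (is.finite(meta$trap_stiffness)) meta$trap_stiffness else 0.25
    tr <- trap_trace(b$time_s, b$separation_nm, force,
                     trap_stiffness = stiff,
                     sampling_rate = if (is.finite(meta$sampling_rate)) meta$sampling_rate else NULL,
                     assay = if (meta$assay %in% c("SM", "SMSC")) meta$assay else "SM",
                     label = if (meta$label != "") meta$label else id)
    tr
  }) |> unname()
}

#' Write traces to the TSV format read by [read_traces()]
#'
#' @param traces A `trap_trace` or list of them (metadata taken from the
#'   first).
#' @param path Output path.
#' @param extra_header Named list of extra `# key: value` lines (e.g. seed).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, extra_header = list()) {
  if (inherits(traces, "trap_trace")) traces <- list(traces)
  meta <- trace_meta(traces[[1]])
  hdr <- c(sprintf("# trap_stiffness_pN_per_nm: %.6g", meta$trap_stiffness),
           sprintf("# sampling_rate_hz: %.6g", meta$sampling_rate),
           sprintf("# assay: %s", meta$assay),
           sprintf("# label: %s", meta$label),
           purrr::imap_chr(extra_header, function(v, k) sprintf("# %s: %s", k, format(v))))
  body <- purrr::imap_dfr(traces, function(tr, i) {
    tibble::tibble(trace = as.character(i), time_s = tr$time_s,
                   separation_nm = tr$separation_nm, force_pN = tr$force_pN)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("trace", "time_s", "separation_nm", "force_pN"), collapse = "\t"), con)
  writeLines(sprintf("%s\t%.9g\t%.6f\t%.6f", body$trace, body$time_s,
                     body$separation_nm, body$force_pN), con)
  invisible(path)
}
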