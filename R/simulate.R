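# run code under a local, restorable RNG state so generators are
# bit-reproducible from (params, seed) without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Describe a contact to plant in a synthetic trajectory
#'
#' @param kind `"HB"` or `"NP"`.
#' @param atom_a,atom_b Atom ids of the pair (for HB: donor hydrogen and
#'   acceptor).
#' @param occupancy Target occupancy in `[0, 1]`.
#' @param model Temporal model: `"iid"` per-frame Bernoulli draws (default)
#'   or `"markov"` two-state with stationary probability `occupancy` and
#'   correlation time `corr_time` ns.
#' @param corr_time Correlation time in ns for the Markov model.
#' @return List of class `planted_contact`.
#' @export
planted_contact <- function(kind = c("HB", "NP"), atom_a, atom_b, occupancy,
                            model = c("iid", "markov"), corr_time = 1) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  stopifnot(occupancy >= 0, occupancy <= 1, corr_time > 0)
  structure(list(kind = kind, atom_a = atom_a, atom_b = atom_b,
                 occupancy = occupancy, model = model, corr_time = corr_time),
            class = "planted_contact")
}

plant_states <- function(plant, n_frames, frame_interval) {
  p <- plant$occupancy
  if (plant$model == "iid" || p %in% c(0, 1)) {
    return(runif(n_frames) < p)
  }
  lam <- exp(-frame_interval / plant$corr_time)
  a <- p * (1 - lam)       # P(off -> on)
  b <- (1 - p) * (1 - lam) # P(on -> off)
  s <- logical(n_frames)
  s[1] <- runif(1) < p
  u <- runif(n_frames - 1)
  for (i in seq_len(n_frames - 1)) {
    s[i + 1] <- if (s[i]) u[i] >= b else u[i] < a
  }
  s
}

#' Simulate a trajectory with planted contact occupancies
#'
#' Each planted contact is switched ON/OFF frame by frame according to its
#' temporal model; when ON the pair is placed at its detection cutoff minus
#' 0.3 Angstrom, when OFF at cutoff plus 1.0 Angstrom (along the template
#' direction between the two atoms). All other atoms are jittered by
#' isotropic Gaussian noise of SD 0.1 Angstrom around the template.
#'
#' @param topology Annotated topology tibble.
#' @param template Template coordinates `n_atoms x 3` (Angstrom).
#' @param plants List of [planted_contact()]s; no two may share an atom.
#' @param n_frames Number of frames.
#' @param frame_interval Frame spacing in ns (default 0.02).
#' @param seed Integer seed; output is deterministic given (inputs, seed).
#' @param params [contact_params()] supplying the cutoffs.
#' @return An `md_trajectory` with a `truth` attribute: tibble `key-free`
#'   plant index, per-frame ON states (list-column) and empirical occupancy.
#' @export
simulate_trajectory <- function(topology, template, plants, n_frames,
                                frame_interval = 0.02, seed = 1,
                                params = contact_params()) {
  atoms_used <- unlist(lapply(plants, function(p) c(p$atom_a, p$atom_b)))
  if (anyDuplicated(atoms_used)) {
    abort("Planted contacts may not share atoms")
  }
  if (!all(atoms_used %in% topology$atom_id)) {
    abort("Planted contact atoms missing from topology")
  }
  n_atoms <- nrow(topology)
  with_seed(seed, {
    xyz <- matrix(0, nrow = n_frames, ncol = 3 * n_atoms)
    jitter <- array(rnorm(n_frames * n_atoms * 3, sd = 0.1),
                    dim = c(n_frames, 3 * n_atoms))
    base <- rep(as.vector(t(template)), each = 1)
    xyz <- sweep(jitter, 2, base, "+")
    states <- lapply(plants, plant_states, n_frames = n_frames,
                     frame_interval = frame_interval)
    for (pi in seq_along(plants)) {
      pl <- plants[[pi]]
      cutoff <- if (pl$kind == "HB") params$hbond_cutoff else params$nonpolar_cutoff
      d_on <- cutoff - 0.3
      d_off <- cutoff + 1.0
      ia <- match(pl$atom_a, topology$atom_id)
      ib <- match(pl$atom_b, topology$atom_id)
      u <- template[ib, ] - template[ia, ]
      nu <- sqrt(sum(u^2))
      u <- if (nu > 0) u / nu else c(1, 0, 0)
      ca <- 3 * (ia - 1) + 1:3
      cb <- 3 * (ib - 1) + 1:3
      # pair atoms placed exactly: anchor at template, partner at distance d
      xyz[, ca] <- matrix(template[ia, ], n_frames, 3, byrow = TRUE)
      d <- ifelse(states[[pi]], d_on, d_off)
      xyz[, cb] <- matrix(template[ia, ], n_frames, 3, byrow = TRUE) + outer(d, u)
    }
    times <- (seq_len(n_frames) - 1) * frame_interval
    traj <- new_trajectory(topology, xyz, times)
    attr(traj, "truth") <- tibble::tibble(
      plant = seq_along(plants),
      kind = vapply(plants, function(p) p$kind, character(1)),
      atom_a = vapply(plants, function(p) p$atom_a, numeric(1)),
      atom_b = vapply(plants, function(p) p$atom_b, numeric(1)),
      target_occupancy = vapply(plants, function(p) p$occupancy, numeric(1)),
      empirical_occupancy = vapply(states, mean, numeric(1)),
      states = states)
    traj
  })
}

#' Simulation parameters for optical-trap traces
#'
#' Defaults describe a single-beam trap assay on a TCR-ligand tether:
#' 0.25 pN/nm stiffness, 20 pN/s loading, 1 kHz sampling, 2 nm bead noise,
#' and dual-pathway dissociation kinetics (slip-only when `k_c = 0`).
#'
#' @param k_c,x_c Catch-pathway rate (1/s) and distance (nm).
#' @param k_s,x_s Slip-pathway rate (1/s) and distance (nm).
#' @param kBT Thermal energy, pN nm.
#' @param transition_rate Conformational-transition rate during dwell, 1/s
#'   (0 disables transitions).
#' @param transition_distance Step size of the transition, nm.
#' @param post_transition_rate_scale Multiplier on the off-rate after the
#'   transition.
#' @param trap_stiffness pN/nm.
#' @param load_rate Loading rate, pN/s.
#' @param clamp_force Target clamp force, pN.
#' @param noise_sd Gaussian bead-position noise SD, nm.
#' @param sampling_rate Hz.
#' @param max_dwell Censoring horizon for the dwell, s.
#' @return List of class `trace_sim_params`.
#' @export
trace_sim_params <- function(k_c = 0, x_c = 0, k_s = 2, x_s = 0.5,
                             kBT = 4.114, transition_rate = 0,
                             transition_distance = 8,
                             post_transition_rate_scale = 1,
                             trap_stiffness = 0.25, load_rate = 20,
                             clamp_force = 10, noise_sd = 2,
                             sampling_rate = 1000, max_dwell = 120) {
  stopifnot(k_c >= 0, k_s >= 0, x_c >= 0, x_s >= 0, kBT > 0,
            transition_rate >= 0, transition_distance >= 0,
            sampling_rate > 0, load_rate > 0, noise_sd >= 0)
  if (trap_stiffness <= 0) {
    abort("clamp_force unreachable: trap_stiffness must be positive")
  }
  structure(as.list(environment()), class = "trace_sim_params")
}

#' Demo kinetic parameterizations
#'
#' `"wt"`: slip-only Bell kinetics (`k_s = 2` 1/s, `x_s = 0.5` nm), lifetimes
#' in the 0.1-0.5 s range at 5-20 pN. `"chimera"`: dual-pathway parameters
#' solved so the true lifetime curve peaks at exactly 15 pN with a 5 s peak
#' lifetime (`x_c = 1.5`, `x_s = 0.8` nm).
#'
#' @param which `"wt"` or `"chimera"`.
#' @param ... Overrides passed to [trace_sim_params()].
#' @return A `trace_sim_params` object.
#' @export
demo_params <- function(which = c("wt", "chimera"), ...) {
  which <- match.arg(which)
  if (which == "wt") {
    base <- list(k_c = 0, x_c = 0, k_s = 2, x_s = 0.5)
  } else {
    kBT <- 4.114
    x_c <- 1.5; x_s <- 0.8
    f_peak <- 15; tau_peak <- 5
    # at the peak the two pathway rates satisfy k_c x_c e^{-F x_c/kBT} =
    # k_s x_s e^{F x_s/kBT}; with their sum = 1/tau_peak this pins both rates
    a <- (1 / tau_peak) * x_s / (x_c + x_s)
    b <- (1 / tau_peak) * x_c / (x_c + x_s)
    base <- list(k_c = a * exp(f_peak * x_c / kBT), x_c = x_c,
                 k_s = b * exp(-f_peak * x_s / kBT), x_s = x_s,
                 transition_rate = 0.5, transition_distance = 8,
                 clamp_force = 15)
  }
  do.call(trace_sim_params, utils::modifyList(base, list(...)))
}

#' Simulate one optical-trap trace with known ground truth
#'
#' The stage loads the tether at `load_rate` until `clamp_force`, then holds.
#' The dwell is drawn from the dual-pathway kinetics at the clamp force; an
#' optional conformational transition (competing exponential at
#' `transition_rate`) steps the bead `transition_distance` nm toward the trap
#' center and rescales the subsequent off-rate (evaluated at the reduced
#' post-transition force, times `post_transition_rate_scale`). Rupture snaps
#' the separation to 0. Gaussian noise of SD `noise_sd` is added per sample.
#'
#' @param params [trace_sim_params()].
#' @param seed Integer seed.
#' @return A `trap_trace` with attribute `truth`: list with `t_clamp`,
#'   `t_transition` (NA if none), `t_rupture` (NA if censored), `lifetime`,
#'   `censored`, `clamp_force`, `transition_distance`.
#' @export
simulate_trace <- function(params = trace_sim_params(), seed = 1) {
  p <- params
  clamp_sep <- p$clamp_force / p$trap_stiffness
  if (p$transition_rate > 0 && p$transition_distance >= clamp_sep) {
    abort("Transition step would cross the trap-center baseline at this clamp force")
  }
  with_seed(seed, {
    dt <- 1 / p$sampling_rate
    t_clamp <- p$clamp_force / p$load_rate
    rate1 <- dual_pathway_rate(p$clamp_force, p$k_c, p$x_c, p$k_s, p$x_s, p$kBT)
    t_transition <- NA_real_
    post_sep <- clamp_sep
    if (p$transition_rate > 0) {
      t_rup1 <- rexp(1, rate1)
      t_tr <- rexp(1, p$transition_rate)
      if (t_tr < t_rup1) {
        t_transition <- t_tr
        post_sep <- clamp_sep - p$transition_distance
        f2 <- p$trap_stiffness * post_sep
        rate2 <- dual_pathway_rate(f2, p$k_c, p$x_c, p$k_s, p$x_s, p$kBT) *
          p$post_transition_rate_scale
        lifetime <- t_tr + rexp(1, rate2)
      } else {
        lifetime <- t_rup1
      }
    } else {
      lifetime <- rexp(1, rate1)
    }
    censored <- lifetime > p$max_dwell
    if (censored) lifetime <- p$max_dwell

    t_rupture <- if (censored) NA_real_ else t_clamp + lifetime
    tail_s <- 0.25
    total <- t_clamp + lifetime + if (censored) 0 else tail_s
    tt <- seq(0, total, by = dt)
    sep <- numeric(length(tt))
    loading <- tt < t_clamp
    sep[loading] <- (p$load_rate / p$trap_stiffness) * tt[loading]
    in_dwell <- !loading & (censored | tt < t_rupture)
    if (is.na(t_transition)) {
      sep[in_dwell] <- clamp_sep
    } else {
      pre <- in_dwell & tt < t_clamp + t_transition
      post <- in_dwell & !pre
      sep[pre] <- clamp_sep
      sep[post] <- post_sep
    }
    if (!censored) sep[tt >= t_rupture] <- 0
    if (p$noise_sd > 0) sep <- sep + rnorm(length(sep), sd = p$noise_sd)
    tr <- trap_trace(tt, sep, trap_stiffness = p$trap_stiffness,
                     sampling_rate = p$sampling_rate)
    attr(tr, "truth") <- list(
      t_clamp = t_clamp,
      t_transition = if (is.na(t_transition)) NA_real_ else t_clamp + t_transition,
      t_rupture = t_rupture, lifetime = lifetime, censored = censored,
      clamp_force = p$clamp_force,
      transition_distance = if (is.na(t_transition)) NA_real_ else p$transition_distance)
    tr
  })
}

#' Simulate a force-clamp experiment across a grid of clamp forces
#'
#' @param forces Clamp forces in pN.
#' @param n_per_force Traces per force.
#' @param params [trace_sim_params()] (its `clamp_force` is overridden per
#'   trace).
#' @param seed Integer master seed; per-trace seeds are derived from it so
#'   the whole set is reproducible.
#' @return List with `traces` (list of `trap_trace`) and `truth` (tibble:
#'   `trace`, `clamp_force_pN`, `lifetime_s`, `t_clamp`, `t_transition`,
#'   `t_rupture`, `censored`, `transition_distance`).
#' @export
simulate_experiment <- function(forces, n_per_force, params = trace_sim_params(),
                                seed = 1) {
  stopifnot(length(forces) >= 1, n_per_force >= 1)
  grid <- tidyr::expand_grid(force = forces, rep = seq_len(n_per_force))
  traces <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p_i <- params
    p_i$clamp_force <- grid$force[i]
    sub_seed <- (seed * 7919 + i * 104729) %% 2147483647
    traces[[i]] <- simulate_trace(p_i, seed = sub_seed)
    tru <- attr(traces[[i]], "truth")
    rows[[i]] <- tibble::tibble(trace = i, clamp_force_pN = tru$clamp_force,
                                lifetime_s = tru$lifetime,
                                t_clamp = tru$t_clamp,
                                t_transition = tru$t_transition,
                                t_rupture = tru$t_rupture,
                                censored = tru$censored,
                                transition_distance = tru$transition_distance)
  }
  list(traces = traces, truth = dplyr::bind_rows(rows))
}

#' Draw bond events directly from the dual-pathway kinetics
#'
#' Event-level shortcut past trace synthesis: lifetimes are exponential with
#' rate `k(F)` at each clamp force. Used for kinetic-model studies
#' (classifier power, parameter recovery) where the trace machinery itself
#' is not under test.
#'
#' @inheritParams simulate_experiment
#' @return Bond-event tibble: `label`, `clamp_force_pN`, `lifetime_s`,
#'   `n_transitions`, `censored`.
#' @export
simulate_bond_events <- function(forces, n_per_force,
                                 params = trace_sim_params(), seed = 1) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(force = forces, rep = seq_len(n_per_force))
    rate <- dual_pathway_rate(grid$force, params$k_c, params$x_c,
                              params$k_s, params$x_s, params$kBT)
    tibble::tibble(label = as.character(seq_len(nrow(grid))),
                   clamp_force_pN = grid$force,
                   lifetime_s = rexp(nrow(grid), rate),
                   n_transitions = 0L, censored = FALSE)
  })
}
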