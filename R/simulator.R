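#' Build cortical input events for a network
#'
#' Gives every cortical synapse of the network its own jitter-and-shift
#' train. Per-synapse frequencies are derived from the summed target rates:
#' `msn_glut_hz` is the total glutamatergic input rate per MSN (summed over
#' its synapses), and likewise for the FSI rates, matching the convention
#' that input frequency is reported as the summed number of inputs per
#' second.
#'
#' @param network a `striatal_network`.
#' @param duration_ms train window.
#' @param msn_glut_hz summed glutamatergic input rate per MSN, Hz.
#' @param fsi_glut_hz,fsi_gaba_hz summed rates per FSI, Hz.
#' @param ensemble optional [ensemble_inputs()] plan over the MSNs: member
#'   cells additionally receive the plan's bit-identical rhythm train on a
#'   fraction of their glutamatergic synapses.
#' @param rhythm_syn_frac fraction of an ensemble cell's glutamatergic
#'   synapses carrying the shared rhythm.
#' @param fsi_plan optional [synchronized_fsi_inputs()] plan replacing the
#'   FSI glutamatergic trains.
#' @param msn_rate_jitter optional per-cell multiplicative spread of the MSN
#'   drive: per-cell rate = `msn_glut_hz * runif(1 - j, 1 + j)`.
#' @param seed master seed (streams per-synapse train seeds).
#' @return a `network_inputs` object: `events` data.frame (`syn_id`,
#'   `time_ms`) over the network's cortical synapse ids, plus metadata.
#' @export
make_network_inputs <- function(network, duration_ms = 2000,
                                msn_glut_hz = 1000, fsi_glut_hz = 600,
                                fsi_gaba_hz = fsi_glut_hz,
                                ensemble = NULL, rhythm_syn_frac = 0.25,
                                fsi_plan = NULL, msn_rate_jitter = 0,
                                seed = 1L) {
  cort <- network$cortical
  n_msn <- nrow(network$msn_positions)
  n_fsi <- nrow(network$fsi_positions)
  n_msn_glut <- network$n_msn_glut
  syn_seed <- derive_seed(seed, "inputs")
  cell_rate <- rep(msn_glut_hz, n_msn)
  if (msn_rate_jitter > 0) {
    cell_rate <- with_seed(derive_seed(seed, "noise"), {
      msn_glut_hz * stats::runif(n_msn, 1 - msn_rate_jitter,
                                 1 + msn_rate_jitter)
    })
  }
  times <- vector("list", nrow(cort))
  is_msn_glut <- cort$cell_type == "MSN"
  is_fsi <- !is_msn_glut
  # MSN glutamatergic trains
  idx <- which(is_msn_glut)
  for (k in idx) {
    f <- cell_rate[cort$cell[k]] / n_msn_glut
    times[[k]] <- generate_train(
      input_train_spec(f, duration_ms, jitter_sd = 250 / f,
                       shift_max = 1000 / f,
                       seed = derive_seed(syn_seed, k)))
  }
  # shared rhythm onto the first rhythm_syn_frac of each member's synapses
  rhythm <- NULL
  if (!is.null(ensemble)) {
    rhythm <- ensemble$shared_rhythm
    n_r <- max(1L, round(rhythm_syn_frac * n_msn_glut))
    for (cell in which(ensemble$membership)) {
      k <- which(is_msn_glut & cort$cell == cell)[seq_len(n_r)]
      for (j in k) times[[j]] <- sort(c(times[[j]], rhythm))
    }
  }
  # FSI trains
  if (n_fsi > 0) {
    for (kind in c("cortical_glut", "cortical_gaba")) {
      tot <- if (kind == "cortical_glut") fsi_glut_hz else fsi_gaba_hz
      for (cell in seq_len(n_fsi)) {
        k <- which(is_fsi & cort$kind == kind & cort$cell == cell)
        if (kind == "cortical_glut" && !is.null(fsi_plan)) {
          tr <- fsi_plan$trains[[cell]]
          m <- min(length(k), length(tr))
          for (j in seq_len(m)) times[[k[j]]] <- tr[[j]]
        } else if (kind == "cortical_gaba" && !is.null(fsi_plan) &&
                   !is.null(fsi_plan$gaba_trains)) {
          tr <- fsi_plan$gaba_trains
          m <- min(length(k), length(tr))
          for (j in seq_len(m)) times[[k[j]]] <- tr[[j]]
        } else if (tot > 0) {
          f <- tot / length(k)
          for (j in k) {
            times[[j]] <- generate_train(
              input_train_spec(f, duration_ms, jitter_sd = 250 / f,
                               shift_max = 1000 / f,
                               seed = derive_seed(syn_seed, j + nrow(cort))))
          }
        } else {
          for (j in k) times[[j]] <- numeric(0)
        }
      }
    }
  }
  n_ev <- lengths(times)
  structure(list(events = data.frame(
    syn_id = rep(cort$syn_id, n_ev),
    time_ms = unlist(times, use.names = FALSE)),
    duration_ms = duration_ms,
    rhythm = rhythm,
    membership = if (is.null(ensemble)) NULL else ensemble$membership,
    burst_onsets = if (is.null(fsi_plan)) NULL else fsi_plan$burst_onsets,
    seed = as.integer(seed)),
    class = "network_inputs")
}

# Assemble flat compartment/synapse arrays and call the C++ core.
# Returns list(raster = list per global cell, traces, spikes, ...)
run_core <- function(network, inputs, config,
                     msn_dyn = cell_dynamics(network$msn_scaffold),
                     fsi_dyn = cell_dynamics(network$fsi_scaffold),
                     syn_ampa = synapse_params("AMPA"),
                     syn_nmda = synapse_params("NMDA"),
                     syn_gaba = synapse_params("GABA_A"),
                     syn_ampa_fsi = synapse_params("AMPA",
                                                   g_max = 0.00020),
                     syn_nmda_fsi = syn_nmda,
                     iclamp = NULL) {
  n_msn <- nrow(network$msn_positions)
  n_fsi <- nrow(network$fsi_positions)
  n_cell <- n_msn + n_fsi
  nm <- nrow(msn_dyn$scaffold$compartments)
  nf <- nrow(fsi_dyn$scaffold$compartments)
  offs <- c(if (n_msn > 0) (seq_len(n_msn) - 1L) * nm,
            if (n_fsi > 0) n_msn * nm + (seq_len(n_fsi) - 1L) * nf)
  ctype <- rep(c("MSN", "FSI"), c(n_msn, n_fsi))

  rep_cell <- function(v_msn, v_fsi) c(rep(v_msn, n_msn), rep(v_fsi, n_fsi))
  par_local <- function(dyn) {
    p <- dyn$scaffold$compartments$parent_id
    ifelse(is.na(p), 0L, as.integer(p)) # 0 marks root; 1-based otherwise
  }
  pm <- par_local(msn_dyn); pf <- par_local(fsi_dyn)
  parent <- integer(n_cell * 0)
  parent <- c(if (n_msn > 0) as.vector(
    vapply(seq_len(n_msn), function(c)
      ifelse(pm == 0L, -1L, pm - 1L + offs[c]), integer(nm))),
    if (n_fsi > 0) as.vector(
      vapply(seq_len(n_fsi), function(c)
        ifelse(pf == 0L, -1L, pf - 1L + offs[n_msn + c]), integer(nf))))
  cap <- c(rep(msn_dyn$cap_nf, n_msn), rep(fsi_dyn$cap_nf, n_fsi))
  gl <- c(rep(msn_dyn$g_leak_us, n_msn), rep(fsi_dyn$g_leak_us, n_fsi))
  el <- c(rep(rep(msn_dyn$e_leak_mv, nm), n_msn),
          rep(rep(fsi_dyn$e_leak_mv, nf), n_fsi))
  gax <- c(rep(ifelse(is.na(msn_dyn$g_axial_us), 0, msn_dyn$g_axial_us),
               n_msn),
           rep(ifelse(is.na(fsi_dyn$g_axial_us), 0, fsi_dyn$g_axial_us),
               n_fsi))

  dt <- config$dt_ms
  n_steps <- as.integer(round(config$duration_ms / dt))

  # --- synapses ---------------------------------------------------------
  syn_comp <- integer(0); syn_w <- numeric(0)
  syn_tr <- numeric(0); syn_td <- numeric(0); syn_e <- numeric(0)
  add_syn <- function(comp, p) {
    n <- length(comp)
    syn_comp <<- c(syn_comp, comp)
    syn_w <<- c(syn_w, rep(p$g_max * syn_peak_norm(p$tau_rise, p$tau_decay),
                           n))
    syn_tr <<- c(syn_tr, rep(p$tau_rise, n))
    syn_td <<- c(syn_td, rep(p$tau_decay, n))
    syn_e <<- c(syn_e, rep(p$e_rev, n))
    length(syn_comp) - n + seq_len(n) # new indices (1-based)
  }

  cort <- network$cortical
  cort_cell_global <- ifelse(cort$cell_type == "MSN", cort$cell,
                             n_msn + cort$cell)
  cort_comp_global <- offs[cort_cell_global] + cort$comp - 1L # 0-based
  glut <- cort$kind == "cortical_glut"
  is_fsi_tgt <- cort$cell_type == "FSI"
  gi_m <- which(glut & !is_fsi_tgt); gi_f <- which(glut & is_fsi_tgt)
  bi <- which(!glut)
  idx_ampa_m <- add_syn(cort_comp_global[gi_m] + 1L, syn_ampa)
  idx_nmda_m <- if (syn_nmda$g_max > 0) {
    add_syn(cort_comp_global[gi_m] + 1L, syn_nmda)
  } else integer(0)
  idx_ampa_f <- add_syn(cort_comp_global[gi_f] + 1L, syn_ampa_fsi)
  idx_nmda_f <- if (syn_nmda_fsi$g_max > 0) {
    add_syn(cort_comp_global[gi_f] + 1L, syn_nmda_fsi)
  } else integer(0)
  idx_cgaba <- add_syn(cort_comp_global[bi] + 1L, syn_gaba)
  # map cortical syn_id -> the synapse indices receiving its events
  syn_map <- vector("list", max(cort$syn_id))
  for (q in seq_along(gi_m)) {
    syn_map[[cort$syn_id[gi_m[q]]]] <- c(idx_ampa_m[q],
                                         if (length(idx_nmda_m))
                                           idx_nmda_m[q])
  }
  for (q in seq_along(gi_f)) {
    syn_map[[cort$syn_id[gi_f[q]]]] <- c(idx_ampa_f[q],
                                         if (length(idx_nmda_f))
                                           idx_nmda_f[q])
  }
  for (q in seq_along(bi)) syn_map[[cort$syn_id[bi[q]]]] <- idx_cgaba[q]

  # network contacts (lateral / feedforward), honouring the toggles
  conns <- network$connections
  keep_kind <- c(if (config$lateral_on) "lateral",
                 if (config$feedforward_on) "feedforward")
  conns <- conns[conns$kind %in% keep_kind, , drop = FALSE]
  contacts <- network$contacts[network$contacts$conn_id %in% conns$conn_id, ,
                               drop = FALSE]
  m <- match(contacts$conn_id, conns$conn_id)
  src_global <- ifelse(conns$kind[m] == "lateral", conns$source[m],
                       n_msn + conns$source[m])
  tgt_comp <- offs[conns$target[m]] + contacts$comp - 1L
  idx_net <- add_syn(tgt_comp + 1L, syn_gaba)
  delay_steps <- as.integer(round(conns$delay_ms[m] / dt))

  # --- events -----------------------------------------------------------
  ev <- inputs$events
  ev_step <- as.integer(round(ev$time_ms / dt))
  reps <- lengths(syn_map[ev$syn_id])
  ev_syn <- unlist(syn_map[ev$syn_id], use.names = FALSE)
  ev_step <- rep(ev_step, reps)

  ic <- if (is.null(iclamp)) {
    list(comp = integer(0), amp = numeric(0), s0 = integer(0),
         s1 = integer(0))
  } else {
    list(comp = offs[iclamp$cell] + iclamp$comp - 1L,
         amp = iclamp$amp_na,
         s0 = as.integer(round(iclamp$start_ms / dt)),
         s1 = as.integer(round(iclamp$end_ms / dt)))
  }

  res <- .sim_core(parent, cap, gl, el, gax,
                   offs, rep_cell(msn_dyn$v_threshold_mv,
                                  fsi_dyn$v_threshold_mv),
                   rep_cell(msn_dyn$v_reset_mv, fsi_dyn$v_reset_mv),
                   rep_cell(msn_dyn$t_refrac_ms, fsi_dyn$t_refrac_ms),
                   syn_comp - 1L, syn_w, syn_tr, syn_td, syn_e,
                   ev_syn - 1L, ev_step,
                   src_global - 1L, idx_net - 1L, delay_steps,
                   ic$comp, ic$amp, ic$s0, ic$s1,
                   dt, n_steps, config$record_traces - 1L,
                   isTRUE(config$log_events))

  raster <- vector("list", n_cell)
  for (c in seq_len(n_cell)) raster[[c]] <- numeric(0)
  if (length(res$spike_cell) > 0) {
    sp <- split(res$spike_time, res$spike_cell)
    for (nm2 in names(sp)) raster[[as.integer(nm2)]] <- sort(sp[[nm2]])
  }
  traces <- res$traces
  attr(traces, "dt_ms") <- dt
  attr(traces, "cells") <- config$record_traces
  attr(traces, "time_ms") <- seq(0, by = dt, length.out = n_steps + 1L)
  out <- list(raster = raster, traces = traces, n_msn = n_msn,
              n_fsi = n_fsi, config = config, cell_type = ctype)
  if (isTRUE(config$log_events)) {
    n_cort_syn <- length(idx_ampa_m) + length(idx_nmda_m) +
      length(idx_ampa_f) + length(idx_nmda_f) + length(idx_cgaba)
    out$events <- data.frame(
      syn = res$event_syn + 1L,
      time_ms = (res$event_step + 1L) * dt,
      comp = syn_comp[res$event_syn + 1L],
      kind = c(rep("cortical", n_cort_syn),
               conns$kind[m])[res$event_syn + 1L])
  }
  structure(out, class = "sim_result")
}

#' Simulate the network
#'
#' Event-driven simulation of the full network on the reduced dynamics
#' tier: cortical input events drive two-state synapses on the passive
#' cable trees; somatic threshold crossings emit spikes that are delivered
#' to lateral / feedforward GABA-A contacts after the conduction delay
#' (quantized to the dt grid). The `lateral_on` / `feedforward_on` toggles
#' in `config` silence the respective connection kinds without altering
#' anything else, enabling paired ON/OFF comparisons on identical inputs.
#' The run is fully deterministic given network, inputs and config.
#'
#' @param network a `striatal_network`.
#' @param inputs a `network_inputs` object (see [make_network_inputs()]).
#' @param config a [sim_config()].
#' @param ... dynamics and synapse parameter overrides passed to the core
#'   (`msn_dyn`, `fsi_dyn`, `syn_ampa`, `syn_nmda`, `syn_gaba`,
#'   `syn_ampa_fsi`, `syn_nmda_fsi`, `iclamp`). The `_fsi` variants apply
#'   to cortical glutamatergic synapses onto FSIs (default scaled from
#'   `syn_ampa`); GABA-A parameters are shared by lateral, feedforward and
#'   cortical GABAergic synapses.
#' @return a `sim_result`: `raster` (list of sorted spike times per global
#'   cell id; MSNs first, then FSIs), `traces` (matrix, one row per
#'   recorded cell, with `dt_ms`/`time_ms` attributes), and bookkeeping.
#' @export
run_network <- function(network, inputs, config = sim_config(), ...) {
  if (max(c(0L, config$record_traces)) >
      nrow(network$msn_positions) + nrow(network$fsi_positions)) {
    stop("record_traces refers to cells beyond the network")
  }
  if (inputs$duration_ms < config$duration_ms) {
    stop("inputs cover ", inputs$duration_ms,
         " ms but the simulation lasts ", config$duration_ms, " ms")
  }
  run_core(network, inputs, config, ...)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim result: %d cells, %d spikes, %.0f ms at dt %.3f ms>\n",
              length(x$raster), sum(lengths(x$raster)),
              x$config$duration_ms, x$config$dt_ms))
  invisible(x)
}

#' Inputs for the paired-subtraction IPSP protocol
#'
#' One designated presynaptic cell receives enough depolarizing input to
#' spike: a synchronized glutamatergic volley (one event on each of
#' `drive_n_syn` of its input synapses, at independent uniform times in
#' `[drive_start_ms, drive_start_ms + drive_len_ms]`) elicits a spike at a
#' known time and leaves the rest of the recording clean, so the
#' post-spike window holds a single synaptic response. Every other cell
#' receives a unique, weaker full-length input train placing it at a
#' potential below firing threshold (per-cell summed rates drawn uniformly
#' over `bg_range_hz`, giving a spread of subthreshold baselines). FSIs
#' other than a designated FSI get weak drive so they stay silent.
#'
#' @param network a `striatal_network`.
#' @param presyn_cell global cell id (MSN index, or `n_msn + fsi` index).
#' @param duration_ms window.
#' @param drive_n_syn number of the driven cell's glutamatergic synapses
#'   firing in the trigger volley (the FSI default is smaller because the
#'   cell is more excitable).
#' @param drive_start_ms,drive_len_ms placement of the drive volley.
#' @param bg_range_hz length-2 range of summed background rates for the
#'   non-driven MSNs.
#' @param fsi_bg_hz summed background rate for non-driven FSIs.
#' @param seed master seed.
#' @return a `network_inputs` object.
#' @export
ipsp_protocol_inputs <- function(network, presyn_cell, duration_ms = 250,
                                 drive_n_syn = if (presyn_cell <=
                                                   nrow(network$msn_positions))
                                   84L else 20L,
                                 drive_start_ms = 40, drive_len_ms = 2,
                                 bg_range_hz = c(150, 750),
                                 fsi_bg_hz = 60, seed = 1L) {
  n_msn <- nrow(network$msn_positions)
  n_fsi <- nrow(network$fsi_positions)
  cort <- network$cortical
  n_fsi_glut <- if (n_fsi > 0)
    sum(cort$cell_type == "FSI" & cort$kind == "cortical_glut" &
          cort$cell == 1L) else 0L
  rates <- with_seed(derive_seed(seed, "noise"), {
    stats::runif(n_msn, bg_range_hz[1], bg_range_hz[2])
  })
  syn_seed <- derive_seed(seed, "drive")
  volley <- function(n_syn, k0) {
    # one event per participating synapse, uniform over the trigger window
    t_ev <- with_seed(derive_seed(syn_seed, k0), {
      drive_start_ms + stats::runif(n_syn, 0, drive_len_ms)
    })
    out <- lapply(seq_len(n_syn), function(q)
      if (q <= drive_n_syn) t_ev[q] else numeric(0))
    out
  }
  times <- vector("list", nrow(cort))
  driven_msn <- presyn_cell <= n_msn
  drive_trains <- NULL
  for (k in seq_len(nrow(cort))) {
    if (cort$cell_type[k] == "MSN") {
      if (driven_msn && cort$cell[k] == presyn_cell) {
        if (is.null(drive_trains)) {
          drive_trains <- volley(network$n_msn_glut, 1L)
        }
        times[[k]] <- drive_trains[[sum(cort$cell[seq_len(k)] ==
                                          presyn_cell &
                                          cort$cell_type[seq_len(k)] ==
                                          "MSN")]]
      } else {
        f <- rates[cort$cell[k]] / network$n_msn_glut
        times[[k]] <- generate_train(
          input_train_spec(f, duration_ms, jitter_sd = 250 / f,
                           shift_max = 1000 / f,
                           seed = derive_seed(syn_seed, k)))
      }
    } else if (cort$kind[k] == "cortical_glut") {
      if (!driven_msn && presyn_cell == n_msn + cort$cell[k]) {
        if (is.null(drive_trains)) {
          drive_trains <- volley(n_fsi_glut, 2L)
        }
        times[[k]] <- drive_trains[[sum(cort$cell[seq_len(k)] ==
                                          cort$cell[k] &
                                          cort$kind[seq_len(k)] ==
                                          "cortical_glut" &
                                          cort$cell_type[seq_len(k)] ==
                                          "FSI")]]
      } else if (fsi_bg_hz > 0) {
        f <- fsi_bg_hz / n_fsi_glut
        times[[k]] <- generate_train(
          input_train_spec(f, duration_ms, jitter_sd = 250 / f,
                           shift_max = 1000 / f,
                           seed = derive_seed(syn_seed, k)))
      } else times[[k]] <- numeric(0)
    } else times[[k]] <- numeric(0)
  }
  n_ev <- lengths(times)
  structure(list(events = data.frame(
    syn_id = rep(cort$syn_id, n_ev),
    time_ms = unlist(times, use.names = FALSE)),
    duration_ms = duration_ms, rhythm = NULL, membership = NULL,
    burst_onsets = NULL, seed = as.integer(seed)),
    class = "network_inputs")
}

#' Paired inhibition ON/OFF run for IPSP extraction
#'
#' Runs the same network on the same inputs twice, toggling one inhibition
#' kind, and returns time-aligned somatic traces for all recorded MSNs
#' together with the designated presynaptic cell's first spike time. The
#' difference `trace_on - trace_off` is identically zero before the first
#' presynaptic spike plus the conduction delay (causality), and afterwards
#' isolates the postsynaptic potentials contributed by the toggled
#' projection.
#'
#' @param network a `striatal_network`.
#' @param inputs inputs from [ipsp_protocol_inputs()] (one suprathreshold
#'   cell).
#' @param config a [sim_config()]; its `record_traces` defaults to all
#'   MSNs except the presynaptic cell.
#' @param presyn_cell global id of the cell driven above threshold.
#' @param kind `"lateral"` or `"feedforward"`: which projection is toggled.
#' @param check_silent error if any non-designated cell spikes (the
#'   protocol requires all other cells subthreshold).
#' @param ... overrides forwarded to [run_network()].
#' @return list: `trace_on`, `trace_off` (aligned matrices), `presyn_spike`
#'   (ms), `recorded` (cell ids), `dt_ms`.
#' @export
paired_ipsp_run <- function(network, inputs, config = sim_config(
                              duration_ms = inputs$duration_ms,
                              dt_ms = 0.025),
                            presyn_cell, kind = c("lateral", "feedforward"),
                            check_silent = TRUE, ...) {
  kind <- match.arg(kind)
  n_msn <- nrow(network$msn_positions)
  if (length(config$record_traces) == 0) {
    config$record_traces <- setdiff(seq_len(n_msn), presyn_cell)
  }
  cfg_on <- config; cfg_off <- config
  if (kind == "lateral") {
    cfg_on$lateral_on <- TRUE; cfg_off$lateral_on <- FALSE
  } else {
    cfg_on$feedforward_on <- TRUE; cfg_off$feedforward_on <- FALSE
  }
  run_on <- run_network(network, inputs, cfg_on, ...)
  run_off <- run_network(network, inputs, cfg_off, ...)
  presyn_spikes <- run_off$raster[[presyn_cell]]
  if (length(presyn_spikes) == 0) {
    stop("designated presynaptic cell ", presyn_cell,
         " did not spike within the simulation")
  }
  if (check_silent) {
    others <- setdiff(seq_along(run_off$raster), presyn_cell)
    n_bad <- sum(lengths(run_off$raster[others]) > 0)
    if (n_bad > 0) {
      stop(n_bad, " non-designated cell(s) spiked; lower the background ",
           "drive so all other cells stay subthreshold")
    }
  }
  list(trace_on = run_on$traces, trace_off = run_off$traces,
       presyn_spike = presyn_spikes[1],
       recorded = config$record_traces, dt_ms = config$dt_ms)
}

#' Write traces to a TSV container
#'
#' Long format (`cell`, `time_ms`, `v_mv`) with a JSON sidecar holding dt
#' and units.
#'
#' @param traces trace matrix from a `sim_result`.
#' @param path output file.
#' @export
write_traces_tsv <- function(traces, path) {
  tm <- attr(traces, "time_ms"); cells <- attr(traces, "cells")
  df <- data.frame(cell = rep(cells, each = length(tm)),
                   time_ms = rep(tm, length(cells)),
                   v_mv = as.vector(t(traces)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(dt_ms = attr(traces, "dt_ms"),
                            units = list(time = "ms", voltage = "mV")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
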