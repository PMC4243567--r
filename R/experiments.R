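#' Experiment configuration
#'
#' One configuration object drives the three experiment families: input
#' -frequency rate curves with an inhibition kind toggled, the lateral
#' -inhibition ensemble experiment (half the MSNs entrained to a shared
#' 8 Hz rhythm), and the feedforward experiments with synchronized
#' (identical-input, bursting every 125 ms) or desynchronized
#' (independent-input) FSIs. The desk-scale default network is the 512-MSN
#' cube (8 points per side); the full 2744-MSN network is supported but
#' long-running.
#'
#' @param experiment one of `"rate_curves"`, `"lateral_ensemble"`,
#'   `"feedforward_sync"`, `"feedforward_desync"`.
#' @param n_per_side MSN lattice points per side.
#' @param duration_ms simulated time per run.
#' @param dt_ms integration step.
#' @param msn_freqs_hz swept summed MSN glutamatergic rates (rate curves).
#' @param msn_glut_hz summed MSN rate for the ensemble/feedforward runs
#'   (default places the reduced-tier MSNs in the active regime).
#' @param fsi_glut_hz summed FSI glutamatergic rate (default 300 Hz for
#'   the rate curves and feedforward designs, 600 Hz for the lateral
#'   ensemble design).
#' @param fsi_burst_gain in-burst input multiplier for synchronized FSI
#'   bursts, calibrated so the synchronized mean FSI rate is at least the
#'   desynchronized one (the sync/desync contrast is read at matched or
#'   conservatively higher sync rate).
#' @param rhythm_freq shared ensemble rhythm, Hz.
#' @param ensemble_fraction fraction of MSNs in the ensemble.
#' @param fsi_burst_period ms between synchronized FSI bursts.
#' @param fsi_burst_len ms of FSI drive per burst.
#' @param toggle which inhibition kind the paired runs toggle
#'   (`"lateral"` or `"feedforward"`).
#' @param seed master seed.
#' @param out_dir optional output directory for artifacts.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(experiment = c("rate_curves",
                                             "lateral_ensemble",
                                             "feedforward_sync",
                                             "feedforward_desync"),
                              n_per_side = 8L, duration_ms = 2000,
                              dt_ms = 0.1,
                              msn_freqs_hz = c(600, 800, 1000, 1100),
                              msn_glut_hz = 1400,
                              fsi_glut_hz = NULL,
                              rhythm_freq = 8, ensemble_fraction = 0.5,
                              fsi_burst_period = 125, fsi_burst_len = 40,
                              fsi_burst_gain = 3.5,
                              toggle = c("lateral", "feedforward"),
                              seed = 1L, out_dir = NULL) {
  experiment <- match.arg(experiment)
  toggle <- match.arg(toggle)
  if (is.null(fsi_glut_hz)) {
    fsi_glut_hz <- if (experiment == "lateral_ensemble") 600 else 300
  }
  stopifnot(all(msn_freqs_hz > 0), msn_glut_hz > 0, fsi_glut_hz >= 0,
            rhythm_freq > 0, fsi_burst_period > 0)
  structure(list(experiment = experiment,
                 n_per_side = as.integer(n_per_side),
                 duration_ms = duration_ms, dt_ms = dt_ms,
                 msn_freqs_hz = msn_freqs_hz, msn_glut_hz = msn_glut_hz,
                 fsi_glut_hz = fsi_glut_hz, rhythm_freq = rhythm_freq,
                 ensemble_fraction = ensemble_fraction,
                 fsi_burst_period = fsi_burst_period,
                 fsi_burst_len = fsi_burst_len,
                 fsi_burst_gain = fsi_burst_gain,
                 toggle = toggle, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

build_experiment_network <- function(config) {
  build_network(placement_params(n_per_side = config$n_per_side,
                                 seed = config$seed))
}

#' Rate curves across an input-frequency sweep
#'
#' For each swept summed MSN input rate, runs the network twice on
#' identical inputs with the configured inhibition kind active and
#' inactive, and reports the mean and across-cell standard deviation of
#' the MSN firing-rate distribution per condition.
#'
#' @param config an [experiment_config()].
#' @param network optional prebuilt network (rebuilt from config if
#'   missing).
#' @return list: `rates` data.frame (freq_hz, condition, mean_hz, sd_hz),
#'   `manifest`.
#' @export
run_rate_curves <- function(config = experiment_config("rate_curves"),
                            network = build_experiment_network(config)) {
  rows <- list()
  n_msn <- nrow(network$msn_positions)
  for (i in seq_along(config$msn_freqs_hz)) {
    f <- config$msn_freqs_hz[i]
    inputs <- make_network_inputs(network, config$duration_ms,
                                  msn_glut_hz = f,
                                  fsi_glut_hz = config$fsi_glut_hz,
                                  msn_rate_jitter = 0.2,
                                  seed = derive_seed(config$seed, i))
    for (cond in c("on", "off")) {
      cfg <- sim_config(config$duration_ms, config$dt_ms,
                        lateral_on = !(config$toggle == "lateral" &&
                                         cond == "off"),
                        feedforward_on = !(config$toggle == "feedforward" &&
                                             cond == "off"),
                        seed = config$seed)
      res <- run_network(network, inputs, cfg)
      rs <- rate_stats(res$raster, config$duration_ms, seq_len(n_msn))
      rows[[length(rows) + 1L]] <- data.frame(
        freq_hz = f, condition = cond, mean_hz = rs$mean_hz,
        sd_hz = rs$sd_hz)
    }
  }
  list(rates = do.call(rbind, rows),
       manifest = run_manifest(config, network))
}

#' Lateral-inhibition ensemble experiment
#'
#' Half of the MSNs (the first `ensemble_fraction`) receive a shared,
#' precisely timed rhythm on top of distinct noise; the rest receive
#' distinct noise only; FSIs receive distinct noisy input. Paired runs
#' toggle lateral inhibition on identical inputs. Reports peri-event
#' histograms of non-ensemble spiking aligned to ensemble spikes, the
#' post-ensemble-spike suppression fraction in the 5-30 ms window, and the
#' ensemble spike-timing standard deviation with and without lateral
#' inhibition.
#'
#' @param config an [experiment_config()].
#' @param network optional prebuilt network.
#' @return list: `raster_on`, `raster_off`, `peh_on`, `peh_off`,
#'   `suppression`, `sd_on_ms`, `sd_off_ms`, `rhythm`, `membership`,
#'   `manifest`.
#' @export
run_lateral_ensemble <- function(config =
                                   experiment_config("lateral_ensemble"),
                                 network = build_experiment_network(config)) {
  n_msn <- nrow(network$msn_positions)
  plan <- ensemble_inputs(n_msn, config$ensemble_fraction,
                          config$rhythm_freq,
                          uncorrelated_spec(config$msn_glut_hz,
                                            config$duration_ms),
                          seed = config$seed)
  inputs <- make_network_inputs(network, config$duration_ms,
                                msn_glut_hz = config$msn_glut_hz,
                                fsi_glut_hz = config$fsi_glut_hz,
                                ensemble = plan,
                                seed = derive_seed(config$seed, "inputs"))
  on <- run_network(network, inputs, sim_config(
    config$duration_ms, config$dt_ms, lateral_on = TRUE,
    seed = config$seed))
  off <- run_network(network, inputs, sim_config(
    config$duration_ms, config$dt_ms, lateral_on = FALSE,
    seed = config$seed))
  ens <- which(plan$membership)
  non <- which(!plan$membership)
  # ensemble spikes of each run are its own alignment events; the OFF-run
  # ensemble spikes serve as the common event set for the paired fraction
  ev_off <- sort(unlist(off$raster[ens], use.names = FALSE))
  ev_on <- sort(unlist(on$raster[ens], use.names = FALSE))
  peh_off <- perievent_histogram(off$raster, ev_off, c(-50, 50), 5, non)
  peh_on <- perievent_histogram(on$raster, ev_on, c(-50, 50), 5, non)
  sup <- suppression_fraction(on$raster, off$raster, ev_off,
                              window = c(5, 30), cells = non)
  sd_on <- ensemble_spike_sd(on$raster, plan$shared_rhythm, cells = ens)
  sd_off <- ensemble_spike_sd(off$raster, plan$shared_rhythm, cells = ens)
  list(raster_on = on$raster, raster_off = off$raster,
       peh_on = peh_on, peh_off = peh_off, suppression = sup,
       sd_on_ms = sd_on, sd_off_ms = sd_off,
       rhythm = plan$shared_rhythm, membership = plan$membership,
       manifest = run_manifest(config, network))
}

#' Feedforward-inhibition experiments
#'
#' `fsi_mode = "identical"`: every FSI receives exactly the same input and
#' spikes in perfectly synchronized bursts every `fsi_burst_period` ms;
#' all MSNs receive distinct noise. Reports MSN peri-event histograms
#' aligned to the burst onsets with feedforward inhibition toggled.
#'
#' `fsi_mode = "independent"`: FSIs receive distinct noisy trains; half
#' the MSNs form an 8 Hz ensemble. Reports ensemble vs non-ensemble
#' suppression fractions aligned to the OFF-run ensemble spikes.
#'
#' @param config an [experiment_config()].
#' @param fsi_mode `"identical"` or `"independent"`.
#' @param network optional prebuilt network.
#' @return list of rasters, histograms/suppression summaries and the
#'   manifest.
#' @export
run_feedforward <- function(config = experiment_config("feedforward_sync"),
                            fsi_mode = c("identical", "independent"),
                            network = build_experiment_network(config)) {
  fsi_mode <- match.arg(fsi_mode)
  n_msn <- nrow(network$msn_positions)
  n_fsi <- nrow(network$fsi_positions)
  fsi_plan <- synchronized_fsi_inputs(
    n_fsi, mode = fsi_mode, burst_period = config$fsi_burst_period,
    burst_len = config$fsi_burst_len, burst_gain = config$fsi_burst_gain,
    noise_freq = config$fsi_glut_hz / 84,
    n_syn = 84L, duration = config$duration_ms,
    seed = derive_seed(config$seed, "drive"))
  plan <- NULL
  if (fsi_mode == "independent") {
    plan <- ensemble_inputs(n_msn, config$ensemble_fraction,
                            config$rhythm_freq,
                            uncorrelated_spec(config$msn_glut_hz,
                                              config$duration_ms),
                            seed = config$seed)
  }
  inputs <- make_network_inputs(network, config$duration_ms,
                                msn_glut_hz = config$msn_glut_hz,
                                fsi_glut_hz = config$fsi_glut_hz,
                                ensemble = plan, fsi_plan = fsi_plan,
                                seed = derive_seed(config$seed, "inputs"))
  on <- run_network(network, inputs, sim_config(
    config$duration_ms, config$dt_ms, feedforward_on = TRUE,
    seed = config$seed))
  off <- run_network(network, inputs, sim_config(
    config$duration_ms, config$dt_ms, feedforward_on = FALSE,
    seed = config$seed))
  out <- list(raster_on = on$raster, raster_off = off$raster,
              fsi_mode = fsi_mode,
              manifest = run_manifest(config, network))
  if (fsi_mode == "identical") {
    onsets <- fsi_plan$burst_onsets
    out$peh_on <- perievent_histogram(on$raster, onsets, c(-20, 60), 5,
                                      seq_len(n_msn))
    out$peh_off <- perievent_histogram(off$raster, onsets, c(-20, 60), 5,
                                       seq_len(n_msn))
    out$burst_onsets <- onsets
    out$suppression <- suppression_fraction(on$raster, off$raster, onsets,
                                            window = c(5, 30),
                                            cells = seq_len(n_msn))
  } else {
    ens <- which(plan$membership); non <- which(!plan$membership)
    ev <- sort(unlist(off$raster[ens], use.names = FALSE))
    out$suppression_ensemble <- suppression_fraction(
      on$raster, off$raster, ev, window = c(5, 30), cells = ens)
    out$suppression_nonensemble <- suppression_fraction(
      on$raster, off$raster, ev, window = c(5, 30), cells = non)
    out$membership <- plan$membership
    out$rhythm <- plan$shared_rhythm
  }
  out
}

#' Run manifest: everything needed to reproduce a run bit-exactly
#'
#' Records the configuration, the master seed and the derived per-stage
#' sub-seeds, and the package version. Rebuilding the network from the
#' manifest reproduces it bit-exactly.
#'
#' @param config an [experiment_config()].
#' @param network the built network (its build parameters are snapshotted).
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(config, network) {
  stages <- c("fsi_placement", "lateral", "feedforward", "cortical",
              "inputs", "drive", "noise")
  structure(list(
    version = as.character(utils::packageVersion("striatnet")),
    config = unclass(config),
    placement = network$params, topology = network$topo,
    n_msn_glut = network$n_msn_glut,
    sub_seeds = stats::setNames(
      lapply(stages, function(s) derive_seed(network$params$seed, s)),
      stages)),
    class = "run_manifest")
}

#' Write / read a run manifest (JSON)
#'
#' @param manifest a `run_manifest`.
#' @param path file path.
#' @return `read_manifest` returns the manifest; a version mismatch with
#'   the installed package emits a warning.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cur <- as.character(utils::packageVersion("striatnet"))
  if (!identical(doc$version, cur)) {
    warning("manifest written by version ", doc$version,
            ", current version is ", cur)
  }
  doc$placement <- lapply(doc$placement, function(x)
    if (is.numeric(x) && all(x == round(x))) as.integer(x) else x)
  tp <- doc$topology
  tp$lateral_contact_pmf <- as.numeric(unlist(tp$lateral_contact_pmf))
  tp$ff_contact_range <- as.integer(unlist(tp$ff_contact_range))
  doc$topology <- tp
  structure(doc, class = "run_manifest")
}

#' Rebuild the network recorded in a manifest
#'
#' @param manifest a `run_manifest` (e.g. from [read_manifest()]).
#' @return a `striatal_network` identical to the one the manifest was
#'   written from.
#' @export
rebuild_network <- function(manifest) {
  build_network(params = do.call(placement_params,
                                 manifest$placement[c("n_per_side",
                                                      "spacing", "fsi_per",
                                                      "msn_per", "seed")]),
                topo = do.call(topology_params, manifest$topology),
                n_msn_glut = manifest$n_msn_glut)
}
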