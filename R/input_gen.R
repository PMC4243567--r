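#' Jitter-and-shift synaptic input train generation
#'
#' Presynaptic input trains are generated by a three-step algorithm rather
#' than a Poisson process, so partially synchronized but still randomized
#' trains can be produced: (1) a constant interspike-interval (ISI) scaffold
#' at the desired frequency; (2) each spike time is re-drawn from a Gaussian
#' centered at its original time (sd = `jitter_sd`); (3) the whole train is
#' shifted by a single uniform draw in `[0, shift_max]`. Spikes outside
#' `[0, duration]` are dropped (never wrapped). Uncorrelated input uses a
#' large jitter (ISI/4) and a large shift (one ISI); rhythmic shared input
#' uses zero jitter and zero shift.
#'
#' @name input_gen
NULL

#' Specification of one input train
#'
#' @param frequency spikes per second (Hz), > 0.
#' @param duration train window, milliseconds.
#' @param jitter_sd Gaussian re-draw standard deviation, ms.
#' @param shift_max upper bound of the uniform global shift, ms.
#' @param seed RNG seed for this train.
#' @return an `input_train_spec` list.
#' @export
input_train_spec <- function(frequency, duration, jitter_sd = 0,
                             shift_max = 0, seed = 1L) {
  stopifnot(frequency > 0, duration > 0, jitter_sd >= 0, shift_max >= 0)
  structure(list(frequency = frequency, duration = duration,
                 jitter_sd = jitter_sd, shift_max = shift_max,
                 seed = as.integer(seed)),
            class = "input_train_spec")
}

#' Uncorrelated-input specification
#'
#' Uncorrelated trains use a jitter sd of one quarter ISI and a shift bound
#' of one full ISI, which decorrelates trains generated from independent
#' seeds while preserving the mean rate.
#'
#' @param frequency Hz.
#' @param duration ms.
#' @param seed RNG seed.
#' @return an `input_train_spec` with `jitter_sd = ISI/4`,
#'   `shift_max = ISI`.
#' @export
#' @examples
#' s <- uncorrelated_spec(1000, 2000)
#' s$jitter_sd  # 0.25 ms
#' s$shift_max  # 1 ms
uncorrelated_spec <- function(frequency, duration = 2000, seed = 1L) {
  isi <- 1000 / frequency
  input_train_spec(frequency, duration, jitter_sd = isi / 4,
                   shift_max = isi, seed = seed)
}

#' Generate one spike train
#'
#' The constant-ISI scaffold extends past both edges of the recording
#' window by a margin of `shift_max + 6 * jitter_sd`, and the jittered,
#' shifted train is then clipped to the half-open window `(0, duration]`.
#' With this convention spikes displaced out of the window are balanced, in
#' expectation, by spikes displaced in from the margins, so the clipped
#' train's expected rate equals the requested frequency exactly (the
#' process restricted to the window is stationary). Spikes outside the
#' window are dropped, never wrapped. Jittered spikes are re-sorted (the
#' Gaussian re-draw may reorder neighbours at large sd).
#'
#' In the deterministic limit (`jitter_sd = 0`, `shift_max = 0`) the result
#' is exactly the constant-ISI train `ISI, 2*ISI, ...` up to `duration`.
#'
#' @param spec an [input_train_spec()].
#' @return sorted numeric vector of spike times in ms within
#'   `(0, duration]`.
#' @export
#' @examples
#' generate_train(input_train_spec(100, 100)) # exactly 10, 20, ..., 100
generate_train <- function(spec) {
  isi <- 1000 / spec$frequency
  margin <- spec$shift_max + 6 * spec$jitter_sd
  i_lo <- -ceiling(margin / isi)
  i_hi <- floor((spec$duration + margin) / isi)
  if (i_hi < i_lo) return(numeric(0))
  scaffold <- (i_lo:i_hi) * isi
  n <- length(scaffold)
  with_seed(spec$seed, {
    jittered <- if (spec$jitter_sd > 0) {
      stats::rnorm(n, mean = scaffold, sd = spec$jitter_sd)
    } else scaffold
    shift <- if (spec$shift_max > 0) {
      stats::runif(1, 0, spec$shift_max)
    } else 0
    t <- sort(jittered + shift)
    t[t > 0 & t <= spec$duration]
  })
}

#' Generate a set of independent trains
#'
#' One train per synapse, each with its own seed streamed from `seed`.
#'
#' @param n number of trains.
#' @param frequency Hz per train.
#' @param duration ms.
#' @param jitter_sd,shift_max as in [input_train_spec()]; defaults give
#'   uncorrelated trains (ISI/4 and one ISI).
#' @param seed master seed.
#' @return list of spike-time vectors.
#' @export
generate_train_set <- function(n, frequency, duration,
                               jitter_sd = 250 / frequency,
                               shift_max = 1000 / frequency, seed = 1L) {
  lapply(seq_len(n), function(k) {
    generate_train(input_train_spec(frequency, duration, jitter_sd,
                                    shift_max,
                                    seed = derive_seed(seed, k)))
  })
}

#' Ensemble input plan: shared rhythm plus per-cell noise
#'
#' The first `ceiling(ensemble_fraction * n_cells)` cells are ensemble
#' members. All cells receive independent noise trains (per-synapse, built
#' later from `noise_spec`); ensemble members additionally receive one
#' bit-identical, precisely timed rhythm train (zero jitter, zero shift) at
#' `rhythm_freq`, representing theta-coordinated input shared across the
#' ensemble.
#'
#' @param n_cells number of cells covered by the plan.
#' @param ensemble_fraction fraction in (0, 1] marked as ensemble.
#' @param rhythm_freq shared rhythm frequency, Hz.
#' @param noise_spec an [input_train_spec()] template for the noise
#'   component (its seed is re-streamed per cell/synapse at build time).
#' @param seed master seed recorded in the plan.
#' @return an `ensemble_input_plan`: `membership` (logical per cell),
#'   `shared_rhythm` (spike times), `noise_spec`, `seed`.
#' @export
#' @examples
#' p <- ensemble_inputs(10, 0.5, 8, uncorrelated_spec(600, 2000))
#' sum(p$membership) # 5
#' length(p$shared_rhythm) # 16 events in 2 s at 8 Hz
ensemble_inputs <- function(n_cells, ensemble_fraction, rhythm_freq,
                            noise_spec, seed = 1L) {
  stopifnot(ensemble_fraction > 0, ensemble_fraction <= 1)
  n_ens <- ceiling(ensemble_fraction * n_cells)
  membership <- seq_len(n_cells) <= n_ens
  rhythm <- generate_train(input_train_spec(rhythm_freq,
                                            noise_spec$duration,
                                            jitter_sd = 0, shift_max = 0))
  structure(list(membership = membership, shared_rhythm = rhythm,
                 rhythm_freq = rhythm_freq, noise_spec = noise_spec,
                 seed = as.integer(seed)),
            class = "ensemble_input_plan")
}

#' FSI input plans: synchronized bursts or independent noise
#'
#' `identical` mode gives every FSI exactly the same burst-gated input set,
#' so all FSIs spike in perfectly synchronized bursts (one burst per
#' `burst_period`); `independent` mode gives each FSI its own seed-streamed
#' uncorrelated trains at `noise_freq`.
#'
#' In `identical` mode each synapse's uncorrelated train is gated to burst
#' windows of length `burst_len` at the start of each period, with the
#' in-window rate `noise_freq * burst_gain`; `burst_gain` is calibrated so
#' the time-averaged FSI output rate matches the desynchronized condition
#' (the sync/desync comparison is made at matched mean FSI rate). The
#' GABAergic input set is also shared bit-exactly across FSIs in this mode
#' (`gaba_trains`), so every FSI sees precisely the same total input. The
#' within-burst FSI output rate (how many spikes each burst elicits) is
#' shaped by the simulator's dynamics; `burst_rate` is recorded in the
#' plan for reporting.
#'
#' @param n_fsi number of FSIs.
#' @param mode `"identical"` or `"independent"`.
#' @param burst_rate nominal within-burst FSI output rate, Hz (reporting).
#' @param burst_period ms between burst onsets.
#' @param burst_len ms of drive per burst (identical mode).
#' @param burst_gain in-burst input rate multiplier (identical mode).
#' @param noise_freq per-synapse time-averaged input frequency, Hz.
#' @param n_syn synapses per FSI covered by the plan.
#' @param duration ms.
#' @param seed master seed.
#' @return an `fsi_input_plan`: `trains` is a list (length `n_fsi`) of lists
#'   (length `n_syn`) of spike-time vectors; plus `burst_onsets` (ms) and
#'   `gaba_trains` (one shared set) in identical mode.
#' @export
synchronized_fsi_inputs <- function(n_fsi, mode = c("identical",
                                                    "independent"),
                                    burst_rate = 60, burst_period = 125,
                                    burst_len = 40, burst_gain = 1.5,
                                    noise_freq = 600,
                                    n_syn = 84L, duration = 2000,
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_fsi >= 1)
  if (mode == "independent") {
    trains <- lapply(seq_len(n_fsi), function(f) {
      generate_train_set(n_syn, noise_freq, duration,
                         seed = derive_seed(seed, f))
    })
    return(structure(list(mode = mode, trains = trains,
                          burst_onsets = NULL, burst_rate = burst_rate,
                          noise_freq = noise_freq, seed = as.integer(seed)),
                     class = "fsi_input_plan"))
  }
  # identical: one burst-gated input set, duplicated across FSIs
  onsets <- burst_period * (seq_len(ceiling(duration / burst_period)) - 1)
  gate_freq <- noise_freq * burst_gain
  one_set <- lapply(seq_len(n_syn), function(k) {
    t <- generate_train(input_train_spec(gate_freq, duration,
                                         jitter_sd = 250 / gate_freq,
                                         shift_max = 1000 / gate_freq,
                                         seed = derive_seed(seed, k)))
    phase <- t %% burst_period
    t[phase < burst_len]
  })
  gaba <- generate_train_set(n_syn, noise_freq, duration,
                             seed = derive_seed(seed, n_syn + 1L))
  trains <- rep(list(one_set), n_fsi)
  structure(list(mode = mode, trains = trains, burst_onsets = onsets,
                 gaba_trains = gaba,
                 burst_rate = burst_rate, noise_freq = noise_freq,
                 seed = as.integer(seed)),
            class = "fsi_input_plan")
}

#' Write / read a raster or input-train table as TSV
#'
#' Long format: one row per spike, columns `id` (synapse or cell id) and
#' `time_ms`. A JSON sidecar (same path + `.json`) can carry spec
#' parameters and seeds.
#'
#' @param times_list list of spike-time vectors, one per id.
#' @param path output file.
#' @param meta optional list written as the JSON sidecar.
#' @export
write_raster_tsv <- function(times_list, path, meta = NULL) {
  n <- lengths(times_list)
  df <- data.frame(id = rep(seq_along(times_list), n),
                   time_ms = unlist(times_list, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @param n_ids number of ids expected (trailing silent ids preserved).
#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path, n_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (is.null(n_ids)) n_ids <- if (nrow(df) > 0) max(df$id) else 0L
  out <- vector("list", n_ids)
  for (k in seq_len(n_ids)) out[[k]] <- sort(df$time_ms[df$id == k])
  out
}
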