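#' Two-state synapse parameters
#'
#' Conductance follows the difference-of-exponentials form
#' `g(t) = g_max * N * (exp(-t / tau_decay) - exp(-t / tau_rise))`, with `N`
#' normalizing the peak to `g_max`; multiple events on one synapse sum
#' linearly in the two state variables. Lateral and feedforward contacts
#' share one GABA-A conductance (`g_max`) by construction, reflecting the
#' approximately equal per-contact conductances of the two projections; the
#' large feedforward IPSP arises from contact number (7-12 vs 1-3) and
#' proximal placement, not from a stronger synapse.
#'
#' Time constants and conductances are calibration choices of the reduced
#' tier (the source models take theirs from voltage-clamp literature); the
#' GABA-A default is calibrated so single lateral IPSPs fall in the
#' +/-0.2 mV range.
#'
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA_A"`.
#' @param g_max peak conductance per contact, microsiemens.
#' @param tau_rise,tau_decay ms; `tau_rise < tau_decay` required.
#' @param e_rev reversal potential, mV (GABA-A default -60).
#' @return a `synapse_params` list.
#' @export
synapse_params <- function(kind = c("AMPA", "NMDA", "GABA_A"),
                           g_max = NULL, tau_rise = NULL, tau_decay = NULL,
                           e_rev = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    AMPA   = list(g_max = 0.00030, tau_rise = 1.1, tau_decay = 5.75,
                  e_rev = 0),
    NMDA   = list(g_max = 0.000018, tau_rise = 2.8, tau_decay = 160,
                  e_rev = 0),
    GABA_A = list(g_max = 0.00009, tau_rise = 0.6, tau_decay = 11,
                  e_rev = -60))
  p <- list(kind = kind,
            g_max = if (is.null(g_max)) defaults$g_max else g_max,
            tau_rise = if (is.null(tau_rise)) defaults$tau_rise else tau_rise,
            tau_decay = if (is.null(tau_decay)) defaults$tau_decay
                        else tau_decay,
            e_rev = if (is.null(e_rev)) defaults$e_rev else e_rev)
  if (p$g_max < 0) stop("g_max must be >= 0")
  if (p$tau_rise >= p$tau_decay) stop("tau_rise must be < tau_decay")
  structure(p, class = "synapse_params")
}

# peak-normalisation constant N so that max_t N*(e^{-t/td} - e^{-t/tr}) = 1
syn_peak_norm <- function(tau_rise, tau_decay) {
  tp <- syn_peak_time(tau_rise, tau_decay)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Closed-form peak time of the difference-of-exponentials waveform
#'
#' `t_peak = ln(tau_decay / tau_rise) * tau_rise * tau_decay /
#' (tau_decay - tau_rise)`.
#'
#' @param tau_rise,tau_decay time constants, ms.
#' @return peak time, ms.
#' @export
syn_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Two-state synaptic conductance waveform
#'
#' Conductance at time `t_since_event` after a single presynaptic event.
#' Zero at onset; peaks at [syn_peak_time()] with value `g_max`.
#'
#' @param t_since_event ms (>= 0); vectorized.
#' @param params a [synapse_params()] list.
#' @return conductance in the units of `g_max`.
#' @export
#' @examples
#' p <- synapse_params("GABA_A")
#' synapse_conductance(0, p)                                  # 0
#' synapse_conductance(syn_peak_time(p$tau_rise, p$tau_decay), p) # g_max
synapse_conductance <- function(t_since_event, params) {
  stopifnot(all(t_since_event >= 0))
  N <- syn_peak_norm(params$tau_rise, params$tau_decay)
  params$g_max * N * (exp(-t_since_event / params$tau_decay) -
                      exp(-t_since_event / params$tau_rise))
}

#' Reduced cell dynamics: passive cable plus spiking-soma surrogate
#'
#' Per-compartment passive membrane (specific capacitance, leak
#' conductance and reversal, axial resistivity) on the scaffold tree, with
#' a leaky-integrate-and-fire surrogate at the soma (threshold, reset,
#' absolute refractory period) standing in for the source models' full
#' voltage-gated channel complement. Dendritic spines are not modeled
#' explicitly; `spine_factor` scales dendritic capacitance and leak to
#' account for their membrane area (MSN only).
#'
#' @param scaffold a `morph_scaffold`.
#' @param cm_uf_cm2 specific membrane capacitance, uF/cm^2.
#' @param g_pas_s_cm2 leak conductance density, S/cm^2.
#' @param e_leak_mv leak reversal, mV (MSN default near the down-state).
#' @param ra_ohm_cm axial resistivity, ohm cm.
#' @param spine_factor multiplier on dendritic (non-soma) capacitance and
#'   leak for spine membrane area.
#' @param v_threshold_mv,v_reset_mv,t_refrac_ms soma surrogate parameters.
#' @return a `cell_dynamics` object carrying per-compartment `cap_nf`,
#'   `g_leak_us`, `g_axial_us` (coupling to parent) and the soma surrogate
#'   parameters.
#' @export
cell_dynamics <- function(scaffold,
                          cm_uf_cm2 = 1, g_pas_s_cm2 = 5e-5,
                          e_leak_mv = if (scaffold$cell_type == "MSN")
                            -85 else -70,
                          ra_ohm_cm = 150,
                          spine_factor = if (scaffold$cell_type == "MSN")
                            2 else 1,
                          v_threshold_mv = if (scaffold$cell_type == "MSN")
                            -45 else -50,
                          v_reset_mv = if (scaffold$cell_type == "MSN")
                            -70 else -65,
                          t_refrac_ms = if (scaffold$cell_type == "MSN")
                            2 else 1.5) {
  comps <- scaffold$compartments
  area_cm2 <- pi * comps$diam_um * comps$length_um * 1e-8
  spine <- ifelse(comps$branch_order == "soma", 1, spine_factor)
  cap_nf <- cm_uf_cm2 * area_cm2 * 1e3 * spine
  g_leak_us <- g_pas_s_cm2 * area_cm2 * 1e6 * spine
  # axial coupling between compartment centers (half-lengths in series)
  half_r <- (ra_ohm_cm * 1e4) * (comps$length_um / 2) /
    (pi * comps$diam_um^2 / 4)            # ohm
  g_axial_us <- rep(NA_real_, nrow(comps))
  pid <- comps$parent_id
  has_p <- !is.na(pid)
  g_axial_us[has_p] <- 1e6 / (half_r[has_p] + half_r[match(pid[has_p],
                                                           comps$id)])
  structure(list(scaffold = scaffold,
                 cap_nf = cap_nf, g_leak_us = g_leak_us,
                 e_leak_mv = e_leak_mv, g_axial_us = g_axial_us,
                 v_threshold_mv = v_threshold_mv, v_reset_mv = v_reset_mv,
                 t_refrac_ms = t_refrac_ms),
            class = "cell_dynamics")
}

#' Simulation configuration
#'
#' @param duration_ms simulated time.
#' @param dt_ms integration step (backward Euler); 0.1 ms default for
#'   network runs, 0.025 ms recommended for IPSP studies.
#' @param lateral_on,feedforward_on inhibition toggles; turning a kind off
#'   silences those connections without altering anything else.
#' @param record_traces global cell ids whose somatic voltage is recorded.
#' @param seed run seed (recorded; the dynamics are deterministic given the
#'   network and inputs).
#' @param log_events if `TRUE`, return the delivered synaptic event log.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_ms = 2000, dt_ms = 0.1,
                       lateral_on = TRUE, feedforward_on = TRUE,
                       record_traces = integer(0), seed = 1L,
                       log_events = FALSE) {
  stopifnot(dt_ms > 0, duration_ms >= dt_ms)
  structure(list(duration_ms = duration_ms, dt_ms = dt_ms,
                 lateral_on = lateral_on, feedforward_on = feedforward_on,
                 record_traces = as.integer(record_traces),
                 seed = as.integer(seed), log_events = log_events),
            class = "sim_config")
}
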