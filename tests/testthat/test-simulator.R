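# direct access to the integration core for closed-form oracles
sim1 <- function(cap, gl, el, dt, n_steps, amp = 0, s0 = 0L, s1 = 0L,
                 syn = NULL, ev_step = integer(0)) {
  ns <- if (is.null(syn)) 0L else length(syn$comp)
  striatnet:::.sim_core(
    -1L, cap, gl, el, 0,
    0L, 1e6, -60, 2,                      # threshold far above reach
    if (ns) syn$comp else integer(0),
    if (ns) syn$w else numeric(0),
    if (ns) syn$tr else numeric(0),
    if (ns) syn$td else numeric(0),
    if (ns) syn$e else numeric(0),
    if (length(ev_step)) syn$ev_syn else integer(0), ev_step,
    integer(0), integer(0), integer(0),
    if (amp != 0) 0L else integer(0),
    if (amp != 0) amp else numeric(0),
    if (amp != 0) s0 else integer(0),
    if (amp != 0) s1 else integer(0),
    dt, n_steps, 0L, FALSE)
}

test_that("synapse conductance follows the two-state closed form", {
  p <- synapse_params("GABA_A", g_max = 0.5, tau_rise = 2, tau_decay = 12)
  expect_equal(synapse_conductance(0, p), 0)
  tp <- syn_peak_time(2, 12)
  expect_equal(tp, log(6) * 24 / 10)
  expect_equal(synapse_conductance(tp, p), 0.5) # peak normalized to g_max
  expect_lt(synapse_conductance(tp + 5, p), 0.5)
  p0 <- synapse_params("AMPA", g_max = 0)
  expect_equal(synapse_conductance(c(0, 1, 10), p0), c(0, 0, 0))
  expect_error(synapse_params("AMPA", tau_rise = 6, tau_decay = 5),
               "tau_rise")
})

test_that("single-compartment step response matches the RC closed form", {
  cap <- 0.1; gl <- 0.005; el <- -80            # tau = 20 ms, R = 200 MOhm
  dt <- 0.01; n <- 6000; amp <- 0.05            # 10 mV steady state
  r <- sim1(cap, gl, el, dt, n, amp = amp, s0 = 0L, s1 = n)
  t <- seq_len(n) * dt
  v_exact <- el + amp / gl * (1 - exp(-t / (cap / gl)))
  expect_lt(max(abs(r$traces[1, -1] - v_exact)), 0.01)
})

test_that("resting state is a fixed point and empty inputs give no spikes", {
  net <- tiny_net()
  r <- run_network(net, empty_inputs(100),
                   sim_config(100, 0.1, record_traces = c(1L, 28L)))
  expect_true(all(lengths(r$raster) == 0))
  expect_lt(max(abs(r$traces[1, ] + 85)), 1e-9) # MSN leak reversal
  expect_lt(max(abs(r$traces[2, ] + 70)), 1e-9) # FSI leak reversal
})

test_that("subthreshold responses sum approximately linearly", {
  cap <- 0.1; gl <- 0.005; el <- -80
  syn2 <- list(comp = c(0L, 0L), w = c(2e-4, 2e-4), tr = c(1, 1),
               td = c(8, 8), e = c(0, 0), ev_syn = c(0L, 1L))
  dt <- 0.05; n <- 2000
  both <- sim1(cap, gl, el, dt, n, syn = syn2,
               ev_step = c(200L, 600L))$traces[1, ]
  a <- sim1(cap, gl, el, dt, n,
            syn = list(comp = 0L, w = 2e-4, tr = 1, td = 8, e = 0,
                       ev_syn = 0L), ev_step = 200L)$traces[1, ]
  b <- sim1(cap, gl, el, dt, n,
            syn = list(comp = 0L, w = 2e-4, tr = 1, td = 8, e = 0,
                       ev_syn = 0L), ev_step = 600L)$traces[1, ]
  superpos <- a + b - el
  # conductance inputs are weakly nonlinear; small inputs nearly superpose
  expect_lt(max(abs(both - superpos)), 0.05 * max(abs(both - el)))
})

test_that("distal GABA events deflect the soma less than somatic ones", {
  net <- build_network(placement_params(n_per_side = 2, seed = 3),
                       lateral = FALSE, feedforward = FALSE)
  comps <- net$msn_scaffold$compartments
  tip <- max(comps$id[comps$branch_order == "tertiary"])
  net$cortical <- data.frame(syn_id = 1:2,
                             cell_type = "MSN", cell = 1L,
                             comp = c(1L, tip),
                             kind = "cortical_gaba")
  deflect <- function(syn) {
    inputs <- structure(list(events = data.frame(syn_id = syn,
                                                 time_ms = 20),
                             duration_ms = 120, seed = 1L),
                        class = "network_inputs")
    r <- run_network(net, inputs,
                     sim_config(120, 0.025, record_traces = 1L))
    max(abs(r$traces[1, ] - r$traces[1, 1]))
  }
  at_soma <- deflect(1L); at_tip <- deflect(2L)
  expect_gt(at_soma, 0)
  expect_gt(at_tip, 0)
  expect_lt(at_tip, at_soma)
})

test_that("halving dt changes subthreshold traces only slightly", {
  net <- build_network(placement_params(n_per_side = 2, seed = 3),
                       lateral = FALSE, feedforward = FALSE)
  inp <- make_network_inputs(net, 300, msn_glut_hz = 500, fsi_glut_hz = 0,
                             fsi_gaba_hz = 0, seed = 7)
  tr1 <- run_network(net, inp,
                     sim_config(300, 0.1, record_traces = 1L))$traces
  tr2 <- run_network(net, inp,
                     sim_config(300, 0.05, record_traces = 1L))$traces
  common <- seq(1, ncol(tr2), by = 2)
  expect_lt(max(abs(tr1[1, ] - tr2[1, common])), 0.25)
})

test_that("identical configurations give bit-identical results", {
  net <- tiny_net()
  inp <- make_network_inputs(net, 400, msn_glut_hz = 1500,
                             fsi_glut_hz = 600, seed = 2)
  cfg <- sim_config(400, 0.1, record_traces = 1:3)
  r1 <- run_network(net, inp, cfg)
  r2 <- run_network(net, inp, cfg)
  expect_identical(r1$raster, r2$raster)
  expect_identical(unclass(r1$traces), unclass(r2$traces))
})

test_that("the lateral toggle only removes MSN-sourced GABA events", {
  net <- tiny_net()
  inp <- make_network_inputs(net, 400, msn_glut_hz = 1800,
                             fsi_glut_hz = 600, seed = 2)
  cfg_on <- sim_config(400, 0.1, lateral_on = TRUE, log_events = TRUE)
  cfg_off <- sim_config(400, 0.1, lateral_on = FALSE, log_events = TRUE)
  on <- run_network(net, inp, cfg_on)
  off <- run_network(net, inp, cfg_off)
  expect_gt(sum(on$events$kind == "lateral"), 0)  # drive strong enough
  expect_equal(sum(off$events$kind == "lateral"), 0)
  key <- function(ev, k) {
    e <- ev[ev$kind == k, ]
    sort(paste(e$time_ms, e$comp))
  }
  # cortical and feedforward event streams are untouched by the toggle
  expect_identical(key(on$events, "cortical"), key(off$events, "cortical"))
  expect_identical(key(on$events, "feedforward"),
                   key(off$events, "feedforward"))
})

test_that("run_network validates inputs against the network", {
  net <- tiny_net()
  expect_error(run_network(net, empty_inputs(100),
                           sim_config(100, 0.1, record_traces = 99L)),
               "beyond")
  expect_error(run_network(net, empty_inputs(100), sim_config(200, 0.1)),
               "inputs cover")
})

test_that("paired runs obey causality and report the first presyn spike", {
  net <- fixture("net2_full", function() {
    build_network(placement_params(n_per_side = 2, seed = 3),
                  topo = topology_params(p_lateral = 1))
  })
  inp <- ipsp_protocol_inputs(net, 1, duration_ms = 200, seed = 6)
  pr <- paired_ipsp_run(net, inp, sim_config(200, 0.05),
                        presyn_cell = 1, kind = "lateral")
  expect_gt(pr$presyn_spike, 40) # volley placement
  i_before <- seq_len(floor((pr$presyn_spike + 2.4) / pr$dt_ms) - 1)
  expect_true(all(pr$trace_on[, i_before] == pr$trace_off[, i_before]))
  expect_false(all(pr$trace_on == pr$trace_off))
})

test_that("IPSP amplitude grows with the GABA-A conductance", {
  net <- fixture("net2_full", function() {
    build_network(placement_params(n_per_side = 2, seed = 3),
                  topo = topology_params(p_lateral = 1))
  })
  inp <- ipsp_protocol_inputs(net, 1, duration_ms = 200, seed = 6)
  med_amp <- function(g) {
    pr <- paired_ipsp_run(net, inp, sim_config(200, 0.05),
                          presyn_cell = 1, kind = "lateral",
                          syn_gaba = synapse_params("GABA_A", g_max = g))
    ips <- extract_ipsp_set(pr, window_ms = 80)
    median(abs(ips$amplitude_mv[!ips$excluded]))
  }
  a1 <- med_amp(0.00009); a2 <- med_amp(0.00018); a3 <- med_amp(0.00036)
  expect_lt(a1, a2)
  expect_lt(a2, a3)
})

test_that("a never-spiking designated cell raises an error", {
  net <- fixture("net2_full", function() {
    build_network(placement_params(n_per_side = 2, seed = 3),
                  topo = topology_params(p_lateral = 1))
  })
  inp <- ipsp_protocol_inputs(net, 1, duration_ms = 200, drive_n_syn = 0L,
                              seed = 6)
  expect_error(paired_ipsp_run(net, inp, sim_config(200, 0.05),
                               presyn_cell = 1, kind = "lateral"),
               "did not spike")
})

test_that("traces export to TSV with a JSON sidecar", {
  net <- tiny_net()
  r <- run_network(net, empty_inputs(50),
                   sim_config(50, 0.1, record_traces = 1:2))
  path <- tempfile(fileext = ".tsv")
  write_traces_tsv(r$traces, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 2 * 501)
  expect_equal(unique(df$cell), 1:2)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$dt_ms, 0.1)
  unlink(c(path, paste0(path, ".json")))
})
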