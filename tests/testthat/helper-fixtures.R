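# Shared fixtures, built lazily and cached for the whole test run.
# All networks are generated in code; seeds are fixed so every run sees
# the same objects.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

msn_sc <- function() fixture("msn_sc", build_msn_scaffold)
fsi_sc <- function() fixture("fsi_sc", build_fsi_scaffold)

# 27 MSNs + 1 FSI: smallest network with both connection kinds
tiny_net <- function() fixture("tiny_net", function() {
  build_network(placement_params(n_per_side = 3, seed = 5))
})

# 216 MSNs + 9 FSIs: all pairs in range, good wiring statistics
mid_net <- function() fixture("mid_net", function() {
  build_network(placement_params(n_per_side = 6, seed = 11))
})

# 512 MSNs + 22 FSIs: the desk-scale tier used by the directional suite
net512 <- function() fixture("net512", function() {
  build_network(placement_params(n_per_side = 8, seed = 11))
})

# full-size 2744 MSN + 121 FSI network (single fixed seed)
full_net <- function() fixture("full_net", function() {
  build_network(placement_params(n_per_side = 14, seed = 101))
})

empty_inputs <- function(duration_ms = 200) {
  structure(list(events = data.frame(syn_id = integer(0),
                                     time_ms = numeric(0)),
                 duration_ms = duration_ms, seed = 1L),
            class = "network_inputs")
}
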