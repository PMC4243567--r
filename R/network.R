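#' Placement and topology parameters
#'
#' Defaults encode the network's anatomy: a cubic MSN lattice with 20 um
#' spacing (14 points per side, 2744 cells, spanning a ~280 um tissue cube),
#' FSIs interspersed uniformly at a 4:90 FSI:MSN ratio, lateral MSN-to-MSN
#' connections with 15.5% unidirectional probability within 380 um and 1-3
#' contacts per connection (83%/13%/4%), feedforward FSI-to-MSN connections
#' with 25% probability within 250 um and 7-12 contacts (uniform), and a
#' 2.4 ms conduction delay on both kinds.
#'
#' @param n_per_side MSN lattice points per side (14 gives 2744 MSNs; 8 the
#'   512-MSN desk-scale network).
#' @param spacing lattice spacing, micrometers.
#' @param fsi_per,msn_per FSI:MSN number ratio (4 per 90).
#' @param seed master seed for all stochastic build stages.
#' @return a parameter list.
#' @export
placement_params <- function(n_per_side = 14L, spacing = 20,
                             fsi_per = 4L, msn_per = 90L, seed = 1L) {
  stopifnot(n_per_side >= 2, spacing > 0, fsi_per >= 0, msn_per >= 1)
  list(n_per_side = as.integer(n_per_side), spacing = spacing,
       fsi_per = as.integer(fsi_per), msn_per = as.integer(msn_per),
       seed = as.integer(seed))
}

#' @param p_lateral,r_lateral lateral connection probability and distance
#'   cutoff (um) for ordered MSN pairs.
#' @param p_feedforward,r_feedforward feedforward probability and cutoff (um).
#' @param lateral_contact_pmf probability of 1, 2, 3 contacts per lateral
#'   connection.
#' @param ff_contact_range inclusive integer range of feedforward contact
#'   counts, sampled uniformly.
#' @param delay_ms synaptic conduction delay, milliseconds.
#' @rdname placement_params
#' @export
topology_params <- function(p_lateral = 0.155, r_lateral = 380,
                            p_feedforward = 0.25, r_feedforward = 250,
                            lateral_contact_pmf = c(0.83, 0.13, 0.04),
                            ff_contact_range = c(7L, 12L),
                            delay_ms = 2.4) {
  stopifnot(p_lateral >= 0, p_lateral <= 1,
            p_feedforward >= 0, p_feedforward <= 1,
            length(lateral_contact_pmf) == 3,
            abs(sum(lateral_contact_pmf) - 1) < 1e-9,
            length(ff_contact_range) == 2,
            ff_contact_range[1] <= ff_contact_range[2],
            delay_ms > 0)
  list(p_lateral = p_lateral, r_lateral = r_lateral,
       p_feedforward = p_feedforward, r_feedforward = r_feedforward,
       lateral_contact_pmf = lateral_contact_pmf,
       ff_contact_range = as.integer(ff_contact_range),
       delay_ms = delay_ms)
}

#' Place MSNs on a cubic lattice
#'
#' Deterministic: `n_per_side^3` points spaced `spacing` micrometers apart,
#' starting at the origin. Projections are never wrapped across the cube
#' boundary, so peripheral cells receive fewer afferents than central cells.
#'
#' @param params a [placement_params()] list.
#' @return numeric matrix (n x 3) of coordinates in micrometers.
#' @export
#' @examples
#' nrow(place_msns(placement_params(n_per_side = 8))) # 512
place_msns <- function(params = placement_params()) {
  n <- params$n_per_side
  ax <- (seq_len(n) - 1) * params$spacing
  g <- expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Place FSIs uniformly within the MSN cube
#'
#' `floor(n_msn * fsi_per / msn_per)` cells, coordinates drawn independently
#' and uniformly along each axis of the MSN lattice bounding cube.
#'
#' @param n_msn number of MSNs in the network.
#' @param params a [placement_params()] list.
#' @param rng_seed seed for the placement draw.
#' @return numeric matrix (n_fsi x 3) of coordinates in micrometers.
#' @export
#' @examples
#' nrow(place_fsis(2744, placement_params(), 1)) # 121
place_fsis <- function(n_msn, params = placement_params(),
                       rng_seed = derive_seed(params$seed, "fsi_placement")) {
  stopifnot(n_msn >= 1)
  n_fsi <- floor(n_msn * params$fsi_per / params$msn_per)
  extent <- (params$n_per_side - 1) * params$spacing
  with_seed(rng_seed, {
    matrix(stats::runif(3 * n_fsi, 0, extent), ncol = 3,
           dimnames = list(NULL, c("x", "y", "z")))
  })
}

# ordered in-range pairs between two position sets; returns data.frame(i, j)
# with Euclidean distance <= cutoff; drop_self removes i == j (same set)
inrange_pairs <- function(pos_a, pos_b, cutoff, drop_self = FALSE) {
  # chunked to keep the distance matrix memory bounded on large networks
  n_a <- nrow(pos_a); n_b <- nrow(pos_b)
  chunk <- max(1L, floor(4e7 / max(n_b, 1L)))
  out_i <- vector("list", ceiling(n_a / chunk))
  out_j <- vector("list", ceiling(n_a / chunk))
  bb2 <- rowSums(pos_b^2)
  c2 <- cutoff^2
  k <- 0L
  for (start in seq(1L, n_a, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_a)
    a <- pos_a[idx, , drop = FALSE]
    d2 <- outer(rowSums(a^2), bb2, "+") - 2 * a %*% t(pos_b)
    hit <- d2 <= c2 + 1e-9
    if (drop_self) {
      sel <- cbind(seq_along(idx), idx)
      hit[sel[sel[, 2] <= n_b, , drop = FALSE]] <- FALSE
    }
    w <- which(hit, arr.ind = TRUE)
    k <- k + 1L
    out_i[[k]] <- idx[w[, 1]]
    out_j[[k]] <- w[, 2]
  }
  data.frame(i = unlist(out_i), j = unlist(out_j))
}

#' Wire lateral (MSN-to-MSN) inhibitory connections
#'
#' Every ordered MSN pair with soma-to-soma distance within the lateral
#' cutoff receives an independent Bernoulli draw at the lateral probability.
#' Connected pairs draw a contact count from the 1/2/3-contact distribution
#' and each contact is assigned a uniformly random compartment in the
#' lateral target zone (secondary + tertiary dendrites), with replacement.
#' Self-connections are excluded; reciprocal connections are permitted.
#'
#' @param msn_pos MSN position matrix from [place_msns()].
#' @param scaffold MSN `morph_scaffold` (for the placement zone).
#' @param topo a [topology_params()] list.
#' @param rng_seed seed for the wiring draws.
#' @return list with `connections` (data.frame: conn_id, source, target,
#'   kind, n_contacts, delay_ms) and `contacts` (data.frame: conn_id, comp).
#'   Cell ids are 1-based MSN indices.
#' @export
connect_lateral <- function(msn_pos, scaffold, topo = topology_params(),
                            rng_seed = 1L) {
  zone <- placement_zone(scaffold, "lateral_target")
  pairs <- inrange_pairs(msn_pos, msn_pos, topo$r_lateral, drop_self = TRUE)
  with_seed(rng_seed, {
    on <- stats::runif(nrow(pairs)) < topo$p_lateral
    src <- pairs$i[on]; tgt <- pairs$j[on]
    nc <- sample.int(3L, length(src), replace = TRUE,
                     prob = topo$lateral_contact_pmf)
    comp <- zone[sample.int(length(zone), sum(nc), replace = TRUE)]
    connection_tables(src, tgt, nc, comp, "lateral", topo$delay_ms)
  })
}

#' Wire feedforward (FSI-to-MSN) inhibitory connections
#'
#' Every (FSI, MSN) pair within the feedforward cutoff receives an
#' independent Bernoulli draw at the feedforward probability; connected
#' pairs form a uniform 7-12 contacts, each on a uniformly random
#' compartment of the feedforward target zone (soma + primary dendrites).
#'
#' @param fsi_pos,msn_pos position matrices.
#' @param scaffold MSN `morph_scaffold`.
#' @param topo a [topology_params()] list.
#' @param rng_seed seed.
#' @return as [connect_lateral()]; `source` is the 1-based FSI index,
#'   `target` the 1-based MSN index.
#' @export
connect_feedforward <- function(fsi_pos, msn_pos, scaffold,
                                topo = topology_params(), rng_seed = 1L) {
  zone <- placement_zone(scaffold, "feedforward_target")
  if (nrow(fsi_pos) == 0) {
    return(connection_tables(integer(0), integer(0), integer(0),
                             integer(0), "feedforward", topo$delay_ms))
  }
  pairs <- inrange_pairs(fsi_pos, msn_pos, topo$r_feedforward)
  lo <- topo$ff_contact_range[1]; hi <- topo$ff_contact_range[2]
  with_seed(rng_seed, {
    on <- stats::runif(nrow(pairs)) < topo$p_feedforward
    src <- pairs$i[on]; tgt <- pairs$j[on]
    nc <- sample(lo:hi, length(src), replace = TRUE)
    comp <- zone[sample.int(length(zone), sum(nc), replace = TRUE)]
    connection_tables(src, tgt, nc, comp, "feedforward", topo$delay_ms)
  })
}

connection_tables <- function(src, tgt, nc, comp, kind, delay) {
  n <- length(src)
  conns <- data.frame(conn_id = seq_len(n),
                      source = as.integer(src), target = as.integer(tgt),
                      kind = rep(kind, n),
                      n_contacts = as.integer(nc),
                      delay_ms = rep(delay, n))
  contacts <- data.frame(conn_id = rep(conns$conn_id, times = nc),
                         comp = as.integer(comp))
  list(connections = conns, contacts = contacts)
}

#' Assign cortical input synapses
#'
#' Each FSI receives `n_fsi_glut` glutamatergic (AMPA/NMDA pair) and
#' `n_fsi_gaba` GABAergic input synapses placed uniformly over the whole
#' cell; each MSN receives `n_msn_glut` glutamatergic input synapses
#' confined to its dendritic (non-soma) compartments. Each synapse later
#' receives its own independent input spike train.
#'
#' @param n_msn,n_fsi cell counts.
#' @param msn_scaffold,fsi_scaffold scaffolds.
#' @param n_msn_glut glutamatergic inputs per MSN (must be > 0).
#' @param n_fsi_glut,n_fsi_gaba inputs per FSI (defaults 84 and 84).
#' @param rng_seed seed.
#' @return data.frame: syn_id, cell_type ("MSN"/"FSI"), cell (1-based index
#'   within type), comp, kind ("cortical_glut"/"cortical_gaba").
#' @export
assign_cortical_inputs <- function(n_msn, n_fsi, msn_scaffold, fsi_scaffold,
                                   n_msn_glut = 84L, n_fsi_glut = 84L,
                                   n_fsi_gaba = 84L, rng_seed = 1L) {
  if (n_msn_glut <= 0) stop("n_msn_glut must be positive")
  zone_msn <- placement_zone(msn_scaffold, "cortical_target_msn")
  zone_fsi <- placement_zone(fsi_scaffold, "whole_cell")
  syn_block <- function(type, n_cell, n_per, zone, kind) {
    n <- n_cell * n_per
    data.frame(cell_type = rep(type, n),
               cell = rep(seq_len(n_cell), each = n_per),
               comp = zone[sample.int(length(zone), n, replace = TRUE)],
               kind = rep(kind, n))
  }
  with_seed(rng_seed, {
    msn <- syn_block("MSN", n_msn, n_msn_glut, zone_msn, "cortical_glut")
    fsi_g <- syn_block("FSI", n_fsi, n_fsi_glut, zone_fsi, "cortical_glut")
    fsi_b <- syn_block("FSI", n_fsi, n_fsi_gaba, zone_fsi, "cortical_gaba")
    out <- rbind(msn, fsi_g, fsi_b)
    out$syn_id <- seq_len(nrow(out))
    out[, c("syn_id", "cell_type", "cell", "comp", "kind")]
  })
}

#' Build a complete striatal network
#'
#' Runs placement, lateral wiring, feedforward wiring and cortical synapse
#' assignment, streaming stage sub-seeds from the master seed in
#' `params$seed` so each stage is independently reproducible.
#'
#' @param params [placement_params()].
#' @param topo [topology_params()].
#' @param msn_scaffold,fsi_scaffold scaffolds (defaults built in place).
#' @param n_msn_glut cortical glutamatergic inputs per MSN.
#' @param lateral,feedforward logical; set `FALSE` to build without that
#'   connection kind.
#' @return a `striatal_network` object: positions, connection and contact
#'   tables, cortical synapse table, scaffolds and parameters.
#' @export
#' @examples
#' net <- build_network(placement_params(n_per_side = 3, seed = 7))
#' net
build_network <- function(params = placement_params(),
                          topo = topology_params(),
                          msn_scaffold = build_msn_scaffold(),
                          fsi_scaffold = build_fsi_scaffold(),
                          n_msn_glut = 84L,
                          lateral = TRUE, feedforward = TRUE) {
  msn_pos <- place_msns(params)
  fsi_pos <- place_fsis(nrow(msn_pos), params,
                        derive_seed(params$seed, "fsi_placement"))
  lat <- if (lateral) {
    connect_lateral(msn_pos, msn_scaffold, topo,
                    derive_seed(params$seed, "lateral"))
  } else connection_tables(integer(0), integer(0), integer(0), integer(0),
                           "lateral", topo$delay_ms)
  ff <- if (feedforward && nrow(fsi_pos) > 0) {
    connect_feedforward(fsi_pos, msn_pos, msn_scaffold, topo,
                        rng_seed = derive_seed(params$seed, "feedforward"))
  } else connection_tables(integer(0), integer(0), integer(0), integer(0),
                           "feedforward", topo$delay_ms)
  # merge connection tables with disjoint conn ids
  off <- nrow(lat$connections)
  ff$connections$conn_id <- ff$connections$conn_id + off
  ff$contacts$conn_id <- ff$contacts$conn_id + off
  conns <- rbind(lat$connections, ff$connections)
  contacts <- rbind(lat$contacts, ff$contacts)
  cortical <- assign_cortical_inputs(
    nrow(msn_pos), nrow(fsi_pos), msn_scaffold, fsi_scaffold,
    n_msn_glut = n_msn_glut,
    rng_seed = derive_seed(params$seed, "cortical"))
  structure(list(msn_positions = msn_pos, fsi_positions = fsi_pos,
                 connections = conns, contacts = contacts,
                 cortical = cortical,
                 msn_scaffold = msn_scaffold, fsi_scaffold = fsi_scaffold,
                 params = params, topo = topo, n_msn_glut = n_msn_glut),
            class = "striatal_network")
}

#' @export
print.striatal_network <- function(x, ...) {
  cat(sprintf("<striatal network: %d MSNs, %d FSIs, %d lateral + %d feedforward connections>\n",
              nrow(x$msn_positions), nrow(x$fsi_positions),
              sum(x$connections$kind == "lateral"),
              sum(x$connections$kind == "feedforward")))
  invisible(x)
}

#' Summarize a built network
#'
#' Reports per-MSN afferent counts (presynaptic cells and synaptic contacts,
#' by connection kind), realized connection probabilities among in-range
#' pairs, the lateral contact-count histogram, and the set of delays.
#'
#' @param network a `striatal_network`.
#' @return list of summary tables and scalars.
#' @export
network_summary <- function(network) {
  conns <- network$connections
  n_msn <- nrow(network$msn_positions)
  lat <- conns[conns$kind == "lateral", ]
  ff <- conns[conns$kind == "feedforward", ]
  per_msn <- data.frame(
    cell = seq_len(n_msn),
    lateral_cells = tabulate(lat$target, n_msn),
    lateral_contacts = as.vector(
      rowsum(c(lat$n_contacts, rep(0L, n_msn)),
             c(lat$target, seq_len(n_msn)))),
    ff_cells = tabulate(ff$target, n_msn),
    ff_contacts = as.vector(
      rowsum(c(ff$n_contacts, rep(0L, n_msn)),
             c(ff$target, seq_len(n_msn)))))
  n_lat_inrange <- nrow(inrange_pairs(network$msn_positions,
                                      network$msn_positions,
                                      network$topo$r_lateral,
                                      drop_self = TRUE))
  n_ff_inrange <- if (nrow(network$fsi_positions) > 0) {
    nrow(inrange_pairs(network$fsi_positions, network$msn_positions,
                       network$topo$r_feedforward))
  } else 0L
  contact_hist <- tabulate(lat$n_contacts, 3L)
  list(per_msn = per_msn,
       mean_lateral_cells = mean(per_msn$lateral_cells),
       mean_lateral_contacts = mean(per_msn$lateral_contacts),
       mean_ff_cells = mean(per_msn$ff_cells),
       mean_ff_contacts = mean(per_msn$ff_contacts),
       p_lateral_realized = if (n_lat_inrange > 0)
         nrow(lat) / n_lat_inrange else NA_real_,
       p_feedforward_realized = if (n_ff_inrange > 0)
         nrow(ff) / n_ff_inrange else NA_real_,
       lateral_contact_hist = if (nrow(lat) > 0)
         contact_hist / nrow(lat) else rep(NA_real_, 3),
       ff_contact_mean = if (nrow(ff) > 0) mean(ff$n_contacts) else NA_real_,
       delays = sort(unique(conns$delay_ms)))
}

#' Serialize / deserialize a network to JSON
#'
#' Positions in micrometers, connections with target compartment ids and
#' delays, plus the build parameters (sufficient to audit but not rebuild;
#' use a run manifest for bit-exact rebuilds).
#'
#' @param network a `striatal_network`.
#' @param path file path.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    n_msn = nrow(network$msn_positions),
    n_fsi = nrow(network$fsi_positions),
    msn_positions = unname(as.matrix(network$msn_positions)),
    fsi_positions = unname(as.matrix(network$fsi_positions)),
    connections = network$connections,
    contacts = network$contacts,
    cortical = network$cortical,
    params = network$params, topo = network$topo,
    n_msn_glut = network$n_msn_glut)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    msn_positions = matrix(doc$msn_positions, ncol = 3,
                           dimnames = list(NULL, c("x", "y", "z"))),
    fsi_positions = matrix(doc$fsi_positions, ncol = 3,
                           dimnames = list(NULL, c("x", "y", "z"))),
    connections = doc$connections, contacts = doc$contacts,
    cortical = doc$cortical,
    msn_scaffold = build_msn_scaffold(), fsi_scaffold = build_fsi_scaffold(),
    params = doc$params,
    topo = c(doc$topo[setdiff(names(doc$topo),
                              c("lateral_contact_pmf", "ff_contact_range"))],
             list(lateral_contact_pmf = unlist(doc$topo$lateral_contact_pmf),
                  ff_contact_range = as.integer(unlist(doc$topo$ff_contact_range)))),
    n_msn_glut = doc$n_msn_glut), class = "striatal_network")
}
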