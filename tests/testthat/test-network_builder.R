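test_that("MSN lattice placement is exact and deterministic", {
  expect_equal(nrow(place_msns(placement_params(n_per_side = 14))), 2744)
  expect_equal(nrow(place_msns(placement_params(n_per_side = 8))), 512)
  p2 <- place_msns(placement_params(n_per_side = 2, spacing = 20))
  expect_equal(nrow(p2), 8)
  d <- as.matrix(dist(p2))
  expect_equal(min(d[d > 0]), 20) # nearest-neighbour spacing
  expect_identical(place_msns(placement_params(n_per_side = 5)),
                   place_msns(placement_params(n_per_side = 5)))
})

test_that("FSI counts follow floor(n_msn * 4/90) and stay in the cube", {
  expect_equal(nrow(place_fsis(2744, placement_params(), 1)), 121)
  expect_equal(nrow(place_fsis(512, placement_params(n_per_side = 8), 1)),
               22)
  expect_equal(nrow(place_fsis(90, placement_params(), 1)), 4)
  pos <- place_fsis(2744, placement_params(), 7)
  expect_true(all(pos >= 0 & pos <= 13 * 20))
  expect_identical(place_fsis(512, placement_params(n_per_side = 8), 3),
                   place_fsis(512, placement_params(n_per_side = 8), 3))
})

test_that("distance gating forbids out-of-range and self connections", {
  # two cells 500 um apart can never connect, at any seed
  pos <- rbind(c(0, 0, 0), c(500, 0, 0))
  for (s in 1:20) {
    lat <- connect_lateral(pos, msn_sc(),
                           topology_params(p_lateral = 1), rng_seed = s)
    expect_equal(nrow(lat$connections), 0)
  }
  # in-range cells with p = 1 always connect both ways, never to self
  pos2 <- rbind(c(0, 0, 0), c(100, 0, 0))
  lat2 <- connect_lateral(pos2, msn_sc(),
                          topology_params(p_lateral = 1), rng_seed = 1)
  expect_equal(nrow(lat2$connections), 2)
  expect_true(all(lat2$connections$source != lat2$connections$target))
})

test_that("realized lateral wiring matches the stated distribution", {
  net <- mid_net() # 216 MSNs, all pairs within the 380 um cutoff
  s <- network_summary(net)
  n_pairs <- 216 * 215
  sigma <- sqrt(0.155 * 0.845 / n_pairs)
  expect_lt(abs(s$p_lateral_realized - 0.155), 3 * sigma)
  lat <- net$connections[net$connections$kind == "lateral", ]
  expect_true(all(lat$n_contacts %in% 1:3))
  # contact histogram close to (0.83, 0.13, 0.04)
  expect_lt(max(abs(s$lateral_contact_hist - c(0.83, 0.13, 0.04))), 0.02)
  # all contacts land in the lateral target zone
  zone <- placement_zone(net$msn_scaffold, "lateral_target")
  cid <- net$contacts$conn_id %in% lat$conn_id
  expect_true(all(net$contacts$comp[cid] %in% zone))
  # reciprocal pairs occur at ~p^2 among in-range unordered pairs
  key <- paste(pmin(lat$source, lat$target), pmax(lat$source, lat$target))
  n_recip <- sum(table(key) == 2)
  expected <- (n_pairs / 2) * 0.155^2
  expect_lt(abs(n_recip - expected), 3 * sqrt(expected))
})

test_that("realized feedforward wiring matches the stated distribution", {
  net <- mid_net()
  s <- network_summary(net)
  ff <- net$connections[net$connections$kind == "feedforward", ]
  n_pairs <- 9 * 216
  sigma <- sqrt(0.25 * 0.75 / n_pairs)
  expect_lt(abs(s$p_feedforward_realized - 0.25), 3 * sigma)
  expect_true(all(ff$n_contacts >= 7 & ff$n_contacts <= 12))
  # mean contact count near the uniform{7..12} mean of 9.5
  expect_lt(abs(mean(ff$n_contacts) - 9.5),
            3 * sd(ff$n_contacts) / sqrt(nrow(ff)))
  zone <- placement_zone(net$msn_scaffold, "feedforward_target")
  cid <- net$contacts$conn_id %in% ff$conn_id
  expect_true(all(net$contacts$comp[cid] %in% zone))
  expect_equal(s$delays, 2.4)
})

test_that("cortical inputs respect the per-cell counts and zones", {
  net <- tiny_net()
  cort <- net$cortical
  msn_counts <- table(cort$cell[cort$cell_type == "MSN"])
  expect_true(all(msn_counts == 84))
  fsi_glut <- cort$cell_type == "FSI" & cort$kind == "cortical_glut"
  fsi_gaba <- cort$cell_type == "FSI" & cort$kind == "cortical_gaba"
  expect_equal(sum(fsi_glut), 84 * nrow(net$fsi_positions))
  expect_equal(sum(fsi_gaba), 84 * nrow(net$fsi_positions))
  # 1:1 glut:GABA ratio per FSI
  expect_equal(sum(fsi_glut), sum(fsi_gaba))
  # MSN cortical synapses never on the soma
  soma <- net$msn_scaffold$compartments$id[
    net$msn_scaffold$compartments$branch_order == "soma"]
  expect_false(any(cort$comp[cort$cell_type == "MSN"] == soma))
  expect_error(assign_cortical_inputs(2, 1, msn_sc(), fsi_sc(),
                                      n_msn_glut = 0),
               "positive")
})

test_that("builds are seed-reproducible and seed-sensitive", {
  a <- build_network(placement_params(n_per_side = 3, seed = 5))
  b <- build_network(placement_params(n_per_side = 3, seed = 5))
  c <- build_network(placement_params(n_per_side = 3, seed = 6))
  expect_identical(a$connections, b$connections)
  expect_identical(a$contacts, b$contacts)
  expect_identical(a$fsi_positions, b$fsi_positions)
  expect_false(identical(a$connections, c$connections))
  # different seeds, same summary statistics (within loose bounds)
  sa <- network_summary(a); sc2 <- network_summary(c)
  expect_lt(abs(sa$p_lateral_realized - sc2$p_lateral_realized), 0.03)
})

test_that("peripheral cells receive fewer lateral afferents than central", {
  s <- network_summary(full_net())
  pos <- full_net()$msn_positions
  # central block (all coordinates within 40 um of the cube center) vs
  # the 8 corner cells; region means beat single-cell binomial noise
  central <- which(rowSums(abs(pos - 130) <= 40) == 3)
  corners <- which(rowSums(pos == 0 | pos == 260) == 3)
  expect_length(corners, 8)
  expect_gt(mean(s$per_msn$lateral_cells[central]),
            mean(s$per_msn$lateral_cells[corners]))
  expect_gt(mean(s$per_msn$lateral_contacts[central]),
            mean(s$per_msn$lateral_contacts[corners]))
})

test_that("empty networks summarize to zero afferents", {
  net <- build_network(placement_params(n_per_side = 3, seed = 5),
                       lateral = FALSE, feedforward = FALSE)
  s <- network_summary(net)
  expect_true(all(s$per_msn$lateral_contacts == 0))
  expect_true(all(s$per_msn$ff_contacts == 0))
})

test_that("networks survive a JSON round trip", {
  net <- tiny_net()
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$msn_positions, unname(net$msn_positions),
               ignore_attr = TRUE)
  expect_equal(back$connections$source, net$connections$source)
  expect_equal(back$connections$n_contacts, net$connections$n_contacts)
  expect_equal(back$contacts$comp, net$contacts$comp)
  expect_equal(back$topo$delay_ms, 2.4)
  unlink(path)
})
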