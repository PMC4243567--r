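#' Morphology scaffolds for striatal cell models
#'
#' A scaffold is the compartment tree of a model cell: a single somatic
#' compartment plus primary, secondary and tertiary dendrites, each dendrite
#' a chain of cylindrical compartments. Scaffolds carry branch-order labels
#' used by the network builder to place synapses (lateral inhibition targets
#' distal dendrites, feedforward inhibition targets the soma and proximal
#' dendrites) and the geometry used by the reduced cable dynamics.
#'
#' The default medium spiny neuron (MSN) scaffold has 189 compartments:
#' 1 soma, 4 primary dendrites of 1 compartment each, 8 secondary dendrites
#' of 1 compartment each, and 16 tertiary dendrites of 11 compartments each.
#' The default fast-spiking interneuron (FSI) scaffold has 148 compartments:
#' 1 soma, 3 primary dendrites of 3 compartments, 6 secondary dendrites of
#' 5 compartments, and 12 tertiary dendrites of 9 compartments.
#'
#' @name morphology
NULL

BRANCH_ORDERS <- c("soma", "primary", "secondary", "tertiary")

new_scaffold <- function(cell_type, comps, branching) {
  stopifnot(all(c("id", "parent_id", "branch_order", "length_um",
                  "diam_um") %in% names(comps)))
  structure(list(cell_type = cell_type,
                 compartments = comps,
                 branching = branching),
            class = "morph_scaffold")
}

#' @export
print.morph_scaffold <- function(x, ...) {
  b <- x$branching
  cat(sprintf("<%s scaffold: %d compartments (%d primary / %d secondary / %d tertiary dendrites)>\n",
              x$cell_type, nrow(x$compartments),
              b$n_primary, b$n_secondary, b$n_tertiary))
  invisible(x)
}

# Build a binary-branching dendritic tree: n_primary trunks off the soma,
# each splitting into two secondaries, each secondary into two tertiaries.
# Each dendrite is a chain of `comps_per` compartments of given geometry.
build_scaffold <- function(cell_type,
                           n_primary, comps_primary,
                           comps_secondary, comps_tertiary,
                           geom) {
  n_secondary <- 2L * n_primary
  n_tertiary <- 4L * n_primary
  ids <- integer(0); parent <- integer(0); order <- character(0)
  len <- numeric(0); diam <- numeric(0)
  add <- function(n, par, ord, L, d) {
    # appends a chain of n compartments, first attached to `par`
    start <- length(ids)
    for (k in seq_len(n)) {
      ids <<- c(ids, length(ids) + 1L)
      parent <<- c(parent, if (k == 1L) par else ids[length(ids) - 1L])
      order <<- c(order, ord)
      len <<- c(len, L); diam <<- c(diam, d)
    }
    ids[start + n] # tip id
  }
  # soma
  ids <- 1L; parent <- NA_integer_; order <- "soma"
  len <- geom$soma_l; diam <- geom$soma_d
  for (p in seq_len(n_primary)) {
    tip_p <- add(comps_primary, 1L, "primary", geom$primary_l, geom$primary_d)
    for (s in 1:2) {
      tip_s <- add(comps_secondary, tip_p, "secondary",
                   geom$secondary_l, geom$secondary_d)
      for (t in 1:2) {
        add(comps_tertiary, tip_s, "tertiary",
            geom$tertiary_l, geom$tertiary_d)
      }
    }
  }
  comps <- data.frame(id = ids, parent_id = parent,
                      branch_order = factor(order, levels = BRANCH_ORDERS),
                      length_um = len, diam_um = diam)
  new_scaffold(cell_type, comps,
               list(n_primary = n_primary, n_secondary = n_secondary,
                    n_tertiary = n_tertiary))
}

#' Build the default MSN compartment scaffold
#'
#' 189 compartments: 1 soma + 4 primary (1 compartment each) + 8 secondary
#' (1 each) + 16 tertiary dendrites of 11 compartments each. Tertiary
#' dendrites are finely discretized (11 compartments) for spatial accuracy of
#' distal synaptic integration. The branching pattern is configurable; the
#' compartment-count defaults are the model's fixed anatomy.
#'
#' @param n_primary number of primary dendrites (each splits into 2
#'   secondaries, each secondary into 2 tertiaries).
#' @param comps_tertiary compartments per tertiary dendrite.
#' @param geom named list of compartment geometry (micrometers):
#'   `soma_l`, `soma_d`, `primary_l`, `primary_d`, `secondary_l`,
#'   `secondary_d`, `tertiary_l`, `tertiary_d`. Lengths are per compartment.
#' @return a `morph_scaffold` object.
#' @export
#' @examples
#' sc <- build_msn_scaffold()
#' nrow(sc$compartments) # 189
build_msn_scaffold <- function(n_primary = 4L, comps_tertiary = 11L,
                               geom = msn_geometry()) {
  build_scaffold("MSN", as.integer(n_primary),
                 comps_primary = 1L, comps_secondary = 1L,
                 comps_tertiary = as.integer(comps_tertiary), geom = geom)
}

#' Build the default FSI compartment scaffold
#'
#' 148 compartments: 1 soma + 3 primary dendrites of 3 compartments each +
#' 6 secondary dendrites of 5 compartments each + 12 tertiary dendrites of
#' 9 compartments each.
#'
#' @param n_primary number of primary dendrites.
#' @param geom compartment geometry as in [build_msn_scaffold()].
#' @return a `morph_scaffold` object.
#' @export
build_fsi_scaffold <- function(n_primary = 3L, geom = fsi_geometry()) {
  build_scaffold("FSI", as.integer(n_primary),
                 comps_primary = 3L, comps_secondary = 5L,
                 comps_tertiary = 9L, geom = geom)
}

#' Default compartment geometry (micrometers)
#'
#' Generic dimensions giving a roughly 190 um soma-to-tip dendritic path for
#' the MSN and a compact FSI arbor. The source models' exact per-compartment
#' geometry lives in their original single-cell descriptions; these defaults
#' are placeholders that only affect the reduced passive dynamics and are
#' fully configurable.
#'
#' @return named list of lengths/diameters per compartment, in micrometers.
#' @export
msn_geometry <- function() {
  list(soma_l = 16, soma_d = 16,
       primary_l = 20, primary_d = 2.25,
       secondary_l = 24, secondary_d = 1.4,
       tertiary_l = 13.2, tertiary_d = 0.72)
}

#' @rdname msn_geometry
#' @export
fsi_geometry <- function() {
  list(soma_l = 15, soma_d = 15,
       primary_l = 10, primary_d = 1.8,
       secondary_l = 12, secondary_d = 1.0,
       tertiary_l = 12, tertiary_d = 0.6)
}

#' Compartment ids of a synapse-placement zone
#'
#' Zones reflect the anatomical targeting rules of the network: lateral
#' (MSN-to-MSN) contacts land uniformly on secondary and tertiary dendrites;
#' feedforward (FSI-to-MSN) contacts land on the soma and primary dendrites;
#' cortical glutamatergic contacts onto MSNs are confined to dendritic
#' (non-soma) compartments, while cortical contacts onto FSIs cover the
#' whole cell.
#'
#' @param scaffold a `morph_scaffold`.
#' @param zone one of `"lateral_target"`, `"feedforward_target"`,
#'   `"cortical_target_msn"`, `"whole_cell"`.
#' @return integer vector of compartment ids.
#' @export
#' @examples
#' length(placement_zone(build_msn_scaffold(), "feedforward_target")) # 5
placement_zone <- function(scaffold, zone) {
  stopifnot(inherits(scaffold, "morph_scaffold"))
  comps <- scaffold$compartments
  ord <- as.character(comps$branch_order)
  ids <- switch(zone,
    lateral_target = comps$id[ord %in% c("secondary", "tertiary")],
    feedforward_target = comps$id[ord %in% c("soma", "primary")],
    cortical_target_msn = comps$id[ord != "soma"],
    whole_cell = comps$id,
    stop("unknown placement zone: ", zone))
  as.integer(ids)
}

#' Serialize / deserialize a scaffold to JSON
#'
#' Document layout: `{cell_type, compartments: [{id, parent, order,
#' length_um, diam_um}]}`.
#'
#' @param scaffold a `morph_scaffold`.
#' @param path file path.
#' @return `read_scaffold_json` returns a `morph_scaffold`.
#' @export
write_scaffold_json <- function(scaffold, path) {
  comps <- scaffold$compartments
  doc <- list(cell_type = scaffold$cell_type,
              branching = scaffold$branching,
              compartments = data.frame(
                id = comps$id,
                parent = ifelse(is.na(comps$parent_id), -1L, comps$parent_id),
                order = as.character(comps$branch_order),
                length_um = comps$length_um,
                diam_um = comps$diam_um))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaffold_json
#' @export
read_scaffold_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- doc$compartments
  comps <- data.frame(id = as.integer(cc$id),
                      parent_id = ifelse(cc$parent < 0, NA_integer_,
                                         as.integer(cc$parent)),
                      branch_order = factor(cc$order, levels = BRANCH_ORDERS),
                      length_um = cc$length_um, diam_um = cc$diam_um)
  new_scaffold(doc$cell_type, comps,
               lapply(doc$branching, as.integer))
}

# path from a compartment to the root; used by tests and the cable builder
ancestor_chain <- function(scaffold, id) {
  comps <- scaffold$compartments
  chain <- integer(0)
  cur <- id
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- comps$parent_id[match(cur, comps$id)]
  }
  chain
}
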