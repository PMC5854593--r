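#' End-to-end control pipeline: LM -> MLCP -> input matrix -> cost
#'
#' Runs the full local-information control workflow on a directed network:
#' local-game matching identifies the control paths and driver nodes; CCPs
#' are merged onto DCPs; `m0` extra inputs are allocated by the min-max rule;
#' control nodes are placed so each effective path is divided evenly; the
#' input matrix `B` is assembled; and, when the network is small enough for
#' dense matrix exponentials (`N <= energy_cap`), the expected control cost
#' of the resulting `B` is evaluated.
#'
#' @param net a [directed_network()].
#' @param m0 number of extra control inputs beyond the required ones.
#' @param seed integer seed governing all randomness (tie-breaks).
#' @param omega LM waiting probability.
#' @param tf control horizon for the energy stage.
#' @param energy_cap skip the energy stage (cost `NA`, with a message) when
#'   `N` exceeds this (default 200).
#' @return A list report (JSON-serializable): `config` (the arguments), `N`,
#'   `L`, `n_dcps`, `n_ccps`, `required_inputs`, `M`, `longest_before`,
#'   `longest_after`, `allocation` (per effective path: length, extra inputs,
#'   control node labels), `control_nodes`, `rounds`, `cost`.
#' @export
pipeline <- function(net, m0 = 0L, seed = 1L, omega = 0, tf = 1,
                     energy_cap = 200L) {
  stopifnot(inherits(net, "directed_network"))
  config <- list(m0 = as.integer(m0), seed = as.integer(seed), omega = omega,
                 tf = tf, energy_cap = as.integer(energy_cap))
  if (net$N == 0L) {
    return(c(list(config = config, N = 0L, L = 0L, n_dcps = 0L, n_ccps = 0L,
                  required_inputs = 0L, M = 0L, longest_before = 0L,
                  longest_after = 0L, allocation = list(),
                  control_nodes = character(0), rounds = 0L, cost = NA_real_)))
  }
  res <- lm_match(net, omega = omega, seed = seed)
  paths <- effective_paths(res)
  merged <- vapply(paths, length, numeric(1))
  alloc <- allocate_inputs(merged, m0)
  allocation <- vector("list", length(paths))
  control_nodes <- character(0)
  for (i in seq_along(paths)) {
    k <- 1L + alloc$n[i]
    pos <- place_control_nodes(length(paths[[i]]), k)
    nodes_i <- paths[[i]][pos]
    allocation[[i]] <- list(length = length(paths[[i]]), extra_inputs = alloc$n[i],
                            control_nodes = nodes_i)
    control_nodes <- c(control_nodes, nodes_i)
  }
  M <- length(control_nodes)
  cost <- NA_real_
  if (net$N <= energy_cap && M > 0L) {
    sys <- lti_system(net, tf = tf)
    cost <- suppressWarnings(
      expected_cost(sys, build_B(net, control_nodes), on_singular = "inf"))
  } else if (M > 0L) {
    message("energy stage skipped: N = ", net$N, " exceeds energy_cap = ", energy_cap)
  }
  list(
    config = config,
    N = net$N, L = net$L,
    n_dcps = length(res$dcps), n_ccps = length(res$ccps),
    required_inputs = required_inputs(res),
    M = M,
    longest_before = if (length(merged)) as.integer(max(merged)) else 0L,
    longest_after = alloc$longest,
    allocation = allocation,
    control_nodes = control_nodes,
    rounds = res$rounds,
    cost = cost
  )
}

# Concatenate each DCP with the CCPs assigned to it (largest CCP onto the
# currently shortest effective path), mirroring assign_ccps() but keeping the
# node sequences so inputs can be placed. A pure-CCP network gets a virtual
# path seeded by its largest CCP.
effective_paths <- function(res) {
  stopifnot(inherits(res, "lm_result"))
  dcp_nodes <- lapply(res$dcps, `[[`, "nodes")
  ccp_nodes <- lapply(res$ccps, `[[`, "nodes")
  if (!length(dcp_nodes)) {
    if (!length(ccp_nodes)) return(list())
    k <- which.max(lengths(ccp_nodes))
    dcp_nodes <- ccp_nodes[k]
    ccp_nodes <- ccp_nodes[-k]
  }
  for (j in order(lengths(ccp_nodes), decreasing = TRUE)) {
    i <- which.min(lengths(dcp_nodes))
    dcp_nodes[[i]] <- c(dcp_nodes[[i]], ccp_nodes[[j]])
  }
  dcp_nodes
}
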