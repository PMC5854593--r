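#' Local-game matching (LM)
#'
#' Distributed driver-node identification using only local topology. Nodes
#' play synchronous rounds: every node without a fixed child sends one *child
#' request* along a remaining edge to the unmatched child neighbour with the
#' lowest u-input degree, and every node without a fixed parent sends one
#' *parent request* to the unmatched parent neighbour with the lowest u-output
#' degree (a node with a self-loop may request itself). When a pair of
#' requests is mutual the parent-child match is fixed: the parent drops its
#' other outgoing links and the child its other incoming links, so neither can
#' be requested again in that role. The u-input (u-output) degree of a node is
#' its current number of parent (child) neighbours that are still unmatched as
#' parents (children).
#'
#' Ties among minimum-degree candidates are resolved per tie event: with
#' probability `omega` the node waits (sends no request this round), otherwise
#' it picks uniformly at random among the tied candidates. Rounds continue
#' until no further requests can be sent or no request pattern can still
#' produce a match: the protocol stops at a round that fixes no match and
#' involved no random tie-break (the configuration is then a deterministic
#' fixed point), or after `stall_rounds` consecutive matchless rounds.
#'
#' After termination the fixed matches partition the nodes into directed
#' control paths (DCPs), each starting at a node with no matched parent, and
#' circled control paths (CCPs), closed loops of matches. The DCP heads are
#' the driver nodes: each needs an independent external control input.
#'
#' @param net a [directed_network()].
#' @param omega waiting probability in `[0, 1]` used at tie events (default 0).
#' @param seed integer seed for the tie-break randomness; together with `net`
#'   and `omega` it fully determines the result.
#' @param stall_rounds stop after this many consecutive rounds without a new
#'   match (only reachable when random tie-breaks keep the outcome open).
#' @return An object of class `lm_result`: named character vectors
#'   `parent_of`/`child_of` (the fixed matches, `NA` where unmatched), lists
#'   `dcps` and `ccps` of [control_path] objects, `drivers` (character vector
#'   of DCP heads), `n_drivers`, `rounds`, `omega`, `seed`, `n_nodes`.
#' @examples
#' lm_match(make_stem(5))$drivers # "1"
#' @export
lm_match <- function(net, omega = 0, seed = 1L, stall_rounds = 25L) {
  stopifnot(inherits(net, "directed_network"))
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0 || omega > 1) {
    stop("`omega` must be a probability in [0, 1]")
  }
  n <- net$N
  from <- net$from
  to <- net$to
  child_of <- rep(NA_integer_, n)  # fixed child of each node (as parent)
  parent_of <- rep(NA_integer_, n) # fixed parent of each node (as child)
  rounds <- 0L
  with_seed(seed, {
    stall <- 0L
    repeat {
      avail_parent <- is.na(child_of)  # can still fix a child
      avail_child <- is.na(parent_of)  # can still fix a parent
      # an edge x -> c is live iff x can still act as parent and c as child;
      # link removal after a match is implied by these availability flags
      live <- which(avail_parent[from] & avail_child[to])
      if (!length(live)) break
      ef <- from[live]
      et <- to[live]
      u_in <- tabulate(et[avail_parent[ef]], n)  # unmatched-parent count per child
      u_out <- tabulate(ef[avail_child[et]], n)  # unmatched-child count per parent
      creq <- send_requests(sender = ef, receiver = et, key = u_in[et], n, omega)
      preq <- send_requests(sender = et, receiver = ef, key = u_out[ef], n, omega)
      rounds <- rounds + 1L
      xs <- which(!is.na(creq$req))
      mutual <- xs[!is.na(preq$req[creq$req[xs]]) & preq$req[creq$req[xs]] == xs]
      if (length(mutual)) {
        child_of[mutual] <- creq$req[mutual]
        parent_of[creq$req[mutual]] <- mutual
        stall <- 0L
      } else {
        if (!creq$any_tie && !preq$any_tie) break
        stall <- stall + 1L
        if (stall >= stall_rounds) break
      }
    }
  })
  paths <- extract_paths(net, parent_of, child_of)
  res <- structure(
    list(
      parent_of = stats::setNames(
        ifelse(is.na(parent_of), NA_character_, net$nodes[parent_of]), net$nodes),
      child_of = stats::setNames(
        ifelse(is.na(child_of), NA_character_, net$nodes[child_of]), net$nodes),
      dcps = paths$dcps,
      ccps = paths$ccps,
      drivers = vapply(paths$dcps, function(p) p$nodes[1], character(1)),
      n_drivers = length(paths$dcps),
      rounds = rounds,
      omega = omega,
      seed = seed,
      n_nodes = n
    ),
    class = "lm_result"
  )
  res
}

# One synchronous half-round of requests. Each sender owns a group of
# candidate edges; it targets the candidate with the minimum key, breaking
# ties uniformly at random unless it decides to wait (probability omega per
# tie event). Returns req[node] = requested neighbour (NA = no request) and
# whether any tie event occurred.
send_requests <- function(sender, receiver, key, n, omega) {
  o <- order(sender, key)
  s <- sender[o]
  k <- key[o]
  firstpos <- which(!duplicated(s))
  gmin <- k[firstpos][findInterval(seq_along(s), firstpos)]
  tied <- k == gmin
  st <- s[tied]
  rt <- receiver[o][tied]
  # uniform choice among tied candidates via random ordering within groups
  o2 <- order(st, stats::runif(length(st)))
  st <- st[o2]
  rt <- rt[o2]
  fp <- which(!duplicated(st))
  sizes <- diff(c(fp, length(st) + 1L))
  chooser <- st[fp]
  choice <- rt[fp]
  is_tie <- sizes >= 2L
  wait <- is_tie & (stats::runif(length(chooser)) < omega)
  req <- rep(NA_integer_, n)
  req[chooser[!wait]] <- choice[!wait]
  list(req = req, any_tie = any(is_tie))
}

# Decompose the match maps into DCPs (chains starting at an unmatched-parent
# node) and CCPs (closed loops of matches).
extract_paths <- function(net, parent_of, child_of) {
  n <- net$N
  visited <- rep(FALSE, n)
  dcps <- list()
  ccps <- list()
  walk <- function(start) {
    out <- integer(0)
    v <- start
    repeat {
      out <- c(out, v)
      visited[v] <<- TRUE
      v <- child_of[v]
      if (is.na(v) || visited[v]) break
    }
    out
  }
  for (h in which(is.na(parent_of))) {
    nodes <- walk(h)
    dcps[[length(dcps) + 1L]] <- control_path("DCP", net$nodes[nodes])
  }
  for (v in which(!visited)) {
    if (visited[v]) next
    nodes <- walk(v)
    ccps[[length(ccps) + 1L]] <- control_path("CCP", net$nodes[nodes])
  }
  list(dcps = dcps, ccps = ccps)
}

#' Control path
#'
#' An ordered node sequence produced by matching: a `"DCP"` (directed control
#' path) starts at a driver node with no matched parent; a `"CCP"` (circled
#' control path) is a closed loop of matches. The length `L` counts *nodes*
#' (the convention used by the min-max allocator); experiments on circles
#' count *edges* between control nodes instead, and say so where they do.
#'
#' @param kind `"DCP"` or `"CCP"`.
#' @param nodes character vector of node labels in path order.
#' @return an object of class `control_path` with fields `kind`, `nodes`, `L`.
#' @export
control_path <- function(kind = c("DCP", "CCP"), nodes) {
  kind <- match.arg(kind)
  nodes <- as.character(nodes)
  if (!length(nodes)) stop("a control path has at least one node")
  structure(list(kind = kind, nodes = nodes, L = length(nodes)),
            class = "control_path")
}

#' @export
print.control_path <- function(x, ...) {
  cat(sprintf("<%s, L = %d> %s\n", x$kind, x$L, paste(x$nodes, collapse = " -> ")))
  invisible(x)
}

#' @export
print.lm_result <- function(x, ...) {
  cat(sprintf("<lm_result> %d node(s): %d DCP(s), %d CCP(s), %d driver(s), %d round(s)\n",
              x$n_nodes, length(x$dcps), length(x$ccps), x$n_drivers, x$rounds))
  invisible(x)
}

#' Number of independent external control inputs required
#'
#' Equals the number of DCPs found by LM. A non-empty network whose nodes all
#' lie on CCPs still needs one external input to hook the circles onto, so the
#' minimum is 1 for any non-empty network; the empty network needs none.
#'
#' @param res an [lm_match()] result.
#' @return a non-negative integer.
#' @export
required_inputs <- function(res) {
  stopifnot(inherits(res, "lm_result"))
  if (res$n_nodes == 0L) return(0L)
  max(length(res$dcps), 1L)
}

#' Exact maximum matching and minimum driver count
#'
#' The global optimum LM approximates: a maximum matching of the directed
#' network, i.e. the largest edge set in which no two edges share a start
#' node or an end node. Computed on the bipartite out-copy/in-copy
#' representation (vertex `i` is split into an out-copy and an in-copy; edge
#' `i -> j` joins out-copy `i` to in-copy `j`) with igraph's exact bipartite
#' matcher. The minimum number of driver nodes is `N_D = max(N - |matching|,
#' 1)`; the unmatched nodes (in-copies left unmatched) form one driver set
#' realizing it.
#'
#' @param net a [directed_network()].
#' @return an object of class `mm_result`: `matching` (data frame `from`,
#'   `to` of matched edges), `size`, `N_D`, `drivers` (character; empty when
#'   the matching is perfect), `n_nodes`.
#' @export
mm_exact <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$N
  if (n == 0L) {
    return(structure(list(matching = data.frame(from = character(), to = character()),
                          size = 0L, N_D = 0L, drivers = character(), n_nodes = 0L),
                     class = "mm_result"))
  }
  if (net$L == 0L) {
    return(structure(list(matching = data.frame(from = character(), to = character()),
                          size = 0L, N_D = n, drivers = net$nodes, n_nodes = n),
                     class = "mm_result"))
  }
  g <- igraph::make_empty_graph(2L * n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(net$from, n + net$to))
  types <- rep(c(FALSE, TRUE), each = n)
  mb <- igraph::max_bipartite_match(g, types = types)
  partner <- mb$matching # per-vertex partner id, NA if unmatched
  matched_out <- which(!is.na(partner[seq_len(n)]))
  matched_in <- as.integer(partner[matched_out]) - n
  drivers_idx <- which(is.na(partner[n + seq_len(n)]))
  structure(
    list(
      matching = data.frame(from = net$nodes[matched_out],
                            to = net$nodes[matched_in],
                            stringsAsFactors = FALSE),
      size = as.integer(mb$matching_size),
      N_D = max(n - as.integer(mb$matching_size), 1L),
      drivers = net$nodes[drivers_idx],
      n_nodes = n
    ),
    class = "mm_result"
  )
}

#' @export
print.mm_result <- function(x, ...) {
  cat(sprintf("<mm_result> |matching| = %d, N_D = %d\n", x$size, x$N_D))
  invisible(x)
}

#' Degree distributions of the driver nodes
#'
#' Normalized empirical in- and out-degree distributions of a driver set,
#' used to compare the drivers located by LM against those of the exact
#' maximum matching (driver nodes tend to avoid the hubs).
#'
#' @param res an `lm_result` or `mm_result` (anything with a `drivers` field
#'   of node labels).
#' @param net the [directed_network()] the result was computed on.
#' @return list with data frames `in_deg` and `out_deg`, each with columns
#'   `degree` and `prob` (empty when there are no drivers).
#' @export
driver_degree_histogram <- function(res, net) {
  stopifnot(inherits(net, "directed_network"))
  drivers <- res$drivers
  if (!all(drivers %in% net$nodes)) stop("drivers are not a subset of the node set")
  idx <- match(drivers, net$nodes)
  hist_of <- function(deg) {
    if (!length(idx)) {
      return(data.frame(degree = integer(), prob = numeric()))
    }
    tab <- table(deg[idx])
    data.frame(degree = as.integer(names(tab)),
               prob = as.numeric(tab) / length(idx))
  }
  list(in_deg = hist_of(tabulate(net$to, net$N)),
       out_deg = hist_of(tabulate(net$from, net$N)))
}

#' Total-variation distance between two degree histograms
#'
#' @param h1,h2 data frames with columns `degree` and `prob`, as returned in
#'   [driver_degree_histogram()].
#' @return a scalar in `[0, 1]`.
#' @export
histogram_tv <- function(h1, h2) {
  degs <- union(h1$degree, h2$degree)
  p <- h1$prob[match(degs, h1$degree)]
  q <- h2$prob[match(degs, h2$degree)]
  p[is.na(p)] <- 0
  q[is.na(q)] <- 0
  sum(abs(p - q)) / 2
}
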