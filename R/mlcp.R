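#' Min-max allocation of extra control inputs over control paths
#'
#' Distributes `m0` additional control inputs over control paths of lengths
#' `L_i` (in nodes) so as to minimize the longest resulting path: it solves
#'
#' \deqn{\min_n \max_i L_i / (1 + n_i) \quad s.t. \quad \sum_i n_i = m_0,\; 0 \le n_i \le m_0,}
#'
#' where `n_i` is the number of extra inputs granted to path `i`. A path with
#' `1 + n_i` inputs splits into `1 + n_i` segments, the longest of which has
#' `ceiling(L_i / (1 + n_i))` nodes. The allocator is greedy: each input goes
#' to the path with the current largest ratio `L_i / (1 + n_i)`, ties broken
#' toward the lowest path index; an exchange argument makes this optimal, and
#' the test suite verifies it against exhaustive search.
#'
#' @param L numeric vector of path lengths (nodes), all >= 1.
#' @param m0 number of extra inputs to distribute (>= 0).
#' @return An object of class `input_allocation`: `L`, `m0`, `n` (per-path
#'   extra inputs), `objective` (`max_i L_i/(1+n_i)`), `longest`
#'   (`max_i ceiling(L_i/(1+n_i))`, the longest control path in nodes).
#' @examples
#' allocate_inputs(c(7, 3), 1) # n = c(1, 0), longest = 4
#' @export
allocate_inputs <- function(L, m0) {
  m0 <- as.integer(m0)
  if (is.na(m0) || m0 < 0L) stop("`m0` must be a non-negative integer")
  if (!length(L)) {
    if (m0 > 0L) stop("cannot allocate inputs over an empty path list")
    return(structure(list(L = numeric(0), m0 = 0L, n = integer(0),
                          objective = 0, longest = 0L),
                     class = "input_allocation"))
  }
  L <- as.numeric(L)
  if (anyNA(L) || any(L < 1)) stop("all path lengths must be >= 1")
  n <- integer(length(L))
  for (i in seq_len(m0)) {
    j <- which.max(L / (1 + n)) # which.max takes the first (lowest-index) maximum
    n[j] <- n[j] + 1L
  }
  structure(
    list(L = L, m0 = m0, n = n,
         objective = max(L / (1 + n)),
         longest = as.integer(max(ceiling(L / (1 + n))))),
    class = "input_allocation"
  )
}

#' @export
print.input_allocation <- function(x, ...) {
  cat(sprintf("<input_allocation> m0 = %d over %d path(s); longest control path = %d node(s)\n",
              x$m0, length(x$L), x$longest))
  invisible(x)
}

#' Merge CCP lengths into DCP lengths for allocation
#'
#' A circled control path needs no input of its own: it is controlled by
#' hooking it onto an existing input, which effectively lengthens the control
#' path served by that input. Each CCP is therefore assigned to one DCP and
#' its length added to that DCP's effective length. The assignment balances
#' greedily: CCPs are taken largest first and each is added to the currently
#' shortest effective DCP (ties toward the lowest index). When no DCP exists
#' but CCPs do, a virtual path is created from the largest CCP to host the
#' single mandatory input, and the remaining CCPs are balanced onto it.
#'
#' @param dcp_lengths numeric vector of DCP lengths (nodes); may be empty.
#' @param ccp_lengths numeric vector of CCP lengths (nodes); may be empty.
#' @return numeric vector of merged effective lengths, one per (possibly
#'   virtual) control path, with an `assignment` attribute giving, per CCP in
#'   decreasing-length order, the index of the path it was merged into.
#' @export
assign_ccps <- function(dcp_lengths, ccp_lengths) {
  dcp_lengths <- as.numeric(dcp_lengths)
  ccp_lengths <- as.numeric(ccp_lengths)
  if (any(c(dcp_lengths, ccp_lengths) < 1)) stop("path lengths must be >= 1")
  if (!length(dcp_lengths)) {
    if (!length(ccp_lengths)) return(numeric(0))
    k <- which.max(ccp_lengths)
    merged <- ccp_lengths[k]
    rest <- ccp_lengths[-k]
    out <- assign_rest(merged, rest)
    return(out)
  }
  assign_rest(dcp_lengths, ccp_lengths)
}

assign_rest <- function(merged, ccps) {
  assignment <- integer(0)
  for (len in sort(ccps, decreasing = TRUE)) {
    j <- which.min(merged)
    merged[j] <- merged[j] + len
    assignment <- c(assignment, j)
  }
  attr(merged, "assignment") <- assignment
  merged
}

#' Place the inputs of one control path so its segments are balanced
#'
#' Given a control path of `L` nodes carrying `k` inputs (its driver input
#' plus any extras), input `j` (0-based) attaches at node position
#' `floor(j * L / k) + 1` along the path. The first input always sits at the
#' path head (the driver node) and the resulting segments differ in node
#' count by at most 1 -- control nodes divide the path evenly, which is what
#' keeps the control cost down.
#'
#' @param path a [control_path()] or a single integer path length.
#' @param k number of inputs on this path, `1 <= k <= L`.
#' @return integer vector of 1-based node positions; when `path` is a
#'   `control_path` the positions are named with the node labels.
#' @examples
#' place_control_nodes(7, 2) # positions 1 and 4
#' @export
place_control_nodes <- function(path, k) {
  if (inherits(path, "control_path")) {
    L <- path$L
    labels <- path$nodes
  } else {
    L <- as.integer(path)
    labels <- NULL
  }
  k <- as.integer(k)
  if (is.na(L) || L < 1L) stop("path length must be >= 1")
  if (is.na(k) || k < 1L || k > L) stop("`k` must satisfy 1 <= k <= path length")
  pos <- floor((seq_len(k) - 1) * L / k) + 1L
  if (!is.null(labels)) names(pos) <- labels[pos]
  pos
}

#' Build the input matrix B for a set of control nodes
#'
#' One column per control node, each a unit vector at that node's row, so
#' `t(B) %*% B = I_M` exactly (orthonormal by construction) and every network
#' node has a binary connection to at most one external input.
#'
#' @param net a [directed_network()].
#' @param control_nodes distinct node labels (or integer node indices).
#' @return a dense `N x M` base matrix with rownames the node labels.
#' @export
build_B <- function(net, control_nodes) {
  stopifnot(inherits(net, "directed_network"))
  if (is.numeric(control_nodes)) {
    idx <- as.integer(control_nodes)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > net$N)) {
      stop("control node index out of range")
    }
  } else {
    idx <- match(as.character(control_nodes), net$nodes)
    if (anyNA(idx)) stop("unknown control node(s)")
  }
  if (anyDuplicated(idx)) stop("control nodes must be distinct")
  m <- length(idx)
  B <- matrix(0, net$N, m, dimnames = list(net$nodes, net$nodes[idx]))
  B[cbind(idx, seq_len(m))] <- 1
  B
}

#' Random allocation baseline (RAM)
#'
#' The baseline the min-max allocator is compared against: one exact
#' maximum-matching driver set plus `M - N_D` additional network nodes drawn
#' uniformly at random without replacement from the non-drivers. When the
#' matching is perfect (no unmatched node) the mandatory single control node
#' is drawn at random.
#'
#' @param net a [directed_network()].
#' @param M total number of control nodes, `N_D <= M <= N`.
#' @param seed integer seed; determines the random choices.
#' @return character vector of `M` distinct node labels.
#' @export
ram_select <- function(net, M, seed = 1L) {
  stopifnot(inherits(net, "directed_network"))
  M <- as.integer(M)
  if (M > net$N) stop("`M` cannot exceed the number of nodes")
  mm <- mm_exact(net)
  base <- mm$drivers
  if (M < max(length(base), min(net$N, 1L))) {
    stop("`M` must be at least the minimum driver count")
  }
  with_seed(seed, {
    if (!length(base) && M >= 1L) base <- sample(net$nodes, 1L)
    pool <- setdiff(net$nodes, base)
    extra <- if (M > length(base)) sample(pool, M - length(base)) else character(0)
    c(base, extra)
  })
}
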