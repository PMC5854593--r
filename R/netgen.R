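#' Elementary stem
#'
#' A directed path `1 -> 2 -> ... -> n`: the simplest controllable topology.
#' Only the head node (node 1) is unmatched under a maximum matching, so a
#' single external input at the head controls the whole stem.
#'
#' @param n number of nodes (>= 1).
#' @return a [directed_network()] with nodes `"1" ... "n"` and `n - 1` edges.
#' @export
make_stem <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (n == 1L) {
    return(directed_network(nodes = "1"))
  }
  directed_network(as.character(seq_len(n - 1L)), as.character(seq_len(n - 1L) + 1L),
                   nodes = as.character(seq_len(n)))
}

#' Elementary circle
#'
#' A stem of `n` nodes closed by the extra edge `n -> 1`; `n = 1` gives a
#' single self-loop. A circle has no unmatched node and needs no input of its
#' own: it can be controlled by wiring any of its nodes to an existing input.
#'
#' @param n number of nodes (>= 1).
#' @return a [directed_network()].
#' @export
make_circle <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  from <- as.character(seq_len(n))
  to <- as.character(c(seq_len(n)[-1], 1L))
  directed_network(from, to, nodes = as.character(seq_len(n)))
}

#' Elementary dilation
#'
#' A trunk stem whose last node feeds two disjoint branch stems: the trunk's
#' last node has two children (a dilation point), so the topology needs two
#' independent inputs. Nodes are numbered trunk first, then branch A, then
#' branch B.
#'
#' @param trunk,branch_a,branch_b stem lengths in nodes, all >= 1.
#' @return a [directed_network()] with `trunk + branch_a + branch_b` nodes.
#' @export
make_dilation <- function(trunk, branch_a, branch_b) {
  trunk <- as.integer(trunk); branch_a <- as.integer(branch_a); branch_b <- as.integer(branch_b)
  if (anyNA(c(trunk, branch_a, branch_b)) || any(c(trunk, branch_a, branch_b) < 1L)) {
    stop("all segment lengths must be >= 1")
  }
  n <- trunk + branch_a + branch_b
  nodes <- as.character(seq_len(n))
  from <- integer(0); to <- integer(0)
  if (trunk > 1L) {
    from <- c(from, seq_len(trunk - 1L)); to <- c(to, seq_len(trunk - 1L) + 1L)
  }
  a0 <- trunk # last trunk node
  # branch A: a0 -> trunk+1 -> ... ; branch B: a0 -> trunk+branch_a+1 -> ...
  from <- c(from, a0, if (branch_a > 1L) trunk + seq_len(branch_a - 1L))
  to <- c(to, trunk + 1L, if (branch_a > 1L) trunk + seq_len(branch_a - 1L) + 1L)
  b1 <- trunk + branch_a + 1L
  from <- c(from, a0, if (branch_b > 1L) trunk + branch_a + seq_len(branch_b - 1L))
  to <- c(to, b1, if (branch_b > 1L) trunk + branch_a + seq_len(branch_b - 1L) + 1L)
  directed_network(nodes[from], nodes[to], nodes = nodes)
}

#' Generate a synthetic directed network
#'
#' Reproducible generators for the topologies used throughout the package's
#' validation experiments:
#'
#' * `"er"`: directed Erdos-Renyi, each ordered pair (no self-loops) is an
#'   edge independently with probability `mu / (n - 1)`, so the expected mean
#'   degree (edges per node) is `mu`.
#' * `"ba"`: directed preferential attachment; each new node sends `m`
#'   out-edges to existing nodes chosen with probability proportional to
#'   in-degree + 1.
#' * `"chi2"`, `"weibull"`, `"gamma"`: directed configuration model; in- and
#'   out-degree sequences are drawn i.i.d. from the named law, rescaled to
#'   mean `mu`, rounded to integers, balanced by random unit increments, and
#'   realized by random stub pairing (duplicate edges collapsed).
#' * `"stem"`, `"circle"`: see [make_stem()], [make_circle()].
#' * `"dilation"`: see [make_dilation()]; pass `trunk`, `branch_a`,
#'   `branch_b`.
#'
#' The same `(family, parameters, seed)` always yields the identical edge set.
#'
#' @param family generator family (see above).
#' @param n node count.
#' @param mu target mean degree (er and configuration families).
#' @param m out-edges per new node for `"ba"` (default 2).
#' @param shape distribution shape parameter for the configuration families:
#'   degrees of freedom for `"chi2"` (default 2), Weibull shape (default 1.5),
#'   Gamma shape (default 2).
#' @param seed integer seed; fully determines the output.
#' @param trunk,branch_a,branch_b segment lengths for `"dilation"`.
#' @return a [directed_network()].
#' @export
generate_network <- function(family = c("er", "ba", "chi2", "weibull", "gamma",
                                        "stem", "circle", "dilation"),
                             n, mu = NULL, m = 2L, shape = NULL, seed = 1L,
                             trunk = 1L, branch_a = 1L, branch_b = 1L) {
  family <- match.arg(family)
  if (family == "stem") return(make_stem(n))
  if (family == "circle") return(make_circle(n))
  if (family == "dilation") return(make_dilation(trunk, branch_a, branch_b))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (is.null(mu) && family != "ba") stop("`mu` is required for this family")
  if (!is.null(mu) && mu < 0) stop("`mu` must be >= 0")
  with_seed(seed, switch(family,
    er = gen_er(n, mu),
    ba = gen_ba(n, m),
    chi2 = gen_config(n, mu, function(k) stats::rchisq(k, df = shape %||% 2)),
    weibull = gen_config(n, mu, function(k) stats::rweibull(k, shape = shape %||% 1.5)),
    gamma = gen_config(n, mu, function(k) stats::rgamma(k, shape = shape %||% 2))
  ))
}

gen_er <- function(n, mu) {
  nodes <- as.character(seq_len(n))
  if (n == 1L || mu == 0) return(directed_network(nodes = nodes))
  p <- min(mu / (n - 1), 1)
  npairs <- as.double(n) * (n - 1)
  ne <- stats::rbinom(1L, npairs, p)
  idx <- sample(npairs, ne) - 1
  i <- idx %/% (n - 1) + 1
  r <- idx %% (n - 1) + 1
  j <- r + (r >= i)
  directed_network(nodes[i], nodes[j], nodes = nodes)
}

gen_ba <- function(n, m) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  nodes <- as.character(seq_len(n))
  if (n == 1L) return(directed_network(nodes = nodes))
  indeg <- integer(n)
  from <- integer(0); to <- integer(0)
  for (t in 2:n) {
    k <- min(m, t - 1L)
    tgt <- sample.int(t - 1L, k, prob = indeg[seq_len(t - 1L)] + 1)
    from <- c(from, rep.int(t, k))
    to <- c(to, tgt)
    indeg[tgt] <- indeg[tgt] + 1L
  }
  directed_network(nodes[from], nodes[to], nodes = nodes)
}

# directed configuration model from a continuous degree law rescaled to mean mu
gen_config <- function(n, mu, rlaw, ntries = 100L) {
  nodes <- as.character(seq_len(n))
  if (mu == 0) return(directed_network(nodes = nodes))
  draw_degrees <- function() {
    x <- rlaw(n)
    d <- round(x * mu / mean(x))
    pmin(pmax(d, 0L), n - 1L)
  }
  dout <- draw_degrees()
  din <- draw_degrees()
  # balance the stub counts by random unit increments on the deficient side
  tries <- 0L
  while (sum(dout) != sum(din)) {
    if (sum(dout) < sum(din)) {
      room <- which(dout < n - 1L)
      need <- sum(din) - sum(dout)
    } else {
      room <- which(din < n - 1L)
      need <- sum(dout) - sum(din)
    }
    if (!length(room)) {
      tries <- tries + 1L
      if (tries > ntries) stop("infeasible degree sequence: could not balance stubs")
      dout <- draw_degrees(); din <- draw_degrees()
      next
    }
    bump <- sample(room, min(need, length(room)))
    if (sum(dout) < sum(din)) dout[bump] <- dout[bump] + 1L else din[bump] <- din[bump] + 1L
  }
  if (sum(dout) == 0) return(directed_network(nodes = nodes))
  outstubs <- rep.int(seq_len(n), dout)
  instubs <- rep.int(seq_len(n), din)
  instubs <- instubs[sample.int(length(instubs))]
  key <- paste(outstubs, instubs)
  keep <- !duplicated(key)
  directed_network(nodes[outstubs[keep]], nodes[instubs[keep]], nodes = nodes)
}
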