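# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms than the package code.

# Exhaustive maximum matching by recursion over the edge list (tiny graphs).
brute_max_matching <- function(net) {
  el <- cbind(net$from, net$to)
  m <- nrow(el)
  best <- 0L
  recurse <- function(i, used_from, used_to, size) {
    if (size + (m - i + 1L) <= best) return(invisible())
    if (i > m) {
      if (size > best) best <<- size
      return(invisible())
    }
    f <- el[i, 1]; t <- el[i, 2]
    if (!used_from[f] && !used_to[t]) {
      used_from[f] <- TRUE; used_to[t] <- TRUE
      recurse(i + 1L, used_from, used_to, size + 1L)
      used_from[f] <- FALSE; used_to[t] <- FALSE
    }
    recurse(i + 1L, used_from, used_to, size)
  }
  if (m > 0) recurse(1L, rep(FALSE, net$N), rep(FALSE, net$N), 0L)
  best
}

# Exhaustive min-max input allocation over all compositions of m0.
brute_allocate <- function(L, m0) {
  k <- length(L)
  grid <- as.matrix(expand.grid(rep(list(0:m0), k)))
  grid <- grid[rowSums(grid) == m0, , drop = FALSE]
  objs <- apply(grid, 1, function(n) max(L / (1 + n)))
  min(objs)
}

# Gramian by fixed-order Gauss-Legendre quadrature of the defining integral.
quad_gramian <- function(A, Q, tf, nq = 120) {
  gl <- pracma::gaussLegendre(nq, 0, tf)
  W <- matrix(0, nrow(A), nrow(A))
  for (i in seq_len(nq)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(A * gl$x[i])))
    W <- W + gl$w[i] * (E %*% Q %*% t(E))
  }
  W
}

# Validity of an LM result: mutually consistent match maps, node partition
# into DCPs/CCPs, and every consecutive path pair an actual network edge.
expect_valid_lm <- function(res, net) {
  po <- res$parent_of; co <- res$child_of
  for (x in names(co)) {
    if (!is.na(co[[x]])) expect_identical(po[[co[[x]]]], x)
  }
  for (x in names(po)) {
    if (!is.na(po[[x]])) expect_identical(co[[po[[x]]]], x)
  }
  path_nodes <- unlist(lapply(c(res$dcps, res$ccps), `[[`, "nodes"))
  expect_setequal(path_nodes, net$nodes)
  expect_identical(anyDuplicated(path_nodes), 0L)
  ekey <- paste(net$nodes[net$from], net$nodes[net$to])
  for (p in c(res$dcps, res$ccps)) {
    seqs <- p$nodes
    pairs <- if (p$kind == "CCP") {
      cbind(seqs, c(seqs[-1], seqs[1]))
    } else if (length(seqs) > 1) {
      cbind(seqs[-length(seqs)], seqs[-1])
    } else {
      NULL
    }
    if (!is.null(pairs)) {
      expect_true(all(paste(pairs[, 1], pairs[, 2]) %in% ekey),
                  label = sprintf("%s edges exist in network", p$kind))
    }
  }
  invisible(res)
}
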