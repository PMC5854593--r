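#' Linear time-invariant system on a network
#'
#' Container for the finite-horizon control problem `dx/dt = A x + B u` on
#' `[0, t_f]`. `A` is the weighted adjacency matrix under the package's
#' orientation convention (see [adjacency_matrix()]); `Sigma0` is the second
#' moment of the random initial state (identity by default: i.i.d. entries
#' with zero mean and unit variance).
#'
#' @param A square numeric matrix, or a [directed_network()] whose adjacency
#'   matrix is used.
#' @param tf control horizon, a finite positive scalar (default 1).
#' @param Sigma0 optional `N x N` symmetric positive semidefinite matrix;
#'   default identity.
#' @return an object of class `lti_system` with fields `A`, `tf`, `Sigma0`, `N`.
#' @export
lti_system <- function(A, tf = 1, Sigma0 = NULL) {
  if (inherits(A, "directed_network")) A <- adjacency_matrix(A, sparse = FALSE)
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  if (!is.numeric(tf) || length(tf) != 1 || !is.finite(tf) || tf <= 0) {
    stop("`tf` must be a finite positive scalar")
  }
  n <- nrow(A)
  if (is.null(Sigma0)) {
    Sigma0 <- diag(n)
  } else {
    Sigma0 <- as.matrix(Sigma0)
    if (!isTRUE(all.equal(Sigma0, t(Sigma0), tolerance = 1e-10))) {
      stop("`Sigma0` must be symmetric")
    }
    if (min(eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("`Sigma0` must be positive semidefinite")
    }
  }
  structure(list(A = A, tf = tf, Sigma0 = Sigma0, N = n), class = "lti_system")
}

expm_dense <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M)))
}

# Van Loan block-exponential evaluation of int_0^tf e^{A t} Q e^{A' t} dt:
# expm([[-A, Q], [0, A']] tf) = [[*, G], [0, F]] with F = e^{A' tf} and the
# integral equal to t(F) %*% G.
van_loan_integral <- function(A, Q, tf) {
  n <- nrow(A)
  H <- rbind(cbind(-A, Q), cbind(matrix(0, n, n), t(A)))
  E <- expm_dense(H * tf)
  F3 <- E[n + seq_len(n), n + seq_len(n), drop = FALSE]
  G2 <- E[seq_len(n), n + seq_len(n), drop = FALSE]
  W <- t(F3) %*% G2
  (W + t(W)) / 2
}

#' Controllability Gramian
#'
#' `W_B = int_0^tf exp(A t) B B' exp(A' t) dt`, evaluated by the Van Loan
#' block matrix-exponential construction. `W_B` is symmetric positive
#' semidefinite and invertible exactly when `(A, B)` is controllable; its
#' inverse sets the minimum control energy. A warning flags a numerically
#' near-singular Gramian (the numerical controllability transition: too few
#' or badly placed inputs make the network uncontrollable in finite
#' precision even when it is structurally controllable).
#'
#' @param sys an [lti_system()].
#' @param B `N x M` input matrix.
#' @param rcond_warn warn when the reciprocal condition number falls below
#'   this threshold (default `1e-12`).
#' @return an `N x N` symmetric matrix.
#' @export
ctrl_gramian <- function(sys, B, rcond_warn = 1e-12) {
  stopifnot(inherits(sys, "lti_system"))
  B <- as.matrix(B)
  if (nrow(B) != sys$N) stop("`B` must have N rows")
  W <- van_loan_integral(sys$A, B %*% t(B), sys$tf)
  if (!all(is.finite(W))) stop("non-finite entries in the Gramian")
  rc <- Matrix::rcond(Matrix::Matrix(W))
  if (rc < rcond_warn) {
    warning(sprintf("Gramian is near-singular (rcond = %.2e): the system sits in the numerical controllability transition", rc))
  }
  W
}

# Solve W x = Y for symmetric W, with a consistent singularity policy:
# "error" aborts, "inf" returns +Inf sentinel, "na" returns NA sentinel.
solve_gramian <- function(W, Y, on_singular = c("error", "inf", "na")) {
  on_singular <- match.arg(on_singular)
  out <- tryCatch(solve(W, Y), error = function(e) e)
  if (inherits(out, "error")) {
    if (on_singular == "error") {
      stop("Gramian is singular to working precision: (A, B) is not numerically controllable [",
           conditionMessage(out), "]")
    }
    return(if (on_singular == "inf") Inf else NA_real_)
  }
  out
}

#' Minimum-energy control driving the state to the origin
#'
#' Closed-form minimum-energy input
#' `u(t) = -B' exp(A'(tf - t)) W_B^{-1} exp(A tf) x0`, which steers
#' `dx/dt = A x + B u` from `x0` to the origin at `t = tf` with energy
#' `int ||u||^2 dt = x0' exp(A' tf) W_B^{-1} exp(A tf) x0`.
#'
#' @param sys an [lti_system()].
#' @param B `N x M` input matrix; `(A, B)` must be controllable to working
#'   precision.
#' @param x0 initial state vector of length `N`.
#' @return list with `u` (vectorised function of `t` returning an `M x
#'   length(t)` matrix), `cost` (the realized minimum energy), and `v` (the
#'   constant co-state `W_B^{-1} exp(A tf) x0`).
#' @export
min_energy_control <- function(sys, B, x0) {
  stopifnot(inherits(sys, "lti_system"))
  B <- as.matrix(B)
  x0 <- as.numeric(x0)
  if (length(x0) != sys$N) stop("`x0` must have length N")
  W <- suppressWarnings(ctrl_gramian(sys, B))
  etf <- expm_dense(sys$A * sys$tf)
  y <- etf %*% x0
  v <- solve_gramian(W, y, "error")
  cost <- drop(crossprod(y, v))
  At <- t(sys$A)
  u <- function(t) {
    out <- vapply(t, function(ti) {
      drop(-t(B) %*% expm_dense(At * (sys$tf - ti)) %*% v)
    }, numeric(ncol(B)))
    matrix(out, nrow = ncol(B))
  }
  list(u = u, cost = cost, v = v)
}

#' Expected control cost of an input matrix
#'
#' The objective minimized over `B`:
#' `E(B) = tr(W_B^{-1} exp(A tf) Sigma0 exp(A' tf))`, the expected energy of
#' the minimum-energy control over random initial states with second moment
#' `Sigma0` (identity by default, i.e. i.i.d. unit-variance entries).
#'
#' @param sys an [lti_system()].
#' @param B `N x M` input matrix.
#' @param on_singular what to do when the Gramian is singular to working
#'   precision: `"error"` (default), `"inf"` or `"na"` (explicit-failure
#'   sentinels for experiments that sweep ill-conditioned layouts).
#' @return a non-negative scalar (or the chosen sentinel).
#' @export
expected_cost <- function(sys, B, on_singular = c("error", "inf", "na")) {
  on_singular <- match.arg(on_singular)
  stopifnot(inherits(sys, "lti_system"))
  B <- as.matrix(B)
  W <- suppressWarnings(ctrl_gramian(sys, B))
  etf <- expm_dense(sys$A * sys$tf)
  C <- etf %*% sys$Sigma0 %*% t(etf)
  X <- solve_gramian(W, C, on_singular)
  if (length(X) == 1 && !is.finite(X)) return(X)
  sum(diag(X))
}

#' Analytic gradient of the expected control cost
#'
#' Direct matrix calculus of the expected cost gives
#' `dE/dB = -2 [ int_0^tf exp(A' t) W^{-1} C W^{-1} exp(A t) dt ] B` with
#' `C = exp(A tf) Sigma0 exp(A' tf)`; the integral is evaluated with the same
#' Van Loan block-exponential machinery as the Gramian (with `A` transposed).
#' The returned matrix is the true derivative `dE/dB` (negative semidefinite
#' factor times `B`), validated against central finite differences in the
#' test suite; a descent step moves along `-dE/dB`.
#'
#' @param sys an [lti_system()].
#' @param B `N x M` input matrix.
#' @return `N x M` matrix `dE/dB`.
#' @export
grad_cost <- function(sys, B) {
  stopifnot(inherits(sys, "lti_system"))
  B <- as.matrix(B)
  W <- suppressWarnings(ctrl_gramian(sys, B))
  etf <- expm_dense(sys$A * sys$tf)
  C <- etf %*% sys$Sigma0 %*% t(etf)
  K <- solve_gramian(W, t(solve_gramian(W, C, "error")), "error")
  K <- (K + t(K)) / 2
  S <- van_loan_integral(t(sys$A), K, sys$tf)
  -2 * S %*% B
}

#' Orthonormal-constraint projected gradient method (OPGM)
#'
#' Minimizes the expected control cost over the input matrix `B` on the set
#' `t(B) %*% B = I_M`. Each iteration takes a projected gradient step
#' `Bhat = B - eta (I_N - B B') G`, where `G` is the cost gradient direction
#' of increase, then rescales by
#' `sqrt( tr(Bhat' Bhat) / tr((Bhat' Bhat)^2) )`, which restores
#' `tr((B'B)^2) = tr(B'B)` exactly. With `eta` small enough the cost is
#' non-increasing and the iterates approach an orthonormal matrix.
#'
#' @param sys an [lti_system()].
#' @param M number of control inputs (columns of `B`).
#' @param eta learning step (> 0).
#' @param max_iters iteration cap.
#' @param tol stop when the relative cost change falls below this.
#' @param init optional initial `N x M` matrix; default a random matrix with
#'   orthonormalized columns drawn from the seeded RNG.
#' @param seed integer seed for the random initialization.
#' @param patience stop with a warning (suggesting a smaller `eta`) after
#'   this many consecutive cost increases.
#' @return an object of class `opgm_result`: `B` (the final iterate), `cost`
#'   (trajectory of `E(B_k)`, including the initial cost), `iterations`,
#'   `ortho_residual` (`||B'B - I||_F`), `converged`.
#' @export
opgm <- function(sys, M, eta = 1e-3, max_iters = 500L, tol = 1e-8,
                 init = NULL, seed = 1L, patience = 20L) {
  stopifnot(inherits(sys, "lti_system"))
  M <- as.integer(M)
  if (eta <= 0) stop("`eta` must be positive")
  if (tol <= 0) stop("`tol` must be positive")
  n <- sys$N
  if (is.null(init)) {
    B <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(n * M), n, M))))
  } else {
    B <- as.matrix(init)
    if (!all(dim(B) == c(n, M))) stop("`init` must be N x M")
  }
  I_n <- diag(n)
  costs <- expected_cost(sys, B)
  bad <- 0L
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(max_iters)) {
    G <- grad_cost(sys, B)
    Bhat <- B - eta * (I_n - B %*% t(B)) %*% G
    H <- crossprod(Bhat)
    scale <- sqrt(sum(diag(H)) / sum(H * H))
    B <- scale * Bhat
    ck <- expected_cost(sys, B)
    costs <- c(costs, ck)
    iters <- k
    prev <- costs[k]
    if (ck > prev) {
      bad <- bad + 1L
      if (bad > patience) {
        warning("cost increased for ", patience,
                " consecutive iterations; try a smaller `eta`")
        break
      }
    } else {
      bad <- 0L
      if (abs(prev - ck) <= tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
  }
  structure(
    list(B = B, cost = costs, iterations = iters,
         ortho_residual = norm(crossprod(B) - diag(M), "F"),
         converged = converged),
    class = "opgm_result"
  )
}

#' @export
print.opgm_result <- function(x, ...) {
  cat(sprintf("<opgm_result> %d iteration(s), final cost %.6g, ||B'B - I||_F = %.2e%s\n",
              x$iterations, x$cost[length(x$cost)], x$ortho_residual,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Control cost versus longest inter-input segment on a circle
#'
#' Places `M` unit inputs on an `n`-node elementary circle in each given (or
#' randomly drawn) layout and records the expected control cost together with
#' the layout's longest control path, measured as the maximum number of
#' *edges* between two adjacent control nodes around the circle. The cost is
#' dominated by that longest segment, growing roughly like
#' `(g! / tf^g)^2` in the longest gap `g`, which is why evenly spread inputs
#' are cheap and clustered inputs are expensive.
#'
#' The horizon defaults to `n / 4`: signal propagation over a segment of `g`
#' edges enters the Gramian at order `tf^g / g!`, so the horizon must grow
#' with the attainable segment length for the smallest Gramian eigenvalue to
#' stay within double-precision range. Layouts whose Gramian is still
#' numerically singular get `NA` cost (explicit failure) rather than an
#' unreliable number.
#'
#' @param n circle size (nodes).
#' @param M inputs per layout.
#' @param layouts optional list of integer vectors of distinct node positions
#'   in `1..n`; when `NULL`, `n_layouts` layouts are drawn uniformly.
#' @param n_layouts number of random layouts when `layouts` is `NULL`.
#' @param tf control horizon (default `n / 4`).
#' @param seed integer seed for random layouts.
#' @return data frame with columns `layout` (index), `M`, `longest_segment`
#'   (edges) and `cost` (`NA` when the Gramian is singular to working
#'   precision).
#' @export
cost_vs_longest_path <- function(n, M, layouts = NULL, n_layouts = 20L,
                                 tf = n / 4, seed = 1L) {
  net <- make_circle(n)
  sys <- lti_system(net, tf = tf)
  if (is.null(layouts)) {
    layouts <- with_seed(seed, replicate(n_layouts, sort(sample.int(n, M)),
                                         simplify = FALSE))
  }
  etf <- expm_dense(sys$A * sys$tf)
  C <- etf %*% sys$Sigma0 %*% t(etf)
  rows <- lapply(seq_along(layouts), function(i) {
    pos <- sort(unique(as.integer(layouts[[i]])))
    if (length(pos) != length(layouts[[i]])) stop("layout positions must be distinct")
    if (any(pos < 1L | pos > n)) stop("layout positions out of range")
    gaps <- diff(c(pos, pos[1] + n))
    B <- build_B(net, as.character(pos))
    W <- suppressWarnings(ctrl_gramian(sys, B))
    # an rcond too small for any trust in the solve is an explicit failure
    cost <- if (Matrix::rcond(Matrix::Matrix(W)) < 1e-14) {
      NA_real_
    } else {
      X <- solve_gramian(W, C, "na")
      if (length(X) == 1 && !is.finite(X)) NA_real_ else sum(diag(X))
    }
    data.frame(layout = i, M = length(pos),
               longest_segment = max(gaps), cost = cost)
  })
  do.call(rbind, rows)
}
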