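test_that("Gramian matches its definition in closed-form scalar cases", {
  A0 <- matrix(0, 1, 1)
  expect_equal(ctrl_gramian(lti_system(A0, tf = 1), matrix(1)), matrix(1))
  expect_equal(ctrl_gramian(lti_system(A0, tf = 2), matrix(1)), matrix(2))
})

test_that("Gramian agrees with quadrature on random stable systems", {
  set.seed(31)
  for (n in c(3, 5, 8)) {
    A <- matrix(rnorm(n * n), n)
    A <- A - (max(Re(eigen(A, only.values = TRUE)$values)) + 0.5) * diag(n)
    B <- matrix(rnorm(n * 2), n)
    tf <- 1.3
    W <- ctrl_gramian(lti_system(A, tf = tf), B)
    Wq <- quad_gramian(A, B %*% t(B), tf)
    expect_lt(norm(W - Wq, "F") / norm(Wq, "F"), 1e-8)
    expect_equal(W, t(W), tolerance = 1e-12)
    expect_gte(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("minimum-energy control reaches the origin with the predicted cost", {
  skip_if_not_installed("deSolve")
  # scalar closed form: A=0, B=1, tf=1, x0=1 -> u = -1, cost 1
  mec <- min_energy_control(lti_system(matrix(0, 1, 1), tf = 1), matrix(1), 1)
  expect_equal(drop(mec$u(c(0, 0.5, 1))), c(-1, -1, -1))
  expect_equal(mec$cost, 1)
  # zero initial state costs nothing
  mec0 <- min_energy_control(lti_system(matrix(0, 1, 1), tf = 1), matrix(1), 0)
  expect_equal(mec0$cost, 0)
  expect_equal(drop(mec0$u(0.3)), 0)

  # stem(4) driven from its head: simulate the closed loop
  net <- make_stem(4)
  sys <- lti_system(net, tf = 1)
  B <- build_B(net, "1")
  set.seed(9)
  x0 <- rnorm(4)
  mec <- min_energy_control(sys, B, x0)
  A <- adjacency_matrix(net, sparse = FALSE)
  traj <- deSolve::ode(y = x0, times = seq(0, 1, length.out = 201),
                       func = function(t, x, p) list(A %*% x + B %*% mec$u(t)),
                       parms = NULL, rtol = 1e-10, atol = 1e-12)
  xf <- traj[nrow(traj), -1]
  expect_lt(sqrt(sum(xf^2)), 1e-6 * sqrt(sum(x0^2)))
  # realized energy equals the quadratic form
  gl <- pracma::gaussLegendre(80, 0, 1)
  realized <- sum(gl$w * colSums(mec$u(gl$x)^2))
  expect_lt(abs(realized - mec$cost) / mec$cost, 1e-6)

  # uncontrollable input placement fails loudly
  expect_error(min_energy_control(sys, build_B(net, "4"), x0), "controllable")
})

test_that("expected cost equals the Monte-Carlo mean over random initial states", {
  net <- make_stem(3)
  sys <- lti_system(net, tf = 1)
  B <- build_B(net, "1")
  ec <- expected_cost(sys, B)
  expect_equal(expected_cost(lti_system(matrix(0, 1, 1), tf = 1), matrix(1)), 1)
  expect_gte(ec, 0)
  W <- ctrl_gramian(sys, B)
  etf <- as.matrix(Matrix::expm(Matrix::Matrix(adjacency_matrix(net) * 1)))
  K <- t(etf) %*% solve(W, etf)
  set.seed(4)
  X <- matrix(rnorm(3 * 1e4), 3)
  costs <- colSums(X * (K %*% X))
  se <- stats::sd(costs) / sqrt(ncol(X))
  expect_lt(abs(mean(costs) - ec), 3 * se)
})

test_that("analytic gradient matches finite differences and scalar calculus", {
  # A=0, B=1: E = 1/B^2, dE/dB at 1 is -2
  g <- grad_cost(lti_system(matrix(0, 1, 1), tf = 1), matrix(1))
  expect_equal(drop(g), -2)

  fd_check <- function(sys, B, h = 1e-5) {
    fd <- B * 0
    for (i in seq_along(B)) {
      Bp <- B; Bp[i] <- Bp[i] + h
      Bm <- B; Bm[i] <- Bm[i] - h
      fd[i] <- (expected_cost(sys, Bp) - expected_cost(sys, Bm)) / (2 * h)
    }
    fd
  }
  net <- make_stem(3)
  sys <- lti_system(net, tf = 1)
  B <- build_B(net, "1")
  expect_lt(norm(grad_cost(sys, B) - fd_check(sys, B), "F") /
              norm(fd_check(sys, B), "F"), 1e-4)
  # a random two-input system
  set.seed(21)
  A <- matrix(rnorm(16), 4) / 4
  sys2 <- lti_system(A, tf = 0.8)
  B2 <- qr.Q(qr(matrix(rnorm(8), 4)))
  expect_lt(norm(grad_cost(sys2, B2) - fd_check(sys2, B2), "F") /
              norm(fd_check(sys2, B2), "F"), 1e-4)

  # homogeneity: scaling B by c scales E by c^-2, so B.grad = -2E
  expect_equal(sum(B2 * grad_cost(sys2, B2)), -2 * expected_cost(sys2, B2),
               tolerance = 1e-8)
})

test_that("OPGM descends, stays trace-normalized and fixes M = N identity", {
  net <- make_stem(3)
  sys <- lti_system(net, tf = 1)
  res <- opgm(sys, 1, eta = 1e-4, max_iters = 300, seed = 2)
  expect_true(all(diff(res$cost) <= 1e-9 * pmax(abs(res$cost[-length(res$cost)]), 1)))
  expect_lt(res$ortho_residual, 1e-6)
  expect_true(res$converged)
  # the optimal single input concentrates on the path head
  expect_equal(which.max(abs(res$B[, 1])), 1L)

  # printed rescale restores tr((B'B)^2) = tr(B'B) for arbitrary matrices
  set.seed(11)
  for (i in 1:5) {
    Bhat <- matrix(rnorm(12), 4)
    H <- crossprod(Bhat)
    Bk <- sqrt(sum(diag(H)) / sum(H * H)) * Bhat
    Hk <- crossprod(Bk)
    expect_lt(abs(sum(Hk * Hk) - sum(diag(Hk))), 1e-10)
  }

  # M = N with identity init is a fixed point of the update
  sysc <- lti_system(make_circle(4), tf = 1)
  r <- opgm(sysc, 4, eta = 1e-3, max_iters = 5, init = diag(4))
  expect_equal(r$B, diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(diff(range(r$cost)), 1e-9 * abs(r$cost[1]))
})

test_that("circle cost grows with the longest inter-input segment", {
  # evenly spaced inputs beat one adjacent cluster
  even <- seq(1, 12, by = 2)
  cluster <- 1:6
  tab <- cost_vs_longest_path(12, 6, layouts = list(even, cluster))
  expect_lt(tab$cost[1], tab$cost[2])
  expect_equal(tab$longest_segment, c(2L, 7L))
  # full coverage gives segment 1 and the smallest cost of the three
  tab2 <- cost_vs_longest_path(12, 12, layouts = list(1:12))
  expect_equal(tab2$longest_segment, 1L)
  expect_lt(tab2$cost, tab$cost[1])
})
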