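test_that("LM resolves the elementary topologies by hand-checkable rounds", {
  # stem: every request is forced and mutual; one DCP headed by node 1
  res <- lm_match(make_stem(5))
  expect_equal(length(res$dcps), 1)
  expect_equal(res$dcps[[1]]$nodes, as.character(1:5))
  expect_equal(res$drivers, "1")
  expect_equal(required_inputs(res), 1)

  # circle: all requests forced and mutual; one CCP, no driver, still 1 input
  res <- lm_match(make_circle(3))
  expect_equal(length(res$dcps), 0)
  expect_equal(length(res$ccps), 1)
  expect_equal(res$ccps[[1]]$L, 3)
  expect_equal(res$drivers, character(0))
  expect_equal(required_inputs(res), 1)

  # isolated nodes: no requests possible, every node a singleton DCP driver
  iso <- directed_network(nodes = as.character(1:4))
  res <- lm_match(iso)
  expect_equal(length(res$dcps), 4)
  expect_setequal(res$drivers, as.character(1:4))

  # a self-loop can self-match into a singleton CCP
  res <- lm_match(make_circle(1))
  expect_equal(length(res$ccps), 1)
  expect_equal(required_inputs(res), 1)

  # empty network
  res <- lm_match(directed_network())
  expect_equal(required_inputs(res), 0)
  expect_equal(res$rounds, 0)
})

test_that("LM results are valid partitions on random networks", {
  for (s in 1:10) {
    fam <- if (s %% 2) "er" else "ba"
    net <- generate_network(fam, 80, mu = 1 + (s %% 4), m = 1 + (s %% 4),
                            seed = 100 + s)
    res <- lm_match(net, omega = (s %% 3) / 4, seed = s)
    expect_valid_lm(res, net)
  }
})

test_that("LM is deterministic given network, omega and seed", {
  net <- generate_network("er", 200, mu = 4, seed = 5)
  a <- lm_match(net, omega = 0.3, seed = 9)
  b <- lm_match(net, omega = 0.3, seed = 9)
  expect_identical(a, b)
  c <- lm_match(net, omega = 0.3, seed = 10)
  expect_false(identical(a$drivers, c$drivers) && identical(a$child_of, c$child_of))
})

test_that("exact maximum matching agrees with exhaustive search on small graphs", {
  expect_equal(mm_exact(make_stem(5))$size, 4)
  expect_equal(mm_exact(make_stem(5))$N_D, 1)
  expect_equal(mm_exact(make_circle(3))$size, 3)
  expect_equal(mm_exact(make_circle(3))$N_D, 1) # perfect matching still needs one input
  star <- directed_network(c("1", "1", "1"), c("2", "3", "4"))
  expect_equal(mm_exact(star)$size, 1)
  expect_equal(mm_exact(star)$N_D, 3)
  for (s in 1:15) {
    net <- generate_network("er", 6, mu = 1.5, seed = 200 + s)
    mm <- mm_exact(net)
    expect_equal(mm$size, brute_max_matching(net), label = paste("seed", s))
    # matching validity: no shared start or end nodes
    expect_equal(anyDuplicated(mm$matching$from), 0L)
    expect_equal(anyDuplicated(mm$matching$to), 0L)
  }
})

test_that("LM never beats the exact optimum and rounds stay modest", {
  for (s in 1:8) {
    net <- generate_network("er", 150, mu = s, seed = 300 + s)
    lm <- lm_match(net, seed = s)
    expect_gte(max(lm$n_drivers, 1), mm_exact(net)$N_D)
    expect_lte(lm$rounds, 60) # empirically ~4-15; far below N
  }
})

test_that("driver degree histograms are normalized and sensible", {
  s5 <- make_stem(5)
  h <- driver_degree_histogram(lm_match(s5), s5)
  expect_equal(h$in_deg, data.frame(degree = 0L, prob = 1))
  star <- directed_network(c("1", "1", "1"), c("2", "3", "4"))
  hm <- driver_degree_histogram(mm_exact(star), star)
  expect_equal(sum(hm$in_deg$prob), 1)
  # the three unmatched nodes are the hub (in-degree 0) and two leaves
  expect_setequal(hm$in_deg$degree, c(0L, 1L))
  # empty driver set -> empty histograms
  h0 <- driver_degree_histogram(lm_match(make_circle(4)), make_circle(4))
  expect_equal(nrow(h0$in_deg), 0)
  # total variation of a histogram with itself is 0
  expect_equal(histogram_tv(h$in_deg, h$in_deg), 0)
  expect_equal(histogram_tv(h$in_deg, hm$in_deg), 2 / 3)
})
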