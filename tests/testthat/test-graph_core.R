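test_that("edge-list construction, dedup and degree bookkeeping", {
  net <- directed_network(c("1", "2"), c("2", "3"))
  expect_equal(net$N, 3)
  expect_equal(net$L, 2)
  expect_equal(mean_degree(net), 2 / 3)

  expect_warning(dup <- directed_network(c("1", "1"), c("2", "2")), "duplicate")
  expect_equal(dup$N, 2)
  expect_equal(dup$L, 1)

  # self-loops are allowed
  self <- directed_network("a", "a")
  expect_equal(self$L, 1)

  # degree sums equal the edge count
  net <- generate_network("er", 200, mu = 3, seed = 11)
  dv <- degree_view(net)
  expect_equal(sum(dv$in_degree), net$L)
  expect_equal(sum(dv$out_degree), net$L)
  expect_true(all(dv$u_in <= dv$in_degree))
  expect_true(all(dv$u_out <= dv$out_degree))

  # after LM, u-degrees are restricted to unmatched neighbours
  lm <- lm_match(net, seed = 1)
  dv2 <- degree_view(net, lm)
  expect_true(all(dv2$u_in <= dv$u_in))
  expect_true(all(dv2$u_out <= dv$u_out))

  expect_error(directed_network("a", "b", nodes = "a"), "not in node set")
})

test_that("edge-list files read and write verbatim, with line-level errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "1 2", "2 3"), path)
  net <- read_edge_list(path)
  expect_equal(net$N, 3)
  expect_equal(net$L, 2)
  expect_setequal(net$nodes, c("1", "2", "3"))

  writeLines(character(0), path)
  empty <- read_edge_list(path)
  expect_equal(empty$N, 0)
  expect_equal(empty$L, 0)

  writeLines(c("1 2", "1 2"), path)
  expect_warning(dup <- read_edge_list(path), "duplicate")
  expect_equal(c(dup$N, dup$L), c(2, 1))

  writeLines(c("1 2", "3"), path)
  expect_error(read_edge_list(path), "line 2")
  writeLines(c("1 2 heavy"), path)
  expect_error(read_edge_list(path), "non-numeric weight at line 1")

  # round trip preserves topology and weights
  net <- directed_network(c("x", "y"), c("y", "z"), weight = c(0.5, 2))
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(edge_list(back), edge_list(net))

  expect_error(read_edge_list(path, directed = FALSE), "not supported")
})

test_that("adjacency orientation: edge i->j is stored at A[j, i]", {
  net <- directed_network("1", "2", weight = 3)
  A <- adjacency_matrix(net, sparse = FALSE)
  expect_equal(A["2", "1"], 3)
  expect_equal(A["1", "2"], 0)
  back <- network_from_adjacency(A)
  expect_equal(edge_list(back), edge_list(net))
})

test_that("Matrix Market adjacency round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".mtx")
  chain <- directed_network("1", "2")
  write_adjacency(chain, path)
  expect_equal(unname(as.matrix(read_matrix_market(path))),
               unname(as.matrix(adjacency_matrix(chain))))

  loop <- directed_network("1", "1", weight = 2.25)
  write_adjacency(loop, path)
  A <- as.matrix(read_matrix_market(path))
  expect_equal(A[1, 1], 2.25)

  tri <- make_circle(3)
  write_adjacency(tri, path)
  A <- as.matrix(read_matrix_market(path))
  expect_equal(sum(A != 0), 3)
  expect_equal(unname(A), unname(as.matrix(adjacency_matrix(tri))))

  expect_error(write_adjacency(directed_network(), path), "empty")
})

test_that("GraphML import reads nodes, edges and weights", {
  path <- withr::local_tempfile(fileext = ".graphml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '<graph edgedefault="directed">',
    '<node id="a"/><node id="b"/><node id="c"/>',
    '<edge source="a" target="b"><data key="w">2.5</data></edge>',
    '<edge source="b" target="c"/>',
    '</graph></graphml>'
  ), path)
  g <- read_graphml(path)
  expect_equal(g$N, 3)
  expect_equal(g$L, 2)
  el <- edge_list(g)
  expect_equal(el$weight[el$from == "a"], 2.5)
  expect_equal(el$weight[el$from == "b"], 1)
})
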