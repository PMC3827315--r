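test_that("signed weights bin into the four categories", {
  b <- weight_bins(boundary = 1)
  expect_equal(bin_weight(2, b), "large_positive")
  expect_equal(bin_weight(-2, b), "large_negative")
  expect_equal(bin_weight(0.4, b), "small_positive")
  expect_equal(bin_weight(-0.4, b), "small_negative")
  expect_equal(bin_weight(0, b), "small_positive")  # tie-break convention
  expect_equal(bin_weight(c(-1, 1), b), c("large_negative", "large_positive"))
})

test_that("the colored-graph transform subdivides every connection", {
  set.seed(1)
  net <- rand_network(n_in = 2, n_hid = 3, n_out = 2, p_edge = 0.5)
  cg <- to_colored_graph(net, prune = FALSE)
  N <- nrow(net$neurons); C <- nrow(net$connections)
  expect_equal(nrow(cg$vertices), N + C)
  expect_equal(nrow(cg$edges), 2 * C)
  expect_setequal(unique(cg$vertices$color[seq_len(N)]), c("n", "m"))

  # biases are ignored: changing them changes nothing
  net2 <- net
  net2$neurons$bias <- rev(net2$neurons$bias) + 0.5
  expect_identical(to_colored_graph(net2, prune = FALSE), cg)

  # flipping one connection's sign flips exactly one vertex color
  net3 <- net
  big <- which(net3$connections$weight >= 1)[1]
  net3$connections$sign[big] <- -net3$connections$sign[big]
  cg3 <- to_colored_graph(net3, prune = FALSE)
  expect_equal(sum(cg3$vertices$color != cg$vertices$color), 1)
})

test_that("plastic weights are normalized to the midpoint by default", {
  net <- make_fixture("hand_learner")
  set.seed(2)
  net <- reset_plastic_weights(net)
  cg_mid <- to_colored_graph(net)
  set.seed(3)
  cg_mid2 <- to_colored_graph(reset_plastic_weights(net))
  expect_identical(cg_mid, cg_mid2)   # independent of learning history
  # snapshot mode reflects the current magnitudes instead
  net$connections$weight[net$connections$plastic] <- 0.3
  snap <- to_colored_graph(net, plastic_weights = "snapshot")
  expect_false(identical(snap, cg_mid))
})

test_that("automorphism counts match Fig.-style canonical cases", {
  # a single vertex has only the identity
  expect_equal(count_automorphisms(
    colored_graph(tibble::tibble(id = "a", color = "n"), NULL)), 1)
  # uniform complete digraphs have n! automorphisms (brute force, n <= 5)
  for (n in 2:5) {
    net <- make_fixture("fully_connected", n = n)
    plain <- colored_graph(
      tibble::tibble(id = net$neurons$id, color = "n"),
      net$connections[, c("from", "to")])
    expect_equal(brute_force_automorphisms(plain), factorial(n))
    expect_equal(count_automorphisms(net), factorial(n))
  }
  # layered nets: swaps within each layer, independently
  expect_equal(count_automorphisms(make_fixture("mlp", layers = c(2, 2))), 4)
  expect_equal(count_automorphisms(make_fixture("mlp", layers = c(4, 4))),
               factorial(4)^2)
  # the lamprey-like CPG ladder has two independent axial symmetries
  lam <- make_fixture("lamprey_cpg")
  expect_equal(count_automorphisms(lam), 4)
  plain_lam <- colored_graph(
    tibble::tibble(id = lam$neurons$id, color = "n"),
    lam$connections[, c("from", "to")])
  expect_equal(brute_force_automorphisms(plain_lam), 4)
  # a typical random network has only itself
  expect_equal(count_automorphisms(make_fixture("random_rigid")), 1)
})

test_that("exact counter agrees with brute force on random colored graphs", {
  set.seed(4)
  for (i in 1:80) {
    cg <- rand_colored_graph(max_n = 7, n_colors = sample(1:3, 1))
    expect_equal(count_automorphisms(cg), brute_force_automorphisms(cg))
  }
})

test_that("counts are at least 1 and rigid unions stay rigid", {
  set.seed(5)
  for (i in 1:20)
    expect_gte(count_automorphisms(rand_colored_graph()), 1)
  # disjoint union of two non-isomorphic rigid graphs: still 1
  path3 <- colored_graph(
    tibble::tibble(id = c("a", "b", "c"), color = "n"),
    tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  expect_equal(brute_force_automorphisms(path3), 1)
  union <- colored_graph(
    tibble::tibble(id = c("a", "b", "c", "d", "e"), color = "n"),
    tibble::tibble(from = c("a", "b", "d"), to = c("b", "c", "e")))
  expect_equal(count_automorphisms(union), 1)
  expect_equal(brute_force_automorphisms(union), 1)
  # two isolated same-colored vertices can swap
  two <- colored_graph(tibble::tibble(id = c("a", "b"), color = "n"), NULL)
  expect_equal(brute_force_automorphisms(two), 2)
  # a directed 3-cycle has its 3 rotations
  cyc <- colored_graph(
    tibble::tibble(id = c("a", "b", "c"), color = "n"),
    tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a")))
  expect_equal(brute_force_automorphisms(cyc), 3)
  expect_equal(count_automorphisms(cyc), 3)
  big <- colored_graph(
    tibble::tibble(id = paste0("v", 1:11), color = "n"), NULL)
  expect_error(brute_force_automorphisms(big), "10 vertices")
})

test_that("colored graphs export to GraphML and DIMACS-like text", {
  set.seed(6)
  cg <- rand_colored_graph()
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".col")
  write_colored_graph_graphml(cg, p1)
  write_colored_graph_dimacs(cg, p2)
  expect_true(file.exists(p1) && file.exists(p2))
  lines <- readLines(p2)
  expect_match(lines[1], "^p edge")
  expect_equal(length(lines), 1 + nrow(cg$vertices) + nrow(cg$edges))
})
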