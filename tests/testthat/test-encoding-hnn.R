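test_that("CPPN evaluation composes its function nodes", {
  # single linear pass-through: output equals input
  g <- const_cppn(1, 0)
  g$edges <- tibble::tibble(from = "in_1", to = "out_1", sign = 1, weight = 1)
  for (x in c(-2, 0, 0.7)) expect_equal(cppn_eval(g, x), x)
  # Gaussian node peaks at 1 for input 0
  g$nodes$fun[g$nodes$id == "out_1"] <- "gaussian"
  expect_equal(cppn_eval(g, 0), 1)
  # two-node composition: gaussian(2 * x), then sigmoid(0.5 * g + 0.3)
  h <- const_cppn(1, 0)
  h$nodes <- rbind(h$nodes, tibble::tibble(
    id = "mid", role = "hidden", kind = "standard", bias = 0,
    fun = "gaussian", label = NA_character_))
  h$nodes$fun[h$nodes$id == "out_1"] <- "sigmoid"
  h$nodes$bias[h$nodes$id == "out_1"] <- 0.3
  h$edges <- tibble::tibble(from = c("in_1", "mid"), to = c("mid", "out_1"),
                            sign = 1, weight = c(2, 0.5))
  x <- 0.4
  expect_equal(cppn_eval(h, x),
               1 / (1 + exp(-(0.5 * exp(-(2 * x)^2) + 0.3))))
  expect_error(cppn_eval(h, c(1, 2)), "arity")
})

test_that("cyclic CPPNs raise a classed genotype error", {
  g <- const_cppn(1, 0)
  g$nodes <- rbind(g$nodes, tibble::tibble(
    id = c("a", "b"), role = "hidden", kind = "standard", bias = 0,
    fun = "linear", label = NA_character_))
  g$edges <- tibble::tibble(from = c("a", "b"), to = c("b", "a"),
                            sign = 1, weight = 1)
  expect_error(cppn_eval(g, 0), class = "plastevo_cppn_cycle")
})

test_that("the default substrate is layered, distinct and mirror-symmetric", {
  s <- default_substrate()
  expect_equal(nrow(s), 19)
  s9 <- default_substrate(9)
  expect_equal(nrow(s9), 18)
  for (sub in list(s, s9)) {
    expect_equal(anyDuplicated(sub[, c("x", "y", "z")]), 0)
    expect_equal(sort(unique(sub$z)), c(-1, 0, 1))
    expect_equal(unique(sub$z[sub$role == "input"]), -1)
    expect_equal(unique(sub$z[sub$role == "output"]), 1)
  }
  # left-right mirror pairs stimulus i with stimulus 5 - i
  stim_x <- s$x[s$group == "stimulus"]
  expect_equal(stim_x, -rev(stim_x))
  expect_identical(default_substrate(), default_substrate())
})

test_that("development follows LEO threshold and modulatory cutoff", {
  s <- default_substrate()
  node <- const_cppn(4, c(0.5, 0.8))       # bias 0.5, kind 0.8 -> standard
  below <- list(conn = const_cppn(7, c(0.4, 0.7)), node = node)
  net0 <- develop_hnn(below, s)
  expect_equal(nrow(net0$connections), 0)
  above <- list(conn = const_cppn(7, c(0.9, 0.7)), node = node)
  net1 <- develop_hnn(above, s)
  # all allowed ordered pairs: sources 15 (10 in + 5 hid), targets of
  # hidden/output kind; hidden-hidden includes self-loops
  n_pairs <- 10 * 9 + 5 * 9
  expect_equal(nrow(net1$connections), n_pairs)
  expect_true(all(net1$connections$weight == 0.7 * 2))
  expect_true(all(net1$connections$sign == 1))
  expect_true(all(net1$neurons$kind == "standard"))

  # kind output below 0.4 makes hidden neurons modulatory, 0.41 does not
  kindify <- function(k)
    develop_hnn(list(conn = const_cppn(7, c(0.9, 0.5)),
                     node = const_cppn(4, c(0, k))), s)
  expect_true(all(
    kindify(0.39)$neurons$kind[kindify(0.39)$neurons$role == "hidden"] ==
      "modulatory"))
  expect_true(all(kindify(0.41)$neurons$kind == "standard"))
  # inputs and outputs stay standard regardless
  expect_true(all(
    kindify(0.39)$neurons$kind[kindify(0.39)$neurons$role != "hidden"] ==
      "standard"))
  # development is deterministic
  expect_identical(develop_hnn(above, s), develop_hnn(above, s))
})

test_that("a mirror-invariant connection CPPN yields a symmetric network", {
  # LEO depends only on (x1 - x2)^2, so the substrate's left-right
  # mirror is an automorphism of the developed network
  conn <- const_cppn(7, c(0, 0.6))
  conn$nodes <- rbind(conn$nodes, tibble::tibble(
    id = "d", role = "hidden", kind = "standard", bias = 0,
    fun = "gaussian", label = NA_character_))
  conn$edges <- tibble::tibble(
    from = c("in_1", "in_4", "d"), to = c("d", "d", "out_1"),
    sign = c(1, -1, 1), weight = c(2, 2, 1))
  net <- develop_hnn(list(conn = conn, node = const_cppn(4, c(0.2, 0.8))))
  expect_gt(nrow(net$connections), 0)
  expect_gte(count_automorphisms(net), 2)
  expect_true(all(net$connections$weight >= 0 & net$connections$weight <= 2))
})

test_that("random CPPN pairs develop into bounded task-shaped networks", {
  set.seed(2)
  for (i in 1:5) {
    hg <- random_init_hnn()
    for (k in 1:10) hg <- mutate_hnn(hg)
    net <- tryCatch(develop_hnn(hg), condition = function(c) NULL)
    if (is.null(net)) next    # cyclic genotype: rejected at evaluation
    expect_equal(sum(net$neurons$role == "input"), 10)
    expect_equal(sum(net$neurons$role == "output"), 4)
    expect_true(all(net$connections$weight <= 2 + 1e-12))
  }
})
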