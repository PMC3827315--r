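test_that("a driven neuron outputs the sigmoid of its summed input", {
  # all-zero inputs and biases: every non-input neuron sits at phi(0) = 0.5
  set.seed(1)
  net <- rand_network()
  net$neurons$bias[] <- 0
  net <- net_step(net, rep(0, 3))
  expect_equal(unname(net$state[net$neurons$role != "input"]),
               rep(0.5, sum(net$neurons$role != "input")))

  # a neuron with no incoming connections outputs phi(bias)
  iso <- plastic_network(
    tibble::tibble(id = c("i", "o"), role = c("input", "output"),
                   kind = "standard", bias = c(0, 0.7)),
    NULL, lambda = 5)
  iso <- net_step(iso, 0.3)
  expect_equal(unname(iso$state["o"]), 1 / (1 + exp(-5 * 0.7)))
  expect_equal(unname(iso$state["i"]), 0.3)  # inputs relay, no sigmoid

  # hand evaluation of a 3-neuron chain, two steps
  ch <- chain_network(w1 = 1.5, w2 = 0.8, bias_h = 0.2, bias_o = -0.3)
  ch <- net_step(ch, 1)
  phi <- function(x) 1 / (1 + exp(-5 * x))
  h1 <- phi(1.5 * 1 + 0.2)           # input visible at its first step
  expect_equal(unname(ch$state["h"]), h1)
  expect_equal(unname(ch$state["out"]), phi(0.8 * 0 - 0.3))  # h was 0
  ch <- net_step(ch, 1)
  expect_equal(unname(ch$state["out"]), phi(0.8 * h1 - 0.3))
})

test_that("step rejects an input vector of the wrong length", {
  set.seed(2)
  net <- rand_network(n_in = 3)
  expect_error(net_step(net, c(1, 0)), "does not match")
})

test_that("step matches a naive two-buffer reference on random networks", {
  set.seed(3)
  for (rep in 1:10) {
    net <- rand_network(n_in = 2, n_hid = 5, n_out = 2, p_edge = 0.5)
    inputs <- stats::runif(2)
    a <- net_step(net, inputs)
    b <- naive_step(net, inputs)
    expect_equal(a$state, b$state)
    expect_equal(a$mod, b$mod)
  }
})

test_that("Hebbian updates follow the modulated rule exactly", {
  # one hand-checked update: dw = eta * tanh(m) * o_post * o_pre
  net <- chain_network(modulated = TRUE, eta = 0.1)
  net <- net_step(net, 1)   # activations now defined; m uses pre-step 0s
  net <- net_step(net, 1)   # now the modulatory neuron's output reaches out
  w_before <- net$connections$weight[net$connections$from == "h"]
  m_out <- net$mod[["out"]]
  expect_gt(m_out, 0)
  dw <- 0.1 * tanh(m_out) * net$state[["out"]] * net$state[["h"]]
  net2 <- apply_plasticity(net)
  w_after <- net2$connections$weight[net2$connections$from == "h"]
  expect_equal(w_after, w_before + dw)
  # the modulatory connection itself must not change
  expect_equal(net2$connections$weight[net2$connections$from == "m"],
               net$connections$weight[net$connections$from == "m"])
})

test_that("zero modulation freezes all weights", {
  # no modulatory neurons: no plastic connections, nothing ever changes
  set.seed(4)
  net <- rand_network(p_mod = 0)
  expect_false(any(net$connections$plastic))
  w0 <- net$connections$weight
  for (i in 1:20) {
    net <- net_step(net, stats::runif(3))
    net <- apply_plasticity(net)
  }
  expect_equal(net$connections$weight, w0)
})

test_that("sustained modulation saturates plastic weights at w_max", {
  net <- chain_network(modulated = TRUE, eta = 0.5)
  prev <- net$connections$weight[net$connections$from == "h"]
  for (i in 1:100) {
    net <- net_step(net, 1)
    net <- apply_plasticity(net)
    w <- net$connections$weight[net$connections$from == "h"]
    expect_gte(w, prev)           # monotone increase under positive m
    prev <- w
  }
  expect_equal(prev, net$params$w_max)
})

test_that("magnitudes stay in bounds under random operation sequences", {
  set.seed(5)
  for (rep in 1:5) {
    net <- rand_network(p_mod = 0.5, p_edge = 0.6)
    net$params$eta <- 2  # aggressive learning to stress the clamp
    for (i in 1:50) {
      op <- sample(3, 1)
      if (op == 1) net <- net_step(net, stats::runif(3))
      else if (op == 2) net <- apply_plasticity(net)
      else net <- reset_plastic_weights(net)
    }
    expect_true(all(net$connections$weight >= net$params$w_min - 1e-12))
    expect_true(all(net$connections$weight <= net$params$w_max + 1e-12))
  }
})

test_that("activate respects the learn flag and is deterministic", {
  set.seed(6)
  net <- rand_network(p_mod = 0.5)
  frozen <- activate(net, c(1, 0, 0.5), n_steps = 8, learn = FALSE)
  expect_equal(frozen$connections$weight, net$connections$weight)
  expect_error(activate(net, c(1, 0, 0.5), n_steps = 0), "n_steps")
  # identical calls give bitwise-identical traces
  a <- activate(net, c(1, 0, 0.5), n_steps = 5, learn = FALSE)
  b <- activate(net, c(1, 0, 0.5), n_steps = 5, learn = FALSE)
  expect_identical(a$state, b$state)
})

test_that("signals propagate one layer per synchronous step", {
  # depth-2 path: the output can depend on the input only after 2 steps
  ch0 <- chain_network()
  ch1 <- chain_network()
  a0 <- net_step(ch0, 0); a1 <- net_step(ch1, 1)
  expect_equal(a0$state[["out"]], a1$state[["out"]])  # not yet reached
  b0 <- net_step(a0, 0); b1 <- net_step(a1, 1)
  expect_false(isTRUE(all.equal(b0$state[["out"]], b1$state[["out"]])))
})

test_that("reset_plastic_weights redraws only plastic magnitudes", {
  set.seed(7)
  net <- rand_network(p_mod = 0)
  w0 <- net$connections$weight
  expect_equal(reset_plastic_weights(net)$connections$weight, w0)

  net <- chain_network(modulated = TRUE)
  set.seed(123); a <- reset_plastic_weights(net)
  set.seed(123); b <- reset_plastic_weights(net)
  expect_identical(a$connections$weight, b$connections$weight)
  expect_equal(unname(a$state), rep(0, nrow(a$neurons)))
  # fixed (non-plastic) wiring untouched
  expect_equal(a$connections$weight[!a$connections$plastic],
               net$connections$weight[!net$connections$plastic])

  # uniform moments: mean of many resets near (w_min + w_max) / 2
  set.seed(8)
  draws <- replicate(10000,
    reset_plastic_weights(net)$connections$weight[net$connections$plastic][1])
  se <- sqrt(1 / 3) / sqrt(10000)  # sd of U(0, 2) is 2/sqrt(12)
  expect_lt(abs(mean(draws) - 1), 3 * se)
})

test_that("pruning keeps exactly the input-output core", {
  set.seed(9)
  g <- random_init_direct(list(n_in = 3, n_out = 2))
  net <- develop_direct(g)
  expect_equal(prune_to_io(net)$neurons, net$neurons)

  # isolated hidden neuron disappears; one with no path onward too
  aug <- net
  aug$neurons <- rbind(aug$neurons, tibble::tibble(
    id = c("iso", "deadend"), role = "hidden", kind = "standard",
    bias = 0, label = NA_character_))
  aug$state <- c(aug$state, iso = 0, deadend = 0)
  aug$mod <- c(aug$mod, iso = 0, deadend = 0)
  aug$connections <- rbind(aug$connections, tibble::tibble(
    from = "in_1", to = "deadend", sign = 1, weight = 1, plastic = FALSE))
  pr <- prune_to_io(aug)
  expect_false(any(c("iso", "deadend") %in% pr$neurons$id))
  expect_setequal(pr$neurons$id, net$neurons$id)
})

test_that("networks survive a JSON round trip", {
  set.seed(10)
  net <- rand_network(p_mod = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$neurons, net$neurons)
  expect_equal(back$connections, net$connections)
  expect_equal(back$params, net$params)
})

test_that("network validation catches malformed inputs", {
  n <- tibble::tibble(id = c("a", "b"), role = c("input", "output"),
                      kind = "standard", bias = 0)
  expect_error(plastic_network(n[c(1, 1), ], NULL), "unique")
  expect_error(plastic_network(
    tibble::tibble(id = "a", role = "input", kind = "modulatory", bias = 0),
    NULL), "modulatory")
  expect_error(plastic_network(
    n, tibble::tibble(from = "a", to = "zz", sign = 1, weight = 1)),
    "existing")
  expect_error(plastic_network(
    n, tibble::tibble(from = "a", to = "b", sign = 1, weight = 5)),
    "magnitudes")
})
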