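test_that("the global training set enumerates every association set once", {
  g <- enumerate_global_set(4, 4)
  expect_equal(nrow(g), 256)
  expect_equal(ncol(g), 4)
  expect_equal(anyDuplicated(g), 0)
  # lexicographic order, stimulus 1 most significant
  expect_equal(g[1, ], c(stimulus_1 = 1, stimulus_2 = 1,
                         stimulus_3 = 1, stimulus_4 = 1))
  expect_equal(g[256, ], c(stimulus_1 = 4, stimulus_2 = 4,
                           stimulus_3 = 4, stimulus_4 = 4))
  expect_equal(unname(g[2, "stimulus_4"]), 2)

  # size law |G| = n_actions ^ n_stimuli, against a brute-force product
  for (ns in 1:3) for (na in 1:3) {
    gg <- enumerate_global_set(ns, na)
    expect_equal(nrow(gg), na^ns)
    expect_equal(anyDuplicated(gg), 0)
  }
  expect_equal(nrow(enumerate_global_set(1, 7)), 7)
  expect_equal(nrow(enumerate_global_set(2, 3)), 9)
  expect_error(enumerate_global_set(0, 4), "positive")
})

test_that("evolutionary training sets are reproducible distinct subsets", {
  g <- enumerate_global_set(4, 4)
  expect_error(sample_training_set(g, 0), "between")
  expect_error(sample_training_set(g, 300), "between")
  set.seed(1)
  full <- sample_training_set(g, 256)
  expect_equal(nrow(full), 256)
  expect_equal(anyDuplicated(full), 0)
  set.seed(5); a <- sample_training_set(g, 7)
  set.seed(5); b <- sample_training_set(g, 7)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a), 0)
})

test_that("softmax selection follows the Boltzmann distribution", {
  expect_error(softmax_probs(c(1, 0), tau = 0), "positive")
  # equal outputs: uniform choice, checked over 10,000 draws
  set.seed(2)
  draws <- replicate(10000, softmax_select(rep(0.5, 4), tau = 0.1))
  p_hat <- tabulate(draws, 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(p_hat - 0.25) < 3 * se))
  # near-zero temperature acts as a max function
  set.seed(3)
  picks <- replicate(200, softmax_select(c(0.2, 0.9, 0.1, 0.3), tau = 1e-3))
  expect_true(all(picks == 2))
  # closed form: outputs (1,0,0,0), tau = 0.5 -> p1 = e^2 / (e^2 + 3)
  p <- softmax_probs(c(1, 0, 0, 0), tau = 0.5)
  expect_equal(p[1], exp(2) / (exp(2) + 3))
  expect_equal(sum(p), 1)
})

test_that("input vectors encode stimulus, reward and feedback blocks", {
  expect_equal(encode_input_vector(1),
               c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(encode_input_vector(1, action = 3, reward = "neg"),
               c(1, 0, 0, 0, 0, 1, 0, 0, 1, 0))
  expect_equal(encode_input_vector(4, action = 4, reward = "pos"),
               c(0, 0, 0, 1, 1, 0, 0, 0, 0, 1))
  expect_error(encode_input_vector(5), "stimulus")
  expect_error(encode_input_vector(1, action = 9), "action")
})

test_that("the oracle agent attains the fitness and GLA upper bounds", {
  sets <- rbind(c(1, 2, 3, 4), c(2, 2, 1, 3))
  ev <- evaluate_fitness(oracle_agent(), sets)
  expect_equal(ev$fitness, 1)
  expect_equal(ev$set_fitness, 1)
  expect_true(all(ev$success))
  expect_length(ev$descriptor, 16 * 2)
  g <- gla_score(oracle_agent(), n_repeats = 1)
  expect_equal(g$set_level, 1)
  expect_equal(g$association_level, 1)
})

test_that("compiled and reference engines agree bitwise under one seed", {
  set.seed(11)
  hl <- make_fixture("hand_learner")
  cfg <- task_config(n_episodes = 12)
  sets <- rbind(c(2, 3, 1, 4), c(1, 1, 2, 2))
  set.seed(77); a <- evaluate_fitness(hl, sets, cfg, engine = "cpp")
  set.seed(77); b <- evaluate_fitness(hl, sets, cfg, engine = "r")
  expect_identical(a$correct, b$correct)
  expect_identical(a$chosen, b$chosen)
  expect_equal(a$descriptor, b$descriptor)
  # and on a random evolved-style network
  set.seed(12)
  g <- random_init_direct(list(n_in = 10, n_out = 4))
  for (i in 1:60) g <- mutate_direct(g)
  net <- develop_direct(g)
  set.seed(88); a <- evaluate_fitness(net, c(3, 1, 4, 2), cfg, engine = "cpp")
  set.seed(88); b <- evaluate_fitness(net, c(3, 1, 4, 2), cfg, engine = "r")
  expect_identical(a$correct, b$correct)
  expect_equal(a$descriptor, b$descriptor)
})

test_that("fitness evaluation validates its inputs and stays in [0, 1]", {
  set.seed(13)
  net <- zero_network()
  expect_error(evaluate_fitness(net, matrix(numeric(0), 0, 4)), "empty")
  expect_error(evaluate_fitness(chain_network(), c(1, 2, 3, 4)),
               "input neurons")
  ev <- evaluate_fitness(net, rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)),
                         task_config(n_episodes = 5))
  expect_gte(ev$fitness, 0); expect_lte(ev$fitness, 1)
  expect_gte(ev$set_fitness, 0); expect_lte(ev$set_fitness, 1)
  expect_length(ev$descriptor, 32)
})

test_that("descriptor length is 16 per association set in E", {
  set.seed(14)
  net <- zero_network()
  cfg <- task_config(n_episodes = 2)
  for (k in c(1, 3, 5)) {
    sets <- unclass(enumerate_global_set(4, 4))[seq_len(k), , drop = FALSE]
    ev <- evaluate_fitness(net, sets, cfg)
    expect_length(ev$descriptor, 16 * k)
  }
})

test_that("without plasticity, lifetime length does not change behavior", {
  # a network with no modulatory neurons cannot adapt: last-episode
  # output activations are identical whether it lives 1 or 30 episodes
  set.seed(15)
  g <- random_init_direct(list(n_in = 10, n_out = 4))
  net <- develop_direct(g)   # generation-0: no plastic weights
  set.seed(1); e1 <- evaluate_fitness(net, c(1, 2, 3, 4),
                                      task_config(n_episodes = 1))
  set.seed(2); e30 <- evaluate_fitness(net, c(1, 2, 3, 4),
                                       task_config(n_episodes = 30))
  expect_equal(e1$descriptor, e30$descriptor, tolerance = 1e-10)
})

test_that("the hand-wired learner learns far above chance", {
  hl <- make_fixture("hand_learner")
  set.seed(16)
  sets <- sample_training_set(enumerate_global_set(4, 4), 10)
  ev <- evaluate_fitness(hl, sets)
  expect_gt(ev$fitness, 0.6)      # chance is 0.25
  expect_gt(ev$set_fitness, 0.2)  # chance is ~0.004
})

test_that("association sets survive both serialization formats", {
  sets <- rbind(c(1, 3, 2, 4), c(2, 2, 2, 2))
  for (fmt in c("json", "table")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_association_sets(sets, path, format = fmt)
    back <- read_association_sets(path, format = fmt)
    expect_equal(unname(back), unname(sets))
  }
})
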