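#' Canonical networks for testing and calibration
#'
#' Deterministic hand-built networks:
#' \describe{
#'   \item{`fully_connected`}{`n` standard neurons, every ordered pair
#'     connected with uniform excitatory weight 1; maximally regular —
#'     any node can be swapped with any other, so the automorphism
#'     count is `n!`.}
#'   \item{`mlp`}{A layered feed-forward network with uniform weights;
#'     nodes within a layer are interchangeable, so the count is the
#'     product of the layer-size factorials.}
#'   \item{`lamprey_cpg`}{An 8-neuron central-pattern-generator-like
#'     ladder: 4 segments of mutually inhibiting left/right
#'     oscillator halves, neighboring segments coupled excitatorily in
#'     both directions. Two independent axial symmetries (left-right
#'     and top-down), hence 4 automorphisms.}
#'   \item{`random_rigid`}{A small asymmetric network with a single
#'     automorphism (the identity).}
#'   \item{`hand_learner`}{A hand-wired plastic network that solves
#'     the conditioning task: a plastic stimulus-to-output fan (via a
#'     two-stage relay) and per-action modulatory gates that fire only
#'     when an action's feedback line coincides with a reward line, so
#'     reinforcement lands on the chosen action's connections only.
#'     Validates the task end-to-end: its GLA score is far above the
#'     chance level.}
#' }
#'
#' @param name Fixture name.
#' @param n Size for `fully_connected`.
#' @param layers Layer sizes for `mlp` (first layer becomes inputs,
#'   last becomes outputs).
#' @return A `plastic_network`.
#' @export
make_fixture <- function(name = c("fully_connected", "mlp", "lamprey_cpg",
                                  "random_rigid", "hand_learner"),
                         n = 4, layers = c(4, 4)) {
  name <- match.arg(name)
  switch(name,
    fully_connected = {
      ids <- paste0("v", seq_len(n))
      pairs <- tidyr::expand_grid(from = ids, to = ids)
      pairs <- pairs[pairs$from != pairs$to, ]
      plastic_network(
        tibble::tibble(id = ids, role = "hidden", kind = "standard",
                       bias = 0),
        tibble::tibble(from = pairs$from, to = pairs$to, sign = 1,
                       weight = 1))
    },
    mlp = {
      stopifnot(length(layers) >= 2)
      ids <- purrr::imap(layers, function(k, l)
        paste0("l", l, "_", seq_len(k)))
      roles <- c("input", rep("hidden", length(layers) - 2), "output")
      neurons <- dplyr::bind_rows(purrr::imap(ids, function(v, l)
        tibble::tibble(id = v, role = roles[l], kind = "standard",
                       bias = 0)))
      edges <- dplyr::bind_rows(purrr::map(seq_len(length(layers) - 1),
        function(l) tidyr::expand_grid(from = ids[[l]], to = ids[[l + 1]])))
      plastic_network(neurons,
                      tibble::tibble(from = edges$from, to = edges$to,
                                     sign = 1, weight = 1))
    },
    lamprey_cpg = {
      seg <- 1:4
      ids <- c(paste0("L", seg), paste0("R", seg))
      rung <- tibble::tibble(from = c(paste0("L", seg), paste0("R", seg)),
                             to = c(paste0("R", seg), paste0("L", seg)),
                             sign = -1, weight = 1)
      up <- tibble::tibble(
        from = c(paste0("L", 1:3), paste0("R", 1:3),
                 paste0("L", 2:4), paste0("R", 2:4)),
        to = c(paste0("L", 2:4), paste0("R", 2:4),
               paste0("L", 1:3), paste0("R", 1:3)),
        sign = 1, weight = 1)
      plastic_network(
        tibble::tibble(id = ids, role = "hidden", kind = "standard",
                       bias = 0),
        rbind(rung, up))
    },
    random_rigid = {
      plastic_network(
        tibble::tibble(id = c("a", "b", "c", "d", "e"),
                       role = c("input", "hidden", "hidden", "hidden",
                                "output"),
                       kind = "standard", bias = 0),
        tibble::tibble(from = c("a", "a", "b", "c", "d", "b"),
                       to = c("b", "c", "d", "d", "e", "e"),
                       sign = c(1, -1, 1, 1, 1, 1),
                       weight = c(1.8, 0.3, 1.5, 0.2, 1.9, 0.4)))
    },
    hand_learner = make_hand_learner())
}

# Hand-wired solution of the conditioning task, built from the three
# "discoveries" a successful evolved network needs: (1) the reward
# lines reach modulatory neurons, (2) the reward is gated by the
# softmax choice — one modulatory gate per (action, reward polarity),
# active only when its action-feedback line and its reward line fire
# together (conjunction via bias -3), each projecting one-to-one onto
# its output neuron — and (3) the reinforcement lands on a plastic
# stimulus-to-output fan. The fan's presynaptic side is a two-stage
# relay (stimulus -> relay -> relay2 -> outputs): when the clamped
# input switches to the next association, the stale gate signal from
# the previous reward phase dies out before the new stimulus's relay2
# activity arrives, so updates are always credited to the association
# that earned the reward. Gates and relays receive no modulatory
# input, so their wiring is fixed; only the 16 relay2-to-output
# magnitudes are plastic.
make_hand_learner <- function() {
  in_ids <- c(paste0("stim_", 1:4), "rpos", "rneg", paste0("fb_", 1:4))
  out_ids <- paste0("out_", 1:4)
  r1 <- paste0("relay_", 1:4); r2 <- paste0("relay2_", 1:4)
  mp <- paste0("gate_pos_", 1:4); mn <- paste0("gate_neg_", 1:4)
  neurons <- tibble::tibble(
    id = c(in_ids, r1, r2, mp, mn, out_ids),
    role = c(rep("input", 10), rep("hidden", 16), rep("output", 4)),
    kind = c(rep("standard", 10), rep("standard", 8),
             rep("modulatory", 8), rep("standard", 4)),
    bias = c(rep(0, 10), rep(-1, 8), rep(-3, 8), rep(-1, 4)))
  fan <- tidyr::expand_grid(from = r2, to = out_ids)
  connections <- dplyr::bind_rows(
    tibble::tibble(from = paste0("stim_", 1:4), to = r1, sign = 1, weight = 2),
    tibble::tibble(from = r1, to = r2, sign = 1, weight = 2),
    tibble::tibble(from = fan$from, to = fan$to, sign = 1, weight = 1),
    tibble::tibble(from = paste0("fb_", 1:4), to = mp, sign = 1, weight = 2),
    tibble::tibble(from = "rpos", to = mp, sign = 1, weight = 2),
    tibble::tibble(from = paste0("fb_", 1:4), to = mn, sign = 1, weight = 2),
    tibble::tibble(from = "rneg", to = mn, sign = 1, weight = 2),
    tibble::tibble(from = mp, to = out_ids, sign = 1, weight = 1),
    tibble::tibble(from = mn, to = out_ids, sign = -1, weight = 1))
  plastic_network(neurons, connections)
}
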