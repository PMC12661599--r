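# Independent brute-force oracles used across tests.

# enumerate terminal payoffs by naive recursion over the raw list structure
oracle_paths <- function(node, prob = 1) {
  if (node$type == "terminal") {
    return(data.frame(prob = prob, cost = node$cost, effect = node$effect))
  }
  do.call(rbind, lapply(node$branches, function(b) {
    oracle_paths(b$node, prob * b$p)
  }))
}

oracle_expectation <- function(strat) {
  paths <- oracle_paths(strat$root)
  c(
    cost = strat$upfront_cost + sum(paths$prob * paths$cost),
    effect = sum(paths$prob * paths$effect)
  )
}

# random valid tree, independent of the package's synthetic generators
random_tree <- function(max_depth = 4, branch_max = 3) {
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35) {
      return(terminal_node(
        cost = stats::runif(1, 0, 5000),
        effect = stats::runif(1, 0, 3)
      ))
    }
    k <- sample(2:branch_max, 1)
    probs <- as.numeric(prop.table(stats::runif(k, 0.05, 1)))
    chance_node(lapply(seq_len(k), function(i) {
      branch(probs[i], build(depth + 1))
    }))
  }
  strategy("random", build(1), upfront_cost = stats::runif(1, 0, 600))
}
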