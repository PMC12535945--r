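# Shared fixtures and independent oracles. Everything here is built in
# code; no binary data.

# --- random instances -------------------------------------------------------

# random directed graph as a 0/1 adjacency matrix
rand_digraph <- function(n, p = 0.25) {
  matrix(as.integer(stats::runif(n * n) < p), n, n)
}

# random metabolic network with spontaneous rules (activity is exercised
# through explicit masks); reactant sets may be empty, product sets not
rand_network <- function(n_met = 12L, n_rxn = 16L) {
  mets <- sprintf("m%d", seq_len(n_met))
  reactions <- lapply(seq_len(n_rxn), function(j) {
    nr <- sample(0:min(3L, n_met), 1L)
    np <- sample(1:min(2L, n_met), 1L)
    list(id = sprintf("R%d", j),
         reactants = sample(mets, nr),
         products = sample(mets, np),
         rule = "")
  })
  metabolic_network(reactions, metabolites = mets)
}

rand_medium <- function(net) {
  n <- length(net$metabolites)
  k <- sample(0:max(1L, n %/% 3L), 1L)
  sample(net$metabolites, k)
}

rand_mask <- function(net) {
  as.integer(stats::runif(length(net$reactions)) < 0.8)
}

# --- oracles ----------------------------------------------------------------

# Floyd-Warshall style reachability (>= 1 step) oracle
warshall_closure <- function(R) {
  n <- nrow(R)
  cl <- R != 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (cl[i, k]) cl[i, ] <- cl[i, ] | cl[k, ]
    }
  }
  m <- matrix(as.integer(cl), n, n)
  m
}

# exact expected-cost recurrence on tiny instances.
# H: posterior weights (renormalised at every recursion level);
# pred: |H| x |T| prediction matrix; costs: per-experiment costs.
exact_ec <- function(post, pred, costs) {
  rec <- function(h_idx, t_idx) {
    if (length(h_idx) <= 1L || length(t_idx) == 0L) return(0)
    w <- post[h_idx] / sum(post[h_idx])
    best <- Inf
    for (t in t_idx) {
      pos <- h_idx[pred[h_idx, t] == 1L]
      neg <- setdiff(h_idx, pos)
      p <- sum(w[match(pos, h_idx)])
      rest <- setdiff(t_idx, t)
      val <- costs[t] + p * rec(pos, rest) + (1 - p) * rec(neg, rest)
      if (val < best) best <- val
    }
    best
  }
  # returns the argmin experiment for the first split
  scores <- vapply(seq_along(costs), function(t) {
    pos <- which(pred[, t] == 1L)
    neg <- setdiff(seq_len(nrow(pred)), pos)
    p <- sum(post[pos]) / sum(post)
    rest <- setdiff(seq_along(costs), t)
    costs[t] + p * rec(pos, rest) + (1 - p) * rec(neg, rest)
  }, numeric(1L))
  list(scores = scores, best = which.min(scores))
}

# --- hand-built fixtures ----------------------------------------------------

# five-metabolite essential-pathway fixture: base metabolite a, masked
# reaction Rm (a -> x, truly catalysed by g3), downstream x -> e with an
# isoenzyme pair, and a side pathway a -> y -> z kept by g4.
pathway_fixture <- function() {
  # g3 (the true catalyst of the masked Rm) appears in no rule, so the
  # gene list must be given explicitly for deletion experiments on it
  net <- metabolic_network(list(
    list(id = "Rm", reactants = "a", products = "x", rule = "?"),
    list(id = "Rd", reactants = "x", products = "e", rule = "g1 or g2"),
    list(id = "Rs1", reactants = "a", products = "y", rule = "g4"),
    list(id = "Rs2", reactants = "y", products = "z", rule = "")
  ), genes = c("g1", "g2", "g3", "g4"))
  list(net = net, base_medium = "a", essential = "e")
}

# small gem parameters for fast soundness sweeps
small_params <- function() {
  gem_params(n_layers = 2L, metabolites_per_layer = 4L, n_reactions = 18L,
             max_reactants = 2L, n_genes = 8L, isoenzyme_fraction = 0.3,
             n_optional_nutrients = 2L, n_essential = 2L)
}
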