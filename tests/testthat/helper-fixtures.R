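# shared fixtures: a minimal single-endpoint study config and a brute-force
# d-separation oracle used by the pSEM tests

single_endpoint_config <- function(betas = c("ZR^2" = 1.2, "ZR:PR" = -0.9),
                                   noise_sd = 0.25, seed = 1,
                                   n_per_group = 5) {
  study_config(
    n_per_group = n_per_group,
    true_effects = list(Y = list(intercept = 0, terms = betas)),
    baselines = list(Y = c(control = -3, model = 2)),
    mediation = data.frame(from = character(0), to = character(0),
                           beta = numeric(0)),
    mediators = data.frame(name = character(0), type = character(0)),
    noise_sd = noise_sd, seed = seed
  )
}

# Bayes-ball reachability: returns TRUE when x and y are d-separated given z
# in the DAG described by an edge data.frame (from, to). Independent of the
# package's Shipley-basis construction.
dsep_oracle <- function(edges, x, y, z) {
  parents <- function(v) edges$from[edges$to == v]
  children <- function(v) edges$to[edges$from == v]
  visited <- character(0)              # "node|dir" states
  queue <- list(list(v = x, dir = "up"))
  reached <- character(0)
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    key <- paste(st$v, st$dir)
    if (key %in% visited) next
    visited <- c(visited, key)
    v <- st$v
    if (v != x) reached <- union(reached, v)
    if (st$dir == "up") {             # ball arrived from a child
      if (!(v %in% z)) {
        for (p in parents(v)) queue[[length(queue) + 1]] <- list(v = p, dir = "up")
        for (cc in children(v)) queue[[length(queue) + 1]] <- list(v = cc, dir = "down")
      }
    } else {                           # ball arrived from a parent
      if (!(v %in% z)) {
        for (cc in children(v)) queue[[length(queue) + 1]] <- list(v = cc, dir = "down")
      }
      if (v %in% z) {
        for (p in parents(v)) queue[[length(queue) + 1]] <- list(v = p, dir = "up")
      }
    }
  }
  !(y %in% reached)
}

# random DAG over `n` nodes as an upper-triangular edge list (acyclic by
# construction); used to build the basis-set test catalog
random_dag_edges <- function(n, p_edge = 0.4) {
  nodes <- LETTERS[seq_len(n)]
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (stats::runif(1) < p_edge) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}
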