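# Reference implementations used as independent oracles in the tests.

ref_params <- function() sipinrs_params()

# Naive per-node synchronous round: loops over nodes, recomputing each
# neighborhood summary from scratch. Consumes one uniform draw per node in
# node order, partitioned among exits exactly like the vectorized engine, so
# with an identical RNG state the two must agree node for node.
naive_step <- function(net, params) {
  n <- net$n_nodes
  g <- net$graph
  deg <- igraph::degree(g)
  st <- as.integer(net$state)
  u <- runif(n)
  new <- st
  for (i in seq_len(n)) {
    nb <- as.integer(igraph::neighbors(g, i))
    d <- vapply(1:4, function(s) sum(deg[nb[st[nb] == s]]), numeric(1))
    tp <- transition_probabilities(
      list(d_S = d[1], d_Ip = d[2], d_In = d[3], d_R = d[4]),
      k_i = deg[i], params)
    exits <- switch(st[i],
      list(p = c(tp$F_SIp, tp$F_SIn, tp$F_SR), to = c(2L, 3L, 4L)),
      list(p = c(tp$F_IpIn, tp$F_IpR), to = c(3L, 4L)),
      list(p = c(tp$F_InIp, tp$F_InR), to = c(2L, 4L)),
      list(p = params$epsilon, to = 1L))
    p <- exits$p
    if (sum(p) > 1) p <- p / sum(p)
    cum <- cumsum(p)
    hit <- which(u[i] < cum)[1L]
    if (!is.na(hit) && u[i] >= c(0, cum)[hit]) new[i] <- exits$to[hit]
  }
  net$state <- factor(c("S", "Ip", "In", "R")[new],
                      levels = c("S", "Ip", "In", "R"))
  net
}

# Random valid 4-compartment state
random_state <- function() {
  x <- runif(4)
  x / sum(x)
}

state_counts <- function(net) tabulate(as.integer(net$state), 4L)
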