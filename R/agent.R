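#' Neighbor-degree sums of a focal node, grouped by neighbor state
#'
#' For node `i` with neighborhood \eqn{\Gamma(g_i)}, returns the sums of the
#' degrees of its neighbors currently in each emotional state
#' (\eqn{d_S, d_{Ip}, d_{In}, d_R}) together with the emotional-imbalance
#' signal \eqn{A = |d_{Ip} - d_{In}|}. These degree-weighted tallies — not
#' plain neighbor counts — drive all contact-mediated transition
#' probabilities: a high-degree neighbor carries proportionally more
#' influence.
#'
#' @param net A [contagion_network()] with states assigned.
#' @param node Node index (1-based).
#' @return A list with `d_S`, `d_Ip`, `d_In`, `d_R`, and `A`.
#' @export
neighborhood_summary <- function(net, node) {
  stopifnot(inherits(net, "contagion_network"))
  if (!is.numeric(node) || length(node) != 1L || node < 1 || node > net$n_nodes)
    stop("unknown node: ", node, call. = FALSE)
  nb <- as.integer(neighbors(net$graph, node))
  deg <- degree(net$graph)
  st <- as.integer(net$state)[nb]
  d <- vapply(1:4, function(s) sum(deg[nb[st == s]]), numeric(1))
  list(d_S = d[1L], d_Ip = d[2L], d_In = d[3L], d_R = d[4L],
       A = abs(d[2L] - d[3L]))
}

#' Per-round transition probabilities of a focal node
#'
#' Evaluates the seven neighborhood-dependent transition probabilities.
#' Writing \eqn{d_S, d_{Ip}, d_{In}, d_R} for the neighbor-degree sums,
#' \eqn{A = |d_{Ip} - d_{In}|}, and \eqn{k_i} for the focal degree:
#' \itemize{
#'   \item susceptible to immune:
#'     \eqn{F_{SR} = \gamma (d_S + d_R) / (d_S + d_R + A)};
#'   \item infection, only for the locally dominant camp:
#'     \eqn{F_{SIp} = \alpha_1\, 2 A d_{Ip} / (k_i (d_{Ip} + d_{In}))} when
#'     \eqn{d_{Ip} > d_{In}} (else 0), and symmetrically \eqn{F_{SIn}} with
#'     \eqn{\alpha_2} when \eqn{d_{In} > d_{Ip}};
#'   \item conversion between camps:
#'     \eqn{F_{InIp} = \theta_1 A / k_i} when \eqn{d_{Ip} > d_{In}},
#'     \eqn{F_{IpIn} = \theta_2 A / k_i} when \eqn{d_{In} > d_{Ip}};
#'   \item immunization of disseminators:
#'     \eqn{F_{IpR} = \beta_1\, 2 (d_S + d_R) / (d_S + d_R + A)}, and
#'     \eqn{F_{InR}} with \eqn{\beta_2}.
#' }
#' A balanced neighborhood (\eqn{A = 0}: the two camps neutralize each other)
#' yields zero infection and conversion probability. Raw values above 1 —
#' which the formulas do produce on highly imbalanced neighborhoods — are
#' clamped to 1; the number of clamped entries is attached as attribute
#' `"n_clamped"`. Degenerate cases: an isolated node (`k_i = 0`) makes no
#' contact-driven transitions except plain-\eqn{\gamma} direct immunization;
#' when \eqn{d_S + d_R + A = 0} with \eqn{k_i > 0} the damping ratio is taken
#' at its balanced-neighborhood limit 1.
#'
#' All arguments are vectorized over nodes.
#'
#' @param summary A list with components `d_S`, `d_Ip`, `d_In`, `d_R`
#'   (numeric vectors of equal length), as from [neighborhood_summary()].
#' @param k_i Focal node degree(s).
#' @param params A [sipinrs_params()] object.
#' @return A list of seven probability vectors `F_SIp`, `F_SIn`, `F_SR`,
#'   `F_InIp`, `F_IpIn`, `F_IpR`, `F_InR`, each in `[0, 1]`, with attribute
#'   `"n_clamped"`.
#' @examples
#' transition_probabilities(list(d_S = 0, d_Ip = 3, d_In = 1, d_R = 0),
#'                          k_i = 2, sipinrs_params())$F_SIp # 0.675
#' @export
transition_probabilities <- function(summary, k_i, params) {
  stopifnot(inherits(params, "sipinrs_params"))
  d_S <- summary$d_S; d_Ip <- summary$d_Ip
  d_In <- summary$d_In; d_R <- summary$d_R
  if (any(c(d_S, d_Ip, d_In, d_R) < 0) || any(k_i < 0))
    stop("neighbor-degree sums and k_i must be non-negative", call. = FALSE)
  A <- abs(d_Ip - d_In)
  dsr <- d_S + d_R
  den <- dsr + A
  ratio <- ifelse(den > 0, dsr / den, 1)
  pos <- d_Ip > d_In
  neg <- d_In > d_Ip
  den_inf <- k_i * (d_Ip + d_In)
  raw <- list(
    F_SIp = ifelse(pos & den_inf > 0,
                   params$alpha1 * 2 * A * d_Ip / pmax(den_inf, 1), 0),
    F_SIn = ifelse(neg & den_inf > 0,
                   params$alpha2 * 2 * A * d_In / pmax(den_inf, 1), 0),
    F_SR = params$gamma * ratio,
    F_InIp = ifelse(pos & k_i > 0, params$theta1 * A / pmax(k_i, 1), 0),
    F_IpIn = ifelse(neg & k_i > 0, params$theta2 * A / pmax(k_i, 1), 0),
    F_IpR = ifelse(k_i > 0, params$beta1 * 2 * ratio, 0),
    F_InR = ifelse(k_i > 0, params$beta2 * 2 * ratio, 0)
  )
  n_clamped <- sum(vapply(raw, function(f) sum(f > 1), numeric(1)))
  out <- lapply(raw, function(f) pmin(1, f))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Assign initial emotional states to network nodes
#'
#' The number of nodes per non-susceptible state is `round(fraction * n)`,
#' with the remainder susceptible. Seeding strategies:
#' \describe{
#'   \item{`uniform_random`}{all seed nodes drawn uniformly without
#'     replacement;}
#'   \item{`top_degree_positive`}{the positive disseminators are the
#'     highest-degree nodes (ties broken by node id), other seeds uniform at
#'     random among the rest;}
#'   \item{`top_degree_negative`}{same with the negative disseminators on the
#'     hubs.}
#' }
#' Uses the session RNG; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param net A [contagion_network()].
#' @param fractions Numeric `(S, Ip, In, R)` fractions summing to 1.
#' @param seeding One of `"uniform_random"`, `"top_degree_positive"`,
#'   `"top_degree_negative"`.
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return The network with its `state` vector replaced.
#' @export
seed_states <- function(net, fractions = c(S = 0.96, Ip = 0.02, In = 0.02, R = 0),
                        seeding = c("uniform_random", "top_degree_positive",
                                    "top_degree_negative"),
                        seed = NULL) {
  stopifnot(inherits(net, "contagion_network"))
  seeding <- match.arg(seeding)
  fractions <- validate_fractions(fractions, c("S", "Ip", "In", "R"))
  deg <- degree(net$graph)
  st <- with_seed(seed, seed_states_raw(net$n_nodes, deg, fractions, seeding))
  net$state <- factor(state_levels()[st], levels = state_levels())
  net
}

# integer-state seeding core shared with the simulation loop
seed_states_raw <- function(n, deg, fractions, seeding) {
  n_ip <- round(fractions[["Ip"]] * n)
  n_in <- round(fractions[["In"]] * n)
  n_r <- round(fractions[["R"]] * n)
  if (n_ip + n_in + n_r > n)
    stop("seed counts exceed the number of nodes", call. = FALSE)
  st <- rep(1L, n)
  if (seeding == "uniform_random") {
    picks <- sample.int(n, n_ip + n_in + n_r)
    st[picks[seq_len(n_ip)]] <- 2L
    st[picks[n_ip + seq_len(n_in)]] <- 3L
    st[picks[n_ip + n_in + seq_len(n_r)]] <- 4L
  } else {
    hub_state <- if (seeding == "top_degree_positive") 2L else 3L
    n_hub <- if (hub_state == 2L) n_ip else n_in
    n_other <- if (hub_state == 2L) n_in else n_ip
    hubs <- order(-deg, seq_len(n))[seq_len(n_hub)]
    st[hubs] <- hub_state
    rest <- setdiff(seq_len(n), hubs)
    picks <- rest[sample.int(length(rest), n_other + n_r)]
    st[picks[seq_len(n_other)]] <- if (hub_state == 2L) 3L else 2L
    st[picks[n_other + seq_len(n_r)]] <- 4L
  }
  st
}

# Precompute the static structures the synchronous update needs: degrees and
# a sparse matrix W with W[i, j] = degree(j) for every edge (i, j), so that
# the per-state neighbor-degree sums are one sparse matrix product per round.
build_engine <- function(net) {
  g <- net$graph
  n <- vcount(g)
  deg <- degree(g)
  el <- as_edgelist(g, names = FALSE)
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  W <- sparseMatrix(i = from, j = to, x = deg[to], dims = c(n, n))
  list(n = n, deg = deg, W = W)
}

# One synchronous round on an integer state vector. All probabilities are
# computed from the pre-round snapshot; each node consumes exactly one
# uniform draw, partitioned among its exits in the fixed order
#   S:  F_SIp, F_SIn, F_SR      Ip: F_IpIn, F_IpR
#   In: F_InIp, F_InR           R:  epsilon
# with the exit set rescaled only if its (clamped) sum exceeds 1.
step_raw <- function(st, eng, params) {
  n <- eng$n
  Ind <- sparseMatrix(i = seq_len(n), j = st, x = 1, dims = c(n, 4L))
  D <- as.matrix(eng$W %*% Ind)
  tp <- transition_probabilities(
    list(d_S = D[, 1L], d_Ip = D[, 2L], d_In = D[, 3L], d_R = D[, 4L]),
    k_i = eng$deg, params)
  u <- runif(n)
  new <- st

  apply_exits <- function(from_state, probs, targets) {
    i <- which(st == from_state)
    if (length(i) == 0L) return()
    tot <- 0
    for (p in probs) tot <- tot + p[i]
    scale <- ifelse(tot > 1, 1 / tot, 1)
    lower <- 0
    for (j in seq_along(probs)) {
      p <- probs[[j]][i] * scale
      hit <- u[i] >= lower & u[i] < lower + p
      new[i[hit]] <<- targets[j]
      lower <- lower + p
    }
  }
  apply_exits(1L, list(tp$F_SIp, tp$F_SIn, tp$F_SR), c(2L, 3L, 4L))
  apply_exits(2L, list(tp$F_IpIn, tp$F_IpR), c(3L, 4L))
  apply_exits(3L, list(tp$F_InIp, tp$F_InR), c(2L, 4L))
  # degradation: immune nodes revert to susceptible with plain epsilon,
  # independent of neighborhood
  iR <- which(st == 4L)
  new[iR[u[iR] < params$epsilon]] <- 1L
  new
}

#' Advance a network contagion by one synchronous round
#'
#' All transition probabilities are evaluated on the state at the start of
#' the round; every node then makes at most one transition, sampled by
#' partitioning a single uniform draw among its applicable exits. Uses the
#' session RNG.
#'
#' @param net A [contagion_network()] with states assigned.
#' @param params A [sipinrs_params()] object.
#' @return A list with `network` (updated) and `counts` (named per-state node
#'   counts, summing to the node count).
#' @export
step_contagion <- function(net, params) {
  stopifnot(inherits(net, "contagion_network"))
  eng <- build_engine(net)
  st <- step_raw(as.integer(net$state), eng, params)
  net$state <- factor(state_levels()[st], levels = state_levels())
  list(network = net,
       counts = stats::setNames(tabulate(st, 4L), state_levels()))
}

#' Simulation settings for the agent-based model
#'
#' @param rounds Number of update rounds per replicate (default 50).
#' @param replicates Number of independent runs (default 25).
#' @param seed Base RNG seed; replicate `r` uses `seed + r` for both its
#'   initial seeding and its update draws. Default 20220801.
#' @param initial_fractions `(S, Ip, In, R)` fractions summing to 1.
#' @param seeding Seeding strategy, see [seed_states()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(rounds = 50, replicates = 25, seed = 20220801,
                              initial_fractions = c(S = 0.96, Ip = 0.02,
                                                    In = 0.02, R = 0),
                              seeding = c("uniform_random",
                                          "top_degree_positive",
                                          "top_degree_negative")) {
  stopifnot(rounds >= 1, replicates >= 1)
  structure(list(rounds = as.integer(rounds),
                 replicates = as.integer(replicates),
                 seed = seed,
                 initial_fractions = validate_fractions(
                   initial_fractions, c("S", "Ip", "In", "R")),
                 seeding = match.arg(seeding)),
            class = "simulation_config")
}

#' Run the agent-based contagion on a network
#'
#' Performs `replicates` independent runs of `rounds` synchronous update
#' rounds each on a fixed network, re-drawing the initial seed nodes per
#' replicate. Replicate `r` is seeded with `config$seed + r`, so a run is
#' fully reproducible from the config alone. The caller's RNG state is
#' preserved.
#'
#' @param net A [contagion_network()].
#' @param params A [sipinrs_params()] object.
#' @param config A [simulation_config()].
#' @return An object of class `count_trajectory`: a list with
#'   \describe{
#'     \item{`counts`}{integer array `replicates x (rounds + 1) x 4`; round 0
#'       is the seeded state;}
#'     \item{`median`, `mean`}{`(rounds + 1) x 4` across-replicate matrices;}
#'     \item{`n_nodes`, `config`}{bookkeeping.}
#'   }
#' @examples
#' net <- generate_ba(500, 4, seed = 1)
#' traj <- simulate_contagion(net, sipinrs_params(),
#'                            simulation_config(rounds = 10, replicates = 3))
#' detect_peak(traj, "In")
#' @export
simulate_contagion <- function(net, params, config = simulation_config()) {
  stopifnot(inherits(net, "contagion_network"),
            inherits(params, "sipinrs_params"),
            inherits(config, "simulation_config"))
  eng <- build_engine(net)
  counts <- array(0L, dim = c(config$replicates, config$rounds + 1L, 4L),
                  dimnames = list(NULL, NULL, state_levels()))
  for (r in seq_len(config$replicates)) {
    counts[r, , ] <- with_seed(config$seed + r, {
      st <- seed_states_raw(eng$n, eng$deg, config$initial_fractions,
                            config$seeding)
      rep_counts <- matrix(0L, config$rounds + 1L, 4L)
      rep_counts[1L, ] <- tabulate(st, 4L)
      for (k in seq_len(config$rounds)) {
        st <- step_raw(st, eng, params)
        rep_counts[k + 1L, ] <- tabulate(st, 4L)
      }
      rep_counts
    })
  }
  structure(list(counts = counts,
                 median = apply(counts, c(2L, 3L), median),
                 mean = apply(counts, c(2L, 3L), mean),
                 n_nodes = eng$n,
                 config = config),
            class = "count_trajectory")
}

#' @export
print.count_trajectory <- function(x, ...) {
  cat(sprintf("Agent-based count trajectory: %d replicates x %d rounds on %d nodes\n",
              dim(x$counts)[1L], dim(x$counts)[2L] - 1L, x$n_nodes))
  term <- x$median[nrow(x$median), ]
  cat("median terminal counts:",
      paste(sprintf("%s = %g", state_levels(), term), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format data frame of a count trajectory
#'
#' @param x A `count_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `replicate, round, S, Ip, In, R` (rounds
#'   0-based).
#' @export
as.data.frame.count_trajectory <- function(x, ...) {
  reps <- dim(x$counts)[1L]
  rounds <- dim(x$counts)[2L]
  df <- data.frame(
    replicate = rep(seq_len(reps), each = rounds),
    round = rep(0:(rounds - 1L), times = reps))
  for (s in seq_along(state_levels()))
    df[[state_levels()[s]]] <- as.vector(t(x$counts[, , s]))
  df
}

#' Locate the peak of a compartment's median count
#'
#' The peak is the argmax of the across-replicate median count over rounds;
#' ties resolve to the earliest round.
#'
#' @param traj A `count_trajectory` from [simulate_contagion()].
#' @param compartment One of `"S"`, `"Ip"`, `"In"` (default), `"R"`.
#' @return A list with `round` (0-based) and `count` (median count at the
#'   peak).
#' @export
detect_peak <- function(traj, compartment = "In") {
  stopifnot(inherits(traj, "count_trajectory"))
  compartment <- match.arg(compartment, state_levels())
  med <- traj$median[, match(compartment, state_levels())]
  if (length(med) == 0L) stop("empty trajectory", call. = FALSE)
  i <- which.max(med)   # which.max takes the first maximum
  list(round = i - 1L, count = med[i])
}
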