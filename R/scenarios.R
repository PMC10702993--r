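#' Catalog of built-in reference scenarios
#'
#' The named parameter groups of the package's reference experiments, keyed
#' by table and row: the reference SIpInRS group and its SIRS comparator
#' (`table1.*`), initial-proportion variations (`table2.*`), infection-rate
#' variations (`table3.*`), purification/incitement variations (`table4.*`),
#' degradation-rate variations (`table5.*`), and the network-model reference
#' configuration (`network.reference`, the same rates and fractions run as an
#' agent-based simulation on a generated network).
#'
#' @return A named list of `scenario` objects (length 11). Each scenario has
#'   `name`, `model` (`"sipinrs_ode"`, `"sirs_ode"` or `"network"`),
#'   `parameters`, `initial`, and (for the network model) a `network` spec.
#' @examples
#' names(builtin_scenarios())
#' builtin_scenarios()[["table5.group2"]]$parameters$epsilon # 0.03
#' @export
builtin_scenarios <- function() {
  ref_init <- c(S = 0.96, Ip = 0.02, In = 0.02, R = 0)
  sc <- function(name, model, parameters, initial, network = NULL,
                 description = "") {
    structure(list(name = name, model = model, parameters = parameters,
                   initial = initial, network = network,
                   description = description),
              class = "scenario")
  }
  out <- list(
    sc("table1.reference", "sipinrs_ode", sipinrs_params(), ref_init,
       description = "reference SIpInRS group"),
    sc("table1.sirs", "sirs_ode", sirs_params(alpha = 0.45, beta = 0.06,
                                              epsilon = 0.05),
       c(S = 0.96, I = 0.04, R = 0),
       description = "classical SIRS comparator"),
    sc("table2.group1", "sipinrs_ode", sipinrs_params(),
       c(S = 0.90, Ip = 0.08, In = 0.02, R = 0),
       description = "more initial positive disseminators"),
    sc("table2.group2", "sipinrs_ode", sipinrs_params(),
       c(S = 0.90, Ip = 0.02, In = 0.08, R = 0),
       description = "more initial negative disseminators"),
    sc("table3.group1", "sipinrs_ode", sipinrs_params(alpha2 = 0.80), ref_init,
       description = "raised negative infection rate"),
    sc("table3.group2", "sipinrs_ode", sipinrs_params(alpha1 = 0.80), ref_init,
       description = "raised positive infection rate"),
    sc("table4.group1", "sipinrs_ode", sipinrs_params(theta1 = 0.10), ref_init,
       description = "raised purification rate"),
    sc("table4.group2", "sipinrs_ode", sipinrs_params(theta2 = 0.05), ref_init,
       description = "raised incitement rate"),
    sc("table5.group1", "sipinrs_ode", sipinrs_params(epsilon = 0.08), ref_init,
       description = "raised degradation rate"),
    sc("table5.group2", "sipinrs_ode", sipinrs_params(epsilon = 0.03), ref_init,
       description = "lowered degradation rate"),
    sc("network.reference", "network", sipinrs_params(), ref_init,
       network = list(type = "ws", n = 10000, k = 8, p = 0.4),
       description = "agent-based reference run on a small-world network")
  )
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %s [%s]%s\n", x$name, x$model,
              if (nzchar(x$description)) paste0(": ", x$description) else ""))
  cat("initial:", paste(sprintf("%s = %g", names(x$initial), x$initial),
                        collapse = ", "), "\n")
  print(x$parameters)
  invisible(x)
}

#' Run a scenario and summarize its outcome
#'
#' Dispatches to the mean-field integrator or to the agent-based simulator
#' according to the scenario's `model`. The summary reports, per compartment,
#' the peak value and its time/round, the terminal composition, and — for the
#' ODE models — the time at which the trajectory reached equilibrium (largest
#' derivative component below 1e-7 per unit time; the reported terminal
#' composition is taken there rather than at an arbitrary horizon). For
#' reduced-parameter models the contagion threshold is included. When
#' `out_dir` is given, the trajectory CSV and a JSON summary (tagged with the
#' seed and an md5 hash of the configuration) are written there.
#'
#' @param scenario A scenario from [builtin_scenarios()], possibly modified.
#' @param out_dir Optional output directory.
#' @param t_end,dt Integration settings for the ODE models.
#' @param config A [simulation_config()] for the network model.
#' @param network Optional pre-built [contagion_network()] overriding the
#'   scenario's network spec.
#' @return A list with `trajectory` (a `contagion_trajectory` or
#'   `count_trajectory`) and `summary`.
#' @export
run_scenario <- function(scenario, out_dir = NULL, t_end = 500, dt = 0.1,
                         config = simulation_config(), network = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (scenario$model == "sipinrs_ode") {
    traj <- integrate_sipinrs(scenario$initial, scenario$parameters, t_end, dt)
    summ <- summarize_ode_run(traj, scenario$parameters, rhs = sipinrs_rhs)
  } else if (scenario$model == "sirs_ode") {
    traj <- integrate_sirs(scenario$initial, scenario$parameters, t_end, dt)
    summ <- summarize_ode_run(traj, scenario$parameters, rhs = sirs_rhs)
    summ$R0 <- compute_R0(reduced_params(alpha = scenario$parameters$alpha,
                                         beta = scenario$parameters$beta,
                                         gamma = 0,
                                         epsilon = scenario$parameters$epsilon))
  } else if (scenario$model == "network") {
    if (is.null(network)) network <- build_scenario_network(scenario$network,
                                                            seed = config$seed)
    cfg <- config
    cfg$initial_fractions <- validate_fractions(scenario$initial,
                                                c("S", "Ip", "In", "R"))
    traj <- simulate_contagion(network, scenario$parameters, cfg)
    summ <- summarize_network_run(traj)
  } else stop("unknown scenario model: ", scenario$model, call. = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(scenario$name, "_trajectory.csv"))
    if (inherits(traj, "count_trajectory")) {
      df <- as.data.frame(traj)
      write.csv(df, csv, row.names = FALSE, quote = FALSE)
    } else {
      write_trajectory(traj, csv)
    }
    summ$config_md5 <- config_hash(scenario)
    summ$seed <- if (scenario$model == "network") config$seed else NULL
    jsonlite::write_json(summ, file.path(out_dir, paste0(scenario$name,
                                                         "_summary.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  list(trajectory = traj, summary = summ)
}

build_scenario_network <- function(spec, seed = NULL) {
  if (is.null(spec)) stop("network scenario needs a network spec", call. = FALSE)
  switch(spec$type,
         ws = generate_ws(spec$n, spec$k, spec$p, seed = seed),
         ba = generate_ba(spec$n, spec$m, seed = seed),
         edgelist = read_edge_list(spec$path),
         stop("unknown network type: ", spec$type, call. = FALSE))
}

summarize_ode_run <- function(traj, params, rhs) {
  comps <- setdiff(names(traj), "t")
  m <- as.matrix(traj[, comps, drop = FALSE])
  # equilibrium: first grid point where the flow has stalled
  dnorm <- apply(m, 1L, function(y) max(abs(rhs(y, params))))
  eq_i <- which(dnorm < 1e-7)[1L]
  term_i <- if (is.na(eq_i)) nrow(m) else eq_i
  peaks <- lapply(comps, function(cc) {
    i <- which.max(traj[[cc]])
    list(value = traj[[cc]][i], t = traj$t[i])
  })
  list(model = "ode",
       peaks = stats::setNames(peaks, comps),
       terminal = as.list(m[term_i, ]),
       equilibrium_time = if (is.na(eq_i)) NA else traj$t[eq_i],
       R0 = NULL)
}

summarize_network_run <- function(traj) {
  peaks <- lapply(state_levels(), function(cc) detect_peak(traj, cc))
  list(model = "network",
       n_nodes = traj$n_nodes,
       peaks = stats::setNames(peaks, state_levels()),
       terminal_median = as.list(stats::setNames(
         traj$median[nrow(traj$median), ], state_levels())))
}

config_hash <- function(scenario) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(scenario[c("name", "model", "parameters", "initial", "network")],
          f, version = 2)
  unname(tools::md5sum(f))
}

#' Serialize a scenario to a YAML config (and back)
#'
#' `write_scenario_config()` writes a scenario as YAML; `read_scenario_config()`
#' reconstructs it. Every built-in scenario round-trips unchanged.
#'
#' @param scenario A `scenario` object.
#' @param path File path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a `scenario`.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  yaml::write_yaml(list(name = scenario$name,
                        model = scenario$model,
                        parameters = unclass(scenario$parameters),
                        initial = as.list(scenario$initial),
                        network = scenario$network,
                        description = scenario$description),
                   path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ctor <- switch(cfg$model,
                 sipinrs_ode = sipinrs_params,
                 network = sipinrs_params,
                 sirs_ode = sirs_params,
                 stop("unknown model in config: ", cfg$model, call. = FALSE))
  structure(list(name = cfg$name,
                 model = cfg$model,
                 parameters = do.call(ctor, cfg$parameters),
                 initial = unlist(cfg$initial),
                 network = cfg$network,
                 description = if (is.null(cfg$description)) "" else
                   cfg$description),
            class = "scenario")
}

#' Compare two trajectories on a shared time grid
#'
#' Interpolates `b` linearly onto `a`'s time grid (restricted to the
#' overlapping time range) and reports, per shared compartment, the
#' root-mean-square error and the maximum absolute deviation. Intended for
#' comparing a simulated trajectory against an observed sentiment time
#' series, or two simulation runs against each other.
#'
#' @param a,b `contagion_trajectory` objects (or any data frames with a `t`
#'   column and shared compartment columns).
#' @return An object of class `comparison_report`: a data frame with columns
#'   `compartment`, `rmse`, `max_abs_dev`.
#' @examples
#' traj <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), sipinrs_params(),
#'                           t_end = 20)
#' compare_trajectories(traj, traj) # all zeros
#' @export
compare_trajectories <- function(a, b) {
  if (!"t" %in% names(a) || !"t" %in% names(b))
    stop("both trajectories need a 't' column", call. = FALSE)
  comps <- setdiff(intersect(names(a), names(b)), "t")
  if (length(comps) == 0L) stop("no shared compartments", call. = FALSE)
  lo <- max(min(a$t), min(b$t))
  hi <- min(max(a$t), max(b$t))
  if (lo > hi) stop("disjoint time grids: no overlap", call. = FALSE)
  grid <- a$t[a$t >= lo & a$t <= hi]
  if (length(grid) == 0L) stop("disjoint time grids: no overlap", call. = FALSE)
  rows <- lapply(comps, function(cc) {
    av <- a[[cc]][a$t >= lo & a$t <= hi]
    bv <- approx(b$t, b[[cc]], xout = grid, rule = 1)$y
    d <- av - bv
    data.frame(compartment = cc,
               rmse = sqrt(mean(d^2)),
               max_abs_dev = max(abs(d)))
  })
  structure(do.call(rbind, rows), class = c("comparison_report", "data.frame"))
}
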