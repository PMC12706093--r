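#' Build a continuous-time Markov chain over fusion states
#'
#' The baseline chain runs 1 -> 2 -> 3 -> 4 -> 5 -> 6 -> F (full fusion,
#' absorbing), with the 1 -> 2 transition optionally reversible (the only
#' backward rate allowed in the baseline topology). The tight-docking
#' variants insert a docked state D either between tethering and stalk
#' formation (`dock_before_stalk`: 1 -> D -> 2) or after it
#' (`dock_after_stalk`: 2 -> D -> 3); the links replacing the reversible
#' 1 -> 2 step may carry backward rates.
#'
#' Rates are per ms. All mass starts in state 1 at the action potential
#' (configurable via `p0`), and the observation window is `T_ms`.
#'
#' @param variant `"baseline"`, `"dock_before_stalk"`, `"dock_after_stalk"`.
#' @param rates named vector/list of transition rates, names like `"1->2"`;
#'   unspecified allowed edges default to 0. Negative rates are an error.
#' @param p0 initial distribution over the chain's states (default: all
#'   mass in state 1).
#' @param T_ms observation window in ms (default 2).
#' @return a `chain_model` list: `states`, `Q` (generator matrix), `p0`,
#'   `T_ms`, `variant`, `edges`.
#' @export
build_chain <- function(variant = c("baseline", "dock_before_stalk",
                                    "dock_after_stalk"),
                        rates = NULL, p0 = NULL, T_ms = 2) {
  variant <- match.arg(variant)
  states <- switch(variant,
    baseline = c("1", "2", "3", "4", "5", "6", "F"),
    dock_before_stalk = c("1", "D", "2", "3", "4", "5", "6", "F"),
    dock_after_stalk = c("1", "2", "D", "3", "4", "5", "6", "F"))
  n <- length(states)
  forward <- paste(states[-n], states[-1], sep = "->")
  backward <- switch(variant,
    baseline = "2->1",
    dock_before_stalk = c("D->1", "2->D"),
    dock_after_stalk = c("2->1", "D->2"))
  edges <- c(forward, backward)

  rv <- setNames(rep(0, length(edges)), edges)
  if (!is.null(rates)) {
    rates <- unlist(rates)
    bad <- setdiff(names(rates), edges)
    if (length(bad))
      abort(paste0("rate for edge not in the ", variant, " topology: ",
                   paste(bad, collapse = ", ")))
    if (any(rates < 0)) abort("negative rate")
    rv[names(rates)] <- rates
  }
  Q <- matrix(0, n, n, dimnames = list(states, states))
  for (e in edges) {
    ft <- strsplit(e, "->", fixed = TRUE)[[1]]
    Q[ft[1], ft[2]] <- rv[e]
  }
  diag(Q) <- -rowSums(Q)
  if (is.null(p0)) {
    p0 <- setNames(rep(0, n), states); p0["1"] <- 1
  } else {
    if (length(p0) != n || abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
      abort("p0 must be a probability vector over the chain states")
    p0 <- setNames(as.numeric(p0), states)
  }
  structure(list(states = states, Q = Q, p0 = p0, T_ms = T_ms,
                 variant = variant, edges = edges, rates = rv),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("<chain_model>", x$variant, "states:",
      paste(x$states, collapse = " "), "\n")
  nz <- x$rates[x$rates > 0]
  if (length(nz))
    cat("  rates/ms:", paste(names(nz), signif(nz, 4), sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

#' State occupancy of the chain at time t
#'
#' Forward solution p(t) = p0 exp(Qt).
#'
#' @param model a [build_chain()] model.
#' @param t time in ms (>= 0), scalar or vector.
#' @return matrix with one row per t, columns = states.
#' @export
occupancy <- function(model, t) {
  stopifnot(inherits(model, "chain_model"))
  if (any(t < 0)) abort("t must be >= 0")
  out <- t(vapply(t, function(ti) {
    as.numeric(model$p0 %*% as.matrix(Matrix::expm(model$Q * ti)))
  }, numeric(length(model$states))))
  colnames(out) <- model$states
  out
}

#' Fit transition rates from a single snapshot of state counts
#'
#' Maximises the multinomial log-likelihood of the observed per-state event
#' counts under the snapshot model: profiles are observations of the chain
#' at the freezing time T, conditioned on not having reached full fusion,
#' so the category probabilities are p_i(T) / sum_j p_j(T) over the counted
#' transient states. The exit rate from the last transient state (6 -> F)
#' is not identifiable from relative occupancies (the likelihood is flat in
#' it) and must be pinned by convention; the default (`NA`) pins it to the
#' mean of the fitted forward rates in a second pass, a neutral data-driven
#' identification, but any fixed value can be supplied. Because the
#' remaining parameters still outnumber the multinomial degrees of freedom,
#' the maximum-likelihood set is generically a ridge; it is resolved by a
#' weak parsimony penalty (`ridge_penalty` times the sum of free rates)
#' that deterministically prefers the slowest kinetics consistent with the
#' data. Bounded multi-start L-BFGS-B on log rates.
#'
#' @param observed_counts named vector of event counts per transient state
#'   (e.g. `c("1" = 10, "2" = 22, ...)`); at least two nonzero.
#' @param variant chain topology, see [build_chain()].
#' @param T_ms observation window (default 2).
#' @param fixed named vector of rates to hold fixed; an `NA` value means
#'   "pin to the mean fitted forward rate" (default `c("6->F" = NA)`).
#' @param n_restarts number of optimisation starts (default 20).
#' @param seed RNG seed for the restarts.
#' @param rate_bounds lower/upper bounds on each free rate, per ms.
#' @param ridge_penalty weight of the rate-parsimony penalty (default 1e-3
#'   per rate unit; 0 disables it).
#' @return an `msm_fit` list: `model` (fitted [build_chain()]), `rates`,
#'   `logLik`, `convergence`, `n_restarts`, `seed`, `counts`.
#' @export
fit_rates <- function(observed_counts,
                      variant = "baseline",
                      T_ms = 2,
                      fixed = c("6->F" = NA),
                      n_restarts = 20,
                      seed = 1L,
                      rate_bounds = c(1e-3, 30),
                      ridge_penalty = 1e-3) {
  counts <- observed_counts
  if (is.null(names(counts))) abort("observed_counts must be named")
  if (any(counts < 0)) abort("counts must be >= 0")
  if (sum(counts > 0) < 2) {
    warn("fewer than two nonzero counts; boundary solution likely")
  }
  proto <- build_chain(variant, T_ms = T_ms)
  transient <- setdiff(proto$states, "F")
  bad <- setdiff(names(counts), transient)
  if (length(bad)) abort(paste0("counts for unknown states: ",
                                paste(bad, collapse = ", ")))
  cnt <- setNames(rep(0, length(transient)), transient)
  cnt[names(counts)] <- counts

  auto <- names(fixed)[is.na(fixed)]
  if (length(auto)) {
    # first pass with a provisional terminal rate, then pin the
    # unidentifiable exit to the mean fitted forward rate and refit
    fixed1 <- fixed; fixed1[auto] <- 1
    fit1 <- fit_rates(observed_counts, variant, T_ms, fixed1,
                      n_restarts, seed, rate_bounds, ridge_penalty)
    n_st <- length(proto$states)
    spine <- paste(proto$states[-n_st], proto$states[-1], sep = "->")
    ref <- setdiff(spine, names(fixed))
    fixed[auto] <- mean(fit1$rates[ref])
    return(fit_rates(observed_counts, variant, T_ms, fixed,
                     n_restarts, seed, rate_bounds, ridge_penalty))
  }

  free <- setdiff(proto$edges, names(fixed))
  nll <- function(logk) {
    rates <- c(setNames(exp(logk), free), fixed)
    m <- build_chain(variant, rates = rates, T_ms = T_ms)
    p <- occupancy(m, T_ms)[1, transient]
    s <- sum(p)
    if (s <= 0 || any(p < -1e-12)) return(1e10)
    pr <- pmax(p / s, 1e-300)
    -sum(cnt * log(pr)) + ridge_penalty * sum(exp(logk))
  }
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  set.seed(seed)
  starts <- matrix(runif(n_restarts * length(free), lb, ub),
                   n_restarts, length(free))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(starts[r, ], nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("all optimisation starts failed")
  rates <- c(setNames(exp(best$par), free), fixed)
  model <- build_chain(variant, rates = rates, T_ms = T_ms)
  loglik <- -best$value + ridge_penalty * sum(exp(best$par))
  structure(list(model = model, rates = rates, logLik = loglik,
                 convergence = best$convergence == 0,
                 n_restarts = n_restarts, seed = seed, counts = cnt,
                 transient = transient, free_edges = free),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("<msm_fit>", x$model$variant, " logLik =", format(x$logLik), "\n")
  print(signif(x$rates, 4))
  invisible(x)
}

#' Mean first-passage time between chain states
#'
#' Solves the linear system for the expected hitting time of `target`
#' starting from `source`. Unreachable targets give Inf (flagged with a
#' message).
#'
#' @param model a [build_chain()] model.
#' @param source,target state names.
#' @return time in ms (possibly Inf).
#' @export
mean_waiting_time <- function(model, source, target) {
  stopifnot(inherits(model, "chain_model"))
  states <- model$states
  if (!source %in% states || !target %in% states)
    abort("unknown state name")
  if (source == target) return(0)
  # the hitting-time system lives on the states that can reach the target
  reach <- .reachable(model$Q, target)
  if (!source %in% reach) {
    inform(paste0("target ", target, " unreachable from ", source))
    return(Inf)
  }
  keep <- setdiff(reach, target)
  A <- model$Q[keep, keep, drop = FALSE]
  t_ <- tryCatch(solve(-A, rep(1, length(keep))),
                 error = function(e) rep(Inf, length(keep)))
  out <- setNames(t_, keep)[source]
  if (!is.finite(out)) Inf else unname(out)
}

.reachable <- function(Q, target) {
  # states that can reach target (reverse BFS on the adjacency of Q)
  states <- rownames(Q)
  adj <- Q > 0
  frontier <- target; seen <- target
  while (length(frontier)) {
    preds <- states[apply(adj[, frontier, drop = FALSE], 1, any)]
    new <- setdiff(preds, seen)
    seen <- c(seen, new); frontier <- new
  }
  seen
}

#' Simulate chain trajectories (Gillespie)
#'
#' Exact stochastic simulation of the CTMC; used as the independent oracle
#' for [occupancy()], [mean_waiting_time()] and [fit_rates()] parameter
#' recovery. Deterministic given the seed.
#'
#' @param model a [build_chain()] model.
#' @param n_paths number of trajectories.
#' @param t_max end time (ms).
#' @param seed RNG seed.
#' @param keep_paths return the full jump chains (default FALSE: only end
#'   states and first-passage info).
#' @return list with `end_state` (factor over states at t_max),
#'   `first_absorption_ms` (time of hitting the last state, NA if not
#'   reached), and optionally `paths`.
#' @export
simulate_chain <- function(model, n_paths, t_max, seed = 1L,
                           keep_paths = FALSE) {
  stopifnot(inherits(model, "chain_model"))
  if (n_paths < 1) abort("n_paths must be >= 1")
  set.seed(seed)
  states <- model$states
  n <- length(states)
  Q <- model$Q
  exit <- -diag(Q)
  jump_prob <- Q; diag(jump_prob) <- 0
  jump_prob <- jump_prob / ifelse(exit > 0, exit, 1)

  start <- sample.int(n, n_paths, replace = TRUE, prob = model$p0)
  cur <- start
  t_cur <- rep(0, n_paths)
  absorbed_at <- rep(NA_real_, n_paths)
  active <- exit[cur] > 0
  paths <- if (keep_paths)
    lapply(seq_len(n_paths), function(i)
      list(states = states[cur[i]], times = 0)) else NULL
  final <- states[n]
  while (any(active)) {
    idx <- which(active)
    dwell <- rexp(length(idx), exit[cur[idx]])
    t_new <- t_cur[idx] + dwell
    over <- t_new > t_max
    t_cur[idx] <- pmin(t_new, t_max)
    active[idx[over]] <- FALSE
    mv <- idx[!over]
    if (length(mv)) {
      nxt <- vapply(mv, function(i)
        sample.int(n, 1, prob = jump_prob[cur[i], ]), integer(1))
      if (keep_paths) for (j in seq_along(mv)) {
        i <- mv[j]
        paths[[i]]$states <- c(paths[[i]]$states, states[nxt[j]])
        paths[[i]]$times <- c(paths[[i]]$times, t_cur[i])
      }
      newly_final <- states[nxt] == final & is.na(absorbed_at[mv])
      absorbed_at[mv[newly_final]] <- t_cur[mv[newly_final]]
      cur[mv] <- nxt
      active[mv] <- exit[cur[mv]] > 0
    }
  }
  list(end_state = factor(states[cur], levels = states),
       first_absorption_ms = absorbed_at,
       paths = paths)
}
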