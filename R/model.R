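#' RL-DDM parameters for one agent
#'
#' Either a single learning rate `eta`, or a dual pair `eta_pos` / `eta_neg`
#' applied to positive and negative prediction errors respectively; a drift
#' scaling `v_scaling` mapping Q-value differences to drift rates; boundary
#' separation `a` (evidence units); and non-decision time `t0` (seconds).
#'
#' @param eta Single learning rate in `[0, 1]` (mutually exclusive with the
#'   dual pair).
#' @param eta_pos,eta_neg Learning rates in `[0, 1]` for positive / negative
#'   prediction errors.
#' @param v_scaling Drift-rate scaling, unitless, `>= 0`.
#' @param a Boundary separation, `> 0`.
#' @param t0 Non-decision time in seconds, `>= 0`.
#' @return An object of class `"agent_params"` with a `rate_structure`
#'   attribute of `"single"` or `"dual"`.
#' @examples
#' agent_params(eta = 0.2, v_scaling = 2, a = 1.5, t0 = 0.3)
#' agent_params(eta_pos = 0.3, eta_neg = 0.1, v_scaling = 2, a = 1.5, t0 = 0.3)
#' @export
agent_params <- function(eta = NULL, eta_pos = NULL, eta_neg = NULL,
                         v_scaling, a, t0) {
  single <- !is.null(eta)
  dual <- !is.null(eta_pos) || !is.null(eta_neg)
  if (single && dual)
    stop("supply either a single eta or the eta_pos/eta_neg pair, not both")
  if (!single && !dual) stop("a learning rate must be supplied")
  if (dual && (is.null(eta_pos) || is.null(eta_neg)))
    stop("dual-rate parameters require both eta_pos and eta_neg")
  rates <- if (single) c(eta = eta) else c(eta_pos = eta_pos, eta_neg = eta_neg)
  if (any(rates < 0 | rates > 1)) stop("learning rates must lie in [0, 1]")
  if (!(a > 0)) stop("boundary separation a must be positive")
  if (t0 < 0) stop("non-decision time t0 must be non-negative")
  if (v_scaling < 0) stop("v_scaling must be non-negative")
  structure(c(as.list(rates), list(v_scaling = v_scaling, a = a, t0 = t0)),
            rate_structure = if (single) "single" else "dual",
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("RL-DDM agent parameters (", attr(x, "rate_structure"), " rate):\n",
      sep = "")
  print(unlist(x))
  invisible(x)
}

# internal: (eta_pos, eta_neg) view regardless of rate structure
.rates_of <- function(params) {
  if (attr(params, "rate_structure") == "single")
    c(params$eta, params$eta)
  else c(params$eta_pos, params$eta_neg)
}

#' Initialise the Q-value table
#'
#' All symbols start at 0.5: with rewards coded in `{0, 1}` this is the
#' uninformed value, and it makes the initial drift rate of every pair
#' exactly zero (first choices are guesses).
#'
#' @param config A `"pst_task"`.
#' @return Named numeric vector, symbol -> Q-value.
#' @export
init_q <- function(config) {
  stopifnot(inherits(config, "pst_task"))
  symbols <- unlist(lapply(config$pairs,
                           function(p) c(p$better_symbol, p$worse_symbol)))
  stats::setNames(rep(0.5, length(symbols)), symbols)
}

#' Delta-rule update of the chosen symbol's Q-value
#'
#' Single rate: `Q <- Q + eta * (R - Q)`. Dual rate: the update uses
#' `eta_pos` when the prediction error `R - Q` is positive and `eta_neg`
#' when it is negative (no update at exactly zero). Only the chosen symbol
#' changes.
#'
#' @param q Named Q-value vector from [init_q()].
#' @param chosen Symbol identifier present in `q`.
#' @param reward Reward in `{0, 1}`.
#' @param params An `"agent_params"` object.
#' @return The updated Q-value vector.
#' @export
update_q <- function(q, chosen, reward, params) {
  if (!chosen %in% names(q)) stop("unknown symbol: ", chosen)
  stopifnot(reward %in% c(0, 1), inherits(params, "agent_params"))
  r <- .rates_of(params)
  pe <- reward - q[[chosen]]
  rate <- if (pe > 0) r[1] else if (pe < 0) r[2] else 0
  q[[chosen]] <- q[[chosen]] + rate * pe
  q
}

#' Trial drift rate from Q-values
#'
#' `v = (Q[better] - Q[worse]) * v_scaling`; positive drift favours the
#' upper boundary, which is response-coded as the pair's optimal symbol.
#'
#' @param q Named Q-value vector.
#' @param pair A `"pst_pair"`.
#' @param params An `"agent_params"`.
#' @return Signed drift rate.
#' @export
trial_drift <- function(q, pair, params) {
  stopifnot(inherits(pair, "pst_pair"), inherits(params, "agent_params"))
  if (!all(c(pair$better_symbol, pair$worse_symbol) %in% names(q)))
    stop("pair symbols missing from Q table")
  (q[[pair$better_symbol]] - q[[pair$worse_symbol]]) * params$v_scaling
}

#' Closed-form upper-boundary absorption probability
#'
#' For an unbiased start (a/2) and unit diffusion coefficient the probability
#' that drift `v` reaches the upper boundary is `1 / (1 + exp(-a v))` — the
#' analytic oracle used to validate the first-passage simulator and the
#' likelihood.
#'
#' @param a Boundary separation, `> 0`.
#' @param v Drift rate.
#' @return Probability of upper-boundary absorption.
#' @export
choice_prob_upper <- function(a, v) {
  if (!is.numeric(a) || any(a <= 0)) stop("boundary separation a must be positive")
  stats::plogis(a * v)
}

#' Simulate first passages of the decision diffusion
#'
#' Euler–Maruyama simulation (default step `dt = 1e-4` s) from the unbiased
#' start `a/2` with unit diffusion coefficient, including the exact
#' Brownian-bridge probability of an unobserved within-step crossing so that
#' absorption is unbiased at the step size used. The non-decision time is
#' added to every passage time.
#'
#' @param n Number of draws.
#' @param a Boundary separation, `> 0`.
#' @param v Drift rate.
#' @param t0 Non-decision time (seconds).
#' @param dt Integration step (seconds).
#' @param max_t Safety cap on decision time (seconds).
#' @return A data frame with columns `rt` (seconds) and `upper` (logical).
#' @export
simulate_first_passage <- function(n, a, v, t0 = 0, dt = 1e-4, max_t = 300) {
  stopifnot(n >= 1, a > 0, t0 >= 0)
  res <- .fp_sim_cpp(as.integer(n), a, v, t0, dt, max_t)
  data.frame(rt = res$rt, upper = res$upper)
}

#' Wiener first-passage-time log-density
#'
#' Joint density of hitting the stated boundary at time `rt`, for boundary
#' separation `a`, signed drift `v`, non-decision time `t0`, unbiased start
#' `a/2` and unit diffusion coefficient. Computed from the small-time /
#' large-time series expansions with automatic regime switching and
#' truncation error below 1e-7; zero density (log-density `-Inf`) for
#' `rt <= t0`.
#'
#' @param rt Response time(s), seconds.
#' @param a Boundary separation, `> 0`.
#' @param v Drift rate.
#' @param t0 Non-decision time, seconds.
#' @param boundary `"upper"` or `"lower"`, recycled over `rt`.
#' @return Log-density vector, same length as `rt`.
#' @export
wfpt_logdensity <- function(rt, a, v, t0 = 0,
                            boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  .wfpt_logd_cpp(rt, a, v, t0, boundary == "upper")
}

#' Simulate one RL-DDM trial
#'
#' Computes the trial drift from the current Q-values, simulates a first
#' passage, and maps the upper boundary to the pair's better symbol and the
#' lower boundary to the worse symbol (response coding).
#'
#' @inheritParams trial_drift
#' @param dt Integration step for the diffusion (seconds).
#' @return `list(chosen =, rt =, upper =)`.
#' @export
simulate_agent_trial <- function(q, pair, params, dt = 1e-4) {
  v <- trial_drift(q, pair, params)
  fp <- simulate_first_passage(1L, params$a, v, params$t0, dt = dt)
  list(chosen = if (fp$upper) pair$better_symbol else pair$worse_symbol,
       rt = fp$rt, upper = fp$upper)
}

#' A learning RL-DDM agent for the session runner
#'
#' Couples the delta rule to the diffusion choice process: on each trial the
#' agent derives its drift from the current Q-difference of the presented
#' pair, diffuses to a boundary, and updates the chosen symbol's Q-value
#' from the feedback it receives.
#'
#' @param params An `"agent_params"`.
#' @param task A `"pst_task"`.
#' @param dt Diffusion integration step (seconds).
#' @return An agent list usable with [run_session()]; its mutable Q table is
#'   accessible as `agent$q()`.
#' @export
agent_rlddm <- function(params, task, dt = 1e-4) {
  stopifnot(inherits(params, "agent_params"), inherits(task, "pst_task"))
  q <- init_q(task)
  list(
    act = function(pair, left, right) {
      res <- simulate_agent_trial(q, task$pairs[[pair]], params, dt = dt)
      res[c("chosen", "rt")]
    },
    learn = function(chosen, reward) {
      q <<- update_q(q, chosen, reward, params)
    },
    q = function() q
  )
}
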