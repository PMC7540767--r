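.rm_maxn <- 4096L

.pack_parms <- function(g, w, pr, steady_tol, num_floor, imm, mask) {
  n <- length(g)
  if (n > .rm_maxn) {
    stop(sprintf("compiled right-hand side supports at most %d strains",
                 .rm_maxn), call. = FALSE)
  }
  parms <- numeric(9L + 4L * .rm_maxn)
  parms[1:9] <- c(pr$eta, pr$beta, pr$delta, pr$alpha, pr$C, steady_tol,
                  num_floor, imm, n)
  parms[9L + seq_len(n)] <- g
  parms[9L + n + seq_len(n)] <- w
  parms[9L + 2L * n + seq_len(2L * n)] <- as.numeric(mask)
  parms
}

#' Integrate the ecosystem dynamics
#'
#' Advances an [ecosystem_state()] by `duration` time units with an
#' adaptive-step solver (deSolve, compiled right-hand side). Densities
#' driven marginally below zero by round-off are clamped to zero. With
#' `stop_at_steady = TRUE` the solver watches the largest relative rate of
#' change and stops integrating once it falls below `steady_tol`
#' (densities below one individual are scaled absolutely so strains
#' decaying to extinction do not block termination); the state's clock is
#' still advanced by the full `duration`, since nothing changes after the
#' community settles.
#'
#' @param state an [ecosystem_state()].
#' @param params an [eco_params()].
#' @param duration integration time, `> 0`.
#' @param rtol,atol relative and absolute solver tolerances. The defaults
#'   put `atol` three orders of magnitude below the one-individual
#'   extinction threshold.
#' @param stop_at_steady stop early once the dynamics settle (see above).
#' @param steady_tol threshold on the largest relative rate of change.
#' @param num_floor numerical extinction floor (individuals). Boom-and-bust
#'   transients can drive a density tens of orders of magnitude below a
#'   single individual, where the continuous equations are physically
#'   meaningless and the integrator grinds to a halt near the denormal
#'   range. Any density crossing `num_floor` from above is zeroed (the
#'   solver stops exactly at the crossing, via root finding, and
#'   restarts); a zeroed phage variant can still regrow through its
#'   cross-infection source term. Set to `0` to disable.
#' @param imm constant refuge influx (individuals per time) added to
#'   every density derivative. The boom-and-bust transients of these
#'   equations drive densities hundreds of orders of magnitude below one
#'   individual, from which the exact flow later recovers; any
#'   tolerance-limited integration instead recovers from its own noise
#'   floor. `imm` makes that refuge explicit, deterministic and
#'   reproducible: densities bottom out near `imm / rate`, still orders
#'   of magnitude below one individual, and anything below the extinction
#'   threshold at the end of a round is culled as usual. (For phage
#'   variants the refuge is qualitatively redundant: a variant regrows
#'   from zero through its cross-infection source term `eta omega beta b
#'   P` regardless.) The default (`1e-6`) perturbs interior steady states
#'   (order `1e5` individuals and up) negligibly; set to `0` for the
#'   unmodified equations.
#' @param maxsteps maximal internal solver steps per leg.
#' @return the advanced [ecosystem_state()].
#' @export
integrate_ecosystem <- function(state, params, duration, rtol = 1e-6,
                                atol = 1e-3,
                                stop_at_steady = FALSE, steady_tol = 1e-8,
                                num_floor = 1e-10, imm = 1e-6,
                                maxsteps = 1e5) {
  stopifnot(duration > 0)
  n <- length(state$b)
  if (n == 0) {
    state$t <- state$t + duration
    return(state)
  }
  y <- c(state$b, state$p)
  g <- state$strains$gamma
  w <- state$strains$omega
  remaining <- duration
  repeat {
    # watch only densities currently above the floor; a density at zero can
    # legitimately regrow through the floor (cross-infection source term)
    # and must not be re-zeroed on the way up; nothing is watched while
    # the refuge influx bounds all densities away from the floor
    mask <- if (imm > 0) rep(FALSE, 2L * n) else y > num_floor
    parms <- .pack_parms(g, w, params,
                         if (stop_at_steady) steady_tol else -1,
                         if (any(mask)) num_floor else -1, imm, mask)
    out <- deSolve::lsodar(y = y, times = c(0, remaining),
                           func = "rm_derivs", parms = parms,
                           dllname = "rmphage", initfunc = "rm_initmod",
                           rootfunc = "rm_root", nroot = 2L, rtol = rtol,
                           atol = atol, maxsteps = maxsteps)
    istate <- attr(out, "istate")
    code <- if (is.null(istate)) 0L else istate[1]
    t_reached <- out[nrow(out), 1]
    if (code < 0 && (code != -1L || t_reached <= 0)) {
      # -1 (step budget exhausted) is resumable as long as time advanced
      stop(sprintf(
        paste0("ODE solver failed (istate = %d) at t = %.6g with %d ",
               "strains (B = %.4g, P = %.4g)"),
        code, state$t + duration - remaining, n, sum(y[seq_len(n)]),
        sum(y[n + seq_len(n)])), call. = FALSE)
    }
    y <- as.numeric(out[nrow(out), -1])
    y[y < 0 | (mask & y <= num_floor)] <- 0
    iroot <- attr(out, "iroot")
    hit_floor <- !is.null(iroot) && length(iroot) >= 2 && iroot[2] == 1
    steady <- !is.null(iroot) && length(iroot) >= 1 && iroot[1] == 1
    remaining <- remaining - t_reached
    if (steady || remaining <= 0 || (!hit_floor && code != -1L)) break
  }
  state$b <- y[seq_len(n)]
  state$p <- y[n + seq_len(n)]
  state$t <- state$t + duration
  state
}

#' Remove extinct strains and phage variants
#'
#' Applies the open-ecosystem culling rule: every strain whose bacterial
#' density is below `params$ext_threshold` is removed together with its
#' paired phage variant (the whole slot is deleted); a phage variant whose
#' density is below threshold while its host strain survives is set to
#' zero but keeps its slot, so the strain can persist with its variant
#' extinct.
#'
#' @param state an [ecosystem_state()].
#' @param params an [eco_params()].
#' @return list with the culled `state` and `removed`, the indices (into
#'   the incoming state) of deleted strains.
#' @export
cull_extinct <- function(state, params) {
  thr <- params$ext_threshold
  state$p[state$p < thr] <- 0
  drop <- which(state$b < thr)
  if (length(drop)) {
    state$b <- state$b[-drop]
    state$p <- state$p[-drop]
    state$strains <- state$strains[-drop, , drop = FALSE]
  }
  list(state = state, removed = drop)
}

#' Open-ecosystem assembly by direct integration
#'
#' The full dynamical version of the open-ecosystem protocol: at each
#' multiple of `params$T` the extinct strains are culled
#' ([cull_extinct()]), one newly sampled strain and its matched phage
#' variant are introduced at a density of a single individual each, and
#' the differential equations are integrated for `T`.
#'
#' @inheritParams iterative_evolution
#' @param M0 number of initial resident strains (sampled from the same
#'   distribution, introduced at one individual each before round 1).
#' @param rtol,atol,stop_at_steady,steady_tol,num_floor,imm,maxsteps passed to
#'   [integrate_ecosystem()]. Early stopping at steady state is on by
#'   default: with `T = 1e4` and rates of order one the community settles
#'   long before the next invasion, and skipping the settled stretch does
#'   not change the recorded states. The engine defaults are tighter than
#'   the plain integrator's: at `rtol = 1e-6` solver noise can pump the
#'   community's weakly damped oscillatory mode and keep rounds from ever
#'   reaching the steady-stop, which costs far more time than the extra
#'   accuracy does.
#' @return an `assembly_record` (see [iterative_evolution()]) with
#'   attribute `engine = "ode"` and `final_state`, the final
#'   [ecosystem_state()].
#' @export
evolve_open_ecosystem <- function(sampler, n_rounds, params, M0 = 0,
                                  seed = NULL, rtol = 1e-8, atol = 1e-5,
                                  stop_at_steady = TRUE,
                                  steady_tol = 1e-6, num_floor = 1e-10,
                                  imm = 1e-6, maxsteps = 1e5) {
  stopifnot(n_rounds >= 1, M0 >= 0)
  with_seed(seed, {
    draws <- sampler(n_rounds + M0)
    state <- ecosystem_state(draws[seq_len(M0), , drop = FALSE],
                             b = rep(1, M0), p = rep(1, M0), t = 0)
    D <- integer(n_rounds); Bv <- numeric(n_rounds); Pv <- numeric(n_rounds)
    Sv <- numeric(n_rounds); fmin <- numeric(n_rounds)
    nrem <- integer(n_rounds)
    for (r in seq_len(n_rounds)) {
      cl <- cull_extinct(state, params)
      state <- cl$state
      nrem[r] <- length(cl$removed)
      k <- M0 + r
      state$strains <- rbind(state$strains, draws[k, , drop = FALSE])
      state$b <- c(state$b, 1)
      state$p <- c(state$p, 1)
      state <- integrate_ecosystem(state, params, params$T, rtol = rtol,
                                   atol = atol,
                                   stop_at_steady = stop_at_steady,
                                   steady_tol = steady_tol,
                                   num_floor = num_floor, imm = imm,
                                   maxsteps = maxsteps)
      alive <- state$b >= params$ext_threshold
      B <- sum(state$b); P <- sum(state$p)
      D[r] <- sum(alive)
      Bv[r] <- B; Pv[r] <- P
      Sv[r] <- if (B > 0) sum(state$strains$omega * state$b) / B else NA_real_
      fmin[r] <- if (any(alive)) {
        min(viability(state$strains$gamma[alive], state$strains$omega[alive],
                      B, P, params))
      } else NA_real_
    }
    rec <- new_assembly_record(
      data.frame(round = seq_len(n_rounds),
                 time = seq_len(n_rounds) * params$T,
                 D = D, B = Bv, P = Pv, S_omega = Sv, f_min = fmin,
                 n_removed = nrem, accepted = TRUE),
      engine = "ode", params = params,
      final = data.frame(gamma = state$strains$gamma,
                         omega = state$strains$omega,
                         b = state$b, p = state$p))
    attr(rec, "final_state") <- state
    rec
  })
}

#' Batch culture of a fixed strain set
#'
#' Inoculates all strains at equal sub-capacity density (`b_i = C / (10
#' n)`, each matched phage variant at `b_i / 10`), integrates for
#' `duration` with periodic extinction culling, and returns the final
#' state. This mimics the co-culture used to read off which strains
#' survive and how survivor biomass ranks with the fitness predictor
#' `gamma'/omega` (see [fitness_table()]).
#'
#' @param strains a [strain_params()] table, non-empty.
#' @param params an [eco_params()].
#' @param duration total culture time.
#' @param cull_every interval between extinction culls.
#' @param ... passed to [integrate_ecosystem()].
#' @return the final [ecosystem_state()] (after a final cull).
#' @export
batch_culture <- function(strains, params, duration = 1e4,
                          cull_every = duration / 10, ...) {
  strains <- as_strain_params(strains)
  n <- nrow(strains)
  if (n == 0) stop("`strains` must be non-empty", call. = FALSE)
  b0 <- params$C / (10 * n)
  state <- ecosystem_state(strains, b = rep(b0, n), p = rep(b0 / 10, n))
  elapsed <- 0
  while (elapsed < duration) {
    step <- min(cull_every, duration - elapsed)
    state <- integrate_ecosystem(state, params, step, ...)
    state <- cull_extinct(state, params)$state
    elapsed <- elapsed + step
  }
  state
}

#' Integrate and return the full trajectory
#'
#' Like [integrate_ecosystem()] but records the state on a user-supplied
#' time grid and returns the whole trajectory, e.g. for plotting
#' transients or averaging densities over an oscillatory attractor.
#'
#' @inheritParams integrate_ecosystem
#' @param times increasing vector of output times (starting at 0, relative
#'   to `state$t`).
#' @return a data frame with columns `time`, `b.1..b.n`, `p.1..p.n`.
#' @export
integrate_trajectory <- function(state, params, times, rtol = 1e-6,
                                 atol = 1e-3, imm = 1e-6, maxsteps = 1e5) {
  n <- length(state$b)
  stopifnot(n >= 1, length(times) >= 2)
  parms <- .pack_parms(state$strains$gamma, state$strains$omega, params,
                       -1, -1, imm, rep(FALSE, 2L * n))
  out <- deSolve::lsodar(y = c(state$b, state$p), times = times,
                         func = "rm_derivs", parms = parms,
                         dllname = "rmphage", initfunc = "rm_initmod",
                         rtol = rtol, atol = atol, maxsteps = maxsteps)
  out <- as.data.frame(out)
  names(out) <- c("time", paste0("b.", seq_len(n)), paste0("p.", seq_len(n)))
  out
}
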