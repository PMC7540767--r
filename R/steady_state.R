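#' Viability criterion
#'
#' Net per-capita growth rate of a (gamma, omega) strain at ambient total
#' bacterial density `B` and total phage density `P`:
#' \deqn{f(\gamma, \omega) = \gamma (1 - B/C) - \alpha - \eta \omega P.}
#' A strain can invade and persist at steady state iff `f > 0`: it must
#' out-grow dilution (`alpha`) and the restriction-discounted phage
#' pressure (`eta omega P`).
#'
#' @param gamma,omega strain parameters (vectorised).
#' @param B,P ambient total bacterial and phage densities.
#' @param params an [eco_params()].
#' @return numeric vector of `f` values.
#' @examples
#' viability(0.5, 1e-2, B = 5e7, P = 1e7, params = eco_params())  # 0.149
#' @export
viability <- function(gamma, omega, B, P, params) {
  gamma * (1 - B / params$C) - params$alpha - params$eta * omega * P
}

# ---- internal steady-state machinery ---------------------------------------
# Setting db_i = 0 with b_i > 0 gives   p_i = f(g_i, w_i) / (eta (1 - w_i))
# Setting dp_i = 0 with p_i > 0 gives   b_i = (eta B + delta) p_i / (beta g'_i)
# with g'_i = g_i (1 - B/C) - alpha. Summing the p relation yields P as an
# explicit function of B; substituting into B = sum(b_i) leaves one scalar
# residual in B, solved by bracketed root finding.

.ss_components <- function(B, g, w, pr) {
  gp <- g * (1 - B / pr$C) - pr$alpha
  P <- sum(gp / (1 - w)) / (pr$eta * (1 + sum(w / (1 - w))))
  p <- (gp - pr$eta * w * P) / (pr$eta * (1 - w))
  b <- (pr$eta * B + pr$delta) * p / (pr$beta * gp)
  list(resid = sum(b) - B, P = P, p = p, b = b)
}

# residual over a vector of candidate totals B (columns), vectorised for
# the bracketing scans of .ss_solve
.ss_resid_vec <- function(Bv, g, w, pr) {
  gp <- outer(g, 1 - Bv / pr$C) - pr$alpha          # n x m
  iw <- 1 / (1 - w)
  Pv <- colSums(gp * iw) / (pr$eta * (1 + sum(w * iw)))
  p <- (gp - pr$eta * outer(w, Pv)) * (iw / pr$eta)
  b <- rep(pr$eta * Bv + pr$delta, each = length(g)) * p / (pr$beta * gp)
  colSums(b) - Bv
}

.ss_empty <- function(n) {
  list(B = 0, P = 0, b = rep(0, n), p = rep(0, n), phage_free = FALSE,
       no_root = TRUE)
}

.ss_phage_free <- function(g, pr) {
  i <- which.max(g)
  b <- rep(0, length(g))
  b[i] <- pr$C * (1 - pr$alpha / g[i])
  list(B = b[i], P = 0, b = b, p = rep(0, length(g)), phage_free = TRUE,
       no_root = FALSE)
}

# Coexistence fixed point for the full strain set (may contain negative
# densities when the set is infeasible; see .ss_prune). Root search is
# restricted to (0, min_i C(1 - alpha/g_i)), the interval on which every
# effective growth rate g'_i is positive and the residual is continuous;
# beyond the first pole a strain would need b_i <= 0 anyway. When no root
# exists (the set supports no joint fixed point with phage), the
# components at the quasi-equilibrium -- the B minimising the absolute
# residual -- are returned with no_root = TRUE, so the caller can still
# rank strains by steady-state density to decide which to remove.
.ss_solve <- function(g, w, pr, B_hint = NA_real_) {
  n <- length(g)
  if (n == 0) return(.ss_empty(0))
  if (any(w >= 1)) {
    stop("analytic steady state requires all omega < 1", call. = FALSE)
  }
  if (max(g) <= pr$alpha) {
    # nothing out-grows dilution even without phage
    return(.ss_empty(n))
  }
  grow <- g[g > pr$alpha]
  upper <- min(pr$C * (1 - pr$alpha / grow))
  lo <- upper * 1e-10
  hi <- upper * (1 - 1e-9)
  fn <- function(B) .ss_components(B, g, w, pr)$resid
  scan <- function(grid) {
    vals <- .ss_resid_vec(grid, g, w, pr)
    ok <- is.finite(vals)
    sgn <- sign(vals)
    brk <- which(ok[-1] & ok[-length(ok)] & sgn[-1] * sgn[-length(sgn)] < 0)
    roots <- vapply(brk, function(k) {
      uniroot(fn, grid[c(k, k + 1)], tol = pr$C * 1e-13)$root
    }, numeric(1))
    if (!length(roots)) return(list(root = NA_real_, grid = grid,
                                    vals = vals, ok = ok))
    comp <- lapply(roots, .ss_components, g = g, w = w, pr = pr)
    full <- vapply(comp, function(cc) {
      cc$P > 0 && all(cc$b > 0) && all(cc$p > 0)
    }, logical(1))
    list(root = if (any(full)) max(roots[full]) else max(roots),
         positive = any(full), grid = grid, vals = vals, ok = ok)
  }
  root <- NA_real_
  quasi <- NA_real_
  # community assembly moves the total density only a little per step, so
  # a local bracket around the caller's hint usually suffices
  if (is.finite(B_hint) && B_hint > lo && B_hint < hi) {
    win <- c(max(lo, 0.3 * B_hint), min(hi, 6 * B_hint))
    if (win[1] < win[2]) {
      res <- scan(exp(seq(log(win[1]), log(win[2]), length.out = 49)))
      if (is.finite(res$root) && isTRUE(res$positive)) root <- res$root
    }
  }
  if (!is.finite(root)) {
    # scan the whole interval: the residual can have several roots, and
    # the dynamically stable community sits at the largest fully positive
    # one. Roots cluster many decades below the upper end (total
    # densities of order delta/(eta beta) against an interval reaching
    # order C), so the scan is log-spaced with a linear complement.
    res <- scan(sort(c(exp(seq(log(lo), log(hi), length.out = 257)),
                       seq(lo, hi, length.out = 65))))
    root <- res$root
    if (!is.finite(root) && any(res$ok)) {
      quasi <- res$grid[res$ok][which.min(abs(res$vals[res$ok]))]
    }
  }
  if (is.finite(root)) {
    cc <- .ss_components(root, g, w, pr)
    if (is.finite(cc$P) && cc$P > 0) {
      return(list(B = root, P = cc$P, b = cc$b, p = cc$p,
                  phage_free = FALSE, no_root = FALSE))
    }
    quasi <- root
  }
  if (!is.finite(quasi)) return(.ss_empty(n))
  cc <- .ss_components(quasi, g, w, pr)
  list(B = quasi, P = cc$P, b = cc$b, p = cc$p, phage_free = FALSE,
       no_root = TRUE)
}

# Iteratively remove the strain with the smallest steady-state density until
# every remaining strain satisfies f > 0 (and, when enforce_threshold, has an
# analytic density at or above the extinction threshold, mirroring the culling
# of the dynamical protocol). Returns indices kept/removed plus the solution.
.ss_prune <- function(g, w, pr, enforce_threshold = TRUE,
                      B_hint = NA_real_) {
  keep <- seq_along(g)
  removed <- integer(0)
  sol <- .ss_empty(0)
  # strains that cannot out-grow dilution even without phage are dead on
  # arrival; left in, their negative effective growth rate flips the sign
  # of the density formula and corrupts the smallest-density ranking
  doa <- keep[g <= pr$alpha]
  if (length(doa)) {
    removed <- doa
    keep <- setdiff(keep, doa)
  }
  drop_one <- function(b) {
    j <- which.min(b)  # ties: first (insertion order) wins
    removed <<- c(removed, keep[j])
    keep <<- keep[-j]
  }
  while (length(keep)) {
    sol <- .ss_solve(g[keep], w[keep], pr, B_hint = B_hint)
    if (!sol$no_root) B_hint <- sol$B
    if (sol$no_root) {
      if (sol$B == 0) {  # nothing out-grows dilution: all extinct
        removed <- c(removed, keep)
        keep <- integer(0)
        sol <- .ss_empty(0)
        break
      }
      if (length(keep) == 1) {
        # a lone strain that grows but cannot sustain its phage settles
        # at the phage-free logistic fixed point
        sol <- .ss_phage_free(g[keep], pr)
        break
      }
      # no joint fixed point: remove the most suppressed strain at the
      # quasi-equilibrium and retry
      drop_one(sol$b)
      next
    }
    f <- viability(g[keep], w[keep], sol$B, sol$P, pr)
    bad <- f <= 0 | sol$b <= 0 | sol$p <= 0
    if (enforce_threshold) bad <- bad | sol$b < pr$ext_threshold
    if (!any(bad)) break
    drop_one(sol$b)
    if (!length(keep)) sol <- .ss_empty(0)
  }
  list(sol = sol, keep = keep, removed = removed)
}

new_steady_state <- function(sol, strains) {
  structure(list(B = sol$B, P = sol$P, b = sol$b, p = sol$p,
                 survivors = which(sol$b > 0), strains = strains,
                 phage_free = sol$phage_free),
            class = "steady_state")
}

#' Analytic steady state of the ecosystem
#'
#' Computes the coexistence fixed point of the dynamical equations for a
#' given strain set: per-variant densities `p_i = f(gamma_i, omega_i) /
#' (eta (1 - omega_i))`, per-strain densities `b_i = (eta B + delta) p_i /
#' (beta gamma'_i)`, with the total `B` obtained by bracketed root finding
#' of the self-consistency condition `sum(b_i) = B` on `(0, C)`. If no
#' phage-sustaining root exists, the phage-free branch is returned:
#' competitive exclusion leaves only the fastest-growing strain at its
#' logistic fixed point `B = C (1 - alpha/gamma_max)`, `P = 0`.
#'
#' The returned densities satisfy the fixed point algebraically whether or
#' not they are all positive; a negative `b_i` flags an infeasible strain.
#' Use [prune_to_feasible()] to obtain the self-consistent survivor set.
#'
#' @param strains a [strain_params()] table; all `omega < 1`.
#' @param params an [eco_params()].
#' @return a `steady_state` object: fields `B`, `P`, `b`, `p`,
#'   `survivors` (indices with `b > 0`), `strains`, `phage_free`.
#' @examples
#' pr <- eco_params()
#' ss <- solve_steady_state(strain_params(0.5, 0), pr)
#' ss$B * pr$eta * (pr$beta - 1) / pr$delta  # = 1 (the delta/(eta(beta-1)) law)
#' @export
solve_steady_state <- function(strains, params) {
  strains <- as_strain_params(strains)
  sol <- .ss_solve(strains$gamma, strains$omega, params)
  if (sol$no_root && nrow(strains) > 0) {
    sol <- if (max(strains$gamma) > params$alpha) {
      .ss_phage_free(strains$gamma, params)
    } else {
      .ss_empty(nrow(strains))
    }
  }
  new_steady_state(sol, strains)
}

#' Prune a strain set to a feasible steady state
#'
#' Repeatedly solves the steady state and, while any strain violates the
#' viability criterion `f > 0` (or its analytic density falls below the
#' extinction threshold when `enforce_threshold = TRUE`), removes the
#' strain with the smallest steady-state density and re-solves. Terminates
#' with a self-consistent survivor set (possibly empty).
#'
#' @inheritParams solve_steady_state
#' @param enforce_threshold also remove survivors whose analytic density is
#'   below `params$ext_threshold`, mirroring the culling used by the
#'   dynamical protocol. Set `FALSE` for the strict `f > 0` rule.
#' @return a `steady_state` for the surviving subset, carrying the
#'   attribute `removed` (indices into `strains` in order of removal).
#' @export
prune_to_feasible <- function(strains, params, enforce_threshold = TRUE) {
  strains <- as_strain_params(strains)
  res <- .ss_prune(strains$gamma, strains$omega, params,
                   enforce_threshold = enforce_threshold)
  out <- new_steady_state(res$sol, strains[res$keep, , drop = FALSE])
  attr(out, "kept") <- res$keep
  attr(out, "removed") <- res$removed
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "<steady_state> %d strain(s), %d survivor(s), B = %.4g, P = %.4g%s\n",
    length(x$b), length(x$survivors), x$B, x$P,
    if (isTRUE(x$phage_free)) " (phage-free)" else ""))
  invisible(x)
}

#' Iterative community assembly
#'
#' The fast approximation of the open-ecosystem protocol built on the
#' analytic steady state. Starting from an empty ecosystem (`B = P = 0`),
#' each round draws one `(gamma, omega)` pair from the sampler; if it
#' satisfies the viability criterion `f > 0` at the current `(B, P)` it is
#' added and the steady state re-solved via [prune_to_feasible()] (removing
#' newly infeasible residents, smallest density first); time then advances
#' by `params$T`. The approximation is good whenever `T` is long enough
#' for the full dynamics to settle between invasions.
#'
#' @param sampler a function of `n` returning a [strain_params()] table,
#'   e.g. from [make_sampler()].
#' @param n_rounds number of invasion rounds, `>= 1`.
#' @param params an [eco_params()].
#' @param seed optional RNG seed (caller's RNG state restored).
#' @param enforce_threshold see [prune_to_feasible()].
#' @return an `assembly_record`: a data frame with one row per round
#'   (`round`, `time`, `D`, `B`, `P`, `S_omega` = the biomass-weighted mean
#'   imperfection `sum(omega_i b_i)/B`, `f_min` = the smallest survivor
#'   viability, `n_removed`, `accepted`), with attributes `engine`
#'   (`"iterative"`), `params`, and `final` (the surviving strain table
#'   with densities).
#' @export
iterative_evolution <- function(sampler, n_rounds, params, seed = NULL,
                                enforce_threshold = TRUE) {
  stopifnot(n_rounds >= 1)
  with_seed(seed, {
    draws <- sampler(n_rounds)
    gseq <- draws$gamma
    wseq <- draws$omega
    g <- numeric(0); w <- numeric(0)
    b <- numeric(0); p <- numeric(0)
    B <- 0; P <- 0
    D <- integer(n_rounds); Bv <- numeric(n_rounds); Pv <- numeric(n_rounds)
    Sv <- numeric(n_rounds); fmin <- numeric(n_rounds)
    nrem <- integer(n_rounds); acc <- logical(n_rounds)
    invC <- 1 / params$C
    # survivor statistics only change on accepted rounds; cache them so
    # the (frequent) rejected rounds cost O(1)
    S_cur <- NA_real_
    fmin_cur <- NA_real_
    for (r in seq_len(n_rounds)) {
      gi <- gseq[r]; wi <- wseq[r]
      f_new <- gi * (1 - B * invC) - params$alpha - params$eta * wi * P
      if (f_new > 0) {
        acc[r] <- TRUE
        g2 <- c(g, gi); w2 <- c(w, wi)
        res <- .ss_prune(g2, w2, params,
                         enforce_threshold = enforce_threshold,
                         B_hint = if (B > 0) B else NA_real_)
        g <- g2[res$keep]; w <- w2[res$keep]
        b <- res$sol$b; p <- res$sol$p
        B <- res$sol$B; P <- res$sol$P
        nrem[r] <- length(res$removed)
        S_cur <- if (B > 0) sum(w * b) / B else NA_real_
        fmin_cur <- if (length(g)) {
          min(g * (1 - B * invC) - params$alpha - params$eta * w * P)
        } else NA_real_
      }
      D[r] <- length(g)
      Bv[r] <- B; Pv[r] <- P
      Sv[r] <- S_cur
      fmin[r] <- fmin_cur
    }
    new_assembly_record(
      data.frame(round = seq_len(n_rounds), time = seq_len(n_rounds) * params$T,
                 D = D, B = Bv, P = Pv, S_omega = Sv, f_min = fmin,
                 n_removed = nrem, accepted = acc),
      engine = "iterative", params = params,
      final = data.frame(gamma = g, omega = w, b = b, p = p))
  })
}

new_assembly_record <- function(df, engine, params, final) {
  structure(df, engine = engine, params = params, final = final,
            class = c("assembly_record", "data.frame"))
}

#' @export
print.assembly_record <- function(x, ...) {
  pr <- attr(x, "params")
  last <- x[nrow(x), ]
  cat(sprintf(
    paste0("<assembly_record> engine = %s, %d round(s)\n",
           "  final: D = %d (D/beta = %.3g), B/C = %.3g, P/C = %.3g\n"),
    attr(x, "engine"), nrow(x), last$D, last$D / pr$beta,
    last$B / pr$C, last$P / pr$C))
  invisible(x)
}
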