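#' Phage propagation probability
#'
#' Probability that a phage of variant `j`, having adsorbed to a random
#' bacterium, successfully propagates: it lands on its methylated host `j`
#' (probability `b_j / B`, certain success) or on any other strain `i`
#' (probability `b_i / B`), where it must escape restriction with
#' probability `omega_i`:
#' \deqn{p_j = b_j/B + \sum_{i \ne j} \omega_i b_i / B.}
#'
#' @param b vector of bacterial densities, with `sum(b) > 0`.
#' @param omega vector of RM imperfections, same length.
#' @param j optional variant index; default returns the whole vector.
#' @return propagation probabilities in `[0, 1]`.
#' @examples
#' propagation_probability(c(1, 1), c(0, 0.5))  # 0.75, 0.50
#' @export
propagation_probability <- function(b, omega, j = NULL) {
  if (length(b) != length(omega)) {
    stop("`b` and `omega` must have the same length", call. = FALSE)
  }
  B <- sum(b)
  if (B <= 0) stop("total bacterial density must be positive", call. = FALSE)
  pj <- (b + sum(omega * b) - omega * b) / B
  if (is.null(j)) pj else pj[j]
}

#' Burst-size bound on diversity
#'
#' For a steady ecosystem, at least one phage from each burst must on
#' average propagate, which aggregates into the bound
#' \deqn{D/\beta \le \frac{1 - S}{1 - \beta S}, \quad
#'       S = \sum_i \omega_i b_i / B,}
#' valid while `beta * S < 1`. With perfect RM systems (`S = 0`) the bound
#' is 1 — diversity limited by the burst size — while leaky RM systems
#' (`S > 0`) relax it, which is how the growth-defence trade-off lets
#' diversity exceed `beta`.
#'
#' @param b vector of bacterial densities, `sum(b) > 0`.
#' @param omega vector of RM imperfections, same length.
#' @param beta phage burst size.
#' @return list with `S` (the biomass-weighted mean imperfection), `bound`
#'   (the right-hand side above, `NA` when invalid) and `valid`
#'   (`beta * S < 1`).
#' @seealso [check_diversity_bound()]
#' @examples
#' diversity_bound(b = c(1, 1), omega = c(0.005, 0.005), beta = 100)$bound
#' @export
diversity_bound <- function(b, omega, beta) {
  B <- sum(b)
  if (B <= 0) stop("total bacterial density must be positive", call. = FALSE)
  S <- sum(omega * b) / B
  valid <- beta * S < 1
  list(S = S,
       bound = if (valid) (1 - S) / (1 - beta * S) else NA_real_,
       valid = valid)
}

#' Check the diversity bound for a community
#'
#' @inheritParams diversity_bound
#' @param D the diversity (number of coexisting strains).
#' @return `TRUE`/`FALSE` when the bound is valid, `NA` when
#'   `beta * S >= 1` (bound uninformative).
#' @export
check_diversity_bound <- function(D, b, omega, beta) {
  db <- diversity_bound(b, omega, beta)
  if (!db$valid) return(NA)
  D / beta <= db$bound
}

#' Survivor fitness table
#'
#' Per-survivor fitness diagnostics at a steady state: the effective
#' growth rate `gamma' = gamma (1 - B/C) - alpha` (net growth at ambient
#' crowding and dilution), the RM strength `1/omega`, the predictor ratio
#' `gamma'/omega`, and the achieved biomass `b`. Spearman rank
#' correlations of biomass against `gamma'` alone, against `1/omega`
#' alone, and against `gamma'/omega` are attached — the ratio is the
#' near-perfect biomass predictor, while neither factor alone is.
#'
#' @param steady a `steady_state` from [solve_steady_state()] or
#'   [prune_to_feasible()], with at least one survivor; alternatively any
#'   list with fields `B`, `b` and a `strains` table (e.g. built from the
#'   `final` attribute of an assembly record).
#' @param params an [eco_params()].
#' @return a data frame (one row per survivor) with columns `gamma`,
#'   `omega`, `gamma_eff`, `ratio`, `b`, and attribute `correlations`, a
#'   named vector of the three Spearman correlations (`NA` when degenerate,
#'   e.g. all survivors identical).
#' @export
fitness_table <- function(steady, params) {
  idx <- if (!is.null(steady$survivors)) steady$survivors
         else seq_along(steady$b)
  if (!length(idx)) stop("no survivors", call. = FALSE)
  g <- steady$strains$gamma[idx]
  w <- steady$strains$omega[idx]
  b <- steady$b[idx]
  gp <- g * (1 - steady$B / params$C) - params$alpha
  tab <- data.frame(gamma = g, omega = w, gamma_eff = gp,
                    ratio = gp / w, b = b)
  rank_cor <- function(x) {
    if (length(b) < 2 || sd(b) == 0 || sd(x) == 0) return(NA_real_)
    cor(b, x, method = "spearman")
  }
  attr(tab, "correlations") <- c(
    ratio = rank_cor(rank(tab$ratio)),  # rank() absorbs Inf from omega = 0
    gamma_eff = rank_cor(gp),
    rm_strength = rank_cor(rank(1 / w)))
  tab
}

#' Diversity summary of a community
#'
#' @param b vector of surviving bacterial densities.
#' @param strains the matching [strain_params()] table.
#' @param params an [eco_params()].
#' @return list with `D`, `D_over_beta`, and the survivor distributions
#'   `log10_b`, `gamma`, `log10_omega`.
#' @export
diversity_summary <- function(b, strains, params) {
  strains <- as_strain_params(strains)
  stopifnot(length(b) == nrow(strains))
  list(D = length(b), D_over_beta = length(b) / params$beta,
       log10_b = log10(b), gamma = strains$gamma,
       log10_omega = log10(strains$omega))
}

#' Parameter sweep of the assembly protocol
#'
#' Re-runs the community assembly across a grid of values for one
#' ecosystem parameter, with several seed replicates per value, and
#' records the final diversity and total densities — the protocol used to
#' probe how robust the high-diversity state is to phage virulence and
#' bacterial mortality.
#'
#' @param param_name one of `"alpha"`, `"beta"`, `"delta"`, `"eta"`.
#' @param values numeric vector of parameter values (each must satisfy the
#'   [eco_params()] constraints).
#' @param sampler a sampler closure, see [make_sampler()].
#' @param n_rounds invasion rounds per run.
#' @param params baseline [eco_params()]; one field is overridden per run.
#' @param seeds integer vector of seed replicates (default five).
#' @param engine `"iterative"` (fast, default) or `"ode"` (full dynamics).
#' @return a data frame with one row per (value, seed): columns `param`,
#'   `value`, `seed`, `D`, `D_over_beta`, `B_over_C`, `P_over_C`; attribute
#'   `summary` holds the per-value mean and standard error of the mean.
#' @export
parameter_sweep <- function(param_name = c("alpha", "beta", "delta", "eta"),
                            values, sampler, n_rounds, params = eco_params(),
                            seeds = 1:5, engine = c("iterative", "ode")) {
  param_name <- match.arg(param_name)
  engine <- match.arg(engine)
  rows <- vector("list", length(values) * length(seeds))
  k <- 0
  for (v in values) {
    pr <- params
    pr[[param_name]] <- v
    validate_eco_params(pr)
    for (s in seeds) {
      rec <- if (engine == "iterative") {
        iterative_evolution(sampler, n_rounds, pr, seed = s)
      } else {
        evolve_open_ecosystem(sampler, n_rounds, pr, seed = s)
      }
      last <- rec[nrow(rec), ]
      k <- k + 1
      rows[[k]] <- data.frame(param = param_name, value = v, seed = s,
                              D = last$D, D_over_beta = last$D / pr$beta,
                              B_over_C = last$B / pr$C,
                              P_over_C = last$P / pr$C)
    }
  }
  out <- do.call(rbind, rows)
  agg <- aggregate(cbind(D, D_over_beta, B_over_C, P_over_C) ~ value, out,
                   function(x) c(mean = mean(x),
                                 se = sd(x) / sqrt(length(x))))
  attr(out, "summary") <- agg
  out
}

#' Bound and viability checks along an assembly record
#'
#' Evaluates, for every recorded round of an assembly run, whether the
#' burst-size diversity bound holds (using the recorded biomass-weighted
#' imperfection `S_omega`) and whether every survivor had positive
#' viability `f`.
#'
#' @param record an `assembly_record`.
#' @return data frame with per-round columns `round`, `D_over_beta`,
#'   `bound` (`NA` while empty or when `beta * S >= 1`), `bound_ok`, and
#'   `f_ok` (`f_min > 0`).
#' @export
assembly_checks <- function(record) {
  pr <- attr(record, "params")
  beta <- pr$beta
  S <- record$S_omega
  valid <- !is.na(S) & beta * S < 1
  bound <- ifelse(valid, (1 - S) / (1 - beta * S), NA_real_)
  # assembled communities can saturate the bound exactly, and survivor
  # viabilities can sit at the feasibility edge, so both checks carry a
  # small numerical slack relative to the root-finding tolerance
  data.frame(round = record$round,
             D_over_beta = record$D / beta,
             bound = bound,
             bound_ok = ifelse(valid,
                               record$D / beta <= bound * (1 + 1e-9) + 1e-12,
                               NA),
             f_ok = ifelse(record$D > 0, record$f_min > -1e-9, NA))
}
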