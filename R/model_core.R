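#' Bacterial strain parameters
#'
#' A table of per-strain parameters: the maximal growth rate `gamma` (per
#' unit time, kept in `[0, 1]` by the samplers) and the RM imperfection
#' `omega`, the probability that an unmethylated phage escapes restriction
#' and lyses the host. `omega = 0` is a perfect RM system, `omega = 1` no
#' defence at all.
#'
#' @param gamma numeric vector of maximal growth rates, `gamma >= 0`.
#' @param omega numeric vector of RM imperfections in `[0, 1]`, same length.
#' @return a `strain_params` data frame with columns `gamma` and `omega`.
#' @examples
#' strain_params(gamma = c(0.9, 0.4), omega = c(0.1, 0.001))
#' @export
strain_params <- function(gamma = numeric(0), omega = numeric(0)) {
  gamma <- as.numeric(gamma)
  omega <- as.numeric(omega)
  if (length(gamma) != length(omega)) {
    stop("`gamma` and `omega` must have the same length", call. = FALSE)
  }
  if (length(gamma) && (any(!is.finite(gamma)) || any(gamma < 0))) {
    stop("`gamma` must be finite and >= 0", call. = FALSE)
  }
  if (length(omega) && (any(!is.finite(omega)) || any(omega < 0) ||
                        any(omega > 1))) {
    stop("`omega` must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(gamma = gamma, omega = omega),
            class = c("strain_params", "data.frame"))
}

#' Shared ecosystem parameters
#'
#' Phage and environment constants, identical for all strains and phage
#' variants. Defaults place the model in the large-population,
#' phage-limited regime: carrying capacity `C = 1e8` individuals with
#' `eta * C = 1` so that time is measured in units of the maximal growth
#' rate scale, burst size `beta = 100`, phage decay and bacterial dilution
#' `delta = alpha = 0.1`, invasion interval `T = 1e4` (long enough for the
#' community to settle between invasions), and an extinction threshold of a
#' single individual.
#'
#' @param eta phage adsorption rate (per density per time), `> 0`.
#' @param beta burst size, phage progeny per lysis, `> 1`.
#' @param delta phage decay rate (per time), `> 0`.
#' @param alpha bacterial dilution/death rate (per time), `> 0`.
#' @param C carrying capacity (individuals), `> 0`.
#' @param T interval between strain invasions (time), `> 0`.
#' @param ext_threshold extinction density (individuals), `> 0`.
#' @return an `eco_params` list.
#' @examples
#' eco_params()              # the defaults
#' eco_params(beta = 50)     # a less fecund phage
#' @export
eco_params <- function(eta = 1e-8, beta = 100, delta = 0.1, alpha = 0.1,
                       C = 1e8, T = 1e4, ext_threshold = 1) {
  pr <- list(eta = as.numeric(eta), beta = as.numeric(beta),
             delta = as.numeric(delta), alpha = as.numeric(alpha),
             C = as.numeric(C), T = as.numeric(T),
             ext_threshold = as.numeric(ext_threshold))
  validate_eco_params(pr)
  structure(pr, class = "eco_params")
}

validate_eco_params <- function(pr) {
  num <- vapply(pr, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    stop("ecosystem parameters must be single finite numbers: ",
         paste(names(pr)[!num], collapse = ", "), call. = FALSE)
  }
  pos <- c("eta", "delta", "alpha", "C", "T", "ext_threshold")
  bad <- pos[vapply(pos, function(f) pr[[f]] <= 0, logical(1))]
  if (length(bad)) {
    stop("ecosystem parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (pr$beta <= 1) stop("`beta` must be > 1", call. = FALSE)
  invisible(pr)
}

#' Ecosystem state
#'
#' Paired density vectors for an ecosystem of `n` bacterial strains and the
#' `n` matching epigenetic phage variants (variant `i` is methylated so as
#' to evade the RM system of strain `i`), plus the current time.
#'
#' @param strains a [strain_params()] table with one row per strain.
#' @param b bacterial density vector (individuals), `>= 0`.
#' @param p phage variant density vector (individuals), `>= 0`, same
#'   length and order as `b`.
#' @param t current time.
#' @return an `ecosystem_state` list with fields `t`, `strains`, `b`, `p`.
#' @export
ecosystem_state <- function(strains, b, p, t = 0) {
  strains <- as_strain_params(strains)
  b <- as.numeric(b)
  p <- as.numeric(p)
  if (nrow(strains) != length(b) || length(b) != length(p)) {
    stop("`strains`, `b` and `p` must describe the same number of strains",
         call. = FALSE)
  }
  if ((length(b) && any(!is.finite(b) | b < 0)) ||
      (length(p) && any(!is.finite(p) | p < 0))) {
    stop("densities must be finite and >= 0", call. = FALSE)
  }
  structure(list(t = as.numeric(t), strains = strains, b = b, p = p),
            class = "ecosystem_state")
}

as_strain_params <- function(x) {
  if (inherits(x, "strain_params")) return(x)
  if (is.data.frame(x) && all(c("gamma", "omega") %in% names(x))) {
    return(strain_params(x$gamma, x$omega))
  }
  stop("expected a `strain_params` table (columns gamma, omega)",
       call. = FALSE)
}

#' Right-hand side of the dynamical equations
#'
#' Time derivatives of the bacterial and phage densities. Strain `i` grows
#' logistically at rate `gamma_i (1 - B/C)`, is lysed by its matched
#' (methylated) phage variant at rate `eta b_i p_i`, by all other variants
#' at the restriction-discounted rate `eta omega_i b_i (P - p_i)`, and is
#' diluted at rate `alpha`. Each successful lysis on host `i` releases
#' `beta` progeny methylated as variant `i`; free phage are lost by
#' adsorption (rate `eta B`) and decay (rate `delta`):
#'
#' \deqn{\dot b_i = \gamma_i b_i (1 - B/C) - \eta b_i p_i -
#'       \eta \omega_i b_i (P - p_i) - \alpha b_i}
#' \deqn{\dot p_i = \eta \beta b_i p_i + \eta \omega_i \beta b_i (P - p_i) -
#'       \eta p_i B - \delta p_i}
#'
#' with \eqn{B = \sum_i b_i} and \eqn{P = \sum_i p_i}.
#'
#' @param state an [ecosystem_state()].
#' @param params an [eco_params()].
#' @return list with numeric vectors `db` and `dp`.
#' @export
ode_rhs <- function(state, params) {
  b <- state$b
  p <- state$p
  if (length(b) != length(p) || length(b) != nrow(state$strains)) {
    stop("state vectors have mismatched dimensions", call. = FALSE)
  }
  g <- state$strains$gamma
  w <- state$strains$omega
  B <- sum(b)
  P <- sum(p)
  crowd <- 1 - B / params$C
  pm <- P - p
  db <- g * b * crowd - params$eta * b * p - params$eta * w * b * pm -
    params$alpha * b
  dp <- params$eta * params$beta * b * (p + w * pm) - params$eta * p * B -
    params$delta * p
  list(db = db, dp = dp)
}

#' Total bacterial and phage densities
#'
#' @param state an [ecosystem_state()].
#' @return named numeric vector `c(B = sum(b), P = sum(p))`.
#' @export
totals <- function(state) {
  c(B = sum(state$b), P = sum(state$p))
}

#' @export
print.ecosystem_state <- function(x, ...) {
  tot <- totals(x)
  cat(sprintf(
    "<ecosystem_state> t = %g, %d strain(s), B = %.4g, P = %.4g\n",
    x$t, length(x$b), tot[["B"]], tot[["P"]]))
  invisible(x)
}

#' @export
print.eco_params <- function(x, ...) {
  cat("<eco_params>\n")
  for (f in names(x)) cat(sprintf("  %-13s %g\n", f, x[[f]]))
  invisible(x)
}
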