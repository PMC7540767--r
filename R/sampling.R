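#' Samplers of strain parameters
#'
#' @description
#' Joint distributions of the growth rate `gamma` and RM imperfection
#' `omega` used to generate invading strains. All families share the same
#' marginal expectations, `E[gamma] = 0.5` and `E[log10 omega] = -2`, and
#' the same supports, `gamma` in `[0, 1]` and `omega` in `[1e-4, 1]`, so
#' that correlated and uncorrelated ecosystems are compared under identical
#' average cost and average defence strength.
#'
#' * `sample_uncorrelated()`: `gamma ~ U(0, 1)` and
#'   `log10(omega) ~ U(-4, 0)`, independent. Cost and efficacy unrelated.
#' * `sample_correlated_product()`: a growth-defence trade-off. A common
#'   uniform variate `u` sets the defence strength, `log10(omega) = -4u`,
#'   and scales the growth-rate draw: `gamma = mu(u) + (v - 1/2) * wid(u)`
#'   with `v ~ U(0, 1)`, conditional mean `mu(u) = 1/2 + k(1/2 - u)` and
#'   width `wid(u) = 1 - 2k|u - 1/2|`, where `k = steepness` in `[0, 1]`.
#'   Stronger RM systems (larger `u`, smaller `omega`) thus cost growth
#'   rate. The construction is exactly mean-symmetric, so both marginal
#'   expectations hold identically for every `k`, and the least-squares
#'   slope of `gamma` on `log10(omega)` is exactly `k/4`.
#' * `sample_steepness_scaled()`: the correlated-product family with
#'   `gamma` affinely contracted towards `1/2` so that the fitted slope
#'   matches `slope_target` (shallower trade-offs, i.e. cheaper RM
#'   systems) while `E[gamma]` stays `1/2` and the correlation structure
#'   is unchanged.
#' * `sample_truncated_bvn()`: `(gamma, log10 omega)` from a bivariate
#'   normal with means `(0.5, -2)`, standard deviations matching the
#'   uniform marginals (`1/sqrt(12)` and `4/sqrt(12)`), and correlation
#'   parameter `rho`, truncated to the box `[0,1] x [-4,0]`. The box is
#'   symmetric about the means, so truncation preserves them. `rho = 1`
#'   degenerates to the exact line `gamma = 1/2 + (log10(omega) + 2)/4`.
#'
#' @param n number of strains to draw.
#' @param seed optional RNG seed; the caller's RNG state is restored
#'   afterwards. With `seed = NULL` the ambient RNG stream is used (and
#'   advanced), which is how the assembly engines consume samplers.
#' @param steepness trade-off steepness `k` in `[0, 1]`; the default
#'   [default_steepness()] is the package's baseline strong trade-off.
#' @param slope_target desired least-squares slope of `gamma` on
#'   `log10(omega)`; must not exceed the unscaled slope `steepness/4`.
#' @param rho correlation parameter of the underlying normal, in `[0, 1]`.
#'   Note the achieved post-truncation Pearson correlation is attenuated
#'   by the truncation; [fit_slope()] reports the realised association.
#' @return a [strain_params()] table with `n` rows.
#' @seealso [fit_slope()], [make_sampler()]
#' @examples
#' s <- sample_correlated_product(5000, seed = 1)
#' fit_slope(s)   # close to steepness/4
#' @name samplers
NULL

#' Baseline trade-off steepness
#'
#' The default `steepness` of [sample_correlated_product()], the package's
#' baseline growth-defence trade-off. It is calibrated once so that the
#' baseline correlated ecosystem assembled over `1e5` invasion rounds at
#' the default [eco_params()] settles in the reference high-diversity
#' regime, with about twice as many coexisting strains as the phage burst
#' size. At this steepness the strongest RM systems (`omega = 1e-4`) cost
#' their carriers a few per cent of growth rate on average
#' (`E[gamma]` drops from `0.5 + k/2` to `0.5 - k/2`), the magnitude
#' competition experiments report for efficient RM systems.
#'
#' @return a single number, `0.03`.
#' @export
default_steepness <- function() 0.03

#' @rdname samplers
#' @export
sample_uncorrelated <- function(n, seed = NULL) {
  stopifnot(n >= 0)
  with_seed(seed, {
    gamma <- runif(n)
    omega <- 10^runif(n, -4, 0)
    strain_params(gamma, omega)
  })
}

#' @rdname samplers
#' @export
sample_correlated_product <- function(n, steepness = default_steepness(),
                                      seed = NULL) {
  stopifnot(n >= 0)
  if (!is.numeric(steepness) || length(steepness) != 1 ||
      steepness < 0 || steepness > 1) {
    stop("`steepness` must be a single number in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    u <- runif(n)
    v <- runif(n)
    mu <- 0.5 + steepness * (0.5 - u)
    wid <- 1 - 2 * steepness * abs(u - 0.5)
    gamma <- mu + (v - 0.5) * wid
    omega <- 10^(-4 * u)
    strain_params(gamma, omega)
  })
}

#' @rdname samplers
#' @export
sample_steepness_scaled <- function(n, slope_target,
                                    steepness = default_steepness(),
                                    seed = NULL) {
  base_slope <- steepness / 4
  if (!is.numeric(slope_target) || length(slope_target) != 1 ||
      slope_target < 0 || slope_target > base_slope * (1 + 1e-9)) {
    stop(sprintf(
      "`slope_target` must lie in [0, %g] (the unscaled slope steepness/4)",
      base_slope), call. = FALSE)
  }
  with_seed(seed, {
    s <- sample_correlated_product(n, steepness = steepness)
    shrink <- slope_target / base_slope
    strain_params(0.5 + shrink * (s$gamma - 0.5), s$omega)
  })
}

#' @rdname samplers
#' @export
sample_truncated_bvn <- function(n, rho, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1) {
    stop("`rho` must be a single number in [0, 1]", call. = FALSE)
  }
  sd_g <- 1 / sqrt(12)
  sd_w <- 4 / sqrt(12)
  with_seed(seed, {
    if (rho >= 1) {
      # degenerate covariance: all mass on the diagonal of the box
      lo <- pnorm(-4, mean = -2, sd = sd_w)
      hi <- pnorm(0, mean = -2, sd = sd_w)
      w <- qnorm(runif(n, lo, hi), mean = -2, sd = sd_w)
      return(strain_params(0.5 + (w + 2) / 4, 10^w))
    }
    g <- numeric(0)
    w <- numeric(0)
    while (length(g) < n) {
      m <- max(1000L, ceiling(2 * (n - length(g))))
      z1 <- rnorm(m)
      z2 <- rnorm(m)
      wi <- -2 + sd_w * z1
      gi <- 0.5 + sd_g * (rho * z1 + sqrt(1 - rho^2) * z2)
      ok <- wi >= -4 & wi <= 0 & gi >= 0 & gi <= 1
      g <- c(g, gi[ok])
      w <- c(w, wi[ok])
    }
    strain_params(g[seq_len(n)], 10^w[seq_len(n)])
  })
}

#' Least-squares slope of the growth-defence trade-off
#'
#' Ordinary least squares fit of `gamma = a * log10(omega) + b` over a set
#' of strains, the summary used to quantify the steepness of a joint
#' (gamma, omega) distribution. Positive `a` means stronger RM systems
#' (smaller omega) go with slower growth.
#'
#' @param strains a [strain_params()] table with at least two distinct
#'   `omega` values.
#' @return named numeric vector `c(a = slope, b = intercept)`.
#' @export
fit_slope <- function(strains) {
  strains <- as_strain_params(strains)
  if (nrow(strains) < 2) stop("need at least two strains", call. = FALSE)
  w <- log10(strains$omega)
  vw <- var(w)
  if (!is.finite(vw) || vw <= .Machine$double.eps) {
    stop("slope undefined: all `omega` values identical", call. = FALSE)
  }
  a <- cov(strains$gamma, w) / vw
  c(a = a, b = mean(strains$gamma) - a * mean(w))
}

#' Build a sampler closure for the assembly engines
#'
#' Returns a function `f(n)` drawing `n` strains from the requested family
#' using the ambient RNG stream, so an engine seeded once consumes a single
#' reproducible sequence of invaders.
#'
#' @param family one of `"uncorrelated"`, `"correlated_product"`,
#'   `"steepness_scaled"`, `"truncated_bvn"`.
#' @param steepness,slope_target,rho family-specific shape parameters; see
#'   [samplers].
#' @return a function of `n` returning a [strain_params()] table.
#' @examples
#' draw <- make_sampler("truncated_bvn", rho = 0.8)
#' set.seed(1); draw(3)
#' @export
make_sampler <- function(family = c("uncorrelated", "correlated_product",
                                    "steepness_scaled", "truncated_bvn"),
                         steepness = default_steepness(),
                         slope_target = NULL, rho = NULL) {
  family <- match.arg(family)
  switch(family,
    uncorrelated = function(n) sample_uncorrelated(n),
    correlated_product = function(n) {
      sample_correlated_product(n, steepness = steepness)
    },
    steepness_scaled = {
      if (is.null(slope_target)) {
        stop("family \"steepness_scaled\" requires `slope_target`",
             call. = FALSE)
      }
      force(slope_target)
      function(n) sample_steepness_scaled(n, slope_target = slope_target,
                                          steepness = steepness)
    },
    truncated_bvn = {
      if (is.null(rho)) {
        stop("family \"truncated_bvn\" requires `rho`", call. = FALSE)
      }
      force(rho)
      function(n) sample_truncated_bvn(n, rho = rho)
    }
  )
}
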