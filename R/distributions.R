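#' Distribution specification
#'
#' A tagged parametric distribution used as a probabilistic model input.
#' Five families are supported, matching the families used to express the
#' model's uncertain quantities:
#'
#' * `dirichlet` — `params` are pseudo-counts, one per category (all > 0);
#' * `beta` — `params` are the two shape parameters;
#' * `lognormal` — `params` are the mean and standard deviation on the
#'   natural-log scale;
#' * `normal` — `params` are the mean and standard deviation;
#' * `deterministic` — `params` is a single fixed value.
#'
#' An optional closed `truncation` interval clamps draws after sampling;
#' it is used, for example, to keep a lognormal risk ratio usable as a
#' probability (upper bound 1) and to keep durations and QALY decrements
#' non-negative.
#'
#' @param family One of `"dirichlet"`, `"beta"`, `"lognormal"`, `"normal"`,
#'   `"deterministic"`.
#' @param params Numeric vector of parameters (see above).
#' @param truncation Optional length-2 numeric `c(lower, upper)` with
#'   `lower <= upper`; draws are clamped into this interval.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", c(217, 23))
#' dist_spec("lognormal", c(-0.25, 0.086), truncation = c(0, 1))
#' @export
dist_spec <- function(family = c("dirichlet", "beta", "lognormal", "normal",
                                 "deterministic"),
                      params, truncation = NULL) {
  family <- match.arg(family)
  params <- as.numeric(params)
  if (anyNA(params) || !all(is.finite(params))) {
    stop("dist_spec: 'params' must be finite and non-missing", call. = FALSE)
  }
  switch(family,
    dirichlet = {
      if (length(params) < 2 || any(params <= 0))
        stop("dirichlet pseudo-counts must be > 0 (length >= 2)", call. = FALSE)
    },
    beta = {
      if (length(params) != 2 || any(params <= 0))
        stop("beta requires two positive shape parameters", call. = FALSE)
    },
    lognormal = {
      if (length(params) != 2 || params[2] <= 0)
        stop("lognormal requires (mu, sigma) with sigma > 0", call. = FALSE)
    },
    normal = {
      if (length(params) != 2 || params[2] < 0)
        stop("normal requires (mean, sd) with sd >= 0", call. = FALSE)
    },
    deterministic = {
      if (length(params) != 1)
        stop("deterministic requires a single value", call. = FALSE)
    }
  )
  if (!is.null(truncation)) {
    truncation <- as.numeric(truncation)
    if (length(truncation) != 2 || anyNA(truncation) ||
        truncation[1] > truncation[2]) {
      stop("truncation must be c(lower, upper) with lower <= upper",
           call. = FALSE)
    }
  }
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)", x$family,
              paste(format(x$params, trim = TRUE), collapse = ", ")))
  if (!is.null(x$truncation)) {
    cat(sprintf(" truncated to [%g, %g]", x$truncation[1], x$truncation[2]))
  }
  cat("\n")
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Sample a Dirichlet matrix via normalised gamma variates
#'
#' @param n Number of draws.
#' @param alpha Pseudo-count vector.
#' @return `n x length(alpha)` matrix; rows sum to 1.
#' @keywords internal
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Draw samples from a distribution specification
#'
#' Sampling uses the current R random-number stream; callers control
#' reproducibility with [set.seed()]. Truncation, when present, clamps
#' the draws to the stated interval after sampling.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return For `dirichlet`, an `n x k` matrix whose rows sum to 1;
#'   otherwise a numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n = 1) {
  stopifnot(is_dist_spec(spec), n >= 1)
  x <- switch(spec$family,
    dirichlet = rdirichlet_mat(n, spec$params),
    beta = stats::rbeta(n, spec$params[1], spec$params[2]),
    lognormal = stats::rlnorm(n, spec$params[1], spec$params[2]),
    normal = stats::rnorm(n, spec$params[1], spec$params[2]),
    deterministic = rep(spec$params[1], n)
  )
  if (!is.null(spec$truncation)) {
    x <- pmin(pmax(x, spec$truncation[1]), spec$truncation[2])
  }
  x
}

#' Expected value of a distribution specification
#'
#' Returns the analytic mean of the untruncated distribution (Dirichlet:
#' the normalised pseudo-count vector; lognormal: `exp(mu + sigma^2/2)`),
#' clamped into the truncation interval when one is present. For the
#' truncation intervals used in this model the clamp is inactive or its
#' effect on the mean is negligible (tail mass below ~0.2%), so this
#' serves as the model's expected-value ("deterministic") input.
#'
#' @param spec A [dist_spec()].
#' @return Numeric scalar, or a probability vector for `dirichlet`.
#' @export
dist_mean <- function(spec) {
  stopifnot(is_dist_spec(spec))
  m <- switch(spec$family,
    dirichlet = spec$params / sum(spec$params),
    beta = spec$params[1] / sum(spec$params),
    lognormal = exp(spec$params[1] + spec$params[2]^2 / 2),
    normal = spec$params[1],
    deterministic = spec$params[1]
  )
  if (!is.null(spec$truncation) && spec$family != "dirichlet") {
    m <- min(max(m, spec$truncation[1]), spec$truncation[2])
  }
  m
}
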