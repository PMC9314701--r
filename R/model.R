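# The hierarchical log-normal SSD.
#
#   log10(LOEC_i) ~ Normal(mu_i, sigma)
#   mu_i = alpha + beta_size * x_size_i + beta_media * x_media_i
#                + beta_polymer * x_polymer_i + r_{j(i)}
#   r_j ~ Normal(0, sigma_ref)
#
# with noninformative priors: flat on alpha and each beta, flat on
# sigma > 0 and sigma_ref >= 0 (approximated by wide proper uniforms,
# see `prior_bounds` in sampler_config()). Candidate models differ only in
# which fixed-effect predictors enter; the reference-level random intercept
# is present in all of them.

#' Candidate model specifications
#'
#' A model specification selects which of the three fixed-effect predictors
#' -- log10 particle size, test medium, polymer type -- enter the SSD mean.
#' The reference-level random intercept is part of every candidate.
#'
#' @param size,media,polymer Logical flags: include the predictor?
#' @param label A specification label: `"null"` or a `+`-joined subset of
#'   `size`, `media`, `polymer` (e.g. `"size+media"`).
#' @return A `hssd_spec` object.
#' @export
#' @examples
#' hssd_spec(size = TRUE, media = TRUE)
#' parse_spec_label("size+media")
hssd_spec <- function(size = FALSE, media = FALSE, polymer = FALSE) {
  spec <- structure(
    list(use_size = isTRUE(size), use_media = isTRUE(media),
         use_polymer = isTRUE(polymer)),
    class = "hssd_spec"
  )
  spec$label <- spec_label(spec)
  spec
}

spec_label <- function(spec) {
  parts <- c("size", "media", "polymer")[c(spec$use_size, spec$use_media,
                                           spec$use_polymer)]
  if (length(parts) == 0) "null" else paste(parts, collapse = "+")
}

#' @rdname hssd_spec
#' @export
parse_spec_label <- function(label) {
  if (identical(label, "null")) return(hssd_spec())
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  bad <- setdiff(parts, c("size", "media", "polymer"))
  if (length(bad) > 0 || length(parts) == 0) {
    rlang::abort(paste0("unknown model label: ", label))
  }
  hssd_spec(size = "size" %in% parts, media = "media" %in% parts,
            polymer = "polymer" %in% parts)
}

#' @export
print.hssd_spec <- function(x, ...) {
  cat("<hssd_spec>", x$label, "\n")
  invisible(x)
}

#' Enumerate all candidate models
#'
#' All eight subsets of \{size, media, polymer\}, in a deterministic order
#' (by number of predictors, then size before media before polymer).
#'
#' @return A named list of eight [hssd_spec()] objects.
#' @export
#' @examples
#' names(enumerate_models())
enumerate_models <- function() {
  flags <- list(
    c(FALSE, FALSE, FALSE),
    c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
    c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE)
  )
  specs <- purrr::map(flags, ~ hssd_spec(.x[1], .x[2], .x[3]))
  stats::setNames(specs, purrr::map_chr(specs, "label"))
}

# number of fixed-effect coefficients (including the intercept)
n_fixed <- function(spec) 1L + spec$use_size + spec$use_media + spec$use_polymer

fixed_names <- function(spec) {
  c("alpha",
    if (spec$use_size) "beta_size",
    if (spec$use_media) "beta_media",
    if (spec$use_polymer) "beta_polymer")
}

# design matrix for the fixed effects of `spec`
design_matrix <- function(data, spec) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (spec$use_size) X <- cbind(X, x_size = data$x_size)
  if (spec$use_media) X <- cbind(X, x_media = data$x_media)
  if (spec$use_polymer) X <- cbind(X, x_polymer = data$x_polymer)
  colnames(X) <- fixed_names(spec)
  X
}

#' SSD mean function
#'
#' Evaluates the linear predictor `mu` for each observation: intercept plus
#' the included fixed-effect terms plus the reference-level intercept.
#' Predictors excluded by `spec` are ignored even if supplied.
#'
#' @param params Named list with `alpha`, any of `beta_size`, `beta_media`,
#'   `beta_polymer` required by `spec`, and `r`, a vector of reference
#'   intercepts (recycled from a scalar).
#' @param spec A [hssd_spec()].
#' @param x_size,x_media,x_polymer Predictor vectors (log10 um; 0/1; 0/1).
#' @param ref_index Integer vector mapping observations to references.
#' @return The vector of SSD means, log10 ug/L.
#' @export
#' @examples
#' mean_function(list(alpha = 3.20, beta_size = -0.21, beta_media = -0.95, r = 0),
#'               hssd_spec(size = TRUE, media = TRUE),
#'               x_size = -1, x_media = 1, ref_index = 1)
mean_function <- function(params, spec, x_size = NULL, x_media = NULL,
                          x_polymer = NULL, ref_index = 1L) {
  need <- function(name, x) {
    if (is.null(x)) rlang::abort(paste0("spec includes ", name, " but no predictor column was supplied"))
    if (is.null(params[[paste0("beta_", name)]])) {
      rlang::abort(paste0("spec includes ", name, " but params lacks beta_", name))
    }
    x
  }
  n <- max(length(x_size), length(x_media), length(x_polymer),
           length(ref_index), 1L)
  mu <- rep(params$alpha, n)
  if (spec$use_size) mu <- mu + params$beta_size * need("size", x_size)
  if (spec$use_media) mu <- mu + params$beta_media * need("media", x_media)
  if (spec$use_polymer) mu <- mu + params$beta_polymer * need("polymer", x_polymer)
  r <- params$r %||% 0
  if (length(r) == 1L) r <- rep(r, max(ref_index))
  mu + r[ref_index]
}

#' Pointwise log likelihood
#'
#' The log density of each observed log10 chronic LOEC under the normal SSD,
#' conditional on the reference intercepts in `params`.
#'
#' @inheritParams mean_function
#' @param data A `hssd_data` dataset (see [encode_predictors()]).
#' @return A numeric vector, one log density per observation.
#' @export
log_likelihood_pointwise <- function(params, spec, data) {
  if (is.null(params$sigma) || params$sigma <= 0) {
    rlang::abort("sigma must be positive")
  }
  mu <- mean_function(params, spec, data$x_size, data$x_media,
                      data$x_polymer, data$ref_index)
  stats::dnorm(data$y, mean = mu, sd = params$sigma, log = TRUE)
}

#' Log prior density
#'
#' Flat over the intercept and coefficients within `loc_bound`, flat over
#' `sigma` and `sigma_ref` on `(0, scale_bound]`, plus the Gaussian
#' hierarchy term `sum_j log Normal(r_j | 0, sigma_ref)`. Returns `-Inf`
#' outside the support. The flat parts contribute an arbitrary additive
#' constant (zero here).
#'
#' @inheritParams mean_function
#' @param bounds Named list with `loc_bound` and `scale_bound`; see
#'   [sampler_config()].
#' @return A scalar log density (up to a constant).
#' @export
log_prior <- function(params, spec,
                      bounds = list(loc_bound = 50, scale_bound = 50)) {
  loc <- unlist(params[fixed_names(spec)], use.names = FALSE)
  if (length(loc) < n_fixed(spec) || anyNA(loc)) {
    rlang::abort("params must supply alpha and every coefficient in spec")
  }
  if (any(abs(loc) > bounds$loc_bound)) return(-Inf)
  sigma <- params$sigma
  sigma_ref <- params$sigma_ref
  if (is.null(sigma) || sigma <= 0 || sigma > bounds$scale_bound) return(-Inf)
  if (is.null(sigma_ref) || sigma_ref < 0 || sigma_ref > bounds$scale_bound) {
    return(-Inf)
  }
  r <- params$r %||% numeric(0)
  if (sigma_ref == 0) {
    if (any(r != 0)) return(-Inf)
    return(0)
  }
  sum(stats::dnorm(r, 0, sigma_ref, log = TRUE))
}

#' Joint log posterior (up to a constant)
#'
#' Sum of the pointwise log likelihood and the log prior; used for testing
#' the sampler against independent evaluations.
#'
#' @inheritParams log_likelihood_pointwise
#' @inheritParams log_prior
#' @return A scalar.
#' @export
log_posterior <- function(params, spec, data,
                          bounds = list(loc_bound = 50, scale_bound = 50)) {
  lp <- log_prior(params, spec, bounds)
  if (!is.finite(lp)) return(lp)
  lp + sum(log_likelihood_pointwise(params, spec, data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
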