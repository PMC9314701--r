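# Posterior sampling via a blocked Gibbs sampler.
#
# Under flat priors every full conditional is available in closed form:
#   - fixed effects b | r, sigma^2      ~ Normal(b_hat, sigma^2 (X'X)^-1)
#   - reference intercepts r_j | ...    ~ Normal (precision-weighted)
#   - sigma^2 | b, r                    ~ Inv-Gamma((n-1)/2, SS/2)
#   - sigma_ref^2 | r                   ~ Inv-Gamma((J-1)/2, sum r^2 / 2)
# The Inv-Gamma shapes include the Jacobian of the flat-on-sigma prior.
# The wide uniform prior bounds are enforced by rejection; with the default
# bounds (+-50 on locations, (0, 50] on scales, log10 ug/L units) they are
# effectively never active on real toxicity data.

#' Sampler configuration
#'
#' `sampler_config()` defaults mirror the study design this model targets:
#' three chains, 20,000 burn-in iterations, 10,000 sampling iterations
#' thinned to every 10th draw, i.e. 1,000 retained draws per chain and
#' 3,000 in total, with convergence declared when every split-chain
#' Gelman--Rubin statistic is below 1.1. `sampler_config_fast()` is a
#' reduced profile (3 chains x 2,000/2,000, no thinning) for tests and
#' simulation studies.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param burnin Discarded iterations per chain.
#' @param draws Post-burn-in iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in draw; must divide `draws`.
#' @param seed Integer seed; identical seed, config and data give
#'   bit-identical draws.
#' @param rhat_threshold Warn when any parameter's split-chain R-hat is at
#'   or above this value.
#' @param loc_bound,scale_bound Half-width of the flat prior on location
#'   parameters, and upper bound of the flat prior on `sigma` and
#'   `sigma_ref` (log10 ug/L). Wide proper stand-ins for the improper flat
#'   priors.
#' @return A `hssd_sampler_config` list.
#' @export
#' @examples
#' sampler_config_fast(seed = 42)
sampler_config <- function(chains = 3, burnin = 20000, draws = 10000,
                           thin = 10, seed = 1, rhat_threshold = 1.1,
                           loc_bound = 50, scale_bound = 50) {
  if (chains < 1 || burnin < 0 || draws < 1 || thin < 1) {
    rlang::abort("chains, draws and thin must be positive; burnin non-negative")
  }
  if (draws %% thin != 0) rlang::abort("thin must divide draws evenly")
  structure(
    list(chains = as.integer(chains), burnin = as.integer(burnin),
         draws = as.integer(draws), thin = as.integer(thin),
         seed = as.integer(seed), rhat_threshold = rhat_threshold,
         loc_bound = loc_bound, scale_bound = scale_bound),
    class = "hssd_sampler_config"
  )
}

#' @rdname sampler_config
#' @export
sampler_config_fast <- function(seed = 1, ...) {
  sampler_config(chains = 3, burnin = 2000, draws = 2000, thin = 1,
                 seed = seed, ...)
}

#' Fit the hierarchical SSD model
#'
#' Draws posterior samples for one candidate model by blocked Gibbs
#' sampling (closed-form conditional updates for the fixed effects,
#' reference intercepts, and both variance parameters). Draws are retained
#' after burn-in and thinning; a warning is raised when any parameter's
#' split-chain R-hat reaches the configured threshold.
#'
#' @param data A `hssd_data` dataset (see [encode_predictors()] or
#'   [prepare_hssd_data()]).
#' @param spec A [hssd_spec()]; defaults to the size + media model.
#' @param config A [sampler_config()].
#' @param sigma_ref_fixed Optional: fix `sigma_ref` at this value instead of
#'   sampling it (0 collapses the model to a plain log-normal SSD
#'   regression; all reference intercepts are then 0).
#' @return A `hssd_fit` object: retained draws (iterations x chains x
#'   parameters), per-parameter split-chain R-hat, the spec, config and
#'   data. Methods: [tidy()][generics::tidy], [glance()][generics::glance],
#'   [posterior_summary()], [waic()], [hc5()].
#' @export
#' @examples
#' rec <- simulate_hssd_records(n_refs = 6, obs_per_ref = 4, seed = 7)
#' dat <- encode_predictors(rec)
#' fit <- fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
#'                 sampler_config(chains = 2, burnin = 200, draws = 200,
#'                                thin = 1, seed = 7))
#' posterior_summary(fit)
fit_hssd <- function(data, spec = hssd_spec(size = TRUE, media = TRUE),
                     config = sampler_config(), sigma_ref_fixed = NULL) {
  if (!inherits(data, "hssd_data")) {
    rlang::abort("data must be a hssd_data object (see encode_predictors())")
  }
  n <- nrow(data)
  if (n == 0) rlang::abort("empty dataset")
  if (!all(is.finite(data$y))) rlang::abort("non-finite response values")
  p <- n_fixed(spec)
  if (n < p + 2) rlang::abort("too few observations for the requested model")
  J <- n_refs(data)
  if (is.null(sigma_ref_fixed) && J < 2) {
    rlang::abort("sampling sigma_ref needs >= 2 references; use sigma_ref_fixed")
  }

  X <- design_matrix(data, spec)
  y <- data$y
  ref <- data$ref_index
  XtX <- crossprod(X)
  XtX_inv <- chol2inv(chol(XtX))
  L <- t(chol(XtX_inv)) # lower-triangular: b = b_hat + sigma * L %*% z
  n_j <- as.numeric(table(factor(ref, levels = seq_len(J))))

  n_keep <- config$draws %/% config$thin
  par_names <- c(fixed_names(spec), "sigma", "sigma_ref",
                 paste0("r[", seq_len(J), "]"))
  out <- array(NA_real_,
               dim = c(n_keep, config$chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))

  set.seed(config$seed)
  ols <- qr.solve(X, y)
  sd0 <- max(sd(y - drop(X %*% ols)), 0.1)

  for (ch in seq_len(config$chains)) {
    # overdispersed chain starts around the least-squares solution
    b <- ols + rnorm(p, 0, sd0)
    r <- rep(0, J)
    sigma2 <- (sd0 * exp(rnorm(1, 0, 0.3)))^2
    sref2 <- if (is.null(sigma_ref_fixed)) {
      (0.5 * sd0 * exp(rnorm(1, 0, 0.3)))^2
    } else {
      sigma_ref_fixed^2
    }
    keep_i <- 0L
    total <- config$burnin + config$draws
    for (it in seq_len(total)) {
      # fixed effects
      z <- y - r[ref]
      b_hat <- drop(XtX_inv %*% crossprod(X, z))
      repeat {
        b <- b_hat + sqrt(sigma2) * drop(L %*% rnorm(p))
        if (all(abs(b) <= config$loc_bound)) break
      }
      resid <- y - drop(X %*% b)
      # reference intercepts
      if (sref2 > 0) {
        s_j <- drop(rowsum(resid, ref, reorder = TRUE))
        prec <- n_j / sigma2 + 1 / sref2
        r <- s_j / sigma2 / prec + rnorm(J) / sqrt(prec)
      } else {
        r <- rep(0, J)
      }
      # residual variance
      SS <- sum((resid - r[ref])^2)
      repeat {
        sigma2 <- 1 / rgamma(1, shape = (n - 1) / 2, rate = SS / 2)
        if (sigma2 > 0 && sqrt(sigma2) <= config$scale_bound) break
      }
      # random-effect variance
      if (is.null(sigma_ref_fixed)) {
        repeat {
          sref2 <- 1 / rgamma(1, shape = (J - 1) / 2, rate = sum(r^2) / 2)
          if (sref2 > 0 && sqrt(sref2) <= config$scale_bound) break
        }
      }
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
        keep_i <- keep_i + 1L
        out[keep_i, ch, ] <- c(b, sqrt(sigma2), sqrt(sref2), r)
      }
    }
  }

  rhat <- apply(out, 3, gelman_rubin_matrix)
  fit <- structure(
    list(draws = out, spec = spec, config = config, data = data,
         rhat = rhat, sigma_ref_fixed = sigma_ref_fixed,
         param_names = par_names, n_refs = J),
    class = "hssd_fit"
  )
  bad <- rhat[is.finite(rhat) & rhat >= config$rhat_threshold]
  if (length(bad) > 0) {
    rlang::warn(sprintf(
      "convergence not assured: R-hat >= %.2f for %s",
      config$rhat_threshold, paste(names(bad), collapse = ", ")))
  }
  fit
}

#' @export
print.hssd_fit <- function(x, ...) {
  cat(sprintf(
    "<hssd_fit> model '%s': %d retained draws (%d chains), %d obs, %d refs\n",
    x$spec$label, prod(dim(x$draws)[1:2]), dim(x$draws)[2], nrow(x$data),
    x$n_refs))
  cat(sprintf("  max split R-hat: %.3f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

# all retained draws of one parameter as a (draw x chain) matrix
param_matrix <- function(fit, name) fit$draws[, , name, drop = TRUE]

# draws pooled across chains, as a vector (chain-major order)
param_vector <- function(fit, name) {
  as.vector(fit$draws[, , name])
}

#' Posterior draws in long format
#'
#' @param fit A [fit_hssd()] result.
#' @return A tibble with columns `chain`, `draw`, `parameter`, `value`.
#' @export
posterior_draws <- function(fit) {
  d <- dim(fit$draws)
  tibble::tibble(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    draw = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(fit$param_names, each = d[1] * d[2]),
    value = as.vector(fit$draws)
  )
}

#' Gelman--Rubin convergence diagnostic (split chains)
#'
#' The potential scale reduction factor computed after splitting each chain
#' in half, so within-chain drift also registers as disagreement:
#' `R-hat = sqrt(((m-1)/m * W + B/m) / W)` with `m` the split-chain length,
#' `W` the mean within-chain variance and `B/m` the variance of the
#' split-chain means.
#'
#' @param draws A draws x chains numeric matrix (at least 2 chains and 4
#'   draws per chain), or a list of equal-length chain vectors.
#' @return The scalar R-hat (>= 1 up to floating error; `NA` for constant
#'   draws).
#' @export
#' @examples
#' gelman_rubin(cbind(rnorm(100), rnorm(100)))
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) {
    rlang::abort("R-hat needs >= 2 chains; run a multi-chain configuration")
  }
  if (nrow(draws) < 4) rlang::abort("R-hat needs >= 4 draws per chain")
  gelman_rubin_matrix(draws)
}

gelman_rubin_matrix <- function(draws) {
  draws <- as.matrix(draws)
  half <- nrow(draws) %/% 2
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[half + seq_len(half), , drop = FALSE])
  m <- nrow(split)
  W <- mean(apply(split, 2, var))
  B_over_m <- var(colMeans(split))
  if (W == 0) return(if (B_over_m == 0) NA_real_ else Inf)
  sqrt(((m - 1) / m * W + B_over_m) / W)
}

#' Posterior summary table
#'
#' Medians and central 95% credible intervals (2.5th and 97.5th
#' percentiles, linear interpolation between order statistics) for each
#' parameter, pooling draws across chains.
#'
#' @param fit A [fit_hssd()] result.
#' @param include_ranef Include the reference intercepts `r[j]`?
#' @param probs Lower and upper interval probabilities.
#' @return A tibble: `parameter`, `median`, `ci_low`, `ci_high`, `rhat`.
#' @export
posterior_summary <- function(fit, include_ranef = FALSE,
                              probs = c(0.025, 0.975)) {
  keep <- fit$param_names
  if (!include_ranef) keep <- keep[!startsWith(keep, "r[")]
  purrr::map_dfr(keep, function(p) {
    x <- param_vector(fit, p)
    q <- quantile(x, c(probs[1], 0.5, probs[2]), names = FALSE, type = 7)
    tibble::tibble(parameter = p, median = q[2], ci_low = q[1],
                   ci_high = q[3], rhat = unname(fit$rhat[p]))
  })
}

#' Tidy a fitted hierarchical SSD
#'
#' `tidy()` returns one row per parameter with the posterior median and 95%
#' credible interval; `glance()` returns a one-row model summary.
#'
#' @param x A `hssd_fit` object.
#' @param include_ranef Include the reference intercepts?
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hssd_fit
#' @export
tidy.hssd_fit <- function(x, include_ranef = FALSE, ...) {
  posterior_summary(x, include_ranef = include_ranef) |>
    dplyr::transmute(term = .data$parameter, estimate = .data$median,
                     conf.low = .data$ci_low, conf.high = .data$ci_high,
                     rhat = .data$rhat)
}

#' @rdname tidy.hssd_fit
#' @method glance hssd_fit
#' @export
glance.hssd_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$label,
    n_obs = nrow(x$data),
    n_refs = x$n_refs,
    n_chains = dim(x$draws)[2],
    n_draws = prod(dim(x$draws)[1:2]),
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = max(x$rhat, na.rm = TRUE) < x$config$rhat_threshold
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
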