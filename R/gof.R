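# Dirichlet-multinomial goodness of fit with parametric-bootstrap LRT.
#
# Replicate-to-replicate variation in mock-community read counts exceeds
# multinomial sampling noise (overdispersion). The Dirichlet-multinomial
# (DM) is the standard exchangeable overdispersion model for multivariate
# counts: per-replicate proportions are Dirichlet(theta * pi), counts are
# multinomial given the proportions. theta > 0 is a concentration: as
# theta -> Inf the DM collapses to the multinomial. The model sits behind
# the overdispersed_model() interface so an alternative density could be
# swapped in without touching the test machinery.

THETA_BOUNDS <- c(1e-2, 1e8)  # 1e8 = declared "effectively multinomial" ceiling

#' Overdispersed count model
#'
#' @param proportions mean composition pi (named proportion vector).
#' @param theta concentration parameter (> 0); larger values mean less
#'   overdispersion, `1e8` is treated as effectively multinomial.
#' @return an `overdispersed_model` object.
#' @export
overdispersed_model <- function(proportions, theta) {
  validate_proportions(proportions, "model proportions")
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) ||
      theta <= 0) {
    stop("theta must be a single positive number")
  }
  structure(list(proportions = proportions, theta = theta),
            class = "overdispersed_model")
}

# Core DM log-likelihood on a raw counts matrix (taxa x replicates).
# Includes the multinomial coefficient so values are comparable with
# dmultinom(). pi_i = 0 with positive counts gives -Inf by contract.
dm_loglik_mat <- function(x, pi, theta) {
  n_rep <- ncol(x)
  totals <- colSums(x)
  alpha <- theta * pi
  pos <- alpha > 0
  if (any(x[!pos, , drop = FALSE] > 0)) return(-Inf)
  xp <- x[pos, , drop = FALSE]
  ap <- alpha[pos]
  sum(lgamma(totals + 1)) - sum(lgamma(x + 1)) +
    n_rep * lgamma(theta) - sum(lgamma(totals + theta)) +
    sum(lgamma(xp + ap)) - n_rep * sum(lgamma(ap))
}

#' Dirichlet-multinomial log-likelihood of a count table
#'
#' Sums the DM log-pmf over replicate columns. For two taxa this is the
#' beta-binomial with shape parameters `theta * pi`. As `theta` grows the
#' value approaches the multinomial log-likelihood.
#'
#' @param table a [count_table()] (or bare counts matrix).
#' @param model an [overdispersed_model()].
#' @return a single finite number, or `-Inf` when a taxon with zero model
#'   proportion has positive counts.
#' @export
dm_log_likelihood <- function(table, model) {
  stopifnot(inherits(model, "overdispersed_model"))
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (nrow(x) != length(model$proportions)) {
    stop("count table and model have different numbers of taxa")
  }
  dm_loglik_mat(x, model$proportions, model$theta)
}

# Profile out theta for fixed pi by 1-D optimization on the log scale.
optimize_theta <- function(x, pi, bounds = THETA_BOUNDS, tol = 1e-7) {
  f <- function(lt) dm_loglik_mat(x, pi, exp(lt))
  lb <- log(bounds)
  opt <- optimize(f, lb, maximum = TRUE, tol = tol)
  ll_lo <- f(lb[1])
  ll_hi <- f(lb[2])
  theta <- exp(opt$maximum)
  ll <- opt$objective
  at_bound <- NA_character_
  # optimize() never returns the interval ends; promote to a bound when the
  # boundary value is at least as good (monotone profile likelihood). The
  # tolerance absorbs lgamma round-off at huge theta.
  tol_b <- 1e-6 * max(1, abs(ll))
  if (ll_hi >= ll - tol_b && ll_hi >= ll_lo) {
    theta <- bounds[2]; ll <- ll_hi; at_bound <- "upper"
  } else if (ll_lo >= ll - tol_b) {
    theta <- bounds[1]; ll <- ll_lo; at_bound <- "lower"
  }
  list(theta = theta, loglik = ll, at_bound = at_bound)
}

#' Fit the null model (composition fixed at expectation)
#'
#' Under the null hypothesis the mean composition equals the expected
#' proportions; only the concentration `theta` is estimated, by direct
#' 1-D maximization of the DM log-likelihood over `log(theta)` on
#' `[1e-2, 1e8]`.
#'
#' @param table a [count_table()].
#' @param expected expected proportions from [expected_proportions()].
#' @param theta_bounds search interval for theta.
#' @param tol optimizer tolerance on the `log(theta)` scale.
#' @return an [overdispersed_model()] with extra fields `loglik`,
#'   `theta_at_bound`, `theta_bounds`, `tol`.
#' @export
fit_null <- function(table, expected, theta_bounds = THETA_BOUNDS,
                     tol = 1e-7) {
  stopifnot(inherits(table, "count_table"))
  validate_proportions(expected, "expected proportions")
  x <- table$counts
  if (nrow(x) != length(expected)) {
    stop("count table and expected proportions have different lengths")
  }
  opt <- optimize_theta(x, expected, theta_bounds, tol)
  m <- overdispersed_model(expected, opt$theta)
  m$loglik <- opt$loglik
  m$theta_at_bound <- opt$at_bound
  m$theta_bounds <- theta_bounds
  m$tol <- tol
  m$converged <- TRUE
  m
}

# One sweep of the fixed-point update for DM shape parameters alpha
# (Minka-type bound optimization; monotone in the likelihood). Taxa whose
# alpha has collapsed to 0 (all-zero counts) stay at 0.
dm_alpha_update <- function(x, alpha) {
  n_rep <- ncol(x)
  totals <- colSums(x)
  A <- sum(alpha)
  denom <- sum(digamma(totals + A)) - n_rep * digamma(A)
  pos <- alpha > 0
  num <- numeric(length(alpha))
  ap <- alpha[pos]
  num[pos] <- rowSums(digamma(x[pos, , drop = FALSE] + ap)) -
    n_rep * digamma(ap)
  alpha_new <- alpha
  alpha_new[pos] <- ap * num[pos] / denom
  alpha_new
}

#' Fit the alternative model (free composition and concentration)
#'
#' Joint maximum-likelihood estimation of (pi, theta). With `theta` free
#' the DM shape vector `alpha = theta * pi` is optimized by a monotone
#' fixed-point iteration (initialized at the pooled proportions with a
#' profiled theta) until the log-likelihood changes by less than `tol` or
#' `max_iter` sweeps. Taxa with all-zero counts get `pi = 0`. When the
#' data show no detectable overdispersion `theta` is capped at the upper
#' bound and the fit is refreshed there. With `theta` supplied and held
#' fixed, the composition is optimized directly over softmax logits.
#'
#' @param table a [count_table()].
#' @param theta optional fixed concentration; `NULL` (default) estimates it.
#' @param max_iter maximum fixed-point sweeps.
#' @param tol convergence tolerance on the log-likelihood.
#' @param theta_bounds allowed range for the estimated theta.
#' @return an [overdispersed_model()] with fields `loglik`, `converged`,
#'   `iterations`, `theta_at_bound`.
#' @export
fit_alternative <- function(table, theta = NULL, max_iter = 500, tol = 1e-8,
                            theta_bounds = THETA_BOUNDS) {
  stopifnot(inherits(table, "count_table"))
  x <- table$counts
  p0 <- grand_proportions(table)

  if (!is.null(theta)) {
    # composition-only optimization at fixed concentration
    keep <- rowSums(x) > 0
    z0 <- log(pmax(p0[keep], 1e-12))
    nll <- function(z) {
      pi <- numeric(length(p0))
      w <- exp(z - max(z))
      pi[keep] <- w / sum(w)
      -dm_loglik_mat(x, pi, theta)
    }
    opt <- optim(z0, nll, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12))
    pi <- numeric(length(p0))
    w <- exp(opt$par - max(opt$par))
    pi[keep] <- w / sum(w)
    names(pi) <- names(p0)
    m <- overdispersed_model(pi, theta)
    m$loglik <- -opt$value
    m$converged <- opt$convergence == 0
    m$iterations <- NA_integer_
    m$theta_at_bound <- NA_character_
    if (!m$converged) warning("fit_alternative: composition optimizer did not converge")
    return(m)
  }

  th0 <- optimize_theta(x, p0, theta_bounds)
  alpha <- min(th0$theta, theta_bounds[2]) * p0
  ll <- dm_loglik_mat(x, alpha / sum(alpha), sum(alpha))
  converged <- FALSE
  iter <- 0
  at_bound <- NA_character_
  while (iter < max_iter) {
    iter <- iter + 1
    alpha <- dm_alpha_update(x, alpha)
    A <- sum(alpha)
    if (!is.finite(A) || A <= 0) {
      stop("fit_alternative: degenerate alpha update")
    }
    # the fixed point converges slowly along the overall-concentration
    # direction; a periodic 1-D profile step over theta fixes that
    if (iter %% 20 == 0 && A < theta_bounds[2]) {
      th <- optimize_theta(x, alpha / A, theta_bounds)
      alpha <- alpha * (th$theta / A)
      A <- th$theta
    }
    if (A >= theta_bounds[2]) {
      alpha <- alpha * (theta_bounds[2] / sum(alpha))
      at_bound <- "upper"
      ll <- dm_loglik_mat(x, alpha / sum(alpha), sum(alpha))
      converged <- TRUE
      break
    }
    ll_new <- dm_loglik_mat(x, alpha / A, A)
    if (abs(ll_new - ll) < tol && iter %% 20 != 0) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  pi <- alpha / sum(alpha)
  names(pi) <- rownames(x)
  m <- overdispersed_model(pi, sum(alpha))
  m$loglik <- ll
  m$converged <- converged
  m$iterations <- iter
  m$theta_at_bound <- at_bound
  if (!converged) {
    warning("fit_alternative did not converge in ", max_iter, " iterations; ",
            "returning best-found estimate")
  }
  m
}

# Simulate a DM count matrix: per-replicate Dirichlet(theta*pi) proportions,
# then multinomial draws at the given depths. Shared with simulate_counts().
rdm_counts <- function(depths, pi, theta) {
  k <- length(pi)
  out <- matrix(0, k, length(depths))
  alpha <- theta * pi
  for (j in seq_along(depths)) {
    g <- rgamma(k, shape = alpha)
    if (sum(g) == 0) g[which.max(alpha)] <- 1  # numerical underflow guard
    out[, j] <- rmultinom(1, depths[j], g / sum(g))
  }
  rownames(out) <- names(pi)
  out
}

#' Likelihood-ratio goodness-of-fit test with parametric bootstrap
#'
#' Tests whether observed count compositions are consistent with the
#' expected proportions. The statistic is
#' `Lambda = 2 * (loglik_alt - loglik_null)` (clipped at zero), comparing
#' the free Dirichlet-multinomial fit against the fit with composition
#' pinned at expectation. Because the null distribution of `Lambda` is not
#' chi-squared at small replicate numbers, it is estimated by parametric
#' bootstrap: `n_bootstrap` datasets are simulated from the fitted null
#' (same depths, DM with `pi = expected`, `theta = theta_null`), both
#' models are refitted on each, and
#' `p = (1 + #\{Lambda* >= Lambda\}) / (B + 1)` — never exactly zero.
#'
#' One parent seed deterministically spawns a sub-seed per bootstrap
#' dataset, so results are reproducible and independent of execution
#' order.
#'
#' @param table a [count_table()].
#' @param expected expected proportions.
#' @param n_bootstrap number of bootstrap datasets B (>= 99 recommended).
#' @param seed integer seed (required; recorded in the result).
#' @param theta_bounds concentration search range passed to the fitters.
#' @return a `gof_result` list: `lrt_stat`, `p_value`, `theta_null`,
#'   `theta_alt`, `pi_alt`, `n_bootstrap`, `seed`, `bootstrap_stats`,
#'   `loglik_null`, `loglik_alt`.
#' @export
lrt_gof <- function(table, expected, n_bootstrap = 999, seed,
                    theta_bounds = THETA_BOUNDS) {
  stopifnot(inherits(table, "count_table"))
  validate_proportions(expected, "expected proportions")
  if (missing(seed)) stop("seed is required for a reproducible bootstrap")
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  x <- table$counts
  if (any(expected == 0 & rowSums(x) > 0)) {
    stop("expected proportion is zero for a taxon with positive counts; ",
         "the community definition does not match the count table")
  }

  null_fit <- fit_null(table, expected, theta_bounds)
  alt_fit <- fit_alternative(table, theta_bounds = theta_bounds)
  lambda <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (lambda < 0) {
    if (lambda < -1e-6) {
      warning("negative LRT statistic (", format(lambda),
              ") clipped to 0; alternative fit may be at a local optimum")
    }
    lambda <- 0
  }

  depths <- colSums(x)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_bootstrap)
  boot <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    set.seed(sub_seeds[b])
    xb <- rdm_counts(depths, expected, null_fit$theta)
    tb <- count_table(xb)
    nb <- fit_null(tb, expected, theta_bounds)
    ab <- fit_alternative(tb, theta_bounds = theta_bounds)
    boot[b] <- max(0, 2 * (ab$loglik - nb$loglik))
  }
  p <- (1 + sum(boot >= lambda)) / (n_bootstrap + 1)

  structure(list(lrt_stat = lambda,
                 p_value = p,
                 theta_null = null_fit$theta,
                 theta_alt = alt_fit$theta,
                 pi_alt = alt_fit$proportions,
                 n_bootstrap = n_bootstrap,
                 seed = seed,
                 bootstrap_stats = boot,
                 loglik_null = null_fit$loglik,
                 loglik_alt = alt_fit$loglik),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Dirichlet-multinomial goodness-of-fit (parametric bootstrap LRT)\n")
  cat(sprintf("  LRT statistic : %.4f\n", x$lrt_stat))
  cat(sprintf("  p-value       : %.4g  (B = %d, seed = %d)\n",
              x$p_value, x$n_bootstrap, x$seed))
  cat(sprintf("  theta (null)  : %.4g\n", x$theta_null))
  cat(sprintf("  theta (alt)   : %.4g\n", x$theta_alt))
  invisible(x)
}

#' Serialize a goodness-of-fit result to JSON
#'
#' @param result a `gof_result` from [lrt_gof()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gof_result <- function(result, path) {
  stopifnot(inherits(result, "gof_result"))
  obj <- unclass(result)
  obj$pi_alt <- as.list(obj$pi_alt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
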