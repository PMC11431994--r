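# Huber M-estimation robust regression of component scores on environmental
# covariates.

#' Robust MAD residual scale
#'
#' `1.4826 * median(|r - median(r)|)` (consistent for the Gaussian SD);
#' falls back to the mean absolute deviation about the median when the MAD
#' is exactly zero. Returns 0 for a constant vector.
#'
#' @param residuals nonempty numeric vector.
#' @return Nonnegative scale estimate.
#' @export
mad_scale <- function(residuals) {
  stopifnot(length(residuals) > 0)
  med <- median(residuals)
  m <- median(abs(residuals - med))
  if (m > 0) return(1.4826 * m)
  mean(abs(residuals - med))
}

#' Huber robust regression by IRLS
#'
#' Iteratively reweighted least squares with Huber weights
#' `w_i = min(1, c * s / |r_i|)` and the scale `s` re-estimated by
#' [mad_scale()] at each iteration; converges when the largest coefficient
#' change falls below `tol`. Standard errors use the standard M-estimation
#' asymptotic covariance (Huber's correction factor on the weighted
#' least-squares covariance).
#'
#' @param X n x p design matrix (include the intercept column).
#' @param y response vector.
#' @param c Huber tuning constant (1.345 gives 95% Gaussian efficiency).
#' @param tol convergence tolerance on coefficients.
#' @param max_iter maximum IRLS iterations.
#' @return An object of class `robust_fit`: `coefficients`, `std_errors`,
#'   `t_values`, `scale`, `n_iter`, `converged`, `weights`, `residuals`.
#' @export
huber_irls <- function(X, y, c = 1.345, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  beta <- qr.solve(X, y)
  s <- mad_scale(y - X %*% beta)
  n_iter <- 0L
  converged <- FALSE
  w <- rep(1, n)
  repeat {
    n_iter <- n_iter + 1L
    r <- as.numeric(y - X %*% beta)
    s <- mad_scale(r)
    if (s <= .Machine$double.eps^0.5 * max(1, mean(abs(y)))) {
      # (near-)exact fit: zero-residual fixed point
      converged <- TRUE
      w <- rep(1, n)
      break
    }
    w <- pmin(1, c * s / abs(r))
    w[abs(r) < 1e-300] <- 1
    wX <- X * w
    beta_new <- solve(crossprod(wX, X), crossprod(wX, y))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  r <- as.numeric(y - X %*% beta)
  if (s > 0) {
    u <- r / s
    psi <- s * pmin(pmax(u, -c), c)        # Huber psi on the raw scale
    psi_prime <- as.numeric(abs(u) <= c)
    m1 <- mean(psi_prime)
    kappa <- 1 + p / n * var(psi_prime) / m1^2   # Huber (1981) correction
    sigma2 <- kappa^2 * sum(psi^2) / (n - p) / m1^2
    covm <- sigma2 * solve(crossprod(X))
    se <- sqrt(diag(covm))
  } else {
    se <- rep(0, p)
  }
  coef <- as.numeric(beta)
  names(coef) <- colnames(X)
  structure(list(coefficients = coef,
                 std_errors = setNames(se, colnames(X)),
                 t_values = setNames(ifelse(se > 0, coef / se, 0),
                                     colnames(X)),
                 scale = s,
                 n_iter = n_iter,
                 converged = converged,
                 weights = w,
                 residuals = r,
                 tuning_c = c),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("Huber robust fit (c =", x$tuning_c, ", scale =",
      format(x$scale, digits = 5), ",", x$n_iter, "iterations",
      if (!x$converged) "- NOT converged" else "", ")\n")
  print(data.frame(estimate = x$coefficients,
                   std_error = x$std_errors,
                   t_value = x$t_values))
  invisible(x)
}

#' Regress component scores on environmental covariates
#'
#' One Huber robust fit per retained component of a caste's morphospace
#' model, on the design (intercept, annual mean temperature, annual mean
#' precipitation, relative humidity, elevation), covariates untransformed.
#' By default every worker is a regression unit (its site's covariates
#' repeated within site); `unit = "site"` aggregates scores to site means
#' first, avoiding pseudoreplication.
#'
#' @param model a `morphospace_model`.
#' @param sites a `site_table`.
#' @param unit `"worker"` (default) or `"site"`.
#' @param c Huber tuning constant.
#' @return List of `robust_fit`, one per component, plus a tidy `table`
#'   (component, term, estimate, std_error, t_value).
#' @export
fit_pc_environment <- function(model, sites, unit = c("worker", "site"),
                               c = 1.345) {
  unit <- match.arg(unit)
  idx <- match(model$site_id, sites$site_id)
  if (anyNA(idx))
    stop("scores reference site(s) missing from the site table: ",
         paste(unique(model$site_id[is.na(idx)]), collapse = ", "))
  env_cols <- c("temp_mean", "precip_mean", "rel_humidity", "elevation")
  env <- as.matrix(as.data.frame(sites)[idx, env_cols])
  scores <- model$scores
  if (unit == "site") {
    site_f <- factor(model$site_id, levels = unique(model$site_id))
    scores <- apply(scores, 2L, function(v) tapply(v, site_f, mean))
    env <- env[match(levels(site_f), model$site_id), , drop = FALSE]
  }
  X <- cbind(intercept = 1, env)
  fits <- lapply(seq_len(model$n_pcs), function(k)
    huber_irls(X, scores[, k], c = c))
  names(fits) <- paste0("PC", seq_len(model$n_pcs))
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(component = nm,
               caste = model$caste,
               term = names(f$coefficients),
               estimate = as.numeric(f$coefficients),
               std_error = as.numeric(f$std_errors),
               t_value = as.numeric(f$t_values),
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, table = tab)
}
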