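# Rank-based inference: midranks, Mann-Whitney U (exact + normal),
# Scheirer-Ray-Hare two-way test on ranks, Bonferroni correction.

#' Midranks
#'
#' Ranks 1..n with ties assigned the mean of the ranks they cover.
#'
#' @param values finite numeric vector.
#' @return Rank vector; always sums to n(n+1)/2.
#' @export
midranks <- function(values) {
  stopifnot(all(is.finite(values)))
  rank(values, ties.method = "average")
}

# U statistic of x against y from joint midranks
u_statistic <- function(x, y) {
  n <- length(x)
  r <- midranks(c(x, y))
  sum(r[seq_len(n)]) - n * (n + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs with `x_i > y_j` (ties count 1/2). The exact p-value
#' enumerates all choose(n+m, n) group labelings of the observed values
#' (valid under ties, conditional on the observed midranks) and is used when
#' `n + m <= 16` or `mode = "exact"`; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `u` (min of the two one-sided statistics), `u_x`,
#'   `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n <- length(x); m <- length(y); N <- n + m
  u_x <- u_statistic(x, y)
  if (mode == "exact" || (mode == "auto" && N <= 16L)) {
    r <- midranks(c(x, y))
    offset <- n * (n + 1) / 2
    centre <- n * m / 2
    dev_obs <- abs(u_x - centre)
    us <- combn(N, n, FUN = function(ix) sum(r[ix])) - offset
    p <- mean(abs(us - centre) >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_x - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(u = min(u_x, n * m - u_x), u_x = u_x, p_value = p, method = method)
}

#' Scheirer-Ray-Hare two-way test on ranks
#'
#' All n values are midranked jointly, a two-way cell-means ANOVA
#' decomposition is computed on the ranks (unweighted means with the
#' harmonic mean cell size, so unbalanced designs are handled; for balanced
#' data this is the classical decomposition), and each effect's
#' `H = SS_effect / MS_total` is divided by the tie correction
#' `D = 1 - sum(t^3 - t) / (n^3 - n)` and referred to the chi-square
#' distribution at the effect's degrees of freedom.
#'
#' @param values numeric response.
#' @param factor_a,factor_b grouping labels (>= 2 levels each; every cell of
#'   the crossing must be nonempty).
#' @param bonferroni_m family size for the corrected p-values.
#' @return An object of class `srh_result`: per-effect df, rank-scale sum of
#'   squares, H, raw and Bonferroni-corrected p, plus `residual_df`, `n` and
#'   `tie_correction`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b,
                              bonferroni_m = 1L) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  a <- nlevels(fa); b <- nlevels(fb); n <- length(values)
  if (a < 2L || b < 2L) stop("both factors need at least 2 levels")
  tab <- table(fa, fb)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", levels(fa)[empty[1]], " x ", levels(fb)[empty[2]])
  }
  r <- midranks(values)

  cell_means <- tapply(r, list(fa, fb), mean)
  grand <- mean(cell_means)
  a_means <- rowMeans(cell_means)
  b_means <- colMeans(cell_means)
  n_h <- 1 / mean(1 / tab)  # harmonic mean cell size
  ss_a <- n_h * b * sum((a_means - grand)^2)
  ss_b <- n_h * a * sum((b_means - grand)^2)
  dev_ab <- cell_means - outer(a_means, rep(1, b)) -
    outer(rep(1, a), b_means) + grand
  ss_ab <- n_h * sum(dev_ab^2)
  fitted <- cell_means[cbind(fa, fb)]
  ss_res <- sum((r - fitted)^2)
  ss_total <- sum((r - mean(r))^2)
  ms_total <- ss_total / (n - 1)

  ties <- table(r)
  D <- 1 - sum(ties^3 - ties) / (n^3 - n)

  df <- c(factor_a = a - 1L, factor_b = b - 1L,
          interaction = (a - 1L) * (b - 1L))
  ss <- c(factor_a = ss_a, factor_b = ss_b, interaction = ss_ab)
  H <- ss / ms_total / D
  p_raw <- pchisq(H, df, lower.tail = FALSE)
  p_corr <- vapply(seq_along(H),
                   function(i) srh_corrected_p(H[i], df[i], bonferroni_m),
                   numeric(1))
  effects <- data.frame(effect = names(df),
                        df = as.integer(df),
                        sum_sq = as.numeric(ss),
                        H = as.numeric(H),
                        p_raw = as.numeric(p_raw),
                        p_corrected = as.numeric(p_corr),
                        stringsAsFactors = FALSE)
  structure(list(effects = effects,
                 residual_ss = ss_res,
                 residual_df = n - a * b,
                 n = n,
                 ss_total = ss_total,
                 tie_correction = D,
                 bonferroni_m = as.integer(bonferroni_m)),
            class = "srh_result")
}

#' @export
print.srh_result <- function(x, ...) {
  cat("Scheirer-Ray-Hare test (n =", x$n, ", tie correction D =",
      format(x$tie_correction, digits = 6), ")\n")
  print(x$effects, row.names = FALSE)
  cat("residual df:", x$residual_df, "\n")
  invisible(x)
}

#' Bonferroni-corrected chi-square p-value for an H statistic
#'
#' `min(1, m * P(chi^2_df >= H))`.
#'
#' @param H rank-test statistic (>= 0).
#' @param df degrees of freedom.
#' @param m Bonferroni family size.
#' @return Corrected p-value in `[0, 1]`.
#' @export
srh_corrected_p <- function(H, df, m) {
  stopifnot(H >= 0, df >= 1, m >= 1)
  min(1, m * pchisq(H, df, lower.tail = FALSE))
}

#' Advisory distributional diagnostics for a two-way layout
#'
#' Rank tests need no normality gate; this reports descriptive indicators
#' only: per-cell skewness range and the max/min cell-SD ratio (a
#' Levene-style dispersion heterogeneity indicator).
#'
#' @inheritParams scheirer_ray_hare
#' @return List with `skewness_range` and `sd_ratio`.
#' @export
rank_test_diagnostics <- function(values, factor_a, factor_b) {
  cell <- interaction(factor_a, factor_b, drop = TRUE)
  skew <- tapply(values, cell, function(v) {
    if (length(v) < 3L || sd(v) == 0) return(NA_real_)
    mean(((v - mean(v)) / sd(v))^3)
  })
  sds <- tapply(values, cell, sd)
  sds <- sds[is.finite(sds) & sds > 0]
  list(skewness_range = range(skew, na.rm = TRUE),
       sd_ratio = if (length(sds)) max(sds) / min(sds) else NA_real_)
}

#' Scheirer-Ray-Hare tests across retained components
#'
#' Runs the two-way rank test (climate zone x habitat) on each retained
#' component's scores for one caste, with Bonferroni correction over the
#' family of all effects x components.
#'
#' @param model a `morphospace_model`.
#' @param sites a `site_table`.
#' @param bonferroni_m family size (default 3 effects x n_pcs).
#' @param alpha significance threshold for the `significant` flag.
#' @return Tidy data frame: component, effect, df, sum_sq, H, p_raw,
#'   p_corrected, significant (at p < 0.001).
#' @export
srh_by_component <- function(model, sites,
                             bonferroni_m = 3L * model$n_pcs,
                             alpha = 0.001) {
  idx <- match(model$site_id, sites$site_id)
  if (anyNA(idx))
    stop("scores reference site(s) absent from the site table: ",
         paste(unique(model$site_id[is.na(idx)]), collapse = ", "))
  zone <- sites$climate_zone[idx]
  hab <- sites$habitat[idx]
  out <- lapply(seq_len(model$n_pcs), function(k) {
    res <- scheirer_ray_hare(model$scores[, k], zone, hab, bonferroni_m)
    cbind(component = paste0("PC", k), res$effects,
          residual_df = res$residual_df)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_corrected < alpha
  out$caste <- model$caste
  out
}
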