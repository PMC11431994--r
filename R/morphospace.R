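# Standardization, PCA on the correlation matrix, varimax rotation, scores.

#' Standardize the trait matrix of one caste
#'
#' Column-wise z-scores (sample SD, denominator n - 1) of the eight traits
#' for the requested caste. Castes are analyzed fully independently
#' throughout the package; no operation mixes them.
#'
#' @param traits a `trait_table`.
#' @param caste `"major"` or `"minor"`.
#' @return List with `x` (n x 8 standardized matrix), `trait_means`,
#'   `trait_sds`, and `rows` (indices of the caste's rows in `traits`).
#' @export
standardize_traits <- function(traits, caste = c("major", "minor")) {
  caste <- match.arg(caste)
  rows <- which(traits$caste == caste)
  if (length(rows) < 2L)
    stop("need at least 2 rows of caste '", caste, "' to standardize")
  x <- as.matrix(as.data.frame(traits)[rows, trait_names()])
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero))
    stop("zero-variance trait(s): ",
         paste(trait_names()[zero], collapse = ", "))
  list(x = sweep(sweep(x, 2L, mu, "-"), 2L, s, "/"),
       trait_means = mu, trait_sds = s, rows = rows)
}

# largest-|loading| entry of each column made positive, for reproducible
# output across linear-algebra backends
fix_loading_signs <- function(L) {
  flip <- apply(L, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(L, 2L, flip, "*")
}

#' Principal component analysis of standardized traits
#'
#' Eigendecomposition of the 8 x 8 correlation matrix (the covariance of the
#' standardized data). Loadings follow the sign convention that each
#' column's largest-magnitude entry is positive.
#'
#' @param std_matrix n x 8 standardized trait matrix.
#' @return List with `eigenvalues` (descending), `loadings_raw` (orthonormal
#'   columns) and `variance_explained_raw` (percent, sums to 100).
#' @export
fit_pca <- function(std_matrix) {
  n <- nrow(std_matrix)
  p <- ncol(std_matrix)
  if (n <= p)
    stop("need more rows than traits (n > ", p, ") for a full-rank PCA")
  R <- crossprod(std_matrix) / (n - 1)
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  L <- fix_loading_signs(e$vectors)
  dimnames(L) <- list(colnames(std_matrix), paste0("PC", seq_len(p)))
  list(eigenvalues = lam,
       loadings_raw = L,
       variance_explained_raw = 100 * lam / sum(lam))
}

# Kaiser-normalized varimax criterion: sum over columns of the variance of
# squared normalized loadings
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  W <- (L / h)^2
  p <- nrow(L)
  sum(colMeans(W^2) - colMeans(W)^2) * p
}

#' Varimax rotation of retained loadings
#'
#' Orthogonal varimax rotation with Kaiser row normalization (pairwise
#' rotation algorithm). For `k < 2` rotation is undefined and the input is
#' returned with `rotmat = 1`.
#'
#' @param loadings 8 x k loading matrix (first k principal axes).
#' @param tol convergence tolerance on the criterion increase.
#' @param max_iter maximum sweeps.
#' @return List with `rotated` (8 x k, sign-fixed), `rotmat` (k x k
#'   orthogonal, `rotated = loadings %*% rotmat`) and `criterion`.
#' @export
varimax_rotate <- function(loadings, tol = 1e-8, max_iter = 1000L) {
  k <- ncol(loadings)
  if (k < 2L)
    return(list(rotated = loadings, rotmat = matrix(1, 1L, 1L),
                criterion = varimax_criterion(loadings)))
  v <- stats::varimax(loadings, normalize = TRUE, eps = tol)
  rot <- loadings %*% v$rotmat
  flip <- apply(rot, 2L, function(z) sign(z[which.max(abs(z))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, "*")
  rotmat <- sweep(v$rotmat, 2L, flip, "*")
  colnames(rot) <- paste0("RC", seq_len(k))
  list(rotated = rot, rotmat = rotmat, criterion = varimax_criterion(rot))
}

#' Build the morphospace model of one caste
#'
#' Pipeline: standardize -> PCA on the correlation matrix -> retain the
#' first `n_pcs` axes -> varimax rotation -> scores. Scores are the
#' standardized data projected on the rotated loadings, aligned to the
#' caste's rows of `traits`. Rotated variance explained is computed from the
#' rotated-component score variances (out of total variance 8); its sum
#' equals the sum of the first `n_pcs` raw shares.
#'
#' @param traits a `trait_table`.
#' @param caste `"major"` or `"minor"`.
#' @param n_pcs number of retained components (default 4).
#' @return An object of class `morphospace_model`.
#' @export
build_morphospace <- function(traits, caste = c("major", "minor"),
                              n_pcs = 4L) {
  caste <- match.arg(caste)
  std <- standardize_traits(traits, caste)
  pca <- fit_pca(std$x)
  p <- ncol(std$x)
  n_pcs <- as.integer(n_pcs)
  stopifnot(n_pcs >= 1L, n_pcs <= p)
  L_k <- pca$loadings_raw[, seq_len(n_pcs), drop = FALSE]
  rot <- varimax_rotate(L_k)
  scores <- std$x %*% rot$rotated
  ve_rot <- 100 * apply(scores, 2L, var) / sum(pca$eigenvalues)
  structure(list(
    caste = caste,
    n_pcs = n_pcs,
    trait_means = std$trait_means,
    trait_sds = std$trait_sds,
    eigenvalues = pca$eigenvalues,
    loadings_raw = pca$loadings_raw,
    loadings_rotated = rot$rotated,
    rotmat = rot$rotmat,
    variance_explained_raw = pca$variance_explained_raw,
    variance_explained_rotated = ve_rot,
    scores = scores,
    rows = std$rows,
    site_id = traits$site_id[std$rows],
    colony_id = traits$colony_id[std$rows]
  ), class = "morphospace_model")
}

#' @export
print.morphospace_model <- function(x, ...) {
  cat("Morphospace model (", x$caste, " workers, n = ", nrow(x$scores),
      ")\n", sep = "")
  cat("  retained components:", x$n_pcs, "\n")
  cat(sprintf("  variance explained (raw PC1-%d): %s  [total %.2f%%]\n",
              x$n_pcs,
              paste(sprintf("%.2f%%",
                            x$variance_explained_raw[seq_len(x$n_pcs)]),
                    collapse = " "),
              sum(x$variance_explained_raw[seq_len(x$n_pcs)])))
  invisible(x)
}

#' Serialize / export a morphospace model
#'
#' `morphospace_to_json()` writes the standardization parameters, both
#' loading matrices, the rotation matrix and variance shares to JSON;
#' `write_scores_csv()` exports the rotated scores keyed by row index, site
#' and colony.
#'
#' @param model a `morphospace_model`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
morphospace_to_json <- function(model, path) {
  obj <- list(caste = model$caste,
              n_pcs = model$n_pcs,
              trait_means = as.list(model$trait_means),
              trait_sds = as.list(model$trait_sds),
              eigenvalues = model$eigenvalues,
              loadings_raw = model$loadings_raw,
              loadings_rotated = model$loadings_rotated,
              rotmat = model$rotmat,
              variance_explained_raw = model$variance_explained_raw,
              variance_explained_rotated = model$variance_explained_rotated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname morphospace_to_json
#' @export
write_scores_csv <- function(model, path) {
  df <- data.frame(row = model$rows,
                   site_id = model$site_id,
                   colony_id = model$colony_id,
                   caste = model$caste,
                   model$scores,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
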