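# Convex-hull-volume and centroid-displacement null models in morphospace.
#
# Observed distributions draw colony-stratified subsamples within a unit
# (site, or a site chosen uniformly within a climate-habitat combo); null
# distributions draw simple random subsamples from the pooled caste. The two
# are compared with a Mann-Whitney U test at alpha = 0.001.

#' Exact convex hull volume
#'
#' Lebesgue volume of the convex hull of `points` (rows) in d dimensions,
#' computed exactly by supporting-hyperplane enumeration (cost
#' choose(m, d)); affinely degenerate point sets return 0. Intended for the
#' small subsamples used here (m of order 10-20, d <= 6).
#'
#' @param points m x d numeric matrix, m >= d + 1.
#' @return Nonnegative hull volume.
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < ncol(points) + 1L)
    stop("need at least d + 1 = ", ncol(points) + 1L,
         " points for a ", ncol(points), "-D hull")
  if (any(!is.finite(points))) stop("points must be finite")
  .hull_volume_cpp(points)
}

#' Colony-stratified subsample
#'
#' Draws `n` distinct row indices without replacement such that every colony
#' contributes at least `min_per_colony`; the colonies receiving the extra
#' draws beyond the floor are chosen uniformly (subject to remaining
#' capacity). Uses the current RNG state.
#'
#' @param colony_labels vector of colony labels, one per row of the unit.
#' @param n subsample size.
#' @param min_per_colony per-colony floor.
#' @return Integer vector of `n` indices into `colony_labels`.
#' @export
stratified_subsample <- function(colony_labels, n = 10L,
                                 min_per_colony = 3L) {
  idx_by_colony <- split(seq_along(colony_labels), colony_labels)
  sizes <- lengths(idx_by_colony)
  k <- length(idx_by_colony)
  if (any(sizes < min_per_colony))
    stop("infeasible stratum: colony '",
         names(sizes)[which(sizes < min_per_colony)[1]], "' has ",
         min(sizes), " row(s) < min_per_colony = ", min_per_colony)
  if (k * min_per_colony > n)
    stop("min_per_colony x number of colonies exceeds subsample size")
  if (sum(sizes) < n)
    stop("unit has fewer than n = ", n, " rows")
  take <- setNames(rep(min_per_colony, k), names(idx_by_colony))
  extra <- n - k * min_per_colony
  while (extra > 0L) {
    open <- names(take)[take < sizes]
    pick <- open[sample.int(length(open), 1L)]
    take[pick] <- take[pick] + 1L
    extra <- extra - 1L
  }
  out <- unlist(lapply(names(idx_by_colony), function(cl) {
    ix <- idx_by_colony[[cl]]
    ix[sample.int(length(ix), take[cl])]
  }), use.names = FALSE)
  sort(out)
}

# rows (indices into the score matrix) of each feasible site of a unit
unit_feasible_sites <- function(site_id, colony_id, members, n,
                                min_per_colony) {
  out <- list()
  for (s in unique(site_id[members])) {
    rows <- members[site_id[members] == s]
    sizes <- table(colony_id[rows])
    if (all(sizes >= min_per_colony) &&
        length(sizes) * min_per_colony <= n && sum(sizes) >= n)
      out[[s]] <- rows
  }
  out
}

# one stratified draw from a unit: pick a feasible site uniformly (unit =
# combo spans several sites; the colony constraint applies within the site
# actually drawn), then stratify over its colonies
draw_unit_subsample <- function(feasible, colony_id, n, min_per_colony) {
  rows <- feasible[[sample.int(length(feasible), 1L)]]
  rows[stratified_subsample(colony_id[rows], n, min_per_colony)]
}

#' Observed hull-volume distribution of a unit
#'
#' `reps` convex-hull volumes, each from one colony-stratified subsample of
#' the unit (a site, or a combo whose member sites are first chosen
#' uniformly).
#'
#' @param scores n x k score matrix of the caste.
#' @param site_id,colony_id per-row labels aligned to `scores`.
#' @param members integer indices of the unit's rows.
#' @param n subsample size.
#' @param min_per_colony per-colony floor.
#' @param reps number of replicates.
#' @return Numeric vector of `reps` volumes.
#' @export
observed_hull_distribution <- function(scores, site_id, colony_id, members,
                                       n = 10L, min_per_colony = 3L,
                                       reps = 100L) {
  feasible <- unit_feasible_sites(site_id, colony_id, members, n,
                                  min_per_colony)
  if (!length(feasible))
    stop("unit has no feasible site (every colony needs >= ",
         min_per_colony, " workers and the site >= ", n, ")")
  vapply(seq_len(reps), function(i) {
    ix <- draw_unit_subsample(feasible, colony_id, n, min_per_colony)
    hull_volume(scores[ix, , drop = FALSE])
  }, numeric(1))
}

#' Null hull-volume distribution from the pooled caste
#'
#' `reps` convex-hull volumes of simple random subsamples of size `n` drawn
#' from all rows of the caste (no colony constraint: the pool is the
#' reference).
#'
#' @inheritParams observed_hull_distribution
#' @return Numeric vector of `reps` volumes.
#' @export
null_hull_distribution <- function(scores, n = 10L, reps = 1000L) {
  m <- nrow(scores)
  if (m < n) stop("pooled caste has fewer than n = ", n, " rows")
  vapply(seq_len(reps), function(i) {
    hull_volume(scores[sample.int(m, n), , drop = FALSE])
  }, numeric(1))
}

#' Centroid displacement
#'
#' Euclidean distance between the mean vector of `sample_scores` and the
#' pooled centroid.
#'
#' @param sample_scores m x k matrix (m >= 1).
#' @param pooled_centroid k-vector.
#' @return Nonnegative distance.
#' @export
centroid_distance <- function(sample_scores, pooled_centroid) {
  sample_scores <- rbind(sample_scores)
  sqrt(sum((colMeans(sample_scores) - pooled_centroid)^2))
}

new_null_model_result <- function(statistic, unit_label, caste, observed,
                                  null, alpha) {
  mw <- mann_whitney_u(observed, null, mode = "normal")
  structure(list(statistic = statistic,
                 unit_label = unit_label,
                 caste = caste,
                 observed = observed,
                 null = null,
                 observed_median = median(observed),
                 null_median = median(null),
                 direction = if (median(observed) < median(null))
                   "smaller" else "larger",
                 u_statistic = mw$u,
                 p_value = mw$p_value,
                 alpha = alpha,
                 significant = mw$p_value < alpha),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "%s null model, %s %s: observed median %.4g %s null median %.4g, U = %.0f, p = %.3g%s\n",
    x$statistic, x$unit_label, x$caste, x$observed_median,
    if (x$direction == "smaller") "<" else ">", x$null_median,
    x$u_statistic, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Environmental-filtering test (hull volume vs pooled null)
#'
#' Compares a unit's observed hull-volume distribution (colony-stratified
#' subsamples, `hull_reps` draws) against the pooled-caste null
#' (`null_reps` simple random subsamples) with a Mann-Whitney U test. A
#' significantly *smaller* observed volume indicates trait clustering,
#' supporting environmental filtering.
#'
#' @inheritParams observed_hull_distribution
#' @param unit_label label of the unit (combo or site id).
#' @param caste caste label carried into the result.
#' @param hull_reps,null_reps replicate counts.
#' @param alpha significance threshold.
#' @return A `null_model_result`.
#' @export
hull_test <- function(scores, site_id, colony_id, members, unit_label,
                      caste = "major", n = 10L, min_per_colony = 3L,
                      hull_reps = 100L, null_reps = 1000L, alpha = 0.001) {
  obs <- observed_hull_distribution(scores, site_id, colony_id, members,
                                    n, min_per_colony, hull_reps)
  nul <- null_hull_distribution(scores, n, null_reps)
  new_null_model_result("hull_volume", unit_label, caste, obs, nul, alpha)
}

#' Optimal-transfer test (centroid displacement vs pooled null)
#'
#' Observed distribution: `null_reps` centroid displacements of
#' colony-stratified subsamples of the unit from the pooled centroid. Null:
#' centroid displacements of simple random pooled subsamples of the same
#' size. Compared with a Mann-Whitney U test; a significantly *larger*
#' observed displacement supports the optimal-transfer hypothesis.
#'
#' @inheritParams hull_test
#' @param reps replicates for both distributions.
#' @return A `null_model_result`.
#' @export
centroid_test <- function(scores, site_id, colony_id, members, unit_label,
                          caste = "major", n = 10L, min_per_colony = 3L,
                          reps = 1000L, alpha = 0.001) {
  feasible <- unit_feasible_sites(site_id, colony_id, members, n,
                                  min_per_colony)
  if (!length(feasible))
    stop("unit has no feasible site (every colony needs >= ",
         min_per_colony, " workers and the site >= ", n, ")")
  pooled_centroid <- colMeans(scores)
  obs <- vapply(seq_len(reps), function(i) {
    ix <- draw_unit_subsample(feasible, colony_id, n, min_per_colony)
    centroid_distance(scores[ix, , drop = FALSE], pooled_centroid)
  }, numeric(1))
  m <- nrow(scores)
  nul <- vapply(seq_len(reps), function(i) {
    centroid_distance(scores[sample.int(m, n), , drop = FALSE],
                      pooled_centroid)
  }, numeric(1))
  new_null_model_result("centroid_distance", unit_label, caste, obs, nul,
                        alpha)
}

#' Run both null models across all units of a caste
#'
#' Applies [hull_test()] and [centroid_test()] to every climate-habitat
#' combo (or site, per `config$unit`) of the caste.
#'
#' @param model a `morphospace_model`.
#' @param sites a `site_table`.
#' @param config an [analysis_config()].
#' @param seed optional seed set before the draws.
#' @return List with `results` (list of `null_model_result`) and `table`
#'   (tidy data frame: combo, caste, statistic, observed_median,
#'   null_median, U, p, significant).
#' @export
run_null_models <- function(model, sites, config = analysis_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match(model$site_id, sites$site_id)
  if (anyNA(idx))
    stop("scores reference site(s) absent from the site table")
  unit_of_row <- if (config$unit == "combo") sites$combo[idx] else
    model$site_id
  units <- if (config$unit == "combo") combo_levels() else
    unique(model$site_id)
  results <- list()
  for (u in intersect(units, unique(unit_of_row))) {
    members <- which(unit_of_row == u)
    results[[paste0(u, ".hull")]] <-
      hull_test(model$scores, model$site_id, model$colony_id, members, u,
                model$caste, config$subsample_size, config$min_per_colony,
                config$hull_reps, config$null_reps, config$alpha)
    results[[paste0(u, ".centroid")]] <-
      centroid_test(model$scores, model$site_id, model$colony_id, members,
                    u, model$caste, config$subsample_size,
                    config$min_per_colony, config$null_reps, config$alpha)
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(combo = r$unit_label, caste = r$caste,
               statistic = r$statistic,
               observed_median = r$observed_median,
               null_median = r$null_median,
               direction = r$direction,
               U = r$u_statistic, p = r$p_value,
               significant = r$significant,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(results = results, table = tab)
}
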