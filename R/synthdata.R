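# Synthetic hierarchical trait data with planted effects.
#
# The generator emulates the study design: 22 sites spanning the 9 climate x
# habitat combos, 3 colonies per site, two worker castes, 8 positively
# correlated traits, site-level environmental covariates inside the reported
# ranges, and optional planted effects (per-combo variance shrink and
# centroid shift, per-trait environmental slopes) used to validate the
# downstream hypothesis tests.

default_site_allocation <- function(n_sites = 22L) {
  combos <- combo_levels()
  if (n_sites < length(combos))
    stop("n_sites must be >= ", length(combos),
         " so every climate-habitat combo is represented")
  n_each <- rep(n_sites %/% 9L, 9L)
  extra <- n_sites %% 9L
  if (extra > 0L) n_each[seq_len(extra)] <- n_each[seq_len(extra)] + 1L
  setNames(n_each, combos)
}

default_trait_means <- function() {
  # plausible minor-worker baselines (mm) for a large Camponotus
  setNames(c(7.5, 2.0, 1.8, 2.4, 1.5, 3.3, 1.1, 0.45), trait_names())
}

default_trait_sds <- function() {
  setNames(0.08 * default_trait_means(), trait_names())
}

default_caste_offset <- function() {
  # major workers are distinctly larger, with disproportionately broad heads
  # and mandibles but relatively short scapes
  setNames(c(4.0, 1.1, 1.3, 0.15, 0.7, 1.1, 0.55, 0.10), trait_names())
}

#' Exchangeable trait correlation matrix
#'
#' A single dominant size factor: all pairwise correlations equal `r`.
#'
#' @param r common pairwise correlation.
#' @param p number of traits.
#' @return A p x p positive-definite correlation matrix (for r in
#'   (-1/(p-1), 1)).
#' @export
exchangeable_correlation <- function(r = 0.6, p = 8L) {
  m <- matrix(r, p, p)
  diag(m) <- 1
  m
}

#' Synthetic-data configuration
#'
#' Defaults reproduce the study design: 22 sites over the 9 combos, 3
#' colonies per site, 7 workers per colony per caste (21 per site per caste,
#' 462 per caste in total), an exchangeable trait correlation of 0.6 and a
#' colony random intercept of 0.3 trait SD.
#'
#' @param n_sites number of sites (>= 9).
#' @param sites_per_combo named integer vector allocating sites to combos;
#'   default spreads `n_sites` as evenly as possible.
#' @param n_colonies colonies per site.
#' @param workers_per_colony_per_caste workers measured per colony and caste.
#' @param trait_base_means,trait_base_sds named 8-vectors (mm) for the minor
#'   caste baseline.
#' @param trait_correlation 8 x 8 positive-definite correlation matrix.
#' @param colony_sd_frac colony random-intercept SD as a fraction of each
#'   trait's SD (shared by both castes of a colony).
#' @param rng_seed default seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_sites = 22L,
                         sites_per_combo = default_site_allocation(n_sites),
                         n_colonies = 3L,
                         workers_per_colony_per_caste = 7L,
                         trait_base_means = default_trait_means(),
                         trait_base_sds = default_trait_sds(),
                         trait_correlation = exchangeable_correlation(),
                         colony_sd_frac = 0.3,
                         rng_seed = 1L) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 9L)
    stop("n_sites must be >= 9 so every climate-habitat combo is represented")
  if (!setequal(names(sites_per_combo), combo_levels()) ||
      any(sites_per_combo < 1L))
    stop("sites_per_combo must allocate >= 1 site to each of the 9 combos")
  if (sum(sites_per_combo) != n_sites)
    stop("sites_per_combo must sum to n_sites")
  stopifnot(n_colonies >= 1L, workers_per_colony_per_caste >= 1L)
  if (!isTRUE(all.equal(trait_correlation, t(trait_correlation))) ||
      any(eigen(trait_correlation, symmetric = TRUE,
                only.values = TRUE)$values <= 1e-10))
    stop("trait_correlation must be symmetric positive definite")
  stopifnot(length(trait_base_means) == 8L, length(trait_base_sds) == 8L,
            all(trait_base_sds > 0), all(trait_base_means > 0))
  structure(list(n_sites = n_sites,
                 sites_per_combo = sites_per_combo[combo_levels()],
                 n_colonies = as.integer(n_colonies),
                 workers_per_colony_per_caste =
                   as.integer(workers_per_colony_per_caste),
                 trait_base_means = setNames(trait_base_means, trait_names()),
                 trait_base_sds = setNames(trait_base_sds, trait_names()),
                 trait_correlation = trait_correlation,
                 colony_sd_frac = colony_sd_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

#' Planted-effect plan
#'
#' Encodes the two hypotheses under test as generative effects:
#' `variance_shrink` multiplies the within-population trait SD of a combo
#' (environmental filtering: shrink < 1 contracts its morphospace);
#' `centroid_shift` displaces a combo's trait means (optimal transfer), in
#' trait-SD units; `env_slopes` adds per-trait linear responses to the four
#' site covariates (temperature, precipitation, humidity, elevation), in
#' trait-SD per covariate unit (covariates centered across sites);
#' `caste_offset` separates major from minor trait means (mm).
#'
#' @param variance_shrink named numeric, combo -> positive SD multiplier.
#' @param centroid_shift named list, combo -> 8-vector of trait-SD units.
#' @param env_slopes 8 x 4 matrix (traits x temp/precip/humidity/elevation).
#' @param caste_offset named 8-vector (mm) added to major-worker means.
#' @return An object of class `effect_plan`.
#' @export
effect_plan <- function(variance_shrink = NULL, centroid_shift = NULL,
                        env_slopes = NULL,
                        caste_offset = default_caste_offset()) {
  combos <- combo_levels()
  shrink <- setNames(rep(1, 9L), combos)
  if (!is.null(variance_shrink)) {
    bad <- setdiff(names(variance_shrink), combos)
    if (length(bad)) stop("unknown combo in variance_shrink: ",
                          paste(bad, collapse = ", "))
    if (any(variance_shrink <= 0)) stop("variance_shrink must be > 0")
    shrink[names(variance_shrink)] <- variance_shrink
  }
  shift <- setNames(rep(list(setNames(rep(0, 8L), trait_names())), 9L),
                    combos)
  if (!is.null(centroid_shift)) {
    bad <- setdiff(names(centroid_shift), combos)
    if (length(bad)) stop("unknown combo in centroid_shift: ",
                          paste(bad, collapse = ", "))
    for (cb in names(centroid_shift)) {
      v <- centroid_shift[[cb]]
      if (is.null(names(v))) {
        stopifnot(length(v) == 8L)
        names(v) <- trait_names()
      }
      bad_tr <- setdiff(names(v), trait_names())
      if (length(bad_tr)) stop("unknown trait in centroid_shift: ",
                               paste(bad_tr, collapse = ", "))
      shift[[cb]][names(v)] <- v
    }
  }
  if (is.null(env_slopes)) {
    env_slopes <- matrix(0, 8L, 4L,
                         dimnames = list(trait_names(),
                                         c("temp_mean", "precip_mean",
                                           "rel_humidity", "elevation")))
  } else {
    stopifnot(is.matrix(env_slopes), nrow(env_slopes) == 8L,
              ncol(env_slopes) == 4L)
    dimnames(env_slopes) <- list(trait_names(),
                                 c("temp_mean", "precip_mean",
                                   "rel_humidity", "elevation"))
  }
  stopifnot(length(caste_offset) == 8L)
  structure(list(variance_shrink = shrink,
                 centroid_shift = shift,
                 env_slopes = env_slopes,
                 caste_offset = setNames(caste_offset, trait_names())),
            class = "effect_plan")
}

# zone-specific generating ranges; overall ranges match the study region
# (temperature -0.65..21.52 C decreasing toward the mid-temperate zone,
# precipitation 27.75..191.35 mm, elevation 35..1275 m, longitude 88..126 E,
# latitude 24..47 N; relative humidity range is not reported -- U(40, 80) is
# an invented but climatically plausible default)
zone_env_ranges <- function() {
  list(
    MTZ = list(temp = c(-0.65, 6.5), precip = c(27.75, 90),
               lat = c(40, 47)),
    WTZ = list(temp = c(6.5, 14), precip = c(50, 130), lat = c(32, 40)),
    STZ = list(temp = c(14, 21.52), precip = c(100, 191.35), lat = c(24, 32))
  )
}

#' Generate a synthetic site table
#'
#' Draws `n_sites` sites covering all nine combos, with mean temperature
#' decreasing from the subtropical to the mid-temperate zone and all
#' covariates inside the study-region ranges. Deterministic given `seed`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$rng_seed`).
#' @return A `site_table`.
#' @export
generate_sites <- function(config = synth_config(), seed = config$rng_seed) {
  set.seed(seed)
  alloc <- config$sites_per_combo
  combos <- rep(names(alloc), alloc)
  zones <- sub("\\..*$", "", combos)
  habs <- sub("^[A-Z]+\\.", "", combos)
  rng <- zone_env_ranges()
  n <- length(combos)
  temp <- precip <- lat <- numeric(n)
  for (i in seq_len(n)) {
    zr <- rng[[zones[i]]]
    temp[i] <- runif(1, zr$temp[1], zr$temp[2])
    precip[i] <- runif(1, zr$precip[1], zr$precip[2])
    lat[i] <- runif(1, zr$lat[1], zr$lat[2])
  }
  df <- data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    climate_zone = zones,
    habitat = habs,
    temp_mean = round(temp, 2),
    precip_mean = round(precip, 2),
    rel_humidity = round(runif(n, 40, 80), 1),
    elevation = round(runif(n, 35, 1275)),
    longitude = round(runif(n, 88, 126), 3),
    latitude = round(lat, 3),
    stringsAsFactors = FALSE
  )
  validate_site_table(df)
}

#' Generate a synthetic worker trait table
#'
#' For every site x colony x caste draws
#' `workers_per_colony_per_caste` workers. Each trait vector is
#' `base mean + caste offset + combo centroid shift (SD units x base SD) +
#' env_slopes %*% centered site covariates (SD units) + colony random
#' intercept + multivariate Gaussian noise` with correlation
#' `trait_correlation` and SD `base SD x variance_shrink(combo)`, clipped to
#' stay positive. Deterministic given `seed`.
#'
#' @param sites a `site_table`.
#' @param config a [synth_config()].
#' @param plan an [effect_plan()].
#' @param seed integer seed.
#' @return A `trait_table` (majors and minors interleaved by site/colony).
#' @export
generate_workers <- function(sites, config = synth_config(),
                             plan = effect_plan(),
                             seed = config$rng_seed) {
  set.seed(seed)
  p <- 8L
  mu0 <- config$trait_base_means
  sd0 <- config$trait_base_sds
  chol_r <- chol(config$trait_correlation)
  env_cols <- c("temp_mean", "precip_mean", "rel_humidity", "elevation")
  env_center <- colMeans(as.data.frame(sites)[, env_cols])
  nw <- config$workers_per_colony_per_caste
  out <- vector("list", nrow(sites) * config$n_colonies * 2L)
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    cb <- sites$combo[i]
    env_dev <- as.numeric(as.data.frame(sites)[i, env_cols]) - env_center
    env_term <- as.numeric(plan$env_slopes %*% env_dev) * sd0
    shift_term <- plan$centroid_shift[[cb]] * sd0
    noise_sd <- sd0 * plan$variance_shrink[[cb]]
    for (j in seq_len(config$n_colonies)) {
      colony_int <- rnorm(p) * config$colony_sd_frac * sd0
      for (caste in c("major", "minor")) {
        mu <- mu0 + shift_term + env_term + colony_int +
          if (caste == "major") plan$caste_offset else 0
        z <- matrix(rnorm(nw * p), nw, p) %*% chol_r
        traits <- sweep(sweep(z, 2L, noise_sd, "*"), 2L, mu, "+")
        # clip to a 0.1 um floor and round to measurement precision (1e-4 mm)
        # so CSV round-trips are exact
        traits <- pmax(round(pmax(traits, 1e-6), 4L), 1e-4)
        colnames(traits) <- trait_names()
        k <- k + 1L
        out[[k]] <- data.frame(site_id = sites$site_id[i],
                               colony_id = sprintf("C%d", j),
                               caste = caste,
                               traits,
                               stringsAsFactors = FALSE)
      }
    }
  }
  validate_trait_table(do.call(rbind, out))
}

#' Write a synthetic fixture to disk
#'
#' Writes the site and trait tables as CSV, readable back bit-identically by
#' [read_site_table()] and [read_trait_table()].
#'
#' @param sites a `site_table`.
#' @param traits a `trait_table`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the two file paths.
#' @export
write_fixture <- function(sites, traits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sites = file.path(dir, "sites.csv"),
             traits = file.path(dir, "traits.csv"))
  write_site_table(sites, paths[["sites"]])
  write_trait_table(traits, paths[["traits"]])
  paths
}
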