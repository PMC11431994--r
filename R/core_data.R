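# Domain tables, CSV I/O and validation.

#' The eight worker morphological traits (mm)
#'
#' Column names used throughout for the continuous traits measured on each
#' worker: total body length, head capsule length and width, antennal scape
#' length, pronotum width, Weber's length (mesosoma, the standard ant
#' body-size proxy), mandible length and compound-eye width.
#'
#' @export
trait_names <- function() {
  c("body_length", "head_length", "head_width", "scape_length",
    "pronotum_width", "webers_length", "mandible_length", "eye_width")
}

#' @rdname combo_levels
#' @export
climate_zones <- function() c("MTZ", "WTZ", "STZ")

#' @rdname combo_levels
#' @export
habitat_types <- function() c("F", "SW", "UP")

#' Climate zone, habitat and combo levels
#'
#' Three climate zones (mid-temperate MTZ, warm-temperate WTZ, subtropical
#' STZ) crossed with three habitat types (farmland F, sparse woodland SW,
#' urban park UP) give the nine climate-habitat combinations, labelled
#' `"<zone>.<habitat>"` (e.g. `"MTZ.F"`).
#'
#' @return Character vectors of the factor levels / combo labels.
#' @export
combo_levels <- function() {
  as.vector(t(outer(climate_zones(), habitat_types(), paste, sep = ".")))
}

#' Combo label for climate zone x habitat
#'
#' @param climate_zone character vector of zone codes.
#' @param habitat character vector of habitat codes.
#' @return `"<zone>.<habitat>"` labels.
#' @export
combo_label <- function(climate_zone, habitat) {
  paste(climate_zone, habitat, sep = ".")
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the morphospace analysis. Defaults are
#' the study design values: 4 retained components, subsamples of 10 workers
#' with at least 3 per colony, 100 observed-hull draws, 1000 null draws,
#' significance at p < 0.001, and a Bonferroni family of 12 (3 rank-test
#' effects x 4 components).
#'
#' @param n_pcs retained principal components.
#' @param subsample_size workers per subsample draw.
#' @param min_per_colony minimum workers drawn from each colony.
#' @param hull_reps observed hull-volume replicates per unit.
#' @param null_reps null replicates (both statistics).
#' @param alpha significance threshold.
#' @param bonferroni_m Bonferroni family size for corrected p-values.
#' @param unit unit of analysis for null models: `"combo"` (default) or
#'   `"site"`.
#' @param rng_seed master seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(n_pcs = 4L, subsample_size = 10L,
                            min_per_colony = 3L, hull_reps = 100L,
                            null_reps = 1000L, alpha = 0.001,
                            bonferroni_m = 12L, unit = c("combo", "site"),
                            rng_seed = 1L) {
  unit <- match.arg(unit)
  cfg <- list(n_pcs = as.integer(n_pcs),
              subsample_size = as.integer(subsample_size),
              min_per_colony = as.integer(min_per_colony),
              hull_reps = as.integer(hull_reps),
              null_reps = as.integer(null_reps),
              alpha = alpha,
              bonferroni_m = as.integer(bonferroni_m),
              unit = unit,
              rng_seed = as.integer(rng_seed))
  if (cfg$subsample_size < cfg$n_pcs + 1L)
    stop("subsample_size must be at least n_pcs + 1 (a ", cfg$n_pcs,
         "-D hull needs ", cfg$n_pcs + 1L, " points)")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]")
  if (any(vapply(cfg[c("n_pcs", "subsample_size", "min_per_colony",
                       "hull_reps", "null_reps", "bonferroni_m")],
                 function(v) v < 1L, logical(1))))
    stop("counts in analysis_config must be >= 1")
  structure(cfg, class = "analysis_config")
}

validate_trait_table <- function(df) {
  req <- c("site_id", "colony_id", "caste", trait_names())
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  df$colony_id <- as.character(df$colony_id)
  df$caste <- as.character(df$caste)
  bad_caste <- !df$caste %in% c("major", "minor")
  if (any(bad_caste))
    stop("invalid caste value(s) in row(s) ",
         paste(which(bad_caste), collapse = ", "),
         " (must be 'major' or 'minor')")
  for (tr in trait_names()) {
    v <- df[[tr]]
    if (!is.numeric(v))
      stop("trait column '", tr, "' is not numeric")
    bad <- !is.finite(v) | v <= 0
    if (any(bad))
      stop("non-positive or non-finite '", tr, "' in row(s) ",
           paste(which(bad), collapse = ", "))
  }
  structure(df[, req], class = c("trait_table", "data.frame"))
}

validate_site_table <- function(df) {
  req <- c("site_id", "climate_zone", "habitat", "temp_mean", "precip_mean",
           "rel_humidity", "elevation", "longitude", "latitude")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("site table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  df$climate_zone <- as.character(df$climate_zone)
  df$habitat <- as.character(df$habitat)
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  bad_zone <- !df$climate_zone %in% climate_zones()
  if (any(bad_zone))
    stop("unknown climate_zone code(s): ",
         paste(unique(df$climate_zone[bad_zone]), collapse = ", "))
  bad_hab <- !df$habitat %in% habitat_types()
  if (any(bad_hab))
    stop("unknown habitat code(s): ",
         paste(unique(df$habitat[bad_hab]), collapse = ", "))
  for (cl in c("temp_mean", "precip_mean", "rel_humidity", "elevation",
               "longitude", "latitude")) {
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("environmental column '", cl, "' must be finite numeric")
  }
  df <- df[, req]
  df$combo <- combo_label(df$climate_zone, df$habitat)
  structure(df, class = c("site_table", "data.frame"))
}

#' Read a worker trait table
#'
#' Reads a CSV with columns `site_id`, `colony_id`, `caste` and the eight
#' trait columns ([trait_names()]), validating types, caste codes and trait
#' positivity. Row order is preserved.
#'
#' @param path CSV file path.
#' @return A validated `trait_table` data frame.
#' @export
read_trait_table <- function(path) {
  validate_trait_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a site metadata table
#'
#' Reads a CSV with `site_id`, `climate_zone`, `habitat` and the four
#' environmental covariates plus coordinates; validates uniqueness of
#' `site_id` and the zone/habitat codes and derives the `combo` label.
#'
#' @param path CSV file path.
#' @return A validated `site_table` data frame (with a derived `combo`
#'   column).
#' @export
read_site_table <- function(path) {
  validate_site_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trait_table
#' @param traits a `trait_table`.
#' @export
write_trait_table <- function(traits, path) {
  write.csv(as.data.frame(traits)[, c("site_id", "colony_id", "caste",
                                      trait_names())],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_site_table
#' @param sites a `site_table`.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("site_id", "climate_zone", "habitat", "temp_mean", "precip_mean",
            "rel_humidity", "elevation", "longitude", "latitude")
  write.csv(as.data.frame(sites)[, cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Cross-validate trait and site tables
#'
#' Checks that every worker's site exists in the site table (error), flags
#' site/colony/caste cells with fewer than `min_per_colony` workers (warning:
#' those units are infeasible for colony-stratified subsampling), and
#' tabulates workers per climate-habitat combo and caste.
#'
#' @param traits a `trait_table`.
#' @param sites a `site_table`.
#' @param min_per_colony stratified-subsampling floor per colony.
#' @return A `validation_report` list with `errors`, `warnings` and
#'   `combo_counts`.
#' @export
validate_dataset <- function(traits, sites, min_per_colony = 3L) {
  errors <- character(0)
  warnings <- character(0)
  unknown <- setdiff(unique(traits$site_id), sites$site_id)
  if (length(unknown))
    errors <- c(errors, paste0("trait rows reference unknown site_id '",
                               unknown, "'"))
  known <- traits[traits$site_id %in% sites$site_id, , drop = FALSE]
  if (nrow(known)) {
    cnt <- aggregate(list(n = seq_len(nrow(known))),
                     by = list(site_id = known$site_id,
                               colony_id = known$colony_id,
                               caste = known$caste),
                     FUN = length)
    low <- cnt[cnt$n < min_per_colony, , drop = FALSE]
    if (nrow(low))
      warnings <- c(warnings, sprintf(
        "site %s colony %s has only %d %s worker(s) (< %d): caste excluded from stratified subsampling",
        low$site_id, low$colony_id, low$n, low$caste, min_per_colony))
    combo <- sites$combo[match(known$site_id, sites$site_id)]
    combo_counts <- as.data.frame(table(combo = combo, caste = known$caste),
                                  stringsAsFactors = FALSE)
    names(combo_counts)[3] <- "n_workers"
  } else {
    combo_counts <- data.frame(combo = character(0), caste = character(0),
                               n_workers = integer(0))
  }
  structure(list(errors = errors, warnings = warnings,
                 combo_counts = combo_counts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Dataset validation report\n")
  cat("  errors:  ", length(x$errors), "\n")
  for (e in x$errors) cat("    - ", e, "\n", sep = "")
  cat("  warnings:", length(x$warnings), "\n")
  for (w in x$warnings) cat("    - ", w, "\n", sep = "")
  invisible(x)
}
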