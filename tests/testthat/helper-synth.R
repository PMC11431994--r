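# Shared fixtures built in code.

tiny_trait_df <- function() {
  tr <- matrix(c(
    10.1, 2.1, 1.9, 2.5, 1.6, 3.4, 1.2, 0.50,
    10.3, 2.2, 2.0, 2.6, 1.7, 3.5, 1.3, 0.52,
    7.2, 1.8, 1.6, 2.3, 1.4, 3.1, 1.0, 0.44,
    7.4, 1.9, 1.7, 2.4, 1.5, 3.2, 1.1, 0.46
  ), nrow = 4, byrow = TRUE)
  colnames(tr) <- trait_names()
  data.frame(site_id = c("S01", "S01", "S01", "S01"),
             colony_id = c("C1", "C1", "C2", "C2"),
             caste = c("major", "major", "minor", "minor"),
             tr, stringsAsFactors = FALSE)
}

tiny_site_df <- function() {
  data.frame(site_id = c("S01", "S02"),
             climate_zone = c("MTZ", "STZ"),
             habitat = c("F", "UP"),
             temp_mean = c(3.2, 18.5),
             precip_mean = c(45.0, 150.0),
             rel_humidity = c(55.0, 72.0),
             elevation = c(420, 80),
             longitude = c(112.5, 118.2),
             latitude = c(43.1, 26.4),
             stringsAsFactors = FALSE)
}

# site/colony labels and 4-D scores for null-model unit tests: `n_sites`
# sites of 3 colonies x `per_colony` workers; optionally degenerate or
# shifted units are layered on by the tests themselves
toy_scores <- function(n_sites = 4, per_colony = 7, k = 4, sd = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_sites * 3 * per_colony
  list(scores = matrix(rnorm(n * k, sd = sd), n, k),
       site_id = rep(sprintf("S%02d", seq_len(n_sites)),
                     each = 3 * per_colony),
       colony_id = rep(rep(c("C1", "C2", "C3"), each = per_colony),
                       n_sites))
}

# previously published reference values for C. japonicus worker morphospace
reference_variance_shares <- function() {
  list(major = c(PC1 = 41.73, PC2 = 14.97, PC3 = 11.17, PC4 = 9.11),
       minor = c(PC1 = 39.40, PC2 = 13.78, PC3 = 11.82, PC4 = 9.99),
       total_major = 76.98, total_minor = 74.99)
}

reference_srh_cells <- function() {
  data.frame(H = c(7.17, 9.57, 17.56, 12.82),
             df = 2L,
             p_corrected = c(0.333, 0.1, 0.0018, 0.020),
             digits = c(3L, 1L, 4L, 3L))
}
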