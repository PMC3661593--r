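# Independent brute-force oracles: naive loop implementations kept separate
# from the package code paths they check.

oracle_total <- function(M) {
  s <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) s <- s + M[i, j]
  s
}

oracle_links <- function(M) {
  s <- 0L
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[i, j] > 0) s <- s + 1L
  }
  s
}

oracle_evenness <- function(M) {
  w <- c()
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[i, j] > 0) w <- c(w, M[i, j])
  }
  if (length(w) <= 1) return(NA_real_)
  H <- 0
  for (wi in w) H <- H - (wi / sum(w)) * log(wi / sum(w))
  H / log(length(w))
}

oracle_weighted_generalism <- function(M, j) {
  col <- M[, j]
  V <- sum(col)
  H <- 0
  for (a in col) {
    if (a > 0) H <- H - (a / V) * log(a / V)
  }
  H
}

oracle_rs <- function(M, i) {
  r <- 0
  for (j in seq_len(ncol(M))) {
    V <- sum(M[, j])
    if (V > 0) r <- r + (M[i, j] / V)^2 * V
  }
  r
}

# exact Mantel reference: enumerate all permutations via recursive insertion
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- oracle_perms(n - 1L)
  out <- list()
  for (s in shorter) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos)
    }
  }
  out
}

oracle_mantel_exact_p <- function(D1, D2) {
  ut <- upper.tri(D1)
  r_obs <- cor(D1[ut], D2[ut])
  rs <- sapply(oracle_perms(nrow(D1)), function(pm) {
    Dp <- D2[pm, pm]
    cor(D1[ut], Dp[ut])
  })
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

random_web <- function(n = 5, m = 9, lambda = 3, site = "S", cfg = "random") {
  counts <- matrix(rpois(n * m, lambda), n, m,
                   dimnames = list(paste0("p", seq_len(n)),
                                   paste0("v", seq_len(m))))
  pollweb:::new_interaction_matrix(counts, site_id = site,
                                   spatial_config = cfg, rounds = 1:4)
}

# small deterministic record set used across IO tests
toy_records <- function() {
  data.frame(
    site_id = rep(c("A", "A", "B"), each = 4),
    landscape_context = rep(c("urban", "urban", "semi-natural"), each = 4),
    round = rep(c(1L, 3L), 6),
    plot_id = rep(c("P1", "P3"), each = 2, times = 3),
    spatial_config = rep(c("systematic", "random"), each = 2, times = 3),
    plant_species = rep(c("M. sativa", "M. inodora"), 6),
    insect_morphotype = rep(c("bumblebees", "Syrphidae"), 6),
    visit_count = c(2L, 5L, 1L, 0L, 3L, 2L, 4L, 1L, 7L, 2L, 0L, 6L),
    stringsAsFactors = FALSE)
}
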