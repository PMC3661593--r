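new_test_result <- function(method, statistic, df = NA_integer_, p_value,
                            n_perm = NA_integer_, seed = NA_integer_,
                            extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p_value, n_perm = n_perm, seed = seed), extra),
            class = "pollweb_test")
}

#' @export
print.pollweb_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic, digits = 5), sep = "")
  if (!is.na(x$df)) cat(", df =", x$df)
  cat(", p =", format.pval(x$p_value, digits = 4), "\n")
  if (!is.na(x$n_perm)) {
    cat("  ", x$n_perm, " permutations",
        if (!is.na(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  }
  invisible(x)
}

#' Pearson chi-squared homogeneity test on a contingency table
#'
#' Tests whether visit proportions over the rows (e.g. plant species) are
#' homogeneous across the columns (e.g. landscape contexts). Uses the standard
#' Pearson statistic sum (O - E)^2 / E, df = (rows - 1)(cols - 1), asymptotic
#' upper-tail p-value, no continuity correction. A 5-plant x 4-context table
#' has df = 12.
#'
#' @param tab A matrix of non-negative counts with all row and column sums
#'   positive.
#' @return A `pollweb_test` with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("contingency table has negative entries")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency table: a row or column sum is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result("Pearson chi-squared homogeneity test",
                  statistic = unname(ct$statistic),
                  df = unname(ct$parameter),
                  p_value = unname(ct$p.value))
}

#' Bray-Curtis similarity between two count vectors
#'
#' Similarity = 1 - sum|u_i - v_i| / sum(u_i + v_i), computed on raw counts.
#' Identical vectors give 1; vectors with disjoint support give 0.
#'
#' @param u,v Equal-length non-negative count vectors, not both all-zero.
#' @return A number in \[0, 1\].
#' @export
bray_curtis_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("counts must be non-negative")
  if (sum(u) + sum(v) == 0) {
    stop("Bray-Curtis similarity is undefined for two all-zero vectors")
  }
  1 - as.numeric(vegan::vegdist(rbind(u, v), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix over sites
#'
#' Pairwise 1 - similarity on the rows of a site x species (or site x
#' morphotype) count matrix; the usual input to [mantel_test()].
#'
#' @param counts Matrix with one row per site.
#' @return A symmetric `matrix` with zero diagonal and the site rownames.
#' @export
bray_curtis_matrix <- function(counts) {
  d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation r between the upper-triangle entries of D1 and D2,
#' assessed by jointly permuting rows and columns of D2. The test is two-sided
#' on |r|. For small designs (`factorial(n) - 1 <= n_perm`) all n! relabellings
#' are enumerated and the p-value is exact:
#' p = #\{permutations with |r*| >= |r|\} / n! (the identity included).
#' Otherwise `n_perm` random permutations are drawn and
#' p = (1 + #\{|r*| >= |r|\}) / (1 + n_perm), which never returns 0.
#'
#' @param D1,D2 Symmetric distance/dissimilarity matrices with matching site
#'   labels (rownames); D2 is reordered to D1's labels if necessary.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param method Correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @return A `pollweb_test` with `statistic` (r), `p_value`, `n_perm`,
#'   `seed`, and `exact` flag.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2))) {
      stop("distance matrices have mismatching site labels")
    }
    D2 <- D2[rownames(D1), rownames(D1)]
  } else if (nrow(D1) != nrow(D2)) {
    stop("distance matrices have mismatching dimensions")
  }
  n <- nrow(D1)
  if (n_perm < 1) stop("n_perm must be >= 1")
  ut <- upper.tri(D1)
  x <- D1[ut]
  if (stats::sd(x) == 0 || stats::sd(D2[ut]) == 0) {
    stop("constant upper triangle: Mantel correlation undefined")
  }
  r_stat <- function(perm) {
    Dp <- D2[perm, perm]
    stats::cor(x, Dp[ut], method = method)
  }
  r_obs <- r_stat(seq_len(n))

  exact <- factorial(n) - 1 <= n_perm
  if (exact) {
    perms <- all_permutations(n)
    r_all <- vapply(perms, r_stat, numeric(1))
    p <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(r_stat(sample.int(n))) >= abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  new_test_result("Mantel permutation test (two-sided)",
                  statistic = r_obs, p_value = p, n_perm = n_used,
                  seed = if (is.null(seed)) NA_integer_ else seed,
                  extra = list(exact = exact, correlation = method))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Permutation comparison of a per-web metric across landscape contexts
#'
#' For every pair of landscape contexts, tests the difference of context means
#' under random relabelling of the observations. This is a deliberately simple
#' permutation surrogate for mixed-model contrasts: it ignores site random
#' effects and is labelled as a surrogate in all outputs. When the number of
#' distinct relabellings `choose(n, n1)` does not exceed `n_perm`, all of them
#' are enumerated and p = #\{|d*| >= |d|\} / #relabellings (exact, identity
#' included; the minimum attainable two-sided p for balanced groups is
#' 2 / #relabellings). Otherwise `n_perm` Monte-Carlo relabellings are drawn
#' with the +1 correction.
#'
#' @param values Numeric vector of per-web (or per-site) metric values.
#' @param contexts Character/factor vector of the same length giving each
#'   value's landscape context.
#' @param n_perm Permutation budget per pair (default 999).
#' @param seed Integer seed.
#' @return A `data.frame` with one row per context pair: means, mean
#'   difference, p-value, method and permutation count.
#' @export
permutation_context_compare <- function(values, contexts, n_perm = 999,
                                        seed = NULL) {
  if (length(values) != length(contexts)) {
    stop("values and contexts must have equal length")
  }
  contexts <- as.character(contexts)
  tab <- table(contexts)
  if (length(tab) < 2) stop("need at least two landscape contexts")
  if (any(tab < 2)) {
    stop("insufficient replication: context(s) with fewer than 2 values: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  ctx_levels <- order_labels(names(tab), landscape_contexts())
  pairs <- utils::combn(ctx_levels, 2)
  res <- apply(pairs, 2, function(pr) {
    va <- values[contexts == pr[1]]
    vb <- values[contexts == pr[2]]
    pooled <- c(va, vb)
    n1 <- length(va)
    d_obs <- mean(va) - mean(vb)
    n_comb <- choose(length(pooled), n1)
    if (n_comb <= n_perm) {
      idx <- utils::combn(length(pooled), n1)
      d_all <- apply(idx, 2, function(ii)
        mean(pooled[ii]) - mean(pooled[-ii]))
      p <- mean(abs(d_all) >= abs(d_obs) - 1e-12)
      method <- "exact relabelling"
      n_used <- n_comb
    } else {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        lab <- sample.int(length(pooled), n1)
        if (abs(mean(pooled[lab]) - mean(pooled[-lab])) >=
            abs(d_obs) - 1e-12) hits <- hits + 1L
      }
      p <- (1 + hits) / (1 + n_perm)
      method <- "Monte-Carlo relabelling"
      n_used <- n_perm
    }
    data.frame(context_a = pr[1], context_b = pr[2],
               mean_a = mean(va), mean_b = mean(vb), diff = d_obs,
               p_value = p, n_perm = n_used,
               method = paste0("permutation surrogate (", method, ")"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "seed") <- seed
  out
}

#' Pairwise planar distance matrix between sites
#'
#' @param sites Site metadata (`data.frame` with `site_id`, `x`, `y`).
#' @return Symmetric Euclidean distance matrix labelled by `site_id`.
#' @export
site_distance_matrix <- function(sites) {
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  dimnames(d) <- list(sites$site_id, sites$site_id)
  d
}
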