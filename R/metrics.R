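#' Total number of interactions in a web
#'
#' @param M An `interaction_matrix` (or plain non-negative count matrix).
#' @return Integer sum of all cells.
#' @export
total_interactions <- function(M) {
  sum(as.numeric(M))
}

#' Number of realised links in a web
#'
#' A link is a plant-morphotype pair with at least one observed visit
#' (a nonzero matrix cell).
#'
#' @inheritParams total_interactions
#' @return Integer count of nonzero cells.
#' @export
link_count <- function(M) {
  sum(M > 0)
}

#' Interaction evenness of a quantitative web
#'
#' Shannon evenness of the distribution of interactions over the *realised*
#' links only: zero cells (absent links) are excluded from the calculation.
#' With link proportions p_ij = A_ij / total over the L nonzero cells,
#' the index is H / ln(L) where H = -sum p_ij ln p_ij. It reaches 1 exactly
#' when visits are uniformly spread over the realised links, and is undefined
#' for L <= 1 because the normaliser ln(L) vanishes.
#'
#' @inheritParams total_interactions
#' @return A number in (0, 1].
#' @export
#' @examples
#' M <- matrix(5L, 2, 2, dimnames = list(c("p1", "p2"), c("m1", "m2")))
#' interaction_evenness(M)  # 1
interaction_evenness <- function(M) {
  w <- as.numeric(M[M > 0])
  L <- length(w)
  if (L <= 1) {
    stop("interaction evenness is undefined for webs with fewer than 2 links")
  }
  p <- w / sum(w)
  -sum(p * log(p)) / log(L)
}

#' Visit distribution of one morphotype over plants
#'
#' For morphotype p, the profile holds its visit counts by plant, the total
#' V = sum of its column, and the plant-choice probabilities
#' P(p, f) = A\[f, p\] / V (the share of the morphotype's visits that went to
#' plant f). P is undefined when the morphotype was never observed (V = 0);
#' the profile is then flagged rather than an error being raised.
#'
#' @inheritParams total_interactions
#' @param morphotype Column label.
#' @return A list of class `visit_profile` with elements `morphotype`,
#'   `counts_by_plant`, `V` and `P` (`NULL` when V = 0).
#' @export
visit_distribution <- function(M, morphotype) {
  if (!morphotype %in% colnames(M)) {
    stop("unknown morphotype: ", morphotype)
  }
  counts <- M[, morphotype]
  V <- sum(counts)
  structure(list(morphotype = morphotype,
                 counts_by_plant = counts,
                 V = as.integer(V),
                 P = if (V > 0) counts / V else NULL),
            class = "visit_profile")
}

#' Qualitative generalism (degree) of a morphotype
#'
#' The number of plant species with which the morphotype interacts in the web
#' (plants receiving at least one of its visits).
#'
#' @inheritParams visit_distribution
#' @return Integer degree.
#' @export
qualitative_generalism <- function(M, morphotype) {
  prof <- visit_distribution(M, morphotype)
  if (prof$V == 0) {
    stop("generalism is undefined for a morphotype with no visits: ",
         morphotype)
  }
  sum(prof$counts_by_plant > 0)
}

#' Weighted generalism of a morphotype
#'
#' Shannon index (natural log) of the morphotype's visit distribution over
#' plants, accounting for link intensity: H = -sum_f P(p, f) ln P(p, f) over
#' the plants it visits. H = 0 for a perfect specialist and ln(k) for a
#' visitor spreading visits equally over k plants. Reported in nats.
#'
#' @inheritParams visit_distribution
#' @return Non-negative Shannon index in nats.
#' @export
weighted_generalism <- function(M, morphotype) {
  prof <- visit_distribution(M, morphotype)
  if (prof$V == 0) {
    stop("generalism is undefined for a morphotype with no visits: ",
         morphotype)
  }
  p <- prof$P[prof$P > 0]
  -sum(p * log(p))
}

#' Per-web summary of network-level indices
#'
#' @inheritParams total_interactions
#' @return A one-row `data.frame` with `site_id`, `spatial_config`,
#'   `landscape_context`, `total_interactions`, `link_count` and
#'   `interaction_evenness` (`NA` when undefined, i.e. fewer than 2 links).
#' @export
network_summary <- function(M) {
  p <- attr(M, "provenance")
  ie <- tryCatch(interaction_evenness(M), error = function(e) NA_real_)
  data.frame(site_id = p$site_id %||% NA_character_,
             spatial_config = p$spatial_config %||% NA_character_,
             landscape_context = p$landscape_context %||% NA_character_,
             total_interactions = total_interactions(M),
             link_count = link_count(M),
             interaction_evenness = ie,
             stringsAsFactors = FALSE)
}

#' Per-web generalism table
#'
#' Degree and weighted generalism for every morphotype observed at least once
#' in the web; zero-visit morphotypes are excluded (with a message) because
#' both measures are undefined for them.
#'
#' @inheritParams total_interactions
#' @return A `data.frame` with one row per active morphotype.
#' @export
generalism_table <- function(M) {
  p <- attr(M, "provenance")
  V <- colSums(M)
  inactive <- colnames(M)[V == 0]
  if (length(inactive) > 0) {
    message("excluding zero-visit morphotype(s): ",
            paste(inactive, collapse = ", "))
  }
  active <- colnames(M)[V > 0]
  data.frame(site_id = rep(p$site_id %||% NA_character_, length(active)),
             spatial_config = rep(p$spatial_config %||% NA_character_,
                                  length(active)),
             landscape_context = rep(p$landscape_context %||% NA_character_,
                                     length(active)),
             morphotype = active,
             visits = as.integer(V[active]),
             degree = vapply(active, function(m)
               as.integer(qualitative_generalism(M, m)), integer(1)),
             weighted_generalism = vapply(active, function(m)
               weighted_generalism(M, m), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
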