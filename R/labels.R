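#' Canonical labels for the experimental community design
#'
#' The study design plants a fixed five-species experimental community at
#' every site and scores flower visitors into nine morphological functional
#' groups ("morphotypes"). These vectors fix the row/column order of every
#' interaction matrix the package builds, so outputs are deterministic and
#' comparable across webs. Labels found in data but absent from these lists
#' are accepted and appended after the canonical ones (with a message).
#'
#' @return A character vector of labels, in canonical order.
#' @name canonical-labels
NULL

#' @rdname canonical-labels
#' @export
plant_labels <- function() {
  c("M. sativa", "C. regalis", "L. corniculatus", "M. inodora", "S. arvensis")
}

#' @rdname canonical-labels
#' @export
morphotype_labels <- function() {
  c("solitary bees", "Apis mellifera", "bumblebees", "Coleoptera",
    "Lepidoptera", "Syrphidae", "other flies", "bugs", "other Hymenoptera")
}

#' @rdname canonical-labels
#' @export
landscape_contexts <- function() {
  c("semi-natural", "agricultural", "suburban", "urban")
}

#' Floral functional-group map
#'
#' Plants are split into two corolla-morphology groups: "tubular" flowers hide
#' their rewards at the bottom of a corolla tube (accessible mainly to
#' long-mouthpart visitors) and "open" flowers expose rewards on a flat
#' corolla. The default map covers the five-species experimental community:
#' tubular = \emph{L. corniculatus}, \emph{M. sativa}, \emph{C. regalis};
#' open = \emph{M. inodora}, \emph{S. arvensis}.
#'
#' @return A named character vector mapping plant label to `"open"` or
#'   `"tubular"`.
#' @export
#' @examples
#' functional_groups()
functional_groups <- function() {
  c("M. sativa" = "tubular", "C. regalis" = "tubular",
    "L. corniculatus" = "tubular",
    "M. inodora" = "open", "S. arvensis" = "open")
}

# Short-mouthpart morphotypes forage mostly on open corollas; long-mouthpart
# ones reach into tubes. Used by the synthetic generator presets.
short_mouthpart_morphotypes <- function() {
  c("solitary bees", "Coleoptera", "Syrphidae", "other flies", "bugs")
}

long_mouthpart_morphotypes <- function() {
  c("bumblebees", "Lepidoptera", "Apis mellifera", "other Hymenoptera")
}

# order labels canonically, unknown ones appended in first-appearance order
order_labels <- function(found, canonical) {
  extra <- setdiff(found, canonical)
  c(intersect(canonical, found), extra)
}
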