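#' Reproductive-success index of one plant species
#'
#' Pollination requires conspecific pollen, so a visit is most likely to count
#' towards reproduction when the visitor arrives from a flower of the same
#' species (flower constancy). Modelling each visitor group's plant choices as
#' independent draws from its visit distribution P, the probability that a
#' visitor of morphotype p makes two consecutive visits to plant f is
#' P(p, f)^2; scaling by the group's observed visit total V_p gives its
#' expected number of potentially pollinating events. The index for plant f is
#'
#'   R_f = sum over morphotypes p with V_p > 0 of  P(p, f)^2 * V_p
#'       = sum_p A\[f, p\]^2 / V_p.
#'
#' Morphotypes never observed in the web (V_p = 0) contribute 0, so sparse
#' urban webs remain computable. For a perfect specialist on f, R_f = V_p.
#'
#' @param M An `interaction_matrix`.
#' @param plant Plant row label.
#' @return Non-negative real.
#' @export
#' @examples
#' M <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("A", "B"), c("x", "y")))
#' plant_rs_index(M, "A")  # 3^2/4 = 2.25
plant_rs_index <- function(M, plant) {
  if (!plant %in% rownames(M)) stop("unknown plant label: ", plant)
  V <- colSums(M)
  active <- V > 0
  if (!any(active)) return(0)
  sum(as.numeric(M[plant, active])^2 / V[active])
}

#' Reproductive-success index of a floral functional group
#'
#' The group index is the sum of [plant_rs_index()] over the group's member
#' plants, so the two groups partition the community total.
#'
#' @inheritParams plant_rs_index
#' @param groups Named character vector mapping every plant in `M` to
#'   `"open"` or `"tubular"` (default [functional_groups()]).
#' @param group Which group to sum, `"open"` or `"tubular"`.
#' @return Non-negative real.
#' @export
group_rs_index <- function(M, groups = functional_groups(), group) {
  unmapped <- setdiff(rownames(M), names(groups))
  if (length(unmapped) > 0) {
    stop("plant(s) without a functional-group mapping: ",
         paste(unmapped, collapse = ", "))
  }
  members <- rownames(M)[groups[rownames(M)] == group]
  sum(vapply(members, function(f) plant_rs_index(M, f), numeric(1)))
}

#' Full reproductive-success report for one web
#'
#' @inheritParams group_rs_index
#' @return A list of class `rs_report`: `per_plant` (named vector of R_f),
#'   `per_group` (named vector over `"open"`/`"tubular"`), `n_p` (number of
#'   morphotypes with at least one visit) and `provenance`.
#' @export
rs_report <- function(M, groups = functional_groups()) {
  per_plant <- vapply(rownames(M), function(f) plant_rs_index(M, f),
                      numeric(1))
  unmapped <- setdiff(rownames(M), names(groups))
  if (length(unmapped) > 0) {
    message("plant(s) without a functional-group mapping excluded from ",
            "group sums: ", paste(unmapped, collapse = ", "))
  }
  mapped <- intersect(rownames(M), names(groups))
  grp_levels <- unique(unname(groups[mapped]))
  per_group <- vapply(grp_levels, function(g)
    sum(per_plant[mapped[groups[mapped] == g]]), numeric(1))
  names(per_group) <- grp_levels
  structure(list(per_plant = per_plant,
                 per_group = per_group,
                 n_p = sum(colSums(M) > 0),
                 provenance = attr(M, "provenance")),
            class = "rs_report")
}

#' @export
print.rs_report <- function(x, ...) {
  cat("reproductive-success index (", x$n_p, " active morphotypes)\n",
      sep = "")
  print(round(x$per_plant, 3))
  cat("by functional group:\n")
  print(round(x$per_group, 3))
  invisible(x)
}
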