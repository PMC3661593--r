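#' Read a table of flower-visitation records
#'
#' Parses a delimited text file in which each row is one observation cell: the
#' number of visits by one insect morphotype on one plant species during one
#' 10-minute observation session (site x round x plot). Required columns:
#' `site_id`, `landscape_context`, `round`, `plot_id`, `spatial_config`,
#' `plant_species`, `insect_morphotype`, `visit_count`; `flowering_quality`
#' (an integer indicator of per-species flowering state, 0--6) is optional and
#' carried through unmodified.
#'
#' Label columns are validated softly: plant, morphotype, landscape-context or
#' spatial-configuration values outside the canonical sets are accepted and
#' reported via a message, so pooled or ad-hoc datasets remain readable.
#' Numeric fields are validated strictly.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, `","` (default) or `"\t"`.
#' @return A `data.frame` of validated visitation records, one row per
#'   observation cell.
#' @export
#' @examples
#' f <- system.file("extdata", "overall_morphotype_totals.csv",
#'                  package = "pollweb")
#' recs <- read_visitation_table(f)
#' sum(recs$visit_count)
read_visitation_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("visitation file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          quote = "\"", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("site_id", "landscape_context", "round", "plot_id",
                "spatial_config", "plant_species", "insect_morphotype",
                "visit_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("visitation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  # drop rows with missing required fields, with a message
  complete <- stats::complete.cases(df[required])
  if (any(!complete)) {
    message("dropping ", sum(!complete),
            " row(s) with missing required fields")
    df <- df[complete, , drop = FALSE]
  }

  vc <- suppressWarnings(as.numeric(df$visit_count))
  bad <- which(is.na(vc) | vc < 0 | vc != round(vc))
  if (length(bad) > 0) {
    stop("visit_count must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df$visit_count <- as.integer(vc)

  rnd <- suppressWarnings(as.numeric(df$round))
  if (any(is.na(rnd) | rnd < 1 | rnd != round(rnd))) {
    stop("round must be a positive integer")
  }
  df$round <- as.integer(rnd)

  if ("flowering_quality" %in% names(df)) {
    fq <- suppressWarnings(as.numeric(df$flowering_quality))
    ok <- is.na(fq) | (fq >= 0 & fq <= 6 & fq == round(fq))
    if (!all(ok)) {
      stop("flowering_quality must be an integer in [0, 6] when present")
    }
    df$flowering_quality <- as.integer(fq)
  }

  report_unknown(df$plant_species, plant_labels(), "plant species")
  report_unknown(df$insect_morphotype, morphotype_labels(),
                 "insect morphotype")
  report_unknown(df$landscape_context, landscape_contexts(),
                 "landscape context")
  report_unknown(df$spatial_config, c("systematic", "random"),
                 "spatial configuration")
  rownames(df) <- NULL
  df
}

report_unknown <- function(values, canonical, what) {
  unknown <- setdiff(unique(values), canonical)
  if (length(unknown) > 0) {
    message("non-canonical ", what, " label(s) accepted: ",
            paste(unknown, collapse = ", "))
  }
  invisible(unknown)
}

#' Read site metadata
#'
#' @param path Path to a delimited file with columns `site_id`,
#'   `landscape_context`, `x`, `y` (planar coordinates in metres).
#' @param delimiter Field separator, `","` (default) or `"\t"`.
#' @return A `data.frame` with one row per site.
#' @export
read_sites_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("sites file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("site_id", "landscape_context", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("sites table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$site_id)) stop("site_id values must be unique")
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    stop("site coordinates x, y must be numeric")
  }
  df
}

#' Construct a quantitative interaction matrix for one web
#'
#' Aggregates visitation records of one site and one plot spatial
#' configuration into a plant x morphotype count matrix A, cumulated over all
#' observation rounds and over the plots sharing that configuration. Cell
#' A\[i, j\] is the total number of visits of morphotype j recorded on plant i.
#' Cumulation over rounds removes the effect of asynchronous flowering phases.
#'
#' Rows and columns always span the full canonical label sets (plus any
#' non-canonical labels present in the selection), so webs from the same study
#' share dimensions; all-zero rows/columns are meaningful and preserved.
#'
#' @param records Visitation records (`data.frame` as returned by
#'   [read_visitation_table()]).
#' @param site_id Site to select.
#' @param spatial_config Plot spatial configuration to select (e.g.
#'   `"systematic"` or `"random"`).
#' @return An object of class `interaction_matrix`: an integer matrix with
#'   plant rows and morphotype columns and a `provenance` attribute
#'   (`site_id`, `spatial_config`, `rounds`, `landscape_context`).
#' @export
build_interaction_matrix <- function(records, site_id, spatial_config) {
  sel <- records[records$site_id == site_id &
                 records$spatial_config == spatial_config, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no visitation records match site '", site_id,
         "' with spatial configuration '", spatial_config, "'")
  }
  plants <- order_labels(union(plant_labels(), unique(sel$plant_species)),
                         plant_labels())
  morphs <- order_labels(union(morphotype_labels(),
                               unique(sel$insect_morphotype)),
                         morphotype_labels())
  counts <- matrix(0L, nrow = length(plants), ncol = length(morphs),
                   dimnames = list(plants, morphs))
  agg <- stats::aggregate(visit_count ~ plant_species + insect_morphotype,
                          data = sel, FUN = sum)
  counts[cbind(agg$plant_species, agg$insect_morphotype)] <-
    as.integer(agg$visit_count)
  new_interaction_matrix(counts,
                         site_id = site_id,
                         spatial_config = spatial_config,
                         rounds = sort(unique(sel$round)),
                         landscape_context = unique(sel$landscape_context)[1])
}

new_interaction_matrix <- function(counts, site_id, spatial_config, rounds,
                                   landscape_context = NA_character_) {
  stopifnot(is.matrix(counts), all(counts >= 0), all(counts == round(counts)))
  storage.mode(counts) <- "integer"
  structure(counts,
            provenance = list(site_id = site_id,
                              spatial_config = spatial_config,
                              rounds = rounds,
                              landscape_context = landscape_context),
            class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("interaction matrix: %d plants x %d morphotypes, %d visits\n",
              nrow(x), ncol(x), sum(x)))
  cat(sprintf("  site %s | %s plots | rounds %s | context %s\n",
              p$site_id, p$spatial_config,
              paste(p$rounds, collapse = ","),
              p$landscape_context))
  print(unclass(x), ...)
  invisible(x)
}

#' Build all cumulated webs of a study
#'
#' One interaction matrix is built for every (site x spatial configuration)
#' pair present in the records: the full twelve-site, two-configuration design
#' yields 24 webs. Sites listed in `sites` but absent from the records are
#' skipped with a message.
#'
#' @param records Visitation records.
#' @param sites Optional site metadata (`data.frame` from
#'   [read_sites_table()]); defaults to the sites present in `records`.
#' @return A named list of `interaction_matrix` objects; names are
#'   `"<site_id>:<spatial_config>"`.
#' @export
build_all_networks <- function(records, sites = NULL) {
  site_ids <- if (is.null(sites)) unique(records$site_id) else sites$site_id
  pairs <- unique(records[records$site_id %in% site_ids,
                          c("site_id", "spatial_config")])
  absent <- setdiff(site_ids, pairs$site_id)
  if (length(absent) > 0) {
    message("no records for site(s): ", paste(absent, collapse = ", "))
  }
  pairs <- pairs[order(match(pairs$site_id, site_ids), pairs$spatial_config), ,
                 drop = FALSE]
  webs <- Map(function(s, cfg) build_interaction_matrix(records, s, cfg),
              pairs$site_id, pairs$spatial_config)
  names(webs) <- paste(pairs$site_id, pairs$spatial_config, sep = ":")
  webs
}

#' Write / read an interaction matrix as TSV
#'
#' The on-disk format is a tab-separated table (first row = morphotype
#' labels, first column = plant labels) preceded by `#`-prefixed provenance
#' header lines. The round-trip is lossless for labels, counts and
#' provenance.
#'
#' @param M An `interaction_matrix`.
#' @param path Output (or input) file path.
#' @return `write_matrix` invisibly returns `path`; `read_matrix` returns an
#'   `interaction_matrix`.
#' @export
write_matrix <- function(M, path) {
  stopifnot(inherits(M, "interaction_matrix"))
  p <- attr(M, "provenance")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# site_id=", p$site_id),
    paste0("# spatial_config=", p$spatial_config),
    paste0("# rounds=", paste(p$rounds, collapse = ",")),
    paste0("# landscape_context=", p$landscape_context)
  ), con)
  writeLines(paste(c("plant", colnames(M)), collapse = "\t"), con)
  for (i in seq_len(nrow(M))) {
    writeLines(paste(c(rownames(M)[i], M[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(site_id = NA_character_, spatial_config = NA_character_,
               rounds = integer(0), landscape_context = NA_character_)
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "rounds") {
      meta$rounds <- as.integer(strsplit(val, ",")[[1]])
    } else if (key %in% names(meta)) {
      meta[[key]] <- if (identical(val, "NA")) NA_character_ else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2) stop("matrix file has no data rows: ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  if (any(vapply(fields, length, 1L) != ncols)) {
    stop("matrix file is ragged (label/dimension mismatch): ", path)
  }
  morphs <- fields[[1]][-1]
  plants <- vapply(fields[-1], `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(fields[-1], function(f) as.numeric(f[-1]), numeric(ncols - 1L)))
  counts <- t(matrix(vals, nrow = ncols - 1L))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("matrix file contains non-count entries: ", path)
  }
  dimnames(counts) <- list(plants, morphs)
  new_interaction_matrix(counts, site_id = meta$site_id,
                         spatial_config = meta$spatial_config,
                         rounds = meta$rounds,
                         landscape_context = meta$landscape_context)
}
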