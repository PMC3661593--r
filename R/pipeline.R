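#' Run the full network-analysis pipeline
#'
#' Orchestrates the whole analysis: load (or generate) visitation records,
#' cumulate them into one web per site x spatial configuration, compute
#' network indices, per-morphotype generalism, the reproductive-success index,
#' per-morphotype plant x context chi-squared homogeneity tests, the Mantel
#' spatial-autocorrelation check (geographic distance vs Bray-Curtis
#' dissimilarity of per-site morphotype visit totals), and permutation
#' comparisons of per-web metrics across landscape contexts. All reports are
#' plain delimited text; a JSON manifest records the seed and row counts.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config A list with exactly one of:
#'   \describe{
#'     \item{`input`}{list(`records_path`, `sites_path`, optional
#'       `delimiter`) — analyse existing CSV files.}
#'     \item{`generator`}{a `generator_config` from [default_presets()] —
#'       simulate the study first.}
#'   }
#'   plus optional `groups` (plant functional-group map, default
#'   [functional_groups()]), `n_perm` (default 999), `seed` (default 1) and
#'   `out_dir` (default `tempfile("pollweb_run")`).
#' @return Invisibly, a list with all result tables (`webs`,
#'   `network_summary`, `generalism`, `rs`, `chi_squared`, `mantel`,
#'   `context_comparisons`, `by_context`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen) {
    stop("config error: exactly one of 'input' or 'generator' must be set")
  }
  groups <- config$groups %||% functional_groups()
  n_perm <- config$n_perm %||% 999L
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("pollweb_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (has_gen) {
    message("stage generate: simulating study (seed ", config$generator$seed,
            ")")
    study <- generate_study(config$generator)
    records <- study$records
    sites <- study$sites
  } else {
    delim <- config$input$delimiter %||% ","
    records <- read_visitation_table(config$input$records_path, delim)
    sites <- if (!is.null(config$input$sites_path)) {
      read_sites_table(config$input$sites_path, delim)
    } else NULL
  }
  message("stage ingest: ", nrow(records), " visitation records, ",
          sum(records$visit_count), " interactions")

  webs <- build_all_networks(records, sites)
  message("stage webs: ", length(webs), " cumulated interaction matrices")

  net_tab <- do.call(rbind, lapply(webs, network_summary))
  rownames(net_tab) <- NULL
  gen_tab <- do.call(rbind, lapply(webs, function(M)
    suppressMessages(generalism_table(M))))
  rownames(gen_tab) <- NULL
  rs_tab <- do.call(rbind, lapply(webs, function(M) {
    rep <- rs_report(M, groups)
    p <- attr(M, "provenance")
    data.frame(site_id = p$site_id, spatial_config = p$spatial_config,
               landscape_context = p$landscape_context,
               plant_or_group = c(names(rep$per_plant), names(rep$per_group)),
               level = c(rep("plant", length(rep$per_plant)),
                         rep("group", length(rep$per_group))),
               rs_index = c(rep$per_plant, rep$per_group),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(rs_tab) <- NULL

  chi_tab <- chi_squared_by_morphotype(records)
  mantel_res <- pipeline_mantel(records, sites, n_perm, seed)

  multi_ctx <- length(unique(net_tab$landscape_context)) >= 2 &&
    all(table(net_tab$landscape_context) >= 2)
  cmp_tab <- if (multi_ctx) {
    cbind(metric = "total_interactions",
          permutation_context_compare(net_tab$total_interactions,
                                      net_tab$landscape_context,
                                      n_perm = n_perm, seed = seed))
  } else {
    message("stage compare: skipped (needs >= 2 contexts with >= 2 webs)")
    NULL
  }
  by_ctx <- summarize_by_context(net_tab, "total_interactions")

  write_tsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  write_tsv(net_tab, "network_summary.tsv")
  write_tsv(gen_tab, "generalism.tsv")
  write_tsv(rs_tab, "rs_index.tsv")
  write_tsv(chi_tab, "chi_squared.tsv")
  write_tsv(cmp_tab, "context_comparisons.tsv")
  write_tsv(by_ctx, "summary_by_context.tsv")
  if (!is.null(mantel_res)) {
    write_tsv(data.frame(test = "mantel", statistic = mantel_res$statistic,
                         p_value = mantel_res$p_value,
                         n_perm = mantel_res$n_perm,
                         exact = mantel_res$exact, seed = seed),
              "mantel.tsv")
  }
  manifest <- list(package = "pollweb",
                   version = as.character(utils::packageVersion("pollweb")),
                   seed = seed, n_perm = n_perm,
                   n_records = nrow(records),
                   n_interactions = sum(records$visit_count),
                   n_webs = length(webs),
                   tables = list(network_summary = nrow(net_tab),
                                 generalism = nrow(gen_tab),
                                 rs_index = nrow(rs_tab),
                                 chi_squared = nrowz(chi_tab),
                                 context_comparisons = nrowz(cmp_tab)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("stage report: tables written to ", out_dir)
  invisible(list(webs = webs, network_summary = net_tab,
                 generalism = gen_tab, rs = rs_tab, chi_squared = chi_tab,
                 mantel = mantel_res, context_comparisons = cmp_tab,
                 by_context = by_ctx, out_dir = out_dir))
}

nrowz <- function(x) if (is.null(x)) 0L else nrow(x)

# per-morphotype plant x landscape-context homogeneity tests on pooled counts
chi_squared_by_morphotype <- function(records) {
  morphs <- order_labels(unique(records$insect_morphotype),
                         morphotype_labels())
  out <- lapply(morphs, function(m) {
    sel <- records[records$insect_morphotype == m, , drop = FALSE]
    tab <- stats::xtabs(visit_count ~ plant_species + landscape_context,
                        data = sel)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      message("chi-squared skipped for ", m,
              " (degenerate plants x contexts table)")
      return(NULL)
    }
    tr <- pearson_chi_squared(tab)
    data.frame(morphotype = m, statistic = tr$statistic, df = tr$df,
               p_value = tr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

pipeline_mantel <- function(records, sites, n_perm, seed) {
  if (is.null(sites) || nrow(sites) < 4) {
    message("stage mantel: skipped (needs site coordinates for >= 4 sites)")
    return(NULL)
  }
  tab <- stats::xtabs(visit_count ~ site_id + insect_morphotype,
                      data = records)
  tab <- as.matrix(unclass(tab))
  tab <- tab[match(sites$site_id, rownames(tab)), , drop = FALSE]
  keep <- !is.na(rownames(tab)) & rowSums(tab) > 0
  if (sum(keep) < 4) {
    message("stage mantel: skipped (fewer than 4 sites with visits)")
    return(NULL)
  }
  tab <- tab[keep, , drop = FALSE]
  sites <- sites[match(rownames(tab), sites$site_id), ]
  geo <- site_distance_matrix(sites)
  bc <- bray_curtis_matrix(tab)  # dissimilarity = 1 - similarity
  mantel_test(geo, bc, n_perm = n_perm, seed = seed)
}

#' Summarise a per-web metric by landscape context
#'
#' @param per_web_table A `data.frame` with a `landscape_context` column,
#'   e.g. the `network_summary` table of [run_pipeline()].
#' @param metric Name of the numeric column to summarise.
#' @return A `data.frame` with per-context `mean`, `sd` and `n` (webs); empty
#'   groups are excluded with a warning.
#' @export
summarize_by_context <- function(per_web_table, metric) {
  if (!metric %in% names(per_web_table)) {
    stop("no such metric column: ", metric)
  }
  v <- per_web_table[[metric]]
  ctx <- per_web_table$landscape_context
  keep <- !is.na(v) & !is.na(ctx)
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " web(s) with missing ", metric,
            " or context")
  }
  v <- v[keep]; ctx <- ctx[keep]
  ctx_levels <- order_labels(unique(ctx), landscape_contexts())
  data.frame(landscape_context = ctx_levels,
             metric = metric,
             mean = vapply(ctx_levels, function(g) mean(v[ctx == g]),
                           numeric(1)),
             sd = vapply(ctx_levels, function(g) stats::sd(v[ctx == g]),
                         numeric(1)),
             n = vapply(ctx_levels, function(g) sum(ctx == g), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
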