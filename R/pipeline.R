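#' Pipeline run configuration
#'
#' Validates the knobs of a full stability run before any computation.
#'
#' @param input path to the Ct CSV.
#' @param layout `"long"` or `"wide"`.
#' @param group_map group-map CSV path (wide layout only).
#' @param methods subset of `delta_ct`, `genorm`, `normfinder`,
#'   `bestkeeper` (default: all four).
#' @param efficiency_table optional path to a TSV/CSV with columns
#'   `gene`, `efficiency_percent` used for the relative-quantity
#'   transform.
#' @param aggregate collapse replicate measurements by this statistic
#'   before analysis (`"mean"`, `"median"`, or `"none"` to treat
#'   replicates as independent samples).
#' @param grouped use the grouped NormFinder model.
#' @param dispersion BestKeeper dispersion estimator.
#' @param v_threshold geNorm pairwise-variation cutoff.
#' @param out output directory (created on run) or `NULL` for no files.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(input, layout = "long", group_map = NULL,
                       methods = c("delta_ct", "genorm", "normfinder",
                                   "bestkeeper"),
                       efficiency_table = NULL,
                       aggregate = c("mean", "median", "none"),
                       grouped = TRUE,
                       dispersion = "sample_sd",
                       v_threshold = 0.15,
                       out = NULL) {
  aggregate <- match.arg(aggregate)
  known <- c("delta_ct", "genorm", "normfinder", "bestkeeper")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(known, collapse = ", "), ")")
  if (!length(methods)) stop("at least one method required")
  for (p in c(input, group_map, efficiency_table))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  if (!layout %in% c("long", "wide")) stop("unknown layout: ", layout)
  structure(list(input = input, layout = layout, group_map = group_map,
                 methods = methods, efficiency_table = efficiency_table,
                 aggregate = aggregate, grouped = grouped,
                 dispersion = dispersion, v_threshold = v_threshold,
                 out = out),
            class = "run_config")
}

#' Run the full stability pipeline
#'
#' read -> (aggregate replicates) -> relative-quantity transform -> the
#' selected stability methods -> geometric-mean consensus. When
#' `config$out` is set, writes one `<method>.tsv` per method (gene,
#' stability, rank), `genorm_v.tsv` (n, V, below_threshold),
#' `consensus.tsv`, and a machine-readable `report.json`.
#'
#' @param config a [run_config()].
#' @return report bundle (class `stability_bundle`): `ct`, `results`
#'   (named list of [stability_result()]), `consensus`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t <- read_ct_table(config$input, layout = config$layout,
                     group_map = config$group_map)
  if (config$aggregate != "none" && !is.null(t$replicate_of) &&
      anyDuplicated(t$replicate_of))
    t <- aggregate_replicates(t, how = config$aggregate)
  eff <- NULL
  if (!is.null(config$efficiency_table)) {
    ef <- utils::read.delim(config$efficiency_table, sep = "",
                            stringsAsFactors = FALSE)
    if (!all(c("gene", "efficiency_percent") %in% names(ef)))
      stop("efficiency table needs columns gene, efficiency_percent")
    eff <- stats::setNames(ef$efficiency_percent, ef$gene)
  }
  results <- list()
  for (m in config$methods) {
    results[[m]] <- switch(m,
      delta_ct = delta_ct_stability(t),
      genorm = genorm(to_relative_quantities(t, efficiencies = eff),
                      v_threshold = config$v_threshold),
      normfinder = normfinder(t, use_groups = config$grouped,
                              efficiencies = eff),
      bestkeeper = bestkeeper(t, dispersion = config$dispersion))
  }
  consensus <- if (length(results) >= 2L)
    geomean_consensus(build_rank_table(results)) else NULL
  bundle <- structure(list(ct = t, results = results,
                           consensus = consensus, config = config),
                      class = "stability_bundle")
  if (!is.null(config$out)) write_bundle(bundle, config$out)
  bundle
}

write_bundle <- function(bundle, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (m in names(bundle$results)) {
    r <- bundle$results[[m]]
    ord <- order(r$ranks, names(r$values))
    utils::write.table(
      data.frame(gene = names(r$values)[ord],
                 stability = unname(r$values[ord]),
                 rank = unname(r$ranks[ord])),
      file.path(out, paste0(m, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("genorm" %in% names(bundle$results)) {
    d <- bundle$results$genorm$details
    vs <- d$v_series
    utils::write.table(
      data.frame(n = sub("V(\\d+)/.*", "\\1", names(vs)), v = unname(vs),
                 below_threshold = unname(vs < d$v_threshold)),
      file.path(out, "genorm_v.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$consensus)) {
    cs <- bundle$consensus
    tab <- cs$rank_table[cs$ordering, , drop = FALSE]
    colnames(tab) <- paste0("rank_", colnames(tab))
    utils::write.table(
      data.frame(gene = cs$ordering, tab,
                 geomean = unname(cs$geomean[cs$ordering]),
                 overall_rank = unname(cs$overall_rank[cs$ordering]),
                 row.names = NULL),
      file.path(out, "consensus.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    n_genes = nrow(bundle$ct$ct), n_samples = ncol(bundle$ct$ct),
    groups = as.list(table(bundle$ct$groups)),
    warnings = bundle$ct$meta$warnings,
    methods = lapply(bundle$results, function(r)
      list(values = as.list(r$values), ranks = as.list(r$ranks))),
    recommended_pair = bundle$consensus$recommended_pair)
  if ("genorm" %in% names(bundle$results)) {
    d <- bundle$results$genorm$details
    report$genorm <- list(v_series = as.list(d$v_series),
                          v_threshold = d$v_threshold,
                          n_recommended = d$n_recommended,
                          elimination_order = d$elimination_order,
                          final_pair = d$final_pair)
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Render a plain-text summary of a pipeline run
#'
#' @param bundle a `stability_bundle` from [run_pipeline()].
#' @return character vector of report lines (also usable with
#'   `writeLines`).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "stability_bundle"))
  if (!length(bundle$results)) stop("bundle contains no method results")
  lines <- c("Reference-gene stability report",
             sprintf("%d genes x %d samples; groups: %s",
                     nrow(bundle$ct$ct), ncol(bundle$ct$ct),
                     paste(unique(bundle$ct$groups), collapse = ", ")), "")
  for (m in names(bundle$results)) {
    r <- bundle$results[[m]]
    ord <- order(r$ranks, names(r$values))
    lines <- c(lines, sprintf("[%s]", m),
               sprintf("  %-8s %8.4f  rank %d", names(r$values)[ord],
                       r$values[ord], r$ranks[ord]), "")
    if (anyDuplicated(r$ranks))
      lines <- c(lines, "  (ties present; dense ranking, documented",
                 "   tie-breaks applied)", "")
  }
  if ("genorm" %in% names(bundle$results)) {
    d <- bundle$results$genorm$details
    lines <- c(lines, "[geNorm pairwise variation]",
               sprintf("  %s = %.4f (%s %.2f)", names(d$v_series),
                       d$v_series,
                       ifelse(d$v_series < d$v_threshold, "<", ">="),
                       d$v_threshold),
               if (!is.na(d$n_recommended))
                 sprintf("  => %d reference genes suffice", d$n_recommended)
               else "  => no n below the threshold; use more genes",
               "")
  }
  if (!is.null(bundle$consensus)) {
    cs <- bundle$consensus
    lines <- c(lines, "[consensus: geometric mean of ranks]",
               sprintf("  %-8s geomean %.3f  overall rank %d",
                       cs$ordering, cs$geomean[cs$ordering],
                       cs$overall_rank[cs$ordering]),
               sprintf("recommended pair: %s",
                       paste(cs$recommended_pair, collapse = " + ")))
  }
  lines
}
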