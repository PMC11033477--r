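#' Ct table: the universal qPCR input container
#'
#' A `ct_table` holds a genes x samples matrix of cycle-threshold (Ct)
#' values together with a group (condition level) label per sample and,
#' optionally, a biological-replicate map. It is the input to every
#' stability method in the package.
#'
#' @param ct numeric matrix, genes in rows, samples in columns, with
#'   dimnames. Missing measurements are `NA`; all non-missing values must
#'   lie in (0, 45] cycles.
#' @param groups character vector of group labels, one per sample, named
#'   by sample or in column order.
#' @param replicate_of optional character vector mapping each sample
#'   (column) to the biological unit it measures; samples sharing a value
#'   are replicates of one unit.
#' @param meta free-form provenance list (condition name, source file,
#'   accumulated warnings).
#'
#' @return An object of class `ct_table` with fields `ct`, `groups`,
#'   `replicate_of`, `meta`.
#' @export
#' @examples
#' m <- rbind(A = c(20, 21), B = c(22, 23))
#' colnames(m) <- c("s1", "s2")
#' ct_table(m, groups = c(s1 = "g1", s2 = "g1"))
ct_table <- function(ct, groups, replicate_of = NULL, meta = list()) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene rownames and sample colnames")
  if (nrow(ct) < 2L || ncol(ct) < 2L)
    stop("a ct_table needs at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  bad <- !is.na(ct) & (ct <= 0 | ct > 45)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "Ct value %g for gene %s, sample %s outside (0, 45] cycles",
      ct[bad][1L], rownames(ct)[i[1L]], colnames(ct)[i[2L]]))
  }
  groups <- resolve_per_sample(groups, colnames(ct), "groups")
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("every sample needs exactly one non-empty group label")
  if (!is.null(replicate_of))
    replicate_of <- resolve_per_sample(replicate_of, colnames(ct), "replicate_of")
  structure(list(ct = ct, groups = groups, replicate_of = replicate_of,
                 meta = meta),
            class = "ct_table")
}

# align a per-sample vector with the sample order, by name when named
resolve_per_sample <- function(x, samples, what) {
  x <- as.character(stats::setNames(x, names(x)))
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing))
      stop(sprintf("`%s` lacks entries for samples: %s",
                   what, paste(missing, collapse = ", ")))
    x <- x[samples]
  } else {
    if (length(x) != length(samples))
      stop(sprintf("`%s` must have one entry per sample", what))
    names(x) <- samples
  }
  x
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d genes x %d samples, %d group(s)\n",
              nrow(x$ct), ncol(x$ct), length(unique(x$groups))))
  cat("genes:  ", paste(rownames(x$ct), collapse = ", "), "\n")
  cat("groups: ", paste(unique(x$groups), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$ct))
  if (nmiss) cat("missing cells:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

#' Read a Ct table from CSV
#'
#' Two layouts are supported. `long`: one measurement per row with header
#' columns `sample, group, gene, replicate, ct`. `wide`: genes in rows
#' (first column `gene`), samples in columns, plus a separate group map
#' CSV with columns `sample, group`. Files are comma-separated UTF-8 with
#' a header row and dot decimal separator.
#'
#' In the long layout, when a sample carries several replicate
#' measurements, each (sample, replicate) pair becomes its own column
#' named `<sample>.<replicate>` and `replicate_of` records the parent
#' sample, so [aggregate_replicates()] can collapse them later.
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @param group_map for `layout = "wide"`: path to a `sample, group` CSV,
#'   or a named character vector of group labels.
#' @return A validated [ct_table()]. Cells absent from a long file are
#'   recorded as missing.
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), group_map = NULL) {
  layout <- match.arg(layout)
  if (layout == "long") read_ct_long(path) else read_ct_wide(path, group_map)
}

read_ct_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("long layout requires columns: ", paste(need, collapse = ", "),
         " (missing: ", paste(setdiff(need, names(df)), collapse = ", "), ")")
  key <- paste(df$gene, df$sample, df$replicate, sep = " / ")
  if (anyDuplicated(key))
    stop("duplicate record for (gene, sample, replicate) = (",
         key[duplicated(key)][1L], ")")
  ctv <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ctv) & nzchar(df$ct) & !toupper(df$ct) %in% c("NA", ""))
  if (length(bad))
    stop(sprintf("non-numeric ct value '%s' at data row %d", df$ct[bad[1L]],
                 bad[1L]))
  out <- which(!is.na(ctv) & (ctv <= 0 | ctv > 45))
  if (length(out))
    stop(sprintf(
      "ct value %g at data row %d outside the (0, 45] cycle contract",
      ctv[out[1L]], out[1L]))
  # one column per (sample, replicate); plain sample name if unambiguous
  multi <- tapply(df$replicate, df$sample,
                  function(r) length(unique(r)) > 1L)
  col_id <- ifelse(multi[df$sample], paste(df$sample, df$replicate, sep = "."),
                   df$sample)
  genes <- unique(df$gene)
  cols <- unique(col_id)
  m <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, cols))
  m[cbind(match(df$gene, genes), match(col_id, cols))] <- ctv
  grp <- df$group[match(cols, col_id)]
  conflict <- tapply(df$group, col_id, function(g) length(unique(g)) > 1L)
  if (any(conflict))
    stop("sample with conflicting group labels: ",
         names(conflict)[conflict][1L])
  rep_of <- df$sample[match(cols, col_id)]
  ct_table(m, groups = stats::setNames(grp, cols),
           replicate_of = stats::setNames(rep_of, cols),
           meta = list(source = path, layout = "long"))
}

read_ct_wide <- function(path, group_map) {
  if (is.null(group_map))
    stop("wide layout requires a `group_map` (CSV path or named vector)")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene")
    stop("wide layout requires the first column to be named 'gene'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  if (is.character(group_map) && length(group_map) == 1L &&
      is.null(names(group_map)) && file.exists(group_map)) {
    gm <- utils::read.csv(group_map, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(gm)))
      stop("group map CSV needs columns sample, group")
    group_map <- stats::setNames(gm$group, gm$sample)
  }
  ct_table(m, groups = group_map,
           meta = list(source = path, layout = "wide"))
}

#' Write a Ct table as a wide CSV
#'
#' Writes the genes x samples matrix with a leading `gene` column, and
#' optionally the sample -> group map next to it.
#'
#' @param t a [ct_table()].
#' @param path output CSV path.
#' @param group_path optional path for a `sample, group` CSV.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(t, path, group_path = NULL) {
  stopifnot(inherits(t, "ct_table"))
  df <- data.frame(gene = rownames(t$ct), t$ct, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(group_path))
    utils::write.csv(data.frame(sample = names(t$groups), group = t$groups),
                     group_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse replicate measurements into one column per biological unit
#'
#' Samples sharing a `replicate_of` value are averaged gene-wise.
#' Missing values are ignored; a unit with no usable measurement for some
#' gene keeps a missing cell and the event is recorded in
#' `meta$warnings`.
#'
#' @param t a [ct_table()] with `replicate_of` set.
#' @param how `"mean"` (default) or `"median"`.
#' @return A [ct_table()] with one column per biological unit; the
#'   replicate count per unit is kept in `meta$n_replicates`.
#' @export
aggregate_replicates <- function(t, how = c("mean", "median")) {
  stopifnot(inherits(t, "ct_table"))
  how <- match.arg(how)
  if (is.null(t$replicate_of))
    stop("`replicate_of` is not set; nothing to aggregate")
  units <- unique(t$replicate_of)
  for (u in units) {
    g <- unique(t$groups[t$replicate_of == u])
    if (length(g) > 1L)
      stop(sprintf("replicates of unit %s span several groups: %s",
                   u, paste(g, collapse = ", ")))
  }
  fun <- if (how == "mean") mean else stats::median
  agg <- sapply(units, function(u) {
    cols <- t$ct[, t$replicate_of == u, drop = FALSE]
    apply(cols, 1L, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_real_ else fun(x)
    })
  })
  agg <- matrix(agg, nrow = nrow(t$ct),
                dimnames = list(rownames(t$ct), units))
  warnings <- t$meta$warnings
  if (anyNA(agg)) {
    idx <- which(is.na(agg), arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      warnings <- c(warnings, sprintf(
        "no non-missing Ct for gene %s in unit %s; cell left missing",
        rownames(agg)[idx[r, 1L]], colnames(agg)[idx[r, 2L]]))
  }
  meta <- t$meta
  meta$warnings <- warnings
  meta$n_replicates <- stats::setNames(
    as.integer(table(t$replicate_of)[units]), units)
  meta$aggregated <- how
  ct_table(agg, groups = stats::setNames(
    t$groups[match(units, t$replicate_of)], units), meta = meta)
}
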