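#' Stability results
#'
#' All four stability methods return a `stability_result`: per-gene
#' stability values (lower = more stable for every method), dense ranks
#' (1 = most stable; ties share a rank, no gaps), and a method-specific
#' `details` payload.
#'
#' @param method one of `delta_ct`, `genorm`, `normfinder`, `bestkeeper`.
#' @param values named numeric vector of per-gene stability values.
#' @param details method-specific list.
#' @param ranks optional named integer ranks; computed by dense ranking
#'   of `values` when omitted.
#' @return object of class `stability_result`.
#' @export
stability_result <- function(method, values, details = list(), ranks = NULL) {
  stopifnot(method %in% c("delta_ct", "genorm", "normfinder", "bestkeeper"),
            is.numeric(values), !is.null(names(values)))
  if (any(values < 0 & abs(values) > 1e-12))
    stop("stability values must be non-negative")
  values[values < 0] <- 0
  if (is.null(ranks)) ranks <- dense_rank(values)
  stopifnot(identical(sort(names(ranks)), sort(names(values))))
  structure(list(method = method, values = values,
                 ranks = ranks[names(values)], details = details),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  ord <- order(x$ranks, names(x$values))
  cat(sprintf("stability_result [%s] (lower = more stable)\n", x$method))
  print(data.frame(gene = names(x$values)[ord],
                   stability = round(unname(x$values[ord]), 4L),
                   rank = unname(x$ranks[ord])), row.names = FALSE)
  invisible(x)
}

# sample SD of pairwise Ct differences, pairwise-complete samples.
# Returns K x K symmetric matrix (diagonal NA); entries with < 2 complete
# samples are NA.
pairwise_diff_sd <- function(ct) {
  k <- nrow(ct)
  v <- matrix(NA_real_, k, k, dimnames = list(rownames(ct), rownames(ct)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- ct[i, ] - ct[j, ]
    d <- d[!is.na(d)]
    if (length(d) >= 2L) v[i, j] <- v[j, i] <- stats::sd(d)
  }
  v
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair the per-sample Ct differences are formed
#' and their sample standard deviation (n - 1 denominator) taken; a
#' gene's stability is the mean of these SDs over all partners. Stable
#' genes co-vary with every other candidate, so their pairwise
#' differences have low spread. Per-sample loading shifts cancel in the
#' differences.
#'
#' @param t a [ct_table()].
#' @return [stability_result()] with `details$pairwise_sd`, the full
#'   K x K matrix of pairwise difference SDs.
#' @export
delta_ct_stability <- function(t) {
  stopifnot(inherits(t, "ct_table"))
  ct <- t$ct
  if (nrow(ct) < 2L) stop("delta-Ct method needs at least 2 genes")
  v <- pairwise_diff_sd(ct)
  dropped <- sum(is.na(v[upper.tri(v)]))
  if (dropped > 0L)
    warning(dropped, " gene pair(s) had < 2 complete samples and were excluded")
  values <- rowMeans(v, na.rm = TRUE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("gene with no valid partner pair: ",
         paste(names(values)[!is.finite(values)], collapse = ", "))
  stability_result("delta_ct", values, details = list(pairwise_sd = v))
}

#' geNorm stability (M-values, stepwise elimination, pairwise variation V)
#'
#' Works on relative quantities. The pairwise variation of genes i and k
#' is the sample SD of `log2(q_i / q_k)` across samples; a gene's M is
#' the mean of its pairwise variations with all remaining candidates.
#' The gene with the largest M is removed and M recomputed until two
#' genes remain; these two can never be separated and share rank 1 with
#' identical reported M (their mutual variation in the final 2-gene
#' panel). Each other gene's reported value is its M at the step of its
#' elimination; ties for the largest M are broken by removing the
#' lexicographically last gene id.
#'
#' The V series guides how many reference genes are needed: `NF_n` is
#' the per-sample geometric mean of the n most stable genes' quantities
#' and `V_{n/n+1}` the sample SD of `log2(NF_n / NF_{n+1})`. The first n
#' (minimum 2) with V below 0.15 is reported as sufficient.
#'
#' @param rq an `rq_table` from [to_relative_quantities()].
#' @param v_threshold pairwise-variation cutoff, conventionally 0.15.
#' @return [stability_result()]; `details` is a `genorm_detail` list with
#'   `initial_m`, `stepwise_m`, `elimination_order`, `final_pair`,
#'   `v_series`, `v_threshold`, `n_recommended`.
#' @export
genorm <- function(rq, v_threshold = 0.15) {
  stopifnot(inherits(rq, "rq_table"))
  q <- rq$q
  if (any(!is.na(q) & q <= 0)) stop("relative quantities must be positive")
  if (nrow(q) < 2L) stop("geNorm needs at least 2 genes")
  lq <- log2(q)
  m_values <- function(mat) {
    v <- pairwise_diff_sd(mat)   # sd(log2 qi - log2 qk) = sd(log2(qi/qk))
    rowMeans(v, na.rm = TRUE)
  }
  initial_m <- m_values(lq)
  panel <- rownames(q)
  elimination_order <- character(0)
  reported <- stats::setNames(numeric(nrow(q)), rownames(q))
  stepwise_m <- list()
  while (length(panel) > 2L) {
    m <- m_values(lq[panel, , drop = FALSE])
    stepwise_m[[length(stepwise_m) + 1L]] <- m
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]   # lexicographically last on ties
    reported[worst] <- m[worst]
    elimination_order <- c(elimination_order, worst)
    panel <- setdiff(panel, worst)
  }
  final_m <- m_values(lq[panel, , drop = FALSE])
  stepwise_m[[length(stepwise_m) + 1L]] <- final_m
  reported[panel] <- final_m          # mutual V, identical for both
  ranks <- dense_rank(reported)
  stability_order <- names(reported)[order(reported, names(reported))]
  v_series <- genorm_v_series(q, stability_order)
  n_rec <- if (length(v_series)) {
    below <- which(v_series < v_threshold)
    if (length(below))
      max(2L, as.integer(sub("V(\\d+)/.*", "\\1", names(below)[1L])))
    else NA_integer_
  } else NA_integer_
  details <- structure(list(
    initial_m = initial_m,
    stepwise_m = stepwise_m,
    elimination_order = elimination_order,
    final_pair = sort(panel),
    v_series = v_series,
    v_threshold = v_threshold,
    n_recommended = n_rec), class = "genorm_detail")
  stability_result("genorm", reported, details = details, ranks = ranks)
}

# V_{n/n+1} for n = 2..K-1 over the stability-ordered gene list
genorm_v_series <- function(q, stability_order) {
  k <- length(stability_order)
  if (k < 3L) return(stats::setNames(numeric(0), character(0)))
  lq <- log2(q[stability_order, , drop = FALSE])
  nf_log <- function(n) colMeans(lq[seq_len(n), , drop = FALSE])  # log2 NF_n
  v <- vapply(2L:(k - 1L), function(n) {
    d <- nf_log(n) - nf_log(n + 1L)
    stats::sd(d[!is.na(d)])
  }, numeric(1))
  stats::setNames(v, paste0("V", 2L:(k - 1L), "/", 3L:k))
}

#' NormFinder model-based stability
#'
#' Works on a log2 expression scale (`y = -Ct * log2(base)`, so the
#' default base-2 assay gives `y = -Ct`). Per-sample means over genes are
#' subtracted first, removing loading differences. Ungrouped mode scores
#' each gene by the sample SD of its centered values. Grouped mode
#' decomposes variation into intragroup variance `s2` and an intergroup
#' deviation `d` per (gene, group); the between-group variance `tau2` is
#' estimated by a method-of-moments step, deviations are shrunk toward 0
#' by `tau2 / (tau2 + s2/n)`, and the stability is the mean over groups
#' of `|d_shrunk| + sqrt(s2/n)` — genes must be both consistent within
#' groups and unbiased between them to score low.
#'
#' @param t a [ct_table()].
#' @param use_groups use the grouped variance model (default when >1
#'   group present). Falls back to ungrouped with a warning if only one
#'   group exists.
#' @param efficiencies optional per-gene efficiencies in percent, giving
#'   per-gene bases as in [to_relative_quantities()].
#' @return [stability_result()]; `details` is a `normfinder_detail` list
#'   with `grouped`, `z` (centered matrix), and in grouped mode
#'   `group_means`, `group_vars`, `d_raw`, `d_shrunk`, `tau2`.
#' @export
normfinder <- function(t, use_groups = TRUE, efficiencies = NULL) {
  stopifnot(inherits(t, "ct_table"))
  ct <- t$ct
  if (nrow(ct) < 3L)
    stop("NormFinder needs at least 3 genes for sample centering")
  base <- if (is.null(efficiencies)) {
    stats::setNames(rep(2, nrow(ct)), rownames(ct))
  } else 1 + resolve_per_gene(efficiencies, rownames(ct)) / 100
  y <- -ct * log2(base)           # log2-expression scale
  z <- sweep(y, 2L, colMeans(y, na.rm = TRUE))   # remove per-sample loading
  groups <- t$groups
  n_groups <- length(unique(groups))
  if (use_groups && n_groups < 2L) {
    warning("only one group present; falling back to ungrouped NormFinder")
    use_groups <- FALSE
  }
  if (!use_groups) {
    values <- apply(z, 1L, function(x) stats::sd(x[!is.na(x)]))
    return(stability_result("normfinder", values,
                            details = structure(list(grouped = FALSE, z = z),
                                                class = "normfinder_detail")))
  }
  glabels <- unique(groups)
  n_g <- vapply(glabels, function(g) sum(groups == g), integer(1))
  small <- glabels[n_g < 2L]
  if (length(small))
    stop("group with a single sample (variance undefined): ",
         paste(small, collapse = ", "))
  gm <- vapply(glabels, function(g)
    rowMeans(z[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(z)))
  gv <- vapply(glabels, function(g)
    apply(z[, groups == g, drop = FALSE], 1L,
          function(x) stats::var(x[!is.na(x)])),
    numeric(nrow(z)))
  dimnames(gm) <- dimnames(gv) <- list(rownames(z), glabels)
  # raw deviations: group means centered on the size-weighted grand mean
  grand <- as.numeric(gm %*% n_g) / sum(n_g)
  d_raw <- gm - grand
  se2 <- sweep(gv, 2L, n_g, "/")               # s2_ig / n_g
  tau2 <- pmax(0, rowSums(d_raw ^ 2) / (length(glabels) - 1L) -
                    rowMeans(se2))
  shrink <- tau2 / (tau2 + se2)                # 0/0 avoided below
  shrink[tau2 == 0, ] <- 0
  d_shrunk <- d_raw * shrink
  values <- rowMeans(abs(d_shrunk) + sqrt(se2))
  details <- structure(list(
    grouped = TRUE, z = z, group_means = gm, group_vars = gv,
    d_raw = d_raw, d_shrunk = d_shrunk, tau2 = tau2,
    group_sizes = n_g), class = "normfinder_detail")
  stability_result("normfinder", values, details = details)
}

#' BestKeeper descriptive stability
#'
#' Operates on raw Ct. Each gene is described by its arithmetic and
#' geometric mean Ct, extremes, a dispersion statistic, and CV percent;
#' the stability value used for ranking is the dispersion of raw Ct
#' (default: sample SD, matching the usage where reported stabilities
#' behave like raw-Ct SDs; mean absolute deviation from the mean is the
#' historically faithful alternative). The per-sample BestKeeper index
#' (geometric mean Ct over genes) and each gene's Pearson correlation
#' with it are reported for inspection but never used for the ranking.
#'
#' @param t a [ct_table()].
#' @param dispersion `"sample_sd"` (default) or `"mean_abs_dev"`.
#' @return [stability_result()]; `details` is a `bestkeeper_detail` list
#'   with `descriptives` (per-gene data frame), `index` (per-sample),
#'   and `correlations` (gene, r, p).
#' @export
bestkeeper <- function(t, dispersion = c("sample_sd", "mean_abs_dev")) {
  stopifnot(inherits(t, "ct_table"))
  dispersion <- match.arg(dispersion)
  ct <- t$ct
  if (ncol(ct) < 2L) stop("BestKeeper needs at least 2 samples")
  if (any(!is.na(ct) & ct <= 0)) stop("all Ct must be positive")
  if (anyNA(ct))
    warning("missing Ct cells: BestKeeper index computed over ",
            "available genes per sample")
  disp_fun <- switch(dispersion,
    sample_sd = function(x) stats::sd(x),
    mean_abs_dev = function(x) mean(abs(x - mean(x))))
  desc <- do.call(rbind, lapply(rownames(ct), function(g) {
    x <- ct[g, ]; x <- x[!is.na(x)]
    data.frame(gene = g, n = length(x), mean_ct = mean(x),
               geo_mean_ct = geometric_mean(x), min_ct = min(x),
               max_ct = max(x), dispersion = disp_fun(x),
               cv_percent = 100 * disp_fun(x) / mean(x))
  }))
  index <- apply(ct, 2L, function(x) geometric_mean(x, na.rm = TRUE))
  correlations <- do.call(rbind, lapply(rownames(ct), function(g) {
    ok <- !is.na(ct[g, ]) & !is.na(index)
    x <- ct[g, ok]; y <- index[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0 || length(x) < 3L)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_))
    r <- stats::cor(x, y)
    df <- length(x) - 2L
    tv <- r * sqrt(df / (1 - r ^ 2))
    data.frame(gene = g, r = r, p = 2 * stats::pt(-abs(tv), df))
  }))
  values <- stats::setNames(desc$dispersion, desc$gene)
  details <- structure(list(descriptives = desc, index = index,
                            correlations = correlations,
                            dispersion = dispersion),
                       class = "bestkeeper_detail")
  stability_result("bestkeeper", values, details = details)
}
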