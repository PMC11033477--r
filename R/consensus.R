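#' Assemble a gene x method rank table
#'
#' Collects the dense per-gene ranks of several stability methods into
#' one integer matrix. All results must cover the identical gene set.
#'
#' @param results list of [stability_result()] objects (at least 2).
#' @return integer matrix, genes in rows, one column per method.
#' @export
build_rank_table <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  ok <- vapply(results, inherits, logical(1), what = "stability_result")
  if (!all(ok)) stop("all elements must be stability_result objects")
  methods <- vapply(results, `[[`, character(1), "method")
  if (anyDuplicated(methods)) stop("duplicate methods in consensus input")
  genes <- sort(names(results[[1L]]$values))
  for (r in results) {
    g <- sort(names(r$values))
    if (!identical(g, genes)) {
      diffs <- c(setdiff(genes, g), setdiff(g, genes))
      stop("gene sets differ between methods; symmetric difference: ",
           paste(diffs, collapse = ", "))
    }
  }
  tab <- vapply(results, function(r) r$ranks[genes], integer(length(genes)))
  dimnames(tab) <- list(genes, methods)
  tab
}

#' Geometric-mean-of-ranks consensus
#'
#' Aggregates per-method dense ranks by the geometric mean, the
#' comprehensive-ranking convention: a lower geometric mean of ranks
#' denotes more stable expression. Ties are broken by mean rank, then
#' gene id. The recommended reference pair is the first two genes of
#' the consensus ordering.
#'
#' @param rank_table integer matrix from [build_rank_table()].
#' @return object of class `consensus_result`: `rank_table`, `geomean`
#'   (per gene), `ordering` (most to least stable), `overall_rank`
#'   (dense, by geomean), `recommended_pair`, `methods_used`.
#' @export
geomean_consensus <- function(rank_table) {
  if (is.null(dim(rank_table)) || nrow(rank_table) == 0L)
    stop("empty rank table")
  if (any(rank_table < 1L) || any(rank_table != round(rank_table)))
    stop("ranks must be integers >= 1")
  gm <- apply(rank_table, 1L, geometric_mean)
  mean_rank <- rowMeans(rank_table)
  ordering <- rownames(rank_table)[order(gm, mean_rank, rownames(rank_table))]
  structure(list(rank_table = rank_table,
                 geomean = gm,
                 ordering = ordering,
                 overall_rank = dense_rank(gm),
                 recommended_pair = ordering[seq_len(min(2L, length(ordering)))],
                 methods_used = colnames(rank_table)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus (geometric mean of ranks; lower = more stable)\n")
  ord <- x$ordering
  print(data.frame(gene = ord,
                   x$rank_table[ord, , drop = FALSE],
                   geomean = round(x$geomean[ord], 3L),
                   overall = x$overall_rank[ord],
                   row.names = NULL))
  cat("recommended pair:", paste(x$recommended_pair, collapse = " + "), "\n")
  invisible(x)
}
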