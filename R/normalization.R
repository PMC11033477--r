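#' Relative expression of a target gene by 2^-ddCt
#'
#' Normalizes a target gene against an aggregated reference set: per
#' sample, the reference aggregate is the arithmetic mean of the
#' reference genes' Ct (equivalent to the geometric mean of their
#' relative quantities at base 2), dCt is target Ct minus that
#' aggregate, ddCt re-centers dCt on the calibrator group's mean, and
#' the fold change is `2^-ddCt`. The calibrator group therefore has mean
#' ddCt 0 by construction.
#'
#' @param t a [ct_table()].
#' @param target target gene id.
#' @param refs character vector of reference gene ids (non-empty,
#'   excluding the target).
#' @param calibrator group label whose mean dCt anchors the fold scale.
#' @return object of class `relative_expression`: `target`,
#'   `reference_set`, `calibrator`, `per_sample` (data frame sample,
#'   group, delta_ct, delta_delta_ct, rq) and `per_group` (group,
#'   mean_rq, se, n).
#' @export
relative_expression <- function(t, target, refs, calibrator) {
  stopifnot(inherits(t, "ct_table"))
  genes <- rownames(t$ct)
  if (!target %in% genes) stop("target gene not in table: ", target)
  if (!length(refs)) stop("reference set must be non-empty")
  if (target %in% refs) stop("target gene cannot be in the reference set")
  missing <- setdiff(refs, genes)
  if (length(missing))
    stop("reference genes not in table: ", paste(missing, collapse = ", "))
  if (!calibrator %in% t$groups)
    stop("calibrator group not present: ", calibrator)
  sub <- t$ct[c(target, refs), , drop = FALSE]
  usable <- colSums(is.na(sub)) == 0L
  if (!all(usable))
    warning(sum(!usable), " sample(s) dropped: incomplete Ct for target ",
            "or references")
  ct <- sub[, usable, drop = FALSE]
  groups <- t$groups[usable]
  if (!any(groups == calibrator))
    stop("calibrator group has no complete samples: ", calibrator)
  ref_aggregate <- colMeans(ct[refs, , drop = FALSE])
  delta_ct <- ct[target, ] - ref_aggregate
  ddct <- delta_ct - mean(delta_ct[groups == calibrator])
  rq <- 2 ^ (-ddct)
  per_sample <- data.frame(sample = colnames(ct), group = unname(groups),
                           delta_ct = unname(delta_ct),
                           delta_delta_ct = unname(ddct),
                           rq = unname(rq))
  per_group <- do.call(rbind, lapply(unique(groups), function(g) {
    x <- rq[groups == g]
    data.frame(group = g, mean_rq = mean(x),
               se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                    else NA_real_,
               n = length(x))
  }))
  structure(list(target = target, reference_set = refs,
                 calibrator = calibrator, per_sample = per_sample,
                 per_group = per_group),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("relative expression of %s vs {%s}, calibrator = %s\n",
              x$target, paste(x$reference_set, collapse = ", "),
              x$calibrator))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD letters on relative expression
#'
#' Tests whether group mean fold changes differ, then groups them with a
#' compact letter display: groups sharing a letter are not significantly
#' different at `alpha` by Tukey's HSD. Groups with fewer than 2
#' replicates are excluded with a warning; if every value is identical
#' the p-value is reported as 1 with a single letter.
#'
#' @param re a [relative_expression()] result.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `p_value` (overall ANOVA F-test), `tukey` (pairwise
#'   table), and `letters` (named by group).
#' @export
group_anova <- function(re, alpha = 0.05) {
  stopifnot(inherits(re, "relative_expression"))
  df <- re$per_sample
  cnt <- table(df$group)
  small <- names(cnt)[cnt < 2L]
  if (length(small)) {
    warning("group(s) with < 2 replicates excluded: ",
            paste(small, collapse = ", "))
    df <- df[!df$group %in% small, , drop = FALSE]
  }
  if (length(unique(df$group)) < 2L)
    stop("ANOVA needs at least 2 groups with >= 2 replicates")
  groups <- sort(unique(df$group))
  if (stats::sd(df$rq) == 0)
    return(list(p_value = 1,
                tukey = NULL,
                letters = stats::setNames(rep("a", length(groups)), groups)))
  df$group <- factor(df$group, levels = groups)
  fit <- stats::aov(rq ~ group, data = df)
  p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  # adjacency: TRUE where the pair is NOT significantly different
  k <- length(groups)
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (pair in rownames(tk)) {
    ab <- strsplit(pair, "-", fixed = TRUE)[[1L]]
    sig <- tk[pair, "p adj"] < alpha
    nsd[ab[1L], ab[2L]] <- nsd[ab[2L], ab[1L]] <- !sig
  }
  letters <- compact_letters(nsd, order(-tapply(df$rq, df$group, mean)))
  list(p_value = p, tukey = tk, letters = letters)
}

# compact letter display from a non-significant-difference adjacency
# matrix: each maximal clique of mutually indistinct groups gets one
# letter; letters assigned in descending-mean order of the groups.
compact_letters <- function(nsd, mean_order) {
  groups <- rownames(nsd)
  cliques <- max_cliques(nsd)
  # order cliques by the best (first in mean_order) group they contain
  first_pos <- vapply(cliques, function(cl)
    min(match(cl, groups[mean_order])), numeric(1))
  cliques <- cliques[order(first_pos)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out[order(match(groups, groups))]
}

# Bron-Kerbosch maximal cliques on a small logical adjacency matrix
max_cliques <- function(adj) {
  nodes <- rownames(adj)
  res <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      res[[length(res) + 1L]] <<- r
      return(invisible())
    }
    for (v in p) {
      nb <- nodes[adj[v, ] & nodes != v]
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(character(0), nodes, character(0))
  res
}
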