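#' Transform Ct values to linear-scale relative quantities
#'
#' geNorm operates on relative quantities, not raw Ct. Each gene row is
#' anchored at its minimum Ct and exponentiated:
#' `q_ij = base_i ^ (anchor_i - Ct_ij)` with `base_i = 1 + efficiency_i/100`,
#' so the best-expressed sample of each gene gets q = 1 and every q lies
#' in (0, 1]. With the default 100% efficiency one cycle equals a
#' two-fold change (base 2).
#'
#' @param t a [ct_table()].
#' @param efficiencies optional per-gene amplification efficiencies in
#'   percent (named by gene, or one per gene in row order). Values
#'   outside [50, 150] are rejected as implausible assays. Default: 100
#'   for all genes.
#' @return An object of class `rq_table` with fields `q` (genes x samples
#'   matrix), `base` (per-gene amplification base in (1, 2.5]), `anchor`
#'   (per-gene anchoring Ct), and `groups`, `meta` carried over.
#'   Missing Ct cells stay missing.
#' @export
#' @examples
#' m <- rbind(A = c(20, 21), B = c(20, 20))
#' colnames(m) <- c("s1", "s2")
#' t <- ct_table(m, groups = c("g", "g"))
#' to_relative_quantities(t)$q   # A: 1, 0.5; B: 1, 1
to_relative_quantities <- function(t, efficiencies = NULL) {
  stopifnot(inherits(t, "ct_table"))
  genes <- rownames(t$ct)
  if (is.null(efficiencies)) {
    eff <- stats::setNames(rep(100, length(genes)), genes)
  } else {
    eff <- resolve_per_gene(efficiencies, genes)
    if (any(eff < 50 | eff > 150))
      stop(sprintf(
        "efficiency %g%% for gene %s outside the plausible [50, 150]%% range",
        eff[eff < 50 | eff > 150][1L],
        genes[which(eff < 50 | eff > 150)[1L]]))
  }
  base <- 1 + eff / 100
  anchor <- apply(t$ct, 1L, min, na.rm = TRUE)
  q <- base ^ (anchor - t$ct)   # base, anchor recycle down columns
  dimnames(q) <- dimnames(t$ct)
  structure(list(q = q, base = base, anchor = anchor,
                 groups = t$groups, meta = t$meta),
            class = "rq_table")
}

resolve_per_gene <- function(x, genes) {
  x <- as.numeric(stats::setNames(x, names(x)))
  if (!is.null(names(x))) {
    missing <- setdiff(genes, names(x))
    if (length(missing))
      stop("efficiencies lack entries for genes: ",
           paste(missing, collapse = ", "))
    x <- x[genes]
  } else {
    if (length(x) == 1L) x <- rep(x, length(genes))
    if (length(x) != length(genes))
      stop("efficiencies must be named by gene or have one value per gene")
    names(x) <- genes
  }
  x
}

#' @export
print.rq_table <- function(x, ...) {
  cat(sprintf("rq_table: %d genes x %d samples (relative quantities)\n",
              nrow(x$q), ncol(x$q)))
  invisible(x)
}
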