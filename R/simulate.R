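#' Specify a synthetic Ct experiment
#'
#' The generator draws Ct values as
#' `Ct = mu_i + L_j + delta_i * u_ig + eps`, where `mu_i` is the gene
#' baseline, `L_j ~ N(0, loading_sd^2)` a per-biological-sample loading
#' shift shared by all genes (cDNA input differences), `u_ig ~ N(0, 1)`
#' a per-(gene, group) biological effect scaled by `delta_i`, and
#' `eps ~ N(0, sigma_i^2)` per measurement. Genes with small
#' `sigma` and `delta` are the stable candidates.
#'
#' @param genes data frame with columns `gene`, `mu` (baseline Ct,
#'   cycles, in (5, 40)), `sigma` (technical/biological noise SD,
#'   cycles, >= 0), `delta` (group-effect scale, cycles, >= 0).
#' @param groups data frame with columns `label`, `n_biological`,
#'   `n_technical`.
#' @param loading_sd per-sample loading-shift SD in cycles (>= 0).
#' @param seed integer seed; all randomness flows from it.
#' @param target_spec optional list with `gene`, `mu`, `sigma`, and
#'   `fold` (named per-group true fold changes relative to 1): adds a
#'   target gene whose group means follow `mu - log2(fold_g)`.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(genes, groups, loading_sd = 0.5, seed = 1L,
                            target_spec = NULL) {
  need <- c("gene", "mu", "sigma", "delta")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("`genes` must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(genes) < 2L) stop("field `genes`: at least 2 genes required")
  if (anyDuplicated(genes$gene)) stop("field `genes`: duplicate gene ids")
  if (any(genes$mu <= 5 | genes$mu >= 40))
    stop("field `genes$mu`: baselines must lie in (5, 40) cycles")
  if (any(genes$sigma < 0)) stop("field `genes$sigma`: must be >= 0")
  if (any(genes$delta < 0)) stop("field `genes$delta`: must be >= 0")
  if (!is.data.frame(groups) ||
      !all(c("label", "n_biological", "n_technical") %in% names(groups)))
    stop("`groups` must have columns label, n_biological, n_technical")
  if (any(groups$n_biological < 1L) || any(groups$n_technical < 1L))
    stop("field `groups`: replicate counts must be >= 1")
  if (sum(groups$n_biological) < 2L)
    stop("field `groups`: at least 2 samples in total")
  if (loading_sd < 0) stop("field `loading_sd`: must be >= 0")
  if (!is.null(target_spec)) {
    if (!all(c("gene", "mu", "sigma", "fold") %in% names(target_spec)))
      stop("field `target_spec`: needs gene, mu, sigma, fold")
    if (!all(groups$label %in% names(target_spec$fold)))
      stop("field `target_spec$fold`: needs one fold change per group")
  }
  structure(list(genes = genes, groups = groups, loading_sd = loading_sd,
                 seed = as.integer(seed), target_spec = target_spec),
            class = "simulation_spec")
}

#' Generate a synthetic Ct table with known ground truth
#'
#' Draws a [ct_table()] from a [simulation_spec()] and records the
#' ground truth: realized loading shifts, realized group effects, and a
#' per-gene disturbance `sqrt(sigma_i^2 + delta_i^2 * v_i)` with `v_i`
#' the population variance of the gene's realized group effects — the
#' quantity the stability statistics estimate. The true stability
#' ordering sorts genes ascending by disturbance (ties by gene id).
#' Bit-identical output for equal seeds; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [simulation_spec()].
#' @return list with `ct` (a [ct_table()]; columns named
#'   `<group>_r<b>[_t<k>]`, with `replicate_of` set when technical
#'   replicates are simulated) and `truth` (class `simulation_truth`:
#'   `disturbance`, `ordering`, `loading`, `group_effects`, and
#'   `target_fold` when a target was simulated).
#' @export
simulate_ct <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  genes <- spec$genes
  groups <- spec$groups
  has_tech <- any(groups$n_technical > 1L)
  bio <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i)
    data.frame(group = groups$label[i],
               unit = paste0(groups$label[i], "_r",
                             seq_len(groups$n_biological[i])),
               n_tech = groups$n_technical[i])))
  # standard normals scaled afterwards: the draw stream is identical
  # across noise settings, so equal seeds align realizations
  loading <- stats::setNames(stats::rnorm(nrow(bio)) * spec$loading_sd,
                             bio$unit)
  u <- matrix(stats::rnorm(nrow(genes) * nrow(groups)),
              nrow(genes), nrow(groups),
              dimnames = list(genes$gene, groups$label))

  cols <- do.call(rbind, lapply(seq_len(nrow(bio)), function(i)
    data.frame(group = bio$group[i], unit = bio$unit[i],
               sample = if (bio$n_tech[i] > 1L)
                 paste0(bio$unit[i], "_t", seq_len(bio$n_tech[i]))
               else bio$unit[i])))
  m <- matrix(NA_real_, nrow(genes), nrow(cols),
              dimnames = list(genes$gene, cols$sample))
  for (i in seq_len(nrow(genes))) {
    eff <- genes$mu[i] + loading[cols$unit] +
      genes$delta[i] * u[i, cols$group]
    m[i, ] <- eff + stats::rnorm(nrow(cols)) * genes$sigma[i]
  }

  target_fold <- NULL
  if (!is.null(spec$target_spec)) {
    ts <- spec$target_spec
    target_fold <- ts$fold[groups$label]
    trow <- ts$mu - log2(target_fold[cols$group]) + loading[cols$unit] +
      stats::rnorm(nrow(cols)) * ts$sigma
    m <- rbind(m, matrix(trow, 1L, dimnames = list(ts$gene, NULL)))
  }

  effects <- genes$delta * u      # realized per-(gene, group) shifts
  v <- apply(u, 1L, function(x) mean((x - mean(x)) ^ 2))
  disturbance <- stats::setNames(
    sqrt(genes$sigma ^ 2 + genes$delta ^ 2 * v), genes$gene)
  ordering <- names(disturbance)[order(disturbance, names(disturbance))]

  ct <- ct_table(
    m, groups = stats::setNames(cols$group, cols$sample),
    replicate_of = if (has_tech) stats::setNames(cols$unit, cols$sample),
    meta = list(simulated = TRUE, seed = spec$seed))
  truth <- structure(list(disturbance = disturbance, ordering = ordering,
                          loading = loading, group_effects = effects,
                          target_fold = target_fold),
                     class = "simulation_truth")
  list(ct = ct, truth = truth)
}

# the candidate panel used throughout: baselines are typical Ct levels
# for abundant housekeeping transcripts; sigma/delta give ribosomal
# protein genes the most stable profile and GAPDH/ACT the least, with a
# > 3x disturbance separation between the two extremes.
default_panel <- function() {
  data.frame(
    gene  = c("ACT", "ARF1", "AK", "EF1a", "GAPDH",
              "aTUB", "RPL6", "RPL13", "RPS3", "RPS18"),
    mu    = c(18.5, 22.0, 20.5, 19.0, 19.5,
              21.0, 17.5, 18.0, 20.0, 17.0),
    sigma = c(0.45, 0.25, 0.30, 0.22, 0.40,
              0.32, 0.12, 0.13, 0.25, 0.22),
    delta = c(0.90, 0.28, 0.40, 0.22, 0.80,
              0.45, 0.05, 0.06, 0.25, 0.20))
}

#' Ready-made simulation designs mirroring a typical insect RT-qPCR study
#'
#' Returns a [simulation_spec()] for one of four experimental
#' conditions — adult ages (3 groups), adult tissues (6), rearing
#' temperatures (5), or sex (2) — each with 3 biological replicates per
#' group, a 10-gene candidate panel (ACT, ARF1, AK, EF1a, GAPDH, aTUB,
#' RPL6, RPL13, RPS3, RPS18), and a default disturbance profile in
#' which the ribosomal protein genes RPL6/RPL13 are most stable and
#' GAPDH/ACT least.
#'
#' @param condition one of `"ages"`, `"tissues"`, `"temperature"`,
#'   `"sex"`.
#' @param seed integer seed stored in the spec.
#' @param n_technical technical replicates per biological sample
#'   (default 1: one pre-averaged Ct per biological replicate).
#' @return a [simulation_spec()].
#' @export
paper_like_design <- function(condition = c("ages", "tissues",
                                            "temperature", "sex"),
                              seed = 1L, n_technical = 1L) {
  condition <- match.arg(condition)
  labels <- switch(condition,
    ages = c("day1", "day2", "day3"),
    tissues = c("epidermis", "foregut", "midgut", "hindgut",
                "trachea", "antenna"),
    temperature = c("T04", "T15", "T20", "T26", "T35"),
    sex = c("female", "male"))
  # loading_sd calibrated from published stability tables: for the most
  # stable candidates, raw-Ct SD (~0.47) barely exceeds the pairwise
  # delta-Ct noise (0.60/sqrt(2) ~ 0.42), implying per-sample loading
  # shifts of roughly 0.2-0.3 cycles
  simulation_spec(
    genes = default_panel(),
    groups = data.frame(label = labels, n_biological = 3L,
                        n_technical = as.integer(n_technical)),
    loading_sd = 0.25, seed = seed)
}
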