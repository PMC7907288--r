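#' Facial treatment score from two percent-significant values
#'
#' The treatment score is the relative reduction, attributable to
#' treatment, in the percentage of significantly different inter-landmark
#' distances between the affected and control groups:
#' `100 * (pct_ref - pct_trt) / pct_ref`, where `pct_ref` is the percent of
#' significant distances in the affected-vs-control contrast and `pct_trt`
#' the percent in the treated-affected-vs-control contrast. A score of 100
#' means complete rescue (no residual significant differences), 0 means no
#' change, and negative values mean the treatment worsened the
#' dysmorphology. Undefined when `pct_ref = 0` (the affected group is
#' already indistinguishable from control).
#'
#' @param pct_ref,pct_trt percentages in `[0, 100]`; `pct_ref > 0`.
#' @return score as a percentage (at most 100; unbounded below).
#' @export
compute_fts <- function(pct_ref, pct_trt) {
  if (!is.finite(pct_ref) || !is.finite(pct_trt))
    stop("percentages must be finite")
  if (pct_ref < 0 || pct_ref > 100 || pct_trt < 0 || pct_trt > 100)
    stop("percentages must lie in [0, 100]")
  if (pct_ref == 0)
    stop("treatment score undefined: reference contrast has no ",
         "significant distances (pct_ref = 0)")
  100 * (pct_ref - pct_trt) / pct_ref
}

#' Configuration for the treatment score and its scaffolded null
#'
#' Names the four group roles entering the two EDMA contrasts and sets the
#' scaffolded-bootstrap parameters. In a design with treated controls
#' (mouse-style), `ref_control` and `trt_control` differ (untreated vs
#' treated controls); in an observational design without treated controls
#' (human-style) both point at the single control group.
#'
#' @param ref_affected,ref_control group labels of the reference contrast
#'   (untreated affected vs control).
#' @param trt_affected,trt_control group labels of the treated contrast
#'   (treated affected vs control).
#' @param m_values integers in `0..N-1`: numbers of truly treated
#'   individuals per pseudo-treated group of the null scaffold. `NULL`
#'   (default) uses the full range `0..N-1`; the fully treated set
#'   (`M = N`) is the observed score, not part of the null. Set
#'   `include_m_n = TRUE` to also scaffold `M = N` into the null.
#' @param reps_per_m pseudo-sample replicates per `M` (default 75).
#' @param alpha,n_resamples,statistic EDMA contrast settings, see
#'   [edma_contrast()].
#' @param seed master seed; every random draw in the procedure derives
#'   from it.
#' @param include_m_n include `M = N` replicates in the null (default
#'   `FALSE`).
#' @return a list of class `fts_config`.
#' @export
fts_config <- function(ref_affected, ref_control, trt_affected, trt_control,
                       m_values = NULL, reps_per_m = 75L, alpha = 0.10,
                       n_resamples = 10000L, seed = 1L,
                       statistic = c("ratio", "difference"),
                       include_m_n = FALSE) {
  statistic <- match.arg(statistic)
  if (reps_per_m < 1L) stop("reps_per_m must be >= 1")
  structure(list(ref_affected = ref_affected, ref_control = ref_control,
                 trt_affected = trt_affected, trt_control = trt_control,
                 m_values = m_values, reps_per_m = as.integer(reps_per_m),
                 alpha = alpha, n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), statistic = statistic,
                 include_m_n = isTRUE(include_m_n)),
            class = "fts_config")
}

# Both contrasts and the score for explicit specimen index sets. The two
# contrasts share one bootstrap stream (same role labels, same seed):
# identical inputs then give identical contrasts (a copy of the affected
# group as "treated" scores exactly 0), and the reference and treated
# percentages are compared under common random numbers.
.fts_for_sets <- function(dt, idx_ref_aff, idx_ref_ctl, idx_trt_aff,
                          idx_trt_ctl, config, seed) {
  ref <- edma_contrast(subset_specimens(dt, idx_ref_aff),
                       subset_specimens(dt, idx_ref_ctl),
                       alpha = config$alpha,
                       n_resamples = config$n_resamples,
                       seed = seed,
                       group_a = "affected", group_b = "control",
                       statistic = config$statistic)
  trt <- edma_contrast(subset_specimens(dt, idx_trt_aff),
                       subset_specimens(dt, idx_trt_ctl),
                       alpha = config$alpha,
                       n_resamples = config$n_resamples,
                       seed = seed,
                       group_a = "affected", group_b = "control",
                       statistic = config$statistic)
  pr <- ref$percent_significant
  pt <- trt$percent_significant
  list(fts = if (pr <= 0) NA_real_ else 100 * (pr - pt) / pr,
       pct_ref = pr, pct_trt = pt)
}

.fts_group_idx <- function(groups, label, role) {
  idx <- which(groups == label)
  if (length(idx) < 3L)
    stop("group '", label, "' (", role, ") has ", length(idx),
         " specimens; at least 3 are required")
  idx
}

#' Observed treatment score for an aligned cohort
#'
#' Runs the reference and treated EDMA contrasts on the aligned shape
#' coordinates and applies [compute_fts()] to their percent-significant
#' values.
#'
#' @param aligned an `aligned_dataset`.
#' @param groups character vector of per-specimen group labels (one per
#'   specimen) in which the four roles of `config` resolve to at least 3
#'   specimens each.
#' @param config an [fts_config()].
#' @return list with `fts`, `pct_ref`, `pct_trt`.
#' @export
fts_observed <- function(aligned, groups, config) {
  stopifnot(inherits(aligned, "aligned_dataset"),
            inherits(config, "fts_config"))
  if (length(groups) != n_specimens(aligned))
    stop("`groups` must have one label per specimen")
  dt <- pairwise_distances(aligned)
  res <- .fts_for_sets(dt,
                       .fts_group_idx(groups, config$ref_affected, "reference affected"),
                       .fts_group_idx(groups, config$ref_control, "reference control"),
                       .fts_group_idx(groups, config$trt_affected, "treated affected"),
                       .fts_group_idx(groups, config$trt_control, "treated control"),
                       config, derive_seed(config$seed, "observed"))
  if (is.na(res$fts))
    stop("treatment score undefined: reference contrast has no ",
         "significant distances")
  res
}

#' Scaffolded-bootstrap null distribution and p-value of the treatment score
#'
#' Tests whether the observed treatment score could have arisen without any
#' treatment effect, by re-partitioning the pooled affected sample
#' (treated and untreated affected specimens together) into pseudo-treated
#' groups of the true treated size `N` that contain a controlled number
#' `M` of truly treated individuals. For each `M` in `m_values` and each of
#' `reps_per_m` replicates, a pseudo-treated set of exactly `M` treated and
#' `N - M` untreated affected specimens is drawn uniformly without
#' replacement; the remaining affected specimens form the pseudo-untreated
#' group; both EDMA contrasts and the score are recomputed. Control groups
#' are never re-partitioned. The observed score uses the true treated set
#' (`M = N`), and the p-value is the fraction of null simulations with a
#' strictly higher score (ties count as non-exceedances). Simulations whose
#' reference contrast has no significant distances leave the score
#' undefined; they are recorded as `NA` and excluded from the p-value's
#' numerator and denominator.
#'
#' @inheritParams fts_observed
#' @return an object of class `fts_result`: `observed_fts`,
#'   `observed_pcts`, `null_fts` (named list mapping each `M` to its
#'   replicate scores), `p_value`, `n_simulations_total` (valid, non-`NA`
#'   simulations), `n_invalid`, `config`.
#' @export
fts_null_distribution <- function(aligned, groups, config) {
  stopifnot(inherits(aligned, "aligned_dataset"),
            inherits(config, "fts_config"))
  if (length(groups) != n_specimens(aligned))
    stop("`groups` must have one label per specimen")
  dt <- pairwise_distances(aligned)
  treated <- which(groups == config$trt_affected)
  untreated <- which(groups == config$ref_affected)
  idx_rc <- .fts_group_idx(groups, config$ref_control, "reference control")
  idx_tc <- .fts_group_idx(groups, config$trt_control, "treated control")
  N <- length(treated)
  if (N < 1L) stop("no specimens in treated affected group '",
                   config$trt_affected, "'")
  pool <- c(treated, untreated)
  if (length(pool) < N + 3L)
    stop("pooled affected sample (", length(pool),
         ") must exceed the treated size N = ", N, " by at least 3")

  m_values <- config$m_values %||%
    (0:(N - if (config$include_m_n) 0L else 1L))
  if (any(m_values < 0L) || any(m_values > N))
    stop("m_values must lie in 0..N = ", N)
  if (any(N - m_values > length(untreated)))
    stop("infeasible M: fewer than N - M untreated affected ",
         "specimens available")

  # one bootstrap stream shared by the observed score and every scaffold
  # simulation (common random numbers): simulations then differ only in
  # group composition, not in bootstrap Monte-Carlo noise
  contrast_seed <- derive_seed(config$seed, "edma_crn")
  obs <- .fts_for_sets(dt, untreated, idx_rc, treated, idx_tc, config,
                       contrast_seed)
  if (is.na(obs$fts))
    stop("observed treatment score undefined: reference contrast has no ",
         "significant distances")

  null_fts <- list()
  for (M in m_values) {
    vals <- numeric(config$reps_per_m)
    for (r in seq_len(config$reps_per_m)) {
      s <- derive_seed(config$seed, sprintf("scaffold_m%d_r%d", M, r))
      pseudo_trt <- with_seed(s, {
        c(if (M > 0L) sample(treated, M),
          if (N - M > 0L) sample(untreated, N - M))
      })
      pseudo_unt <- setdiff(pool, pseudo_trt)
      vals[r] <- .fts_for_sets(dt, pseudo_unt, idx_rc, pseudo_trt, idx_tc,
                               config, contrast_seed)$fts
    }
    null_fts[[as.character(M)]] <- vals
  }
  all_null <- unlist(null_fts, use.names = FALSE)
  n_valid <- sum(!is.na(all_null))
  if (n_valid == 0L) stop("all null simulations were undefined")
  structure(list(observed_fts = obs$fts,
                 observed_pcts = c(ref = obs$pct_ref, trt = obs$pct_trt),
                 null_fts = null_fts,
                 p_value = sum(all_null > obs$fts, na.rm = TRUE) / n_valid,
                 n_simulations_total = n_valid,
                 n_invalid = sum(is.na(all_null)),
                 config = config),
            class = "fts_result")
}

#' @export
print.fts_result <- function(x, ...) {
  cat("Facial treatment score\n")
  cat(sprintf("observed FTS: %.1f%%  (ref %.1f%% -> treated %.1f%% significant distances)\n",
              x$observed_fts, x$observed_pcts["ref"], x$observed_pcts["trt"]))
  cat("scaffolded null:", x$n_simulations_total, "valid simulations over M =",
      paste(names(x$null_fts), collapse = ","),
      if (x$n_invalid > 0L) sprintf("(%d undefined, excluded)", x$n_invalid),
      "\n")
  cat(sprintf("p-value (fraction of null simulations with higher FTS): %.4g\n",
              x$p_value))
  invisible(x)
}
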