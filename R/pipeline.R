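#' Run the full landmark analysis pipeline
#'
#' Config-driven orchestration of the analysis stages in order:
#' validation, generalized Procrustes superimposition, optional allometric
#' correction, PCA ordination, EDMA contrasts, the treatment score with
#' its scaffolded null, and a permutation test. All stages operate on the
#' same aligned dataset; each stage logs its parameters, group sizes and
#' wall time, and when `out_dir` is set writes its tabular output so every
#' report number can be re-derived from the stage artifacts.
#'
#' @param config a named list, or the path to a YAML file holding one,
#'   with elements:
#' \describe{
#'   \item{coords, meta}{input file paths for [read_landmark_table()];
#'     alternatively pass a `landmark_dataset` as `config$dataset`.}
#'   \item{groups}{named list of role definitions (`ref_affected`,
#'     `ref_control`, `trt_affected`, `trt_control`), each a named list of
#'     metadata field = value filters (e.g.
#'     `list(genotype = "trisomic", treatment = "none")`). Specimens
#'     matching a role are assigned its name as group label.}
#'   \item{allometry}{optional list: `enabled` (logical) and `grouping`
#'     (metadata column for the strata, default `"age_group"`).}
#'   \item{stratify_by}{optional metadata column; when set, all statistics
#'     are computed independently within each stratum (e.g. age group)
#'     and the report carries one block per stratum. GPA and allometric
#'     correction remain global.}
#'   \item{edma}{list: `alpha` (default 0.10), `n_resamples` (default
#'     10000), `statistic` (default `"ratio"`).}
#'   \item{fts}{optional list: `enabled`, `reps_per_m` (default 75),
#'     `m_values`.}
#'   \item{perm}{optional list: `label` (metadata column with two
#'     classes), `n_rounds` (default 10000).}
#'   \item{seed}{master seed (default 1).}
#'   \item{out_dir}{optional output directory for stage artifacts.}
#' }
#' @return an object of class `run_report` with per-stage outputs
#'   (consensus, PC percent variance, contrast summaries, treatment score
#'   and p-values), the config echo, package version and per-stage wall
#'   times.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t <- system.time(v <- force(expr))[["elapsed"]]
    timings[[stage]] <<- t
    v
  }

  dataset <- tick("validate", {
    if (!is.null(config$dataset)) config$dataset
    else read_landmark_table(config$coords, config$meta)
  })

  aligned <- tick("gpa", gpa_superimpose(dataset))
  allo_cfg <- config$allometry
  models <- NULL
  if (isTRUE(allo_cfg$enabled)) {
    ac <- tick("allometry", {
      grouping <- as.character(
        dataset$meta[[allo_cfg$grouping %||% "age_group"]])
      allometry_correct(aligned, grouping)
    })
    aligned <- ac$aligned
    models <- ac$models
  }
  if (!is.null(out_dir)) {
    write_landmark_table(
      landmark_dataset(aligned$shape_coords, aligned$landmark_labels,
                       aligned$source_meta,
                       scale_note = "Procrustes shape coordinates"),
      file.path(out_dir, "aligned_coords.csv"),
      file.path(out_dir, "aligned_meta.csv"))
  }

  groups <- .resolve_groups(dataset$meta, config$groups)
  strata <- if (!is.null(config$stratify_by)) {
    as.character(dataset$meta[[config$stratify_by]])
  } else rep("all", n_specimens(dataset))

  results <- list()
  for (st in unique(strata)) {
    sel <- which(strata == st)
    sub <- .subset_aligned(aligned, sel)
    results[[st]] <- .analyse_stratum(sub, groups[sel], config, seed,
                                      out_dir, st, tick)
  }

  report <- structure(list(
    n_specimens = n_specimens(dataset),
    n_landmarks = n_landmarks(dataset),
    gpa = list(n_iterations = aligned$n_iterations,
               converged = aligned$converged,
               consensus = aligned$consensus,
               allometry_corrected = isTRUE(aligned$allometry_corrected)),
    allometry_models = models,
    strata = results,
    seed = seed,
    version = as.character(utils::packageVersion("morphoscore")),
    timings = timings,
    config = config[setdiff(names(config), "dataset")]),
    class = "run_report")
  if (!is.null(out_dir)) .write_report_json(report, out_dir)
  report
}

# Roles with identical filter definitions (e.g. a single control group
# serving both contrasts) share one canonical label: the first such role's
# name.
.role_map <- function(defs) {
  keys <- vapply(defs, function(d)
    paste(names(d), vapply(d, paste, "", collapse = "|"), sep = "=",
          collapse = ";"), "")
  vapply(seq_along(defs), function(i)
    names(defs)[match(keys[i], keys)], "")
}

.resolve_groups <- function(meta, defs) {
  if (is.null(defs)) return(rep(NA_character_, nrow(meta)))
  canon <- .role_map(defs)
  defs <- defs[unique(canon)]
  groups <- rep(NA_character_, nrow(meta))
  for (role in names(defs)) {
    sel <- rep(TRUE, nrow(meta))
    for (field in names(defs[[role]])) {
      if (is.null(meta[[field]]))
        stop("group role '", role, "' filters on unknown metadata field '",
             field, "'")
      sel <- sel & meta[[field]] %in% defs[[role]][[field]]
    }
    groups[sel & is.na(groups)] <- role
  }
  groups
}

.subset_aligned <- function(aligned, idx) {
  aligned$shape_coords <- aligned$shape_coords[idx, , , drop = FALSE]
  aligned$centroid_sizes <- aligned$centroid_sizes[idx]
  aligned$source_meta <- aligned$source_meta[idx, , drop = FALSE]
  aligned
}

.analyse_stratum <- function(aligned, groups, config, seed, out_dir, st,
                             tick) {
  res <- list(n = n_specimens(aligned),
              group_sizes = table(groups, useNA = "no"))
  ecfg <- config$edma %||% list()
  alpha <- ecfg$alpha %||% 0.10
  B <- ecfg$n_resamples %||% 10000L
  statistic <- ecfg$statistic %||% "ratio"

  if (n_specimens(aligned) >= 3L) {
    pca <- tick(paste0("pca_", st), pca_fit(aligned))
    res$percent_variance <- pca$percent_variance
    res$pc12_percent <- sum(pca$percent_variance[1:2])
    if (!is.null(out_dir)) {
      utils::write.csv(
        data.frame(specimen_id = rownames(pca$scores), pca$scores),
        file.path(out_dir, paste0("pca_scores_", st, ".csv")),
        row.names = FALSE)
    }
  }

  roles <- config$groups
  rmap <- if (!is.null(roles)) {
    m <- .role_map(roles); names(m) <- names(roles); m
  }
  have <- function(...) all(vapply(list(...), function(r)
    !is.null(rmap[r]) && !is.na(rmap[r]) &&
      sum(groups == rmap[[r]], na.rm = TRUE) >= 3L,
    logical(1)))
  dt <- pairwise_distances(aligned)
  contrasts <- list()
  if (have("ref_affected", "ref_control"))
    contrasts$reference <- list(a = rmap[["ref_affected"]],
                                b = rmap[["ref_control"]])
  if (have("trt_affected", "trt_control"))
    contrasts$treated <- list(a = rmap[["trt_affected"]],
                              b = rmap[["trt_control"]])
  res$edma <- list()
  for (nm in names(contrasts)) {
    cc <- contrasts[[nm]]
    con <- tick(paste0("edma_", nm, "_", st), edma_contrast(
      subset_specimens(dt, which(groups == cc$a)),
      subset_specimens(dt, which(groups == cc$b)),
      alpha = alpha, n_resamples = B,
      seed = derive_seed(seed, paste0("edma_", nm, "_", st)),
      group_a = cc$a, group_b = cc$b, statistic = statistic))
    res$edma[[nm]] <- list(percent_significant = con$percent_significant,
                           n_significant = sum(con$significant))
    if (!is.null(out_dir)) {
      utils::write.csv(
        data.frame(pair = con$pair_labels, statistic = con$statistic,
                   ci_low = con$ci_low, ci_high = con$ci_high,
                   significant = con$significant),
        file.path(out_dir, paste0("edma_", nm, "_", st, ".csv")),
        row.names = FALSE)
    }
  }

  fcfg <- config$fts
  if (isTRUE(fcfg$enabled) &&
      have("ref_affected", "ref_control", "trt_affected", "trt_control")) {
    cfg <- fts_config(rmap[["ref_affected"]], rmap[["ref_control"]],
                      rmap[["trt_affected"]], rmap[["trt_control"]],
                      m_values = fcfg$m_values,
                      reps_per_m = fcfg$reps_per_m %||% 75L,
                      alpha = alpha, n_resamples = B,
                      seed = derive_seed(seed, paste0("fts_", st)),
                      statistic = statistic)
    fr <- tick(paste0("fts_", st),
               fts_null_distribution(aligned, groups, cfg))
    res$fts <- list(observed = fr$observed_fts, p_value = fr$p_value,
                    n_simulations = fr$n_simulations_total)
    if (!is.null(out_dir)) {
      utils::write.csv(
        data.frame(M = rep(names(fr$null_fts),
                           vapply(fr$null_fts, length, 1L)),
                   fts = unlist(fr$null_fts, use.names = FALSE)),
        file.path(out_dir, paste0("fts_null_", st, ".csv")),
        row.names = FALSE)
    }
  }

  pcfg <- config$perm
  if (!is.null(pcfg$label)) {
    lab <- as.character(aligned$source_meta[[pcfg$label]])
    if (length(unique(lab)) == 2L && min(table(lab)) >= 2L) {
      pt <- tick(paste0("perm_", st), procrustes_perm_test(
        aligned, lab, n_rounds = pcfg$n_rounds %||% 10000L,
        seed = derive_seed(seed, paste0("perm_", st))))
      res$perm <- list(labels = pt$group_labels,
                       observed_distance = pt$observed_distance,
                       p_value = pt$p_value)
    }
  }
  res
}

.write_report_json <- function(report, out_dir) {
  flat <- report
  flat$gpa$consensus <- NULL
  flat$allometry_models <- NULL
  jsonlite::write_json(flat, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("morphoscore pipeline report (v", x$version, ")\n", sep = "")
  cat(x$n_specimens, "specimens x", x$n_landmarks, "landmarks; GPA",
      x$gpa$n_iterations, "iterations",
      if (x$gpa$converged) "(converged)" else "(NOT converged)", "\n")
  for (st in names(x$strata)) {
    s <- x$strata[[st]]
    cat("stratum '", st, "' (n = ", s$n, ")\n", sep = "")
    if (!is.null(s$pc12_percent))
      cat(sprintf("  PC1+PC2 variance: %.1f%%\n", s$pc12_percent))
    for (nm in names(s$edma))
      cat(sprintf("  EDMA %s contrast: %.1f%% significant\n", nm,
                  s$edma[[nm]]$percent_significant))
    if (!is.null(s$fts))
      cat(sprintf("  FTS: %.1f%% (p = %.4g, %d simulations)\n",
                  s$fts$observed, s$fts$p_value, s$fts$n_simulations))
    if (!is.null(s$perm))
      cat(sprintf("  permutation test (%s): p = %.4g\n",
                  paste(s$perm$labels, collapse = " vs "), s$perm$p_value))
  }
  cat("total wall time:", sprintf("%.1f s", sum(unlist(x$timings))), "\n")
  invisible(x)
}
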