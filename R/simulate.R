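#' Built-in landmark templates
#'
#' Fixed, non-degenerate 3D landmark configurations used as the mean shape
#' of simulated cohorts: a 12-landmark snout-like configuration (4 midline
#' points plus 4 bilateral pairs, murine cranium analog) and a 21-landmark
#' face-like configuration (7 midline points plus 7 bilateral pairs,
#' human facial analog). Axes: x lateral, y rostro-caudal/vertical, z
#' depth. Templates are centered at the origin and scaled to unit centroid
#' size; calls are deterministic.
#'
#' @param K landmark count, 12 or 21 for the built-ins.
#' @return a `K x 3` matrix with landmark labels as row names.
#' @export
make_template <- function(K) {
  if (K == 12L) {
    mid <- rbind(nasale        = c(0, 1.30,  0.15),
                 nasion        = c(0, 0.55,  0.45),
                 premaxilla    = c(0, 1.25, -0.25),
                 palate_mid    = c(0, 0.45, -0.35))
    lat <- rbind(snout_lat     = c(0.35, 1.05, -0.05),
                 orbit_med     = c(0.45, 0.35,  0.35),
                 zygoma_ant    = c(0.70, 0.25, -0.10),
                 zygoma_post   = c(0.75, -0.35, 0.00))
  } else if (K == 21L) {
    mid <- rbind(glabella      = c(0,  1.05, 0.95),
                 nasion        = c(0,  0.90, 0.90),
                 pronasale     = c(0,  0.45, 1.25),
                 subnasale     = c(0,  0.30, 1.00),
                 labiale_sup   = c(0,  0.10, 1.02),
                 labiale_inf   = c(0, -0.12, 0.98),
                 pogonion      = c(0, -0.55, 0.95))
    lat <- rbind(endocanthion  = c(0.30,  0.80,  0.80),
                 exocanthion   = c(0.85,  0.78,  0.60),
                 alare         = c(0.32,  0.35,  0.95),
                 cheilion      = c(0.48,  0.00,  0.85),
                 zygion        = c(1.05,  0.55,  0.20),
                 gonion        = c(0.95, -0.40,  0.10),
                 tragion       = c(1.15,  0.70, -0.10))
  } else {
    stop("no built-in template for K = ", K,
         " (12 and 21 are provided); supply your own template")
  }
  s <- .mirror_bilateral(mid, lat)
  s <- sweep(s, 2L, colMeans(s))
  s <- s / sqrt(sum(s^2))
  colnames(s) <- c("x", "y", "z")
  s
}

# midline rows, then right (+x) / left (-x) copies of each bilateral row
.mirror_bilateral <- function(mid, lat) {
  right <- lat; left <- lat; left[, 1L] <- -left[, 1L]
  rownames(right) <- paste0(rownames(lat), "_R")
  rownames(left) <- paste0(rownames(lat), "_L")
  rbind(mid, right, left)
}

# Genotype displacement direction, concentrated on midface/snout-analog
# landmarks: retraction and flattening of the nasal region, echoing
# midfacial hypoplasia. Normalized so the most-displaced landmark moves by
# unit distance, making the magnitude parameter directly comparable to the
# per-landmark noise sd. Deterministic per K.
.delta_field <- function(K) {
  if (K == 12L) {
    mid <- rbind(nasale      = c(0, -1.0, -0.20),
                 nasion      = c(0, -0.2,  0.00),
                 premaxilla  = c(0, -1.0, -0.10),
                 palate_mid  = c(0, -0.3,  0.00))
    lat <- rbind(snout_lat   = c(-0.30, -0.80, 0),
                 orbit_med   = c(-0.15, -0.10, 0),
                 zygoma_ant  = c(0, 0, 0),
                 zygoma_post = c(0, 0, 0))
  } else if (K == 21L) {
    mid <- rbind(glabella    = c(0, 0, -0.10),
                 nasion      = c(0, 0, -0.40),
                 pronasale   = c(0, 0, -1.00),
                 subnasale   = c(0, 0, -0.60),
                 labiale_sup = c(0, 0, -0.25),
                 labiale_inf = c(0, 0,  0.00),
                 pogonion    = c(0, 0,  0.00))
    lat <- rbind(endocanthion = c( 0.15, 0, -0.10),
                 exocanthion  = c( 0.00, 0,  0.00),
                 alare        = c(-0.30, 0, -0.50),
                 cheilion     = c( 0.00, 0, -0.10),
                 zygion       = c(-0.20, 0,  0.20),
                 gonion       = c( 0.00, 0,  0.00),
                 tragion      = c( 0.00, 0,  0.00))
  } else stop("no built-in displacement field for K = ", K)
  f <- .mirror_bilateral(mid, lat)
  f / max(sqrt(rowSums(f^2)))
}

# Growth direction for allometric shape change (normalized like the
# displacement field): elongation of the lower face and nasal projection.
.growth_field <- function(K) {
  if (K == 21L) {
    mid <- rbind(glabella    = c(0,  0.2, 0.0),
                 nasion      = c(0,  0.1, 0.0),
                 pronasale   = c(0,  0.0, 0.6),
                 subnasale   = c(0, -0.1, 0.2),
                 labiale_sup = c(0, -0.2, 0.0),
                 labiale_inf = c(0, -0.4, 0.0),
                 pogonion    = c(0, -0.9, 0.1))
    lat <- rbind(endocanthion = c(0, 0.1, 0),
                 exocanthion  = c(0, 0.1, 0),
                 alare        = c(0.1, 0, 0.2),
                 cheilion     = c(0, -0.2, 0),
                 zygion       = c(0.1, 0, 0),
                 gonion       = c(0.1, -0.6, 0),
                 tragion      = c(0, 0.1, 0))
    f <- .mirror_bilateral(mid, lat)
    return(f / max(sqrt(rowSums(f^2))))
  }
  stop("no built-in growth field for K = ", K)
}

#' Simulation configuration for a synthetic landmark cohort
#'
#' Defines a cohort with the statistical structure that landmark-based
#' dysmorphology studies assume: a genotype mean-shape displacement, a
#' treatment that rescues a fraction of affected individuals toward the
#' control mean (responder/non-responder mixture), optional variance
#' inflation in treated individuals, linear allometric shape change with
#' age, and isotropic per-landmark Gaussian noise.
#'
#' Defaults follow the two study designs the package targets. The
#' mouse-style cohort uses the 12-landmark template, group sizes 14/15/6/5
#' (untreated control, treated control, untreated affected, treated
#' affected — the low-dose design), a single age (postnatal day 29, no
#' allometry) and noise `sigma = 0.02` shape units. The human-style cohort
#' uses the 21-landmark template, group sizes 57/20/7 (control, affected,
#' treated affected — the 0-3-year stratum; no treated control exists in
#' an observational design), ages uniform on 0-3 years with a linear
#' allometric field, and the same noise scale. Treated responders (drawn
#' per specimen with probability `pi_resp`) have their mean displaced back
#' toward the control mean by fraction `rho`; non-responders are
#' unaffected by treatment.
#'
#' @param cohort `"mouse"` or `"human"` preset; sets all defaults below
#'   unless overridden.
#' @param K landmark count (must match `template` if both given).
#' @param template `K x 3` mean shape; defaults to [make_template()].
#' @param groups data frame with columns `label`, `genotype`
#'   (euploid/trisomic), `treatment` (none/low/high/unspecified), `n`,
#'   `age_min`, `age_max`.
#' @param delta genotype displacement magnitude, template (shape) units.
#' @param delta_field `K x 3` unit-norm displacement direction; defaults
#'   to a built-in midface field.
#' @param rho rescue fraction in `[0, 1]` applied to responders.
#' @param pi_resp responder probability in `[0, 1]`.
#' @param kappa variance-inflation factor (`>= 1`) for treated affected
#'   specimens (models the enlarged phenotypic variation seen under
#'   aggressive dosing).
#' @param sigma isotropic per-landmark noise standard deviation, template
#'   units.
#' @param allometry_slope scalar magnitude of linear shape change per unit
#'   age (template units/year), applied along a built-in growth field;
#'   `NULL` disables allometry.
#' @param scale_mm factor converting template units to mm in the emitted
#'   coordinates (documents the nominal organism size).
#' @param seed integer seed; cohorts are bit-reproducible given the seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(cohort = c("mouse", "human"), K = NULL,
                              template = NULL, groups = NULL, delta = 0.10,
                              delta_field = NULL, rho = 1, pi_resp = 0.6,
                              kappa = 1, sigma = 0.02,
                              allometry_slope = NULL, scale_mm = NULL,
                              seed = 1L) {
  cohort <- match.arg(cohort)
  if (cohort == "mouse") {
    K <- K %||% 12L
    groups <- groups %||% data.frame(
      label = c("WT", "WT_TE", "TS", "TS_TE"),
      genotype = c("euploid", "euploid", "trisomic", "trisomic"),
      treatment = c("none", "low", "none", "low"),
      n = c(14L, 15L, 6L, 5L),
      age_min = 29, age_max = 29,
      stringsAsFactors = FALSE)
    scale_mm <- scale_mm %||% 15
  } else {
    K <- K %||% 21L
    groups <- groups %||% data.frame(
      label = c("EU", "DS", "DS_TE"),
      genotype = c("euploid", "trisomic", "trisomic"),
      treatment = c("none", "none", "unspecified"),
      n = c(57L, 20L, 7L),
      age_min = 0, age_max = 3,
      stringsAsFactors = FALSE)
    scale_mm <- scale_mm %||% 100
    if (is.null(allometry_slope)) allometry_slope <- 0.01
  }
  template <- template %||% make_template(K)
  if (nrow(template) != K) stop("template has ", nrow(template),
                                " landmarks but K = ", K)
  delta_field <- delta_field %||% .delta_field(K)
  stopifnot(is.data.frame(groups),
            all(c("label", "genotype", "treatment", "n",
                  "age_min", "age_max") %in% names(groups)))
  .check_enum(groups$genotype, c("euploid", "trisomic", "mosaic"),
              "genotype")
  .check_enum(groups$treatment, c("none", "low", "high", "unspecified"),
              "treatment")
  if (any(groups$n < 0L)) stop("group sizes must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  if (kappa < 1) stop("kappa must be >= 1")
  if (rho < 0 || rho > 1 || pi_resp < 0 || pi_resp > 1)
    stop("rho and pi_resp must lie in [0, 1]")
  structure(list(cohort = cohort, K = as.integer(K), template = template,
                 groups = groups, delta = delta, delta_field = delta_field,
                 rho = rho, pi_resp = pi_resp, kappa = kappa, sigma = sigma,
                 allometry_slope = allometry_slope, scale_mm = scale_mm,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a landmark cohort with known ground truth
#'
#' Generates every specimen as
#' `template + genotype displacement + treatment rescue + allometry + noise`
#' according to its group in the configuration (see
#' [simulation_config()] for the model), emits coordinates in mm, and
#' returns the ground truth needed for parameter-recovery tests.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (a validated [landmark_dataset()]) and
#'   `truth` (list: `table` — per-specimen group, responder flag and age;
#'   `pre_noise` — the n x K x 3 array of noise-free configurations in
#'   template units).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$groups
  n <- sum(g$n)
  K <- config$K
  coords <- array(NA_real_, dim = c(n, K, 3L))
  pre <- array(NA_real_, dim = c(n, K, 3L))
  meta <- data.frame(specimen_id = character(n), cohort = "synthetic",
                     genotype = character(n), treatment = character(n),
                     sex = character(n), age = numeric(n),
                     age_group = NA_character_, stringsAsFactors = FALSE)
  truth <- data.frame(specimen_id = character(n), group = character(n),
                      responder = NA, age = numeric(n),
                      stringsAsFactors = FALSE)
  growth <- if (!is.null(config$allometry_slope)) .growth_field(K)
  geno_shift <- config$delta * config$delta_field

  with_seed(config$seed, {
    i <- 0L
    for (r in seq_len(nrow(g))) {
      for (j in seq_len(g$n[r])) {
        i <- i + 1L
        affected <- g$genotype[r] == "trisomic"
        treated <- g$treatment[r] != "none"
        mean_shape <- config$template
        if (affected) mean_shape <- mean_shape + geno_shift
        responder <- NA
        if (affected && treated) {
          responder <- stats::runif(1) < config$pi_resp
          if (responder)
            mean_shape <- mean_shape - config$rho * geno_shift
        }
        age <- stats::runif(1, g$age_min[r], g$age_max[r])
        if (!is.null(config$allometry_slope))
          mean_shape <- mean_shape + config$allometry_slope * age * growth
        sdn <- config$sigma * if (affected && treated) config$kappa else 1
        obs <- mean_shape + matrix(stats::rnorm(K * 3L, 0, sdn), K, 3L)
        pre[i, , ] <- mean_shape
        coords[i, , ] <- obs * config$scale_mm
        meta$specimen_id[i] <- sprintf("%s_%03d", g$label[r], j)
        meta$genotype[i] <- g$genotype[r]
        meta$treatment[i] <- g$treatment[r]
        meta$sex[i] <- if (stats::runif(1) < 0.5) "female" else "male"
        meta$age[i] <- age
        truth$specimen_id[i] <- meta$specimen_id[i]
        truth$group[i] <- g$label[r]
        truth$responder[i] <- responder
        truth$age[i] <- age
      }
    }
  })
  meta$age_group <- .bin_age(meta$age, config$cohort)
  dataset <- landmark_dataset(coords, rownames(config$template), meta,
                              scale_note = sprintf(
                                "template units x %g mm", config$scale_mm))
  list(dataset = dataset, truth = list(table = truth, pre_noise = pre))
}

# human-style age strata; mouse cohorts are single-age (days)
.bin_age <- function(age, cohort) {
  if (cohort == "human")
    cut(age, breaks = c(-0.001, 3, 12, 18, Inf),
        labels = c("0-3", "4-12", "13-18", "adult")) |> as.character()
  else as.character(age)
}

#' Per-specimen group labels of a simulated cohort
#'
#' Convenience accessor pairing a simulated dataset with its ground-truth
#' group labels, in specimen order.
#'
#' @param sim the list returned by [simulate_cohort()].
#' @return character vector of group labels.
#' @export
cohort_groups <- function(sim) sim$truth$table$group
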