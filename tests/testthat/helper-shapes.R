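# Shared fixtures: small datasets and geometric helpers, built in code.

# A non-degenerate 4-landmark tetrahedron.
tetra <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.4, 1.1, 0), c(0.5, 0.4, 0.9))
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a random rigid motion + uniform scaling to each specimen.
perturb_rigid <- function(coords, seed = 1) {
  withr::with_seed(seed, {
    for (i in seq_len(dim(coords)[1])) {
      R <- random_rotation()
      s <- runif(1, 0.5, 2)
      tr <- rnorm(3, sd = 5)
      coords[i, , ] <- s * coords[i, , ] %*% R +
        matrix(tr, dim(coords)[2], 3, byrow = TRUE)
    }
    coords
  })
}

# Tiny valid dataset: n specimens as noisy copies of a base shape.
toy_dataset <- function(n = 4, base = tetra(), sd = 0.01, seed = 42) {
  K <- nrow(base)
  coords <- array(NA_real_, dim = c(n, K, 3))
  withr::with_seed(seed, {
    for (i in seq_len(n)) coords[i, , ] <- base + rnorm(K * 3, sd = sd)
  })
  landmark_dataset(coords, paste0("lm", seq_len(K)),
                   data.frame(specimen_id = paste0("S", seq_len(n))))
}

# Two-group cohort generator used across statistical tests.
two_group_config <- function(n_a = 20, n_b = 20, delta = 0, sigma = 0.02,
                             seed = 1) {
  simulation_config(
    "mouse",
    groups = data.frame(
      label = c("A", "B"),
      genotype = c("euploid", if (delta > 0) "trisomic" else "euploid"),
      treatment = "none", n = c(n_a, n_b), age_min = 29, age_max = 29),
    delta = delta, sigma = sigma, seed = seed)
}

# Three-group rescue cohort: control EU, affected DS, treated DS_TE.
rescue_config <- function(n_eu = 20, n_ds = 20, n_te = 7, delta = 0.1,
                          rho = 1, pi_resp = 1, sigma = 0.02, seed = 1) {
  simulation_config(
    "mouse",
    groups = data.frame(
      label = c("EU", "DS", "DS_TE"),
      genotype = c("euploid", "trisomic", "trisomic"),
      treatment = c("none", "none", "low"),
      n = c(n_eu, n_ds, n_te), age_min = 29, age_max = 29),
    delta = delta, rho = rho, pi_resp = pi_resp, sigma = sigma, seed = seed)
}
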