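test_that("a rotated, translated, scaled copy aligns exactly onto the original", {
  base <- tetra()
  R <- withr::with_seed(1, random_rotation())
  copy <- 2 * base %*% R + matrix(c(3, -1, 5), 4, 3, byrow = TRUE)
  coords <- array(NA_real_, dim = c(2, 4, 3))
  coords[1, , ] <- base; coords[2, , ] <- copy
  d <- landmark_dataset(coords, paste0("l", 1:4),
                        data.frame(specimen_id = c("a", "b")))
  al <- gpa_superimpose(d)
  expect_true(al$converged)
  expect_lt(procrustes_distance(al$shape_coords[1, , ],
                                al$shape_coords[2, , ]), 1e-9)
})

test_that("identical specimens converge immediately to their common shape", {
  base <- tetra()
  coords <- array(rep(base, each = 3), dim = c(3, 4, 3))
  d <- landmark_dataset(coords, paste0("l", 1:4),
                        data.frame(specimen_id = c("a", "b", "c")))
  al <- gpa_superimpose(d)
  expect_true(al$converged)
  expect_equal(al$n_iterations, 1L)
  for (i in 1:3)
    expect_equal(al$shape_coords[i, , ], al$consensus, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("aligned configurations are centered with unit centroid size", {
  al <- gpa_superimpose(toy_dataset(n = 6))
  for (i in 1:6) {
    s <- al$shape_coords[i, , ]
    expect_lt(max(abs(colMeans(s))), 1e-9)
    expect_equal(centroid_size(s), 1, tolerance = 1e-9)
  }
  expect_equal(al$consensus, apply(al$shape_coords, c(2, 3), mean),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GPA output is invariant to per-specimen rigid motions and scalings", {
  sim <- simulate_cohort(simulation_config("mouse", seed = 3))
  al1 <- gpa_superimpose(sim$dataset)
  pert <- sim$dataset
  pert$coordinates <- perturb_rigid(pert$coordinates, seed = 99)
  al2 <- gpa_superimpose(landmark_dataset(pert$coordinates,
                                          pert$landmark_labels, pert$meta))
  expect_lt(max(abs(al1$shape_coords - al2$shape_coords)), 1e-8)
})

test_that("summed squared distances to the consensus are non-increasing over iterations", {
  # re-run GPA capped at increasing iteration counts; the objective
  # (total misfit about the evolving mean) must not increase
  d <- toy_dataset(n = 8, sd = 0.05)
  obj <- vapply(1:4, function(it) {
    al <- suppressWarnings(gpa_superimpose(d, tol = 0, max_iter = it))
    sum((sweep(al$shape_coords, c(2, 3),
               apply(al$shape_coords, c(2, 3), mean)))^2)
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-12))
})

test_that("a specimen with coincident landmarks is rejected by name", {
  coords <- array(0, dim = c(2, 4, 3))
  coords[1, , ] <- tetra()
  d <- landmark_dataset(coords, paste0("l", 1:4),
                        data.frame(specimen_id = c("ok", "flat")))
  expect_error(gpa_superimpose(d), "flat")
})

test_that("procrustes_distance is a rotation-invariant metric", {
  s <- tetra(); s <- scale(s, scale = FALSE); s <- s / sqrt(sum(s^2))
  expect_equal(procrustes_distance(s, s), 0)
  R <- withr::with_seed(7, random_rotation())
  expect_lt(procrustes_distance(s, s %*% R), 1e-9)
  s2 <- s; s2[1, ] <- s2[1, ] + 0.2
  expect_equal(procrustes_distance(s, s2), procrustes_distance(s2, s),
               tolerance = 1e-12)
  expect_error(procrustes_distance(s, s[1:3, ]), "mismatch")
})

test_that("procrustes_distance matches an independent optimisation over rotations", {
  # oracle: minimize ||a - b R(angles)|| over Euler angles by multi-start
  # Nelder-Mead, independent of the SVD solution path
  euler <- function(th) {
    cz <- cos(th[1]); sz <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cx <- cos(th[3]); sx <- sin(th[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  a <- tetra(); a <- scale(a, scale = FALSE); a <- a / sqrt(sum(a^2))
  b <- tetra(); b[2, ] <- b[2, ] + c(0.3, -0.2, 0.4)
  b <- scale(b, scale = FALSE); b <- b / sqrt(sum(b^2))
  f <- function(th) sqrt(sum((a - b %*% euler(th))^2))
  best <- withr::with_seed(5, min(vapply(1:25, function(i)
    optim(runif(3, -pi, pi), f, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14))$value,
    numeric(1))))
  expect_equal(procrustes_distance(a, b), best, tolerance = 1e-6)
})

test_that("two-shape GPA agrees with the direct ordinary Procrustes fit", {
  a <- tetra()
  b <- tetra(); b[4, ] <- b[4, ] + c(0, 0, 0.5)  # displaced apex
  coords <- array(NA_real_, dim = c(2, 4, 3))
  coords[1, , ] <- a; coords[2, , ] <- b
  d <- landmark_dataset(coords, paste0("l", 1:4),
                        data.frame(specimen_id = c("a", "b")))
  al <- gpa_superimpose(d)
  gpa_dist <- procrustes_distance(al$shape_coords[1, , ],
                                  al$shape_coords[2, , ])
  an <- scale(a, scale = FALSE); an <- an / sqrt(sum(an^2))
  bn <- scale(b, scale = FALSE); bn <- bn / sqrt(sum(bn^2))
  expect_equal(gpa_dist, procrustes_distance(an, bn), tolerance = 1e-6)
})
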