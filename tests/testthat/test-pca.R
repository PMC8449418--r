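# Kabsch superposition, landscape construction, projection, and
# chi-square correlation along landscape coordinates.

rot_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

rand_cloud <- function(n, seed) {
  pentasans:::.with_seed(seed, matrix(rnorm(3 * n, sd = 8), ncol = 3))
}

test_that("superposition handles rotations, mirrors and matches bio3d", {
  A <- rand_cloud(20, 1)
  B <- A %*% t(rot_about(c(1, 2, 3), 1.1))
  B <- sweep(B, 2, c(4, -2, 9), `+`)
  s <- superpose(B, A)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)

  # mirror image: proper rotation cannot null the RMSD
  M <- A; M[, 1] <- -M[, 1]
  expect_gt(superpose(M, A)$rmsd, 1)

  # independent oracle: Horn's quaternion method gives the optimal
  # RMSD in closed form without constructing the rotation
  quat_rmsd <- function(X, Y) {
    X0 <- scale(X, scale = FALSE); Y0 <- scale(Y, scale = FALSE)
    S <- crossprod(X0, Y0)
    K <- matrix(0, 4, 4)
    K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
    K[1, 2:4] <- c(S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1])
    K[2:4, 1] <- K[1, 2:4]
    K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
    K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
    K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
    K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
    K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
    K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
    lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    sqrt(max(sum(X0^2) + sum(Y0^2) - 2 * lam, 0) / nrow(X))
  }
  X <- rand_cloud(10, 2); Y <- rand_cloud(10, 3)
  s2 <- superpose(X, Y)
  expect_equal(s2$rmsd, quat_rmsd(X, Y), tolerance = 1e-9)

  expect_error(superpose(X, rand_cloud(11, 4)), "correspondence")
})

test_that("landscape of a linear morph is one-dimensional", {
  base <- rand_cloud(30, 5)
  dir1 <- rand_cloud(30, 6); dir1 <- dir1 / sqrt(sum(dir1^2))
  structures <- lapply(seq(-2, 2, length.out = 9),
                       function(a) base + a * dir1)
  ls <- build_landscape(structures, n_components = 2)
  expect_gt(ls$variance[1] / ls$total_variance, 0.999)
  # two structures give exactly one nonzero component
  ls2 <- build_landscape(structures[c(1, 9)], n_components = 1)
  expect_equal(ls2$variance[1], ls2$total_variance, tolerance = 1e-8)
})

test_that("orthogonal deformations yield the constructed variance ratio", {
  base <- rand_cloud(40, 7)
  # rigid-body basis at the base conformation (3 translations + 3
  # infinitesimal rotations); deformations orthogonal to it survive
  # the alignment step unchanged
  b0 <- scale(base, scale = FALSE)
  zero <- rep(0, 40); one <- rep(1, 40)
  rigid <- list(
    cbind(one, zero, zero), cbind(zero, one, zero), cbind(zero, zero, one),
    cbind(zero, -b0[, 3], b0[, 2]),
    cbind(b0[, 3], zero, -b0[, 1]),
    cbind(-b0[, 2], b0[, 1], zero)
  )
  flat <- function(M) as.vector(M)
  Rb <- qr.Q(qr(vapply(rigid, flat, numeric(120))))
  ortho <- function(d) {
    v <- flat(d); v <- v - Rb %*% crossprod(Rb, v)
    matrix(v / sqrt(sum(v^2)), ncol = 3)
  }
  d1 <- ortho(rand_cloud(40, 8))
  d2r <- ortho(rand_cloud(40, 9))
  d2v <- flat(d2r) - flat(d1) * sum(flat(d2r) * flat(d1))
  d2 <- matrix(d2v / sqrt(sum(d2v^2)), ncol = 3)
  set.seed(10)
  a1 <- rnorm(24, sd = 2); a2 <- rnorm(24, sd = 1)
  # decorrelate the finite samples so the constructed covariance is
  # exactly diagonal with ratio var(a1)/var(a2)
  a1 <- a1 - mean(a1); a2 <- a2 - mean(a2)
  a2 <- a2 - a1 * sum(a1 * a2) / sum(a1^2)
  structures <- lapply(1:24, function(i) base + a1[i] * d1 + a2[i] * d2)
  ls <- build_landscape(structures, n_components = 2)
  expect_equal(ls$variance[1] / ls$variance[2], var(a1) / var(a2),
               tolerance = 0.05)
  # components orthonormal; projections centred; variance adds up
  expect_equal(crossprod(ls$components), diag(2), tolerance = 1e-8)
  expect_equal(colMeans(ls$projections), c(0, 0), tolerance = 1e-8)
  ls_full <- build_landscape(structures, n_components = 23)
  expect_equal(sum(ls_full$variance), ls_full$total_variance,
               tolerance = 1e-8)
})

test_that("projection recovers constructed coordinates and inputs", {
  base <- rand_cloud(25, 11)
  structures <- lapply(1:8, function(i) {
    base + matrix(rnorm(75, sd = 0.8), ncol = 3)
  })
  ls <- build_landscape(structures, n_components = 2)
  # the mean projects to the origin
  expect_equal(project_landscape(ls, ls$mean), c(0, 0), tolerance = 1e-8)
  # mean + 2 * PC1 projects to (2, 0)
  disp <- matrix(ls$components[, 1], ncol = 3, byrow = TRUE)
  conf <- ls$mean + 2 * disp
  expect_equal(project_landscape(ls, conf), c(2, 0), tolerance = 1e-6)
  # every input structure reconstructs within the residual variance
  ls_all <- build_landscape(structures, n_components = 7)
  for (i in c(1, 5)) {
    proj <- project_landscape(ls_all, structures[[i]])
    recon <- ls_all$mean + matrix(ls_all$components %*% proj, ncol = 3,
                                  byrow = TRUE)
    aligned <- superpose(structures[[i]], ls_all$mean)$coords
    expect_lt(pentasans:::.rmsd(recon, aligned), 1e-6)
  }
  expect_error(project_landscape(ls, rand_cloud(10, 12)), "correspondence")
})

test_that("landscape is invariant to rigid pre-transformation of inputs", {
  structures <- lapply(1:6, function(i) {
    rand_cloud(20, 20) + i * matrix(c(1, 0, 0), 20, 3, byrow = TRUE) * 0.5
  })
  ls1 <- build_landscape(structures, n_components = 2)
  moved <- structures
  moved[[3]] <- moved[[3]] %*% t(rot_about(c(0, 1, 1), 0.9)) + 7
  ls2 <- build_landscape(moved, n_components = 2)
  expect_equal(abs(ls1$projections), abs(ls2$projections), tolerance = 1e-6)
  expect_equal(ls1$variance, ls2$variance, tolerance = 1e-8)
})

test_that("pathway frames progress monotonically along PC1", {
  pw <- ebdims_interpolate(toy_closed, toy_open, n_frames = 11, seed = 2)
  ls <- build_landscape(pw$frames, n_components = 2)
  pc1 <- vapply(pw$frames, function(f) project_landscape(ls, f)[1],
                numeric(1))
  expect_true(all(diff(pc1) > 0) || all(diff(pc1) < 0))
})

test_that("chi-square correlates with landscape coordinates as constructed", {
  x <- seq(-3, 3, length.out = 60)
  proj <- cbind(x, 0 * x)
  # V-shaped chi2: minimum bin at the centre, symmetric profile
  cf <- correlate_fit(proj, abs(x), component = 1, n_bins = 12)
  expect_lt(abs(cf$min_bin_center), 0.55)
  prof <- cf$bin_mean_chi2
  expect_equal(prof, rev(prof), tolerance = 1e-9)
  # linear chi2: perfect rank correlation
  cf_lin <- correlate_fit(proj, 2 + 0.5 * x, component = 1)
  expect_equal(cf_lin$spearman, 1)
  cf_neg <- correlate_fit(proj, -x, component = 1)
  expect_equal(cf_neg$spearman, -1)
  expect_error(correlate_fit(proj[1:2, ], c(1, 2)), "at least 3")
})
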