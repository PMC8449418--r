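# Coarse-grained elastic networks: construction, normal modes,
# distance-space interpolation between two end-state structures
# (an elastic-network-driven stand-in for Brownian-dynamics morphing),
# and thermal-like normal-mode perturbation sampling.

# C-alpha coordinates of a model (bead models use CA-named beads)
.calpha_coords <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  sel <- model$atoms$atom_name == "CA"
  if (sum(sel) < 2L) stop("model has fewer than 2 C-alpha atoms")
  list(xyz = coords(model)[sel, , drop = FALSE], index = which(sel))
}

#' Build an elastic network on C-alpha atoms
#'
#' Nodes are the C-alpha atoms; springs connect every pair within the
#' cutoff, with equilibrium lengths equal to the input distances and a
#' uniform spring constant.
#'
#' @param model an `atomic_model` (C-alpha atoms are selected by atom
#'   name `CA`; toy bead models qualify).
#' @param cutoff interaction cutoff, Angstrom (default 10).
#' @param gamma uniform spring constant (arbitrary energy/A^2).
#' @return an object of class `elastic_network`: `nodes` (n x 3),
#'   `edges` (2-column index matrix, i < j), `d0` (equilibrium
#'   lengths), `cutoff`, `gamma`, `atom_index` (row of each node in
#'   the source model).
#' @export
build_enm <- function(model, cutoff = 10, gamma = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ca <- .calpha_coords(model)
  xyz <- ca$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff & upper.tri(d)
  edges <- which(adj, arr.ind = TRUE)
  colnames(edges) <- NULL
  edges <- edges[, c(1, 2), drop = FALSE]
  if (nrow(edges) == 0L) stop("connectivity error: no edges at cutoff ", cutoff)
  # connectivity check (BFS over the undirected edge list)
  nbr <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    new <- nbr[[v]][!seen[nbr[[v]]]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen)) {
    stop("connectivity error: network splits into multiple components; ",
         "increase the cutoff (", cutoff, " A)")
  }
  structure(
    list(nodes = xyz, edges = edges,
         d0 = d[edges], cutoff = cutoff, gamma = gamma,
         atom_index = ca$index),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("Elastic network: %d nodes, %d springs, cutoff %.1f A\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Anisotropic-network Hessian of an elastic network
#'
#' Standard ANM Hessian: for each spring (i, j) the off-diagonal 3x3
#' block is `-(gamma / d0^2) (r_i - r_j)(r_i - r_j)^T`, diagonal blocks
#' minus the row sums. A connected network has exactly six zero modes
#' (rigid translations and rotations).
#'
#' @param network an `elastic_network`.
#' @return 3n x 3n symmetric matrix.
#' @export
enm_hessian <- function(network) {
  stopifnot(inherits(network, "elastic_network"))
  x <- network$nodes
  n <- nrow(x)
  H <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(network$edges))) {
    i <- network$edges[e, 1]; j <- network$edges[e, 2]
    dv <- x[i, ] - x[j, ]
    d2 <- sum(dv^2)
    blk <- -(network$gamma / d2) * tcrossprod(dv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Low-frequency normal modes of an elastic network
#'
#' Returns the softest genuine deformation modes. A connected network
#' has six zero modes (rigid translations/rotations); an underbraced
#' one can have additional floppy mechanisms, which are skipped (with
#' a warning) rather than returned, since their vanishing eigenvalues
#' would otherwise dominate any thermal-amplitude weighting.
#'
#' @param network an `elastic_network`.
#' @param n_modes number of non-rigid-body modes to return.
#' @param zero_tol eigenvalues below `zero_tol * max(eigenvalue)`
#'   count as zero modes.
#' @return list with `vectors` (3n x n_modes, orthonormal),
#'   `values` (eigenvalues, ascending), `rigid_values` (the six
#'   smallest) and `n_zero` (number of near-zero modes found).
#' @export
enm_modes <- function(network, n_modes = 10, zero_tol = 1e-8) {
  H <- enm_hessian(network)
  eig <- eigen(H, symmetric = TRUE)
  k <- ncol(eig$vectors)
  ord <- k:1 # ascending
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  n_zero <- sum(abs(vals) < zero_tol * max(vals))
  if (n_zero > 6L) {
    warning(sprintf(
      "network has %d floppy mechanism(s) beyond the 6 rigid-body modes; skipping them (consider a larger cutoff)",
      n_zero - 6L))
  }
  n_zero <- max(n_zero, 6L)
  if (n_modes > k - n_zero) stop("n_modes too large for this network")
  sel <- (n_zero + 1L):(n_zero + n_modes)
  list(vectors = vecs[, sel, drop = FALSE], values = vals[sel],
       rigid_values = vals[1:6], n_zero = n_zero)
}

# SMACOF (stress majorisation) relaxation of coordinates toward a set
# of target pairwise distances on an edge list. V-pseudo-inverse is
# precomputed by the caller. Monotone in the stress, no step size.
.smacof_step <- function(X, edges, d0, Vinv) {
  n <- nrow(X)
  dv <- X[edges[, 1], , drop = FALSE] - X[edges[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  d[d < 1e-9] <- 1e-9
  ratio <- d0 / d
  BX <- matrix(0, n, 3)
  # B X with b_ij = -ratio on edges, b_ii = sum of ratios
  contrib <- ratio * X[edges[, 2], , drop = FALSE]
  contrib2 <- ratio * X[edges[, 1], , drop = FALSE]
  for (col in 1:3) {
    BX[, col] <- BX[, col] +
      as.vector(tapply(c(contrib[, col], contrib2[, col]),
                       c(edges[, 1], edges[, 2]), sum)[as.character(1:n)])
  }
  BX[is.na(BX)] <- 0
  diagB <- as.vector(tapply(c(ratio, ratio), c(edges[, 1], edges[, 2]),
                            sum)[as.character(1:n)])
  diagB[is.na(diagB)] <- 0
  BX <- diagB * X - BX
  Vinv %*% BX
}

# pseudo-inverse of the unweighted graph Laplacian
.laplacian_pinv <- function(n, edges) {
  V <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    V[i, j] <- V[i, j] - 1
    V[j, i] <- V[j, i] - 1
    V[i, i] <- V[i, i] + 1
    V[j, j] <- V[j, j] + 1
  }
  eig <- eigen(V, symmetric = TRUE)
  pos <- eig$values > 1e-8 * max(eig$values)
  eig$vectors[, pos, drop = FALSE] %*%
    (t(eig$vectors[, pos, drop = FALSE]) / eig$values[pos])
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Elastic-network interpolation between two end states
#'
#' Generates a physically plausible transition pathway between two
#' conformations of the same molecule. The equilibrium lengths of a
#' union elastic network (springs present in either end state) are
#' scheduled from the source distances to the target distances; at
#' each schedule step the coordinates relax by stress-majorisation
#' (monotone, overdamped updates), optionally with seeded thermal
#' noise. Frames are emitted as the RMSD to the source grows in steps,
#' the first frame being the source itself and the last a conformation
#' within ~1 A RMSD of the target. Interpolating distances rather than
#' Cartesian coordinates keeps intermediate frames locally rigid, and
#' running the scheme with the end states swapped yields a second,
#' generally different pathway.
#'
#' @param source,target `atomic_model`s with identical C-alpha
#'   correspondence (same count, matched order).
#' @param n_frames number of frames to return (default 25).
#' @param step_rmsd frame spacing in RMSD-to-source, Angstrom; default
#'   spreads frames evenly over the source-target RMSD.
#' @param seed RNG seed for the thermal noise.
#' @param cutoff,gamma elastic-network parameters.
#' @param noise_amplitude per-step thermal displacement, Angstrom RMSD
#'   (default 0, fully deterministic).
#' @param n_schedule number of schedule points (default 120).
#' @param tol_target convergence requirement on the final frame's
#'   RMSD to the target, Angstrom.
#' @return an object of class `pathway_ensemble`: `frames` (list of
#'   C-alpha coordinate matrices), `rmsd_to_source`, `rmsd_to_target`,
#'   `source_label`, `target_label`, `params`.
#' @export
ebdims_interpolate <- function(source, target, n_frames = 25,
                               step_rmsd = NULL, seed = 1L,
                               cutoff = 10, gamma = 1,
                               noise_amplitude = 0, n_schedule = 120,
                               tol_target = 1.0) {
  ca_s <- .calpha_coords(source)
  ca_t <- .calpha_coords(target)
  if (nrow(ca_s$xyz) != nrow(ca_t$xyz)) {
    stop("correspondence mismatch: C-alpha counts differ (",
         nrow(ca_s$xyz), " vs ", nrow(ca_t$xyz), ")")
  }
  # centre at the origin: the stress-majorisation update returns
  # centred coordinates, so RMSD bookkeeping must be translation-free
  X_src <- sweep(ca_s$xyz, 2, colMeans(ca_s$xyz))
  X_tgt <- superpose(ca_t$xyz, X_src)$coords
  X_tgt <- sweep(X_tgt, 2, colMeans(X_tgt))
  total_rmsd <- .rmsd(X_src, X_tgt)
  params <- list(n_frames = n_frames, step_rmsd = step_rmsd, seed = seed,
                 cutoff = cutoff, gamma = gamma,
                 noise_amplitude = noise_amplitude)
  if (total_rmsd < 1e-6) {
    return(structure(
      list(frames = list(X_src), rmsd_to_source = 0,
           rmsd_to_target = total_rmsd,
           source_label = source$label, target_label = target$label,
           params = params),
      class = "pathway_ensemble"))
  }
  if (n_frames < 2L) stop("n_frames must be >= 2 for distinct end states")
  # union edge set so contacts formed in either state are restrained
  d_s <- as.matrix(stats::dist(X_src))
  d_t <- as.matrix(stats::dist(X_tgt))
  adj <- (d_s <= cutoff | d_t <= cutoff) & upper.tri(d_s)
  edges <- which(adj, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
  d0_s <- d_s[adj]; d0_t <- d_t[adj]
  n <- nrow(X_src)
  Vinv <- .laplacian_pinv(n, edges)
  lambda <- seq(0, 1, length.out = n_schedule + 1L)[-1]
  X <- X_src
  traj <- list(X_src)
  noise_draws <- if (noise_amplitude > 0) {
    .with_seed(seed, stats::rnorm(n_schedule * n * 3, 0, noise_amplitude))
  } else NULL
  for (s in seq_along(lambda)) {
    d0 <- (1 - lambda[s]) * d0_s + lambda[s] * d0_t
    for (it in 1:3) X <- .smacof_step(X, edges, d0, Vinv)
    if (!is.null(noise_draws)) {
      idx <- ((s - 1) * n * 3 + 1):(s * n * 3)
      X <- X + matrix(noise_draws[idx], n, 3)
    }
    traj[[length(traj) + 1L]] <- X
  }
  # converge fully at lambda = 1
  for (it in 1:200) {
    X_new <- .smacof_step(X, edges, d0_t, Vinv)
    if (.rmsd(X_new, X) < 1e-5) { X <- X_new; break }
    X <- X_new
  }
  traj[[length(traj)]] <- X
  if (.rmsd(X, X_tgt) > tol_target) {
    stop(sprintf(
      "convergence error: final frame is %.2f A RMSD from the target (> %.2f); schedule too coarse or network too sparse",
      .rmsd(X, X_tgt), tol_target))
  }
  r_src <- vapply(traj, .rmsd, numeric(1), b = X_src)
  r_tgt <- vapply(traj, .rmsd, numeric(1), b = X_tgt)
  if (is.null(step_rmsd)) step_rmsd <- max(r_src) / (n_frames - 1L)
  # pick frames at RMSD-to-source checkpoints, enforcing a monotone
  # approach to the target
  picks <- 1L
  for (fidx in 2:(n_frames - 1L)) {
    want <- (fidx - 1L) * step_rmsd
    cand <- which(r_src >= want & seq_along(traj) > picks[length(picks)] &
                    r_tgt <= r_tgt[picks[length(picks)]] + 1e-9)
    picks <- c(picks, if (length(cand)) cand[1] else picks[length(picks)])
  }
  picks <- c(picks, length(traj))
  frames <- traj[picks]
  structure(
    list(frames = frames, rmsd_to_source = r_src[picks],
         rmsd_to_target = r_tgt[picks],
         source_label = source$label, target_label = target$label,
         params = params),
    class = "pathway_ensemble"
  )
}

#' @export
print.pathway_ensemble <- function(x, ...) {
  cat(sprintf(
    "Pathway: %d frames, %s -> %s, final RMSD to target %.2f A\n",
    length(x$frames), x$source_label, x$target_label,
    x$rmsd_to_target[length(x$frames)]))
  invisible(x)
}

#' Rebuild full models along a pathway
#'
#' Carries every atom of the source model rigidly with its C-alpha:
#' each atom is translated by the displacement of the C-alpha of its
#' residue (nearest C-alpha if the residue has none). Adequate at SANS
#' resolution; no side-chain reconstruction is attempted.
#'
#' @param pathway a `pathway_ensemble`.
#' @param model the source `atomic_model` the pathway was built from.
#' @return list of `atomic_model`s, one per frame.
#' @export
pathway_models <- function(pathway, model) {
  stopifnot(inherits(pathway, "pathway_ensemble"),
            inherits(model, "atomic_model"))
  ca <- .calpha_coords(model)
  xyz0 <- coords(model)
  # map each atom to a C-alpha node (same chain+resno, else nearest)
  a <- model$atoms
  ca_key <- paste(a$chain[ca$index], a$resno[ca$index])
  key <- paste(a$chain, a$resno)
  map <- match(key, ca_key)
  if (anyNA(map)) {
    ca_xyz <- xyz0[ca$index, , drop = FALSE]
    for (i in which(is.na(map))) {
      map[i] <- which.min(colSums((t(ca_xyz) - xyz0[i, ])^2))
    }
  }
  lapply(seq_along(pathway$frames), function(f) {
    disp <- pathway$frames[[f]] - pathway$frames[[1]]
    new_xyz <- xyz0 + disp[map, , drop = FALSE]
    m <- model
    m$atoms$x <- new_xyz[, 1]; m$atoms$y <- new_xyz[, 2]
    m$atoms$z <- new_xyz[, 3]
    m$label <- sprintf("%s frame %d", model$label, f)
    m
  })
}

#' Thermal-like normal-mode perturbation sampling
#'
#' Draws conformations around a frame by exciting the low-frequency
#' normal modes of its elastic network: displacement
#' `sum_k c_k v_k` with `c_k ~ N(0, 1/lambda_k)`, rescaled so the
#' expected RMSD equals `amplitude`. A cheap, desk-scale stand-in for
#' thermal sampling of the conformational basin.
#'
#' @param frame an `atomic_model`.
#' @param network the frame's `elastic_network` (built if `NULL`).
#' @param n_modes number of non-rigid modes to excite.
#' @param amplitude expected displacement, Angstrom RMSD.
#' @param n_samples number of conformations to draw.
#' @param seed RNG seed.
#' @return list of `atomic_model`s.
#' @export
nm_perturb_sample <- function(frame, network = NULL, n_modes = 10,
                              amplitude = 1, n_samples = 10, seed = 1L) {
  stopifnot(inherits(frame, "atomic_model"), n_modes >= 1, amplitude >= 0,
            n_samples >= 1)
  if (is.null(network)) network <- build_enm(frame)
  ca <- .calpha_coords(frame)
  n <- nrow(ca$xyz)
  if (amplitude == 0) {
    return(replicate(n_samples, frame, simplify = FALSE))
  }
  modes <- enm_modes(network, n_modes = n_modes)
  sd_k <- 1 / sqrt(modes$values)
  coefs <- .with_seed(seed,
    matrix(stats::rnorm(n_samples * n_modes), n_samples, n_modes))
  coefs <- sweep(coefs, 2, sd_k, `*`)
  # scale so that E[RMSD^2] = amplitude^2
  exp_norm2 <- sum(sd_k^2)
  scale <- amplitude * sqrt(n) / sqrt(exp_norm2)
  xyz0 <- coords(frame)
  a <- frame$atoms
  ca_key <- paste(a$chain[ca$index], a$resno[ca$index])
  map <- match(paste(a$chain, a$resno), ca_key)
  lapply(seq_len(n_samples), function(s) {
    delta <- matrix(modes$vectors %*% coefs[s, ], n, 3, byrow = TRUE) * scale
    new_xyz <- xyz0 + delta[map, , drop = FALSE]
    m <- frame
    m$atoms$x <- new_xyz[, 1]; m$atoms$y <- new_xyz[, 2]
    m$atoms$z <- new_xyz[, 3]
    m$label <- sprintf("%s perturb %d", frame$label, s)
    m
  })
}
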