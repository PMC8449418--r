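# End-to-end workflows: single-structure fitting of candidate models
# to a measured curve, and the ensemble workflow (pathway generation,
# perturbation sampling, forward curves, fits, landscape projection).

.pkg_version <- function() {
  as.character(utils::packageVersion("pentasans"))
}

#' Fit candidate models to a measured curve
#'
#' For each candidate atomic model: compute its theoretical curve in
#' the given solvent, interpolate onto the data grid, fit scale and
#' background, and rank by reduced chi-square.
#'
#' @param models non-empty list of annotated `atomic_model`s.
#' @param data a `sans_curve` with uncertainties.
#' @param solvent a `solvent_spec`.
#' @param q_range optional length-2 trimming window applied to the data.
#' @param labels optional model labels.
#' @param debye_method forwarded to [debye_curve()] (`"histogram"`
#'   trades ~0.2% accuracy for large speedups on bead models).
#' @param out_dir optional directory; when given, the fit table
#'   (TSV + JSON) and a data-vs-fit plot (PDF) are written there.
#' @return list with `fits` (ranked `fit_result`s), `table`
#'   (data.frame), `theories` (interpolated curves, input order),
#'   `data`, `config`.
#' @export
run_single_fit <- function(models, data, solvent = solvent_spec(),
                           q_range = NULL, labels = NULL,
                           debye_method = "auto", out_dir = NULL) {
  if (length(models) == 0L) stop("validation error: empty model list")
  stopifnot(inherits(data, "sans_curve"))
  if (!is.null(q_range)) {
    sel <- data$Q >= q_range[1] & data$Q <= q_range[2]
    data <- scattering_curve(data$Q[sel], data$I[sel],
                             sigma = data$sigma[sel], meta = data$meta,
                             absolute = data$absolute)
  }
  if (is.null(labels)) {
    labels <- vapply(seq_along(models), function(i) {
      lb <- models[[i]]$label
      if (nzchar(lb)) lb else sprintf("model_%02d", i)
    }, character(1))
  }
  theories <- lapply(models, function(m) {
    th <- debye_curve(m, solvent, Q_grid = sort(unique(c(
      seq(min(data$Q), max(data$Q), length.out = 120), data$Q))),
      method = debye_method)
    interpolate_theory(th, data$Q)
  })
  fits <- rank_ensemble(theories, data, labels = labels)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model_label"),
    chi2_reduced = vapply(fits, `[[`, numeric(1), "chi2_reduced"),
    scale = vapply(fits, `[[`, numeric(1), "scale"),
    background = vapply(fits, `[[`, numeric(1), "background"),
    n_points = vapply(fits, `[[`, integer(1), "n_points")
  )
  config <- list(n_models = length(models), q_range = q_range,
                 solvent = unclass(solvent), version = .pkg_version())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "fits.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(config = config, fits = tab),
                         file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    grDevices::pdf(file.path(out_dir, "fit.pdf"), width = 6, height = 5)
    plot_fit(data, theories[[fits[[1]]$index]], fits[[1]])
    grDevices::dev.off()
  }
  list(fits = fits, table = tab, theories = theories, data = data,
       config = config)
}

#' Plot data with a fitted model curve and residuals
#'
#' @param data measured `sans_curve`.
#' @param theory model curve on the data grid.
#' @param fit the corresponding `fit_result`.
#' @return invisibly, `NULL`; draws on the active device.
#' @export
plot_fit <- function(data, theory, fit) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(old))
  yfit <- fit$scale * theory$I + fit$background
  pos <- data$I > 0 # noisy high-Q points can dip below zero
  graphics::plot(data$Q[pos], data$I[pos], log = "xy", pch = 16, cex = 0.4,
                 xlab = "", ylab = "I(Q)",
                 main = sprintf("%s: chi2 = %.2f", fit$model_label,
                                fit$chi2_reduced))
  graphics::lines(data$Q[yfit > 0], yfit[yfit > 0], col = "red", lwd = 1.5)
  graphics::par(mar = c(4, 4, 0.5, 1))
  res <- (data$I - yfit) / data$sigma
  graphics::plot(data$Q, res, log = "x", pch = 16, cex = 0.4,
                 xlab = "Q [1/A]", ylab = "residual / sigma")
  graphics::abline(h = 0, col = "grey")
  invisible(NULL)
}

#' Ensemble workflow: pathway, sampling, fits, landscape
#'
#' End-to-end analysis mirroring the ensemble-modelling strategy for
#' gating studies: generate transition pathways between two endpoint
#' structures in both directions, optionally sample thermal-like
#' perturbations around each frame, compute theoretical curves for all
#' conformations, fit each against the measured curve, build a PCA
#' landscape from the pathway frames, project every conformation, and
#' summarise chi-square along PC1/PC2.
#'
#' @param endpoint_a,endpoint_b annotated `atomic_model`s (e.g.
#'   closed-like and open-like states) with matched correspondence.
#' @param data a `sans_curve` with uncertainties.
#' @param solvent a `solvent_spec`.
#' @param n_frames frames per pathway direction.
#' @param n_perturb perturbation samples per frame (0 to disable).
#' @param perturb_amplitude RMSD amplitude of the perturbations, A.
#' @param seed seed controlling pathway noise and perturbations.
#' @param cutoff elastic-network cutoff, Angstrom.
#' @param n_bins bins for the chi-square-vs-PC summary.
#' @param debye_method forwarded to [debye_curve()].
#' @param out_dir optional output directory (projection table TSV,
#'   summary JSON, multi-MODEL PDB of pathway frames).
#' @return list with `pathways`, `conformations` (coordinate
#'   matrices), `chi2`, `landscape`, `projections`,
#'   `pc1_summary`, `pc2_summary`, `best`, `config`.
#' @export
run_ensemble_workflow <- function(endpoint_a, endpoint_b, data,
                                  solvent = solvent_spec(),
                                  n_frames = 25, n_perturb = 0,
                                  perturb_amplitude = 0.8, seed = 1L,
                                  cutoff = 10, n_bins = 20,
                                  debye_method = "auto", out_dir = NULL) {
  stopifnot(inherits(data, "sans_curve"))
  pw_ab <- ebdims_interpolate(endpoint_a, endpoint_b, n_frames = n_frames,
                              seed = seed, cutoff = cutoff)
  pw_ba <- ebdims_interpolate(endpoint_b, endpoint_a, n_frames = n_frames,
                              seed = seed + 1L, cutoff = cutoff)
  models_ab <- pathway_models(pw_ab, endpoint_a)
  models_ba <- pathway_models(pw_ba, endpoint_b)
  models <- c(models_ab, models_ba)
  origin <- c(sprintf("A>B_%02d", seq_along(models_ab)),
              sprintf("B>A_%02d", seq_along(models_ba)))
  if (n_perturb > 0) {
    extra <- list(); extra_origin <- character(0)
    for (i in seq_along(models)) {
      net <- build_enm(models[[i]], cutoff = cutoff)
      samp <- nm_perturb_sample(models[[i]], net, n_modes = 5,
                                amplitude = perturb_amplitude,
                                n_samples = n_perturb,
                                seed = seed + 100L + i)
      extra <- c(extra, samp)
      extra_origin <- c(extra_origin,
                        sprintf("%s_p%02d", origin[i], seq_len(n_perturb)))
    }
    models <- c(models, extra)
    origin <- c(origin, extra_origin)
  }
  q_theory <- sort(unique(c(seq(min(data$Q), max(data$Q),
                                length.out = 120), data$Q)))
  chi2 <- vapply(models, function(m) {
    th <- interpolate_theory(debye_curve(m, solvent, q_theory,
                                         method = debye_method), data$Q)
    fit_model(th, data)$chi2_reduced
  }, numeric(1))
  # landscape from the pathway frames (the transition coordinate set)
  frame_models <- c(models_ab, models_ba)
  landscape <- build_landscape(lapply(frame_models, .as_conf),
                               n_components = 2,
                               labels = origin[seq_along(frame_models)])
  projections <- t(vapply(models, function(m)
    project_landscape(landscape, m), numeric(2)))
  colnames(projections) <- c("PC1", "PC2")
  pc1 <- correlate_fit(projections, chi2, component = 1, n_bins = n_bins)
  pc2 <- correlate_fit(projections, chi2, component = 2, n_bins = n_bins)
  best <- which.min(chi2)
  config <- list(n_frames = n_frames, n_perturb = n_perturb,
                 perturb_amplitude = perturb_amplitude, seed = seed,
                 cutoff = cutoff, n_bins = n_bins,
                 version = .pkg_version())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(conformation = origin, PC1 = projections[, 1],
                      PC2 = projections[, 2], chi2_reduced = chi2)
    utils::write.table(tab, file.path(out_dir, "projections.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config = config,
           best = list(conformation = origin[best], chi2 = chi2[best],
                       PC1 = projections[best, 1],
                       PC2 = projections[best, 2]),
           pc1_min_bin = pc1$min_bin_center,
           pc2_min_bin = pc2$min_bin_center),
      file.path(out_dir, "ensemble_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_structure(endpoint_a, file.path(out_dir, "pathway_ab.pdb"),
                    frames = lapply(pathway_models(pw_ab, endpoint_a), coords))
  }
  list(pathways = list(ab = pw_ab, ba = pw_ba),
       conformations = lapply(models, coords), origin = origin,
       chi2 = chi2, landscape = landscape, projections = projections,
       pc1_summary = pc1, pc2_summary = pc2,
       best = list(index = best, origin = origin[best], chi2 = chi2[best],
                   PC1 = projections[best, 1], PC2 = projections[best, 2]),
       config = config)
}
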