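#' Study configuration
#'
#' Sweep specification for the full simulation study: a battery of spherical
#' lesions in a 4-shell sphere head, three lesion conductivities, coronal
#' and sagittal montage rotations over a set of angles, and electrode
#' subsets of increasing size. Defaults reproduce the study conditions:
#' lesion radii 2.9, 14.2, 23.0 and 27.3 mm (about 0.1, 12, 51 and 85 ml)
#' at a fixed left-temporal center, conductivities 0.74/1.23/1.71 S/m,
#' angles 0/0.1/0.5/1/5 degrees, subsets 8/16/32/64/128, 0.1 mA.
#'
#' @param head_radii sphere-head surface radii, mm.
#' @param head_conductivities tissue conductivities, S/m.
#' @param elements_per_surface requested mesh elements per head surface.
#' @param lesion_center common lesion center, mm.
#' @param lesion_radii lesion radii battery, mm.
#' @param lesion_elements requested lesion mesh elements.
#' @param lesion_conductivities true lesion conductivities swept, S/m.
#' @param axes rotation axes swept.
#' @param angles_deg rotation angles swept, degrees (0 is evaluated once
#'   and shared across axes).
#' @param subset_sizes electrode subset sizes swept.
#' @param current stimulation current, A.
#' @param estimation an [estimation_config()].
#' @param refine montage-search refinement policy (see [find_optimal_pair()]).
#' @param seed study-level seed recorded in the outputs; the
#'   estimator's starts are drawn from `estimation$seed`.
#' @return object of class `study_config`.
#' @export
study_config <- function(head_radii = c(92, 86, 80, 78),
                         head_conductivities = c(0.414, 0.016, 1.71, 0.37),
                         elements_per_surface = 3200,
                         lesion_center = default_lesion_center(),
                         lesion_radii = c(2.9, 14.2, 23.0, 27.3),
                         lesion_elements = 1280,
                         lesion_conductivities = c(0.74, 1.23, 1.71),
                         axes = c("coronal", "sagittal"),
                         angles_deg = c(0, 0.1, 0.5, 1, 5),
                         subset_sizes = c(8, 16, 32, 64, 128),
                         current = 1e-4,
                         estimation = estimation_config(),
                         refine = "winner",
                         seed = 1L) {
  stopifnot(length(lesion_radii) >= 1, length(lesion_conductivities) >= 1,
            length(axes) >= 1, length(angles_deg) >= 1,
            length(subset_sizes) >= 1)
  if (any(lesion_conductivities <= 0 | lesion_conductivities > 2))
    stop("lesion conductivities must be in (0, 2] S/m")
  structure(list(head_radii = head_radii,
                 head_conductivities = head_conductivities,
                 elements_per_surface = elements_per_surface,
                 lesion_center = lesion_center,
                 lesion_radii = lesion_radii,
                 lesion_elements = lesion_elements,
                 lesion_conductivities = lesion_conductivities,
                 axes = axes, angles_deg = angles_deg,
                 subset_sizes = subset_sizes, current = current,
                 estimation = estimation, refine = refine,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Default left-temporal lesion center
#'
#' 49 mm from the head center towards the left temporal scalp (20 degrees
#' above the left interaural direction), deep enough that the largest
#' battery lesion keeps 1 mm clearance from the brain surface.
#'
#' @return length-3 numeric vector, mm.
#' @export
default_lesion_center <- function() {
  49 * c(-cos(20 * pi / 180), 0, sin(20 * pi / 180))
}

#' Load a study configuration from YAML
#'
#' Fields mirror the arguments of [study_config()]; omitted fields keep
#' their defaults. The `estimation` field may itself be a map of
#' [estimation_config()] arguments.
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$estimation))
    raw$estimation <- do.call(estimation_config, raw$estimation)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(study_config, raw)
}

#' Run the full simulation study
#'
#' For each lesion in the battery: build the with/without-lesion models,
#' find the optimal stimulation pair, then for every combination of true
#' lesion conductivity, rotation axis, angle and electrode subset simulate
#' the recorded potentials at the rotated montage and estimate the
#' conductivity against the nominal montage. The zero-degree rotation is
#' axis-independent and evaluated once per combination (axis "none").
#' Failures in any cell are caught and recorded in the `status` column.
#'
#' @param config a [study_config()].
#' @param progress print per-row progress to stderr.
#' @return a `study_result` data.frame, one row per study cell, with the
#'   seed and a config hash in its attributes.
#' @export
run_study <- function(config = study_config(), progress = TRUE) {
  base <- make_sphere_head(config$head_radii, config$head_conductivities,
                           config$elements_per_surface)
  layout <- place_electrodes_10_5(base$surfaces[[1]])
  angles <- sort(unique(config$angles_deg))
  note <- function(...) if (progress) message(sprintf(...))

  rows <- list()
  for (radius in config$lesion_radii) {
    spec <- lesion_spec(config$lesion_center, radius,
                        config$lesion_conductivities[1])
    lesioned <- add_spherical_lesion(base, spec, config$lesion_elements)
    met <- lesion_metrics(lesioned)
    note("lesion r=%.1f mm (%.1f ml): searching optimal pair", radius,
         met$volume_ml)
    pt <- find_optimal_pair(lesioned, base, layout, config$current,
                            refine = config$refine)
    opt <- attr(pt, "optimal")
    pair <- c(opt$anode, opt$cathode)
    note("  optimal pair %s-%s (RMSD %.3e V)", opt$anode, opt$cathode,
         opt$rmsd_V)

    cells <- expand.grid(sigma_true = config$lesion_conductivities,
                         axis = c("none", config$axes),
                         angle_deg = angles, stringsAsFactors = FALSE)
    cells <- cells[(cells$axis == "none") == (cells$angle_deg == 0), ]
    cache <- lesion_forward_cache(lesioned, pair, layout, config$current)

    for (ci in seq_len(nrow(cells))) {
      sigma_true <- cells$sigma_true[ci]
      axis <- cells$axis[ci]
      angle <- cells$angle_deg[ci]
      rot <- if (axis == "none") NULL else rotation_spec(axis, angle)
      true_model <- set_lesion_conductivity(lesioned, sigma_true)
      for (size in config$subset_sizes) {
        row <- data.frame(lesion_radius_mm = radius,
                          volume_ml = met$volume_ml, depth_mm = met$depth_mm,
                          anode = opt$anode, cathode = opt$cathode,
                          pair_rmsd_V = opt$rmsd_V,
                          sigma_true = sigma_true, axis = axis,
                          angle_deg = angle, subset = size,
                          sigma_hat = NA_real_, absolute_error = NA_real_,
                          relative_error = NA_real_, converged = FALSE,
                          mean_displacement_mm = 0, status = "ok",
                          stringsAsFactors = FALSE)
        out <- tryCatch({
          sub <- select_subset(layout, size)
          if (!is.null(rot))
            row$mean_displacement_mm <- mean_displacement(sub,
                                                          rotate_layout(sub, rot))
          psi <- simulate_recorded(true_model, pair, layout, size, rot,
                                   config$current, cache = cache)
          est <- estimate_lesion_conductivity(
            psi, lesioned, pair, layout, size,
            config = config$estimation, current = config$current,
            cache = cache)
          row$converged <- !is.na(est$best_sigma)
          if (row$converged) {
            err <- error_metrics(est, sigma_true)
            row$sigma_hat <- est$best_sigma
            row$absolute_error <- err$absolute
            row$relative_error <- err$relative
          }
          row
        }, error = function(e) {
          row$status <- paste("error:", conditionMessage(e))
          row
        })
        rows[[length(rows) + 1L]] <- out
        note("  sigma=%.2f axis=%-8s angle=%.1f subset=%3d -> %s", sigma_true,
             axis, angle, size,
             if (out$converged) sprintf("sigma_hat=%.4f (rel err %.2e)",
                                        out$sigma_hat, out$relative_error)
             else out$status)
      }
    }
  }
  tab <- do.call(rbind, rows)
  structure(tab, class = c("study_result", "data.frame"),
            seed = config$seed, config_hash = rlang::hash(unclass(config)))
}

#' Summarize study errors
#'
#' Mean and sample (n-1) standard deviation of the absolute and relative
#' estimation errors by group. Non-converged cells are excluded from the
#' means and counted separately, as are cells that failed outright.
#'
#' @param table a `study_result` from [run_study()].
#' @param group_by character vector of grouping columns.
#' @return data.frame with group columns, n, n_nonconverged, and
#'   mean/sd of absolute (S/m) and relative errors.
#' @export
summarize_study <- function(table, group_by = c("axis", "angle_deg")) {
  if (!nrow(table)) stop("empty study table")
  groups <- interaction(table[group_by], drop = TRUE, lex.order = TRUE)
  parts <- split(seq_len(nrow(table)), groups)
  out <- lapply(parts, function(idx) {
    sub <- table[idx, , drop = FALSE]
    conv <- sub[sub$converged & sub$status == "ok", , drop = FALSE]
    # sample sd; 0 for a single observation, NA when nothing converged
    sd1 <- function(x) {
      if (length(x) == 0) NA_real_ else if (length(x) == 1) 0 else sd(x)
    }
    mean1 <- function(x) if (length(x) == 0) NA_real_ else mean(x)
    cbind(sub[1, group_by, drop = FALSE],
          data.frame(n = nrow(sub), n_converged = nrow(conv),
                     n_nonconverged = sum(!sub$converged),
                     mean_absolute = mean1(conv$absolute_error),
                     sd_absolute = sd1(conv$absolute_error),
                     mean_relative = mean1(conv$relative_error),
                     sd_relative = sd1(conv$relative_error)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write study outputs
#'
#' Writes the result table as CSV and the run metadata (seed, config hash)
#' as JSON next to it.
#'
#' @param table a `study_result`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_study_results <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(table, file.path(dir, "study_results.csv"), row.names = FALSE)
  meta <- list(seed = attr(table, "seed"),
               config_hash = attr(table, "config_hash"),
               n_rows = nrow(table),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(dir, "study_metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
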