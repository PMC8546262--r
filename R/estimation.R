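#' Estimator configuration
#'
#' Defaults follow the study protocol: 10 random initial lesion-conductivity
#' estimates drawn uniformly in [0.033, 2] S/m, iteration until the relative
#' change between successive estimates falls below 0.1%, a 1% relative
#' central finite-difference step for the derivative, and guard bounds
#' [0.01, 4] S/m outside which a start is declared non-converged.
#'
#' @param n_starts number of random initial values.
#' @param interval initial-value interval, S/m.
#' @param tol convergence threshold on the relative inter-iterate change.
#' @param max_iter maximum iterations per start.
#' @param fd_step relative finite-difference step for d phi / d sigma.
#' @param guard guard bounds on the iterates, S/m.
#' @param seed integer seed for the initial draws.
#' @return object of class `estimation_config`.
#' @export
estimation_config <- function(n_starts = 10, interval = c(0.033, 2),
                              tol = 1e-3, max_iter = 100, fd_step = 0.01,
                              guard = c(0.01, 4), seed = 1L) {
  if (interval[1] <= 0) stop("interval lower bound must be positive")
  if (tol <= 0) stop("convergence threshold must be positive")
  structure(list(n_starts = as.integer(n_starts), interval = interval,
                 tol = tol, max_iter = as.integer(max_iter),
                 fd_step = fd_step, guard = guard, seed = as.integer(seed)),
            class = "estimation_config")
}

#' Simulate the "recorded" potentials psi
#'
#' Forward-solves the true model (with locally refined scalp and skull
#' meshes near the stimulation pair) and records the potentials at the
#' chosen electrode subset after applying the coregistration rotation. The
#' stimulation monopoles stay at their true positions: only the measurement
#' montage is mis-placed.
#'
#' @param model the true [head_model()] (with the true lesion conductivity).
#' @param pair character c(anode, cathode).
#' @param layout the full nominal [electrode_layout()].
#' @param subset_size electrode subset size (8, 16, 32, 64, 128).
#' @param rotation optional [rotation_spec()]; NULL or 0 degrees leaves the
#'   montage at its nominal positions.
#' @param current stimulation current, A.
#' @param refine_radius local mesh refinement radius, mm.
#' @param cache optional [lesion_forward_cache()] for this model geometry
#'   and pair; when given, the true-model solve reuses its factorization
#'   (the true model must share the cache's geometry).
#' @return an `electrode_recording` with provenance "recorded".
#' @export
simulate_recorded <- function(model, pair, layout, subset_size = 128,
                              rotation = NULL, current = 1e-4,
                              refine_radius = 25, cache = NULL) {
  sub <- select_subset(layout, subset_size)
  if (!is.null(rotation)) sub <- rotate_layout(sub, rotation)
  if (!is.null(cache)) {
    sigma_true <- model$conductivities[lesion_surface_index(model)]
    return(cache_recording(cache, sigma_true, sub, tolerance = 10,
                           provenance = "recorded"))
  }
  refined <- refine_head_for_pair(model, layout, pair, refine_radius)
  sys <- assemble_system(refined, stim_sources(refined, layout, pair, current))
  fld <- solve_potentials(sys)
  record_at_electrodes(fld, sub, exclude = pair, tolerance = 10,
                       provenance = "recorded")
}

#' Cached forward solver for one lesion geometry and stimulation pair
#'
#' Refines the meshes near the pair, assembles the boundary-element system
#' once, and wraps the low-rank lesion re-solver. All recorded and simulated
#' potentials for this geometry/pair -- at any lesion conductivity, montage
#' rotation or electrode subset -- are then cheap interpolations, which is
#' what makes the estimation sweeps tractable.
#'
#' @param template [head_model()] with a lesion surface.
#' @param pair stimulation pair c(anode, cathode).
#' @param layout the full nominal [electrode_layout()].
#' @param current stimulation current, A.
#' @param refine_radius local mesh refinement radius, mm.
#' @return object of class `lesion_forward_cache`.
#' @export
lesion_forward_cache <- function(template, pair, layout, current = 1e-4,
                                 refine_radius = 25) {
  refined <- refine_head_for_pair(template, layout, pair, refine_radius)
  sys <- assemble_system(refined, stim_sources(refined, layout, pair, current))
  structure(list(model = refined, resolver = lesion_resolver(sys),
                 n_scalp = nrow(refined$surfaces[[1]]$vertices),
                 pair = pair, current = current),
            class = "lesion_forward_cache")
}

#' @export
print.lesion_forward_cache <- function(x, ...) {
  cat(sprintf("<lesion_forward_cache: pair %s-%s, %d scalp vertices>
",
              x$pair[1], x$pair[2], x$n_scalp))
  invisible(x)
}

# recording of the cached field at sigma, at an arbitrary (possibly rotated)
# layout
cache_recording <- function(cache, sigma, layout, tolerance = 10,
                            provenance = "simulated") {
  phi <- cache$resolver(sigma)[seq_len(cache$n_scalp)]
  record_scalp_values(cache$model$surfaces[[1]], phi, layout,
                      exclude = cache$pair, tolerance = tolerance,
                      provenance = provenance)
}

# closure mapping a lesion conductivity to the simulated potentials
# phi(sigma) at the nominal subset (named vector, reference dropped)
lesion_objective <- function(cache, layout, subset_size) {
  sub <- select_subset(layout, subset_size)
  scalp <- cache$model$surfaces[[1]]
  pr <- .project_points_to_mesh(sub$positions, scalp$vertices,
                                scalp$triangles)
  tri <- scalp$triangles[pr$triangle, , drop = FALSE]
  iref <- which(sub$labels == sub$reference)
  keep <- !(sub$labels %in% c(cache$pair, sub$reference))
  function(sigma) {
    phi <- cache$resolver(sigma)[seq_len(cache$n_scalp)]
    v <- pr$bary[, 1] * phi[tri[, 1]] + pr$bary[, 2] * phi[tri[, 2]] +
      pr$bary[, 3] * phi[tri[, 3]]
    v <- v - v[iref]
    setNames(v[keep], sub$labels[keep])
  }
}

#' Estimate the lesion conductivity from recorded potentials
#'
#' Multi-start damped Gauss-Newton on the scalar lesion conductivity,
#' minimizing the sum of squared differences between the recorded potentials
#' psi and the model potentials phi(sigma) at the nominal (unrotated)
#' electrode positions. The derivative is a central finite difference; steps
#' are halved until the residual decreases; a start stops when the relative
#' change between successive iterates falls below the threshold, and is
#' marked non-converged if it hits the guard bounds or the iteration limit.
#' The reported estimate is the minimal-residual converged start.
#'
#' @param psi recorded potentials from [simulate_recorded()].
#' @param template [head_model()] with a lesion surface; its stored lesion
#'   conductivity is only the reference point of the cached solver.
#' @param pair stimulation pair c(anode, cathode).
#' @param layout the full nominal [electrode_layout()].
#' @param subset_size electrode subset size used for `psi`.
#' @param config an [estimation_config()].
#' @param current stimulation current, A.
#' @param refine_radius local mesh refinement radius, mm.
#' @param cache optional [lesion_forward_cache()] to reuse across calls.
#' @return object of class `estimation_result`: per-start traces of
#'   sigma^k, residuals, convergence flags, and the best estimate.
#' @export
estimate_lesion_conductivity <- function(psi, template, pair, layout,
                                         subset_size = 128,
                                         config = estimation_config(),
                                         current = 1e-4, refine_radius = 25,
                                         cache = NULL) {
  if (is.null(cache))
    cache <- lesion_forward_cache(template, pair, layout, current,
                                  refine_radius)
  phi_of <- lesion_objective(cache, layout, subset_size)
  psi_v <- recording_values(psi)
  first <- phi_of(1)
  if (!setequal(names(first), names(psi_v)))
    stop("recorded and simulated potentials have different label sets")
  residual <- function(sigma) psi_v[names(first)] - phi_of(sigma)
  starts <- with_local_seed(config$seed, runif(config$n_starts,
                                               config$interval[1],
                                               config$interval[2]))
  runs <- lapply(starts, function(s0)
    gauss_newton_scalar(residual, s0, config))
  res <- structure(list(starts = starts,
                        traces = lapply(runs, `[[`, "trace"),
                        residuals = vapply(runs, `[[`, numeric(1), "rss"),
                        converged = vapply(runs, `[[`, logical(1), "converged"),
                        iterations = vapply(runs, `[[`, integer(1), "iterations"),
                        seed = config$seed),
                   class = "estimation_result")
  ok <- which(res$converged)
  if (length(ok)) {
    best <- ok[which.min(res$residuals[ok])]
    res$best_sigma <- tail(res$traces[[best]], 1)
    res$best_residual <- res$residuals[best]
    res$best_start <- best
  } else {
    res$best_sigma <- NA_real_
    res$best_residual <- NA_real_
    res$best_start <- NA_integer_
  }
  res
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result: %d starts, %d converged, sigma_hat = %s S/m>\n",
              length(x$starts), sum(x$converged),
              if (is.na(x$best_sigma)) "NA (no start converged)"
              else sprintf("%.4f", x$best_sigma)))
  invisible(x)
}

# damped Gauss-Newton for a scalar least-squares parameter; `residual`
# maps sigma to the residual vector psi - phi(sigma)
gauss_newton_scalar <- function(residual, s0, config) {
  lo <- config$guard[1]; hi <- config$guard[2]
  sigma <- s0
  r <- residual(sigma)
  rss <- sum(r^2)
  trace <- sigma
  converged <- FALSE
  hit_guard <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    h <- config$fd_step * sigma
    jac <- (residual(sigma + h) - residual(sigma - h)) / (2 * h)  # -d phi/d sigma
    jtj <- sum(jac^2)
    if (jtj == 0) { converged <- TRUE; break }  # flat objective
    step <- -sum(jac * r) / jtj
    accepted <- FALSE
    for (k in 0:10) {
      cand <- sigma + step / 2^k
      clamped <- min(max(cand, lo), hi)
      r_new <- residual(clamped)
      rss_new <- sum(r_new^2)
      if (rss_new < rss) {
        if (clamped != cand) hit_guard <- TRUE
        rel_change <- abs(clamped - sigma) / sigma
        sigma <- clamped
        r <- r_new
        rss <- rss_new
        trace <- c(trace, sigma)
        accepted <- TRUE
        if (rel_change < config$tol) converged <- TRUE
        break
      }
    }
    if (!accepted) {
      # damping exhausted: no step improves the residual, so the
      # inter-iterate change is zero and the stopping rule is met
      converged <- TRUE
      break
    }
    if (converged) break
  }
  if (hit_guard) converged <- FALSE
  list(trace = trace, rss = rss, converged = converged, iterations = iter)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Residual profile over a conductivity grid
#'
#' Sum of squared differences between the recorded potentials and the model
#' potentials phi(sigma) over a grid of lesion conductivities, using the
#' same cached solver as the estimator. The grid argmin is an independent
#' check of the Gauss-Newton estimate, and the profile shows the
#' (un)imodality of the objective.
#'
#' @inheritParams estimate_lesion_conductivity
#' @param sigmas conductivity grid, S/m.
#' @param cache optional [lesion_forward_cache()] to reuse across calls.
#' @return data.frame(sigma, rss).
#' @export
residual_profile <- function(psi, template, pair, layout, subset_size = 128,
                             sigmas = seq(0.033, 2, by = 0.005),
                             current = 1e-4, refine_radius = 25,
                             cache = NULL) {
  if (is.null(cache))
    cache <- lesion_forward_cache(template, pair, layout, current,
                                  refine_radius)
  phi_of <- lesion_objective(cache, layout, subset_size)
  psi_v <- recording_values(psi)
  rss <- vapply(sigmas, function(s) {
    v <- phi_of(s)
    sum((psi_v[names(v)] - v)^2)
  }, numeric(1))
  data.frame(sigma = sigmas, rss = rss)
}

#' Absolute and relative estimation error
#'
#' @param result an `estimation_result` (must have a converged start).
#' @param sigma_true the conductivity used to generate the recording, S/m.
#' @return list with `absolute` (S/m) and `relative`.
#' @export
error_metrics <- function(result, sigma_true) {
  if (is.na(result$best_sigma))
    stop("estimation did not converge; no error metrics available")
  abs_err <- abs(result$best_sigma - sigma_true)
  list(absolute = abs_err, relative = abs_err / sigma_true)
}

#' Serialize an estimation result to JSON
#'
#' @param result an `estimation_result`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return the JSON string, invisibly if written to a file.
#' @export
estimation_to_json <- function(result, path = NULL) {
  obj <- list(seed = result$seed, starts = result$starts,
              traces = result$traces, residuals = result$residuals,
              converged = result$converged, iterations = result$iterations,
              best_sigma = result$best_sigma,
              best_residual = result$best_residual)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @importFrom utils tail
NULL
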