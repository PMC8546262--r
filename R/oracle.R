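#' Concentric layered-sphere model for closed-form validation
#'
#' Layer radii are the outer radii of each shell, strictly decreasing and in
#' meters; layer j occupies radii (r[j+1], r[j]) and the innermost
#' conductivity fills the core. The exterior is insulating.
#'
#' @param radii outer radii of the layers in meters, strictly decreasing.
#' @param conductivities layer conductivities, S/m.
#' @param n_max Legendre series truncation order.
#' @return object of class `layered_sphere_model`.
#' @export
layered_sphere_model <- function(radii, conductivities, n_max = 200) {
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  structure(list(radii = as.numeric(radii),
                 conductivities = as.numeric(conductivities),
                 n_max = as.integer(n_max)),
            class = "layered_sphere_model")
}

#' Potential of a point-current source in a layered sphere
#'
#' Closed-form (Legendre series) electric potential of a current monopole
#' inside a concentric layered sphere with insulating exterior. The
#' spherically symmetric n = 0 mode of a lone monopole has no steady state
#' in an insulated conductor and cancels exactly between the two poles of a
#' stimulation pair; the series therefore starts at n = 1 and single-monopole
#' output is the gauge-free part, to be superposed over a balanced pair.
#'
#' Radial coefficients are propagated through the shells by continuity of
#' potential and normal current density at each interface, with per-layer
#' normalized radial basis functions for numerical stability.
#'
#' @param model a [layered_sphere_model()].
#' @param source_radius radial position of the monopole, m.
#' @param source_direction unit vector from the center towards the monopole.
#' @param current injected current, A.
#' @param eval_points matrix (k x 3) of evaluation points, m, on or inside
#'   the outer surface.
#' @param tail_tol required relative magnitude of the last series term;
#'   an error is raised if the series has not decayed below it at `n_max`.
#' @return numeric vector of potentials, V.
#' @export
layered_sphere_potential <- function(model, source_radius, source_direction,
                                     current, eval_points, tail_tol = 1e-8) {
  r_out <- model$radii
  sig <- model$conductivities
  L <- length(r_out)
  if (source_radius <= 0 || source_radius >= r_out[1])
    stop("source must be strictly inside the outermost layer")
  eval_points <- as.matrix(eval_points)
  src_dir <- source_direction / sqrt(sum(source_direction^2))
  b <- source_radius
  s_layer <- layer_of(b, r_out)

  r_eval <- sqrt(rowSums(eval_points^2))
  if (any(r_eval > r_out[1] * (1 + 1e-9)))
    stop("evaluation points must lie on or inside the outer surface")
  cosg <- as.numeric(eval_points %*% src_dir) / pmax(r_eval, 1e-300)
  cosg <- pmin(1, pmax(-1, cosg))
  e_layer <- vapply(r_eval, layer_of, integer(1), r_out = r_out)

  # inner radius of each layer (0 for the core)
  r_in <- c(r_out[-1], 0)
  nu <- length(r_out) * 2 - 1  # unknowns: A_1..A_L, B_1..B_{L-1}

  phi <- numeric(nrow(eval_points))
  # Legendre recursion state per evaluation point
  p_nm1 <- rep(1, length(cosg))   # P_0
  p_n <- cosg                     # P_1
  last_rel <- Inf
  max_abs <- 0
  for (n in seq_len(model$n_max)) {
    co <- radial_coefficients(n, r_out, r_in, sig, b, s_layer, current)
    # evaluate in each point's layer
    term <- numeric(length(r_eval))
    for (j in unique(e_layer)) {
      idx <- e_layer == j
      r <- r_eval[idx]
      u <- co$A[j] * (r / r_out[j])^n
      if (j < L) u <- u + co$B[j] * (r_in[j] / pmax(r, 1e-300))^(n + 1)
      if (j == s_layer) {
        w <- ifelse(r < b, (r / b)^n, (b / r)^(n + 1))
        u <- u + current / (4 * pi * sig[s_layer] * b) * w
      }
      term[idx] <- u
    }
    term <- term * p_n
    phi <- phi + term
    max_abs <- max(max_abs, max(abs(phi)))
    last_rel <- if (max_abs > 0) max(abs(term)) / max_abs else 0
    if (n >= 10 && last_rel < tail_tol) break
    # advance Legendre recursion: P_{n+1}
    p_np1 <- ((2 * n + 1) * cosg * p_n - n * p_nm1) / (n + 1)
    p_nm1 <- p_n
    p_n <- p_np1
  }
  if (last_rel >= tail_tol)
    stop(sprintf(paste("Legendre series not converged at n_max = %d",
                       "(tail ratio %.2e > %.0e); increase n_max"),
                 model$n_max, last_rel, tail_tol))
  phi
}

layer_of <- function(r, r_out) {
  j <- which(r >= c(r_out[-1], 0) - 1e-12)
  as.integer(j[1])
}

# Solve the (2L-1) x (2L-1) interface system for degree n.
# Basis in layer j: A_j (r/r_out[j])^n + B_j (r_in[j]/r)^(n+1), B_L = 0.
radial_coefficients <- function(n, r_out, r_in, sig, b, s_layer, current) {
  L <- length(r_out)
  nu <- 2 * L - 1
  M <- matrix(0, nu, nu)
  rhs <- numeric(nu)
  iA <- function(j) j
  iB <- function(j) L + j  # j in 1..L-1
  q <- current / (4 * pi * sig[s_layer] * b)
  # source radial function and derivative within layer s
  wfun <- function(r) if (r < b) (r / b)^n else (b / r)^(n + 1)
  wder <- function(r) if (r < b) (n / r) * (r / b)^n else -((n + 1) / r) * (b / r)^(n + 1)

  row <- 1
  # insulating outer boundary at r_out[1]: sigma_1 * d/dr [u_1 + src] = 0
  R <- r_out[1]
  M[row, iA(1)] <- n / R                     # d/dr (r/R)^n at r = R
  if (L > 1) M[row, iB(1)] <- -(n + 1) / R * (r_in[1] / R)^(n + 1)
  rhs[row] <- if (s_layer == 1) -q * wder(R) else 0
  row <- row + 1

  for (j in seq_len(L - 1)) {
    R <- r_in[j]  # interface between layer j (outside) and j+1 (inside)
    # potential continuity
    M[row, iA(j)] <- (R / r_out[j])^n
    M[row, iB(j)] <- 1  # (r_in[j]/R)^(n+1) = 1
    M[row, iA(j + 1)] <- -(R / r_out[j + 1])^n
    if (j + 1 < L) M[row, iB(j + 1)] <- -(r_in[j + 1] / R)^(n + 1)
    rhs[row] <- (s_layer == j + 1) * q * wfun(R) - (s_layer == j) * q * wfun(R)
    row <- row + 1
    # normal current continuity: sigma_j u_j' = sigma_{j+1} u_{j+1}'
    M[row, iA(j)] <- sig[j] * n / r_out[j] * (R / r_out[j])^(n - 1)
    M[row, iB(j)] <- -sig[j] * (n + 1) / R
    M[row, iA(j + 1)] <- -sig[j + 1] * n / r_out[j + 1] * (R / r_out[j + 1])^(n - 1)
    if (j + 1 < L) M[row, iB(j + 1)] <- sig[j + 1] * (n + 1) / R *
        (r_in[j + 1] / R)^(n + 1)
    rhs[row] <- (s_layer == j + 1) * sig[j + 1] * q * wder(R) -
      (s_layer == j) * sig[j] * q * wder(R)
    row <- row + 1
  }
  co <- solve(M, rhs)
  list(A = co[1:L], B = if (L > 1) co[(L + 1):nu] else numeric(0))
}

#' Potential of a balanced stimulation pair in a layered sphere
#'
#' Superposes [layered_sphere_potential()] for an anode (+I) and cathode
#' (-I), the configuration whose n = 0 modes cancel exactly.
#'
#' @inheritParams layered_sphere_potential
#' @param anode,cathode monopole positions, m (length-3 vectors).
#' @return numeric vector of potentials, V.
#' @export
layered_sphere_pair_potential <- function(model, anode, cathode, current,
                                          eval_points, tail_tol = 1e-8) {
  ra <- sqrt(sum(anode^2))
  rc <- sqrt(sum(cathode^2))
  layered_sphere_potential(model, ra, anode / ra, current, eval_points,
                           tail_tol = tail_tol) -
    layered_sphere_potential(model, rc, cathode / rc, current, eval_points,
                             tail_tol = tail_tol)
}

#' Topography and magnitude error of a forward solution
#'
#' Standard comparison metrics for two potential vectors at the same sensors:
#' the relative difference measure `RDM = || ref/||ref|| - test/||test|| ||`
#' (0 for identical topographies, up to 2) and the magnitude ratio
#' `MAG = ||test|| / ||ref||`.
#'
#' @param reference,test numeric vectors of equal length, identically
#'   referenced.
#' @return list with `rdm` and `mag`.
#' @export
rdm_mag <- function(reference, test) {
  if (length(reference) != length(test))
    stop("potential vectors must have equal length")
  nr <- sqrt(sum(reference^2))
  nt <- sqrt(sum(test^2))
  if (nr == 0 || nt == 0) stop("zero-norm potential vector")
  list(rdm = sqrt(sum((reference / nr - test / nt)^2)), mag = nt / nr)
}
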