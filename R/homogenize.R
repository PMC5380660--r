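#' Assemble the over-determined Darcy system from directional flow samples
#'
#' Each directional homogenisation sample contributes three scalar
#' equations `<u>_i = (1/mu) sum_j k_ij <grad p>_j`, with the symmetric
#' permeability tensor parameterised by its six independent entries
#' `(k_rr, k_rz, k_rt, k_zz, k_zt, k_tt)`.  Three samples with linearly
#' independent gradients give nine equations in six unknowns.
#'
#' @param samples List of three [volume_average()] samples with linearly
#'   independent mean pressure gradients.
#' @param viscosity_mu Dynamic viscosity, Pa s.
#' @return Object of class `"darcy_system"`: design matrix `A` (9 x 6),
#'   right-hand side `b`, the gradient matrix and its condition number.
#' @export
assemble_darcy_system <- function(samples, viscosity_mu = 6.913e-4) {
  if (length(samples) != 3L ||
      !all(vapply(samples, inherits, logical(1), "homog_sample")))
    stop("`samples` must be a list of three homogenisation samples")
  std <- c("r", "z", "theta")
  reord <- function(v) if (!is.null(names(v)) && setequal(names(v), std))
    v[std] else v
  samples <- lapply(samples, function(s) {
    s$mean_pressure_gradient <- reord(s$mean_pressure_gradient)
    s$mean_velocity <- reord(s$mean_velocity)
    s
  })
  Gm <- t(vapply(samples, function(s) unname(s$mean_pressure_gradient),
                 numeric(3)))
  if (any(rowSums(abs(Gm)) == 0)) stop("a sample has zero pressure gradient")
  if (qr(Gm)$rank < 3L)
    stop("pressure gradients are linearly dependent; ",
         "three independent drive directions are required")
  A <- matrix(0, 9, 6)
  b <- numeric(9)
  # unknown order: k_rr k_rz k_rt k_zz k_zt k_tt
  coef_rows <- function(g) rbind(
    c(g[1], g[2], g[3], 0,    0,    0),
    c(0,    g[1], 0,    g[2], g[3], 0),
    c(0,    0,    g[1], 0,    g[2], g[3]))
  for (s in 1:3) {
    A[(3 * s - 2):(3 * s), ] <- coef_rows(Gm[s, ]) / viscosity_mu
    b[(3 * s - 2):(3 * s)] <- unname(samples[[s]]$mean_velocity)
  }
  structure(list(A = A, b = b, gradients = Gm, condition = kappa(A),
                 viscosity_mu = viscosity_mu),
            class = "darcy_system")
}

#' Solve the Darcy system for the symmetric permeability tensor
#'
#' Minimum-norm least-squares solution via the singular value
#' decomposition; symmetry of the tensor is exact by parameterisation.
#' Principal components are attached via [principal_permeabilities()].
#'
#' @param system A [assemble_darcy_system()] result.
#' @return Object of class `"permeability_tensor"`: the 3 x 3 matrix `k`
#'   (m^2), principal values `K11` (radial), `K12`, `K13`, principal
#'   `axes` (columns, ordered K11, K12, K13) and the least-squares
#'   `residual` norm.
#' @export
solve_permeability_tensor <- function(system) {
  stopifnot(inherits(system, "darcy_system"))
  sv <- svd(system$A)
  keep <- sv$d > max(sv$d) * 1e-12
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% system$b) / sv$d[keep])
  coef <- as.vector(coef)
  k <- matrix(c(coef[1], coef[2], coef[3],
                coef[2], coef[4], coef[5],
                coef[3], coef[5], coef[6]), 3, 3,
              dimnames = list(c("r", "z", "theta"), c("r", "z", "theta")))
  pr <- principal_permeabilities(k)
  structure(list(k = k, K11 = pr$K11, K12 = pr$K12, K13 = pr$K13,
                 axes = pr$axes,
                 residual = sqrt(sum((system$A %*% coef - system$b)^2)),
                 units = "m^2"),
            class = "permeability_tensor")
}

#' Principal permeabilities of a symmetric tensor
#'
#' Eigendecomposition of `k`.  `K11` is the eigenvalue whose eigenvector
#' has the largest absolute component along the radial direction (ties
#' resolved toward the smaller eigenvalue); the remaining two are `K12 >=
#' K13` in descending order.  The radial principal component dominates
#' transmural water transport because the transmural pressure gradient is
#' by far the largest.
#'
#' @param k Symmetric 3 x 3 matrix, m^2.
#' @param radial Unit vector of the radial axis in grid coordinates.
#' @return List with `K11`, `K12`, `K13` and `axes` (unit eigenvector
#'   columns ordered K11, K12, K13).
#' @export
principal_permeabilities <- function(k, radial = c(1, 0, 0)) {
  if (!is.matrix(k) || any(dim(k) != 3) ||
      max(abs(k - t(k))) > 1e-8 * max(abs(k), 1e-300))
    stop("`k` must be a symmetric 3 x 3 matrix")
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)   # values in decreasing order
  score <- abs(as.vector(crossprod(e$vectors, radial)))
  best <- which(score > max(score) - 1e-12)
  i11 <- best[which.min(e$values[best])]         # tie -> smaller eigenvalue
  rest <- setdiff(1:3, i11)                      # already in decreasing order
  list(K11 = e$values[i11], K12 = e$values[rest[1]], K13 = e$values[rest[2]],
       axes = e$vectors[, c(i11, rest)])
}

#' @export
print.permeability_tensor <- function(x, ...) {
  cat("<permeability_tensor> (units of 1e-18 m^2)\n")
  print(signif(x$k / 1e-18, 4))
  cat("  K11 (radial) =", signif(x$K11 / 1e-18, 4),
      " K12 =", signif(x$K12 / 1e-18, 4),
      " K13 =", signif(x$K13 / 1e-18, 4), "\n")
  cat("  LS residual =", signif(x$residual, 3), "\n")
  invisible(x)
}

#' Fit the permeability tensor of a microstructure
#'
#' Convenience wrapper over the full homogenisation chain: solve Brinkman
#' flow along each of the three cylindrical axes (reusing one factored
#' operator bundle in periodic mode), volume-average each solution, and
#' solve the Darcy least-squares system.
#'
#' @param micro A [microstructure()].
#' @param cfg A [solver_config()].
#' @param gradient_magnitude Pa/m, drive used for each direction.
#' @return A [solve_permeability_tensor()] result, with the three samples
#'   attached as attribute `"samples"`.
#' @export
fit_permeability_tensor <- function(micro, cfg = solver_config(),
                                    gradient_magnitude = 100) {
  ops <- if (cfg$bc_mode == "periodic")
    brinkman_operators(micro, cfg) else NULL
  samples <- lapply(micro$axes, function(dirn) {
    o <- ops %||% brinkman_operators(micro, cfg, dirn)
    volume_average(solve_brinkman(micro, cfg, dirn, gradient_magnitude,
                                  operators = o))
  })
  out <- solve_permeability_tensor(
    assemble_darcy_system(samples, cfg$viscosity_mu))
  attr(out, "samples") <- samples
  out
}
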