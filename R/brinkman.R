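#' Brinkman solver configuration
#'
#' Steady flow through the medial microstructure is modelled by Brinkman's
#' equation, `mu lap(u) - (mu / k(x)) u - grad(p) = 0` with `div(u) = 0`,
#' where the local permeability `k(x)` equals `k_ecm` in ECM voxels and
#' `k_ecm / penalty_ratio` in cell/fibre voxels.  The large drag assigned to
#' solid voxels is the penalty that forces flow around, rather than through,
#' impermeable objects.
#'
#' @param k_ecm Isotropic ECM permeability, m^2.  The default 1.32e-18 m^2
#'   is the mean of published interstitial-matrix values.
#' @param viscosity_mu Dynamic viscosity, Pa s (water at 37 C by default).
#' @param density_rho Fluid density, kg m^-3; used only to convert a
#'   kinematic viscosity (`nu = mu / rho`) when one is supplied upstream.
#' @param penalty_ratio Factor (>= 1e3) by which the drag inside solid
#'   voxels exceeds the ECM drag.
#' @param bc_mode `"periodic"` (macroscopic gradient imposed as a constant
#'   body force over a periodic cell; the homogenisation default) or
#'   `"fixed-pressure-faces"` (pressure Dirichlet inlet/outlet on the driven
#'   axis, impermeable free-slip lateral walls).
#' @param tolerance Relative residual for the outer pressure solve; bounds
#'   the discrete divergence of the returned velocity.
#' @param inner_tolerance Relative residual for the inner velocity solves.
#' @param max_voxels Largest grid (total voxels) the solver will accept.
#' @param max_outer Maximum outer conjugate-gradient iterations.
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(k_ecm = 1.32e-18, viscosity_mu = 6.913e-4,
                          density_rho = 993, penalty_ratio = 1e6,
                          bc_mode = c("periodic", "fixed-pressure-faces"),
                          tolerance = 1e-10, inner_tolerance = 1e-12,
                          max_voxels = 262144L, max_outer = 200L) {
  if (!(k_ecm > 0)) stop("`k_ecm` must be > 0")
  if (!(viscosity_mu > 0)) stop("`viscosity_mu` must be > 0")
  if (penalty_ratio < 1e3) stop("`penalty_ratio` must be >= 1e3")
  if (tolerance > 1e-8) stop("`tolerance` must be <= 1e-8")
  structure(list(k_ecm = k_ecm, viscosity_mu = viscosity_mu,
                 density_rho = density_rho, penalty_ratio = penalty_ratio,
                 bc_mode = match.arg(bc_mode), tolerance = tolerance,
                 inner_tolerance = inner_tolerance,
                 max_voxels = as.integer(max_voxels),
                 max_outer = as.integer(max_outer)),
            class = "solver_config")
}

#' Does the ECM phase percolate along an axis?
#'
#' Flood fill (6-connectivity) from the first grid face along `axis`; the
#' phase percolates when the far face is reached.  Transverse wrapping
#' follows the boundary-condition mode.
#'
#' @param mask 3-D logical array, `TRUE` = pore (ECM) phase.
#' @param axis Axis 1..3 along which percolation is tested.
#' @param periodic_transverse Wrap across the transverse faces.
#' @return Logical scalar.
#' @export
phase_percolates <- function(mask, axis, periodic_transverse = TRUE) {
  n <- dim(mask)
  reach <- array(FALSE, n)
  first <- index_axis_assign_seed(reach, mask, axis)
  reach <- first
  if (!any(reach)) return(FALSE)
  last_idx <- n[axis]
  repeat {
    grown <- reach
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      wrap <- if (ax == axis) FALSE else periodic_transverse
      grown <- grown | (shift_logical(reach, s, ax, wrap) & mask)
    }
    if (any(index_axis(grown, last_idx, axis))) return(TRUE)
    if (identical(grown, reach)) return(FALSE)
    reach <- grown
  }
}

index_axis_assign_seed <- function(reach, mask, axis) {
  seed <- index_axis(mask, 1L, axis)
  switch(axis,
         { reach[1, , ] <- seed; reach },
         { reach[, 1, ] <- seed; reach },
         { reach[, , 1] <- seed; reach })
}

shift_logical <- function(a, s, axis, wrap) {
  n <- dim(a)[axis]
  idx <- seq_len(n) - s
  if (wrap) idx <- (idx - 1L) %% n + 1L
  out <- index_axis(a, pmin(pmax(idx, 1L), n), axis)
  if (!wrap) {                     # zero out cells shifted in from outside
    kill <- if (s > 0) seq_len(min(s, n)) else (n - min(-s, n) + 1L):n
    out <- switch(axis,
                  { out[kill, , ] <- FALSE; out },
                  { out[, kill, ] <- FALSE; out },
                  { out[, , kill] <- FALSE; out })
  }
  out
}

## ---- operator assembly -----------------------------------------------------
## Internal dimensionless form on the MAC staggered grid: lengths in units of
## L0 = min voxel spacing, permeability in units of k_ecm, unit driving
## gradient.  Momentum: (1/k* - eps lap*) u* + grad* p* = f,  div* u* = 0,
## with eps = k_ecm / L0^2 (the squared ratio of the Brinkman screening
## length to the voxel size; tiny for tissue-scale voxels).

#' Build (and factor) the Brinkman operators for a microstructure
#'
#' Assembles the staggered-grid momentum and divergence operators and
#' factors the pressure preconditioner once; the result can be passed to
#' [solve_brinkman()] repeatedly, e.g. for the three drive directions of a
#' homogenisation run.  In periodic mode the operators are direction
#' independent; in fixed-pressure mode they depend on the driven axis.
#'
#' @param micro A [microstructure()].
#' @param cfg A [solver_config()].
#' @param direction Driven axis label (required for fixed-pressure mode).
#' @return An opaque operator bundle of class `"brinkman_operators"`.
#' @export
brinkman_operators <- function(micro, cfg = solver_config(),
                               direction = NULL) {
  stopifnot(inherits(micro, "binary_microstructure"),
            inherits(cfg, "solver_config"))
  n <- dim(micro$mask)
  if (prod(n) > cfg$max_voxels)
    stop("grid of ", prod(n), " voxels exceeds max_voxels = ", cfg$max_voxels)
  h_m <- micro$voxel_spacing * 1e-6
  L0 <- min(h_m)
  hstar <- h_m / L0
  eps <- cfg$k_ecm / L0^2
  ops <- if (cfg$bc_mode == "periodic") {
    mac_operators_periodic(micro$mask, hstar, eps, cfg$penalty_ratio)
  } else {
    if (is.null(direction))
      stop("fixed-pressure mode needs `direction` at operator build time")
    d <- match(direction, micro$axes)
    if (is.na(d)) stop("unknown direction label: ", direction)
    mac_operators_fixed(micro$mask, hstar, eps, cfg$penalty_ratio, d)
  }
  St <- Reduce(`+`, lapply(1:3, function(c)
    ops$Dt[[c]] %*% Matrix::Diagonal(x = 1 / ops$dA[[c]]) %*% ops$G[[c]]))
  if (ops$mode == "periodic")
    St <- St + Matrix::Diagonal(ops$N, 1e-10 * mean(Matrix::diag(St)))
  ops$chS <- Matrix::Cholesky(Matrix::forceSymmetric(St), LDL = FALSE,
                              perm = TRUE, super = TRUE)
  ops$L0 <- L0; ops$eps <- eps; ops$hstar <- hstar
  ops$axes <- micro$axes; ops$spacing_um <- micro$voxel_spacing
  ops$mask <- micro$mask
  class(ops) <- "brinkman_operators"
  ops
}

mac_operators_periodic <- function(mask, h, eps, penalty) {
  n <- dim(mask); N <- prod(n)
  idx <- function(i, j, k) i + (j - 1L) * n[1] + (k - 1L) * n[1] * n[2]
  wrap <- function(i, m) ((i - 1L) %% m) + 1L
  ii <- rep(seq_len(n[1]), times = n[2] * n[3])
  jj <- rep(rep(seq_len(n[2]), each = n[1]), times = n[3])
  kk <- rep(seq_len(n[3]), each = n[1] * n[2])
  alpha_c <- ifelse(mask, 1, penalty)
  A <- vector("list", 3); G <- vector("list", 3); dA <- vector("list", 3)
  for (comp in 1:3) {
    im <- list(ii, jj, kk); im[[comp]] <- wrap(im[[comp]] - 1L, n[comp])
    a_face <- (alpha_c[cbind(ii, jj, kk)] +
               alpha_c[cbind(im[[1]], im[[2]], im[[3]])]) / 2
    row <- idx(ii, jj, kk)
    diagv <- a_face + 2 * eps * sum(1 / h^2)
    ti <- list(row); tj <- list(row); tx <- list(diagv); m <- 1L
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- list(ii, jj, kk); nb[[ax]] <- wrap(nb[[ax]] + s, n[ax])
      m <- m + 1L
      ti[[m]] <- row; tj[[m]] <- idx(nb[[1]], nb[[2]], nb[[3]])
      tx[[m]] <- rep(-eps / h[ax]^2, N)
    }
    A[[comp]] <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                      x = unlist(tx), dims = c(N, N))
    G[[comp]] <- Matrix::sparseMatrix(
      i = c(row, row), j = c(row, idx(im[[1]], im[[2]], im[[3]])),
      x = c(rep(1 / h[comp], N), rep(-1 / h[comp], N)), dims = c(N, N))
    dA[[comp]] <- diagv
  }
  list(A = A, G = G, Dt = lapply(G, Matrix::t), dA = dA, n = n, N = N,
       face_dims = rep(list(n), 3), mode = "periodic", dir = NA_integer_,
       solid = as.vector(!mask))
}

# Fixed-pressure-faces mode: pressure Dirichlet ghosts beyond the inlet and
# outlet faces of the driven axis `dir`; lateral walls are impermeable
# (normal faces eliminated) with free-slip tangential conditions (ghost
# mirror, i.e. absent neighbours drop out of the Laplacian).
mac_operators_fixed <- function(mask, h, eps, penalty, dir) {
  n <- dim(mask); N <- prod(n)
  cidx <- function(i, j, k) i + (j - 1L) * n[1] + (k - 1L) * n[1] * n[2]
  alpha_c <- ifelse(mask, 1, penalty)
  A <- vector("list", 3); G <- vector("list", 3); dA <- vector("list", 3)
  frhs <- vector("list", 3); fdims <- vector("list", 3)
  # Ghost-cell centres sit h/2 beyond the inlet/outlet faces, so the imposed
  # drop spans (n+1) cells; this makes the discrete gradient exactly one.
  p_in <- (n[dir] + 1L) * h[dir]       # dimensionless inlet pressure; outlet 0
  for (comp in 1:3) {
    fd <- n
    fd[comp] <- if (comp == dir) n[comp] + 1L else n[comp] - 1L
    off <- if (comp == dir) 0L else 1L  # own-axis face position = index + off
    fdims[[comp]] <- fd
    Nf <- prod(fd)
    fidx <- function(i, j, k) i + (j - 1L) * fd[1] + (k - 1L) * fd[1] * fd[2]
    qi <- rep(seq_len(fd[1]), times = fd[2] * fd[3])
    qj <- rep(rep(seq_len(fd[2]), each = fd[1]), times = fd[3])
    qk <- rep(seq_len(fd[3]), each = fd[1] * fd[2])
    pos <- list(qi, qj, qk); pos[[comp]] <- pos[[comp]] + off
    # adjacent cells along own axis
    dn <- pos; dn[[comp]] <- dn[[comp]] - 1L
    up <- pos
    dn_ok <- dn[[comp]] >= 1L
    up_ok <- up[[comp]] <= n[comp]
    a_dn <- ifelse(dn_ok, alpha_c[cbind(pmax(dn[[1]], 1L), pmax(dn[[2]], 1L),
                                        pmax(dn[[3]], 1L))], NA)
    a_up <- ifelse(up_ok, alpha_c[cbind(pmin(up[[1]], n[1]), pmin(up[[2]], n[2]),
                                        pmin(up[[3]], n[3]))], NA)
    a_face <- rowMeans(cbind(a_dn, a_up), na.rm = TRUE)
    row <- fidx(qi, qj, qk)
    ti <- list(); tj <- list(); tx <- list(); m <- 0L
    diagv <- a_face
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nbq <- list(qi, qj, qk); nbq[[ax]] <- nbq[[ax]] + s
      ok <- nbq[[ax]] >= 1L & nbq[[ax]] <= fd[ax]
      m <- m + 1L
      ti[[m]] <- row[ok]
      tj[[m]] <- fidx(pmin(pmax(nbq[[1]], 1L), fd[1]),
                      pmin(pmax(nbq[[2]], 1L), fd[2]),
                      pmin(pmax(nbq[[3]], 1L), fd[3]))[ok]
      tx[[m]] <- rep(-eps / h[ax]^2, sum(ok))
      diagv <- diagv + ok * (eps / h[ax]^2)
    }
    m <- m + 1L; ti[[m]] <- row; tj[[m]] <- row; tx[[m]] <- diagv
    A[[comp]] <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                      x = unlist(tx), dims = c(Nf, Nf))
    dA[[comp]] <- diagv
    # pressure gradient columns and ghost rhs
    gi <- list(); gj <- list(); gx <- list(); gm <- 0L
    rhs <- numeric(Nf)
    if (any(up_ok)) {
      gm <- gm + 1L
      gi[[gm]] <- row[up_ok]
      gj[[gm]] <- cidx(up[[1]], up[[2]], up[[3]])[up_ok]
      gx[[gm]] <- rep(1 / h[comp], sum(up_ok))
    }
    if (any(dn_ok)) {
      gm <- gm + 1L
      gi[[gm]] <- row[dn_ok]
      gj[[gm]] <- cidx(pmax(dn[[1]], 1L), pmax(dn[[2]], 1L),
                       pmax(dn[[3]], 1L))[dn_ok]
      gx[[gm]] <- rep(-1 / h[comp], sum(dn_ok))
    }
    if (comp == dir) {
      rhs[!dn_ok] <- rhs[!dn_ok] + p_in / h[comp]     # inlet ghost below
      # outlet ghost above has p = 0: contributes nothing
    }
    G[[comp]] <- Matrix::sparseMatrix(i = unlist(gi), j = unlist(gj),
                                      x = unlist(gx), dims = c(Nf, N))
    frhs[[comp]] <- rhs
  }
  list(A = A, G = G, Dt = lapply(G, Matrix::t), dA = dA, n = n, N = N,
       face_dims = fdims, mode = "fixed", dir = dir, frhs = frhs,
       p_in = p_in, solid = as.vector(!mask))
}

## ---- linear solvers --------------------------------------------------------

pcg_jacobi <- function(Amat, dvec, b, tol, maxit = 200L) {
  x <- b / dvec
  r <- b - as.vector(Amat %*% x)
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(x * 0)
  z <- r / dvec; p <- z; rz <- sum(r * z); it <- 0L
  while (sqrt(sum(r * r)) > tol * nb && it < maxit) {
    Ap <- as.vector(Amat %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / dvec
    rz2 <- sum(r * z)
    if (!is.finite(rz2) || rz2 == 0) break
    p <- z + (rz2 / rz) * p
    rz <- rz2
    it <- it + 1L
  }
  x
}

# Outer Schur-complement PCG for the pressure; returns face velocities too.
schur_solve <- function(ops, f, tol, inner_tol, maxit) {
  N <- ops$N
  project <- ops$mode == "periodic"
  Ainv <- function(c, b) pcg_jacobi(ops$A[[c]], ops$dA[[c]], b, inner_tol)
  prec <- function(r) {
    z <- as.vector(Matrix::solve(ops$chS, r, system = "A"))
    if (project) z - mean(z) else z
  }
  Smul <- function(v) {
    w <- numeric(N)
    for (c in 1:3)
      w <- w + as.vector(ops$Dt[[c]] %*% Ainv(c, as.vector(ops$G[[c]] %*% v)))
    if (project) w - mean(w) else w
  }
  rhs <- numeric(N)
  for (c in 1:3) rhs <- rhs + as.vector(ops$Dt[[c]] %*% Ainv(c, f[[c]]))
  if (project) rhs <- rhs - mean(rhs)
  p <- numeric(N); r <- rhs
  nrhs <- sqrt(sum(rhs^2))
  it <- 0L
  res_hist <- numeric(0)
  if (nrhs > 0) {
    z <- prec(r); pd <- z; rz <- sum(r * z)
    while (sqrt(sum(r^2)) > tol * nrhs && it < maxit) {
      Sp <- Smul(pd)
      alpha <- rz / sum(pd * Sp)
      p <- p + alpha * pd
      r <- r - alpha * Sp
      z <- prec(r)
      rz2 <- sum(r * z)
      it <- it + 1L
      res_hist <- c(res_hist, sqrt(sum(r^2)) / nrhs)
      if (!is.finite(rz2) || rz2 <= 0) break
      pd <- z + (rz2 / rz) * pd
      rz <- rz2
    }
    if (sqrt(sum(r^2)) > tol * nrhs)
      stop("pressure solve did not converge: relative residuals ",
           paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
  }
  u <- lapply(1:3, function(c) Ainv(c, f[[c]] - as.vector(ops$G[[c]] %*% p)))
  div <- numeric(N)
  for (c in 1:3) div <- div + as.vector(ops$Dt[[c]] %*% u[[c]])
  if (project) div <- div - mean(div)
  list(u = u, p = p, iters = it, div = div)
}

## ---- public solve ----------------------------------------------------------

#' Solve steady Brinkman flow through a microstructure
#'
#' Drives flow along one cylindrical axis with a macroscopic pressure
#' gradient of the given magnitude and returns the converged velocity and
#' pressure fields.  Periodic mode imposes the gradient as a constant body
#' force over a periodic cell (standard homogenisation practice); the
#' fixed-pressure mode imposes inlet/outlet pressures directly.
#'
#' @param micro A [microstructure()] whose ECM phase percolates along the
#'   driven direction (checked by flood fill).
#' @param cfg A [solver_config()].
#' @param direction `"r"`, `"z"` or `"theta"`.
#' @param gradient_magnitude Macroscopic pressure gradient, Pa / m (> 0).
#' @param operators Optional pre-built [brinkman_operators()] bundle (reused
#'   across directions in periodic mode).
#' @return Object of class `"flow_solution"`: cell-centred `velocity`
#'   (list of 3 arrays, m/s, named by axis), `pressure` (Pa),
#'   `applied_gradient` (Pa/m vector), `direction_label` and `diagnostics`
#'   (outer iterations, relative divergence, solid/ECM mean speeds).
#' @export
solve_brinkman <- function(micro, cfg = solver_config(), direction = "r",
                           gradient_magnitude = 100, operators = NULL) {
  stopifnot(inherits(micro, "binary_microstructure"))
  if (!(gradient_magnitude > 0)) stop("`gradient_magnitude` must be > 0")
  d <- match(direction, micro$axes)
  if (is.na(d)) stop("unknown direction label: ", direction)
  if (any(micro$mask) &&
      !phase_percolates(micro$mask, d,
                        periodic_transverse = cfg$bc_mode == "periodic"))
    stop("no percolating ECM path along '", direction,
         "': the pore phase does not span the driven direction")
  # (an all-solid domain is uniform drag and solvable; flow is penalty-small)
  ops <- operators %||% brinkman_operators(micro, cfg, direction)
  if (ops$mode == "fixed" && ops$dir != d)
    stop("operator bundle was built for a different driven direction")
  f <- if (ops$mode == "periodic") {
    lapply(1:3, function(c) if (c == d) rep(1, ops$N) else numeric(ops$N))
  } else ops$frhs
  sol <- schur_solve(ops, f, cfg$tolerance, cfg$inner_tolerance,
                     cfg$max_outer)
  U0 <- cfg$k_ecm * gradient_magnitude / cfg$viscosity_mu   # velocity scale
  P0 <- gradient_magnitude * ops$L0                          # pressure scale
  vel <- lapply(1:3, function(c)
    face_to_cell(array(sol$u[[c]], ops$face_dims[[c]]), c, ops) * U0)
  names(vel) <- micro$axes
  umax <- max(abs(unlist(sol$u)))
  div_rel <- if (umax > 0) max(abs(sol$div)) * min(ops$hstar) / umax else 0
  speed <- sqrt(vel[[1]]^2 + vel[[2]]^2 + vel[[3]]^2)
  solid <- ops$solid
  grad <- numeric(3); grad[d] <- gradient_magnitude
  names(grad) <- micro$axes
  structure(list(
    velocity = vel,
    pressure = array(sol$p * P0, ops$n),
    applied_gradient = grad,
    direction_label = direction,
    diagnostics = list(
      outer_iterations = sol$iters,
      divergence_relative = div_rel,
      mean_speed_solid = if (any(solid)) mean(speed[solid]) else 0,
      mean_speed_ecm = if (any(!solid)) mean(speed[!solid]) else 0,
      penalty_ratio = cfg$penalty_ratio,
      bc_mode = ops$mode)),
    class = "flow_solution")
}

# Average staggered face values onto cell centres for one component.
face_to_cell <- function(uf, comp, ops) {
  n <- ops$n
  if (ops$mode == "periodic") {
    up <- seq_len(n[comp]) %% n[comp] + 1L
    (uf + index_axis(uf, up, comp)) / 2
  } else if (comp == ops$dir) {
    lo <- index_axis(uf, seq_len(n[comp]), comp)
    hi <- index_axis(uf, seq_len(n[comp]) + 1L, comp)
    (lo + hi) / 2
  } else {
    # retained faces 2..n_c; wall faces (0-velocity) bound the first/last cell
    nf <- n[comp] - 1L
    padded_lo <- index_axis(uf, c(1L, seq_len(nf)), comp)
    padded_lo <- zero_axis_ends(padded_lo, comp, first = TRUE)
    padded_hi <- index_axis(uf, c(seq_len(nf), nf), comp)
    padded_hi <- zero_axis_ends(padded_hi, comp, first = FALSE)
    (padded_lo + padded_hi) / 2
  }
}

zero_axis_ends <- function(a, axis, first) {
  n <- dim(a)[axis]
  i <- if (first) 1L else n
  switch(axis,
         { a[i, , ] <- 0; a },
         { a[, i, ] <- 0; a },
         { a[, , i] <- 0; a })
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> drive", x$direction_label, "|grad p| =",
      signif(max(abs(x$applied_gradient)), 4), "Pa/m,",
      x$diagnostics$bc_mode, "BCs\n")
  cat("  mean u =", paste(signif(sapply(x$velocity, mean), 4),
                          collapse = ", "), "m/s\n")
  cat("  divergence (rel)", signif(x$diagnostics$divergence_relative, 2),
      "; solid/ECM speed ratio",
      signif(x$diagnostics$mean_speed_solid /
             max(x$diagnostics$mean_speed_ecm, .Machine$double.xmin), 2), "\n")
  invisible(x)
}

#' Volume-average a flow solution into a homogenisation sample
#'
#' The mean volumetric velocity is the plain volume average of the velocity
#' over the whole cell (solid voxels included, where the penalty makes `u`
#' negligible).  The mean pressure gradient equals the imposed macroscopic
#' gradient: in periodic mode the periodic pressure fluctuation averages to
#' zero by construction.
#'
#' @param sol A [solve_brinkman()] solution.
#' @return Object of class `"homog_sample"` with `mean_velocity` (m/s),
#'   `mean_pressure_gradient` (Pa/m) and `direction_label`.
#' @export
volume_average <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  structure(list(mean_velocity = vapply(sol$velocity, mean, numeric(1)),
                 mean_pressure_gradient = sol$applied_gradient,
                 direction_label = sol$direction_label),
            class = "homog_sample")
}

#' @export
print.homog_sample <- function(x, ...) {
  cat("<homog_sample> drive", x$direction_label, "\n  <u> =",
      paste(signif(x$mean_velocity, 4), collapse = ", "), "m/s\n  <grad p> =",
      paste(signif(x$mean_pressure_gradient, 4), collapse = ", "), "Pa/m\n")
  invisible(x)
}
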