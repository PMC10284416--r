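# The variational level-set model. The contour is carried as the zero level
# set of a scalar field phi, negative inside the contour and positive
# outside; nu > 0 therefore shrinks the contour, nu < 0 inflates it. A
# penalty energy Ep = integral of (|grad phi| - 1)^2 / 2 keeps phi close to
# a signed distance function throughout the evolution, so the classical
# periodic re-initialization step is never needed.

#' Level-set field
#'
#' Wraps the scalar field phi embedding the contour as its zero level set.
#' Sign convention: negative inside the contour, positive outside.
#'
#' @param phi finite numeric matrix.
#' @return An object of class `level_set`.
#' @export
level_set <- function(phi) {
  phi <- unname(as_pixels_any(phi))
  if (!all(is.finite(phi))) stop("phi must be finite", call. = FALSE)
  structure(list(phi = phi), class = "level_set")
}

as_pixels_any <- function(x) {
  if (inherits(x, "level_set")) return(x$phi)
  if (inherits(x, "gray_image")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a matrix-like 2-D field", call. = FALSE)
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("<level_set %dx%d, phi in [%.3g, %.3g]>\n",
              nrow(x$phi), ncol(x$phi), min(x$phi), max(x$phi)))
  invisible(x)
}

#' Evolution parameters
#'
#' Model constants of the distance-regularized evolution. Defaults are the
#' canonical values for this model family; the stability condition
#' `mu * tau <= 1/4` is enforced (explicit Euler on the penalty diffusion).
#'
#' @param mu penalty (distance-regularization) weight; positive.
#' @param lambda length-term weight; positive.
#' @param nu area/balloon weight; `nu > 0` shrinks, `nu < 0` expands.
#' @param eps Dirac/Heaviside regularization half-width in pixels.
#' @param tau explicit time step.
#' @param n_iter number of evolution iterations.
#' @param c0 height of the binary-step initialization.
#' @return An object of class `evolve_params`.
#' @export
evolve_params <- function(mu = 0.04, lambda = 5, nu = 1.5, eps = 1.5,
                          tau = 5, n_iter = 250L, c0 = 2) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (mu * tau > 0.25 + 1e-12) {
    stop(sprintf("mu * tau = %.3g violates the stability bound 0.25",
                 mu * tau), call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 0L) stop("n_iter must be >= 0", call. = FALSE)
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  structure(list(mu = mu, lambda = lambda, nu = nu, eps = eps, tau = tau,
                 n_iter = n_iter, c0 = c0), class = "evolve_params")
}

#' Binary-step initialization
#'
#' phi = -c0 on the seed region, +c0 elsewhere. The penalty term repairs
#' this rough start into an approximate signed distance function within the
#' first few iterations, so an exact distance transform is unnecessary.
#'
#' @param seed_mask logical matrix marking the initial inside region;
#'   must be neither empty nor full-frame.
#' @param c0 step height; positive.
#' @return A [level_set].
#' @export
init_binary_step <- function(seed_mask, c0 = 2) {
  stopifnot(is.matrix(seed_mask))
  seed_mask <- seed_mask != 0
  if (!any(seed_mask)) stop("seed mask is empty", call. = FALSE)
  if (all(seed_mask)) stop("seed mask covers the full frame", call. = FALSE)
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  phi <- matrix(c0, nrow(seed_mask), ncol(seed_mask))
  phi[seed_mask] <- -c0
  level_set(phi)
}

#' Exact signed distance function of a circle
#'
#' `phi(r, c) = dist((r, c), center) - radius`: negative inside, `|grad phi| = 1`
#' away from the center, zero set exactly the circle. Used as an analytic
#' reference in tests and diagnostics.
#'
#' @param height,width field size.
#' @param center numeric `c(row, col)` (1-based pixel centers).
#' @param radius circle radius; positive.
#' @return A [level_set].
#' @export
signed_distance_disk <- function(height, width, center, radius) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  r <- matrix(seq_len(height), height, width)
  c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
  level_set(sqrt((r - center[1])^2 + (c_ - center[2])^2) - radius)
}

#' Regularized Dirac delta
#'
#' Cosine bump `(1/(2 eps)) (1 + cos(pi x / eps))` on `|x| <= eps`, zero
#' outside; integrates to 1 over the real line.
#'
#' @param phi numeric array (any shape).
#' @param eps half-width; positive.
#' @return Array of the same shape.
#' @export
dirac_reg <- function(phi, eps = 1.5) {
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  x <- as_pixels_any_or_vector(phi)
  out <- (1 / (2 * eps)) * (1 + cos(pi * x / eps))
  out[abs(x) > eps] <- 0
  out
}

#' Regularized Heaviside step
#'
#' `H_eps(x) = (1/2)(1 + x/eps + sin(pi x / eps)/pi)` on `|x| <= eps`,
#' 0 below and 1 above; its derivative is [dirac_reg].
#'
#' @inheritParams dirac_reg
#' @return Array of the same shape, values in \[0, 1\].
#' @export
heaviside_reg <- function(phi, eps = 1.5) {
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  x <- as_pixels_any_or_vector(phi)
  out <- 0.5 * (1 + x / eps + sin(pi * x / eps) / pi)
  out[x < -eps] <- 0
  out[x > eps] <- 1
  # sin() round-off can leave values a few ulp outside [0, 1] at +/- eps
  pmin(pmax(out, 0), 1)
}

as_pixels_any_or_vector <- function(x) {
  if (inherits(x, "level_set")) x$phi else x
}

#' Penalty (internal) energy
#'
#' `Ep = sum over pixels of (|grad phi| - 1)^2 / 2`; zero iff phi has the
#' signed-distance property `|grad phi| = 1` on the discrete grid. Gradients
#' use central differences (one-sided at borders), which are exact for
#' affine fields.
#'
#' @param phi a [level_set] or matrix.
#' @return Non-negative scalar.
#' @export
penalty_energy <- function(phi) {
  m <- gradient_magnitude(as_pixels_any(phi))
  sum(0.5 * (m - 1)^2)
}

#' Geodesic length energy
#'
#' `Lg = sum of g * dirac_eps(phi) * |grad phi|`; with `g = 1` and phi an
#' exact signed distance function this approximates the Euclidean length of
#' the zero contour.
#'
#' @param phi a [level_set] or matrix.
#' @param g an `edge_map` or matrix of the same shape.
#' @param eps Dirac regularization half-width.
#' @return Non-negative scalar.
#' @export
length_energy <- function(phi, g, eps = 1.5) {
  p <- as_pixels_any(phi); gv <- as_g(g)
  if (!all(dim(p) == dim(gv))) stop("phi and g shapes differ", call. = FALSE)
  sum(gv * dirac_reg(p, eps) * gradient_magnitude(p))
}

#' Weighted area energy
#'
#' `Ag = sum of g * H_eps(-phi)`; with `g = 1` this approximates the area of
#' the inside (`phi < 0`) region.
#'
#' @inheritParams length_energy
#' @return Non-negative scalar (for non-negative g).
#' @export
area_energy <- function(phi, g, eps = 1.5) {
  p <- as_pixels_any(phi); gv <- as_g(g)
  if (!all(dim(p) == dim(gv))) stop("phi and g shapes differ", call. = FALSE)
  sum(gv * heaviside_reg(-p, eps))
}

#' Total model energy
#'
#' `E = mu * Ep + lambda * Lg + nu * Ag`.
#'
#' @param phi a [level_set] or matrix.
#' @param g an `edge_map` or matrix.
#' @param params an [evolve_params].
#' @return Scalar energy.
#' @export
total_energy <- function(phi, g, params = evolve_params()) {
  params$mu * penalty_energy(phi) +
    params$lambda * length_energy(phi, g, params$eps) +
    params$nu * area_energy(phi, g, params$eps)
}

# ---- discrete differential operators (replicate boundaries) ----------------

shift_rep <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

grad_central <- function(m) {
  list(dr = (shift_rep(m, 1L, 0L) - shift_rep(m, -1L, 0L)) / 2,
       dc = (shift_rep(m, 0L, 1L) - shift_rep(m, 0L, -1L)) / 2)
}

div_central <- function(u, v) {
  (shift_rep(u, 1L, 0L) - shift_rep(u, -1L, 0L)) / 2 +
    (shift_rep(v, 0L, 1L) - shift_rep(v, 0L, -1L)) / 2
}

laplacian5 <- function(m) {
  shift_rep(m, 1L, 0L) + shift_rep(m, -1L, 0L) +
    shift_rep(m, 0L, 1L) + shift_rep(m, 0L, -1L) - 4 * m
}

# |grad phi| regularized to avoid 0/0 in the unit normal.
GRAD_EPS <- 1e-10

#' One explicit evolution step
#'
#' Gradient descent on the total energy:
#' `phi <- phi + tau * ( mu (lap phi - div(n)) + lambda dirac_eps(phi) div(g n)
#' + nu g dirac_eps(phi) )` with `n = grad phi / |grad phi|`. Central
#' differences, 5-point Laplacian, replicate boundaries.
#'
#' @param phi a [level_set] or matrix.
#' @param g an `edge_map` or matrix.
#' @param params an [evolve_params].
#' @return A [level_set].
#' @export
evolve_step <- function(phi, g, params = evolve_params()) {
  p <- as_pixels_any(phi); gv <- as_g(g)
  if (!all(dim(p) == dim(gv))) stop("phi and g shapes differ", call. = FALSE)
  p2 <- evolve_step_raw(p, gv, params)
  if (!all(is.finite(p2))) {
    stop("evolution produced non-finite values (check tau / mu)",
         call. = FALSE)
  }
  level_set(p2)
}

evolve_step_raw <- function(p, gv, params) {
  gr <- grad_central(p)
  mag <- sqrt(gr$dr^2 + gr$dc^2 + GRAD_EPS)
  nx <- gr$dr / mag
  ny <- gr$dc / mag
  curv <- div_central(nx, ny)
  dirac <- dirac_reg(p, params$eps)
  p + params$tau * (
    params$mu * (laplacian5(p) - curv) +
      params$lambda * dirac * div_central(gv * nx, gv * ny) +
      params$nu * gv * dirac
  )
}

#' Run the level-set evolution
#'
#' Applies [evolve_step] for a fixed number of iterations (no automatic
#' stopping rule, no re-initialization), recording an energy trace each
#' iteration and optionally snapshotting phi at selected iterations.
#'
#' @param phi0 initial [level_set] (e.g. from [init_binary_step]).
#' @param g an `edge_map` or matrix; held fixed throughout.
#' @param params an [evolve_params]; `params$n_iter` steps are taken.
#' @param snapshots integer iterations at which to store a copy of phi.
#' @param trace_energy if `FALSE`, skip the per-iteration energy bookkeeping
#'   (faster; the returned trace has zero rows).
#' @return A list with `phi` (final [level_set]), `trace` (data frame with
#'   columns `iteration`, `penalty`, `length`, `area`, `total`,
#'   `sdf_deviation` — the mean `||grad phi| - 1|` over the `|phi| <= 5` band),
#'   and `snapshots` (named list of [level_set]).
#' @export
evolve <- function(phi0, g, params = evolve_params(),
                   snapshots = integer(0), trace_energy = TRUE) {
  p <- as_pixels_any(phi0); gv <- as_g(g)
  if (!all(dim(p) == dim(gv))) stop("phi and g shapes differ", call. = FALSE)
  snapshots <- as.integer(snapshots)
  n <- params$n_iter
  n_trace <- if (trace_energy) n else 0L
  trace <- data.frame(iteration = seq_len(n_trace),
                      penalty = rep(NA_real_, n_trace),
                      length = rep(NA_real_, n_trace),
                      area = rep(NA_real_, n_trace),
                      total = rep(NA_real_, n_trace),
                      sdf_deviation = rep(NA_real_, n_trace))
  snaps <- list()
  for (it in seq_len(n)) {
    p <- evolve_step_raw(p, gv, params)
    if (!all(is.finite(p))) {
      stop(sprintf("evolution diverged at iteration %d", it), call. = FALSE)
    }
    if (trace_energy) {
      ep <- penalty_energy(p)
      lg <- length_energy(p, gv, params$eps)
      ag <- area_energy(p, gv, params$eps)
      trace$penalty[it] <- ep
      trace$length[it] <- lg
      trace$area[it] <- ag
      trace$total[it] <- params$mu * ep + params$lambda * lg + params$nu * ag
      trace$sdf_deviation[it] <- sdf_band_deviation(p)
    }
    if (it %in% snapshots) snaps[[paste0("iter_", it)]] <- level_set(p)
  }
  list(phi = level_set(p), trace = trace, snapshots = snaps)
}

#' Mean signed-distance deviation near the contour
#'
#' Mean of `||grad phi| - 1|` over the band `|phi| <= band` around the zero
#' level set; the model's headline property is that this stays small without
#' any re-initialization.
#'
#' @param phi a [level_set] or matrix.
#' @param band half-width of the band in phi units (~pixels once phi is
#'   close to a signed distance function).
#' @return Non-negative scalar; `NA` if the band is empty.
#' @export
sdf_band_deviation <- function(phi, band = 5) {
  p <- as_pixels_any(phi)
  sel <- abs(p) <= band
  if (!any(sel)) return(NA_real_)
  m <- gradient_magnitude(p)
  mean(abs(m[sel] - 1))
}

#' Re-initialization PDE (diagnostic)
#'
#' Evolves `dphi/dt = sign(phi0) (1 - |grad phi|)` — the classical
#' correction that the penalty energy makes unnecessary. Kept as a
#' reference/diagnostic operator; the segmentation pipeline never calls it.
#' Discretization: Godunov upwind away from the interface, with the
#' subcell fix of Russo & Smereka at interface-adjacent pixels (they relax
#' toward their initial distance-to-interface estimate), so the zero level
#' set is not displaced. `sign(0)` is taken as 0, so exact-interface pixels
#' are stationary sources.
#'
#' @param phi a [level_set] or matrix.
#' @param n_steps number of explicit steps.
#' @param dt time step; must be at most 0.5 (grid units).
#' @return A [level_set] with `|grad phi|` driven toward 1.
#' @export
reinitialize <- function(phi, n_steps = 50L, dt = 0.5) {
  if (dt > 0.5) stop("dt must be <= 0.5 for stability", call. = FALSE)
  p0 <- as_pixels_any(phi)
  p <- p0
  s <- sign(p0)  # frozen sign of the input field; sign(0) = 0
  pos <- s > 0; neg <- s < 0

  # interface pixels: a 4-neighbour with the opposite (or zero) sign
  nb <- list(shift_rep(p0, 1L, 0L), shift_rep(p0, -1L, 0L),
             shift_rep(p0, 0L, 1L), shift_rep(p0, 0L, -1L))
  iface <- (p0 * nb[[1]] < 0) | (p0 * nb[[2]] < 0) |
    (p0 * nb[[3]] < 0) | (p0 * nb[[4]] < 0) | (p0 == 0)

  # subcell distance estimate D = phi0 / max local slope of phi0
  slope <- pmax(
    abs(nb[[1]] - p0), abs(p0 - nb[[2]]), abs(nb[[3]] - p0),
    abs(p0 - nb[[4]]),
    sqrt(((nb[[1]] - nb[[2]]) / 2)^2 + ((nb[[3]] - nb[[4]]) / 2)^2),
    GRAD_EPS)
  D <- p0 / slope

  for (k in seq_len(n_steps)) {
    a <- p - shift_rep(p, -1L, 0L)   # backward difference, rows
    b <- shift_rep(p, 1L, 0L) - p    # forward difference, rows
    cc <- p - shift_rep(p, 0L, -1L)  # backward, cols
    d <- shift_rep(p, 0L, 1L) - p    # forward, cols
    ap <- pmax(a, 0); am <- pmin(a, 0)
    bp <- pmax(b, 0); bm <- pmin(b, 0)
    cp <- pmax(cc, 0); cm <- pmin(cc, 0)
    dp <- pmax(d, 0); dm <- pmin(d, 0)
    # Godunov upwind |grad phi|, branch chosen by the frozen sign
    G <- matrix(1, nrow(p), ncol(p))  # sign-0 pixels: no update regardless
    Gp <- sqrt(pmax(ap^2, bm^2) + pmax(cp^2, dm^2))
    Gn <- sqrt(pmax(am^2, bp^2) + pmax(cm^2, dp^2))
    G[pos] <- Gp[pos]
    G[neg] <- Gn[neg]
    p_new <- p + dt * s * (1 - G)
    # subcell fix: interface pixels relax to the frozen distance estimate
    p_new[iface] <- p[iface] - dt * (s[iface] * abs(p[iface]) - D[iface])
    p <- p_new
  }
  level_set(p)
}

#' Extract the zero level set as sub-pixel contours
#'
#' Marching-squares tracing with linear interpolation (via
#' `grDevices::contourLines`). Coordinates are 1-based (row, col) pixel
#' centers. A contour whose endpoints coincide is marked closed and the
#' duplicate endpoint is dropped.
#'
#' @param phi a [level_set] or matrix.
#' @return A list of contours, each a list with `points` (n x 2 matrix,
#'   columns `row`, `col`) and `closed` (logical). Empty list if phi does
#'   not change sign.
#' @export
extract_zero_contour <- function(phi) {
  p <- as_pixels_any(phi)
  # single-signed or constant fields carry no zero contour (not an error)
  if (min(p) > 0 || max(p) < 0 || min(p) == max(p)) return(list())
  cl <- grDevices::contourLines(x = seq_len(nrow(p)), y = seq_len(ncol(p)),
                                z = p, levels = 0)
  lapply(cl, function(ln) {
    pts <- cbind(row = ln$x, col = ln$y)
    n <- nrow(pts)
    closed <- n > 2L && all(abs(pts[1L, ] - pts[n, ]) < 1e-9)
    if (closed) pts <- pts[-n, , drop = FALSE]
    list(points = pts, closed = closed)
  })
}

# All contour points stacked into one n x 2 matrix (for distance metrics).
# Accepts a point matrix, a single contour, or a list of contours.
contour_points <- function(x) {
  if (is.matrix(x) && is.numeric(x)) return(x)
  if (is.list(x) && !is.null(x$points)) return(x$points)
  do.call(rbind, lapply(x, `[[`, "points"))
}
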