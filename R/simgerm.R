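# Parametric germination-scene simulator. Radicle lengths follow a truncated
# log-normal law (median 28 mm, mean ~30 mm, right-skewed, bounded to
# 10-80 mm); curvature is expressed as "deviation points" -- strict local
# maxima of the lift profile z(s) where the radicle visibly rises off the
# dish floor -- with four categories (0, 1, 2, >2) whose frequencies and
# positive rank-coupling with length mirror the real germination data the
# simulator emulates.

#' Generator configuration for synthetic germination scenes
#'
#' @param length_law list with `meanlog`, `sdlog` (log-normal parameters of
#'   the radicle arc length in mm) and truncation bounds `min_mm`, `max_mm`.
#'   The defaults give median 28 mm and mean close to 30 mm.
#' @param category_weights probabilities of the four curvature categories
#'   (0, 1, 2, >2 deviation points); must sum to 1.
#' @param coupling_strength correlation (0..1) between the standardized
#'   log-length and the latent variable that is thresholded into curvature
#'   categories; the default reproduces a strong positive rank association
#'   (Spearman around 0.84) between length and deviation-point count.
#' @param px_per_mm rendering scale in pixels per millimetre.
#' @param grid_enabled draw a reference grid on the background.
#' @param grid_mm physical side length of one grid square (mm).
#' @param dish_radius_mm inner radius of the petri dish (mm).
#' @param background_style one of "black", "white", "wood".
#' @param image_size output image side in pixels (square). `NULL` sizes the
#'   image to the dish plus a margin, rounded up to a multiple of 32.
#' @param instances_per_image integer range (min, max) of radicles per scene.
#' @param z_threshold_mm visibility threshold for a deviation point: a lift
#'   maximum counts only if it exceeds this height (mm).
#' @param lift_shading brightness gain per mm of lift, the visual cue that
#'   encodes the third dimension in the rendered image.
#' @param tube_halfwidth_mm half-width of the radicle tube at its base and
#'   tip (mm); the tube tapers linearly between them.
#' @param seed integer seed recorded in dataset manifests.
#' @return an object of class `germ_config`.
#' @export
germ_config <- function(length_law = list(meanlog = log(28),
                                          sdlog = sqrt(2 * log(30 / 28)),
                                          min_mm = 10, max_mm = 80),
                        category_weights = c(0.089, 0.545, 0.288, 0.078),
                        coupling_strength = 0.928,
                        px_per_mm = 8,
                        grid_enabled = TRUE,
                        grid_mm = 10,
                        dish_radius_mm = 44.5,
                        background_style = c("black", "white", "wood"),
                        image_size = NULL,
                        instances_per_image = c(1L, 4L),
                        z_threshold_mm = 1,
                        lift_shading = 0.06,
                        tube_halfwidth_mm = c(0.7, 0.4),
                        seed = 1L) {
  background_style <- match.arg(background_style)
  cfg <- list(length_law = length_law, category_weights = category_weights,
              coupling_strength = coupling_strength, px_per_mm = px_per_mm,
              grid_enabled = grid_enabled, grid_mm = grid_mm,
              dish_radius_mm = dish_radius_mm,
              background_style = background_style,
              image_size = image_size,
              instances_per_image = as.integer(instances_per_image),
              z_threshold_mm = z_threshold_mm, lift_shading = lift_shading,
              tube_halfwidth_mm = tube_halfwidth_mm,
              seed = as.integer(seed))
  if (is.null(cfg$image_size)) {
    raw <- (2 * dish_radius_mm + 6) * px_per_mm
    cfg$image_size <- as.integer(ceiling(raw / 32) * 32)
  }
  validate_germ_config(cfg)
  class(cfg) <- "germ_config"
  cfg
}

validate_germ_config <- function(cfg) {
  w <- cfg$category_weights
  if (length(w) != 4L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("category_weights must be 4 nonnegative probabilities summing to 1")
  if (cfg$px_per_mm <= 0) stop("px_per_mm must be positive")
  ll <- cfg$length_law
  if (!all(c("meanlog", "sdlog", "min_mm", "max_mm") %in% names(ll)))
    stop("length_law must supply meanlog, sdlog, min_mm, max_mm")
  if (ll$min_mm <= 0 || ll$max_mm <= ll$min_mm)
    stop("length truncation bounds must be positive and ordered")
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  invisible(cfg)
}

#' Sample radicle specifications (length, curvature category, pose)
#'
#' Lengths are drawn from the truncated log-normal law by inverse-CDF; the
#' curvature category is obtained by thresholding a latent Gaussian that is
#' correlated with the length's standardized rank, so the category marginal
#' matches `category_weights` while longer radicles receive more deviation
#' points.
#'
#' @param cfg a [germ_config()].
#' @param n number of specifications to draw.
#' @return data frame with columns `length_mm`, `n_dev`, `anchor_x`,
#'   `anchor_y` (mm from dish centre) and `heading` (rad).
#' @export
sample_radicle_spec <- function(cfg, n = 1L) {
  validate_germ_config(cfg)
  ll <- cfg$length_law
  plo <- stats::plnorm(ll$min_mm, ll$meanlog, ll$sdlog)
  phi <- stats::plnorm(ll$max_mm, ll$meanlog, ll$sdlog)
  u <- stats::runif(n, plo, phi)
  length_mm <- stats::qlnorm(u, ll$meanlog, ll$sdlog)
  if (ll$sdlog == 0) length_mm <- rep(exp(ll$meanlog), n)
  # latent = rho * z + sqrt(1-rho^2) * noise, z = standardized length rank
  z <- stats::qnorm(pmin(pmax((u - plo) / max(phi - plo, 1e-12), 1e-9), 1 - 1e-9))
  rho <- cfg$coupling_strength
  lat <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  thr <- stats::qnorm(pmin(cumsum(cfg$category_weights)[1:3], 1 - 1e-12))
  category <- findInterval(lat, thr)          # 0..3
  n_dev <- ifelse(category == 3L,
                  3L + stats::rbinom(n, 1L, 0.25),
                  category)
  r <- cfg$dish_radius_mm * sqrt(stats::runif(n)) * 0.72
  phi_a <- stats::runif(n, 0, 2 * pi)
  ax <- r * cos(phi_a); ay <- r * sin(phi_a)
  to_centre <- atan2(-ay, -ax)
  heading <- to_centre + stats::runif(n, -0.9, 0.9)
  data.frame(length_mm = length_mm, n_dev = as.integer(n_dev),
             anchor_x = ax, anchor_y = ay, heading = heading)
}

# Lift profile: disjoint raised-cosine bumps in relative coordinate t.
make_lift_profile <- function(length_mm, n_dev, z_threshold) {
  if (n_dev == 0L)
    return(list(z = function(t) rep(0, length(t)),
                dz = function(t) rep(0, length(t)), tv = 0))
  slots <- seq(0.12, 0.94, length.out = n_dev + 1L)
  centres <- (slots[-1] + slots[-length(slots)]) / 2 +
    stats::runif(n_dev, -0.1, 0.1) * diff(slots)[1]
  halfw <- 0.32 * diff(slots)[1]
  hmax <- max(z_threshold + 0.4, min(6, 0.22 * length_mm / n_dev))
  h <- stats::runif(n_dev, z_threshold + 0.25, hmax)
  zfun <- function(t) {
    out <- rep(0, length(t))
    for (i in seq_len(n_dev)) {
      d <- abs(t - centres[i])
      inb <- d <= halfw
      out[inb] <- out[inb] + h[i] / 2 * (1 + cos(pi * d[inb] / halfw))
    }
    out
  }
  dzfun <- function(t) {
    out <- rep(0, length(t))
    for (i in seq_len(n_dev)) {
      d <- t - centres[i]
      inb <- abs(d) <= halfw
      out[inb] <- out[inb] - h[i] * pi / (2 * halfw) * sin(pi * d[inb] / halfw)
    }
    out
  }
  list(z = zfun, dz = dzfun, tv = 2 * sum(h))
}

#' Build a 3D centerline realizing a radicle specification
#'
#' Constructs a smooth planar path of the appropriate projected length plus a
#' lift profile with exactly `n_dev` above-threshold maxima, such that the
#' three-dimensional arc length matches `length_mm`. The planar length is
#' solved by root finding, since lifting a curve of fixed 3D length strictly
#' shortens its projection. Draws that would leave the dish are retried.
#'
#' @param spec one row of [sample_radicle_spec()] output (or a list with the
#'   same fields).
#' @param cfg a [germ_config()].
#' @param max_retry planar draws to attempt before failing.
#' @return object of class `centerline3d`.
#' @export
build_centerline <- function(spec, cfg, max_retry = 40L) {
  L <- spec$length_mm
  ll <- cfg$length_law
  if (L < ll$min_mm - 1e-6 || L > ll$max_mm + 1e-6)
    stop("spec length outside configured truncation bounds")
  if (spec$n_dev < 0) stop("n_dev must be nonnegative")
  for (attempt in seq_len(max_retry)) {
    lift <- make_lift_profile(L, spec$n_dev, cfg$z_threshold_mm)
    if (lift$tv >= 0.92 * L) next
    f <- function(lp) {
      tg <- seq(0, 1, length.out = 801L)
      dz <- lift$dz(tg)
      mean(sqrt(lp^2 + dz^2)) - L
    }
    Lp <- if (spec$n_dev == 0L) L else stats::uniroot(f, c(1e-3, L), tol = 1e-8)$root
    # planar unit-speed path from smooth random curvature
    ds <- 0.25
    s <- seq(0, Lp, by = ds)
    if (s[length(s)] < Lp) s <- c(s, Lp)
    curl <- 1 + (attempt - 1) / 10
    base_kappa <- stats::runif(1, -1, 1) * 0.035 * curl
    a1 <- stats::runif(1, 0.01, 0.05); f1 <- stats::runif(1, 0.5, 1.8)
    ph1 <- stats::runif(1, 0, 2 * pi)
    a2 <- stats::runif(1, 0.005, 0.03); f2 <- stats::runif(1, 1.5, 3.5)
    ph2 <- stats::runif(1, 0, 2 * pi)
    kappa <- base_kappa + a1 * sin(2 * pi * f1 * s / max(Lp, 1) + ph1) +
      a2 * sin(2 * pi * f2 * s / max(Lp, 1) + ph2)
    theta <- spec$heading + cumsum(c(0, (kappa[-1] + kappa[-length(s)]) / 2 * diff(s)))
    x <- spec$anchor_x + cumsum(c(0, cos((theta[-1] + theta[-length(s)]) / 2) * diff(s)))
    y <- spec$anchor_y + cumsum(c(0, sin((theta[-1] + theta[-length(s)]) / 2) * diff(s)))
    if (max(sqrt(x^2 + y^2)) > cfg$dish_radius_mm - 1.5) next
    tg <- s / max(Lp, 1e-9)
    z <- lift$z(tg)
    cl <- structure(list(t = tg, x = x, y = y, z = z,
                         sx = stats::splinefun(tg, x, method = "natural"),
                         sy = stats::splinefun(tg, y, method = "natural"),
                         sz = stats::splinefun(tg, z, method = "natural"),
                         planar_length_mm = Lp,
                         length_mm = L, n_dev = as.integer(spec$n_dev),
                         z_threshold = cfg$z_threshold_mm,
                         anchor = c(spec$anchor_x, spec$anchor_y),
                         heading = spec$heading),
                    class = "centerline3d")
    return(cl)
  }
  stop("unreachable geometry: could not fit radicle of ", round(L, 1),
       " mm inside the dish after ", max_retry, " attempts")
}

#' Three-dimensional arc length of a centerline by adaptive quadrature
#'
#' @param cl a `centerline3d`.
#' @return arc length in mm.
#' @export
arc_length <- function(cl) {
  stopifnot(inherits(cl, "centerline3d"))
  if (!all(is.finite(c(cl$x, cl$y, cl$z))))
    stop("non-finite control points in centerline")
  speed <- function(t)
    sqrt(cl$sx(t, deriv = 1)^2 + cl$sy(t, deriv = 1)^2 + cl$sz(t, deriv = 1)^2)
  # piecewise integration keeps the adaptive rule honest across bump edges
  brk <- seq(0, 1, length.out = 17L)
  sum(vapply(seq_len(16L), function(i)
    stats::integrate(speed, brk[i], brk[i + 1], rel.tol = 1e-8,
                     subdivisions = 200L)$value, 0))
}

#' Count deviation points of a centerline
#'
#' A deviation point is a strict local maximum of the lift profile z(t) that
#' exceeds the visibility threshold.
#'
#' @param cl a `centerline3d`.
#' @param threshold visibility threshold in mm; defaults to the value stored
#'   in the centerline.
#' @param n_samples dense sampling resolution.
#' @return integer count.
#' @export
count_deviation_points <- function(cl, threshold = cl$z_threshold,
                                   n_samples = 4001L) {
  stopifnot(inherits(cl, "centerline3d"))
  tg <- seq(0, 1, length.out = n_samples)
  z <- cl$sz(tg)
  i <- 2:(n_samples - 1L)
  peaks <- which(z[i] > z[i - 1L] & z[i] > z[i + 1L] & z[i] > threshold)
  length(peaks)
}

#' Projected (2D) length of a centerline
#'
#' @param cl a `centerline3d`.
#' @return planar arc length in mm (always <= the 3D arc length, with
#'   equality iff the curve is planar).
#' @export
projected_length <- function(cl) {
  stopifnot(inherits(cl, "centerline3d"))
  speed <- function(t) sqrt(cl$sx(t, deriv = 1)^2 + cl$sy(t, deriv = 1)^2)
  brk <- seq(0, 1, length.out = 17L)
  sum(vapply(seq_len(16L), function(i)
    stats::integrate(speed, brk[i], brk[i + 1], rel.tol = 1e-8,
                     subdivisions = 200L)$value, 0))
}
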