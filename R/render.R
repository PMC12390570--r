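# Scene rendering: anti-aliased tapered tubes along projected centerlines,
# with lift encoded as a brightness cue, optional reference grid, dish rim
# and seed bodies. Coordinates: 0-based pixel indices, x right / y down,
# pixel centres at integer coordinates; boxes are continuous
# [x1, y1, x2, y2] with the upper bounds exclusive.

bg_palette <- function(style) {
  switch(style,
    black = list(base = c(0.07, 0.07, 0.08), noise = 0.012,
                 grid = c(0.38, 0.38, 0.40), rim = c(0.30, 0.30, 0.32)),
    white = list(base = c(0.92, 0.92, 0.91), noise = 0.010,
                 grid = c(0.55, 0.65, 0.85), rim = c(0.70, 0.70, 0.72)),
    wood  = list(base = c(0.55, 0.39, 0.23), noise = 0.025,
                 grid = c(0.35, 0.25, 0.15), rim = c(0.40, 0.28, 0.17)))
}

mm_to_pix <- function(xy_mm, cfg) {
  centre <- (cfg$image_size - 1) / 2
  xy_mm * cfg$px_per_mm + centre
}

#' Render an annotated germination scene
#'
#' Builds a 3D centerline for every specification, projects it to the image
#' plane (which foreshortens lifted sections), and rasterizes an
#' anti-aliased tapered tube. Lift is additionally encoded as a brightness
#' gain proportional to z so that the 2D appearance carries a 3D cue.
#' Instances whose masks would overlap an earlier instance by more than
#' `overlap_tol` (intersection over smaller area) are re-drawn.
#'
#' @param specs data frame from [sample_radicle_spec()].
#' @param cfg a [germ_config()].
#' @param overlap_tol maximum tolerated pairwise mask overlap fraction.
#' @param max_retry re-draws per instance before giving up.
#' @return an `annotated_scene`: image (H x W x 3 in [0,1]), per-instance
#'   binary masks, tight boxes, lengths in mm and px, deviation counts,
#'   grid pitch and the centerlines used.
#' @export
render_scene <- function(specs, cfg, overlap_tol = 0.15, max_retry = 25L) {
  validate_germ_config(cfg)
  S <- cfg$image_size
  pal <- bg_palette(cfg$background_style)
  img <- array(0, c(S, S, 3))
  for (ch in 1:3)
    img[, , ch] <- pal$base[ch] +
      matrix(stats::rnorm(S * S, 0, pal$noise), S, S)
  pitch_px <- cfg$grid_mm * cfg$px_per_mm
  if (cfg$grid_enabled) {
    centre <- (S - 1) / 2
    coord <- (0:(S - 1)) - centre
    off <- abs(coord - round(coord / pitch_px) * pitch_px)
    alpha <- pmax(0, pmin(1, 0.9 - off))
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - rep(alpha, S)) +
        pal$grid[ch] * rep(alpha, S)                       # horizontal lines
      img[, , ch] <- img[, , ch] * (1 - rep(alpha, each = S)) +
        pal$grid[ch] * rep(alpha, each = S)                # vertical lines
    }
  }
  # dish rim
  centre <- (S - 1) / 2
  dd <- sqrt(outer(((0:(S - 1)) - centre)^2, ((0:(S - 1)) - centre)^2, `+`))
  rimr <- cfg$dish_radius_mm * cfg$px_per_mm
  rima <- pmax(0, 1 - abs(dd - rimr) / (0.4 * cfg$px_per_mm + 0.5))
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - rima) + pal$rim[ch] * rima

  n <- nrow(specs)
  masks <- vector("list", n)
  centerlines <- vector("list", n)
  boxes <- matrix(0, n, 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  occupied <- matrix(FALSE, S, S)
  seed_col <- c(0.46, 0.34, 0.20)
  tube_col <- c(0.88, 0.86, 0.76)
  for (i in seq_len(n)) {
    sp <- specs[i, ]
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cl <- build_centerline(sp, cfg)
      pxy <- mm_to_pix(cbind(cl$x, cl$y), cfg)
      hw_mm <- cfg$tube_halfwidth_mm[1] +
        (cfg$tube_halfwidth_mm[2] - cfg$tube_halfwidth_mm[1]) * cl$t
      fld <- cpp_tube_field(S, S, pxy, hw_mm * cfg$px_per_mm,
                            pmin(1 + cfg$lift_shading * cl$z, 1.4))
      mask <- fld$sdist <= 0
      if (!any(mask)) next
      inter <- sum(mask & occupied)
      if (inter / sum(mask) > overlap_tol) {
        # re-draw pose for this instance, keep its length/category
        sp$anchor_x <- sp$anchor_x * 0.9 + stats::rnorm(1, 0, 3)
        sp$anchor_y <- sp$anchor_y * 0.9 + stats::rnorm(1, 0, 3)
        sp$heading <- sp$heading + stats::runif(1, -1, 1)
        next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place instance ", i, " without excessive overlap")
    occupied <- occupied | mask
    alpha <- pmax(0, pmin(1, 0.5 - fld$sdist))
    shade <- fld$shade
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) +
        pmin(tube_col[ch] * shade, 1) * alpha
    # seed body (context only; not part of the instance mask)
    apx <- mm_to_pix(matrix(cl$anchor, 1, 2), cfg)
    body <- seed_body_alpha(S, apx[1], apx[2], cl$heading, cfg$px_per_mm)
    body <- body * (1 - alpha)   # radicle stays on top where they meet
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - body) + seed_col[ch] * body
    masks[[i]] <- mask
    centerlines[[i]] <- cl
    wh <- which(mask, arr.ind = TRUE)   # rows = y+1, cols = x+1
    boxes[i, ] <- c(min(wh[, 2]) - 1, min(wh[, 1]) - 1, max(wh[, 2]), max(wh[, 1]))
  }
  img <- pmin(pmax(img, 0), 1)
  length_mm <- vapply(centerlines, function(cl) cl$length_mm, 0)
  structure(list(image = img,
                 masks = masks,
                 boxes = boxes,
                 length_mm = length_mm,
                 length_px = mm_to_px(length_mm, pitch_px, cfg$grid_mm),
                 n_dev = vapply(centerlines, function(cl) cl$n_dev, 0L),
                 grid_pitch_px = pitch_px,
                 centerlines = centerlines,
                 cfg = cfg),
            class = "annotated_scene")
}

seed_body_alpha <- function(S, cx, cy, heading, ppm) {
  a <- 3.1 * ppm; b <- 2.0 * ppm     # semi-axes in px
  r <- ceiling(a) + 2L
  x0 <- max(0, floor(cx - r)); x1 <- min(S - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(S - 1, ceiling(cy + r))
  out <- matrix(0, S, S)
  if (x1 < x0 || y1 < y0) return(out)
  xs <- x0:x1; ys <- y0:y1
  co <- cos(heading); si <- sin(heading)
  for (xi in seq_along(xs)) {
    dx <- xs[xi] - cx
    dy <- ys - cy
    u <- (dx * co + dy * si) / a
    v <- (-dx * si + dy * co) / b
    q <- sqrt(u^2 + v^2)
    out[ys + 1L, xs[xi] + 1L] <- pmax(0, pmin(1, (1 - q) * 6))
  }
  out
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes PNG images, a COCO-dialect annotation JSON (with the extra
#' per-annotation fields `length_mm`, `length_px`, `n_dev` and per-image
#' `grid_pitch_px`), a per-instance CSV mirror and a manifest recording the
#' generator configuration and seed. Fully reproducible from (cfg, seed).
#'
#' @param cfg a [germ_config()].
#' @param n_images number of scenes.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(cfg, n_images, out_dir) {
  validate_germ_config(cfg)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  set.seed(cfg$seed)
  images <- list(); annotations <- list(); rows <- list()
  ann_id <- 0L
  for (k in seq_len(n_images)) {
    ni <- sample(cfg$instances_per_image[1]:cfg$instances_per_image[2], 1L)
    specs <- sample_radicle_spec(cfg, ni)
    scene <- render_scene(specs, cfg)
    fn <- sprintf("scene_%04d.png", k)
    ok <- tryCatch({
      png::writePNG(scene$image, file.path(img_dir, fn)); TRUE
    }, error = function(e)
      stop("failed writing ", file.path(img_dir, fn), ": ", conditionMessage(e)))
    S <- cfg$image_size
    images[[k]] <- list(id = k, file_name = file.path("images", fn),
                        width = S, height = S,
                        grid_pitch_px = scene$grid_pitch_px)
    for (i in seq_along(scene$masks)) {
      ann_id <- ann_id + 1L
      b <- scene$boxes[i, ]
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = k, category_id = 1L,
        segmentation = rle_encode(scene$masks[[i]]),
        bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
        area = sum(scene$masks[[i]]), iscrowd = 0L,
        length_mm = scene$length_mm[i], length_px = scene$length_px[i],
        n_dev = scene$n_dev[i])
      rows[[ann_id]] <- data.frame(
        image = fn, instance = i, length_mm = scene$length_mm[i],
        length_px = scene$length_px[i], n_dev = scene$n_dev[i],
        x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4])
    }
  }
  coco <- list(images = images, annotations = annotations,
               categories = list(list(id = 1L, name = "radicle")))
  jsonlite::write_json(coco, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "instances.csv"),
                   row.names = FALSE)
  manifest <- list(generator = unclass(cfg), n_images = n_images,
                   seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
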