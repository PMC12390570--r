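# Dataset I/O. Annotations use a COCO-dialect JSON: standard images /
# annotations / categories tables, masks as uncompressed column-major RLE
# ({"size": [h, w], "counts": [...]}, first count = leading zeros), plus the
# additive fields length_mm, length_px, n_dev (per annotation) and
# grid_pitch_px (per image). Polygon segmentations are accepted on input.

#' Run-length encode a binary mask (COCO uncompressed RLE)
#'
#' @param mask logical or 0/1 matrix (rows = y, cols = x).
#' @return list with `size` (h, w) and integer `counts`, column-major,
#'   starting with the number of leading zeros.
#' @export
rle_encode <- function(mask) {
  m <- as.integer(as.logical(mask))
  r <- rle(m)
  counts <- r$lengths
  if (length(r$values) && r$values[1] == 1L) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

#' Decode an uncompressed RLE into a binary mask
#'
#' @param r list with `size` and `counts` as produced by [rle_encode()].
#' @return logical matrix.
#' @export
rle_decode <- function(r) {
  size <- as.integer(unlist(r$size))
  counts <- as.integer(unlist(r$counts))
  total <- sum(counts)
  if (total != prod(size)) stop("RLE counts do not cover the mask size")
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(as.logical(vals), size[1], size[2])
}

polygon_to_mask <- function(poly, h, w) {
  # poly: flat vector x1,y1,x2,y2,... in pixel coordinates
  xs <- poly[seq(1, length(poly), 2)]
  ys <- poly[seq(2, length(poly), 2)]
  mask <- matrix(FALSE, h, w)
  for (x in 0:(w - 1)) {
    # even-odd rule per column at pixel centres
    cross <- c()
    np <- length(xs)
    for (k in seq_len(np)) {
      k2 <- if (k == np) 1L else k + 1L
      x1 <- xs[k]; x2 <- xs[k2]
      if ((x1 <= x) != (x2 <= x)) {
        yy <- ys[k] + (x - x1) / (x2 - x1) * (ys[k2] - ys[k])
        cross <- c(cross, yy)
      }
    }
    if (!length(cross)) next
    cross <- sort(cross)
    for (j in seq(1, length(cross) - 1, by = 2)) {
      # half-open span in both axes, matching the crossing rule used for x
      y0 <- max(0L, ceiling(cross[j]))
      y1 <- min(h - 1L, as.integer(ceiling(cross[j + 1])) - 1L)
      if (y1 >= y0) mask[(y0:y1) + 1L, x + 1L] <- TRUE
    }
  }
  mask
}

#' Read a dataset bundle from disk
#'
#' Validates that every annotation references an existing image and that
#' every RLE decodes to the stored image size; polygon segmentations are
#' rasterized. An 80:20 train/validation split is derived deterministically
#' from the manifest seed.
#'
#' @param path dataset directory written by [generate_dataset()] or
#'   [write_dataset()].
#' @param load_images read image pixels (set `FALSE` for metadata-only use).
#' @return a `dataset_bundle`.
#' @export
read_dataset <- function(path, load_images = TRUE) {
  annf <- file.path(path, "annotations.json")
  if (!file.exists(annf)) stop("missing annotation file: ", annf)
  coco <- jsonlite::read_json(annf)
  manifest <- NULL
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf)
  images <- list()
  for (im in coco$images) {
    f <- file.path(path, im$file_name)
    if (!file.exists(f))
      stop("annotation references absent image: ", im$file_name)
    images[[as.character(im$id)]] <-
      list(id = im$id, file = f, width = im$width, height = im$height,
           grid_pitch_px = im$grid_pitch_px %||% NA_real_,
           pixels = if (load_images) png::readPNG(f) else NULL)
  }
  anns <- lapply(coco$annotations, function(a) {
    im <- images[[as.character(a$image_id)]]
    if (is.null(im)) stop("annotation ", a$id, " references unknown image id")
    seg <- a$segmentation
    mask <- if (!is.null(seg$counts)) {
      m <- tryCatch(rle_decode(seg), error = function(e)
        stop("annotation ", a$id, ": ", conditionMessage(e)))
      if (!identical(dim(m), c(im$height, im$width)))
        stop("annotation ", a$id, ": RLE size does not match its image")
      m
    } else {
      polygon_to_mask(as.numeric(unlist(seg)), im$height, im$width)
    }
    bb <- as.numeric(unlist(a$bbox))
    list(id = a$id, image_id = a$image_id, mask = mask,
         box = c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]),
         length_mm = a$length_mm %||% NA_real_,
         length_px = a$length_px %||% NA_real_,
         n_dev = a$n_dev %||% NA_integer_)
  })
  ids <- vapply(coco$images, function(im) im$id, 0)
  seed <- if (!is.null(manifest$seed)) manifest$seed else 0L
  old <- .Random.seed_save()
  set.seed(seed + 982451L)
  ord <- sample(ids)
  .Random.seed_restore(old)
  ntr <- max(1L, floor(0.8 * length(ids)))
  structure(list(images = images, annotations = anns, manifest = manifest,
                 split = list(train = sort(ord[seq_len(ntr)]),
                              val = sort(ord[-seq_len(ntr)]))),
            class = "dataset_bundle")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a list of annotated scenes as a dataset bundle
#'
#' @param scenes list of `annotated_scene` objects.
#' @param path output directory.
#' @param seed seed recorded in the manifest.
#' @return the path, invisibly.
#' @export
write_dataset <- function(scenes, path, seed = 0L) {
  dir.create(file.path(path, "images"), recursive = TRUE, showWarnings = FALSE)
  images <- list(); annotations <- list(); ann_id <- 0L
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    fn <- sprintf("scene_%04d.png", k)
    png::writePNG(sc$image, file.path(path, "images", fn))
    S <- dim(sc$image)[1]
    images[[k]] <- list(id = k, file_name = file.path("images", fn),
                        width = dim(sc$image)[2], height = S,
                        grid_pitch_px = sc$grid_pitch_px)
    for (i in seq_along(sc$masks)) {
      ann_id <- ann_id + 1L
      b <- sc$boxes[i, ]
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = k, category_id = 1L,
        segmentation = rle_encode(sc$masks[[i]]),
        bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
        area = sum(sc$masks[[i]]), iscrowd = 0L,
        length_mm = sc$length_mm[i], length_px = sc$length_px[i],
        n_dev = sc$n_dev[i])
    }
  }
  coco <- list(images = images, annotations = annotations,
               categories = list(list(id = 1L, name = "radicle")))
  jsonlite::write_json(coco, file.path(path, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = seed), file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
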