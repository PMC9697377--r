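# ---------------------------------------------------------------------------
# Seeded synthetic pest-scene generator.
#
# Scenes are textured backgrounds with procedurally drawn elliptical "pests"
# whose class signature is a deterministic colour/shape combination. The
# generator's knobs mirror the statistical structure of field-collected pest
# datasets: per-class relative-size distributions (log-uniform), strongly
# imbalanced class mixtures, variable instance density, and controlled
# occlusion. It is a statistical emulator for exercising the detector and
# the evaluation stack, not a photorealistic renderer.
# ---------------------------------------------------------------------------

#' Configuration for the synthetic scene generator
#'
#' @param image_size `c(width, height)` in pixels
#' @param classes data.frame with columns `name`, `weight` (mixture
#'   proportion; normalized internally), `rel_min`, `rel_max` (bounding-box
#'   area relative to image area; sampled log-uniformly between them)
#' @param instances_min,instances_max per-image instance count (uniform)
#' @param occlusion_prob probability that a placed object is allowed to
#'   overlap an earlier one (up to `max_overlap` IoU); objects not chosen as
#'   occluders are placed essentially disjoint
#' @param max_overlap IoU ceiling enforced between any two boxes
#' @param texture background texture amplitude in `[0, 1]`
#' @param seed default dataset seed
#' @return list of class `scene_config`
#' @export
scene_config <- function(image_size = c(128, 128),
                         classes = data.frame(
                           name = c("A", "B"), weight = c(0.5, 0.5),
                           rel_min = c(0.02, 0.02), rel_max = c(0.2, 0.2)),
                         instances_min = 1, instances_max = 3,
                         occlusion_prob = 0.1, max_overlap = 0.4,
                         texture = 0.3, seed = 0L) {
  stopifnot(all(classes$rel_min > 0), all(classes$rel_max < 1),
            all(classes$rel_min <= classes$rel_max),
            all(classes$weight > 0))
  classes$weight <- classes$weight / sum(classes$weight)
  structure(list(image_size = image_size, classes = classes,
                 instances_min = instances_min,
                 instances_max = instances_max,
                 occlusion_prob = occlusion_prob,
                 max_overlap = max_overlap, texture = texture,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Built-in generator presets
#'
#' * `"easy"`: two large, high-contrast, non-overlapping blob classes on a
#'   quiet background -- the regime used for scaled-down training runs.
#' * `"imbalanced-table1"`: ten classes whose mixture weights and mean
#'   relative sizes follow the instance counts (55...7976) and average
#'   relative sizes (0.007...0.306) characteristic of a field corn-pest
#'   collection.
#' * `"dense-small"`: many tiny instances per image (the aphid-cluster
#'   failure regime).
#' * `"occluded"`: few instances with frequent heavy overlap.
#'
#' @param name preset name
#' @param seed dataset seed
#' @return a `scene_config`
#' @export
scene_preset <- function(name = c("easy", "imbalanced-table1", "dense-small",
                                  "occluded"), seed = 0L) {
  name <- match.arg(name)
  switch(name,
    "easy" = scene_config(
      image_size = c(64, 64),
      classes = data.frame(name = c("blotch_red", "blotch_blue"),
                           weight = c(0.5, 0.5),
                           rel_min = c(0.06, 0.06), rel_max = c(0.2, 0.2)),
      instances_min = 1, instances_max = 2,
      occlusion_prob = 0, max_overlap = 0.1, texture = 0.08, seed = seed),
    "imbalanced-table1" = {
      nm <- c("LLD", "OF", "AY", "SLF", "DP", "HA", "LS", "SEH", "RP", "SF")
      counts <- c(55, 650, 174, 7976, 849, 919, 140, 141, 3875, 1970)
      avg <- c(0.192, 0.042, 0.153, 0.306, 0.038, 0.094, 0.061, 0.048,
               0.007, 0.057)
      scene_config(
        image_size = c(128, 128),
        classes = data.frame(name = nm, weight = counts / sum(counts),
                             rel_min = pmax(avg / 2, 5e-4),
                             rel_max = pmin(avg * 2, 0.6)),
        instances_min = 1, instances_max = 3,
        occlusion_prob = 0.1, max_overlap = 0.4, texture = 0.3, seed = seed)
    },
    "dense-small" = scene_config(
      image_size = c(128, 128),
      classes = data.frame(name = c("mite_a", "mite_b"), weight = c(0.5, 0.5),
                           rel_min = c(0.002, 0.002),
                           rel_max = c(0.01, 0.01)),
      instances_min = 8, instances_max = 15,
      occlusion_prob = 0.15, max_overlap = 0.3, texture = 0.35, seed = seed),
    "occluded" = scene_config(
      image_size = c(96, 96),
      classes = data.frame(name = c("larva_a", "larva_b"),
                           weight = c(0.5, 0.5),
                           rel_min = c(0.04, 0.04), rel_max = c(0.15, 0.15)),
      instances_min = 2, instances_max = 4,
      occlusion_prob = 0.8, max_overlap = 0.6, texture = 0.3, seed = seed))
}

# deterministic class visual signature from its index
class_signature <- function(i) {
  hues <- c(0.0, 0.6, 0.12, 0.75, 0.32, 0.5, 0.85, 0.07, 0.55, 0.95)
  h <- hues[((i - 1) %% length(hues)) + 1]
  col <- grDevices::hsv(h, 0.75, 0.85)
  rgb <- as.vector(grDevices::col2rgb(col)) / 255
  list(color = rgb, aspect = 0.5 + 0.45 * ((i * 7) %% 10) / 10)
}

#' Generate one synthetic pest scene
#'
#' Renders a textured background plus elliptical pest blobs; every rendered
#' object gets a tight bounding box recomputed from its rasterized mask
#' (accurate to within one pixel). Fully deterministic for a fixed seed.
#'
#' @param cfg a `scene_config`
#' @param seed integer seed for this scene (defaults to `cfg$seed`)
#' @param image_name file name recorded in the annotation
#' @return list with `image` ((H, W, 3) array in `[0, 1]`) and `record`
#'   (annotation record as in [read_voc_xml()]); skipped placements are
#'   reported in `attr(record, "skipped")`
#' @export
generate_scene <- function(cfg, seed = cfg$seed, image_name = "scene.png") {
  stopifnot(inherits(cfg, "scene_config"))
  withr::with_seed(as.integer(seed), {
    W <- cfg$image_size[1]
    H <- cfg$image_size[2]
    img <- render_background(W, H, cfg$texture)
    n <- if (cfg$instances_max <= 0) 0 else
      sample(seq(cfg$instances_min, cfg$instances_max), 1)
    placed <- NULL   # corner-form matrix of accepted boxes
    rows <- list()
    skipped <- 0L
    for (k in seq_len(n)) {
      ci <- sample.int(nrow(cfg$classes), 1, prob = cfg$classes$weight)
      rel <- exp(runif(1, log(cfg$classes$rel_min[ci]),
                       log(cfg$classes$rel_max[ci])))
      occluder <- runif(1) < cfg$occlusion_prob
      cap <- if (occluder) cfg$max_overlap else
        min(0.01, cfg$max_overlap)
      ok <- FALSE
      for (try in 1:20) {
        obj <- draw_params(W, H, rel, class_signature(ci)$aspect)
        cand <- matrix(c(obj$cx - obj$bw / 2, obj$cy - obj$bh / 2,
                         obj$cx + obj$bw / 2, obj$cy + obj$bh / 2), 1)
        if (!is.null(placed) && nrow(placed) > 0) {
          ious <- corner_iou_vec(cand, placed)
          if (any(ious > cap)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        skipped <- skipped + 1L
        next
      }
      res <- render_pest(img, obj, class_signature(ci)$color)
      img <- res$img
      if (is.null(res$bbox)) {
        skipped <- skipped + 1L
        next
      }
      placed <- rbind(placed, res$bbox)
      rows[[length(rows) + 1]] <-
        data.frame(x1 = res$bbox[1], y1 = res$bbox[2], x2 = res$bbox[3],
                   y2 = res$bbox[4], label = cfg$classes$name[ci])
    }
    bx <- if (length(rows) == 0) boxes() else {
      tab <- do.call(rbind, rows)
      boxes_from_corners(tab$x1, tab$y1, tab$x2, tab$y2, label = tab$label)
    }
    record <- list(image = image_name, width = W, height = H, boxes = bx)
    attr(record, "skipped") <- skipped
    list(image = img, record = record)
  })
}

render_background <- function(W, H, texture) {
  base <- c(0.32, 0.42, 0.22)  # muted foliage green
  img <- array(rep(base, each = H * W), dim = c(H, W, 3))
  if (texture > 0) {
    # coarse blotches: low-res noise blown up by pixel replication
    ch <- max(2L, H %/% 8)
    cw <- max(2L, W %/% 8)
    coarse <- matrix(rnorm(ch * cw, 0, texture * 0.25), ch, cw)
    up <- coarse[rep(seq_len(ch), each = ceiling(H / ch))[seq_len(H)],
                 rep(seq_len(cw), each = ceiling(W / cw))[seq_len(W)]]
    fine <- matrix(rnorm(H * W, 0, texture * 0.08), H, W)
    for (c in 1:3) img[, , c] <- img[, , c] + up + fine
  }
  pmin(pmax(img, 0), 1)
}

# choose a rotated ellipse whose tight bounding box has area rel * W * H
draw_params <- function(W, H, rel, aspect0) {
  aspect <- aspect0 * exp(rnorm(1, 0, 0.15))
  theta <- runif(1, 0, pi)
  area <- rel * W * H
  # unrotated half-axes a, b with b = aspect * a; bbox half-extents after
  # rotation: ex = sqrt(a^2 cos^2 + b^2 sin^2), ey = sqrt(a^2 sin^2 + b^2 cos^2)
  a0 <- 1
  b0 <- aspect
  ex0 <- sqrt(a0^2 * cos(theta)^2 + b0^2 * sin(theta)^2)
  ey0 <- sqrt(a0^2 * sin(theta)^2 + b0^2 * cos(theta)^2)
  s <- sqrt(area / (4 * ex0 * ey0))
  a <- s * a0
  b <- s * b0
  ex <- s * ex0
  ey <- s * ey0
  cx <- runif(1, ex, W - ex)
  cy <- runif(1, ey, H - ey)
  list(cx = cx, cy = cy, a = a, b = b, theta = theta,
       bw = 2 * ex, bh = 2 * ey)
}

render_pest <- function(img, obj, color) {
  H <- dim(img)[1]
  W <- dim(img)[2]
  # window around the object
  c1 <- max(1L, floor(obj$cx - obj$bw / 2) - 1L)
  c2 <- min(W, ceiling(obj$cx + obj$bw / 2) + 1L)
  r1 <- max(1L, floor(obj$cy - obj$bh / 2) - 1L)
  r2 <- min(H, ceiling(obj$cy + obj$bh / 2) + 1L)
  if (c2 < c1 || r2 < r1) return(list(img = img, bbox = NULL))
  xs <- (c1:c2) - 0.5
  ys <- (r1:r2) - 0.5
  X <- outer(rep(1, length(ys)), xs) - obj$cx
  Y <- outer(ys, rep(1, length(xs))) - obj$cy
  xr <- X * cos(obj$theta) + Y * sin(obj$theta)
  yr <- -X * sin(obj$theta) + Y * cos(obj$theta)
  f <- (xr / obj$a)^2 + (yr / obj$b)^2
  # the alpha = 0.5 contour sits exactly on f = 1, so the annotated box is
  # an unbiased (+-1 px) measurement of the configured shape extent
  alpha <- array(pmin(1, pmax(0, 0.5 + (1 - f) * 3)), dim = dim(f))
  wob <- 0.12 * sin(4 * atan2(yr, xr) + obj$theta * 5)
  if (!any(alpha >= 0.5)) return(list(img = img, bbox = NULL))
  shade <- 1 - 0.55 * pmin(1, pmax(0, (f * (1 + wob) - 0.55) * 2))  # rim
  spots <- 1 - 0.3 * pmin(1, pmax(0, sin(xr * 2.2) * cos(yr * 2.7) - 0.4))
  for (c in 1:3) {
    fg <- color[c] * shade * spots
    img[r1:r2, c1:c2, c] <- img[r1:r2, c1:c2, c] * (1 - alpha) + fg * alpha
  }
  # tight box from the rasterized mask (continuous half-open coords)
  hit <- which(alpha >= 0.5, arr.ind = TRUE)
  rows <- r1 - 1L + range(hit[, 1])
  cols <- c1 - 1L + range(hit[, 2])
  list(img = pmin(pmax(img, 0), 1),
       bbox = c(cols[1] - 1, rows[1] - 1, cols[2], rows[2]))
}

corner_iou_vec <- function(a, b) {
  iw <- pmax(0, pmin(a[1, 3], b[, 3]) - pmax(a[1, 1], b[, 1]))
  ih <- pmax(0, pmin(a[1, 4], b[, 4]) - pmax(a[1, 2], b[, 2]))
  inter <- iw * ih
  aa <- (a[1, 3] - a[1, 1]) * (a[1, 4] - a[1, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (aa + ab - inter)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `img_XXXX.png` images, matching Pascal VOC XML annotations, a
#' `manifest.csv`, and `truth_stats.json` holding the generator's own
#' bookkeeping (per-class instance counts and mean relative sizes). One
#' dataset seed drives everything; each image gets its own derived stream so
#' any single scene can be regenerated independently.
#'
#' @param n_images number of scenes
#' @param cfg a `scene_config`
#' @param out_dir output directory
#' @param force overwrite a non-empty `out_dir`
#' @return (invisibly) list with `manifest` (data.frame), `records`, and
#'   `stats` (the bookkeeping, same layout as [dataset_stats()]`$per_class`)
#' @export
generate_dataset <- function(n_images, cfg, out_dir, force = FALSE) {
  stopifnot(n_images >= 1)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- withr::with_seed(cfg$seed,
                            sample.int(.Machine$integer.max - 1, n_images))
  records <- vector("list", n_images)
  man <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    nm <- sprintf("img_%04d", i)
    sc <- generate_scene(cfg, seed = seeds[i],
                         image_name = paste0(nm, ".png"))
    png::writePNG(sc$image, file.path(out_dir, paste0(nm, ".png")))
    write_voc_xml(sc$record, file.path(out_dir, paste0(nm, ".xml")))
    records[[i]] <- sc$record
    man[[i]] <- data.frame(image = paste0(nm, ".png"),
                           xml = paste0(nm, ".xml"),
                           width = sc$record$width,
                           height = sc$record$height,
                           n_boxes = nrow(sc$record$boxes),
                           stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  st <- dataset_stats(records)
  jsonlite::write_json(st$per_class,
                       file.path(out_dir, "truth_stats.json"),
                       digits = NA)
  invisible(list(manifest = manifest, records = records,
                 stats = st$per_class))
}

#' Load a generated dataset directory
#'
#' Reads every annotation listed in `manifest.csv` (or every `*.xml` when no
#' manifest exists) back into annotation records; images are loaded lazily
#' by [load_scene_image()].
#'
#' @param dir dataset directory
#' @return list of annotation records with an extra `path` field
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  xmls <- if (file.exists(mf)) {
    file.path(dir, utils::read.csv(mf, stringsAsFactors = FALSE)$xml)
  } else {
    list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  }
  lapply(xmls, function(p) {
    r <- read_voc_xml(p)
    r$path <- file.path(dirname(p), r$image)
    r
  })
}

#' @rdname load_dataset
#' @param record an annotation record carrying a `path`
#' @export
load_scene_image <- function(record) {
  img <- png::readPNG(record$path)
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}
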