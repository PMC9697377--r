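#' Read a Pascal VOC XML annotation file
#'
#' Parses the LabelImg dialect of Pascal VOC XML: one `<object>` per pest
#' instance with corner-form `<bndbox>` coordinates. Corners are converted to
#' the center-form `(x, y, w, h, kappa)` representation used throughout the
#' package, treating the stored values as continuous coordinates so that
#' `w = xmax - xmin` (an object spanning corners (10, 20) and (30, 60)
#' becomes center (20, 40) with size 20 x 40). Class names are preserved
#' verbatim.
#'
#' @param path XML file path
#' @return an annotation record: list with `image` (the `<filename>`),
#'   `width`, `height`, and `boxes` (a boxes data.frame with `label`)
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  need <- function(node, tag) {
    x <- xml2::xml_find_first(node, tag)
    if (inherits(x, "xml_missing")) {
      stop("VOC XML parse error in ", path, ": missing <", tag, ">")
    }
    x
  }
  fname <- xml2::xml_text(need(doc, "filename"))
  size <- need(doc, "size")
  w <- as.numeric(xml2::xml_text(need(size, "width")))
  h <- as.numeric(xml2::xml_text(need(size, "height")))
  objs <- xml2::xml_find_all(doc, "object")
  if (length(objs) == 0) {
    bx <- boxes()
  } else {
    parse_obj <- function(o) {
      nm <- xml2::xml_text(need(o, "name"))
      bb <- need(o, "bndbox")
      v <- vapply(c("xmin", "ymin", "xmax", "ymax"),
                  function(t) as.numeric(xml2::xml_text(need(bb, t))), 0)
      if (v["xmax"] <= v["xmin"] || v["ymax"] <= v["ymin"]) {
        stop("invalid box in ", path, ": xmax/ymax must exceed xmin/ymin")
      }
      data.frame(xmin = v[["xmin"]], ymin = v[["ymin"]], xmax = v[["xmax"]],
                 ymax = v[["ymax"]], name = nm, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, lapply(objs, parse_obj))
    bx <- boxes_from_corners(tab$xmin, tab$ymin, tab$xmax, tab$ymax,
                             label = tab$name)
  }
  list(image = fname, width = w, height = h, boxes = bx)
}

#' Write an annotation record as Pascal VOC XML
#'
#' Inverse of [read_voc_xml()]: center-form boxes are written back as
#' corner-form `<bndbox>` entries. Integer-coordinate boxes round-trip
#' losslessly.
#'
#' @param record annotation record as returned by [read_voc_xml()]
#' @param path output file path
#' @export
write_voc_xml <- function(record, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", record$image)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", format(record$width, scientific = FALSE))
  xml2::xml_add_child(sz, "height", format(record$height, scientific = FALSE))
  xml2::xml_add_child(sz, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  if (nrow(record$boxes) > 0) {
    cs <- box_corners(record$boxes)
    num <- function(x) {
      format(round(x, 6), scientific = FALSE, trim = TRUE)
    }
    for (i in seq_len(nrow(cs))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", as.character(record$boxes$label[i]))
      xml2::xml_add_child(ob, "pose", "Unspecified")
      xml2::xml_add_child(ob, "truncated", "0")
      xml2::xml_add_child(ob, "difficult", "0")
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", num(cs[i, "x1"]))
      xml2::xml_add_child(bb, "ymin", num(cs[i, "y1"]))
      xml2::xml_add_child(bb, "xmax", num(cs[i, "x2"]))
      xml2::xml_add_child(bb, "ymax", num(cs[i, "y2"]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Split a dataset into training and testing sets
#'
#' Random, seeded, exhaustive partition with `n_train = floor(frac * N)`,
#' the 9:1 convention of detection benchmarks by default.
#'
#' @param records list (or vector) of annotation records or identifiers
#' @param train_fraction fraction assigned to training, default 0.9
#' @param seed integer seed driving the shuffle
#' @return list with `train` and `test` subsets (same type as `records`)
#' @export
split_dataset <- function(records, train_fraction = 0.9, seed = 0L) {
  n <- length(records)
  if (n == 0) stop("cannot split an empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = records[sort(perm[seq_len(n_train)])],
       test = records[sort(perm[setdiff(seq_len(n), seq_len(n_train))])])
}

#' Relative size of a box within its image
#'
#' By default the area ratio `(w * h) / (W * H)`; with
#' `definition = "linear"` the square root of that ratio (a length scale).
#'
#' @param box one-row boxes data.frame (or several rows, vectorized)
#' @param image_w,image_h image dimensions in pixels
#' @param definition `"area"` (default) or `"linear"`
#' @return numeric vector of ratios in `(0, 1]`
#' @export
relative_size <- function(box, image_w, image_h,
                          definition = c("area", "linear")) {
  definition <- match.arg(definition)
  if (any(image_w <= 0) || any(image_h <= 0)) {
    stop("image dimensions must be positive")
  }
  r <- (box$w * box$h) / (image_w * image_h)
  if (definition == "linear") sqrt(r) else r
}

#' Per-class dataset statistics
#'
#' Computes, for every class, the number of images containing it, the number
#' of annotated instances, and the mean relative size of its boxes -- the
#' summary columns conventionally reported for pest detection datasets --
#' plus a histogram of relative sizes over all instances.
#'
#' @param records list of annotation records ([read_voc_xml()] format)
#' @param breaks histogram break specification passed to [graphics::hist()]
#'   semantics via [base::cut()]; default 20 equal bins on `(0, 1]`
#' @param definition relative-size definition, see [relative_size()]
#' @return object of class `dataset_stats`: list with `per_class`
#'   (data.frame `class, n_images, n_instances, mean_rel_size`),
#'   `rel_sizes` (all instance relative sizes), `histogram` (table)
#' @export
dataset_stats <- function(records, breaks = seq(0, 1, 0.05),
                          definition = "area") {
  if (length(records) == 0) stop("empty dataset")
  rows <- lapply(records, function(r) {
    if (nrow(r$boxes) == 0) return(NULL)
    data.frame(class = as.character(r$boxes$label),
               rel = relative_size(r$boxes, r$width, r$height,
                                   definition = definition),
               image = r$image, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(class = character(), rel = numeric(),
                                      image = character())
  cls <- sort(unique(tab$class))
  per <- do.call(rbind, lapply(cls, function(cl) {
    sub <- tab[tab$class == cl, , drop = FALSE]
    data.frame(class = cl, n_images = length(unique(sub$image)),
               n_instances = nrow(sub), mean_rel_size = mean(sub$rel),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(class = character(), n_images = integer(),
                      n_instances = integer(), mean_rel_size = numeric())
  }
  structure(list(per_class = per, rel_sizes = tab$rel,
                 histogram = table(cut(tab$rel, breaks = breaks,
                                       include.lowest = TRUE))),
            class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat("Dataset statistics (", sum(x$per_class$n_instances),
      " instances, ", nrow(x$per_class), " classes)\n", sep = "")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write per-class dataset statistics as CSV
#' @param stats a `dataset_stats` object
#' @param path output file
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(stats$per_class, path, row.names = FALSE)
  invisible(path)
}
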