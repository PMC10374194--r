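#' Read RGBA sprites from a directory
#'
#' Reads every PNG under `dir` (recursively); the species tag is the
#' containing subdirectory name (or the file stem for files directly in
#' `dir`).  Files without an alpha channel are skipped with a warning.
#'
#' @param dir Directory of RGBA PNG files.
#' @return Named list of `phenosynth_sprite` objects.
#' @export
read_sprites <- function(dir) {
  stopifnot(dir.exists(dir))
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  out <- list()
  for (f in files) {
    px <- tryCatch(png::readPNG(f), error = function(e) NULL)
    if (is.null(px)) {
      warning("Skipping unreadable file: ", f, call. = FALSE)
      next
    }
    if (length(dim(px)) != 3L || dim(px)[3] != 4L) {
      warning("Skipping non-RGBA PNG (no alpha channel): ", f, call. = FALSE)
      next
    }
    rel <- sub("^/+", "", substring(f, nchar(dir) + 1L))
    species <- if (grepl("/", rel)) dirname(rel) else
      sub("\\.png$", "", basename(rel), ignore.case = TRUE)
    nm <- sub("\\.png$", "", basename(f), ignore.case = TRUE)
    out[[nm]] <- new_sprite(px, species, "loaded")
  }
  if (!length(out)) stop("No valid RGBA sprites found in ", dir, call. = FALSE)
  out
}

#' Write a sprite to an RGBA PNG file
#'
#' @param sprite A `phenosynth_sprite`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sprite <- function(sprite, path) {
  stopifnot(inherits(sprite, "phenosynth_sprite"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(sprite$pixels, path)
  invisible(path)
}

# Read RGB backgrounds (PNG) from a directory.
read_backgrounds <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE,
                      ignore.case = TRUE)
  files <- files[!grepl("_mask\\.png$", files)]
  stopifnot(length(files) >= 1L)
  lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3]
    structure(list(image = px, region_mask = NULL),
              class = "phenosynth_background")
  })
}

#' Write scene annotations as COCO JSON
#'
#' Writes an images/annotations/categories COCO file: bbox `[x, y, w, h]`
#' 0-based half-open, `segmentation` as flattened visible-polygon vertex
#' lists, `area` = visible pixel count, `iscrowd = 0`, plus the
#' nonstandard `occlusion_ratio` field.
#'
#' @param scenes List of `synthetic_scene` objects.
#' @param image_files Character vector of image file names, parallel to
#'   `scenes`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_coco <- function(scenes, image_files, path) {
  stopifnot(length(scenes) == length(image_files))
  images <- lapply(seq_along(scenes), function(i) {
    d <- dim(scenes[[i]]$image)
    list(id = i, file_name = image_files[i], width = d[2], height = d[1])
  })
  ann_id <- 0L
  anns <- list()
  for (i in seq_along(scenes)) {
    a <- scenes[[i]]$annotations
    if (!nrow(a)) next
    for (k in seq_len(nrow(a))) {
      ann_id <- ann_id + 1L
      poly <- a$polygon[[k]]
      anns[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = 1L,
        bbox = c(a$x_min[k], a$y_min[k], a$w[k], a$h[k]),
        segmentation = list(as.numeric(t(poly))),
        area = a$area[k], iscrowd = 0L,
        occlusion_ratio = a$occlusion_ratio[k])
    }
  }
  if (anyDuplicated(vapply(anns, `[[`, numeric(1), "id"))) {
    stop("Annotation id collision.", call. = FALSE)
  }
  jsonlite::write_json(
    list(images = images, annotations = anns,
         categories = list(list(id = 1L, name = "fruit"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO JSON annotation file
#'
#' @param path COCO JSON path.
#' @return A list with `images` and `annotations` tibbles (`annotations`
#'   has `image`, `x_min`, `y_min`, `w`, `h`, `area`, `category`, plus
#'   `score` and `occlusion_ratio` when present).
#' @export
read_coco <- function(path) {
  x <- jsonlite::read_json(path)
  images <- dplyr::bind_rows(lapply(x$images, function(im) {
    tibble::tibble(id = im$id, file_name = im$file_name,
                   width = im$width, height = im$height)
  }))
  anns <- dplyr::bind_rows(lapply(x$annotations, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    tibble::tibble(
      id = a$id,
      image = images$file_name[match(a$image_id, images$id)],
      x_min = bb[1], y_min = bb[2], w = bb[3], h = bb[4],
      area = a$area %||% NA_real_,
      category = "fruit",
      score = a$score %||% NA_real_,
      occlusion_ratio = a$occlusion_ratio %||% NA_real_)
  }))
  list(images = images, annotations = anns)
}

#' Write scene annotations as Pascal VOC XML files
#'
#' One XML per image; VOC boxes are 1-based inclusive corners, converted
#' exactly from the 0-based half-open COCO convention:
#' `xmin = x + 1`, `ymin = y + 1`, `xmax = x + w`, `ymax = y + h`.
#'
#' @param scenes List of `synthetic_scene` objects.
#' @param image_files Parallel image file names.
#' @param out_dir Output directory for the XML files.
#' @return Invisibly, the vector of written paths.
#' @export
write_voc <- function(scenes, image_files, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    d <- dim(sc$image)
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", image_files[i])
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(d[2]))
    xml2::xml_add_child(sz, "height", as.character(d[1]))
    xml2::xml_add_child(sz, "depth", "3")
    a <- sc$annotations
    if (nrow(a)) {
      for (k in seq_len(nrow(a))) {
        ob <- xml2::xml_add_child(doc, "object")
        xml2::xml_add_child(ob, "name", "fruit")
        xml2::xml_add_child(ob, "difficult", "0")
        bb <- xml2::xml_add_child(ob, "bndbox")
        xml2::xml_add_child(bb, "xmin", as.character(a$x_min[k] + 1))
        xml2::xml_add_child(bb, "ymin", as.character(a$y_min[k] + 1))
        xml2::xml_add_child(bb, "xmax", as.character(a$x_min[k] + a$w[k]))
        xml2::xml_add_child(bb, "ymax", as.character(a$y_min[k] + a$h[k]))
      }
    }
    paths[i] <- file.path(out_dir,
                          sub("\\.png$", ".xml", image_files[i],
                              ignore.case = TRUE))
    xml2::write_xml(doc, paths[i])
  }
  invisible(paths)
}

#' Convert a COCO bbox to VOC corners
#'
#' @param bbox Numeric length-4 `c(x, y, w, h)`, 0-based half-open.
#' @return Named numeric `c(xmin, ymin, xmax, ymax)`, 1-based inclusive.
#' @export
coco_to_voc_bbox <- function(bbox) {
  c(xmin = bbox[[1]] + 1, ymin = bbox[[2]] + 1,
    xmax = bbox[[1]] + bbox[[3]], ymax = bbox[[2]] + bbox[[4]])
}

#' Convert VOC corners to a COCO bbox
#'
#' Exact inverse of [coco_to_voc_bbox()].
#'
#' @param corners Numeric length-4 `c(xmin, ymin, xmax, ymax)`, 1-based
#'   inclusive.
#' @return Named numeric `c(x, y, w, h)`, 0-based half-open.
#' @export
voc_to_coco_bbox <- function(corners) {
  c(x = corners[[1]] - 1, y = corners[[2]] - 1,
    w = corners[[3]] - corners[[1]] + 1, h = corners[[4]] - corners[[2]] + 1)
}
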