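#' Polygon annotation
#'
#' A polygonal region of interest in pixel coordinates. Coordinates are
#' 0-based, `(x, y) = (column, row)`, and the interior is defined by the
#' even-odd rule. The ring is implicitly closed (the last vertex connects
#' back to the first).
#'
#' @param x,y Numeric vectors of vertex coordinates (at least 3 vertices).
#' @param label Class tag of the region; the tumor class is `"HCC"`.
#' @return An object of class `via_polygon`.
#' @export
via_polygon <- function(x, y, label = "HCC") {
  stopifnot(length(x) == length(y), length(x) >= 3L, is.numeric(x), is.numeric(y))
  vert <- cbind(x = as.numeric(x), y = as.numeric(y))
  # drop a duplicated closing vertex if the caller provided one
  if (nrow(vert) > 3L && all(vert[1L, ] == vert[nrow(vert), ])) {
    vert <- vert[-nrow(vert), , drop = FALSE]
  }
  if (!polygon_is_simple(vert)) {
    stop("polygon must be a simple (non-self-intersecting) ring")
  }
  structure(list(vertices = vert, label = as.character(label)),
            class = "via_polygon")
}

#' Annotated ultrasound frame
#'
#' One grayscale B-mode frame with its polygon annotations and provenance.
#' Pixels are stored as an integer matrix in `[0, 255]`, `pixels[r, c]` being
#' the intensity at 0-based coordinate `(x = c - 1, y = r - 1)`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param annotations List of [via_polygon()] objects.
#' @param patient_id Opaque patient identifier.
#' @param device_tag Acquisition device tag (e.g. `"GE7"`, `"GE9"`).
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, annotations = list(),
                            patient_id = NA_character_,
                            device_tag = NA_character_) {
  stopifnot(is.matrix(pixels), length(pixels) > 0L)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  h <- nrow(pixels); w <- ncol(pixels)
  for (p in annotations) {
    stopifnot(inherits(p, "via_polygon"))
    v <- p$vertices
    if (any(v[, 1L] < 0) || any(v[, 1L] > w - 1L) ||
        any(v[, 2L] < 0) || any(v[, 2L] > h - 1L)) {
      stop("polygon vertex outside image bounds")
    }
  }
  structure(list(pixels = matrix(as.integer(round(pixels)), h, w),
                 annotations = annotations,
                 patient_id = as.character(patient_id),
                 device_tag = as.character(device_tag)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %dx%d px, %d polygon(s), patient %s [%s]\n",
              nrow(x$pixels), ncol(x$pixels), length(x$annotations),
              x$patient_id, x$device_tag))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Raster image I/O. PNG goes through the png package; BMP (the export format
# of the clinical workflow) is decoded here directly: uncompressed 8-bit
# palette or 24-bit BGR, bottom-up or top-down rows.

luminance <- function(rgb3) {
  0.299 * rgb3[, , 1L] + 0.587 * rgb3[, , 2L] + 0.114 * rgb3[, , 3L]
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM") {
    stop("not a BMP file: ", path)
  }
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  data_off <- u32(10L)
  hdr_size <- u32(14L)
  if (hdr_size < 40L) stop("unsupported BMP header in ", path)
  width <- u32(18L)
  height_raw <- u32(22L)
  top_down <- height_raw > 2^31 - 1
  height <- if (top_down) 2^32 - height_raw else height_raw
  bpp <- u16(28L)
  compression <- u32(30L)
  if (compression != 0L) stop("compressed BMP not supported: ", path)
  if (width == 0L || height == 0L) stop("zero-area image: ", path)
  if (!bpp %in% c(8L, 24L)) stop("unsupported BMP bit depth ", bpp)
  if (bpp == 8L) {
    n_colors <- u32(46L)
    if (n_colors == 0L) n_colors <- 256L
    pal_off <- 14L + hdr_size
    pal <- matrix(as.integer(raw[pal_off + seq_len(4L * n_colors)]),
                  ncol = 4L, byrow = TRUE) # B, G, R, reserved
    gray_pal <- 0.299 * pal[, 3L] + 0.587 * pal[, 2L] + 0.114 * pal[, 1L]
    stride <- ((width + 3L) %/% 4L) * 4L
    need <- data_off + stride * height
    if (length(raw) < need) stop("truncated BMP file: ", path)
    px <- matrix(0L, height, width)
    for (r in seq_len(height)) {
      row_off <- data_off + (r - 1L) * stride
      idx <- as.integer(raw[row_off + seq_len(width)]) + 1L
      dest <- if (top_down) r else height - r + 1L
      px[dest, ] <- as.integer(round(gray_pal[idx]))
    }
  } else {
    stride <- ((3L * width + 3L) %/% 4L) * 4L
    need <- data_off + stride * height
    if (length(raw) < need) stop("truncated BMP file: ", path)
    px <- matrix(0L, height, width)
    for (r in seq_len(height)) {
      row_off <- data_off + (r - 1L) * stride
      bytes <- as.integer(raw[row_off + seq_len(3L * width)])
      b <- bytes[seq(1L, by = 3L, length.out = width)]
      g <- bytes[seq(2L, by = 3L, length.out = width)]
      rr <- bytes[seq(3L, by = 3L, length.out = width)]
      dest <- if (top_down) r else height - r + 1L
      px[dest, ] <- as.integer(round(0.299 * rr + 0.587 * g + 0.114 * b))
    }
  }
  px
}

write_bmp_gray <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  stride <- ((w + 3L) %/% 4L) * 4L
  data_off <- 14L + 40L + 4L * 256L
  file_size <- data_off + stride * h
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(file_size); u16(0L); u16(0L); u32(data_off)
  u32(40L); u32(w); u32(h); u16(1L); u16(8L); u32(0L); u32(stride * h)
  u32(2835L); u32(2835L); u32(256L); u32(0L)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256L)))
  writeBin(pal, con)
  pad <- as.raw(rep(0L, stride - w))
  for (r in seq.int(h, 1L)) {
    writeBin(as.raw(as.integer(pixels[r, ])), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

#' Read a grayscale image
#'
#' Decodes an 8-bit PNG or uncompressed BMP raster into an
#' [annotated_image()] with an empty annotation list. Color inputs are
#' collapsed to luminance (`0.299 R + 0.587 G + 0.114 B`).
#'
#' @param path Path to a PNG or BMP file.
#' @param patient_id,device_tag Optional provenance to attach.
#' @return An [annotated_image()] with no annotations.
#' @export
read_gray_image <- function(path, patient_id = NA_character_,
                            device_tag = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 8L)
  png_magic <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8L && all(magic == png_magic)) {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop("undecodable PNG: ", path,
                                             " (", conditionMessage(e), ")"))
    if (length(dim(arr)) == 3L) {
      arr <- if (dim(arr)[3L] >= 3L) luminance(arr) else arr[, , 1L]
    }
    px <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  } else if (length(magic) >= 2L && rawToChar(magic[1:2]) == "BM") {
    px <- read_bmp_gray(path)
  } else {
    stop("undecodable image format: ", path)
  }
  if (length(px) == 0L) stop("zero-area image: ", path)
  annotated_image(px, patient_id = patient_id, device_tag = device_tag)
}

#' Write a grayscale image
#'
#' Writes an intensity matrix (or [annotated_image()]) as 8-bit PNG or BMP,
#' chosen by file extension. The stored pixels round-trip bit-identically
#' through [read_gray_image()].
#'
#' @param image An [annotated_image()] or intensity matrix in `[0, 255]`.
#' @param path Output path ending in `.png` or `.bmp`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  stopifnot(is.matrix(px))
  px <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px / 255, target = path)
  } else if (ext == "bmp") {
    write_bmp_gray(px, path)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# VIA annotation files

#' Read VIA polygon annotations
#'
#' Parses a VGG Image Annotator (VIA) export (either the flat
#' region-data map or a project file with `_via_img_metadata`) and pairs each
#' entry with its image from `image_store`. Only polygon regions are
#' supported; each becomes a [via_polygon()] with the label taken from the
#' region attributes (default `"HCC"`). Polygon vertex order is preserved
#' exactly as stored.
#'
#' @param path VIA JSON export.
#' @param image_store Directory holding the referenced images.
#' @return List of [annotated_image()] objects, one per referenced image.
#' @export
read_via_annotations <- function(path, image_store) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- js[["_via_img_metadata"]] %||% js
  # project files carry bookkeeping keys alongside the metadata map
  entries <- entries[vapply(entries, function(e)
    is.list(e) && !is.null(e$filename), logical(1L))]
  lapply(entries, function(entry) {
    img_path <- file.path(image_store, entry$filename)
    if (!file.exists(img_path)) {
      stop("referenced image missing from image store: ", entry$filename)
    }
    fa <- entry$file_attributes %||% list()
    img <- read_gray_image(img_path,
                           patient_id = fa$patient_id %||% NA_character_,
                           device_tag = fa$device_tag %||% NA_character_)
    polys <- lapply(entry$regions %||% list(), function(region) {
      sa <- region$shape_attributes
      if (!identical(sa$name, "polygon")) {
        stop("unsupported region shape '", sa$name, "': only polygon regions",
             " are supported")
      }
      label <- region$region_attributes$label %||% "HCC"
      via_polygon(unlist(sa$all_points_x), unlist(sa$all_points_y), label)
    })
    img$annotations <- polys
    img
  })
}

#' Write VIA polygon annotations
#'
#' Serializes annotated images to a VIA-style region-data JSON map keyed by
#' `filename` + file size, readable by [read_via_annotations()] and by the
#' VIA tool itself.
#'
#' @param images List of [annotated_image()] objects.
#' @param filenames Image file names (relative to the image store), one per
#'   image; the image files themselves are written separately with
#'   [write_gray_image()].
#' @param path Output JSON path.
#' @param image_store Directory used to look up file sizes (optional; missing
#'   files get size 0 in the key, which VIA tolerates).
#' @return `path`, invisibly.
#' @export
write_via_annotations <- function(images, filenames, path, image_store = NULL) {
  stopifnot(length(images) == length(filenames))
  entries <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    fsize <- 0
    if (!is.null(image_store)) {
      fp <- file.path(image_store, filenames[[i]])
      if (file.exists(fp)) fsize <- file.info(fp)$size
    }
    regions <- lapply(img$annotations, function(p) {
      list(shape_attributes = list(name = "polygon",
                                   all_points_x = as.numeric(p$vertices[, 1L]),
                                   all_points_y = as.numeric(p$vertices[, 2L])),
           region_attributes = list(label = p$label))
    })
    entries[[paste0(filenames[[i]], fsize)]] <-
      list(filename = filenames[[i]], size = fsize,
           regions = regions,
           file_attributes = list(patient_id = img$patient_id,
                                  device_tag = img$device_tag))
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature tables

#' Write a feature table
#'
#' Writes feature vectors plus their class labels as a CSV with one header
#' row (feature names followed by `label`). Reading the file back with
#' [read_feature_table()] reproduces the values to full printed precision.
#'
#' @param rows A data frame of numeric feature columns plus a `label` column
#'   (as produced by [extract_features()]), or a list of identically named
#'   numeric vectors.
#' @param path Output CSV path.
#' @param labels Class labels, required when `rows` is a list of vectors.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path, labels = NULL) {
  if (is.data.frame(rows)) {
    df <- rows
    if (!"label" %in% names(df)) stop("feature table needs a 'label' column")
  } else {
    if (length(rows) == 0L) {
      df <- data.frame(label = character(0L))
    } else {
      hdr <- names(rows[[1L]])
      for (v in rows) {
        if (!identical(names(v), hdr)) {
          stop("inconsistent feature-name headers across rows")
        }
      }
      df <- as.data.frame(do.call(rbind, rows))
      names(df) <- hdr
      if (is.null(labels)) stop("labels required for a list of feature vectors")
      df$label <- as.character(labels)
    }
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Data frame of numeric feature columns plus a character `label`
#'   column.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df
}
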