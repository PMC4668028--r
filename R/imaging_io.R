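#' Construct a mammogram image
#'
#' A mammogram is a 2-D non-negative intensity grid with physical pixel
#' spacing and a nominal bit depth. Pixels are stored as a base-R numeric
#' matrix indexed `[row, col]` with row 1 at the top; all coordinates in the
#' package are 0-based `(row, col)` pairs, so pixel `(0, 0)` is
#' `pixels[1, 1]`.
#'
#' @param pixels Numeric matrix of intensities, at least 3x3, all values in
#'   `[0, 2^bit_depth - 1]`.
#' @param spacing_mm Physical size of one (isotropic) pixel in millimetres.
#' @param bit_depth Integer sample depth: 8, 12 or 16.
#' @return An object of class `mammogram`.
#' @examples
#' img <- mammogram_image(matrix(100, 8, 8), spacing_mm = 0.1)
#' dim(img$pixels)
#' @export
mammogram_image <- function(pixels, spacing_mm, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 3 || ncol(pixels) < 3) {
    stop("mammogram must be at least 3x3 pixels", call. = FALSE)
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0) {
    stop("`spacing_mm` must be a positive scalar", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    stop("intensities must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm, bit_depth = bit_depth),
    class = "mammogram"
  )
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf(
    "<mammogram> %d x %d px, %.3g mm/px, %d-bit, intensity range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$bit_depth,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Read a grayscale mammogram from PGM, PNG or TIFF
#'
#' Bit depth is inferred from the file's sample depth (PGM maxval, PNG/TIFF
#' 8 vs 16 bit). Pixel spacing is never read from the file: PGM has no
#' spacing field and scanned-film archives disagree, so it is always
#' supplied by the caller (or a sidecar config upstream).
#'
#' @param path Path to a grayscale PGM (P2/P5), PNG or TIFF file.
#' @param spacing_mm Pixel spacing in mm/pixel to attach.
#' @return A [mammogram_image()].
#' @export
read_mammogram <- function(path, spacing_mm) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "ppm")) {
    pg <- read_pgm(path)
    return(mammogram_image(pg$pixels, spacing_mm,
                           bit_depth = if (pg$maxval > 255) 16L else 8L))
  }
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] > 1 && !all(arr[, , 1] == arr[, , min(2, dim(arr)[3])])) {
      stop("color images are not supported", call. = FALSE)
    }
    arr <- arr[, , 1]
  }
  # readers return [0,1]; recover integer samples from the 16-bit scale when
  # any value needs more than 8 bits
  px16 <- round(arr * 65535)
  if (all(px16 %% 257 == 0)) {
    mammogram_image(px16 / 257, spacing_mm, bit_depth = 8L)
  } else {
    mammogram_image(px16, spacing_mm, bit_depth = 16L)
  }
}

#' Write a mammogram to PGM, PNG or TIFF
#'
#' @param image A [mammogram_image()].
#' @param path Output path; format chosen by extension (.pgm, .png, .tif).
#' @return `path`, invisibly.
#' @export
write_mammogram <- function(image, path) {
  stopifnot(inherits(image, "mammogram"))
  ext <- tolower(tools::file_ext(path))
  px <- round(image$pixels)
  maxv <- 2^image$bit_depth - 1
  if (ext == "pgm") {
    write_pgm(px, path, maxval = maxv)
  } else if (ext == "png") {
    png::writePNG(px / maxv, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / maxv, path,
                    bits.per.sample = if (image$bit_depth > 8) 16L else 8L)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

# Minimal PGM (P2 ascii / P5 binary) reader; no installed package reads PGM.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens, skipping '#' comments
  while (length(tokens) < 4) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  nc <- as.integer(tokens[2])
  nr <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  n <- nr * nc
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval > 255) {
      raw <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                     endian = "big")
    } else {
      raw <- as.integer(readBin(con, "raw", n = n))
    }
    vals <- raw
  } else {
    stop("not a PGM file (magic ", magic, ")", call. = FALSE)
  }
  if (length(vals) < n) stop("truncated PGM pixel data", call. = FALSE)
  list(pixels = matrix(as.numeric(vals), nrow = nr, ncol = nc, byrow = TRUE),
       maxval = maxval)
}

write_pgm <- function(pixels, path, maxval) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(pixels), nrow(pixels), maxval),
            con, eos = NULL)
  vals <- as.integer(t(pixels))
  if (maxval > 255) {
    writeBin(vals, con, size = 2, endian = "big")
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read individual-microcalcification point annotations
#'
#' @param path CSV with header `image_id,row,col`; coordinates are 0-based
#'   `(row, col)` with row 0 at the top.
#' @param image_shape Optional `(rows, cols)` bounds; when given, any point
#'   outside them is an error.
#' @return A tibble with columns `image_id`, `row`, `col`, in file order.
#' @export
read_mc_points <- function(path, image_shape = NULL) {
  df <- read.csv(path, colClasses = c("character", "integer", "integer"))
  if (!identical(names(df), c("image_id", "row", "col"))) {
    stop("expected header image_id,row,col", call. = FALSE)
  }
  if (anyDuplicated(df[c("image_id", "row", "col")])) {
    stop("duplicate point annotation", call. = FALSE)
  }
  if (!is.null(image_shape) && nrow(df) > 0) {
    if (any(df$row < 0 | df$col < 0 |
            df$row >= image_shape[1] | df$col >= image_shape[2])) {
      stop("point annotation outside image bounds", call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write individual-microcalcification point annotations
#'
#' @param points Tibble with `image_id`, `row`, `col`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mc_points <- function(points, path) {
  write.csv(points[c("image_id", "row", "col")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read cluster annotations (boxes or circles)
#'
#' CSV dialect: `image_id,shape,row_a,col_a,row_b,col_b`. For `shape = box`,
#' `(row_a, col_a)` and `(row_b, col_b)` are the min and max corners; for
#' `shape = circle`, `(row_a, col_a)` is the centre, `row_b` the radius in
#' pixels and `col_b` is empty. Circles are kept as read; containment tests
#' treat them natively (see [match_cluster()]).
#'
#' @param path CSV path.
#' @return Tibble `image_id, shape, row_a, col_a, row_b, col_b`.
#' @export
read_mc_clusters <- function(path) {
  df <- read.csv(path, colClasses = c("character", "character", "numeric",
                                      "numeric", "numeric", "numeric"))
  if (!identical(names(df), c("image_id", "shape", "row_a", "col_a",
                              "row_b", "col_b"))) {
    stop("expected header image_id,shape,row_a,col_a,row_b,col_b",
         call. = FALSE)
  }
  bad_shape <- !df$shape %in% c("box", "circle")
  if (any(bad_shape)) stop("shape must be 'box' or 'circle'", call. = FALSE)
  box <- df$shape == "box"
  if (any(box & (df$row_b <= df$row_a | df$col_b <= df$col_a))) {
    stop("degenerate box annotation (max must exceed min)", call. = FALSE)
  }
  if (any(!box & df$row_b <= 0)) {
    stop("circle radius must be positive", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_mc_clusters
#' @param clusters Tibble in the same dialect.
#' @export
write_mc_clusters <- function(clusters, path) {
  write.csv(clusters[c("image_id", "shape", "row_a", "col_a",
                       "row_b", "col_b")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Convert circle annotations to their tight bounding boxes
#'
#' @param clusters Cluster annotation tibble.
#' @return The same tibble with every circle replaced by the tight square
#'   box enclosing it (shape recoded to "box").
#' @export
clusters_as_boxes <- function(clusters) {
  circ <- clusters$shape == "circle"
  out <- clusters
  if (any(circ)) {
    r <- clusters$row_b[circ]
    out$row_b[circ] <- clusters$row_a[circ] + r
    out$col_b[circ] <- clusters$col_a[circ] + r
    out$row_a[circ] <- clusters$row_a[circ] - r
    out$col_a[circ] <- clusters$col_a[circ] - r
    out$shape[circ] <- "box"
  }
  out
}

#' Read and write detection records
#'
#' Detections are tibbles with columns `image_id`, `row`, `col`, `score`
#' (a probability in `[0, 1]`) and `stage` (`"rf"` or `"drbm"`). Scores are
#' serialized with full double precision so a write/read round trip is
#' lossless to well below 1e-9.
#'
#' @param detections Detection tibble.
#' @param path CSV path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_detections <- function(detections, path) {
  df <- as.data.frame(detections[c("image_id", "row", "col", "score",
                                   "stage")])
  df$score <- sprintf("%.17g", df$score)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- read.csv(path, colClasses = c("character", "integer", "integer",
                                      "numeric", "character"))
  if (!identical(names(df), c("image_id", "row", "col", "score", "stage"))) {
    stop("expected header image_id,row,col,score,stage", call. = FALSE)
  }
  if (nrow(df) > 0 && (any(df$score < 0) || any(df$score > 1))) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(df)
}
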