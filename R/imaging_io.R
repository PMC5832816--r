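#' Read a raster image (TIFF or PNG) as a grayscale intensity matrix
#'
#' RGB(A) images are converted to grayscale with ITU-R BT.601 luminance
#' weights (0.299 R + 0.587 G + 0.114 B), the convention used by ImageJ's
#' 8-bit conversion. Intensities are returned as integers on 0..255.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return A `raster_image`: an integer matrix of intensities, row 1 = top.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "invermass_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           abort(sprintf("unsupported raster format '.%s' (need PNG or TIFF)", ext),
                 "invermass_format_error")),
    error = function(e) {
      if (inherits(e, "invermass_error")) stop(e)
      abort(sprintf("cannot read raster image '%s': %s", path, conditionMessage(e)),
            "invermass_format_error")
    }
  )
  g <- if (length(dim(arr)) == 2L) {
    arr
  } else if (dim(arr)[3L] >= 3L) {
    0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
  } else {
    arr[, , 1L]  # gray + alpha
  }
  if (is.null(dim(g))) g <- matrix(g, dim(arr)[1L], dim(arr)[2L])
  px <- matrix(as.integer(round(g * 255)), nrow(g), ncol(g))
  structure(px, class = c("raster_image", class(matrix(integer()))))
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, intensities %d..%d\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read an ImageJ-style text image as a binary mask
#'
#' A text image is a whitespace-delimited rectangular matrix of integers as
#' exported by ImageJ's File > Save As > Text Image: after thresholding,
#' object pixels are written as 255 and background pixels as 0.
#'
#' @param path path to the text file.
#' @param tolerant if `TRUE`, any strictly positive value is mapped to
#'   object; the default (`FALSE`) rejects values other than 0 and 255.
#' @return A [binary_mask()].
#' @export
read_text_image <- function(path, tolerant = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "invermass_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("text image is empty", "invermass_format_error")
  }
  rows <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    abort("ragged rows: all text-image rows must have the same length",
          "invermass_format_error")
  }
  tokens <- unlist(rows, use.names = FALSE)
  if (any(!grepl("^-?[0-9]+$", tokens))) {
    bad <- tokens[!grepl("^-?[0-9]+$", tokens)][1L]
    abort(sprintf("non-integer token in text image: '%s'", bad),
          "invermass_format_error")
  }
  vals <- as.integer(tokens)
  m <- matrix(vals, nrow = length(rows), ncol = widths[1L], byrow = TRUE)
  if (tolerant) {
    if (any(m < 0L)) {
      abort("negative intensities are not admissible in a text image",
            "invermass_format_error")
    }
    binary_mask(m > 0L)
  } else {
    if (!all(m %in% c(0L, 255L))) {
      bad <- m[!(m %in% c(0L, 255L))][1L]
      abort(sprintf("value %d is neither 0 nor 255; pass tolerant = TRUE to map >0 to object", bad),
            "invermass_format_error")
    }
    binary_mask(m)
  }
}

#' Write a binary mask as an ImageJ-style text image
#'
#' Object pixels are written as 255 and background pixels as 0, one image
#' row per line, single-space delimited. The round trip through
#' [read_text_image()] is bit-exact.
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_text_image <- function(mask, path) {
  m <- as_mask_matrix(mask)
  enc <- matrix("0", nrow(m), ncol(m))
  enc[m] <- "255"
  lines <- apply(enc, 1L, paste, collapse = " ")
  tryCatch(writeLines(lines, path),
           error = function(e) abort(sprintf("cannot write '%s': %s",
                                             path, conditionMessage(e)),
                                     "invermass_io_error"))
  invisible(path)
}

# Otsu's criterion on the histogram of observed integer intensities.
# Operating on observed values (not a fixed 0..255 binning) makes the split
# exactly invariant under adding a constant to all intensities.
otsu_cut <- function(px) {
  vals <- sort(unique(as.vector(px)))
  if (length(vals) < 2L) {
    abort("automatic threshold is degenerate: image has a single intensity",
          "invermass_degenerate_threshold_error")
  }
  counts <- tabulate(match(as.vector(px), vals), nbins = length(vals))
  n <- sum(counts)
  w_cum <- cumsum(counts)
  s_cum <- cumsum(counts * vals)
  total <- s_cum[length(s_cum)]
  k <- seq_len(length(vals) - 1L)          # split after value k: object = vals > vals[k]
  w0 <- w_cum[k]; w1 <- n - w0
  mu0 <- s_cum[k] / w0
  mu1 <- (total - s_cum[k]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  best <- k[which.max(between)]            # which.max: first (lowest) split on ties
  (vals[best] + vals[best + 1L]) / 2
}

#' Threshold a grayscale image into a binary mask
#'
#' Pixels with intensity greater than or equal to the cut become object.
#' `method = "auto"` selects the cut with Otsu's between-class variance
#' criterion computed on the observed intensities; a numeric `method` is a
#' fixed level, matching a manually chosen ImageJ threshold.
#'
#' @param image a `raster_image` from [read_raster()] or an integer matrix.
#' @param method `"auto"` (default) or a single numeric level.
#' @return A [binary_mask()].
#' @examples
#' img <- matrix(c(10, 10, 240, 240), 2, 2)
#' threshold(img, 128)
#' @export
threshold <- function(image, method = "auto") {
  px <- unclass(image)
  if (!is.numeric(px) || !is.matrix(px)) {
    abort("image must be a numeric matrix of intensities", "invermass_format_error")
  }
  cut <- if (identical(method, "auto")) {
    otsu_cut(px)
  } else if (is.numeric(method) && length(method) == 1L && is.finite(method)) {
    method
  } else {
    abort("threshold method must be \"auto\" or a single numeric level",
          "invermass_domain_error")
  }
  binary_mask(px >= cut)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components that
# only touch diagonally are merged afterwards with a union-find over labels.
label_components8 <- function(m) {
  lab <- EBImage::bwlabel(m * 1L)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]
  keep <- a > 0L & b > 0L & a != b
  pairs <- cbind(a[keep], b[keep])
  a <- lab[-nr, -1L]; b <- lab[-1L, -nc]
  keep <- a > 0L & b > 0L & a != b
  pairs <- rbind(pairs, cbind(a[keep], b[keep]))
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) union2(pairs[i, 1L], pairs[i, 2L])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  lab
}

#' Keep only the largest connected component of a mask
#'
#' Isolates the specimen after background extraction: retains the single
#' 8-connected object component with the most pixels. Ties are broken in
#' favour of the component whose topmost (then leftmost) pixel comes first
#' in raster order.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()] containing exactly one component.
#' @export
largest_component <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) {
    abort("mask contains no object pixels", "invermass_empty_object_error")
  }
  lab <- label_components8(m)
  ids <- sort(unique(lab[lab > 0L]))
  sizes <- tabulate(lab, nbins = max(ids))[ids]
  cand <- ids[sizes == max(sizes)]
  if (length(cand) > 1L) {
    # first candidate pixel in (row, col) lexicographic order wins
    first_pos <- vapply(cand, function(id) {
      idx <- which(lab == id, arr.ind = TRUE)
      ord <- order(idx[, 1L], idx[, 2L])
      idx[ord[1L], , drop = TRUE]
    }, numeric(2))
    pick <- order(first_pos[1L, ], first_pos[2L, ])[1L]
    cand <- cand[pick]
  }
  binary_mask(lab == cand[1L])
}
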