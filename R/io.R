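#' Write a mesh as Triangle-style .node/.ele files
#'
#' Writes \code{<basename>.node} (node coordinates), \code{<basename>.ele}
#' (triangles) and a sidecar \code{<basename>.electrodes} listing, per
#' electrode, the boundary-edge node pairs it covers.
#'
#' @param mesh An \code{eit_mesh}.
#' @param basename Path prefix (no extension).
#' @return \code{basename}, invisibly.
#' @export
write_mesh <- function(mesh, basename) {
  n <- nrow(mesh$node_coords)
  node <- file(paste0(basename, ".node"), "w")
  writeLines(sprintf("%d 2 0 1", n), node)
  bn <- unique(as.vector(mesh$boundary_edges))
  onb <- integer(n); onb[bn] <- 1L
  writeLines(sprintf("%d %.17g %.17g %d", seq_len(n),
                     mesh$node_coords[, 1L], mesh$node_coords[, 2L], onb), node)
  close(node)
  ele <- file(paste0(basename, ".ele"), "w")
  writeLines(sprintf("%d 3 0", nrow(mesh$triangles)), ele)
  writeLines(sprintf("%d %d %d %d", seq_len(nrow(mesh$triangles)),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), ele)
  close(ele)
  el <- file(paste0(basename, ".electrodes"), "w")
  writeLines(sprintf("%d %.17g", length(mesh$electrodes), mesh$radius), el)
  for (L in seq_along(mesh$electrodes)) {
    ed <- mesh$boundary_edges[mesh$electrodes[[L]], , drop = FALSE]
    writeLines(sprintf("%d %s", L,
                       paste(paste(ed[, 1L], ed[, 2L], sep = ","),
                             collapse = " ")), el)
  }
  close(el)
  invisible(basename)
}

#' Read a mesh written by \code{\link{write_mesh}}
#'
#' @param basename Path prefix used when writing.
#' @return An \code{eit_mesh}.
#' @export
read_mesh <- function(basename) {
  nl <- readLines(paste0(basename, ".node"))
  n <- as.integer(strsplit(trimws(nl[1L]), "\\s+")[[1L]][1L])
  nf <- do.call(rbind, lapply(strsplit(trimws(nl[1L + seq_len(n)]), "\\s+"),
                              as.numeric))
  coords <- nf[, 2:3, drop = FALSE]
  el <- readLines(paste0(basename, ".ele"))
  m <- as.integer(strsplit(trimws(el[1L]), "\\s+")[[1L]][1L])
  tf <- do.call(rbind, lapply(strsplit(trimws(el[1L + seq_len(m)]), "\\s+"),
                              as.integer))
  triangles <- tf[, 2:4, drop = FALSE]
  ll <- readLines(paste0(basename, ".electrodes"))
  hdr <- strsplit(trimws(ll[1L]), "\\s+")[[1L]]
  S <- as.integer(hdr[1L]); radius <- as.numeric(hdr[2L])
  edges_list <- vector("list", S)
  for (i in seq_len(S)) {
    parts <- strsplit(trimws(ll[1L + i]), "\\s+")[[1L]]
    prs <- do.call(rbind, lapply(strsplit(parts[-1L], ","), as.integer))
    edges_list[[as.integer(parts[1L])]] <- prs
  }
  all_edges <- do.call(rbind, edges_list)
  # reconstruct full boundary edge cycle from the boundary flag column
  bnodes <- which(nf[, 4L] == 1)
  ang <- atan2(coords[bnodes, 2L], coords[bnodes, 1L]) %% (2 * pi)
  bnodes <- bnodes[order(ang)]
  boundary_edges <- cbind(bnodes, c(bnodes[-1L], bnodes[1L]))
  storage.mode(boundary_edges) <- "integer"
  key <- paste(boundary_edges[, 1L], boundary_edges[, 2L])
  electrodes <- lapply(edges_list, function(prs)
    match(paste(prs[, 1L], prs[, 2L]), key))
  structure(list(node_coords = coords, triangles = triangles,
                 boundary_edges = boundary_edges, electrodes = electrodes,
                 radius = radius, n_rings = NA_integer_, n_sectors = S),
            class = "eit_mesh")
}

#' Write a measurement frame as CSV
#'
#' Columns: \code{meas_index, drive_a, drive_b, meas_a, meas_b, voltage_V}.
#'
#' @param frame An \code{eit_frame}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_frame <- function(frame, path) {
  df <- data.frame(frame$protocol, voltage_V = frame$voltages)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement frame CSV
#'
#' @param path CSV written by \code{\link{write_frame}}.
#' @return An \code{eit_frame} (protocol rebuilt from the columns).
#' @export
read_frame <- function(path) {
  df <- utils::read.csv(path)
  pr <- df[c("meas_index", "drive_a", "drive_b", "meas_a", "meas_b")]
  attr(pr, "n_electrodes") <- max(pr$drive_a)
  class(pr) <- c("eit_protocol", "data.frame")
  structure(list(voltages = df$voltage_V, protocol = pr,
                 is_reference = FALSE, noise_snr_db = NULL),
            class = "eit_frame")
}

#' Write a sensitivity matrix (text header + raw doubles)
#'
#' A one-line text header (\code{nrow ncol basis reference_conductivity
#' radius}) followed by the column-major matrix entries as little-endian
#' 8-byte doubles.
#'
#' @param A An \code{eit_sensitivity}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sensitivity <- function(A, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("%d %d %s %.17g %.17g\n", nrow(A$entries), ncol(A$entries),
                 A$basis, A$reference_conductivity, A$radius)
  writeBin(charToRaw(hdr), con)
  writeBin(as.vector(A$entries), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a sensitivity matrix written by \code{\link{write_sensitivity}}
#'
#' @param path File path.
#' @return An \code{eit_sensitivity} (without protocol/grid metadata).
#' @export
read_sensitivity <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L || ch == charToRaw("\n")) break
    hdr <- c(hdr, rawToChar(ch))
  }
  f <- strsplit(trimws(paste(hdr, collapse = "")), "\\s+")[[1L]]
  nr <- as.integer(f[1L]); nc <- as.integer(f[2L])
  vals <- readBin(con, "double", nr * nc, size = 8L, endian = "little")
  structure(list(entries = matrix(vals, nr, nc), basis = f[3L],
                 reference_conductivity = as.numeric(f[4L]),
                 protocol = NULL, radius = as.numeric(f[5L]), grid = NULL),
            class = "eit_sensitivity")
}

#' Write an image (pixel vector on a grid) as a CSV matrix
#'
#' @param x Numeric vector over the in-disk pixels, or a full matrix.
#' @param grid An \code{eit_pixel_grid} (needed when \code{x} is masked).
#' @param path Output CSV path.
#' @param fill Value written for out-of-disk pixels.
#' @return \code{path}, invisibly.
#' @export
write_image_csv <- function(x, grid = NULL, path, fill = 0) {
  img <- if (is.matrix(x)) x else pixels_to_image(x, grid, fill = fill)
  utils::write.table(img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an image as an 8-bit grayscale PNG
#'
#' Min-max normalizes over the in-disk mask and writes an 8-bit PNG
#' (requires the \pkg{png} package).
#'
#' @inheritParams write_image_csv
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(x, grid = NULL, path, fill = 0) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG images")
  if (is.matrix(x)) {
    img <- normalize_to_8bit(x)
  } else {
    v <- normalize_to_8bit(x)
    img <- pixels_to_image(v, grid, fill = fill)
  }
  # image() orientation: flip so row 1 is the top scanline
  png::writePNG(t(img[, ncol(img):1]) / 255, path)
  invisible(path)
}

#' Write a reconstruction result as CSV plus a metadata file
#'
#' \code{<basename>.csv} holds \code{pixel_index, value};
#' \code{<basename>_meta.json} holds method, configuration and the
#' iteration histories (requires \pkg{jsonlite}).
#'
#' @param recon An \code{eit_recon}.
#' @param basename Path prefix.
#' @return \code{basename}, invisibly.
#' @export
write_reconstruction <- function(recon, basename) {
  utils::write.csv(data.frame(pixel_index = seq_along(recon$x),
                              value = recon$x),
                   paste0(basename, ".csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(method = recon$method, iterations = recon$iterations,
                 residual_history = recon$residual_history,
                 objective_history = recon$objective_history,
                 config = recon$config[!vapply(recon$config, is.null,
                                               logical(1))])
    jsonlite::write_json(meta, paste0(basename, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(basename)
}
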