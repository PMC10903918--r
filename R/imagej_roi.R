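#' Export spine ROIs as an ImageJ/FIJI ROI archive
#'
#' Writes one ImageJ `.roi` polygon record per ROI per occupied z-plane
#' (the ImageJ ROI format is 2D per record), bundled into a `.zip` archive
#' readable by the ImageJ ROI Manager. Within a plane, each 4-connected pixel
#' fragment of the ROI is outlined by its outer boundary polygon in pixel
#' corner coordinates; the 1-based slice number is stored in the record's
#' position field. All records of one ROI share the name prefix
#' `roi<id>` (entries `roi<id>-z<plane>[-<fragment>].roi`).
#'
#' @param rois a [roi_set].
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
export_imagej_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  entries <- list()
  for (i in seq_along(rois$rois)) {
    roi <- rois$rois[[i]]
    if (nrow(roi$voxels) == 0) stop(sprintf("ROI %d has no voxels", i))
    for (z in sort(unique(roi$voxels[, 1]))) {
      pix <- roi$voxels[roi$voxels[, 1] == z, c(2, 3), drop = FALSE]  # (y, x)
      loops <- outline_pixel_set(pix)
      for (k in seq_along(loops)) {
        nm <- if (length(loops) == 1) {
          sprintf("roi%04d-z%04d.roi", i, z)
        } else {
          sprintf("roi%04d-z%04d-%d.roi", i, z, k)
        }
        entries[[nm]] <- encode_imagej_polygon(loops[[k]], slice = z)
      }
    }
  }
  write_zip_archive(entries, path)
  invisible(path)
}

#' Read an ImageJ ROI archive written by [export_imagej_rois()]
#'
#' Minimal decoder for polygon-type `.roi` records (byte-offset parsing of
#' the published ImageJ ROI format), independent of the encoder's outline
#' construction.
#'
#' @param path `.zip` archive of `.roi` records.
#' @return list of records, each `list(name, slice, x, y)` with polygon
#'   vertices in pixel corner coordinates.
#' @export
read_imagej_rois <- function(path) {
  exdir <- tempfile("ijroi")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  lapply(sort(files), function(f) {
    raw <- readBin(f, "raw", n = file.size(f))
    con <- rawConnection(raw)
    on.exit(close(con))
    magic <- readChar(con, 4, useBytes = TRUE)
    if (magic != "Iout") stop("not an ImageJ ROI record")
    readBin(con, "integer", 1, size = 2, endian = "big")  # version
    type <- readBin(con, "integer", 1, size = 1)
    readBin(con, "integer", 1, size = 1)
    top <- readBin(con, "integer", 1, size = 2, endian = "big")
    left <- readBin(con, "integer", 1, size = 2, endian = "big")
    readBin(con, "integer", 2, size = 2, endian = "big")  # bottom, right
    n <- readBin(con, "integer", 1, size = 2, endian = "big")
    readBin(con, "raw", 38)  # x1..arc fields
    slice <- readBin(con, "integer", 1, size = 4, endian = "big")
    readBin(con, "integer", 1, size = 4, endian = "big")  # header2 offset
    xs <- readBin(con, "integer", n, size = 2, endian = "big") + left
    ys <- readBin(con, "integer", n, size = 2, endian = "big") + top
    list(name = basename(f), type = type, slice = slice, x = xs, y = ys)
  })
}

# polygon record per the ImageJ ROI byte format (big-endian)
encode_imagej_polygon <- function(loop, slice) {
  xs <- loop[, 1]; ys <- loop[, 2]
  left <- min(xs); top <- min(ys)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(228L, con, size = 2, endian = "big")             # version
  writeBin(as.integer(c(0L, 0L)), con, size = 1)            # type=0 polygon
  writeBin(as.integer(c(top, left, max(ys), max(xs))), con,
           size = 2, endian = "big")
  writeBin(length(xs), con, size = 2, endian = "big")
  writeBin(raw(38), con)                                    # unused fields
  writeBin(as.integer(slice), con, size = 4, endian = "big")  # position
  writeBin(0L, con, size = 4, endian = "big")               # no header2
  writeBin(as.integer(xs - left), con, size = 2, endian = "big")
  writeBin(as.integer(ys - top), con, size = 2, endian = "big")
  rawConnectionValue(con)
}

# outer boundary loops of a 2D pixel set, one loop per 4-connected fragment.
# pix: n x 2 matrix of (row, col) 1-based pixel indices. Returns list of
# m x 2 matrices of (x, y) pixel-corner vertices (0-based corners).
outline_pixel_set <- function(pix) {
  stopifnot(nrow(pix) > 0)
  ny <- max(pix[, 1]); nx <- max(pix[, 2])
  m <- matrix(FALSE, ny, nx)
  m[pix] <- TRUE
  lab <- label_components(m, connectivity = 6)[1, , ]  # 4-connectivity in 2D
  lab <- matrix(lab, ny, nx)
  loops <- list()
  for (k in seq_len(max(lab))) {
    cells <- which(lab == k, arr.ind = TRUE)
    edges <- list()
    inset <- function(r, c) r >= 1 && r <= ny && c >= 1 && c <= nx && lab[r, c] == k
    for (e in seq_len(nrow(cells))) {
      r <- cells[e, 1]; c <- cells[e, 2]
      x0 <- c - 1; x1 <- c; y0 <- r - 1; y1 <- r
      if (!inset(r - 1, c)) edges[[length(edges) + 1]] <- c(x0, y0, x1, y0)
      if (!inset(r, c + 1)) edges[[length(edges) + 1]] <- c(x1, y0, x1, y1)
      if (!inset(r + 1, c)) edges[[length(edges) + 1]] <- c(x1, y1, x0, y1)
      if (!inset(r, c - 1)) edges[[length(edges) + 1]] <- c(x0, y1, x0, y0)
    }
    em <- do.call(rbind, edges)
    # stitch directed edges into loops; keep the loop with the largest
    # enclosed area (outer boundary; holes are dropped)
    from_key <- paste(em[, 1], em[, 2])
    used <- rep(FALSE, nrow(em))
    best <- NULL; best_area <- -Inf
    for (s in seq_len(nrow(em))) {
      if (used[s]) next
      verts <- em[s, 1:2, drop = FALSE]
      cur <- s
      repeat {
        used[cur] <- TRUE
        nxt_key <- paste(em[cur, 3], em[cur, 4])
        verts <- rbind(verts, em[cur, 3:4])
        cand <- which(!used & from_key == nxt_key)
        if (!length(cand)) break
        cur <- cand[1]
      }
      verts <- verts[-nrow(verts), , drop = FALSE]  # closed: drop repeat
      a <- polygon_area(verts)
      if (abs(a) > best_area) { best_area <- abs(a); best <- verts }
    }
    loops[[k]] <- simplify_collinear(best)
  }
  loops
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

simplify_collinear <- function(v) {
  n <- nrow(v)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- v[if (i == 1) n else i - 1, ]
    q <- v[i, ]
    r <- v[if (i == n) 1 else i + 1, ]
    keep[i] <- (q[1] - p[1]) * (r[2] - q[2]) != (q[2] - p[2]) * (r[1] - q[1])
  }
  v[keep, , drop = FALSE]
}

## --- minimal stored-entry ZIP container ------------------------------------

crc32_tab <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L) {
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
      } else bitwShiftR(cc, 1L)
    }
    tab[i + 1] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes)) {
    cc <- bitwXor(bitwShiftR(cc, 8L), crc32_tab[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  }
  bitwXor(cc, -1L)
}

# entries: named list of raw vectors; writes an uncompressed (stored) zip
write_zip_archive <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(entries))
  pos <- 0L
  names_raw <- lapply(names(entries), charToRaw)
  crcs <- vapply(entries, crc32, integer(1))
  for (i in seq_along(entries)) {
    offsets[i] <- pos
    data <- entries[[i]]
    nm <- names_raw[[i]]
    w32(67324752L)              # local file header PK\3\4
    w16(20L); w16(0L); w16(0L)  # version, flags, method=stored
    w16(0L); w16(33L)           # mod time/date (fixed)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(length(nm)); w16(0L)
    writeBin(nm, con); writeBin(data, con)
    pos <- pos + 30L + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    nm <- names_raw[[i]]
    w32(33639248L)              # central directory PK\1\2
    w16(20L); w16(20L); w16(0L); w16(0L)
    w16(0L); w16(33L)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(length(nm)); w16(0L); w16(0L)
    w16(0L); w16(0L); w32(0L)
    w32(offsets[i])
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  w32(101010256L)               # end of central directory PK\5\6
  w16(0L); w16(0L)
  w16(length(entries)); w16(length(entries))
  w32(pos - cd_start); w32(cd_start)
  w16(0L)
  invisible(path)
}
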