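#' Read and write MRC2014 files
#'
#' Minimal MRC2014 support: mode-2 (32-bit float) image stacks (`.mrcs`) and
#' single volumes (`.mrc`), little-endian, no extended header on write;
#' extended headers are skipped on read. Covers the interchange needs of
#' projection stacks and user-supplied density volumes.
#'
#' @param path file path.
#' @return `read_mrc` returns a `projection_set` for stacks (`nz > 1` or
#'   `ispg == 0`) or a `synthetic_volume`-like list for volumes (`ispg == 1`).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  cella <- {seek(con, 40); readBin(con, "numeric", 3, size = 4,
                                   endian = "little")}
  seek(con, 88); ispg <- readBin(con, "integer", 1, size = 4,
                                 endian = "little")
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  nvox <- nx * ny * nz
  dat <- switch(as.character(mode),
    "0" = readBin(con, "integer", nvox, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", nvox, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  px <- if (nx > 0 && cella[1] > 0) cella[1] / nx else 1
  if (ispg == 1 && nx == ny && ny == nz) {
    arr <- array(as.numeric(dat), dim = c(nx, ny, nz))
    structure(list(grid = arr, shape_id = "mrc", seed = NA_integer_),
              class = "synthetic_volume")
  } else {
    # stack: sections are the slowest axis; store images as [i, row, col]
    arr <- array(as.numeric(dat), dim = c(nx, ny, nz))
    imgs <- array(0, dim = c(nz, ny, nx))
    for (i in seq_len(nz)) imgs[i, , ] <- t(arr[, , i])
    projection_set(imgs, pixel_size = px, source = path)
  }
}

#' @rdname read_mrc
#' @param x a `projection_set` (written as a `.mrcs` stack) or a 3D array /
#'   `synthetic_volume` (written as a volume).
#' @param pixel_size physical pixel size stored in the cell dimensions.
#' @export
write_mrc <- function(x, path, pixel_size = NULL) {
  is_vol <- inherits(x, "synthetic_volume") ||
    (is.array(x) && length(dim(x)) == 3 && !inherits(x, "projection_set"))
  if (inherits(x, "projection_set")) {
    d <- dim(x$images); nz <- d[1]; ny <- d[2]; nx <- d[3]
    px <- pixel_size %||% x$pixel_size
    dat <- numeric(nx * ny * nz)
    for (i in seq_len(nz))
      dat[((i - 1) * nx * ny + 1):(i * nx * ny)] <- as.vector(t(x$images[i, , ]))
    ispg <- 0L
  } else if (is_vol) {
    grid <- if (inherits(x, "synthetic_volume")) x$grid else x
    d <- dim(grid); nx <- d[1]; ny <- d[2]; nz <- d[3]
    px <- pixel_size %||% 1
    dat <- as.vector(grid)
    ispg <- 1L
  } else stop("cannot write object of class ", class(x)[1], " as MRC")

  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz))       # words 1-10
  wf(c(nx * px, ny * px, nz * px, 90, 90, 90))        # cella, cellb
  wi(c(1L, 2L, 3L))                                   # mapc, mapr, maps
  wf(c(min(dat), max(dat), mean(dat)))                # dmin, dmax, dmean
  wi(c(ispg, 0L))                                     # ispg, nsymbt
  wi(rep(0L, 25))                                     # extra (incl exttyp)
  wf(c(0, 0, 0))                                      # origin
  writeChar("MAP ", con, 4, eos = NULL)               # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # LE machine stamp
  wf(sd(dat))                                         # rms
  wi(0L)                                              # nlabl
  writeBin(raw(800), con)                             # labels
  wf(dat)
  invisible(path)
}

#' Import / export a projection set as a directory of PNG images
#'
#' Images are min-max scaled to `[0,1]` on export (PNG is 8/16-bit); on
#' import, RGB files are averaged to grayscale. Files are named
#' `img_%05d.png` in index order.
#'
#' @param ps a `projection_set`.
#' @param dir directory path.
#' @export
write_png_dir <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ps)
  for (i in seq_len(n)) {
    im <- ps$images[i, , ]
    rng <- range(im)
    im <- if (diff(rng) > 0) (im - rng[1]) / diff(rng) else im * 0
    png::writePNG(im, file.path(dir, sprintf("img_%05d.png", i - 1)))
  }
  if (!is.null(ps$labels))
    write_labels_tsv(ps$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' @rdname write_png_dir
#' @export
read_png_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG files in ", dir)
  imgs <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    a
  })
  lab_file <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(lab_file)) read_labels_tsv(lab_file) else NULL
  projection_set(imgs, labels = labels, source = dir)
}

#' Read / write ground-truth labels as a two-column TSV
#'
#' Format: `index<TAB>complex_id`, 0-based indices, no header.
#'
#' @param labels character vector of per-image class labels.
#' @param path file path.
#' @export
write_labels_tsv <- function(labels, path) {
  write.table(data.frame(index = seq_along(labels) - 1, complex = labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("index", "complex"),
                   colClasses = c("integer", "character"))
  df <- df[order(df$index), ]
  if (!identical(df$index, seq_len(nrow(df)) - 1L))
    stop("label file indices must be 0..n-1 with no gaps")
  df$complex
}
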