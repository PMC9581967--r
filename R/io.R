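# MRC 2014 (mode 2) and STAR I/O. Little-endian throughout; volumes are
# stored x-fastest which matches R's column-major array layout directly.

mrc_error <- function(msg) {
  stop(errorCondition(msg, class = c("mrc_parse_error", "error", "condition")))
}

star_error <- function(msg) {
  stop(errorCondition(msg, class = c("star_parse_error", "error", "condition")))
}

#' Read and write MRC 2014 maps
#'
#' Mode 2 (32-bit float) maps and images, with the pixel size carried in the
#' header cell dimensions. `read_mrc` returns a [density_map()] for cubic
#' volumes and an [image2d()] for single-section files. Files with a mode
#' other than 2 or a malformed magic word raise a typed `mrc_parse_error`.
#'
#' @param path file path.
#' @param x a [density_map()] or [image2d()].
#' @return `read_mrc`: a `density_map` or `image2d`; `write_mrc`:
#'   (invisibly) `path`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 52 * 4)
  magic <- readBin(con, "raw", 4)
  if (!identical(magic[1:3], charToRaw("MAP")))
    mrc_error("MRC header field `map` is not 'MAP ': not an MRC 2014 file")
  if (mode != 2L)
    mrc_error(sprintf("MRC header field `mode` is %d; only mode 2 (float32) is supported", mode))
  if (nx <= 0 || ny <= 0 || nz < 1)
    mrc_error("MRC header fields `nx/ny/nz` are not positive")
  seek(con, 1024)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  if (length(vals) != nx * ny * nz)
    mrc_error("MRC data section truncated")
  apix <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  if (nz == 1L) return(image2d(matrix(vals, nx, ny), apix))
  density_map(array(vals, dim = c(nx, ny, nz)), apix)
}

#' @rdname read_mrc
#' @export
write_mrc <- function(x, path) {
  v <- x$values
  d <- dim(v)
  if (length(d) == 2L) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(i) writeBin(as.integer(i), con, size = 4, endian = "little")
  wf <- function(f) writeBin(as.numeric(f), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2 = float32
  wi(c(0, 0, 0))                          # nxstart
  wi(d)                                   # mx my mz
  wf(d * x$apix)                          # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1, 2, 3))                          # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))          # dmin dmax dmean
  wi(c(0, 0))                             # ispg, nsymbt
  wi(rep(0, 2))                           # extra 25-26
  writeChar("MRC ", con, nchars = 4, eos = NULL) # exttyp
  wi(20140)                               # nversion
  wi(rep(0, 21))                          # extra 29-49
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # machst little-endian
  wf(stats::sd(v))                        # rms
  wi(1)                                   # nlabl
  lab <- sprintf("%-80s", "helixpsa")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 720, eos = NULL)
  writeBin(as.numeric(as.vector(v)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write STAR tables
#'
#' Minimal STAR dialect used for particle metadata: named `data_` blocks,
#' each a `loop_` with `_name #i` column headers and whitespace-separated
#' rows. Numeric-looking columns are converted to numeric. `read_star`
#' returns a named list of data.frames; `write_star` takes one. Leading
#' underscores are stripped from column names on read and restored on write.
#'
#' @param path file path.
#' @param tables named list of data.frames.
#' @param required for `read_star`: optional character vector of column
#'   names that must be present in the (first) table; a missing column
#'   raises a typed `star_parse_error` naming the field.
#' @return `read_star`: named list of data.frames.
#' @export
read_star <- function(path, required = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "data_")) {
      star_error(sprintf("unexpected STAR content before data_ block: '%s'", lines[i]))
    }
    block <- substring(lines[i], 6L)
    i <- i + 1L
    if (i > length(lines) || lines[i] != "loop_")
      star_error(sprintf("STAR block '%s': expected loop_", block))
    i <- i + 1L
    cols <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      nm <- sub("\\s+#\\d+$", "", lines[i])
      cols <- c(cols, sub("^_", "", nm))
      i <- i + 1L
    }
    if (length(cols) == 0L)
      star_error(sprintf("STAR block '%s': no column definitions", block))
    rows <- list()
    while (i <= length(lines) && !startsWith(lines[i], "data_")) {
      fields <- strsplit(lines[i], "\\s+")[[1]]
      if (length(fields) != length(cols))
        star_error(sprintf("STAR block '%s': row has %d fields, expected %d",
                           block, length(fields), length(cols)))
      rows[[length(rows) + 1L]] <- fields
      i <- i + 1L
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- cols
    for (cc in cols) {
      conv <- suppressWarnings(as.numeric(df[[cc]]))
      if (!anyNA(conv)) df[[cc]] <- conv
    }
    out[[block]] <- df
  }
  if (!is.null(required)) {
    have <- names(out[[1]])
    miss <- setdiff(required, have)
    if (length(miss))
      star_error(sprintf("STAR table missing required column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  out
}

#' @rdname read_star
#' @export
write_star <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(particles = tables)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(tables)) {
    df <- tables[[nm]]
    writeLines(c(paste0("data_", nm), "", "loop_"), con)
    writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
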