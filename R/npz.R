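# Minimal NPY v1.0 reader/writer.  Numpy arrays are C-order (last axis
# fastest); R arrays are column-major, so axes are reversed on the way in
# and out.  Only the dtypes that occur in image-stream archives are
# supported: |u1, <i1, <i2, <i4, <i8, <f4, <f8.

npy_header <- function(descr, shape) {
  shp <- if (length(shape) == 1L) sprintf("(%d,)", shape) else
    sprintf("(%s)", paste(shape, collapse = ", "))
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                  descr, shp)
  # pad with spaces so that 10 + nchar(header) is a multiple of 64
  total <- 10L + nchar(dict) + 1L
  pad <- (64L - total %% 64L) %% 64L
  paste0(dict, strrep(" ", pad), "\n")
}

write_npy <- function(x, path, dtype = c("f8", "u1", "i4")) {
  dtype <- match.arg(dtype)
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  # reverse axes so column-major flattening emits C order
  xt <- if (length(d) > 1L) aperm(x, rev(seq_along(d))) else x
  v <- as.vector(xt)
  descr <- switch(dtype, f8 = "<f8", u1 = "|u1", i4 = "<i4")
  hdr <- npy_header(descr, d)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2, endian = "little")
  writeChar(hdr, con, eos = NULL)
  switch(dtype,
    f8 = writeBin(as.double(v), con, size = 8, endian = "little"),
    u1 = writeBin(as.raw(as.integer(round(v))), con),
    i4 = writeBin(as.integer(v), con, size = 4, endian = "little"))
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", n = 2L)
  hlen <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
  hdr <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shp_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shp_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape)) prod(shape) else 1L
  v <- switch(descr,
    "|u1" = as.numeric(readBin(con, "integer", n = n, size = 1,
                               signed = FALSE)),
    "|i1" = , "<i1" = as.numeric(readBin(con, "integer", n = n, size = 1)),
    "<i2" = as.numeric(readBin(con, "integer", n = n, size = 2,
                               endian = "little")),
    "<i4" = as.numeric(readBin(con, "integer", n = n, size = 4,
                               endian = "little")),
    "<i8" = read_i8(con, n),
    "<f4" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "<f8" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NPY dtype: ", descr))
  if (length(v) != n) stop("truncated NPY payload in ", path)
  if (length(shape) <= 1L) return(v)
  if (fortran) array(v, dim = shape)
  else aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

# little-endian int64 via double arithmetic (labels are small integers)
read_i8 <- function(con, n) {
  raw <- readBin(con, "raw", n = n * 8L)
  m <- matrix(as.numeric(raw), nrow = 8L)
  v <- colSums(m * 2^(8 * (0:7)))
  v[v >= 2^63] <- v[v >= 2^63] - 2^64
  v
}

write_npz <- function(arrays, path) {
  stopifnot(is.list(arrays), !is.null(names(arrays)))
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- character(0)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    f <- file.path(tmp, paste0(nm, ".npy"))
    dtype <- attr(a, "npy_dtype")
    if (is.null(dtype)) dtype <- "f8"
    write_npy(a, f, dtype = dtype)
    files <- c(files, f)
  }
  zip::zipr(path, files, compression_level = 6)
  invisible(path)
}

read_npz <- function(path) {
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  zip::unzip(path, exdir = tmp)
  files <- list.files(tmp, pattern = "\\.npy$", full.names = TRUE)
  out <- lapply(files, read_npy)
  names(out) <- sub("\\.npy$", "", basename(files))
  out
}
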