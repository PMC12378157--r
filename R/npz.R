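# NPY (v1.0) and NPZ (stored-entry zip) input/output.
#
# The MedMNIST distribution dialect is a zip archive of NumPy arrays with the
# six keys train/val/test_images and train/val/test_labels. Images are
# unsigned 8-bit, n x H x W (grayscale) or n x H x W x 3 (RGB); labels are
# integer n x 1 (single-label tasks) or 0/1 n x m (multi-label). Arrays are
# read and written in C (row-major) order.

NPZ_KEYS <- c("train_images", "train_labels", "val_images", "val_labels",
              "test_images", "test_labels")

# ---- little-endian byte helpers ---------------------------------------------

le_bytes <- function(x, width) {
  x <- as.numeric(x)
  out <- raw(width)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

le_value <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

# CRC-32 of a raw vector, taken from the trailer of a gzip stream produced by
# base memCompress (gzip trailer = CRC32 LE + ISIZE LE).
crc32_raw <- function(data) {
  z <- memCompress(data, type = "gzip")
  n <- length(z)
  le_value(z[(n - 7L):(n - 4L)])
}

# ---- NPY --------------------------------------------------------------------

# Serialize an R array to NPY v1.0 bytes. dtype: "|u1", "<i4" or "<f8".
npy_bytes <- function(arr, dtype = c("|u1", "<i4", "<f8")) {
  dtype <- match.arg(dtype)
  dm <- dim(arr) %||% length(arr)
  shape <- paste0("(", paste(dm, collapse = ", "),
                  if (length(dm) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    dtype, shape)
  # pad so that 10 + length(header) + 1 (newline) is a multiple of 64
  pad <- (64L - (10L + nchar(header) + 1L) %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  # C order: last index fastest
  v <- if (length(dm) > 1L) as.vector(aperm(arr, rev(seq_along(dm)))) else as.vector(arr)
  if (dtype == "<f8") {
    payload <- writeBin(as.numeric(v), raw(), size = 8L, endian = "little")
    return(c(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)),
             le_bytes(nchar(header), 2L), charToRaw(header), payload))
  }
  v <- as.integer(v)
  if (dtype == "|u1") {
    if (anyNA(v) || any(v < 0L | v > 255L)) {
      kd_stop("unsigned 8-bit payload requires integer values in [0, 255]",
              class = "kd_npz_error")
    }
    payload <- writeBin(v, raw(), size = 1L)
  } else {
    payload <- writeBin(v, raw(), size = 4L, endian = "little")
  }
  c(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), # \x93NUMPY v1.0
    le_bytes(nchar(header), 2L),
    charToRaw(header),
    payload)
}

# Parse NPY bytes into an R array (integer or double storage).
npy_parse <- function(bytes, what = "array") {
  if (length(bytes) < 10L ||
      !identical(bytes[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    kd_stop(sprintf("%s: not an NPY payload", what), class = "kd_npz_error")
  }
  major <- as.integer(bytes[7])
  hlen_width <- if (major >= 2L) 4L else 2L
  hlen <- le_value(bytes[9:(8 + hlen_width)])
  hdr_start <- 9L + hlen_width
  header <- rawToChar(bytes[hdr_start:(hdr_start + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_txt <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  if (length(shape) == 0L) shape <- integer(0)
  payload <- bytes[(hdr_start + hlen):length(bytes)]
  n <- if (length(shape)) prod(shape) else 1L
  v <- switch(descr,
    "|u1" = , "<u1" = readBin(payload, "integer", n = n, size = 1L, signed = FALSE),
    "|i1" = readBin(payload, "integer", n = n, size = 1L, signed = TRUE),
    "<i2" = readBin(payload, "integer", n = n, size = 2L, endian = "little"),
    "<i4" = readBin(payload, "integer", n = n, size = 4L, endian = "little"),
    "<i8" = {
      lo <- readBin(payload, "integer", n = 2L * n, size = 4L, endian = "little")
      lo32 <- as.numeric(lo[seq(1L, 2L * n, by = 2L)])
      hi32 <- as.numeric(lo[seq(2L, 2L * n, by = 2L)])
      lo32[lo32 < 0] <- lo32[lo32 < 0] + 2^32
      out <- hi32 * 2^32 + lo32
      if (any(abs(out) > .Machine$integer.max)) out else as.integer(out)
    },
    "<f4" = readBin(payload, "double", n = n, size = 4L, endian = "little"),
    "<f8" = readBin(payload, "double", n = n, size = 8L, endian = "little"),
    kd_stop(sprintf("%s: unsupported NPY dtype '%s'", what, descr),
            class = "kd_npz_error")
  )
  attr(v, "descr") <- descr
  if (length(shape) <= 1L) return(v)
  a <- if (fortran) array(v, dim = shape) else
    aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
  attr(a, "descr") <- descr
  a
}

# ---- stored-entry zip writer ------------------------------------------------

# Write a zip archive whose entries are uncompressed (method 0). Deterministic:
# fixed timestamps, entry order as given.
zip_write_stored <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  nm <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    crcs[i] <- crc32_raw(data)
    offsets[i] <- pos
    name_raw <- charToRaw(nm[i])
    local_hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), # PK\3\4
      le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2), # version, flags, method=0
      le_bytes(0, 2), le_bytes(0x21, 2),               # time, date (1981-01-01)
      le_bytes(crcs[i], 4),
      le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(name_raw), 2), le_bytes(0, 2)
    )
    writeBin(local_hdr, con)
    writeBin(name_raw, con)
    writeBin(data, con)
    pos <- pos + length(local_hdr) + length(name_raw) + length(data)
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(entries)) {
    name_raw <- charToRaw(nm[i])
    n <- length(entries[[i]])
    cd <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), # PK\1\2
      le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0x21, 2),
      le_bytes(crcs[i], 4), le_bytes(n, 4), le_bytes(n, 4),
      le_bytes(length(name_raw), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
      le_bytes(offsets[i], 4)
    )
    writeBin(cd, con)
    writeBin(name_raw, con)
    cd_len <- cd_len + length(cd) + length(name_raw)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(entries), 2), le_bytes(length(entries), 2),
    le_bytes(cd_len, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

# ---- NPZ dialect ------------------------------------------------------------

#' Write a dataset bundle to a MedMNIST-dialect NPZ archive
#'
#' The archive holds exactly the six arrays `train_images`, `train_labels`,
#' `val_images`, `val_labels`, `test_images`, `test_labels`. Images are
#' written as unsigned 8-bit, labels as little-endian 32-bit integers; a
#' write → [read_npz()] round trip is bit-exact.
#'
#' @param bundle a `kd_bundle` as returned by [generate_dataset()] or
#'   [read_npz()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_npz()], [load_medmnist_npz()]
#' @export
write_npz <- function(bundle, path) {
  stopifnot(inherits(bundle, "kd_bundle"))
  entries <- list()
  for (split in c("train", "val", "test")) {
    img <- bundle[[split]]$images
    lab <- bundle[[split]]$labels
    entries[[paste0(split, "_images.npy")]] <- npy_bytes(img, "|u1")
    entries[[paste0(split, "_labels.npy")]] <- npy_bytes(lab, "<i4")
  }
  zip_write_stored(path, entries)
  invisible(path)
}

#' Read a MedMNIST-dialect NPZ archive
#'
#' Validates the six-key dialect, checks that image payloads are unsigned
#' 8-bit and that image and label counts agree per split, and infers the task
#' specification from the label layout (see [infer_task_spec()]).
#'
#' @param path NPZ file path.
#' @param task_override optional task kind override; the only accepted value
#'   is `"ordinal"`, because ordered labels are indistinguishable from
#'   multi-class labels by shape.
#' @return a `kd_bundle`: per-split `images` (integer array, `n x H x W` or
#'   `n x H x W x 3`) and `labels` (integer matrix), plus the inferred
#'   `task` ([kd_task()]).
#' @export
read_npz <- function(path, task_override = NULL) {
  if (!file.exists(path)) {
    kd_stop(sprintf("no such file: %s", path), class = "kd_npz_error")
  }
  td <- tempfile("npz_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  files <- utils::unzip(path, exdir = td)
  keys <- sub("\\.npy$", "", basename(files))
  missing <- setdiff(NPZ_KEYS, keys)
  if (length(missing)) {
    kd_stop(sprintf("archive is missing required key(s): %s",
                    paste(missing, collapse = ", ")),
            class = "kd_npz_error")
  }
  extra <- setdiff(keys, NPZ_KEYS)
  if (length(extra)) {
    warning(sprintf("archive has extra key(s), ignored: %s",
                    paste(extra, collapse = ", ")))
  }
  arr <- list()
  for (k in NPZ_KEYS) {
    f <- files[match(paste0(k, ".npy"), basename(files))]
    arr[[k]] <- npy_parse(readBin(f, "raw", n = file.size(f)), what = k)
  }
  for (k in grep("_images$", NPZ_KEYS, value = TRUE)) {
    d <- attr(arr[[k]], "descr")
    if (!d %in% c("|u1", "<u1")) {
      kd_stop(sprintf("%s: image payload must be unsigned 8-bit, got '%s'", k, d),
              class = "kd_npz_error")
    }
  }
  splits <- list()
  for (split in c("train", "val", "test")) {
    img <- arr[[paste0(split, "_images")]]
    lab <- arr[[paste0(split, "_labels")]]
    if (is.null(dim(lab))) lab <- matrix(lab, ncol = 1L)
    if (dim(img)[1] != nrow(lab)) {
      kd_stop(sprintf(
        "%s split: %d images but %d label rows", split, dim(img)[1], nrow(lab)),
        class = "kd_npz_error")
    }
    attr(img, "descr") <- NULL
    attr(lab, "descr") <- NULL
    splits[[split]] <- list(images = img, labels = lab)
  }
  task <- infer_task_spec(splits$train$labels, override = task_override)
  new_bundle(splits$train, splits$val, splits$test, task, source = path)
}

new_bundle <- function(train, val, test, task, source = "synthetic", spec = NULL) {
  structure(
    list(train = train, val = val, test = test, task = task,
         source = source, spec = spec),
    class = "kd_bundle")
}

#' @export
print.kd_bundle <- function(x, ...) {
  dm <- dim(x$train$images)
  cat("<kd_bundle> ", x$task$kind, " task, m = ", x$task$m, "\n", sep = "")
  cat(sprintf("  splits: train %d / val %d / test %d, image %s\n",
              dim(x$train$images)[1], dim(x$val$images)[1],
              dim(x$test$images)[1],
              paste(dm[-1], collapse = "x")))
  cat("  source:", x$source, "\n")
  invisible(x)
}
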