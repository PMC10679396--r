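# Minimal DICOM codec: explicit VR little endian only, which is also the
# only transfer syntax the writers emit. Datasets are named lists keyed by
# "GGGG,EEEE" (uppercase hex); each element is list(vr=, value=). SQ values
# are lists of nested datasets; OB/OW values are raw vectors; IS/DS are kept
# as backslash-joined strings.

.DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")

.tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

.tag_parts <- function(key) {
  strtoi(strsplit(key, ",", fixed = TRUE)[[1]], 16L)
}

.pack_uint16 <- function(x) {
  x <- as.integer(round(x))
  stopifnot(all(x >= 0L), all(x <= 65535L))
  out <- raw(2L * length(x))
  out[c(TRUE, FALSE)] <- as.raw(bitwAnd(x, 255L))
  out[c(FALSE, TRUE)] <- as.raw(bitwShiftR(x, 8L))
  out
}

.pack_uint32 <- function(x) {
  x <- round(as.numeric(x))
  stopifnot(all(x >= 0), all(x < 2^32))
  out <- raw(4L * length(x))
  out[seq(1L, length(out), 4L)] <- as.raw(x %% 256)
  out[seq(2L, length(out), 4L)] <- as.raw((x %/% 256) %% 256)
  out[seq(3L, length(out), 4L)] <- as.raw((x %/% 65536) %% 256)
  out[seq(4L, length(out), 4L)] <- as.raw((x %/% 16777216) %% 256)
  out
}

.unpack_uint16 <- function(r) {
  as.integer(r[c(TRUE, FALSE)]) + 256L * as.integer(r[c(FALSE, TRUE)])
}

.unpack_uint32 <- function(r) {
  as.numeric(r[seq(1L, length(r), 4L)]) +
    256 * as.numeric(r[seq(2L, length(r), 4L)]) +
    65536 * as.numeric(r[seq(3L, length(r), 4L)]) +
    16777216 * as.numeric(r[seq(4L, length(r), 4L)])
}

.dcm_string_value <- function(x, pad = as.raw(0x20)) {
  b <- charToRaw(paste(x, collapse = "\\"))
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

# format numbers for DS without exponent surprises and <= 16 chars
.ds_format <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, format = "g", digits = 10)
    if (nchar(s) > 16) s <- formatC(v, format = "g", digits = 6)
    s
  }, character(1))
}

.encode_value <- function(vr, value) {
  switch(vr,
    UI = .dcm_string_value(value, pad = as.raw(0)),
    SH = , CS = , LO = , PN = , DA = , TM = , ST = , LT = , AE =
      .dcm_string_value(value),
    IS = .dcm_string_value(format(as.integer(value), trim = TRUE, scientific = FALSE)),
    DS = .dcm_string_value(if (is.character(value)) value else .ds_format(value)),
    US = .pack_uint16(value),
    UL = .pack_uint32(value),
    OB = , OW = as.raw(value),
    stop(sprintf("unsupported VR for encoding: %s", vr))
  )
}

.encode_element <- function(key, el) {
  parts <- .tag_parts(key)
  header <- c(.pack_uint16(parts[1]), .pack_uint16(parts[2]))
  vr <- el$vr
  if (vr == "SQ") {
    body <- do.call(c, c(list(raw(0)), lapply(el$value, function(item) {
      content <- .encode_dataset(item)
      c(.pack_uint16(0xFFFE), .pack_uint16(0xE000),
        .pack_uint32(length(content)), content)
    })))
    return(c(header, charToRaw("SQ"), raw(2), .pack_uint32(length(body)), body))
  }
  body <- .encode_value(vr, el$value)
  if (vr %in% .DCM_LONG_VRS) {
    c(header, charToRaw(vr), raw(2), .pack_uint32(length(body)), body)
  } else {
    stopifnot(length(body) <= 65535L)
    c(header, charToRaw(vr), .pack_uint16(length(body)), body)
  }
}

.encode_dataset <- function(ds) {
  keys <- names(ds)
  ord <- order(vapply(keys, function(k) {
    p <- .tag_parts(k); p[1] * 2^16 + p[2]
  }, numeric(1)))
  do.call(c, c(list(raw(0)), lapply(keys[ord], function(k) .encode_element(k, ds[[k]]))))
}

.gasdose_uid_env <- new.env(parent = emptyenv())

# Unique-enough UIDs under the generic 2.25 root; uniqueness matters only
# within a session's fixtures, not globally.
dcm_new_uid <- function() {
  if (is.null(.gasdose_uid_env$counter)) {
    .gasdose_uid_env$counter <- 0L
    .gasdose_uid_env$stem <- sprintf("%d%05d", as.integer(Sys.time()) %% 100000000L,
                                     Sys.getpid() %% 100000L)
  }
  .gasdose_uid_env$counter <- .gasdose_uid_env$counter + 1L
  sprintf("2.25.%s%06d", .gasdose_uid_env$stem, .gasdose_uid_env$counter)
}

# Write a complete Part-10 file: preamble, DICM, file meta group, dataset.
dcm_write_file <- function(path, dataset, sop_class_uid, sop_instance_uid) {
  meta <- list()
  meta[[.tag_key(0x0002, 0x0001)]] <- list(vr = "OB", value = as.raw(c(0, 1)))
  meta[[.tag_key(0x0002, 0x0002)]] <- list(vr = "UI", value = sop_class_uid)
  meta[[.tag_key(0x0002, 0x0003)]] <- list(vr = "UI", value = sop_instance_uid)
  meta[[.tag_key(0x0002, 0x0010)]] <- list(vr = "UI", value = .DCM_EXPLICIT_LE)
  meta[[.tag_key(0x0002, 0x0012)]] <- list(vr = "UI", value = "2.25.424242")
  meta_raw <- .encode_dataset(meta)
  group_len <- .encode_element(.tag_key(0x0002, 0x0000),
                               list(vr = "UL", value = length(meta_raw)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_raw, .encode_dataset(dataset)), con)
  invisible(path)
}

.decode_value <- function(vr, body) {
  switch(vr,
    UI = , SH = , CS = , LO = , PN = , DA = , TM = , ST = , LT = , AE = ,
    IS = , DS = {
      s <- rawToChar(body[body != as.raw(0)])
      sub("[ ]+$", "", s)
    },
    US = .unpack_uint16(body),
    UL = .unpack_uint32(body),
    FL = readBin(body, "double", n = length(body) / 4, size = 4, endian = "little"),
    FD = readBin(body, "double", n = length(body) / 8, size = 8, endian = "little"),
    body  # OB/OW/UN and anything else: keep raw
  )
}

# Parse elements of `r` from `pos` (1-based) up to `end` inclusive.
# Returns list(dataset=, pos=). Stops at an item-delimitation tag when
# `stop_at_item_delim` (used for undefined-length items).
.parse_dataset <- function(r, pos, end, stop_at_item_delim = FALSE) {
  ds <- list()
  while (pos <= end) {
    group <- .unpack_uint16(r[pos:(pos + 1L)])
    element <- .unpack_uint16(r[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (group == 0xFFFE) {
      len <- .unpack_uint32(r[pos:(pos + 3L)])
      pos <- pos + 4L
      if (element == 0xE00D && stop_at_item_delim)
        return(list(dataset = ds, pos = pos))
      stop("unexpected item/sequence delimiter outside a sequence")
    }
    vr <- rawToChar(r[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% .DCM_LONG_VRS) {
      pos <- pos + 2L  # reserved
      len <- .unpack_uint32(r[pos:(pos + 3L)])
      pos <- pos + 4L
    } else {
      len <- .unpack_uint16(r[pos:(pos + 1L)])
      pos <- pos + 2L
    }
    key <- .tag_key(group, element)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {  # undefined length
        repeat {
          ig <- .unpack_uint16(r[pos:(pos + 1L)])
          ie <- .unpack_uint16(r[(pos + 2L):(pos + 3L)])
          ilen <- .unpack_uint32(r[(pos + 4L):(pos + 7L)])
          pos <- pos + 8L
          if (ig != 0xFFFE) stop("malformed sequence")
          if (ie == 0xE0DD) break
          if (ilen == 4294967295) {
            res <- .parse_dataset(r, pos, length(r), stop_at_item_delim = TRUE)
          } else {
            res <- .parse_dataset(r, pos, pos + ilen - 1L)
          }
          items[[length(items) + 1L]] <- res$dataset
          pos <- res$pos
        }
      } else {
        sq_end <- pos + len - 1L
        while (pos <= sq_end) {
          ig <- .unpack_uint16(r[pos:(pos + 1L)])
          ie <- .unpack_uint16(r[(pos + 2L):(pos + 3L)])
          ilen <- .unpack_uint32(r[(pos + 4L):(pos + 7L)])
          pos <- pos + 8L
          if (ig != 0xFFFE || ie != 0xE000) stop("malformed sequence item")
          if (ilen == 4294967295) {
            res <- .parse_dataset(r, pos, length(r), stop_at_item_delim = TRUE)
          } else {
            res <- .parse_dataset(r, pos, pos + ilen - 1L)
          }
          items[[length(items) + 1L]] <- res$dataset
          pos <- res$pos
        }
      }
      ds[[key]] <- list(vr = "SQ", value = items)
    } else {
      body <- if (len > 0) r[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      ds[[key]] <- list(vr = vr, value = .decode_value(vr, body))
    }
  }
  list(dataset = ds, pos = pos)
}

# Read a Part-10 DICOM file; explicit VR little endian only.
dcm_read_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("not a DICOM part-10 file: %s", path))
  pos <- 133L
  # file meta group: always explicit LE; first element is the group length
  res <- .parse_dataset(r, pos, pos + 11L)  # just the (0002,0000) UL element
  meta_len <- res$dataset[[.tag_key(0x0002, 0x0000)]]$value
  meta <- .parse_dataset(r, res$pos, res$pos + meta_len - 1L)
  ts <- meta$dataset[[.tag_key(0x0002, 0x0010)]]$value
  if (!identical(ts, .DCM_EXPLICIT_LE))
    stop(sprintf("unsupported transfer syntax: %s (only explicit VR little endian)", ts))
  body <- .parse_dataset(r, meta$pos, length(r))
  list(meta = meta$dataset, dataset = body$dataset)
}

# convenience accessors -------------------------------------------------

dcm_get <- function(ds, group, element, default = NULL) {
  el <- ds[[.tag_key(group, element)]]
  if (is.null(el)) default else el$value
}

dcm_numbers <- function(ds, group, element) {
  v <- dcm_get(ds, group, element)
  if (is.null(v)) return(NULL)
  as.numeric(strsplit(v, "\\", fixed = TRUE)[[1]])
}
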