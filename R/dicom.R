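# Minimal DICOM RT Structure Set I/O (Explicit VR Little Endian only).
# No general-purpose DICOM library is used: only the Structure Set ROI /
# ROI Contour modules with CLOSED_PLANAR geometry are understood, which is
# all the surface-area engine needs.  Lengths on disk are millimetres per
# the DICOM standard; everything is converted to cm on ingest.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_ROOT <- "1.2.826.0.1.3680043.10763"

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(payload, pad = as.raw(0x20)) {
  if (length(payload) %% 2 == 1) c(payload, pad) else payload
}

dcm_string <- function(s, ui = FALSE) {
  pad_even(charToRaw(s), pad = if (ui) as.raw(0x00) else as.raw(0x20))
}

dcm_elem <- function(group, element, vr, payload) {
  header <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(header, as.raw(c(0, 0)), uint32le(length(payload)), payload)
  } else {
    c(header, uint16le(length(payload)), payload)
  }
}

dcm_item <- function(payload) {
  c(uint16le(0xFFFE), uint16le(0xE000), uint32le(length(payload)), payload)
}

#' Write a minimal DICOM RT Structure Set
#'
#' Serialises a [contour_set()] as a valid Explicit-VR-little-endian
#' RTSTRUCT file containing one ROI with CLOSED_PLANAR contours.  Contour
#' coordinates are converted from the package's cm convention to DICOM mm.
#'
#' @param contours A `contour_set`.
#' @param path Output path.
#' @param roi_number ROI number to assign (default 1).
#' @return `path`, invisibly.
#' @seealso [read_rtstruct()]
#' @export
write_rtstruct <- function(contours, path, roi_number = 1L) {
  stopifnot(inherits(contours, "contour_set"))
  sop_instance <- paste0(UID_ROOT, ".", format(as.integer(Sys.time()) %% 1e8), ".1")

  contour_items <- raw(0)
  for (s in contours$slices) {
    for (ring in s$polygons) {
      xyz_mm <- rbind(t(cbind(ring, s$z)) * 10)  # 3 x n, cm -> mm
      ds <- paste(sprintf("%.6g", as.vector(xyz_mm)), collapse = "\\")
      item <- c(
        dcm_elem(0x3006, 0x0042, "CS", dcm_string("CLOSED_PLANAR")),
        dcm_elem(0x3006, 0x0046, "IS", dcm_string(as.character(nrow(ring)))),
        dcm_elem(0x3006, 0x0050, "DS", dcm_string(ds))
      )
      contour_items <- c(contour_items, dcm_item(item))
    }
  }

  ssroi_item <- dcm_item(c(
    dcm_elem(0x3006, 0x0022, "IS", dcm_string(as.character(roi_number))),
    dcm_elem(0x3006, 0x0026, "LO", dcm_string(contours$roi_name))
  ))
  roicontour_item <- dcm_item(c(
    dcm_elem(0x3006, 0x0040, "SQ", contour_items),
    dcm_elem(0x3006, 0x0084, "IS", dcm_string(as.character(roi_number)))
  ))

  dataset <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_string(UID_RTSTRUCT, ui = TRUE)),
    dcm_elem(0x0008, 0x0018, "UI", dcm_string(sop_instance, ui = TRUE)),
    dcm_elem(0x0008, 0x0060, "CS", dcm_string("RTSTRUCT")),
    dcm_elem(0x3006, 0x0002, "SH", dcm_string("gkr50")),
    dcm_elem(0x3006, 0x0020, "SQ", ssroi_item),
    dcm_elem(0x3006, 0x0039, "SQ", roicontour_item)
  )

  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_elem(0x0002, 0x0002, "UI", dcm_string(UID_RTSTRUCT, ui = TRUE)),
    dcm_elem(0x0002, 0x0003, "UI", dcm_string(sop_instance, ui = TRUE)),
    dcm_elem(0x0002, 0x0010, "UI", dcm_string(UID_EXPLICIT_LE, ui = TRUE)),
    dcm_elem(0x0002, 0x0012, "UI", dcm_string(paste0(UID_ROOT, ".1"), ui = TRUE))
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", uint32le(length(meta_body))), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# --- reader --------------------------------------------------------------

read_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1)], "integer", size = 2, endian = "little", signed = FALSE)
}
read_u32 <- function(buf, pos) {
  readBin(buf[pos:(pos + 3)], "integer", size = 4, endian = "little")
}

# parse explicit-VR-LE elements in buf[pos..end]; returns a list of
# list(tag = "gggg,eeee", vr, value) where SQ values are lists of item
# element-lists.  Handles defined and undefined sequence/item lengths.
parse_elements <- function(buf, pos, end) {
  out <- list()
  while (pos + 7 <= end + 1 && pos + 7 <= length(buf) + 1) {
    group <- read_u16(buf, pos)
    element <- read_u16(buf, pos + 2)
    if (group == 0xFFFE) break  # delimiter handled by caller
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- read_u32(buf, pos + 8)
      body <- pos + 12
    } else {
      len <- read_u16(buf, pos + 6)
      body <- pos + 8
    }
    tag <- sprintf("%04x,%04x", group, element)
    if (vr == "SQ") {
      sq_end <- if (len == -1L) end else body + len - 1
      items <- parse_sequence(buf, body, sq_end)
      out[[tag]] <- list(tag = tag, vr = vr, value = items$items)
      pos <- items$pos
    } else {
      if (len == -1L) stop("undefined length on non-sequence element ", tag,
                           call. = FALSE)
      out[[tag]] <- list(
        tag = tag, vr = vr,
        value = if (len > 0) buf[body:(body + len - 1)] else raw(0)
      )
      pos <- body + len
    }
  }
  list(elements = out, pos = pos)
}

parse_sequence <- function(buf, pos, end) {
  items <- list()
  repeat {
    if (pos + 7 > end + 1 || pos + 7 > length(buf) + 1) break
    group <- read_u16(buf, pos)
    element <- read_u16(buf, pos + 2)
    len <- read_u32(buf, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (group != 0xFFFE || element != 0xE000) {
      stop("malformed sequence: expected item tag", call. = FALSE)
    }
    item_end <- if (len == -1L) end else pos + len - 1
    parsed <- parse_elements(buf, pos, item_end)
    items[[length(items) + 1]] <- parsed$elements
    pos <- parsed$pos
    if (len == -1L) {
      # consume the item delimiter
      if (read_u16(buf, pos) == 0xFFFE && read_u16(buf, pos + 2) == 0xE00D) {
        pos <- pos + 8
      }
    }
  }
  list(items = items, pos = pos)
}

elem_string <- function(el) {
  if (is.null(el)) return(NA_character_)
  trimws(rawToChar(el$value[el$value != as.raw(0)]))
}

elem_numbers <- function(el) {
  as.numeric(strsplit(elem_string(el), "\\\\")[[1]])
}

#' Read one ROI from a DICOM RT Structure Set
#'
#' Parses an Explicit-VR-little-endian RTSTRUCT file and extracts the
#' CLOSED_PLANAR contours of the selected ROI as a [contour_set()], with all
#' coordinates converted mm to cm and rings grouped by slice position.
#'
#' @param path RTSTRUCT file path.
#' @param roi ROI selector: name (character) or ROI number (numeric).
#' @return A `contour_set`.
#' @export
read_rtstruct <- function(path, roi = 1) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }
  # file meta group first (always explicit LE): check the transfer syntax
  # before attempting to parse the dataset
  stopifnot(read_u16(buf, 133) == 2L, read_u16(buf, 135) == 0L)
  meta_len <- read_u32(buf, 141)
  meta <- parse_elements(buf, 145, 144 + meta_len)
  ts <- elem_string(meta$elements[["0002,0010"]])
  if (!is.na(ts) && ts != UID_EXPLICIT_LE) {
    stop("unsupported transfer syntax ", ts,
         " (only Explicit VR Little Endian is supported)", call. = FALSE)
  }
  parsed <- parse_elements(buf, 145 + meta_len, length(buf))
  els <- parsed$elements

  ssroi <- els[["3006,0020"]]
  roictr <- els[["3006,0039"]]
  if (is.null(ssroi) || is.null(roictr)) {
    stop("file has no Structure Set ROI / ROI Contour sequences; not an RTSTRUCT?",
         call. = FALSE)
  }
  roi_numbers <- vapply(ssroi$value, function(it)
    as.integer(elem_string(it[["3006,0022"]])), integer(1))
  roi_names <- vapply(ssroi$value, function(it)
    elem_string(it[["3006,0026"]]), character(1))

  sel <- if (is.numeric(roi)) which(roi_numbers == roi) else which(roi_names == roi)
  if (length(sel) != 1) {
    stop(sprintf("ROI '%s' not found; available: %s", as.character(roi),
                 paste(sprintf("%d='%s'", roi_numbers, roi_names), collapse = ", ")),
         call. = FALSE)
  }

  ref_nums <- vapply(roictr$value, function(it)
    as.integer(elem_string(it[["3006,0084"]])), integer(1))
  ci <- which(ref_nums == roi_numbers[sel])
  if (length(ci) != 1) {
    stop("no ROI Contour item references ROI number ", roi_numbers[sel],
         call. = FALSE)
  }
  contour_sq <- roictr$value[[ci]][["3006,0040"]]
  if (is.null(contour_sq) || length(contour_sq$value) == 0) {
    stop("selected ROI has no contours", call. = FALSE)
  }

  rings_z <- numeric(0)
  rings <- list()
  for (it in contour_sq$value) {
    gtype <- elem_string(it[["3006,0042"]])
    if (!identical(gtype, "CLOSED_PLANAR")) {
      stop("unsupported contour geometry '", gtype,
           "'; only CLOSED_PLANAR is supported", call. = FALSE)
    }
    xyz <- matrix(elem_numbers(it[["3006,0050"]]), ncol = 3, byrow = TRUE) / 10
    rings[[length(rings) + 1]] <- xyz[, 1:2, drop = FALSE]
    rings_z <- c(rings_z, stats::median(xyz[, 3]))
  }
  zs <- sort(unique(round(rings_z, 6)))
  slices <- lapply(zs, function(z) {
    list(z = z, polygons = rings[abs(rings_z - z) < 1e-6])
  })
  contour_set(slices, roi_name = roi_names[sel])
}
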