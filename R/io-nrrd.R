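#' Read a dose grid or structure mask from NRRD
#'
#' Minimal NRRD reader for axis-aligned volumetric grids: single-file NRRD
#' with `ascii`/`text` encoding, 3 dimensions, spacing taken from
#' `spacings` or a diagonal `space directions` matrix, and origin from
#' `space origin`. Oblique orientations (off-diagonal space directions) are
#' rejected.
#'
#' @param path file path.
#' @param as `"auto"` (mask when content is binary and the header carries a
#'   mask label), `"dose"`, or `"mask"`.
#' @param label structure label when reading a mask.
#' @return A [dose_grid()] or [structure_mask()].
#' @export
read_nrrd <- function(path, as = c("auto", "dose", "mask"),
                      label = NULL) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^NRRD", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0 || line == "") break
    if (!grepl("^#", line)) header <- c(header, line)
  }
  fields <- list()
  for (ln in header) {
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields$dimension)
  if (is.na(dimn) || dimn != 3L)
    stop("unsupported NRRD: need dimension 3", call. = FALSE)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  enc <- tolower(fields$encoding %||% "")
  if (!enc %in% c("ascii", "text", "txt"))
    stop("unsupported NRRD encoding '", enc, "' (ascii required)",
         call. = FALSE)
  spacing <- NULL
  if (!is.null(fields$`space directions`)) {
    vecs <- regmatches(fields$`space directions`,
                       gregexpr("\\(([^)]*)\\)",
                                fields$`space directions`))[[1]]
    mat <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]),
      numeric(3)))
    offdiag <- mat; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      stop("unsupported orientation: oblique space directions",
           call. = FALSE)
    spacing <- diag(mat)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else stop("NRRD header lacks spacings/space directions", call. = FALSE)
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields$`space origin`), ",")[[1]])
  values <- scan(con, what = numeric(), quiet = TRUE)
  if (length(values) != prod(sizes))
    stop("NRRD data length ", length(values), " does not match sizes ",
         paste(sizes, collapse = "x"), call. = FALSE)
  arr <- array(values, dim = sizes)
  is_binary <- all(values %in% c(0, 1))
  content_label <- label %||% fields$content
  if (as == "mask" || (as == "auto" && is_binary &&
                       !is.null(content_label))) {
    if (!is_binary)
      stop("mask validation: file contains non-binary values", call. = FALSE)
    structure_mask(arr, spacing, origin, label = content_label %||% "mask")
  } else {
    dose_grid(arr, spacing, origin)
  }
}

#' Write a dose grid or structure mask to NRRD
#'
#' ASCII-encoded single-file NRRD with diagonal space directions; round
#' trips losslessly through [read_nrrd()].
#'
#' @param x a [dose_grid()] or [structure_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path) {
  is_mask <- inherits(x, "structure_mask")
  arr <- if (is_mask) x$voxels * 1L else x$values
  d <- dim(arr)
  hdr <- c(
    "NRRD0004",
    "# generated by sbrtdose",
    sprintf("type: %s", if (is_mask) "unsigned char" else "double"),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            x$spacing[1], x$spacing[2], x$spacing[3]),
    "kinds: domain domain domain",
    "encoding: ascii",
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            x$origin[1], x$origin[2], x$origin[3]),
    if (is_mask) sprintf("content: %s", x$label))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con)
  if (is_mask) {
    writeLines(paste(as.integer(arr), collapse = " "), con)
  } else {
    writeLines(paste(format(as.numeric(arr), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  }
  invisible(path)
}
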