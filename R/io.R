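#' Write a volume as NRRD
#'
#' Minimal NRRD writer covering the rectilinear grids this package uses:
#' 3D, x-fastest storage order, raw little-endian or ascii encoding, with
#' `space directions` / `space origin` carrying spacing and origin in mm.
#' Dose grids are stored as doubles, masks as 8-bit 0/1.
#'
#' @param x a [dose_grid()] or [binary_mask()].
#' @param path output path (conventionally `.nrrd`).
#' @param encoding `"raw"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "dose_grid"))
    stop("'x' must be a dose_grid or binary_mask")
  d <- dim(x$values)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (is_mask) "uint8" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            x$spacing[1], x$spacing[2], x$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            x$origin[1], x$origin[2], x$origin[3]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  v <- as.vector(x$values)
  if (encoding == "ascii") {
    writeLines(paste(if (is_mask) as.integer(v) else
      sprintf("%.17g", v), collapse = " "), con)
  } else if (is_mask) {
    writeBin(as.integer(v), con, size = 1L)
  } else {
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}

nrrd_typemap <- list(
  uint8 = list(what = "integer", size = 1, signed = FALSE),
  uchar = list(what = "integer", size = 1, signed = FALSE),
  int16 = list(what = "integer", size = 2, signed = TRUE),
  short = list(what = "integer", size = 2, signed = TRUE),
  int32 = list(what = "integer", size = 4, signed = TRUE),
  int = list(what = "integer", size = 4, signed = TRUE),
  float = list(what = "numeric", size = 4, signed = TRUE),
  double = list(what = "numeric", size = 8, signed = TRUE)
)

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

#' Read an NRRD volume
#'
#' Supports attached-data NRRD with raw (little/big endian) or ascii
#' encoding, 3 dimensions, and spacing given either as `space directions`
#' (must be axis-aligned) or `spacings`.
#'
#' @param path NRRD file path.
#' @return A [dose_grid()] (numeric data) or [binary_mask()] (8-bit data
#'   containing only 0/1).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-9]", magic))
    stop(sprintf("'%s' is not an NRRD file (bad magic '%s')", path, magic))
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0L)
      stop(sprintf("truncated NRRD header in '%s': no blank line before data", path))
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  need <- c("type", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop(sprintf("NRRD header misses required field(s): %s", paste(miss, collapse = ", ")))
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-dimensional NRRD volumes are supported")
  ty <- nrrd_typemap[[fields$type]]
  if (is.null(ty)) stop(sprintf("unsupported NRRD type '%s'", fields$type))
  enc <- fields$encoding
  if (!enc %in% c("raw", "ascii", "txt", "text"))
    stop(sprintf("unsupported NRRD encoding '%s' (raw and ascii only)", enc))

  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space directions`)) {
    dirs <- parse_nrrd_vectors(fields$`space directions`)
    for (a in 1:3) {
      v <- dirs[[a]]
      if (sum(v != 0) != 1L || v[a] == 0)
        stop("non-axis-aligned NRRD space directions are not supported")
      spacing[a] <- abs(v[a])
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- abs(as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]]))
  }
  if (!is.null(fields$`space origin`))
    origin <- parse_nrrd_vectors(fields$`space origin`)[[1]]

  n <- prod(sizes)
  if (enc == "raw") {
    endian <- if (identical(fields$endian, "big")) "big" else "little"
    v <- readBin(con, what = ty$what, n = n, size = ty$size,
                 signed = ty$signed, endian = endian)
    if (length(v) < n)
      stop(sprintf("truncated NRRD data in '%s': expected %d values, got %d (byte offset %d)",
                   path, n, length(v), seek(con)))
  } else {
    v <- scan(con, what = double(), n = n, quiet = TRUE)
    if (length(v) < n)
      stop(sprintf("truncated NRRD data in '%s': expected %d values, got %d",
                   path, n, length(v)))
  }
  arr <- array(as.numeric(v), sizes)
  if (ty$size == 1 && all(arr %in% c(0, 1)))
    binary_mask(arr == 1, spacing, origin)
  else
    dose_grid(arr, spacing, origin)
}

#' Read a volumetric dose or structure file
#'
#' Dispatches on the file extension: `.nrrd` through the package's NRRD
#' reader, `.nii` / `.nii.gz` through RNifti (spacing from pixdim, origin
#' from the qform offset). DICOM is not supported; dose grids and masks
#' arrive as volumetric files.
#'
#' @param path input file.
#' @return A [dose_grid()] or [binary_mask()].
#' @export
read_dose_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    h <- RNifti::niftiHeader(img)
    spacing <- abs(h$pixdim[2:4])
    origin <- c(h$qoffset_x, h$qoffset_y, h$qoffset_z)
    return(dose_grid(array(as.numeric(img), dim(img)[1:3]), spacing, origin))
  }
  stop(sprintf("unsupported volume format: '%s' (NRRD or NIfTI expected; DICOM is not supported)",
               path))
}

#' Read a structure mask from a volumetric file
#'
#' Reads with [read_dose_volume()] and thresholds at 0.5.
#' @param path input file.
#' @return A [binary_mask()].
#' @export
read_mask_volume <- function(path) {
  v <- read_dose_volume(path)
  if (inherits(v, "binary_mask")) return(v)
  binary_mask(v$values >= 0.5, v$spacing, v$origin)
}

#' Write the fixture volumes of a synthetic plan
#'
#' Emits `dose.nrrd`, `body.nrrd` and `ptv.nrrd` for a
#' [make_radial_dose()] plan so the file-based analysis path can be
#' exercised end-to-end.
#'
#' @param plan a `radial_plan`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_plan_volumes <- function(plan, dir) {
  stopifnot(inherits(plan, "radial_plan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dose = file.path(dir, "dose.nrrd"),
             body = file.path(dir, "body.nrrd"),
             ptv = file.path(dir, "ptv.nrrd"))
  write_nrrd(plan$dose, paths["dose"])
  write_nrrd(plan$body, paths["body"])
  write_nrrd(plan$ptv, paths["ptv"])
  invisible(paths)
}

#' Serialize a DGC table as CSV
#'
#' Writes the level/curve table at full double precision (17 significant
#' digits) with the fitting attributes stored in `#`-comment header lines,
#' so [read_dgc_csv()] reproduces the table exactly.
#'
#' @param x a [dgc()] fit or a `dgc_table` / `isodose_levels` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dgc_csv <- function(x, path) {
  tbl <- if (inherits(x, "dgc")) x$table else x
  meta <- c(step = attr(tbl, "step"),
            reference_dose = attr(tbl, "reference_dose"),
            reference_level = attr(tbl, "reference_level"),
            truncation_dose = attr(tbl, "truncation_dose"))
  scale <- attr(tbl, "dose_scale")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    if (!is.null(meta[[nm]]) && !is.na(meta[[nm]]))
      writeLines(sprintf("# %s: %.17g", nm, meta[[nm]]), con)
  if (!is.null(scale)) writeLines(sprintf("# dose_scale: %s", scale), con)
  df <- as.data.frame(tbl)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(out, sep = ",")), con)
  invisible(path)
}

#' Read a DGC table written by [write_dgc_csv()]
#'
#' @param path CSV path.
#' @return A `dgc_table` data frame with the stored attributes restored.
#' @export
read_dgc_csv <- function(path) {
  lines <- readLines(path)
  metaln <- grep("^# ", lines, value = TRUE)
  df <- read.csv(text = lines[!grepl("^# ", lines)], stringsAsFactors = FALSE)
  for (cn in setdiff(names(df), "n_components")) df[[cn]] <- as.numeric(df[[cn]])
  attrs <- list()
  for (ln in metaln) {
    kv <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    attrs[[kv[2]]] <- kv[3]
  }
  for (nm in c("step", "reference_dose", "reference_level", "truncation_dose"))
    if (!is.null(attrs[[nm]])) attr(df, nm) <- as.numeric(attrs[[nm]])
  if (!is.null(attrs$dose_scale)) attr(df, "dose_scale") <- attrs$dose_scale
  class(df) <- c("dgc_table", "data.frame")
  df
}

#' Run a complete file-based DGC analysis
#'
#' The orchestration entry point behind the command-line tool: reads the
#' dose grid and masks, fits the curves with [dgc()], and writes the curve
#' table CSV, the DVH CSV, an indices JSON and (optionally) plot files into
#' `output_dir`. Progress messages log the quantities that explain
#' surprising curves: the realised voxel spacing, the truncation dose, and
#' the number of disconnected components per level.
#'
#' @param dose_path path of the dose volume (NRRD or NIfTI, Gy).
#' @param prescription prescription dose in Gy.
#' @param output_dir output directory (created if needed).
#' @param body_path,ptv_path optional mask volume paths.
#' @param plots write PNG plots (cumulative + differential, combined when a
#'   DVH exists).
#' @param ... further arguments passed to [dgc()] (`step`, `dose_scale`,
#'   `reference`, `crop_margin`, `range`, ...).
#' @return The [dgc()] fit, invisibly, with the written paths in attribute
#'   `files`.
#' @export
run_dgc_analysis <- function(dose_path, prescription, output_dir,
                             body_path = NULL, ptv_path = NULL,
                             plots = TRUE, ...) {
  dose <- read_dose_volume(dose_path)
  if (inherits(dose, "binary_mask"))
    stop(sprintf("'%s' holds a binary volume, not a dose grid", dose_path))
  body <- if (!is.null(body_path)) read_mask_volume(body_path)
  ptv <- if (!is.null(ptv_path)) read_mask_volume(ptv_path)
  fit <- dgc(dose, prescription = prescription, body = body, ptv = ptv, ...)

  message(sprintf("grid spacing after resampling: %s mm",
                  paste(signif(fit$config$spacing_mm, 4), collapse = " x ")))
  message(sprintf("analysis truncated at the %g%s level",
                  fit$config$truncation_dose,
                  if (fit$config$dose_scale == "percent") "%" else " Gy"))
  nc <- fit$table$n_components
  message(sprintf("isodose components per level: %s",
                  if (max(nc) == 1L) "all single" else
                  sprintf("1-%d (disconnected regions pooled)", max(nc))))

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(table = file.path(output_dir, "dgc_table.csv"),
             indices = file.path(output_dir, "indices.json"))
  write_dgc_csv(fit, files["table"])
  jsonlite::write_json(fit$indices, files["indices"],
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(fit$dvh)) {
    files["dvh"] <- file.path(output_dir, "dvh.csv")
    write.csv(as.data.frame(fit$dvh), files["dvh"], row.names = FALSE)
  }
  if (plots) {
    for (ty in c("cumulative", "differential")) {
      f <- file.path(output_dir, paste0("dgc_", ty, ".png"))
      grDevices::png(f, width = 800, height = 600)
      plot(fit, type = ty)
      grDevices::dev.off()
      files[ty] <- f
    }
    if (!is.null(fit$dvh)) {
      f <- file.path(output_dir, "dgc_combined.png")
      grDevices::png(f, width = 800, height = 600)
      plot(fit, type = "combined")
      grDevices::dev.off()
      files["combined"] <- f
    }
  }
  attr(fit, "files") <- files
  invisible(fit)
}
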