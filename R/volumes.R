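# Volume I/O: NIfTI (via RNifti) and raw binary + JSON header.

.dtype_size <- c(int32 = 4L, float32 = 4L, float64 = 8L)

#' Write a 3D volume to disk
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, spacing stored in pixdim)
#' and raw binary plus JSON header (`.json`; the samples go to the sibling
#' `.raw` file; header records shape, spacing, dtype, origin). Integer data
#' round-trip bitwise; floating-point dose maps default to 32-bit storage
#' (pass `dtype = "float64"` for full precision).
#'
#' @param vol A `dpk_volume` (or 3D array, spacing 1 mm assumed).
#' @param path Output path ending in `.nii`, `.nii.gz`, or `.json`.
#' @param dtype Storage type for the raw format: `"int32"`, `"float32"`,
#'   or `"float64"`. Defaults to `int32` for integer data, else `float32`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dtype = NULL) {
  if (!inherits(vol, "dpk_volume")) vol <- dpk_volume(vol, 1)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.json$", path)) {
    is_int <- is.integer(vol$values) ||
      all(vol$values == round(vol$values))
    if (is.null(dtype)) dtype <- if (is.integer(vol$values)) "int32" else "float32"
    if (!dtype %in% names(.dtype_size)) stop("unsupported dtype: ", dtype)
    hdr <- list(format = "dpkchain/raw-volume",
                shape = dim(vol$values), spacing = vol$spacing,
                dtype = dtype, origin = vol$origin,
                raw_file = basename(sub("\\.json$", ".raw", path)))
    jsonlite::write_json(hdr, path, auto_unbox = FALSE, digits = NA)
    con <- file(sub("\\.json$", ".raw", path), "wb")
    on.exit(close(con))
    v <- as.vector(vol$values)
    if (dtype == "int32") writeBin(as.integer(v), con, size = 4L)
    else writeBin(as.double(v), con,
                  size = .dtype_size[[dtype]])
  } else {
    stop("unsupported volume format (use .nii, .nii.gz, or .json): ", path)
  }
  invisible(path)
}

#' Read a 3D volume written by [write_volume()]
#' @param path Path ending in `.nii`, `.nii.gz`, or `.json`.
#' @return A `dpk_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3)
      stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path)
    sp <- RNifti::pixdim(img)[seq_len(3)]
    dpk_volume(arr, sp)
  } else if (grepl("\\.json$", path)) {
    hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(hdr$format, "dpkchain/raw-volume"))
      stop("not a raw-volume header: ", path)
    if (length(hdr$shape) != 3)
      stop("expected a 3D volume, got ", length(hdr$shape), "D: ", path)
    rawpath <- file.path(dirname(path), hdr$raw_file)
    con <- file(rawpath, "rb")
    on.exit(close(con))
    n <- prod(hdr$shape)
    v <- if (hdr$dtype == "int32") readBin(con, "integer", n, size = 4L)
         else readBin(con, "double", n, size = .dtype_size[[hdr$dtype]])
    dpk_volume(array(v, dim = hdr$shape), hdr$spacing, hdr$origin)
  } else {
    stop("unsupported volume format (use .nii, .nii.gz, or .json): ", path)
  }
}
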