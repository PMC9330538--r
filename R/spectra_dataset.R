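#' Spectral dataset container
#'
#' A `spectra_dataset` bundles a shared wavenumber axis, an intensity matrix
#' (one row per acquired spectrum) and per-spectrum metadata. It is the
#' currency passed between every stage of the pipeline: simulation,
#' preprocessing, MCR-ALS decomposition, classification and statistics.
#'
#' @param wavenumbers Strictly increasing numeric vector, in cm^-1.
#' @param intensities Numeric matrix, spectra in rows, one column per
#'   wavenumber channel.
#' @param meta `data.frame` with columns `spectrum_id`, `mouse_id`, `group`
#'   and optionally `cohort` (defaults to `"primary"`); one row per spectrum.
#' @param provenance Character vector of operations already applied, used to
#'   record the processing chain.
#'
#' @return An object of class `spectra_dataset` with elements `wavenumbers`,
#'   `intensities`, `meta` and `provenance`.
#' @export
spectra_dataset <- function(wavenumbers, intensities, meta,
                            provenance = character()) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(intensities))) {
    intensities <- matrix(intensities, nrow = 1)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (anyNA(wavenumbers) || is.unsorted(wavenumbers, strictly = TRUE)) {
    stop("wavenumber axis must be strictly increasing and free of NA")
  }
  if (ncol(intensities) != length(wavenumbers)) {
    stop(sprintf(
      "intensity matrix has %d channels but the axis has %d wavenumbers",
      ncol(intensities), length(wavenumbers)
    ))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("spectrum_id", "mouse_id", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"cohort" %in% names(meta)) meta$cohort <- rep("primary", nrow(meta))
  if (nrow(meta) != nrow(intensities)) {
    stop(sprintf(
      "metadata has %d rows but the intensity matrix has %d spectra",
      nrow(meta), nrow(intensities)
    ))
  }
  dup <- meta$spectrum_id[duplicated(meta$spectrum_id)]
  if (length(dup) > 0) {
    stop("duplicated spectrum_id: ", paste(unique(dup), collapse = ", "))
  }
  grp_per_mouse <- tapply(meta$group, meta$mouse_id, function(g) length(unique(g)))
  bad_mouse <- names(grp_per_mouse)[grp_per_mouse > 1]
  if (length(bad_mouse) > 0) {
    stop("mouse assigned to more than one group: ",
         paste(bad_mouse, collapse = ", "))
  }
  rownames(intensities) <- meta$spectrum_id
  structure(
    list(
      wavenumbers = wavenumbers,
      intensities = intensities,
      meta = meta,
      provenance = as.character(provenance)
    ),
    class = "spectra_dataset"
  )
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectra_dataset> %d spectra x %d channels (%.0f-%.0f cm^-1)\n",
    nrow(x$intensities), length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)
  ))
  tab <- table(x$meta$group[!duplicated(x$meta$mouse_id)])
  cat("  mice per group:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (length(x$provenance) > 0) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$intensities)

#' Number of spectra in a dataset
#' @param d A `spectra_dataset`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(d) nrow(d$intensities)

#' Subset a spectral dataset by spectrum rows
#'
#' @param d A `spectra_dataset`.
#' @param rows Integer or logical index into the spectrum rows.
#' @return A `spectra_dataset` with the selected spectra.
#' @export
subset_spectra <- function(d, rows) {
  spectra_dataset(
    d$wavenumbers,
    d$intensities[rows, , drop = FALSE],
    d$meta[rows, , drop = FALSE],
    provenance = d$provenance
  )
}

#' Append one processing step to the provenance record
#' @noRd
add_provenance <- function(d, step) {
  d$provenance <- c(d$provenance, step)
  d
}

#' Read a spectral dataset from wide-format TSV files
#'
#' The spectra file is a wide table whose first column is `wavenumber_cm1`
#' and whose remaining columns (one per spectrum id) hold intensities. The
#' metadata file has columns `spectrum_id`, `mouse_id`, `group` and
#' optionally `cohort`. Every spectrum column must have exactly one metadata
#' row and vice versa.
#'
#' @param spectra_path Path to the wide spectra TSV.
#' @param meta_path Path to the metadata TSV.
#' @return A validated [spectra_dataset()].
#' @export
read_dataset <- function(spectra_path, meta_path) {
  for (p in c(spectra_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  wide <- utils::read.delim(spectra_path, check.names = FALSE)
  if (names(wide)[1] != "wavenumber_cm1") {
    stop("first column of ", spectra_path, " must be 'wavenumber_cm1', found '",
         names(wide)[1], "'")
  }
  meta <- utils::read.delim(meta_path, colClasses = "character")
  required <- c("spectrum_id", "mouse_id", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  w <- wide[[1]]
  if (anyNA(w) || is.unsorted(w, strictly = TRUE)) {
    stop("wavenumber axis in ", spectra_path, " is not strictly increasing")
  }
  ids <- names(wide)[-1]
  orphan_meta <- setdiff(meta$spectrum_id, ids)
  orphan_spec <- setdiff(ids, meta$spectrum_id)
  if (length(orphan_meta) > 0) {
    stop("metadata rows without a spectrum column: ",
         paste(orphan_meta, collapse = ", "))
  }
  if (length(orphan_spec) > 0) {
    stop("spectrum columns without a metadata row: ",
         paste(orphan_spec, collapse = ", "))
  }
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  rownames(meta) <- NULL
  mat <- t(as.matrix(wide[, -1, drop = FALSE]))
  spectra_dataset(w, mat, meta)
}

#' Write a spectral dataset to wide-format TSV files
#'
#' Inverse of [read_dataset()]. Values survive a round trip to better than
#' 1e-12 relative precision.
#'
#' @param d A `spectra_dataset`.
#' @param spectra_path Output path for the wide spectra TSV.
#' @param meta_path Output path for the metadata TSV.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(d, spectra_path, meta_path) {
  stopifnot(inherits(d, "spectra_dataset"))
  wide <- data.frame(wavenumber_cm1 = d$wavenumbers, check.names = FALSE)
  mat <- t(d$intensities)
  colnames(mat) <- d$meta$spectrum_id
  wide <- cbind(wide, as.data.frame(mat, check.names = FALSE))
  utils::write.table(format(wide, digits = 17, trim = TRUE, scientific = FALSE),
                     spectra_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(spectra_path, meta_path))
}
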