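#' Structural connectome of one subject
#'
#' A `connectome` is a symmetric, zero-diagonal, nonnegative matrix of
#' tractography streamline counts between atlas parcels, with rows and
#' columns in atlas order. Streamline counts are integers at the source;
#' downstream graph math treats them as reals.
#'
#' @param subject_id subject identifier.
#' @param parcels ordered parcel IDs (matrix dimnames).
#' @param weights square numeric matrix of streamline counts.
#' @return A `connectome` object.
#' @export
connectome <- function(subject_id, parcels, weights) {
  parcels <- as.character(parcels)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("connectome matrix must be square")
  if (nrow(weights) != length(parcels)) {
    stop("connectome dimensions do not match parcel list")
  }
  if (any(weights < 0)) stop("negative streamline count")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("connectome matrix must be symmetric")
  }
  dimnames(weights) <- list(parcels, parcels)
  structure(list(subject_id = as.character(subject_id),
                 parcels = parcels, weights = weights),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> subject ", x$subject_id, ": ", length(x$parcels),
      " parcels, ", format(sum(x$weights) / 2, big.mark = ","),
      " streamlines\n", sep = "")
  invisible(x)
}

#' Read a subject connectivity matrix from CSV
#'
#' The file is a square matrix whose first row and first column hold
#' identical parcel-ID headers (RFC-4180 CSV, UTF-8). Rows and columns are
#' reordered to atlas order; atlas parcels absent from the file are filled in
#' as zero rows/columns with a warning. Asymmetry within a relative tolerance
#' of `1e-6` is repaired by averaging `W` with its transpose; larger
#' asymmetry, negative entries, unknown parcel IDs, non-square input, and
#' (when `strict_integer = TRUE`) non-integer streamline counts are errors.
#'
#' @param path CSV file path.
#' @param atlas the `atlas_topology` the matrix belongs to.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @param strict_integer require integer-valued streamline counts
#'   (default `TRUE`).
#' @return A `connectome` aligned to `atlas$parcels`.
#' @export
read_connectome <- function(path, atlas, subject_id = NULL,
                            strict_integer = TRUE) {
  stopifnot(inherits(atlas, "atlas_topology"))
  if (!file.exists(path)) stop("connectome file not found: ", path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  w <- as.matrix(df)
  if (nrow(w) != ncol(w)) stop("connectome matrix not square: ", path)
  if (!setequal(rownames(w), colnames(w)) ||
      anyDuplicated(rownames(w)) || anyDuplicated(colnames(w))) {
    stop("row and column parcel headers differ: ", path)
  }
  w <- w[, rownames(w), drop = FALSE]  # align columns to row order
  unknown <- setdiff(rownames(w), atlas$parcels)
  if (length(unknown)) {
    stop("unknown parcel ID(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (any(w < 0)) stop("negative streamline count in ", path)
  scale <- max(1, max(abs(w)))
  if (max(abs(w - t(w))) / scale > 1e-6) {
    stop("asymmetry beyond tolerance in ", path)
  }
  w <- (w + t(w)) / 2
  if (strict_integer && max(abs(w - round(w))) > 1e-6) {
    stop("non-integer streamline count in ", path)
  }
  missing <- setdiff(atlas$parcels, rownames(w))
  if (length(missing)) {
    warning("parcels absent from ", basename(path), " filled with zeros: ",
            paste(missing, collapse = ", "))
    full <- matrix(0, length(atlas$parcels), length(atlas$parcels),
                   dimnames = list(atlas$parcels, atlas$parcels))
    full[rownames(w), colnames(w)] <- w
    w <- full
  } else {
    w <- w[atlas$parcels, atlas$parcels]
  }
  diag(w) <- 0
  connectome(subject_id, atlas$parcels, w)
}

#' Write a connectome to CSV
#'
#' Writes the symmetric streamline matrix with parcel-ID row and column
#' headers so that [read_connectome()] round-trips it exactly.
#'
#' @param c a `connectome`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  utils::write.csv(as.data.frame(c$weights), path, quote = FALSE)
  invisible(path)
}
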