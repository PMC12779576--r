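#' Voxel masks
#'
#' A `voxel_mask` is a 3-D boolean lattice with a physical voxel size: the
#' unit of all geometric computation in the package. The stored NIfTI affine
#' (when read from file) is recorded as provenance but never interpreted;
#' all geometry operates on the voxel lattice itself.
#'
#' @param grid A 3-D `logical` (or coercible numeric) array.
#' @param voxel_size_mm Positive numeric of length 1 or 3: voxel edge
#'   lengths in millimetres. A scalar is recycled to isotropic voxels.
#' @param origin_note Free-text provenance (for example, the source file and
#'   its affine). Not interpreted.
#'
#' @return An object of class `voxel_mask`.
#' @examples
#' m <- voxel_mask(array(TRUE, c(3, 3, 3)), voxel_size_mm = 0.5)
#' sum(m$grid)
#' @export
voxel_mask <- function(grid, voxel_size_mm = 1, origin_note = "") {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    abort("`grid` must be a 3-D array.")
  }
  if (any(dim(grid) < 1L)) abort("all lattice extents must be >= 1.")
  storage.mode(grid) <- "logical"
  if (anyNA(grid)) abort("`grid` must not contain NA.")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 1 or 3 positive finite numbers.")
  }
  structure(
    list(grid = grid, voxel_size_mm = voxel_size_mm,
         origin_note = as.character(origin_note)[1]),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<voxel_mask> %d x %d x %d lattice, %s mm voxels, %d foreground\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size_mm, 3), collapse = " x "),
    sum(x$grid)))
  invisible(x)
}

#' Read a binary mask from a NIfTI volume
#'
#' Any numeric volume is accepted; voxels strictly above
#' `binarize_threshold` become foreground, so probability maps binarize at
#' the conventional 0.5 by default while already-binary masks pass through
#' unchanged. Voxel sizes come from the header zooms; the affine is recorded
#' in `origin_note` but never used.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3-D volume.
#' @param binarize_threshold Foreground is `value > binarize_threshold`
#'   (default 0.5).
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path, binarize_threshold = 0.5) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- arr[, , , 1, drop = TRUE]
    d <- utils::head(d, 3L)
    dim(arr) <- d
  }
  if (length(d) < 3L) {
    # stored trailing singleton dimensions are dropped on read
    d <- c(d, rep(1L, 3L - length(d)))
    dim(arr) <- d
  }
  if (length(dim(arr)) != 3L) {
    abort(sprintf("`%s` is not a 3-D volume (dims: %s).", path,
                  paste(dim(arr), collapse = " x ")))
  }
  if (any(dim(arr) < 1L)) abort("volume has a zero-sized dimension.")
  zooms <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(zooms)) || any(zooms <= 0)) zooms <- c(1, 1, 1)
  note <- sprintf("read from %s; affine recorded, not interpreted: %s",
                  path, paste(signif(c(RNifti::xform(img)), 4),
                              collapse = " "))
  voxel_mask(arr > binarize_threshold, voxel_size_mm = zooms,
             origin_note = note)
}

#' Write a mask to NIfTI
#'
#' Foreground voxels are written as 1, background as 0, with voxel sizes in
#' the header. Round-tripping through [read_mask()] reproduces the grid
#' exactly.
#'
#' @param mask A [voxel_mask()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- array(as.integer(mask$grid), dim(mask$grid))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Label volumes and region merging
#'
#' A `label_volume` couples a 3-D non-negative integer lattice with a label
#' table naming each positive label, and an optional merge map that pools
#' sets of source labels into single regions (as when small contiguous
#' parcels are combined into one of the final regions of interest). Label 0
#' is reserved for background.
#'
#' @param grid 3-D integer array; 0 is background.
#' @param label_table Data frame with columns `label` (positive integer) and
#'   `name` (region name), covering every positive label in `grid`.
#' @param merge_table Optional data frame with columns `label` and `region`:
#'   labels mapped to the same `region` are pooled. Labels absent from the
#'   table keep their own `name` as region. A label may appear at most once.
#' @param voxel_size_mm As for [voxel_mask()].
#' @return An object of class `label_volume` with a resolved
#'   `region_of_label` map.
#' @export
label_volume <- function(grid, label_table, merge_table = NULL,
                         voxel_size_mm = 1) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    abort("`grid` must be a 3-D array.")
  }
  storage.mode(grid) <- "integer"
  if (anyNA(grid) || any(grid < 0L)) {
    abort("labels must be non-negative integers (0 = background).")
  }
  label_table <- as_tibble(label_table)
  if (!all(c("label", "name") %in% names(label_table))) {
    abort("`label_table` needs columns `label` and `name`.")
  }
  present <- sort(unique(grid[grid > 0L]))
  missing <- setdiff(present, label_table$label)
  if (length(missing) > 0) {
    abort(sprintf("labels present in volume but absent from table: %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(label_table$label)) {
    abort("duplicated labels in `label_table`.")
  }
  region_of_label <- setNames(label_table$name, label_table$label)
  if (!is.null(merge_table)) {
    merge_table <- as_tibble(merge_table)
    if (!all(c("label", "region") %in% names(merge_table))) {
      abort("`merge_table` needs columns `label` and `region`.")
    }
    if (anyDuplicated(merge_table$label)) {
      abort("merge sets overlap: a label appears in more than one set.")
    }
    unknown <- setdiff(merge_table$label, label_table$label)
    if (length(unknown) > 0) {
      abort(sprintf("merge table refers to unknown labels: %s",
                    paste(unknown, collapse = ", ")))
    }
    region_of_label[as.character(merge_table$label)] <- merge_table$region
  }
  voxel_size_mm <- if (length(voxel_size_mm) == 1L) {
    rep(as.numeric(voxel_size_mm), 3L)
  } else as.numeric(voxel_size_mm)
  structure(
    list(grid = grid, label_table = label_table, merge_table = merge_table,
         region_of_label = region_of_label, voxel_size_mm = voxel_size_mm),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s lattice, %d labels -> %d regions\n",
              paste(dim(x$grid), collapse = " x "),
              nrow(x$label_table), length(unique(x$region_of_label))))
  invisible(x)
}

#' Read a label volume with its label (and optional merge) table
#'
#' @param path Integer-valued NIfTI volume.
#' @param label_table_path CSV with columns `label,name`.
#' @param merge_table_path Optional CSV with columns `label,region`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_table_path,
                              merge_table_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) abort("label volume must be 3-D.")
  if (max(abs(arr - round(arr))) > 1e-6) {
    abort("label volume is not integer-valued.")
  }
  labels <- readr::read_csv(label_table_path, show_col_types = FALSE)
  merges <- if (!is.null(merge_table_path)) {
    readr::read_csv(merge_table_path, show_col_types = FALSE)
  }
  zooms <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(zooms)) || any(zooms <= 0)) zooms <- c(1, 1, 1)
  label_volume(array(as.integer(round(arr)), dim(arr)), labels, merges,
               voxel_size_mm = zooms)
}

#' Split a label volume into per-region masks
#'
#' Returns one [voxel_mask()] per (merged) region. The masks are disjoint
#' and their union covers every labelled voxel; merged regions are voxel
#' unions of their source labels.
#'
#' @param labels A [label_volume()].
#' @return Named list of [voxel_mask()] objects, one per region.
#' @export
parcellate <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  regions <- unique(unname(labels$region_of_label))
  out <- lapply(regions, function(rg) {
    lab <- as.integer(names(labels$region_of_label)[
      labels$region_of_label == rg])
    grid <- array(labels$grid %in% lab, dim(labels$grid))
    voxel_mask(grid, voxel_size_mm = labels$voxel_size_mm,
               origin_note = sprintf("region %s", rg))
  })
  setNames(out, regions)
}
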