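# NIfTI I/O for volumes and displacement fields, with JSON sidecars
# recording conventions and provenance.

#' Write a volume as NIfTI
#'
#' Spacing is stored in the header pixdim; values are written as-is.
#'
#' @param v an [lm_volume()].
#' @param path output path (".nii" or ".nii.gz").
#' @export
write_volume <- function(v, path) {
  a <- v$data
  attr(a, "pixdim") <- v$spacing
  RNifti::writeNifti(a, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @param semantics value-semantics label to attach.
#' @return an [lm_volume()].
#' @export
read_volume <- function(path, semantics = "map") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header is missing positive voxel spacing")
  lm_volume(array(as.numeric(img), d), sp, semantics = semantics)
}

#' Write a displacement field as 4D NIfTI
#'
#' Component axis last, values in mm in physical space. A JSON sidecar
#' (same path with ".json") records the direction convention and units.
#'
#' @param dvf an [lm_dvf()].
#' @param path output path.
#' @export
write_dvf <- function(dvf, path) {
  a <- dvf$data
  attr(a, "pixdim") <- c(dvf$spacing, 1)
  RNifti::writeNifti(a, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = "mm", component_axis = "last",
                            direction = dvf$direction,
                            convention = "u(x); transform phi(x) = x + u(x)"),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Read a 4D NIfTI displacement field
#'
#' Requires exactly 3 components on the last axis and positive spacing in
#' the header; the sidecar's direction tag is restored when present.
#'
#' @param path NIfTI file.
#' @return an [lm_dvf()].
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D NIfTI with 3 vector components on the last axis")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header is missing positive voxel spacing")
  direction <- "fixed_to_moving"
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(side)) {
    meta <- tryCatch(jsonlite::read_json(side), error = function(e) NULL)
    if (!is.null(meta$direction)) direction <- meta$direction
  }
  lm_dvf(array(as.numeric(img), d), sp, direction = direction)
}

#' Export a surface mesh as ASCII PLY
#'
#' @param mesh an `lm_mesh`.
#' @param path output .ply path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
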