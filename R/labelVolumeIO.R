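#' Read a segmentation stack and its role-map sidecar
#'
#' Reads a multi-page TIFF of integer label sections (page k = slice z = k)
#' and a YAML or JSON sidecar holding the voxel geometry and the label-to-role
#' mapping. Voxel sizes always come from the sidecar, never from TIFF tags
#' (TIFF resolution dialects are too ambiguous for anisotropic EM stacks);
#' if the sidecar omits them the defaults \code{(100, 6, 6)} nm are used with
#' a warning.
#'
#' Sidecar layout:
#' \preformatted{voxel_size_nm: [100, 6, 6]
#' roles:
#'   "0": background
#'   "1": lumen
#'   "3": basement_membrane}
#'
#' @param stackPath path to a multi-page TIFF (uint8/uint16).
#' @param roleMapPath path to the sidecar (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return list with elements \code{volume} (\linkS4class{LabelVolume}) and
#'   \code{roleMap} (\linkS4class{RoleMap}).
#' @seealso \code{\link{writeLabelStack}}, \code{\link{roleMask}}
#' @export
readLabelStack <- function(stackPath, roleMapPath) {
  if (!file.exists(stackPath)) stop("stack file not found: ", stackPath)
  if (!file.exists(roleMapPath)) stop("role map file not found: ", roleMapPath)
  pages <- tiff::readTIFF(stackPath, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("pages of unequal shape in ", stackPath)
  if (any(vapply(pages, function(p) any(p != round(p)), logical(1))))
    stop("non-integer pixel type in ", stackPath)
  vox <- array(0L, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- as.integer(pages[[k]])

  sidecar <- readRoleSidecar(roleMapPath)
  rm <- RoleMap(sidecar$roles)
  ids <- as.integer(names(roles(rm)))
  present <- unique(as.vector(vox))
  unmapped <- setdiff(present, ids)
  if (length(unmapped))
    stop("stack contains label(s) missing from the role map: ",
         paste(sort(unmapped), collapse = ", "))
  if (any(!ids %in% present))
    warning("role map references label(s) absent from the stack: ",
            paste(sort(ids[!ids %in% present]), collapse = ", "),
            call. = FALSE)
  list(volume = LabelVolume(vox, sidecar$voxel_size_nm), roleMap = rm)
}

readRoleSidecar <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported role map format: .", ext, " (use YAML or JSON)"))
  if (is.null(doc$roles)) stop("role map lacks a 'roles' entry: ", path)
  rl <- unlist(doc$roles)
  if (anyDuplicated(names(rl))) stop("duplicate label id in role map: ", path)
  vs <- doc$voxel_size_nm
  if (is.null(vs)) {
    warning("sidecar lacks voxel_size_nm; assuming (100, 6, 6) nm", call. = FALSE)
    vs <- c(100, 6, 6)
  }
  if (length(vs) != 3) stop("voxel_size_nm must have three entries (dz, dy, dx)")
  list(roles = rl, voxel_size_nm = as.numeric(vs))
}

#' Write a segmentation stack with its role-map sidecar
#'
#' Writes the volume as an ImageJ-compatible multi-page TIFF (8-bit when all
#' labels fit in 0..255, else 16-bit; labels above 65535 are refused rather
#' than clipped) and the role map plus voxel sizes as a YAML or JSON sidecar.
#' The pair round-trips bit-exactly through \code{\link{readLabelStack}}.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param stackPath output TIFF path.
#' @param roleMap a \linkS4class{RoleMap}.
#' @param roleMapPath output sidecar path (extension selects YAML/JSON).
#' @return invisibly, \code{stackPath}.
#' @export
writeLabelStack <- function(volume, stackPath, roleMap, roleMapPath) {
  stopifnot(is(volume, "LabelVolume"), is(roleMap, "RoleMap"))
  for (p in c(stackPath, roleMapPath))
    if (!dir.exists(dirname(p)))
      stop("output directory does not exist: ", dirname(p))
  vox <- voxelData(volume)
  mx <- max(vox)
  if (mx > 65535L) stop("labels above 65535 are not representable in 16-bit TIFF")
  bits <- if (mx > 255L) 16L else 8L
  scale <- 2^bits - 1
  pages <- lapply(seq_len(dim(vox)[3]), function(k) vox[, , k] / scale)
  tiff::writeTIFF(pages, stackPath, bits.per.sample = bits, compression = "LZW")

  sidecar <- list(voxel_size_nm = as.numeric(voxelSizeNm(volume)),
                  roles = as.list(roles(roleMap)))
  ext <- tolower(tools::file_ext(roleMapPath))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(sidecar, roleMapPath)
  } else if (ext == "json") {
    jsonlite::write_json(sidecar, roleMapPath, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported role map format: .", ext)
  invisible(stackPath)
}

#' Binary mask of one NVU role
#'
#' TRUE exactly where the voxel's label maps to \code{role}. Masks over all
#' roles (including \code{background}) partition the volume, provided the
#' role map covers every label present.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param roleMap a \linkS4class{RoleMap}.
#' @param role one of \code{\link{NVU_ROLES}}.
#' @return logical array with the volume's dimensions.
#' @export
roleMask <- function(volume, roleMap, role) {
  ids <- roleLabels(roleMap, role)   # errors on unknown role
  vox <- voxelData(volume)
  m <- array(vox %in% ids, dim(vox))
  m
}
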