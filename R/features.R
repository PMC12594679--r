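# Detection of NVU ultrastructural features in labeled stacks.
#
# Features are 3D connected components in voxel space with 26-connectivity;
# the 100 nm z-step is ~17x coarser than the 6 nm in-plane grid, so
# z-neighbours are physically distant — 26-connectivity is used regardless
# because real formations persist across sections and 6-connectivity
# fragments thin pegs. Adjacency tests (opening classes, gap contacts) are
# in-plane face adjacency only; z-only contact does not count.
# One 3D component = one counted event, whatever its z-extent.

emptyEvents <- function() data.frame(
  feature_type = character(), target_role = character(),
  z_start = integer(), z_end = integer(), voxel_count = integer(),
  centroid_z = numeric(), centroid_y = numeric(), centroid_x = numeric(),
  attachment_state = character(), opening_class = character(),
  max_gap_nm = numeric(), boundary = logical())

# 3D connected components (26-connectivity) of a logical array, sparse.
# Returns membership per TRUE voxel plus voxel coordinates.
connComp3d <- function(maskArr) {
  d <- dim(maskArr)
  idx <- which(maskArr)
  if (!length(idx))
    return(list(n = 0L, membership = integer(), idx = integer(),
                y = integer(), x = integer(), z = integer()))
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  y <- (idx - 1L) %% ny + 1L
  x <- ((idx - 1L) %/% ny) %% nx + 1L
  z <- (idx - 1L) %/% (ny * nx) + 1L
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  offs <- offs[1:13, ]                     # one of each +/- pair
  edges <- vector("list", 13L)
  for (o in 1:13) {
    yy <- y + offs$dy[o]; xx <- x + offs$dx[o]; zz <- z + offs$dz[o]
    ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx & zz >= 1L & zz <= nz
    nidx <- yy[ok] + (xx[ok] - 1L) * ny + (zz[ok] - 1L) * ny * nx
    j <- match(nidx, idx)
    keep <- !is.na(j)
    edges[[o]] <- cbind(which(ok)[keep], j[keep])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, as.vector(t(e)))
  cmp <- igraph::components(g)
  list(n = cmp$no, membership = as.integer(cmp$membership), idx = idx,
       y = y, x = x, z = z)
}

# labels of the 4 in-plane face neighbours of the given voxels (linear idx)
inPlaneNeighbourIdx <- function(idx, dims) {
  ny <- dims[1]; nx <- dims[2]
  y <- (idx - 1L) %% ny + 1L
  x <- ((idx - 1L) %/% ny) %% nx + 1L
  nb <- c(idx[y > 1L] - 1L, idx[y < ny] + 1L,
          idx[x > 1L] - ny, idx[x < nx] + ny)
  nb
}

touchesMask <- function(idx, maskArr) {
  nb <- inPlaneNeighbourIdx(idx, dim(maskArr))
  any(maskArr[nb])
}

# in-plane dilation of a 3D logical array by a disc of radius rPx
inPlaneDilate <- function(maskArr, rPx) {
  if (rPx <= 0) return(maskArr)
  b <- discBrush(rPx + 0.5)  # offsets with norm <= rPx
  out <- maskArr
  for (k in seq_len(dim(maskArr)[3])) {
    sl <- maskArr[, , k]
    if (any(sl))
      out[, , k] <- EBImage::dilate(matrix(as.integer(sl), nrow(sl)), b) > 0
  }
  out
}

# lazily computed per-slice EDT of the background (electron-lucent) space,
# measured against all labeled voxels
bgEdtCache <- function(bgArr) {
  cache <- vector("list", dim(bgArr)[3])
  function(k) {
    if (is.null(cache[[k]]))
      cache[[k]] <<- edtMatrix(bgArr[, , k])
    cache[[k]]
  }
}

# in-plane width (nm) of a lucent region sampled at the given voxels:
# odd-diameter convention on the background EDT
lucentWidthNm <- function(y, x, z, getEdt, dxy) {
  if (!length(y)) return(0)
  w <- 0
  for (k in unique(z)) {
    e <- getEdt(k)
    sel <- z == k
    w <- max(w, 2 * max(e[cbind(y[sel], x[sel])]) - 1)
  }
  w * dxy
}

requireRole <- function(roleMap, role) {
  if (!length(roleLabels(roleMap, role)))
    stop("required role missing from role map: ", role)
}

eventRow <- function(type, cc, members, vol, extra = list()) {
  sel <- cc$membership == members
  zs <- cc$z[sel]
  row <- data.frame(
    feature_type = type, target_role = NA_character_,
    z_start = min(zs), z_end = max(zs), voxel_count = sum(sel),
    centroid_z = mean(zs), centroid_y = mean(cc$y[sel]),
    centroid_x = mean(cc$x[sel]),
    attachment_state = NA_character_, opening_class = NA_character_,
    max_gap_nm = NA_real_,
    boundary = min(zs) == 1L || max(zs) == nSlices(vol))
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

#' Default detector thresholds
#'
#' Minimum component size, minimum z-persistence, the lucent-gap width at
#' which a peg counts as partially detached, the gap-width window for
#' detachment events and the closing radius defining the endothelial
#' envelope. All overridable through the \code{params} argument of the
#' detectors. These are declared defaults of this implementation, exposed in
#' configuration, not values taken from any particular study.
#'
#' @return named list of defaults: \code{min_voxels} (20), \code{min_z_slices}
#'   (2), \code{lucent_gap_threshold_nm} (12), \code{min_gap_width_nm} (12),
#'   \code{max_gap_width_nm} (90), \code{closing_radius_px} (5).
#' @export
defaultDetectorParams <- function() list(
  min_voxels = 20L, min_z_slices = 2L, lucent_gap_threshold_nm = 12,
  min_gap_width_nm = 12, max_gap_width_nm = 90, closing_radius_px = 5L)

mergeParams <- function(params) {
  p <- defaultDetectorParams()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop("unknown detector parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(params)] <- params
  p
}

# envelope of the capillary wall interior: per-slice closing of
# (endothelium | lumen | BM) with a disc, holes filled. The closing seals
# the BM channel a peg passes through, so the filled interior contains the
# socket, lucent socket spaces and the BM-crossing part of the peg.
endothelialEnvelope <- function(vox, roleMap, closingRadiusPx) {
  ids <- c(roleLabels(roleMap, "endothelium"), roleLabels(roleMap, "lumen"),
           roleLabels(roleMap, "basement_membrane"))
  b <- discBrush(closingRadiusPx + 0.5)
  env <- array(FALSE, dim(vox))
  for (k in seq_len(dim(vox)[3])) {
    sl <- matrix(as.integer(vox[, , k] %in% ids), dim(vox)[1])
    cl <- EBImage::closing(sl, b)
    env[, , k] <- EBImage::fillHull(cl) > 0
  }
  env
}

#' Detect peg-and-socket formations
#'
#' A peg event is a 3D connected component (26-connectivity) of pericyte
#' voxels lying inside the capillary-wall envelope (the hole-filled in-plane
#' morphological closing of endothelium, lumen and BM) — i.e. a pericyte
#' protrusion that has crossed the BM ring into an endothelial invagination.
#' The component must touch the BM in-plane, exceed \code{min_voxels} and
#' persist for \code{min_z_slices} sections. Its state is
#' \code{partially_detached} when the electron-lucent (background) space in
#' contact with it inside the socket forms a shell of in-plane width at least
#' \code{lucent_gap_threshold_nm}, else \code{attached}.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param roleMap a \linkS4class{RoleMap}; \code{pericyte} and
#'   \code{endothelium} must be present.
#' @param params named list overriding \code{\link{defaultDetectorParams}}.
#' @return data.frame of feature events (one row per formation) with an
#'   attribute \code{"lucent_voxels"}: linear indices of socket lucent space
#'   claimed by the events (used to prevent double counting by
#'   \code{\link{detectDetachments}}). Events touching the stack boundary are
#'   flagged in the \code{boundary} column.
#' @export
detectPegSockets <- function(volume, roleMap, params = list()) {
  p <- mergeParams(params)
  requireRole(roleMap, "pericyte"); requireRole(roleMap, "endothelium")
  vox <- voxelData(volume)
  peri <- roleMask(volume, roleMap, "pericyte")
  if (!any(peri)) {
    warning("pericyte role maps to no voxels; no peg-and-socket events",
            call. = FALSE)
    return(structure(emptyEvents(), lucent_voxels = integer()))
  }
  env <- endothelialEnvelope(vox, roleMap, p$closing_radius_px)
  bm <- roleMask(volume, roleMap, "basement_membrane")
  bg <- roleMask(volume, roleMap, "background")
  dxy <- voxelSizeNm(volume)[["dx"]]

  cand <- peri & env
  cc <- connComp3d(cand)
  bgEnv <- bg & env
  ccBg <- connComp3d(bgEnv)
  getEdt <- bgEdtCache(bg)

  events <- emptyEvents()
  lucent <- integer()
  for (m in seq_len(cc$n)) {
    sel <- cc$membership == m
    zs <- cc$z[sel]
    if (sum(sel) < p$min_voxels) next
    if (length(unique(zs)) < p$min_z_slices) next
    vidx <- cc$idx[sel]
    if (!touchesMask(vidx, bm)) next    # must cross the BM ring
    # lucent socket space in contact with the peg
    nb <- inPlaneNeighbourIdx(vidx, dim(vox))
    nbBg <- nb[bgEnv[nb]]
    gapNm <- 0
    if (length(nbBg)) {
      mem <- unique(ccBg$membership[match(nbBg, ccBg$idx)])
      shell <- ccBg$membership %in% mem
      gapNm <- lucentWidthNm(ccBg$y[shell], ccBg$x[shell], ccBg$z[shell],
                             getEdt, dxy)
      lucent <- c(lucent, ccBg$idx[shell])
    }
    state <- if (gapNm >= p$lucent_gap_threshold_nm) "partially_detached"
             else "attached"
    events <- rbind(events, eventRow("peg_socket", cc, m, volume,
      list(attachment_state = state, max_gap_nm = gapNm)))
  }
  structure(events, lucent_voxels = unique(lucent))
}

#' Detect cell-BM detachment events
#'
#' An event is a 3D connected component of electron-lucent (background)
#' voxels lying between the target cell and the basement membrane: the
#' component must be in-plane face-adjacent to both the target role and the
#' BM, have an in-plane width within
#' \code{[min_gap_width_nm, max_gap_width_nm]} (the upper bound separates
#' thin detachment clefts from open extracellular space) and persist for at
#' least \code{min_z_slices} sections. Lucent voxels already claimed by
#' peg-and-socket events can be excluded via \code{excludeVoxels} so no
#' voxel is counted twice.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param roleMap a \linkS4class{RoleMap}.
#' @param targetRole \code{"endothelium"}, \code{"pericyte"} or
#'   \code{"macroglia"}.
#' @param params named list overriding \code{\link{defaultDetectorParams}}.
#' @param excludeVoxels linear voxel indices to remove from the candidate
#'   lucent space (socket interiors; see \code{\link{detectPegSockets}}).
#' @return data.frame of feature events.
#' @export
detectDetachments <- function(volume, roleMap,
                              targetRole = c("endothelium", "pericyte",
                                             "macroglia"),
                              params = list(), excludeVoxels = integer()) {
  targetRole <- match.arg(targetRole)
  p <- mergeParams(params)
  requireRole(roleMap, targetRole); requireRole(roleMap, "basement_membrane")
  vox <- voxelData(volume)
  dxy <- voxelSizeNm(volume)[["dx"]]
  tgt <- roleMask(volume, roleMap, targetRole)
  if (!any(tgt)) {
    warning(targetRole, " role maps to no voxels; no detachment events",
            call. = FALSE)
    return(emptyEvents())
  }
  bm <- roleMask(volume, roleMap, "basement_membrane")
  bg <- roleMask(volume, roleMap, "background")
  reach <- ceiling(p$max_gap_width_nm / dxy)
  cand <- bg & inPlaneDilate(tgt, reach) & inPlaneDilate(bm, reach)
  if (length(excludeVoxels)) cand[excludeVoxels] <- FALSE
  cc <- connComp3d(cand)
  getEdt <- bgEdtCache(bg)

  events <- emptyEvents()
  for (m in seq_len(cc$n)) {
    sel <- cc$membership == m
    zs <- cc$z[sel]
    if (length(unique(zs)) < p$min_z_slices) next
    vidx <- cc$idx[sel]
    if (!touchesMask(vidx, tgt) || !touchesMask(vidx, bm)) next
    width <- lucentWidthNm(cc$y[sel], cc$x[sel], cc$z[sel], getEdt, dxy)
    if (width < p$min_gap_width_nm || width > p$max_gap_width_nm) next
    events <- rbind(events, eventRow("detachment", cc, m, volume,
      list(target_role = targetRole, max_gap_nm = width)))
  }
  events
}

#' Detect endothelial tubules and classify their openings
#'
#' Tubule events are 3D connected components of tubule-labeled voxels.
#' The opening class is decided by in-plane surface adjacency:
#' \code{luminal} if the component touches the lumen, \code{abluminal} if it
#' touches the basement membrane, \code{transendothelial} if both (a
#' complete through-channel), \code{closed} if neither.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param roleMap a \linkS4class{RoleMap}; \code{tubule}, \code{endothelium}
#'   and \code{lumen} roles are required.
#' @param params named list overriding \code{\link{defaultDetectorParams}}
#'   (only \code{min_voxels} applies).
#' @return data.frame of feature events.
#' @export
detectTubules <- function(volume, roleMap, params = list()) {
  p <- mergeParams(params)
  requireRole(roleMap, "tubule"); requireRole(roleMap, "endothelium")
  requireRole(roleMap, "lumen")
  tub <- roleMask(volume, roleMap, "tubule")
  if (!any(tub)) return(emptyEvents())
  lum <- roleMask(volume, roleMap, "lumen")
  bm <- roleMask(volume, roleMap, "basement_membrane")
  cc <- connComp3d(tub)
  events <- emptyEvents()
  for (m in seq_len(cc$n)) {
    sel <- cc$membership == m
    if (sum(sel) < p$min_voxels) next
    vidx <- cc$idx[sel]
    lu <- touchesMask(vidx, lum)
    ab <- touchesMask(vidx, bm)
    cls <- if (lu && ab) "transendothelial" else if (lu) "luminal"
           else if (ab) "abluminal" else "closed"
    events <- rbind(events, eventRow("tubule", cc, m, volume,
      list(opening_class = cls)))
  }
  events
}

#' Feature frequency per 10 micrometres of capillary depth
#'
#' \code{count * 10000 / (nSlices * dzNm)}: the normalisation used for all
#' feature quantifications (capillary depth = slice count times z-step).
#'
#' @param count non-negative integer event count.
#' @param nSlices number of sections (>= 1).
#' @param dzNm section thickness in nm (> 0).
#' @return events per 10 um.
#' @examples
#' frequencyPer10um(6, 300, 100)   # 2.0
#' @export
frequencyPer10um <- function(count, nSlices, dzNm) {
  if (any(nSlices < 1)) stop("nSlices must be >= 1")
  if (any(dzNm <= 0)) stop("dzNm must be > 0")
  count * 10000 / (nSlices * dzNm)
}

#' Full feature summary of one capillary stack
#'
#' Runs the three detectors (pegs first, so socket lucent space is excluded
#' from detachment candidates), tabulates counts by type and subtype and the
#' per-10-um frequencies, and reports the transendothelial tubule count as
#' an explicit row so "no complete transendothelial channels" is a single
#' field check.
#'
#' @param volume a \linkS4class{LabelVolume}.
#' @param roleMap a \linkS4class{RoleMap}.
#' @param params named list overriding \code{\link{defaultDetectorParams}}.
#' @param features which detectors to run.
#' @return A \linkS4class{CapillaryMetrics}.
#' @export
summarizeCapillary <- function(volume, roleMap, params = list(),
                               features = c("peg_socket", "detachment",
                                            "tubule")) {
  events <- emptyEvents()
  lucent <- integer()
  if ("peg_socket" %in% features) {
    ev <- detectPegSockets(volume, roleMap, params)
    lucent <- attr(ev, "lucent_voxels")
    events <- rbind(events, ev)
  }
  if ("detachment" %in% features) {
    for (tr in c("endothelium", "pericyte", "macroglia")) {
      if (!length(roleLabels(roleMap, tr))) next
      events <- rbind(events, detectDetachments(volume, roleMap, tr, params,
                                                excludeVoxels = lucent))
    }
  }
  if ("tubule" %in% features && length(roleLabels(roleMap, "tubule")))
    events <- rbind(events, detectTubules(volume, roleMap, params))

  nz <- nSlices(volume)
  dzNm <- voxelSizeNm(volume)[["dz"]]
  cnt <- function(type, sub = NULL, col = NULL) {
    sel <- events$feature_type == type
    if (!is.null(sub)) sel <- sel & events[[col]] == sub
    sum(sel, na.rm = TRUE)
  }
  cts <- data.frame(
    feature_type = c("peg_socket", "peg_socket", "peg_socket",
                     "detachment", "detachment", "detachment", "detachment",
                     "tubule", "tubule", "tubule", "tubule", "tubule"),
    subtype = c("all", "attached", "partially_detached",
                "all", "endothelium", "pericyte", "macroglia",
                "all", "closed", "luminal", "abluminal", "transendothelial"),
    count = c(cnt("peg_socket"),
              cnt("peg_socket", "attached", "attachment_state"),
              cnt("peg_socket", "partially_detached", "attachment_state"),
              cnt("detachment"),
              cnt("detachment", "endothelium", "target_role"),
              cnt("detachment", "pericyte", "target_role"),
              cnt("detachment", "macroglia", "target_role"),
              cnt("tubule"),
              cnt("tubule", "closed", "opening_class"),
              cnt("tubule", "luminal", "opening_class"),
              cnt("tubule", "abluminal", "opening_class"),
              cnt("tubule", "transendothelial", "opening_class")),
    stringsAsFactors = FALSE)
  cts$freq_per_10um <- frequencyPer10um(cts$count, nz, dzNm)
  new("CapillaryMetrics", depthUm = nz * dzNm / 1000, nSlices = nz,
      counts = cts, events = events)
}
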