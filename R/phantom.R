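# Synthetic capillary phantoms with analytic ground truth.
#
# Geometry is defined in physical nanometres and rasterised by centre
# sampling: a voxel belongs to a structure iff its centre lies in the
# structure's analytic region. The capillary axis is aligned with z.
# Label ids are fixed: 0 background, 1 lumen, 2 endothelium,
# 3 basement membrane, 4 pericyte, 5 macroglia, 6 tubule.

PHANTOM_LABELS <- c(background = 0L, lumen = 1L, endothelium = 2L,
                    basement_membrane = 3L, pericyte = 4L, macroglia = 5L,
                    tubule = 6L)

#' Role map used by all phantoms
#'
#' @return A \linkS4class{RoleMap} with the phantom's fixed label ids
#'   (0 background, 1 lumen, 2 endothelium, 3 basement membrane,
#'   4 pericyte, 5 macroglia, 6 tubule).
#' @export
phantomRoleMap <- function() {
  RoleMap(setNames(names(PHANTOM_LABELS), as.character(PHANTOM_LABELS)))
}

emptyPegs <- function() data.frame(
  z_center = integer(), z_extent_slices = integer(), theta = numeric(),
  radius_nm = numeric(), state = character(), gap_nm = numeric())
emptyDetachments <- function() data.frame(
  target_role = character(), z_center = integer(), z_extent_slices = integer(),
  theta = numeric(), arc_rad = numeric(), gap_nm = numeric())
emptyTubules <- function() data.frame(
  z_center = integer(), z_extent_slices = integer(), theta = numeric(),
  radius_nm = numeric(), opening = character())

#' Planted-feature row constructors
#'
#' Build one-row data frames describing a feature to plant in a phantom;
#' bind rows together and pass them to \code{\link{phantomSpec}}. Angles are
#' radians on the cross-section; z positions are slice indices (1-based).
#'
#' @param z_center centre slice of the feature.
#' @param z_extent_slices number of consecutive slices the feature spans.
#' @param theta angular position (radians). Pegs must lie inside the
#'   pericyte arc; macroglial detachments must lie outside it.
#' @param radius_nm in-plane radius of the peg shaft / tubule.
#' @param state \code{"attached"} or \code{"partially_detached"}: a partially
#'   detached peg is rendered with an electron-lucent (background) shell of
#'   \code{gap_nm} around its tip inside the socket.
#' @param gap_nm lucent gap width (nm) for detached pegs and detachments.
#' @param target_role which cell detaches from the basement membrane:
#'   \code{"endothelium"}, \code{"pericyte"} or \code{"macroglia"}.
#' @param arc_rad angular extent of a detachment gap.
#' @param opening tubule topology: \code{"closed"}, \code{"luminal"},
#'   \code{"abluminal"} or \code{"transendothelial"}.
#' @return one-row data.frame.
#' @name plantedFeatures
NULL

#' @rdname plantedFeatures
#' @export
pegFeature <- function(z_center, theta, z_extent_slices = 3L, radius_nm = 30,
                       state = c("attached", "partially_detached"),
                       gap_nm = 30) {
  state <- match.arg(state)
  data.frame(z_center = as.integer(z_center),
             z_extent_slices = as.integer(z_extent_slices),
             theta = theta, radius_nm = radius_nm, state = state,
             gap_nm = gap_nm)
}

#' @rdname plantedFeatures
#' @export
detachmentFeature <- function(target_role = c("endothelium", "pericyte", "macroglia"),
                              z_center, theta, z_extent_slices = 3L,
                              arc_rad = 0.35, gap_nm = 24) {
  target_role <- match.arg(target_role)
  data.frame(target_role = target_role, z_center = as.integer(z_center),
             z_extent_slices = as.integer(z_extent_slices), theta = theta,
             arc_rad = arc_rad, gap_nm = gap_nm)
}

#' @rdname plantedFeatures
#' @export
tubuleFeature <- function(z_center, theta, z_extent_slices = 3L, radius_nm = 30,
                          opening = c("closed", "luminal", "abluminal",
                                      "transendothelial")) {
  opening <- match.arg(opening)
  data.frame(z_center = as.integer(z_center),
             z_extent_slices = as.integer(z_extent_slices), theta = theta,
             radius_nm = radius_nm, opening = opening)
}

#' Construct a PhantomSpec
#'
#' Defaults describe a scaled-down but geometrically realistic retinal
#' capillary cross-section: 700 nm lumen radius, 250 nm endothelium, a
#' 102 nm basement membrane (17 in-plane voxels at 6 nm/pixel), a pericyte
#' arc covering half the circumference and a macroglial wrap on the rest.
#'
#' @param nSlices number of serial sections.
#' @param voxelSizeNm \code{c(dz, dy, dx)} in nm.
#' @param lumenRadiusNm scalar or per-slice lumen radius.
#' @param endotheliumThicknessNm endothelial band thickness.
#' @param bmBaseNm,bmAmplitudeNm,bmThetaLobes,bmZPeriodNm BM thickness field
#'   \eqn{w(\theta, z) = base + amp \sin(k_\theta\theta + 2\pi z/z_{period})};
#'   \code{bmZPeriodNm = NULL} means one period over the whole stack.
#' @param pericyteArcRad angular interval \code{c(start, end)} of pericyte
#'   coverage (radians; end may exceed \code{2*pi}).
#' @param pericyteThicknessNm,macroglia,macrogliaThicknessNm outer wraps.
#' @param pegs,detachments,tubules planted features; see
#'   \code{\link{pegFeature}}.
#' @param rngSeed integer; the phantom is deterministic, the seed feeds only
#'   optional boundary jitter and cohort sampling.
#' @return validated \linkS4class{PhantomSpec}.
#' @examples
#' sp <- phantomSpec(nSlices = 50)
#' analyticThicknessSummary(sp)
#' @export
phantomSpec <- function(nSlices = 200L, voxelSizeNm = c(100, 6, 6),
                        lumenRadiusNm = 700, endotheliumThicknessNm = 250,
                        bmBaseNm = 102, bmAmplitudeNm = 0, bmThetaLobes = 3L,
                        bmZPeriodNm = NULL, pericyteArcRad = c(0, pi),
                        pericyteThicknessNm = 150, macroglia = TRUE,
                        macrogliaThicknessNm = 150,
                        pegs = emptyPegs(), detachments = emptyDetachments(),
                        tubules = emptyTubules(), rngSeed = 1L) {
  if (is.null(bmZPeriodNm)) bmZPeriodNm <- nSlices * voxelSizeNm[1]
  new("PhantomSpec",
      nSlices = as.integer(nSlices), voxelSizeNm = as.numeric(voxelSizeNm),
      lumenRadiusNm = lumenRadiusNm,
      endotheliumThicknessNm = endotheliumThicknessNm,
      bmBaseNm = bmBaseNm, bmAmplitudeNm = bmAmplitudeNm,
      bmThetaLobes = as.integer(bmThetaLobes), bmZPeriodNm = bmZPeriodNm,
      pericyteArcRad = pericyteArcRad,
      pericyteThicknessNm = pericyteThicknessNm,
      macroglia = macroglia, macrogliaThicknessNm = macrogliaThicknessNm,
      pegs = pegs, detachments = detachments, tubules = tubules,
      rngSeed = as.integer(rngSeed))
}

# --- angular helpers (intervals may wrap) ---

wrap2pi <- function(x) x %% (2 * pi)

circDist <- function(a, b) {
  d <- abs(wrap2pi(a) - wrap2pi(b))
  pmin(d, 2 * pi - d)
}

inArcMat <- function(theta, a0, a1) {
  # membership of angles in the (possibly wrapping) interval [a0, a1)
  wrap2pi(theta - a0) < (a1 - a0)
}

arcContains <- function(a0, a1, c, hw) {
  # is [c-hw, c+hw] inside [a0, a1]?
  off <- wrap2pi(c - a0)
  (off - hw >= 0) && (off + hw <= (a1 - a0))
}

featureZRange <- function(z_center, z_extent) {
  z1 <- z_center - (z_extent - 1L) %/% 2L
  c(z1, z1 + z_extent - 1L)
}

# inventory of (z, theta) footprints used for overlap validation
featureFootprints <- function(object) {
  dx <- object@voxelSizeNm[3]
  rRef <- min(object@lumenRadiusNm) + 0.35 * object@endotheliumThicknessNm
  fp <- list()
  addfp <- function(type, zc, ze, th, hw) {
    zr <- featureZRange(zc, ze)
    fp[[length(fp) + 1L]] <<- list(type = type, z1 = zr[1], z2 = zr[2],
                                   th = th, hw = hw)
  }
  pg <- object@pegs
  for (i in seq_len(nrow(pg))) {
    g <- if (pg$state[i] == "partially_detached") pg$gap_nm[i] else 0
    addfp("peg", pg$z_center[i], pg$z_extent_slices[i], pg$theta[i],
          (pg$radius_nm[i] + g + 4 * dx) / rRef)
  }
  dt <- object@detachments
  for (i in seq_len(nrow(dt)))
    addfp("detachment", dt$z_center[i], dt$z_extent_slices[i], dt$theta[i],
          dt$arc_rad[i] / 2 + 4 * dx / rRef)
  tb <- object@tubules
  for (i in seq_len(nrow(tb)))
    addfp("tubule", tb$z_center[i], tb$z_extent_slices[i], tb$theta[i],
          (tb$radius_nm[i] + 4 * dx) / rRef)
  fp
}

validPhantomSpec <- function(object) {
  msg <- character()
  vs <- object@voxelSizeNm
  if (length(vs) != 3 || any(vs <= 0))
    return("voxel sizes must be three positive values")
  if (abs(vs[2] - vs[3]) > 1e-9)
    msg <- c(msg, "in-plane voxel sizes dy and dx must be equal")
  dx <- vs[3]; dz <- vs[1]
  n <- object@nSlices
  if (n < 1L || n > 10000L) msg <- c(msg, "nSlices must lie in [1, 10000]")
  if (!length(object@lumenRadiusNm) %in% c(1L, n))
    msg <- c(msg, "lumenRadiusNm must be scalar or one value per slice")
  if (any(object@lumenRadiusNm < 10 * dx))
    msg <- c(msg, "lumen radius too small for the grid")
  base <- object@bmBaseNm; amp <- object@bmAmplitudeNm
  if (amp < 0) msg <- c(msg, "bmAmplitudeNm must be >= 0")
  if (base - amp < 2 * dx)
    msg <- c(msg, sprintf(
      "BM shell vanishes: base - amplitude must be >= %g nm (2 in-plane voxels)",
      2 * dx))
  arc <- object@pericyteArcRad
  if (length(arc) != 2 || arc[2] <= arc[1] || arc[2] - arc[1] > 2 * pi + 1e-9)
    msg <- c(msg, "pericyteArcRad must be an increasing interval of width <= 2*pi")
  endoT <- object@endotheliumThicknessNm

  checkZ <- function(zc, ze, what) {
    zr <- featureZRange(zc, ze)
    if (ze < 1L || zr[1] < 1L || zr[2] > n)
      msg <<- c(msg, paste0(what, " z-extent outside the stack"))
  }
  pg <- object@pegs
  for (i in seq_len(nrow(pg))) {
    checkZ(pg$z_center[i], pg$z_extent_slices[i], "peg")
    if (pg$radius_nm[i] < 2 * dx)
      msg <- c(msg, "peg shaft radius must be >= 2 in-plane voxels")
    if (!pg$state[i] %in% c("attached", "partially_detached"))
      msg <- c(msg, paste0("unknown peg state: ", pg$state[i]))
    gap <- if (pg$state[i] == "partially_detached") pg$gap_nm[i] else 0
    if (0.35 * endoT < pg$radius_nm[i] + gap + 2 * dx)
      msg <- c(msg, "peg tip (radius + lucent gap) does not fit in the endothelium")
    rRef <- min(object@lumenRadiusNm) + 0.35 * endoT
    if (!arcContains(arc[1], arc[2], pg$theta[i],
                     (pg$radius_nm[i] + gap) / rRef))
      msg <- c(msg, "peg must lie inside the pericyte arc")
  }
  dt <- object@detachments
  for (i in seq_len(nrow(dt))) {
    checkZ(dt$z_center[i], dt$z_extent_slices[i], "detachment")
    if (dt$gap_nm[i] <= 0 || dt$arc_rad[i] <= 0)
      msg <- c(msg, "detachment gap and arc must be positive")
    tr <- dt$target_role[i]
    if (!tr %in% c("endothelium", "pericyte", "macroglia"))
      msg <- c(msg, paste0("unknown detachment target: ", tr))
    lim <- switch(tr, endothelium = endoT / 2,
                  pericyte = object@pericyteThicknessNm / 2,
                  macroglia = object@macrogliaThicknessNm / 2, Inf)
    if (isTRUE(dt$gap_nm[i] > lim))
      msg <- c(msg, paste0(tr, " detachment gap exceeds half the cell thickness"))
    if (tr == "pericyte" &&
        !arcContains(arc[1], arc[2], dt$theta[i], dt$arc_rad[i] / 2))
      msg <- c(msg, "pericyte detachment must lie inside the pericyte arc")
    if (tr == "macroglia") {
      if (!object@macroglia)
        msg <- c(msg, "macroglial detachment requires macroglia = TRUE")
      else if (!arcContains(wrap2pi(arc[2]), wrap2pi(arc[2]) +
                            (2 * pi - (arc[2] - arc[1])), dt$theta[i],
                            dt$arc_rad[i] / 2))
        msg <- c(msg, "macroglial detachment must lie outside the pericyte arc")
    }
  }
  tb <- object@tubules
  for (i in seq_len(nrow(tb))) {
    checkZ(tb$z_center[i], tb$z_extent_slices[i], "tubule")
    if (!tb$opening[i] %in% c("closed", "luminal", "abluminal", "transendothelial"))
      msg <- c(msg, paste0("unknown tubule opening: ", tb$opening[i]))
    if (tb$radius_nm[i] < dx) msg <- c(msg, "tubule radius below one voxel")
    if (endoT < 2 * (2.5 * dx + tb$radius_nm[i]) + 2 * dx)
      msg <- c(msg, "endothelium too thin to host the tubule")
  }
  # pairwise non-overlap in (z, theta)
  fp <- featureFootprints(object)
  if (length(fp) > 1L) {
    for (i in seq_len(length(fp) - 1L)) for (j in (i + 1L):length(fp)) {
      a <- fp[[i]]; b <- fp[[j]]
      if (a$z1 <= b$z2 && b$z1 <= a$z2 &&
          circDist(a$th, b$th) < a$hw + b$hw)
        msg <- c(msg, sprintf("planted features overlap in (z, arc): %s %d and %s %d",
                              a$type, i, b$type, j))
    }
  }
  if (length(msg)) msg else TRUE
}

#' Analytic mean and maximum of the BM thickness field
#'
#' Quadrature of \eqn{w(\theta, z)} over the full circumference and the
#' stack's slice positions, independent of any rasterisation. With an
#' integer angular wavenumber the mean is exactly the base thickness.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nTheta angular quadrature points.
#' @return named numeric \code{c(mean_nm, max_nm)}.
#' @export
analyticThicknessSummary <- function(spec, nTheta = 2048L) {
  stopifnot(is(spec, "PhantomSpec"))
  base <- spec@bmBaseNm; amp <- spec@bmAmplitudeNm
  if (amp == 0) return(c(mean_nm = base, max_nm = base))
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  z <- (seq_len(spec@nSlices) - 1L) * spec@voxelSizeNm[1]
  phase <- outer(spec@bmThetaLobes * th, 2 * pi * z / spec@bmZPeriodNm, "+")
  w <- base + amp * sin(phase)
  c(mean_nm = mean(w), max_nm = max(w))
}

# distance from every pixel to the radial segment [rA, rB] at angle th0
distToRadialSegment <- function(X, Y, th0, rA, rB) {
  ax <- rA * cos(th0); ay <- rA * sin(th0)
  bx <- rB * cos(th0); by <- rB * sin(th0)
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- ((X - ax) * vx + (Y - ay) * vy) / L2
  t[t < 0] <- 0; t[t > 1] <- 1
  sqrt((X - (ax + t * vx))^2 + (Y - (ay + t * vy))^2)
}

#' Generate a synthetic capillary phantom
#'
#' Rasterises the spec on the anisotropic grid (centre sampling, no z
#' interpolation) and returns the label volume, its role map and the
#' analytic \linkS4class{GroundTruth}. Pegs are rendered as pericyte
#' protrusions crossing the BM into an endothelial invagination; partially
#' detached pegs get a background-labelled lucent shell inside the socket;
#' detachments are background gaps carved between the target cell and the
#' BM; tubules are tubule-labelled rods inside the endothelium touching
#' neither, one, or both surfaces according to their opening class.
#' Deterministic: regeneration yields a bit-identical volume.
#'
#' @param spec a valid \linkS4class{PhantomSpec}.
#' @param imagePx optional in-plane image size (pixels); default auto-fits
#'   the outermost structure plus a margin.
#' @param jitterSdNm optional Gaussian boundary jitter (nm) applied to the
#'   radial coordinate, seeded from \code{spec@rngSeed}; defaults to 0
#'   (clean label volumes).
#' @return list with \code{volume}, \code{roleMap}, \code{groundTruth}.
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 5, lumenRadiusNm = 300,
#'                                   endotheliumThicknessNm = 150,
#'                                   bmBaseNm = 60))
#' ph$groundTruth
#' @export
generatePhantom <- function(spec, imagePx = NULL, jitterSdNm = 0) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  vs <- spec@voxelSizeNm
  dz <- vs[1]; dx <- vs[3]
  n <- spec@nSlices
  Rlum <- rep(spec@lumenRadiusNm, length.out = n)
  endoT <- spec@endotheliumThicknessNm
  base <- spec@bmBaseNm; amp <- spec@bmAmplitudeNm
  periT <- spec@pericyteThicknessNm
  mgT <- if (spec@macroglia) spec@macrogliaThicknessNm else 0
  arc <- spec@pericyteArcRad

  rOuterMax <- max(Rlum) + endoT + base + amp + periT + mgT
  if (is.null(imagePx)) imagePx <- 2L * ceiling(rOuterMax / dx + 6L) + 1L
  npx <- as.integer(imagePx)
  ctr <- (npx + 1) / 2
  idx <- seq_len(npx)
  Y <- matrix((idx - ctr) * dx, npx, npx)         # rows: y
  X <- t(Y)                                       # cols: x
  R0 <- sqrt(X^2 + Y^2)
  TH <- wrap2pi(atan2(Y, X))
  periArc <- inArcMat(TH, arc[1], arc[2])

  if (jitterSdNm > 0) set.seed(spec@rngSeed)

  vox <- array(0L, c(npx, npx, n))
  zr <- function(row) featureZRange(row$z_center, row$z_extent_slices)

  for (k in seq_len(n)) {
    z <- (k - 1L) * dz
    R <- R0
    if (jitterSdNm > 0)
      R <- R + matrix(rnorm(npx * npx, sd = jitterSdNm), npx, npx)
    w <- base + if (amp > 0)
      amp * sin(spec@bmThetaLobes * TH + 2 * pi * z / spec@bmZPeriodNm) else 0
    rl <- Rlum[k]
    rEndo <- rl + endoT
    rBmOut <- rEndo + w
    lab <- matrix(0L, npx, npx)
    lab[R < rl] <- PHANTOM_LABELS[["lumen"]]
    lab[R >= rl & R < rEndo] <- PHANTOM_LABELS[["endothelium"]]
    lab[R >= rEndo & R < rBmOut] <- PHANTOM_LABELS[["basement_membrane"]]
    lab[periArc & R >= rBmOut & R < rBmOut + periT] <- PHANTOM_LABELS[["pericyte"]]
    if (spec@macroglia) {
      mgIn <- rBmOut + ifelse(periArc, periT, 0)
      lab[R >= mgIn & R < mgIn + mgT] <- PHANTOM_LABELS[["macroglia"]]
    }

    # ---- tubules (inside endothelium) ----
    tb <- spec@tubules
    for (i in seq_len(nrow(tb))) {
      zz <- zr(tb[i, ]); if (k < zz[1] || k > zz[2]) next
      rho <- tb$radius_nm[i]; m <- 2.5 * dx
      rin <- switch(tb$opening[i],
                    closed = rl + m + rho, luminal = rl,
                    abluminal = rl + m + rho, transendothelial = rl)
      rout <- switch(tb$opening[i],
                     closed = rEndo - m - rho, luminal = rEndo - m - rho,
                     abluminal = rEndo, transendothelial = rEndo)
      d <- distToRadialSegment(X, Y, tb$theta[i], rin, rout)
      lab[d <= rho & lab == PHANTOM_LABELS[["endothelium"]]] <-
        PHANTOM_LABELS[["tubule"]]
    }

    # ---- detachment gaps (carved as background) ----
    dt <- spec@detachments
    for (i in seq_len(nrow(dt))) {
      zz <- zr(dt[i, ]); if (k < zz[1] || k > zz[2]) next
      g <- dt$gap_nm[i]
      sel <- inArcMat(TH, dt$theta[i] - dt$arc_rad[i] / 2,
                      dt$theta[i] + dt$arc_rad[i] / 2)
      tr <- dt$target_role[i]
      if (tr == "endothelium") {
        lab[sel & lab == PHANTOM_LABELS[["endothelium"]] & R >= rEndo - g] <- 0L
      } else if (tr == "pericyte") {
        lab[sel & lab == PHANTOM_LABELS[["pericyte"]] & R < rBmOut + g] <- 0L
      } else {
        lab[sel & lab == PHANTOM_LABELS[["macroglia"]] & R < rBmOut + g] <- 0L
      }
    }

    # ---- pegs (pericyte protrusions through the BM) ----
    pg <- spec@pegs
    for (i in seq_len(nrow(pg))) {
      zz <- zr(pg[i, ]); if (k < zz[1] || k > zz[2]) next
      th0 <- pg$theta[i]; rho <- pg$radius_nm[i]
      w0 <- base + if (amp > 0)
        amp * sin(spec@bmThetaLobes * th0 + 2 * pi * z / spec@bmZPeriodNm) else 0
      rTip <- rl + 0.35 * endoT
      rBody <- rEndo + w0 + 0.6 * periT
      d <- distToRadialSegment(X, Y, th0, rTip, rBody)
      if (pg$state[i] == "partially_detached") {
        g <- pg$gap_nm[i]
        lab[d > rho & d <= rho + g &
            lab == PHANTOM_LABELS[["endothelium"]]] <- 0L
      }
      lab[d <= rho & lab != PHANTOM_LABELS[["lumen"]]] <-
        PHANTOM_LABELS[["pericyte"]]
    }

    vox[, , k] <- lab
  }

  list(volume = LabelVolume(vox, vs), roleMap = phantomRoleMap(),
       groundTruth = groundTruthFromSpec(spec))
}

#' Ground truth of a phantom, from its spec alone
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{GroundTruth} whose counts equal the planted-feature
#'   inventory exactly and whose frequencies are \code{count * 10 / depthUm}.
#' @export
groundTruthFromSpec <- function(spec) {
  ats <- analyticThicknessSummary(spec)
  depth <- spec@nSlices * spec@voxelSizeNm[1] / 1000
  pg <- spec@pegs; dt <- spec@detachments; tb <- spec@tubules
  cts <- data.frame(
    feature_type = c("peg_socket", "peg_socket", "peg_socket",
                     "detachment", "detachment", "detachment", "detachment",
                     "tubule", "tubule", "tubule", "tubule", "tubule"),
    subtype = c("all", "attached", "partially_detached",
                "all", "endothelium", "pericyte", "macroglia",
                "all", "closed", "luminal", "abluminal", "transendothelial"),
    count = c(nrow(pg), sum(pg$state == "attached"),
              sum(pg$state == "partially_detached"),
              nrow(dt), sum(dt$target_role == "endothelium"),
              sum(dt$target_role == "pericyte"),
              sum(dt$target_role == "macroglia"),
              nrow(tb), sum(tb$opening == "closed"),
              sum(tb$opening == "luminal"), sum(tb$opening == "abluminal"),
              sum(tb$opening == "transendothelial")),
    stringsAsFactors = FALSE)
  cts$freq_per_10um <- cts$count * 10 / depth
  new("GroundTruth", analyticMeanNm = unname(ats["mean_nm"]),
      analyticMaxNm = unname(ats["max_nm"]), depthUm = depth, counts = cts)
}
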