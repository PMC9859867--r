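# Phantom geometry: mirrored vessel trees, MCA boxes, ROI spheres.
#
# All geometry is derived deterministically from the grid shape. The left
# hemisphere is constructed explicitly and the right hemisphere is its exact
# mirror across the midsagittal plane (x -> nx + 1 - x), so a symmetric
# noise-free phantom is voxel-for-voxel mirror-identical.

# Stamp spheres of `radius` voxels along a polyline (relative coordinates),
# recording for each voxel its fractional position u along the path.
stamp_path <- function(grid, rel_points, radius = 1.3) {
  n <- grid
  pts <- t(apply(rel_points, 1, function(p) p * n))
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  # sample every ~0.5 voxels along the path
  samp <- lapply(seq_len(nrow(pts) - 1L), function(i) {
    k <- max(2L, ceiling(seglen[i] / 0.5))
    f <- seq(0, 1, length.out = k)
    cbind(outer(1 - f, pts[i, ]) + outer(f, pts[i + 1L, ]),
          u = (cum[i] + f * seglen[i]) / total)
  })
  samp <- do.call(rbind, samp)
  off <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)
  off <- off[sqrt(off$dx^2 + off$dy^2 + off$dz^2) <= radius, , drop = FALSE]
  vox <- new.env()
  for (i in seq_len(nrow(samp))) {
    c0 <- round(samp[i, 1:3])
    for (j in seq_len(nrow(off))) {
      v <- c0 + as.numeric(off[j, ])
      if (any(v < 1) || any(v > n))
        abort("vessel tree exceeds the phantom grid; enlarge `grid_shape`.",
              class = "collateraltime_config_error")
      key <- paste(v, collapse = ",")
      if (is.null(vox[[key]])) vox[[key]] <- c(v, samp[i, 4])
    }
  }
  m <- do.call(rbind, as.list(vox))
  colnames(m) <- c("x", "y", "z", "u")
  m[order(m[, "x"], m[, "y"], m[, "z"]), , drop = FALSE]
}

# Left-hemisphere subtree polylines in relative grid coordinates (x < 0.5).
left_tree_paths <- function() {
  list(
    arterial = list(
      rbind(c(0.40, 0.32, 0.44), c(0.30, 0.42, 0.50), c(0.24, 0.52, 0.56)),
      rbind(c(0.30, 0.42, 0.50), c(0.22, 0.46, 0.38)),
      rbind(c(0.24, 0.52, 0.56), c(0.20, 0.64, 0.62))
    ),
    venous = list(
      rbind(c(0.22, 0.52, 0.70), c(0.28, 0.66, 0.66)),
      rbind(c(0.28, 0.66, 0.66), c(0.20, 0.72, 0.54))
    )
  )
}

mirror_x <- function(vox, nx) {
  out <- vox
  out[, "x"] <- nx + 1 - vox[, "x"]
  out
}

# Full phantom geometry for a config. Vessel voxel table columns:
# x, y, z, u (path fraction), side ("left"/"right"), compartment ("arterial"/
# "venous"). Also returns brain mask, per-side MCA boxes, and ROI structures.
phantom_geometry <- function(config) {
  n <- config$grid_shape
  nx <- n[1]
  paths <- left_tree_paths()
  tree <- list()
  for (comp in names(paths)) {
    vox <- do.call(rbind, lapply(paths[[comp]], function(p) stamp_path(n, p)))
    # de-duplicate voxels shared between branches, keep smallest u
    key <- paste(vox[, "x"], vox[, "y"], vox[, "z"])
    vox <- vox[order(key, vox[, "u"]), , drop = FALSE]
    vox <- vox[!duplicated(paste(vox[, "x"], vox[, "y"], vox[, "z"])), , drop = FALSE]
    tree[[comp]] <- vox
  }
  sides <- list(left = tree, right = lapply(tree, mirror_x, nx = nx))

  vessels <- dplyr::bind_rows(lapply(names(sides), function(sd) {
    dplyr::bind_rows(lapply(names(sides[[sd]]), function(comp) {
      v <- sides[[sd]][[comp]]
      tibble(x = as.integer(v[, "x"]), y = as.integer(v[, "y"]),
             z = as.integer(v[, "z"]), u = v[, "u"],
             side = sd, compartment = comp)
    }))
  }))
  if (any(vessels$x > nx / 2 & vessels$side == "left"))
    abort("left vessel tree crosses the midsagittal plane.",
          class = "collateraltime_config_error")

  # amplitude weight and onset dispersion along each subtree
  vessels$w <- 1.5 - 1.35 * vessels$u
  vessels$tau <- ifelse(vessels$compartment == "arterial", 2, 3) * vessels$u

  # brain ellipsoid
  ctr <- (n + 1) / 2
  ax <- c(0.45, 0.45, 0.42) * n
  xg <- ((seq_len(n[1]) - ctr[1]) / ax[1])^2
  yg <- ((seq_len(n[2]) - ctr[2]) / ax[2])^2
  zg <- ((seq_len(n[3]) - ctr[3]) / ax[3])^2
  brain <- outer(outer(xg, yg, `+`), zg, `+`) <= 1

  # MCA region boxes: dilated bounding box of each side's vessels, clipped to
  # its hemisphere so the two masks are disjoint by construction
  box_mask <- function(side) {
    v <- vessels[vessels$side == side, ]
    lo <- pmax(c(min(v$x), min(v$y), min(v$z)) - 2L, 1L)
    hi <- pmin(c(max(v$x), max(v$y), max(v$z)) + 2L, n)
    if (side == "left") hi[1] <- min(hi[1], floor(nx / 2)) else lo[1] <- max(lo[1], floor(nx / 2) + 1L)
    m <- array(FALSE, n)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  mca <- list(left = box_mask("left"), right = box_mask("right"))

  # ROI structures: enhancing spheres well outside the MCA boxes; the
  # arterial ROI sits on the non-occluded side (carotid top), the venous ROI
  # posterior near the midline (confluence of sinuses)
  art_side <- if (config$occlusion_side == "left") "right" else "left"
  art_x <- if (art_side == "left") round(0.36 * nx) else round(0.64 * nx)
  roi <- list(
    arterial = list(center = as.integer(c(art_x, round(0.14 * n[2]), round(0.38 * n[3]))),
                    radius_mm = 4.5),
    venous = list(center = as.integer(c(round(0.5 * nx), round(0.90 * n[2]), round(0.50 * n[3]))),
                  radius_mm = 4.5)
  )
  structure_radius_vox <- 2.5
  roi_voxels <- function(center) {
    rng <- lapply(1:3, function(a) (center[a] - 3L):(center[a] + 3L))
    g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
    d <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
    g <- g[d <= structure_radius_vox, ]
    if (any(unlist(g) < 1) || any(g$x > n[1]) || any(g$y > n[2]) || any(g$z > n[3]))
      abort("ROI structure exceeds the phantom grid.", class = "collateraltime_config_error")
    g
  }
  roi_struct <- list(arterial = roi_voxels(roi$arterial$center),
                     venous = roi_voxels(roi$venous$center))

  for (nm in names(roi_struct)) {
    rs <- roi_struct[[nm]]
    idx <- cbind(rs$x, rs$y, rs$z)
    if (any(mca$left[idx]) || any(mca$right[idx]))
      abort("ROI structure overlaps an MCA region mask.", class = "collateraltime_config_error")
  }

  list(vessels = vessels, brain = brain, mca = mca, roi = roi, roi_struct = roi_struct)
}
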