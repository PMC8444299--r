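#' Ball-and-stick rendering style
#'
#' Style block for the snapshot renderer.  Defaults follow the published
#' depiction protocol: 256 x 256 px, zoom 100%, atom spheres at 23% of the
#' van der Waals radius, stick radius 15 milli-Angstrom, bond-perception
#' knobs `min_bond_distance` 0.4 A and `bond_tolerance` 0.8 (recorded for
#' provenance; bonds normally come from the structure, and these are only
#' used when bonds must be perceived from bare coordinates).
#'
#' @param image_px Image side length in pixels (>= 16).
#' @param zoom_pct Zoom as percent of the frame half-width filled by the
#'   molecule's bounding sphere.
#' @param atom_radius_pct_vdw Sphere radius as percent of vdW radius.
#' @param bond_radius_mA Stick radius in milli-Angstrom (15 mA = 0.015 A,
#'   the literal protocol value; sticks thinner than a pixel are drawn one
#'   pixel wide).
#' @param min_bond_distance,bond_tolerance Bond-perception knobs (A /
#'   unitless), recorded in the style.
#' @param color_map Named list element -> RGB in \[0,1\] (CPK scheme).
#' @param background Background RGB.
#' @return A `render_style` list.
#' @export
render_style <- function(image_px = 256L, zoom_pct = 100,
                         atom_radius_pct_vdw = 23, bond_radius_mA = 15,
                         min_bond_distance = 0.4, bond_tolerance = 0.8,
                         color_map = cpk_colors(), background = c(1, 1, 1)) {
  stopifnot(image_px >= 16L, zoom_pct > 0,
            atom_radius_pct_vdw > 0, atom_radius_pct_vdw <= 100,
            bond_radius_mA >= 0, length(background) == 3L)
  structure(list(image_px = as.integer(image_px), zoom_pct = zoom_pct,
                 atom_radius_pct_vdw = atom_radius_pct_vdw,
                 bond_radius_mA = bond_radius_mA,
                 min_bond_distance = min_bond_distance,
                 bond_tolerance = bond_tolerance,
                 color_map = color_map, background = as.numeric(background)),
            class = "render_style")
}

#' Standard CPK element colors
#'
#' @return Named list of RGB triplets in \[0, 1\].
#' @export
cpk_colors <- function() {
  lapply(list(
    H = c(255, 255, 255), C = c(144, 144, 144), N = c(48, 80, 248),
    O = c(255, 13, 13), F = c(144, 224, 80), Cl = c(31, 240, 31),
    S = c(255, 255, 48), P = c(255, 128, 0), Br = c(166, 41, 41),
    I = c(148, 0, 148), default = c(255, 20, 147)), function(v) v / 255)
}

# Bondi van der Waals radii (Angstrom)
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
    S = 1.80, P = 1.80, Br = 1.85, I = 1.98, default = 1.70)
}

lookup <- function(table, elements) {
  idx <- match(elements, names(table))
  idx[is.na(idx)] <- match("default", names(table))
  idx
}

#' Rotation matrix for a pose
#'
#' Intrinsic rotations applied in x-then-y-then-z order, right-handed:
#' `R = Rz(rz) Ry(ry) Rx(rx)` acting on column vectors.
#'
#' @param pose Numeric triple `(rx, ry, rz)` in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(pose) {
  a <- pose * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation lattice for a snapshot set
#'
#' All pose triples `(i*theta, j*theta, k*theta)` with `i, j, k` in
#' `0..floor(360/theta) - 1`, enumerated row-major over (i, j, k) (the
#' z multiple varies fastest), giving `floor(360/theta)^3` poses.
#'
#' @param theta_deg Angle increment in degrees, 0 < theta <= 360.
#' @return A `rotation_grid` list with `theta_deg` and a poses matrix
#'   (columns `rx`, `ry`, `rz`).
#' @export
rotation_grid <- function(theta_deg) {
  if (!is.finite(theta_deg) || theta_deg <= 0 || theta_deg > 360) {
    stop("theta must satisfy 0 < theta <= 360", call. = FALSE)
  }
  k <- floor(360 / theta_deg)
  mult <- (seq_len(k) - 1) * theta_deg
  eg <- expand.grid(rz = mult, ry = mult, rx = mult,
                    KEEP.OUT.ATTRS = FALSE)
  poses <- as.matrix(eg[, c("rx", "ry", "rz")])
  rownames(poses) <- NULL
  structure(list(theta_deg = theta_deg, poses = poses),
            class = "rotation_grid")
}

render_scale <- function(conf, style) {
  # bounding sphere at the identity pose; rotation-invariant by
  # construction, so one scale serves every pose of the molecule
  rad <- vdw_radii()
  r_draw <- rad[lookup(rad, conf$elements)] * style$atom_radius_pct_vdw / 100
  centered <- sweep(conf$coords, 2L, colMeans(conf$coords))
  rmax <- max(sqrt(rowSums(centered^2)) + r_draw)
  if (rmax <= 0) rmax <- 1
  half_width <- rmax / (style$zoom_pct / 100)
  (style$image_px / 2) / half_width
}

#' Render one pose of a conformer as an RGB raster
#'
#' Orthographic projection along -z after rotating the centred coordinates
#' by the pose.  Atoms are Lambert-shaded spheres (light along +z) in CPK
#' colors; bonds are sticks split at the midpoint and colored by their
#' atoms.  Hidden surfaces are resolved by a z-buffer.  The scale is fixed
#' per molecule (bounding-sphere fit at the identity pose), so all poses
#' of one molecule share it.  Fully deterministic.
#'
#' @param conf A [conformer3d()].
#' @param pose Numeric triple `(rx, ry, rz)` in degrees.
#' @param style A [render_style()].
#' @return Numeric array `image_px x image_px x 3` with values in \[0,1\].
#' @export
render_pose <- function(conf, pose = c(0, 0, 0), style = render_style()) {
  px <- style$image_px
  coords <- sweep(conf$coords, 2L, colMeans(conf$coords))
  s <- render_scale(conf, style)
  R <- rotation_matrix(pose)
  xyz <- coords %*% t(R)
  rad_tab <- vdw_radii()
  cols <- style$color_map
  r_draw <- rad_tab[lookup(rad_tab, conf$elements)] *
    style$atom_radius_pct_vdw / 100
  u <- px / 2 + xyz[, 1] * s         # pixel-space centers
  v <- px / 2 - xyz[, 2] * s
  z <- xyz[, 3]
  img_r <- matrix(style$background[1], px, px)
  img_g <- matrix(style$background[2], px, px)
  img_b <- matrix(style$background[3], px, px)
  zbuf <- matrix(-Inf, px, px)
  ambient <- 0.3
  pc <- seq_len(px) - 0.5            # pixel-center coordinates

  paint <- function(rows, cols_idx, mask, zval, rgb) {
    sel <- which(mask & zval > zbuf[cbind(rep(rows, times = length(cols_idx)),
                                          rep(cols_idx, each = length(rows)))])
    if (!length(sel)) return(invisible())
    ij <- cbind(rep(rows, times = length(cols_idx))[sel],
                rep(cols_idx, each = length(rows))[sel])
    zbuf[ij] <<- zval[sel]
    img_r[ij] <<- rgb[[1L]][sel]
    img_g[ij] <<- rgb[[2L]][sel]
    img_b[ij] <<- rgb[[3L]][sel]
  }

  # sticks first is unnecessary: the z-buffer orders everything
  bonds <- conf$bonds
  r_stick_px <- max(style$bond_radius_mA / 1000 * s, 0.6)
  if (nrow(bonds) > 0L) {
    for (bi in seq_len(nrow(bonds))) {
      i <- bonds$i[bi]; j <- bonds$j[bi]
      mid <- c((u[i] + u[j]) / 2, (v[i] + v[j]) / 2, (z[i] + z[j]) / 2)
      for (half in 1:2) {
        a <- if (half == 1L) i else j
        p1 <- c(u[a], v[a], z[a]); p2 <- mid
        lo_c <- max(1L, floor(min(p1[1], p2[1]) - r_stick_px))
        hi_c <- min(px, ceiling(max(p1[1], p2[1]) + r_stick_px))
        lo_r <- max(1L, floor(min(p1[2], p2[2]) - r_stick_px))
        hi_r <- min(px, ceiling(max(p1[2], p2[2]) + r_stick_px))
        if (lo_c > hi_c || lo_r > hi_r) next
        rows <- lo_r:hi_r; cls <- lo_c:hi_c
        dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
        len2 <- dx * dx + dy * dy
        X <- matrix(pc[cls], nrow = length(rows), ncol = length(cls),
                    byrow = TRUE)
        Y <- matrix(pc[rows], nrow = length(rows), ncol = length(cls))
        tt <- if (len2 == 0) matrix(0, length(rows), length(cls)) else
          pmin(pmax(((X - p1[1]) * dx + (Y - p1[2]) * dy) / len2, 0), 1)
        d2 <- (X - (p1[1] + tt * dx))^2 + (Y - (p1[2] + tt * dy))^2
        mask <- d2 <= r_stick_px^2
        zval <- p1[3] + tt * (p2[3] - p1[3])
        rgbcol <- cols[[lookup(cols, conf$elements[a])]] * 0.55
        paint(rows, cls, mask, zval,
              list(rgbcol[1] + 0 * zval, rgbcol[2] + 0 * zval,
                   rgbcol[3] + 0 * zval))
      }
    }
  }

  for (ai in order(z)) {             # order irrelevant given z-buffer
    r_px <- r_draw[ai] * s
    lo_c <- max(1L, floor(u[ai] - r_px)); hi_c <- min(px, ceiling(u[ai] + r_px))
    lo_r <- max(1L, floor(v[ai] - r_px)); hi_r <- min(px, ceiling(v[ai] + r_px))
    if (lo_c > hi_c || lo_r > hi_r) next
    rows <- lo_r:hi_r; cls <- lo_c:hi_c
    dx <- matrix(pc[cls] - u[ai], nrow = length(rows), ncol = length(cls),
                 byrow = TRUE)
    dy <- matrix(pc[rows] - v[ai], nrow = length(rows), ncol = length(cls))
    d2 <- dx * dx + dy * dy
    mask <- d2 <= r_px^2
    rel <- pmin(d2 / (r_px^2), 1)
    nz <- sqrt(1 - rel)              # surface normal z = Lambert term
    zval <- z[ai] + nz * r_draw[ai]
    shade <- ambient + (1 - ambient) * nz
    rgbcol <- cols[[lookup(cols, conf$elements[ai])]]
    paint(rows, cls, mask, zval,
          list(rgbcol[1] * shade, rgbcol[2] * shade, rgbcol[3] * shade))
  }

  array(c(img_r, img_g, img_b), dim = c(px, px, 3L))
}

#' Snapshot set: render a conformer at every pose of a rotation lattice
#'
#' @param conf A [conformer3d()].
#' @param theta_deg Angle increment in degrees (the published protocol
#'   uses 65, 85, 105 or 145).
#' @param style A [render_style()].
#' @param molecule_id Id recorded in the set.
#' @return A `snapshot_set` list: `molecule_id`, `theta_deg`, `poses`,
#'   `images` (list of rasters, pose order).
#' @export
snapshot_molecule <- function(conf, theta_deg = 145, style = render_style(),
                              molecule_id = "mol") {
  grid <- rotation_grid(theta_deg)
  images <- lapply(seq_len(nrow(grid$poses)), function(k) {
    render_pose(conf, grid$poses[k, ], style)
  })
  structure(list(molecule_id = molecule_id, theta_deg = theta_deg,
                 poses = grid$poses, images = images),
            class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  cat("snapshot set for", x$molecule_id, ":", length(x$images),
      "poses at theta =", x$theta_deg, "deg\n")
  invisible(x)
}

#' Write snapshot sets to a PNG directory dataset
#'
#' Layout is `<split>/<class>/<molecule>_<pose>.png` with a manifest CSV
#' (`molecule_id`, `pose_index`, `path`, `class`, `split`) written at
#' `out_dir/manifest.csv`.
#'
#' @param snapshots List of `snapshot_set`s.
#' @param labels Named factor/character (`low`/`high`) covering every
#'   molecule id.
#' @param out_dir Output directory (created).
#' @param split Optional named `"train"`/`"test"`/... vector; defaults to
#'   a single `"all"` split.
#' @return The manifest data.frame, invisibly written to disk.
#' @export
write_image_dataset <- function(snapshots, labels, out_dir, split = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(snapshots) == 0L) {
    warning("no snapshots to write; manifest is empty", call. = FALSE)
    manifest <- data.frame(molecule_id = character(), pose_index = integer(),
                           path = character(), class = character(),
                           split = character(), stringsAsFactors = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    return(manifest)
  }
  ids <- vapply(snapshots, `[[`, "", "molecule_id")
  lab <- stats::setNames(as.character(labels), names(labels))
  missing <- setdiff(ids, names(lab))
  if (length(missing)) {
    stop("no label for molecule(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(split)) split <- stats::setNames(rep("all", length(ids)), ids)
  rows <- vector("list", length(snapshots))
  for (k in seq_along(snapshots)) {
    ss <- snapshots[[k]]
    cls <- lab[[ss$molecule_id]]
    sp <- split[[ss$molecule_id]]
    dir.create(file.path(out_dir, sp, cls), showWarnings = FALSE,
               recursive = TRUE)
    paths <- file.path(sp, cls,
                       sprintf("%s_%03d.png", ss$molecule_id,
                               seq_along(ss$images)))
    for (m in seq_along(ss$images)) {
      png::writePNG(ss$images[[m]], file.path(out_dir, paths[m]))
    }
    rows[[k]] <- data.frame(molecule_id = ss$molecule_id,
                            pose_index = seq_along(ss$images),
                            path = paths, class = cls, split = sp,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Build an in-memory image dataset from snapshot sets
#'
#' The training-side container for the image branch: the rasters plus a
#' per-image info table.  [write_image_dataset()]/[read_image_dataset()]
#' round-trip the same structure through disk.
#'
#' @param snapshots List of `snapshot_set`s.
#' @param labels Named `low`/`high` vector over the molecule ids.
#' @return An `image_dataset` list: `images` (list of arrays), `info`
#'   (data.frame `molecule_id`, `pose_index`, `class`).
#' @export
image_dataset <- function(snapshots, labels) {
  lab <- stats::setNames(as.character(labels), names(labels))
  images <- list(); rows <- list()
  for (ss in snapshots) {
    cls <- if (ss$molecule_id %in% names(lab)) lab[[ss$molecule_id]]
           else NA_character_
    images <- c(images, ss$images)
    rows[[length(rows) + 1L]] <-
      data.frame(molecule_id = ss$molecule_id,
                 pose_index = seq_along(ss$images),
                 class = cls, stringsAsFactors = FALSE)
  }
  structure(list(images = images, info = do.call(rbind, rows)),
            class = "image_dataset")
}

#' Read an image dataset back from a manifest
#'
#' @param dir Directory written by [write_image_dataset()].
#' @return An `image_dataset`.
#' @export
read_image_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) png::readPNG(file.path(dir, p)))
  structure(list(images = images,
                 info = manifest[, c("molecule_id", "pose_index", "class")]),
            class = "image_dataset")
}
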