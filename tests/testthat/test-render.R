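test_that("rotation_grid enumerates floor(360/theta)^3 poses", {
  g360 <- rotation_grid(360)
  expect_equal(nrow(g360$poses), 1L)
  expect_equal(unname(g360$poses[1, ]), c(0, 0, 0))
  g145 <- rotation_grid(145)
  expect_equal(nrow(g145$poses), 8L)
  # explicit enumeration: multiples 0 and 145 on each axis
  expect_setequal(unique(as.vector(g145$poses)), c(0, 145))
  expect_equal(nrow(rotation_grid(105)$poses), 27L)
  expect_equal(nrow(rotation_grid(85)$poses), 64L)
  expect_equal(nrow(rotation_grid(65)$poses), 125L)
  # row-major over (i, j, k): z varies fastest
  expect_equal(unname(g145$poses[2, ]), c(0, 0, 145))
  expect_error(rotation_grid(0), "theta")
  expect_error(rotation_grid(400), "theta")
})

test_that("a single atom renders as a centred, 4-fold symmetric disc", {
  one <- conformer3d("C", matrix(0, 1, 3),
                     data.frame(i = integer(), j = integer(),
                                order = integer()))
  st <- fx_style()
  img <- render_pose(one, c(0, 0, 0), st)
  expect_equal(dim(img), c(64, 64, 3))
  expect_gt(sum(img < 1), 0)
  expect_equal(img, img[64:1, , , drop = FALSE], ignore_attr = TRUE)
  expect_equal(img, img[, 64:1, , drop = FALSE], ignore_attr = TRUE)
  # determinism: byte-identical on repeat
  expect_identical(img, render_pose(one, c(0, 0, 0), st))
  # rotation invariance of a sphere: all poses identical
  ss <- snapshot_molecule(one, 145, st)
  expect_equal(length(ss$images), 8L)
  for (im in ss$images) expect_identical(im, ss$images[[1]])
})

test_that("a 90-degree z rotation swaps a diatomic's image axes", {
  dia <- conformer3d(c("C", "O"),
                     rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                     data.frame(i = 1L, j = 2L, order = 1L))
  st <- fx_style()
  center_of <- function(img, channel_test) {
    # centroid of pixels matching a color predicate
    hit <- which(channel_test(img), arr.ind = TRUE)
    colMeans(hit)
  }
  is_red <- function(img) img[, , 1] > 0.5 & img[, , 2] < 0.3
  i0 <- render_pose(dia, c(0, 0, 0), st)
  i90 <- render_pose(dia, c(0, 0, 90), st)
  c0 <- center_of(i0, is_red)
  c90 <- center_of(i90, is_red)
  # oracle: rotating (0.6, 0, 0) by Rz(90) gives (0, 0.6, 0), i.e. the O
  # atom moves from horizontal offset to vertical offset
  expect_gt(abs(c0[["col"]] - 32.5), 5)     # off-centre horizontally
  expect_lt(abs(c0[["row"]] - 32.5), 1.5)   # centred vertically
  expect_gt(abs(c90[["row"]] - 32.5), 5)    # off-centre vertically
  expect_lt(abs(c90[["col"]] - 32.5), 1.5)  # centred horizontally
})

test_that("rendering a pose equals rendering pre-rotated coordinates", {
  confs <- fx_conformers()
  st <- fx_style()
  set.seed(31)
  for (id in sample(names(confs), 4)) {
    cf <- confs[[id]]
    pose <- runif(3, 0, 360)
    R <- rotation_matrix(pose)
    cf_rot <- cf
    cf_rot$coords <- cf$coords %*% t(R)
    expect_equal(render_pose(cf, pose, st),
                 render_pose(cf_rot, c(0, 0, 0), st), tolerance = 1e-9)
  }
})

test_that("snapshot sets have one image per pose at constant scale", {
  cf <- fx_conformers()[["fx_aspirin"]]
  st <- fx_style()
  ss <- snapshot_molecule(cf, 145, st, "fx_aspirin")
  expect_equal(length(ss$images), nrow(rotation_grid(145)$poses))
  # theta = 360 reduces to the identity rendering
  s1 <- snapshot_molecule(cf, 360, st)
  expect_identical(s1$images[[1]], render_pose(cf, c(0, 0, 0), st))
  # determinism of the whole set
  ss2 <- snapshot_molecule(cf, 145, st, "fx_aspirin")
  expect_identical(ss$images, ss2$images)
})

test_that("write_image_dataset lays out files and a consistent manifest", {
  lib <- fx_library()[1:2, ]
  snaps <- fx_snapshots()[lib$id]
  labels <- setNames(as.character(lib$label), lib$id)
  out <- tempfile("imgds")
  manifest <- write_image_dataset(snaps, labels, out)
  expect_equal(nrow(manifest), 16L)               # 2 molecules x 8 poses
  expect_true(all(file.exists(file.path(out, manifest$path))))
  # class counts match label distribution x poses, recounted from disk
  on_disk <- list.files(out, pattern = "\\.png$", recursive = TRUE)
  expect_equal(length(on_disk), 16L)
  cls_disk <- table(basename(dirname(on_disk)))
  expected <- table(rep(as.character(lib$label), each = 8L))
  expect_equal(as.vector(cls_disk[names(expected)]), as.vector(expected))
  # round-trip
  back <- read_image_dataset(out)
  expect_equal(length(back$images), 16L)
  expect_equal(dim(back$images[[1]]), c(64, 64, 3))
  expect_equal(back$info$class, manifest$class)
  # missing label is fatal and names the molecule
  expect_error(write_image_dataset(snaps, labels[1], tempfile()),
               lib$id[2])
  expect_warning(m0 <- write_image_dataset(list(), labels, tempfile()),
                 "empty")
  expect_equal(nrow(m0), 0L)
  unlink(out, recursive = TRUE)
})
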