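test_that("TIFF + sidecar round trip is bit-exact (YAML and JSON)", {
  ph <- generatePhantom(smallSpec(3L))
  for (ext in c("yaml", "json")) {
    tf <- tempfile(fileext = ".tif")
    sc <- tempfile(fileext = paste0(".", ext))
    writeLabelStack(ph$volume, tf, ph$roleMap, sc)
    # featureless phantom: tubule role is mapped but unused -> warning only
    back <- suppressWarnings(readLabelStack(tf, sc))
    expect_identical(voxelData(back$volume), voxelData(ph$volume))
    expect_equal(voxelSizeNm(back$volume), voxelSizeNm(ph$volume),
                 ignore_attr = TRUE)
    expect_identical(roles(back$roleMap), roles(ph$roleMap))
  }
})

test_that("labels above 255 are written 16-bit without clipping", {
  vox <- array(0L, c(6, 6, 2))
  vox[3, 3, 1] <- 300L
  vol <- LabelVolume(vox)
  rm <- RoleMap(c(`0` = "background", `300` = "basement_membrane"))
  tf <- tempfile(fileext = ".tif")
  sc <- tempfile(fileext = ".json")
  writeLabelStack(vol, tf, rm, sc)
  back <- readLabelStack(tf, sc)
  expect_identical(voxelData(back$volume), vox)
})

test_that("page order k maps to slice z = k", {
  vox <- array(0L, c(4, 4, 3))
  vox[, , 2] <- 1L
  vox[, , 3] <- 2L
  rm <- RoleMap(c(`0` = "background", `1` = "lumen", `2` = "endothelium"))
  tf <- tempfile(fileext = ".tif")
  sc <- tempfile(fileext = ".yaml")
  writeLabelStack(LabelVolume(vox), tf, rm, sc)
  back <- readLabelStack(tf, sc)
  expect_equal(unique(as.vector(voxelData(back$volume)[, , 2])), 1L)
  expect_equal(unique(as.vector(voxelData(back$volume)[, , 3])), 2L)
})

test_that("sidecar problems are reported: duplicates, unknown roles, bad ids", {
  vox <- array(0L, c(4, 4, 2))
  vox[2, 2, 1] <- 1L
  tf <- tempfile(fileext = ".tif")
  writeLabelStack(LabelVolume(vox), tf,
                  RoleMap(c(`0` = "background", `1` = "lumen")),
                  tempfile(fileext = ".json"))
  dup <- tempfile(fileext = ".json")
  writeLines('{"voxel_size_nm":[100,6,6],"roles":{"0":"background","1":"lumen","1":"pericyte"}}',
             dup)
  expect_error(readLabelStack(tf, dup), "duplicate label id")
  bad <- tempfile(fileext = ".json")
  writeLines('{"voxel_size_nm":[100,6,6],"roles":{"0":"background","1":"not_a_role"}}',
             bad)
  expect_error(readLabelStack(tf, bad), "unknown role")
  faraway <- tempfile(fileext = ".json")
  writeLines('{"voxel_size_nm":[100,6,6],"roles":{"0":"background","1":"lumen","9":"pericyte"}}',
             faraway)
  expect_warning(readLabelStack(tf, faraway), "absent from the stack")
  unmapped <- tempfile(fileext = ".json")
  writeLines('{"voxel_size_nm":[100,6,6],"roles":{"0":"background"}}',
             unmapped)
  expect_error(readLabelStack(tf, unmapped), "missing from the role map")
  nosize <- tempfile(fileext = ".json")
  writeLines('{"roles":{"0":"background","1":"lumen"}}', nosize)
  expect_warning(res <- readLabelStack(tf, nosize), "assuming")
  expect_equal(unname(voxelSizeNm(res$volume)), c(100, 6, 6))
})

test_that("missing files, unequal pages and bad output paths error", {
  expect_error(readLabelStack("no/such.tif", "no/such.yaml"), "not found")
  tf <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 5, 5)), tf,
                  bits.per.sample = 8)
  sc <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(voxel_size_nm = c(100, 6, 6),
                        roles = list(`0` = "background")), sc)
  expect_error(readLabelStack(tf, sc), "unequal shape")
  ph <- generatePhantom(smallSpec(2L))
  expect_error(
    writeLabelStack(ph$volume, file.path(tempdir(), "nope", "x.tif"),
                    ph$roleMap, tempfile(fileext = ".yaml")),
    "directory does not exist")
})

test_that("role masks partition the volume and respect the mapping", {
  ph <- generatePhantom(richSpec(10L))
  total <- array(0L, dim(ph$volume))
  for (r in NVU_ROLES) total <- total + roleMask(ph$volume, ph$roleMap, r)
  expect_true(all(total == 1L))
  empty <- LabelVolume(array(0L, c(5, 5, 2)))
  expect_false(any(roleMask(empty, phantomRoleMap(), "basement_membrane")))
  expect_error(roleMask(empty, phantomRoleMap(), "mitochondrion"),
               "unknown role")
})

test_that("RoleMap validity enforces label 0 = background and unique ids", {
  expect_error(RoleMap(c(`1` = "lumen")), "label 0")
  expect_error(RoleMap(c(`0` = "lumen")), "label 0")
  expect_silent(RoleMap(c(`0` = "background")))
})
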