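# Reading/writing stacks, slice quality control, and pre-smoothing.

make_stack <- function(nz = 6, ny = 16, nx = 16, bit_depth = 8L, seed = 1) {
  microglia3d:::with_seed(seed, {
    maxv <- 2^bit_depth - 1
    vox <- array(as.numeric(sample(0:maxv, 2 * nz * ny * nx, replace = TRUE)),
                 dim = c(2, nz, ny, nx))
    image_stack(vox, c(0.4, 0.2, 0.2), bit_depth = bit_depth)
  })
}

test_that("stack writer/reader round-trips voxels and metadata bit-exactly", {
  stk <- make_stack(nz = 16, ny = 64, nx = 64, bit_depth = 16L)
  path <- file.path(tempdir(), "roundtrip.tif")
  write_stack(stk, path)
  back <- read_stack(path)
  expect_identical(back$voxels, stk$voxels)
  expect_equal(back$voxel_size, c(0.4, 0.2, 0.2))
  expect_identical(back$bit_depth, 16L)
  expect_identical(back$channel_roles, stk$channel_roles)
  over <- read_stack(path, voxel_size_override = c(1, 1, 1))
  expect_equal(over$voxel_size, c(1, 1, 1))
  unlink(c(path, paste0(path, ".json")))
})

test_that("single-channel files are rejected unless supplied as a pair", {
  m <- matrix(runif(64), 8, 8)
  path <- file.path(tempdir(), "single.tif")
  tiff::writeTIFF(list(m, m), path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(n_channels = 1, n_slices = 2,
                            voxel_size_um = c(0.4, 0.2, 0.2),
                            bit_depth = 8),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "nuclear channel missing")
  unlink(c(path, paste0(path, ".json")))
})

test_that("a channel pair is assembled into one two-channel stack", {
  stk <- make_stack(nz = 4, ny = 8, nx = 8)
  p1 <- file.path(tempdir(), "mem.tif")
  p2 <- file.path(tempdir(), "nuc.tif")
  for (pc in list(list(p1, 1L), list(p2, 2L))) {
    one <- stk
    one$voxels <- stk$voxels[pc[[2]], , , , drop = FALSE]
    pages <- lapply(seq_len(4), function(z) {
      m <- one$voxels[1, z, , ]
      dim(m) <- c(8, 8)
      m / 255
    })
    tiff::writeTIFF(pages, pc[[1]], bits.per.sample = 8L,
                    compression = "none")
  }
  pair <- read_stack(c(p1, p2), voxel_size_override = c(0.4, 0.2, 0.2))
  expect_identical(pair$voxels, stk$voxels)
  expect_error(read_stack(c(p1, p2)), "voxel size")
  unlink(c(p1, p2))
})

test_that("OME-XML metadata is parsed for layout and physical voxel size", {
  ome <- paste0(
    '<?xml version="1.0"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYCZT" ',
    'Type="uint8" SizeX="64" SizeY="64" SizeC="2" SizeZ="16" SizeT="1" ',
    'PhysicalSizeX="0.2" PhysicalSizeY="0.2" PhysicalSizeZ="0.4"/>',
    '</Image></OME>')
  md <- microglia3d:::parse_ome_metadata(ome)
  expect_identical(md$size_c, 2L)
  expect_identical(md$size_z, 16L)
  expect_equal(unname(md$physical_size), c(0.4, 0.2, 0.2))
  expect_identical(md$bit_depth, 8L)
  expect_null(microglia3d:::parse_ome_metadata("not xml"))
})

test_that("slice correlations are 1 for identical, -1 for inverted slices", {
  base <- matrix(seq(0, 255, length.out = 256), 16, 16)
  vox <- array(0, dim = c(2, 3, 16, 16))
  for (z in 1:3) vox[1, z, , ] <- base
  vox[2, , , ] <- 10
  stk <- image_stack(vox, c(0.4, 0.2, 0.2))
  expect_equal(slice_correlation_profile(stk), c(1, 1))
  vox2 <- vox
  vox2[1, 2, , ] <- 255 - base
  stk2 <- image_stack(vox2, c(0.4, 0.2, 0.2))
  expect_equal(slice_correlation_profile(stk2), c(-1, -1))
})

test_that("noise next to structure correlates weakly; constant slices warn", {
  stk <- microglia3d:::with_seed(11, {
    structured <- outer(sin(seq_len(64) / 4), cos(seq_len(64) / 5)) * 100 + 120
    vox <- array(0, dim = c(2, 2, 64, 64))
    vox[1, 1, , ] <- round(structured)
    vox[1, 2, , ] <- sample(0:255, 64 * 64, replace = TRUE)
    vox[2, , , ] <- 5
    image_stack(vox, c(0.4, 0.2, 0.2))
  })
  expect_lt(abs(slice_correlation_profile(stk)[1]), 0.3)
  con <- stk
  con$voxels[1, 2, , ] <- 7
  expect_warning(p <- slice_correlation_profile(con), "constant")
  expect_equal(p[1], 0)
})

# structured 10-slice stack whose z-profile is smooth, with optional noise
# replacement at the ends
structured_stack <- function(noise_slices = integer(), seed = 5) {
  microglia3d:::with_seed(seed, {
    nz <- 10L
    base <- outer(sin(seq_len(48) / 3), cos(seq_len(48) / 4))
    vox <- array(0, dim = c(2, nz, 48, 48))
    for (z in seq_len(nz)) {
      vox[1, z, , ] <- round(120 + 90 * base * (1 + 0.02 * z) +
                               rnorm(48 * 48, 0, 4))
    }
    for (z in noise_slices) {
      vox[1, z, , ] <- sample(0:255, 48 * 48, replace = TRUE)
    }
    vox[2, , , ] <- 10
    vox[] <- pmax(0, pmin(255, vox))
    image_stack(vox, c(0.4, 0.2, 0.2))
  })
}

test_that("QC trims exactly the noise-replaced end slices and nothing else", {
  stk <- structured_stack(noise_slices = c(1L, 10L))
  res <- trim_low_quality_slices(stk, threshold = 0.78)
  expect_identical(res$qc$retained_range, c(2L, 9L))
  expect_identical(res$qc$removed_top, 1L)
  expect_identical(res$qc$removed_bottom, 1L)
  expect_length(res$qc$per_pair_correlation, 9L)
  expect_true(all(res$qc$per_pair_correlation >= -1 &
                  res$qc$per_pair_correlation <= 1))
  # retained voxel data are bit-identical to the input
  expect_identical(res$stack$voxels, stk$voxels[, 2:9, , , drop = FALSE])
  # idempotence
  again <- trim_low_quality_slices(res$stack, threshold = 0.78)
  expect_identical(again$qc$removed_top, 0L)
  expect_identical(again$qc$removed_bottom, 0L)
  expect_identical(again$stack$voxels, res$stack$voxels)
})

test_that("QC leaves a fully correlated stack unchanged and rejects noise", {
  clean <- structured_stack()
  res <- trim_low_quality_slices(clean)
  expect_identical(res$qc$retained_range, c(1L, 10L))
  noise <- structured_stack(noise_slices = 1:10)
  expect_error(trim_low_quality_slices(noise), "rejected by QC")
})

test_that("smoothing is anisotropy-aware, conservative, and linear", {
  stk <- make_stack(nz = 8, ny = 20, nx = 20)
  expect_identical(smooth_stack(stk, 0)$voxels, stk$voxels)
  const <- stk
  const$voxels[] <- 33
  expect_equal(smooth_stack(const, 0.3)$voxels, const$voxels)
  # single bright voxel: per-axis voxel sigma 1.5 at 0.2 um isotropic,
  # total intensity conserved away from borders
  vox <- array(0, dim = c(1, 21, 21, 21))
  vox[1, 11, 11, 11] <- 1000
  # single-channel container built by hand (role validation needs 2 channels)
  imp <- structure(list(voxels = vox, voxel_size = c(0.2, 0.2, 0.2),
                        bit_depth = 16L,
                        channel_roles = c(membrane_marker = 1L),
                        source = NA_character_),
                   class = "image_stack")
  smv <- smooth_stack(imp, 0.3)$voxels
  expect_equal(sum(smv), 1000, tolerance = 1e-3)
  # linearity: smooth(c I) = c smooth(I)
  sc <- stk
  sc$voxels <- stk$voxels * 0.5
  expect_equal(smooth_stack(sc, 0.3)$voxels,
               smooth_stack(stk, 0.3)$voxels * 0.5, tolerance = 1e-10)
  expect_error(smooth_stack(stk, -1), ">= 0")
})
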