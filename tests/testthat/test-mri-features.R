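blankCase <- function(shape = c(24, 24, 24), spacing = c(1, 1, 1),
                      atlas = NULL, regionNames = NULL, laterality = NULL) {
  lay <- defaultAtlasLayout(shape)
  if (!is.null(atlas)) lay$atlas <- atlas
  if (!is.null(regionNames)) lay$regionNames <- regionNames
  if (!is.null(laterality)) lay$laterality <- laterality
  new("SegmentationCase", compartments = array(0L, shape),
      voxelSpacingMm = spacing, atlas = lay$atlas,
      regionNames = lay$regionNames, laterality = lay$laterality)
}

test_that("1000 voxels at 1 mm isotropic make exactly 1 cm^3", {
  case <- blankCase()
  comp <- compartments(case)
  comp[1:10, 1:10, 1:10] <- 1L
  case@compartments <- comp
  expect_equal(unname(compartmentVolumes(case)),
               c(1, 0, 0))
})

test_that("volumes are additive over disjoint parts", {
  case <- blankCase()
  comp <- compartments(case)
  comp[1:5, 1:5, 1:5] <- 1L
  comp[15:20, 15:20, 15:20] <- 1L
  case@compartments <- comp
  whole <- compartmentVolumes(case)[["enhancingCm3"]]
  partA <- blankCase(); cA <- compartments(partA); cA[1:5, 1:5, 1:5] <- 1L
  partA@compartments <- cA
  partB <- blankCase(); cB <- compartments(partB)
  cB[15:20, 15:20, 15:20] <- 1L
  partB@compartments <- cB
  expect_equal(whole,
               compartmentVolumes(partA)[["enhancingCm3"]] +
                 compartmentVolumes(partB)[["enhancingCm3"]])
})

test_that("anisotropic spacing warns and scales volumes", {
  case <- blankCase(spacing = c(1, 1, 6))
  comp <- compartments(case)
  comp[1:10, 1:10, 1:10] <- 1L
  case@compartments <- comp
  expect_warning(v <- compartmentVolumes(case), "anisotropic")
  expect_equal(unname(v[1]), 6)
})

test_that("corner-touching foci merge under 26- but not 6-connectivity", {
  case <- blankCase()
  comp <- compartments(case)
  comp[5, 5, 5] <- 1L
  comp[6, 6, 6] <- 1L      # touches only across a corner
  case@compartments <- comp
  expect_identical(countFoci(case, connectivity = 26), 1L)
  expect_identical(countFoci(case, connectivity = 6), 2L)
})

test_that("focus counting is invariant under axis permutation and flips", {
  case <- blankCase(shape = c(20, 24, 28))
  comp <- compartments(case)
  comp[3:5, 4:6, 5:7] <- 1L
  comp[12:14, 15:17, 20:22] <- 1L
  comp[18, 2, 2] <- 1L
  case@compartments <- comp
  base <- countFoci(case)
  perm <- aperm(comp, c(3, 1, 2))
  flip <- comp[dim(comp)[1]:1, , ]
  for (variant in list(perm, flip)) {
    vcase <- blankCase(shape = dim(variant))
    vcase@compartments <- variant
    expect_identical(countFoci(vcase), base)
  }
})

test_that("a tumor inside one frontal label is 100% frontal", {
  shape <- c(24, 24, 24)
  atlas <- array(1L, shape)   # everything left-frontal
  case <- blankCase(atlas = atlas)
  comp <- compartments(case)
  comp[8:12, 8:12, 8:12] <- 1L
  case@compartments <- comp
  p <- locationPercentages(case)
  expect_equal(unname(p["pctFrontal"]), 100)
  expect_equal(unname(p["pctDeep"]), 0)
  expect_equal(unname(p["pctLeft"]), 100)
})

test_that("a constructed 30:70 frontal/deep overlap is computed exactly", {
  shape <- c(20, 20, 20)
  atlas <- array(1L, shape)
  atlas[, 11:20, ] <- 9L         # deep (periventricular) half
  case <- blankCase(shape, atlas = atlas)
  comp <- compartments(case)
  comp[1, 8:10, 1] <- 1L         # 3 voxels frontal
  comp[1, 11:17, 1] <- 1L        # 7 voxels deep
  case@compartments <- comp
  p <- locationPercentages(case, massDefinition = "enhancing")
  expect_equal(unname(p["pctFrontal"]), 30)
  expect_equal(unname(p["pctDeep"]), 70)
})

test_that("lobar plus deep percentages partition a fully covered tumor", {
  sc <- simulateSegmentationCase(
    shapeVoxels = c(40, 40, 40),
    plantedFoci = list(list(center = c(20, 20, 20), radiusMm = 12,
                            compartment = 1)))
  p <- locationPercentages(sc)
  lob <- sum(p[c("pctFrontal", "pctParietal", "pctTemporal",
                 "pctOccipital", "pctDeep")])
  expect_equal(lob + p[["pctOther"]], 100, tolerance = 1e-9)
  expect_equal(p[["pctOther"]], 0)
})

test_that("an empty tumor mass flags undefined percentages", {
  case <- blankCase()
  expect_warning(p <- locationPercentages(case), "empty")
  expect_true(all(is.na(p)))
})

test_that("mriFeatures assembles one typed row", {
  sc <- simulateSegmentationCase(
    plantedFoci = list(list(center = c(32, 32, 32), radiusMm = 8,
                            compartment = 1)))
  row <- mriFeatures(sc)
  expect_identical(nrow(row), 1L)
  expect_true(all(c("enhancingCm3", "nFoci", "pctDeep", "pctLeft") %in%
                    names(row)))
  expect_identical(row$nFoci, 1L)
})
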