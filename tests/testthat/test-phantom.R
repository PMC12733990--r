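# Phantom generator: determinism, anatomy, voxelization, cohort sampling,
# patient splitting, augmentation and NIfTI round trips.

test_that("degenerate class mix yields kidney-only phantoms", {
  spec <- phantomSpec(classMix = c(normal = 1, cyst = 0, tumor = 0, stone = 0),
                      seed = 11L)
  v <- generatePhantom(spec, "P1")
  expect_true(all(unique(as.integer(maskArray(v))) %in% c(0L, 1L)))
  expect_gt(sum(maskArray(v) == 1L), 0)
})

test_that("generation is a pure function of (spec, seed, patient id)", {
  spec <- tiny_spec()
  a <- generatePhantom(spec, "P7", lesionClass = "cyst")
  b <- generatePhantom(spec, "P7", lesionClass = "cyst")
  expect_identical(scanArray(a), scanArray(b))
  expect_identical(maskArray(a), maskArray(b))
  c_ <- generatePhantom(spec, "P8", lesionClass = "cyst")
  expect_false(identical(scanArray(a), scanArray(c_)))
})

test_that("implanted sphere voxel count matches a brute-force voxelization", {
  spec <- phantomSpec(lesionRadiusRange = list(cyst = c(4, 8),
                                               tumor = c(5, 8),
                                               stone = c(5, 5)),
                      seed = 3L)
  v <- generatePhantom(spec, "P1", lesionClass = "stone")
  les <- v@meta$lesions[[1]]
  expect_equal(les$radius, 5)
  d <- dim(maskArray(v))
  cnt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c((i - 1) * 1, (j - 1) * 1, (k - 1) * 2.5)
    if (sqrt(sum((p - les$center)^2)) <= les$radius) cnt <- cnt + 1L
  }
  expect_identical(sum(maskArray(v) == 4L), cnt)
})

test_that("lesions stay inside the kidney", {
  spec <- tiny_spec()
  for (cl in c("cyst", "tumor", "stone")) {
    v <- generatePhantom(spec, paste0("P-", cl), lesionClass = cl)
    les <- maskArray(v) >= 2L
    kid <- maskArray(v) >= 1L
    expect_true(all(kid[les]))
  }
})

test_that("cohort class assignment recovers the mix within 3 binomial SEs", {
  mix <- defaultClassMix()
  spec <- phantomSpec(volumeShape = c(24L, 24L, 8L), seed = 42L,
                      lesionRadiusRange = list(cyst = c(2.5, 4),
                                               tumor = c(2.5, 3.5),
                                               stone = c(2, 3)))
  n <- 600L
  vols <- generateCohort(spec, n)
  classes <- vapply(vols, function(v) v@meta$lesionClass, "")
  for (cl in names(mix)) {
    se <- sqrt(mix[[cl]] * (1 - mix[[cl]]) / n)
    expect_lt(abs(mean(classes == cl) - mix[[cl]]), 3 * se + 1e-12)
  }
  expect_error(generateCohort(spec, 0), "nPatients")
})

test_that("cohort volumes carry unique ids and reproducible classes", {
  spec <- tiny_spec(seed = 5L)
  vols <- generateCohort(spec, 4)
  ids <- vapply(vols, patientId, "")
  expect_false(anyDuplicated(ids) > 0)
  vols2 <- generateCohort(spec, 4)
  expect_identical(lapply(vols, maskArray), lapply(vols2, maskArray))
})

test_that("patient split follows the stated rounding rule and partitions", {
  ids <- sprintf("P%04d", 1:3847)
  sp <- splitPatients(ids, seed = 42L)
  expect_length(sp@trainIds, 2693)
  expect_length(sp@valIds, 577)
  expect_length(sp@testIds, 577)
  sp20 <- splitPatients(sprintf("q%02d", 1:20), seed = 1L)
  expect_equal(lengths(list(sp20@trainIds, sp20@valIds, sp20@testIds)),
               c(14L, 3L, 3L))
  all_ids <- c(sp20@trainIds, sp20@valIds, sp20@testIds)
  expect_setequal(all_ids, sprintf("q%02d", 1:20))
  expect_error(splitPatients(c("a", "b")), "at least 3")
})

test_that("identity augmentation parameters reproduce the volume", {
  v <- generatePhantom(tiny_spec(), "P1", lesionClass = "cyst")
  id_par <- list(angle_deg = 0, scale = 1, gamma = 1, elastic = NULL)
  a <- augmentVolume(v, params = id_par)
  expect_lt(max(abs(scanArray(a) - scanArray(v))), 1e-5)
  expect_identical(maskArray(a), maskArray(v))
})

test_that("augmentation preserves the label set and is seed-deterministic", {
  v <- generatePhantom(tiny_spec(), "P2", lesionClass = "tumor")
  a1 <- augmentVolume(v, seed = 9L)
  a2 <- augmentVolume(v, seed = 9L)
  expect_identical(scanArray(a1), scanArray(a2))
  expect_true(all(unique(as.integer(maskArray(a1))) %in% 0:4))
  a3 <- augmentVolume(v, seed = 10L)
  expect_false(identical(scanArray(a1), scanArray(a3)))
})

test_that("NIfTI round trip is voxel-identical with spacing metadata", {
  spec <- tiny_spec(seed = 21L)
  vols <- generateCohort(spec, 3)
  sp <- splitPatients(vapply(vols, patientId, ""), c(0.4, 0.3, 0.3), seed = 1L)
  out <- withr::local_tempdir()
  man <- writeDataset(vols, sp, out)
  expect_equal(nrow(man), 3)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  back <- readVolume(man[1, ])
  orig <- vols[[which(vapply(vols, patientId, "") == man$patient_id[1])]]
  expect_equal(scanArray(back), scanArray(orig), tolerance = 1e-6)
  expect_identical(maskArray(back), maskArray(orig))
  expect_equal(voxelSpacing(back), voxelSpacing(orig), tolerance = 1e-6)
})
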