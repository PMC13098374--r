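## profiles built from the published pre/post cohort-mean MAA series
preMAA <- data.frame(phase = c("MD", "LD", "ED", "MS", "ES"),
                     MAA = c(10.28, 10.45, 8.72, 9.69, 9.56))
postMAA <- data.frame(phase = c("MD", "LD", "ED", "MS", "ES"),
                      MAA = c(10.09, 10.23, 8.39, 9.32, 8.19))

test_that("profiles are ordered, minimal, and reject duplicates", {
  prof <- buildMADProfile(preMAA[c(3, 1, 5, 2, 4), ])  # shuffled input
  expect_identical(profileSeries(prof)$phase, c("MD", "LD", "ED", "MS", "ES"))
  expect_identical(phaseOfMinimum(prof, "MAA"), "ED")
  expect_error(buildMADProfile(rbind(preMAA, preMAA[5, ])), "duplicate")
  expect_error(buildMADProfile(preMAA[1:2, ]))  # lacks ED and ES
  minimal <- buildMADProfile(preMAA[c(3, 5), ])
  expect_identical(profileSeries(minimal)$phase, c("ED", "ES"))
  ## monotone decreasing series: minimum at the last phase
  dec <- data.frame(phase = c("MD", "ED", "MS", "ES"), MAA = c(4, 3, 2, 1))
  expect_identical(phaseOfMinimum(buildMADProfile(dec), "MAA"), "ES")
  ## all equal: tie broken toward the earlier phase
  flat <- data.frame(phase = c("MD", "ED", "ES"), MAA = 5)
  expect_identical(phaseOfMinimum(buildMADProfile(flat), "MAA"), "MD")
})

test_that("systolic behaviour classifies the published mean pattern", {
  pre <- systolicBehavior(buildMADProfile(preMAA), "MAA")
  expect_identical(pre$classification, "expansion")
  expect_equal(pre$delta, 9.56 - 8.72)
  post <- systolicBehavior(buildMADProfile(postMAA), "MAA")
  expect_identical(post$classification, "contraction")
  flat <- buildMADProfile(data.frame(phase = c("ED", "ES"), MAA = c(9, 9)))
  expect_identical(systolicBehavior(flat, "MAA")$classification, "none")
  ## sub-tolerance change is classified none
  tiny <- buildMADProfile(data.frame(phase = c("ED", "ES"), MAA = c(9, 9.05)))
  expect_identical(systolicBehavior(tiny, "MAA")$classification, "none")
})

test_that("profile plotting returns the phase-by-profile matrix", {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  mat <- plotMADProfile(list(buildMADProfile(preMAA),
                             buildMADProfile(postMAA)), "MAA")
  expect_equal(dim(mat), c(6, 2))
  expect_equal(mat[3, 1], 8.72)  # ED, pre
  expect_true(is.na(mat[5, 1]))  # LS absent from the published series
})

test_that("classification is invariant to allometric indexing", {
  idx <- preMAA; idx$MAA <- idx$MAA / 0.464  # divide by a BSA-like constant
  a <- systolicBehavior(buildMADProfile(preMAA), "MAA")
  b <- systolicBehavior(buildMADProfile(idx), "MAA")
  expect_identical(a$classification, b$classification)
  expect_equal(a$relativeChange, b$relativeChange, tolerance = 1e-12)
})
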