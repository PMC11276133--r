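test_that("grade-stratified counts land in the drawn grade's bracket", {
  withr::local_seed(1)
  p0 <- tiny_phantom(grade_probs = c(1, 0, 0, 0, 0))
  expect_true(all(sample_count(p0, 50) == 0))
  p2 <- tiny_phantom(grade_probs = c(0, 0, 1, 0, 0))
  expect_true(all(sample_count(p2, 200) %in% 11:20))
  p4 <- tiny_phantom(grade_probs = c(0, 0, 0, 0, 1))
  expect_true(all(sample_count(p4, 200) %in% 41:48))
  expect_error(phantom_params(grade_probs = rep(0, 5)), "all zero")
})

test_that("empirical grade frequencies converge to the stated weights", {
  withr::local_seed(2)
  params <- tiny_phantom() # default: the 456-image histogram (4,244,138,55,15)
  counts <- sample_count(params, 1e5)
  freq <- tabulate(grade_from_count(counts) + 1L, 5) / 1e5
  expect_true(all(abs(freq - params$grade_probs) < 0.01))
  # chi-squared goodness of fit not rejected at alpha = 0.01
  obs <- tabulate(grade_from_count(sample_count(params, 2e4)) + 1L, 5)
  expect_gt(stats::chisq.test(obs, p = params$grade_probs)$p.value, 0.01)
})

test_that("rendered parts have exactly `count` components and bright puncta", {
  withr::local_seed(3)
  params <- tiny_phantom()
  empty <- render_part(0, params)
  expect_identical(sum(empty$mask), 0L)
  expect_gt(sd(empty$raw), 0) # textured background, not flat

  for (count in c(1, 10, 25)) {
    part <- render_part(count, params)
    expect_identical(label_components(part$mask)$n, as.integer(count))
    expect_gt(mean(part$raw[part$mask == 1]), mean(part$raw[part$mask == 0]))
    expect_gte(min(part$raw), 0)
    expect_lt(max(part$raw), 2^params$bit_depth)
  }

  # the stated maximum burden fits an 80 x 96 part
  part <- render_part(48, phantom_params(part_shape = c(80L, 96L)))
  expect_identical(label_components(part$mask)$n, 48L)
})

test_that("impossible placements raise a placement error", {
  withr::local_seed(4)
  cramped <- phantom_params(part_shape = c(20L, 20L), max_place_retries = 50L)
  expect_error(render_part(40, cramped), class = "pvscade_placement_error")
})

test_that("cohorts have six parts per subject and obey the max rule", {
  cohort <- generate_cohort(20, tiny_phantom(), seed = 7)
  expect_s3_class(cohort, "pvs_cohort")
  expect_identical(nrow(cohort), 120L)
  per <- dplyr::count(cohort, subject_id)
  expect_true(all(per$n == 6))
  expect_setequal(unique(cohort$hemisphere), c("left", "right"))

  # max-rule oracle, brute force per subject
  for (id in unique(cohort$subject_id)) {
    sub <- cohort[cohort$subject_id == id, ]
    expect_identical(unique(sub$subject_grade), max(sub$grade))
  }
  # stored grades and counts are consistent
  expect_identical(cohort$grade, grade_from_count(cohort$count))
  # every mask matches its count (connected-components oracle)
  comps <- vapply(cohort$mask, function(m) label_components(m)$n, integer(1))
  expect_identical(comps, as.integer(cohort$count))
})

test_that("cohort generation is bit-identical under a fixed seed", {
  a <- generate_cohort(2, tiny_phantom(), seed = 42)
  b <- generate_cohort(2, tiny_phantom(), seed = 42)
  expect_identical(a$raw, b$raw)
  expect_identical(a$mask, b$mask)
  expect_identical(a$count, b$count)
  c2 <- generate_cohort(2, tiny_phantom(), seed = 43)
  expect_false(identical(a$raw, c2$raw))
})

test_that("whole-slice emitter produces a usable two-hemisphere ROI", {
  withr::local_seed(9)
  sl <- render_slice(counts = c(4L, 7L), tiny_phantom(),
                     slice_shape = c(160L, 220L))
  expect_identical(dim(sl$raw), dim(sl$roi_mask))
  expect_gt(sum(sl$roi_mask), 0)
  expect_identical(label_components(sl$pvs_mask)$n, 11L)
  # puncta lie inside the ROI
  expect_true(all(sl$roi_mask[sl$pvs_mask == 1] == 1))
})
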