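# small, fast phantom configurations shared across tests

tiny_phantom <- function(...) {
  # large enough that a grade-4 burden (48 puncta) always places
  phantom_params(part_shape = c(72L, 84L), puncta_radius_range = c(1, 2), ...)
}

# a preprocessed mini-cohort at reduced resolution (40 x 48 keeps the nets fast)
tiny_parts <- function(n_subjects = 4, seed = 101, out_shape = c(40L, 48L)) {
  preprocess_cohort(generate_cohort(n_subjects, tiny_phantom(), seed = seed),
                    out_shape = out_shape)
}

# minimal training configuration for smoke tests
tiny_config <- function(...) {
  defaults <- list(enhancer_depth = 2L, enhancer_base_filters = 4L,
                   quantifier_filters = c(4L, 4L, 8L, 8L, 8L),
                   epochs_enhancer = 2L, epochs_quantifier = 2L,
                   batch_size = 8L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, c(list(preset = "desk"), args))
}

expect_unit_image <- function(x, shape = NULL) {
  expect_true(is.matrix(x))
  expect_gte(min(x), 0)
  expect_lte(max(x), 1)
  if (!is.null(shape)) expect_identical(dim(x), as.integer(shape))
}
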