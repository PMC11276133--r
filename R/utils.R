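# internal helpers shared across modules

# run `code` under a fixed seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# min-max rescale to [0, 1]; a constant input maps to all zeros (tie-break)
minmax <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

stopf <- function(fmt, ..., class = "pvscade_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_matrix <- function(x, arg = "image") {
  if (!is.matrix(x) || length(x) == 0) {
    stopf("`%s` must be a nonempty matrix", arg)
  }
  if (anyNA(x)) stopf("`%s` contains missing values", arg)
  invisible(x)
}

check_unit_image <- function(x, arg = "image") {
  check_matrix(x, arg)
  if (min(x) < 0 || max(x) > 1) {
    stopf("`%s` must have values in [0, 1]", arg)
  }
  invisible(x)
}

check_binary_mask <- function(x, arg = "mask") {
  check_matrix(x, arg)
  if (!all(x %in% c(0, 1))) stopf("`%s` must be binary (0/1)", arg)
  invisible(x)
}

check_same_shape <- function(a, b, arg_a = "image", arg_b = "mask") {
  if (!identical(dim(a), dim(b))) {
    stopf("`%s` (%s) and `%s` (%s) must have the same shape",
          arg_a, paste(dim(a), collapse = "x"),
          arg_b, paste(dim(b), collapse = "x"))
  }
  invisible(NULL)
}

# stack a list of equally-shaped matrices into an [H, W, 1, N] array
stack_images <- function(images) {
  if (is.matrix(images)) images <- list(images)
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(d[1], d[2], 1L, length(images)))
}

# split an [H, W, 1, N] array back into a list of matrices
unstack_images <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(n) matrix(x[, , 1L, n], d[1], d[2]))
}

round_half_up <- function(x) floor(x + 0.5)
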