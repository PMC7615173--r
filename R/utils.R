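# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so library calls never perturb a user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Flatten a nested list of numeric arrays into one vector and back.
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(sk) {
    if (is.list(sk)) return(lapply(sk, walk))
    n <- length(sk)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    dim(v) <- dim(sk)
    v
  }
  walk(skeleton)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("mm_invalid_argument", "error")))
}

stop_shape <- function(...) {
  stop(errorCondition(paste0(...), class = c("mm_shape_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("mm_format_error", "error")))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stop_invalid(name, " must be a single integer >= ", min, ", got ",
                 paste(x, collapse = ","))
  as.integer(x)
}

assert_odd <- function(x, name) {
  x <- assert_count(x, name, min = 1L)
  if (x %% 2L == 0L) stop_invalid(name, " must be odd, got ", x)
  x
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_invalid(name, " must be a probability in [0,1], got ", x)
  as.numeric(x)
}

assert_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x))
    stop_invalid(name, " must be TRUE or FALSE")
  x
}

# Coerce 2D matrix input to a (H, W, 1) array; pass arrays through.
as_image_array <- function(x, name = "x") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || !(length(dim(x)) %in% c(3L, 4L)))
    stop_shape(name, " must be a (spatial..., channel) array with 2 or 3 ",
               "spatial dimensions")
  x
}

spatial_dims <- function(x) {
  dx <- dim(x)
  dx[seq_len(length(dx) - 1L)]
}
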