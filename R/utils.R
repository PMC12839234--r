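#' @useDynLib bdnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd var
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

# run expr with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# validate a single-channel intensity image: numeric matrix with values in [0,1]
check_image <- function(img, min_dim = 1L, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid(arg, " must be a numeric matrix")
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop_invalid(arg, " must be at least ", min_dim, "x", min_dim)
  if (anyNA(img)) stop_invalid(arg, " contains missing values")
  rng <- range(img)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop_invalid(arg, " values must lie in [0, 1] (found range [",
                 signif(rng[1], 4), ", ", signif(rng[2], 4), "])")
  invisible(img)
}

check_same_shape <- function(a, b, what = c("pred", "target")) {
  if (!identical(dim(a), dim(b)))
    stop_invalid(what[1], " and ", what[2], " must have identical dimensions (",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"), ")")
  invisible(NULL)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# matrix image -> [H, W, 1, 1] tensor and back
as_tensor <- function(img) array(img, c(nrow(img), ncol(img), 1L, 1L))
as_matrix_image <- function(x4d) {
  d <- dim(x4d)
  matrix(x4d, d[1], d[2])
}

# stack a list of equally-sized matrices into an [H, W, N, 1] batch
stack_batch <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(H, W, length(imgs), 1L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
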