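#' Generate a synthetic fluorescence-like phantom image
#'
#' Draws `n_cells` elliptical cell bodies on a dim, slightly graded
#' background. Each cell has a smooth interior intensity falloff and a
#' bright membrane rim 1-2 px wide; overlapping cells combine by maximum.
#' The sharp rims give the image controlled high-frequency content, which is
#' what the Sobel gradient-consistency loss is designed to preserve.
#'
#' @param height,width Image size in pixels, at least 32.
#' @param n_cells Number of cells to draw (0 gives background only).
#' @param membrane_contrast Rim brightness as a fraction of the remaining
#'   headroom above the cell interior, in \[0, 1\].
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return A numeric matrix with values in \[0, 1\].
#' @export
generate_phantom <- function(height, width, n_cells, membrane_contrast = 0.7,
                             seed = 1L) {
  if (height < 32 || width < 32)
    stop_invalid("height and width must each be at least 32")
  if (n_cells < 0) stop_invalid("n_cells must be non-negative")
  if (membrane_contrast < 0 || membrane_contrast > 1)
    stop_invalid("membrane_contrast must lie in [0, 1]")
  with_seed(seed, {
    # low uniform background with a gentle illumination gradient
    jj <- matrix(seq_len(width), height, width, byrow = TRUE)
    img <- 0.08 + 0.015 * (jj - 1) / max(width - 1, 1)
    if (n_cells > 0) {
      ii <- matrix(seq_len(height), height, width)
      rmin <- min(height, width) / 12
      rmax <- min(height, width) / 6
      for (k in seq_len(n_cells)) {
        cx <- runif(1, rmax, height - rmax)
        cy <- runif(1, rmax, width - rmax)
        a <- runif(1, rmin, rmax)
        b <- runif(1, rmin, rmax)
        th <- runif(1, 0, pi)
        base <- runif(1, 0.35, 0.55)
        dx <- ii - cx; dy <- jj - cy
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        rho <- sqrt(u^2 + v^2)
        cell <- matrix(0, height, width)
        inside <- rho <= 1
        cell[inside] <- base * (1 - 0.35 * rho[inside]^2)
        # rim: within ~1.5 px of the boundary, measured in pixel units
        rim <- abs(rho - 1) * min(a, b) <= 1.5
        cell[rim] <- pmin(1, base + membrane_contrast * (1 - base))
        img <- pmax(img, cell)
      }
    }
    clamp01(img)
  })
}

#' Bundle a noisy/clean image pair with its acquisition metadata
#'
#' @param noisy,clean Numeric matrices of identical size with values in \[0,1\].
#' @param level Positive integer: number of raw frames averaged to form the
#'   noisy observation (1, 2, 4, 8, 16 by convention; more averaging means
#'   less noise).
#' @param modality_tag Free-form label (e.g. imaging modality) used for
#'   stratified splitting.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(noisy, clean, level = 1L, modality_tag = "synthetic") {
  check_image(noisy, arg = "noisy")
  check_image(clean, arg = "clean")
  check_same_shape(noisy, clean, c("noisy", "clean"))
  if (length(level) != 1L || is.na(level) || level < 1 || level != round(level))
    stop_invalid("level must be a positive integer")
  structure(list(noisy = noisy, clean = clean, level = as.integer(level),
                 modality_tag = as.character(modality_tag)),
            class = "paired_sample")
}

#' Stratified train/validation/test split of paired samples
#'
#' Samples are grouped into strata by `(modality_tag, level)` and each
#' stratum is split independently at the requested fractions, so every
#' modality and noise level is represented in every part. Per-stratum counts
#' use floor-then-largest-remainder rounding; strata with fewer than 3
#' samples go entirely to the training set with a warning.
#'
#' @param samples List of [paired_sample()] objects.
#' @param fractions Numeric length-3 `(train, val, test)`, positive and
#'   summing to 1.
#' @param seed Integer seed; the partition is deterministic per seed.
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (!is.list(samples) || !length(samples))
    stop_invalid("samples must be a non-empty list of paired samples")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_invalid("fractions must be three positive values summing to 1")
  strata <- vapply(samples, function(s)
    paste(s$modality_tag, s$level, sep = "\r"), character(1))
  out <- list(train = list(), val = list(), test = list())
  with_seed(seed, {
    for (st in unique(strata)) {
      idx <- which(strata == st)
      n <- length(idx)
      if (n < 3L) {
        warning("stratum '", gsub("\r", "/", st), "' has ", n,
                " sample(s) (< 3): assigned to train", call. = FALSE)
        out$train <- c(out$train, samples[idx])
        next
      }
      target <- n * fractions
      counts <- floor(target)
      rem <- n - sum(counts)
      if (rem > 0) {
        # largest remainders first; ties broken in train < val < test order
        ord <- order(target - counts, decreasing = TRUE)
        counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
      }
      idx <- sample(idx)
      parts <- rep(c("train", "val", "test"), counts)
      out$train <- c(out$train, samples[idx[parts == "train"]])
      out$val <- c(out$val, samples[idx[parts == "val"]])
      out$test <- c(out$test, samples[idx[parts == "test"]])
    }
  })
  out
}

flip_image <- function(img, horizontal = FALSE, vertical = FALSE) {
  if (vertical) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  if (horizontal) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  img
}

#' Flip-only data augmentation for a noisy/clean pair
#'
#' Draws one of the four variants \{identity, horizontal flip, vertical
#' flip, both\} uniformly at random and applies the same flip to the noisy
#' and the clean image, so the pairing (and any full-reference metric
#' between the two) is preserved exactly. Flips are the only augmentation:
#' they are isometries of the pixel grid and do not alter biological
#' morphology.
#'
#' @param pair A [paired_sample()].
#' @param seed Integer seed.
#' @return A [paired_sample()] with the flip applied.
#' @export
augment <- function(pair, seed = 1L) {
  stopifnot(inherits(pair, "paired_sample"))
  v <- with_seed(seed, sample.int(4L, 1L)) - 1L
  apply_flip_variant(pair, v)
}

# variant 0 = identity, 1 = h-flip, 2 = v-flip, 3 = both
apply_flip_variant <- function(pair, v) {
  h <- v %in% c(1L, 3L); vv <- v %in% c(2L, 3L)
  pair$noisy <- flip_image(pair$noisy, h, vv)
  pair$clean <- flip_image(pair$clean, h, vv)
  pair
}

#' Write / read a dataset manifest
#'
#' A manifest is a CSV with columns `noisy_path`, `clean_path`, `level`,
#' `modality_tag` describing paired images on disk.
#'
#' @param samples List of [paired_sample()] objects to write to `dir`.
#' @param dir Output directory (created if needed); images are written as
#'   16-bit TIFFs.
#' @return `write_manifest`: invisibly, the manifest path.
#' @export
write_manifest <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    np <- file.path(dir, sprintf("noisy_%04d.tif", i))
    cp <- file.path(dir, sprintf("clean_%04d.tif", i))
    write_image(s$noisy, np, 16L)
    write_image(s$clean, cp, 16L)
    data.frame(noisy_path = np, clean_path = cp, level = s$level,
               modality_tag = s$modality_tag, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param path Path to a manifest CSV.
#' @return `read_manifest`: a list of [paired_sample()] objects.
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("noisy_path", "clean_path", "level", "modality_tag")
  if (!all(need %in% names(man)))
    stop_invalid("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(man)), function(i)
    paired_sample(read_image(resolve(man$noisy_path[i])),
                  read_image(resolve(man$clean_path[i])),
                  man$level[i], man$modality_tag[i]))
}
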