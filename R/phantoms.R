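# Synthetic phantom generator.  Images follow the forward model
# I = b.J + n: a piecewise-constant class image J (the true image), a
# smooth mean-normalized multiplicative bias field b, and additive
# Gaussian noise.  Ground truth (labels, bias, means) is returned with
# every phantom so recovery can be measured exactly.

#' Specify a synthetic phantom
#'
#' @param shape Integer vector `c(height, width)`.
#' @param n_classes 2 or 3 intensity classes.
#' @param class_means Distinct true class intensities on the 0--255 scale
#'   (one per class).
#' @param geometry One of `"tshape"`, `"star"`, `"disks"` (two-class) or
#'   `"brainlike"` (three nested smooth regions, three-class).
#' @param bias_kind One of `"identity"`, `"linear_ramp"`,
#'   `"gaussian_bump"`, `"polynomial"`.
#' @param bias_range Length-2 positive vector `c(min, max)`; the generated
#'   field attains exactly this max/min ratio before mean normalization.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L), n_classes = 2L,
                         class_means = c(60, 160), geometry = "tshape",
                         bias_kind = "identity", bias_range = c(1, 1),
                         noise_sd = 0, seed = 1L) {
  geometry <- match.arg(geometry, c("tshape", "star", "disks", "brainlike"))
  bias_kind <- match.arg(bias_kind,
                         c("identity", "linear_ramp", "gaussian_bump",
                           "polynomial"))
  stopifnot(
    length(shape) == 2L, all(shape >= 16),
    n_classes %in% c(2L, 3L), length(class_means) == n_classes,
    !anyDuplicated(class_means),
    length(bias_range) == 2L, all(bias_range > 0),
    bias_range[2] >= bias_range[1], noise_sd >= 0
  )
  if ((geometry == "brainlike") != (n_classes == 3L)) {
    stop("`brainlike` geometry is three-class; the others are two-class",
         call. = FALSE)
  }
  structure(
    list(
      shape = as.integer(shape), n_classes = as.integer(n_classes),
      class_means = as.numeric(class_means), geometry = geometry,
      bias_kind = bias_kind, bias_range = as.numeric(bias_range),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Label geometries; all return an integer matrix of class labels with the
# highest label as background.
phantom_labels <- function(spec) {
  h <- spec$shape[1]
  w <- spec$shape[2]
  r <- matrix(seq_len(h) / h, h, w)
  c_ <- matrix(rep(seq_len(w) / w, each = h), h, w)
  lab <- matrix(spec$n_classes, h, w)
  switch(spec$geometry,
    tshape = {
      bar <- r >= 0.15 & r <= 0.35 & c_ >= 0.15 & c_ <= 0.85
      stem <- r >= 0.15 & r <= 0.85 & c_ >= 0.42 & c_ <= 0.58
      lab[bar | stem] <- 1L
    },
    star = {
      th <- atan2(r - 0.5, c_ - 0.5)
      rad <- sqrt((r - 0.5)^2 + (c_ - 0.5)^2)
      star <- rad <= 0.18 + 0.10 * cos(5 * th)
      disk1 <- sqrt((r - 0.22)^2 + (c_ - 0.76)^2) <= 0.08
      disk2 <- sqrt((r - 0.78)^2 + (c_ - 0.24)^2) <= 0.06
      lab[star | disk1 | disk2] <- 1L
    },
    disks = {
      d1 <- sqrt((r - 0.3)^2 + (c_ - 0.3)^2) <= 0.14
      d2 <- sqrt((r - 0.68)^2 + (c_ - 0.62)^2) <= 0.18
      d3 <- sqrt((r - 0.28)^2 + (c_ - 0.75)^2) <= 0.09
      lab[d1 | d2 | d3] <- 1L
    },
    brainlike = {
      th <- atan2(r - 0.5, c_ - 0.5)
      rad <- sqrt((r - 0.5)^2 + (c_ - 0.5)^2)
      mid <- rad <= 0.32 + 0.04 * cos(4 * th + 1)
      inner <- rad <= 0.17 + 0.03 * cos(5 * th + 2)
      lab[mid] <- 2L
      lab[inner] <- 1L
    }
  )
  lab
}

# Smooth bias field spanning exactly bias_range, then mean-normalized
# (so max/min is preserved but the scale matches the model's reported,
# mean-1 bias fields).
phantom_bias <- function(spec) {
  h <- spec$shape[1]
  w <- spec$shape[2]
  r <- matrix(seq_len(h) / h, h, w)
  c_ <- matrix(rep(seq_len(w) / w, each = h), h, w)
  raw <- switch(spec$bias_kind,
    identity = matrix(0.5, h, w),
    linear_ramp = c_,
    gaussian_bump = exp(-((r - 0.35)^2 + (c_ - 0.35)^2) / (2 * 0.3^2)),
    polynomial = 1 - ((r - 0.5)^2 + (c_ - 0.5)^2)
  )
  if (spec$bias_kind != "identity") {
    raw <- (raw - min(raw)) / (max(raw) - min(raw))
  }
  b <- spec$bias_range[1] +
    (spec$bias_range[2] - spec$bias_range[1]) * raw
  b / mean(b)
}

#' Generate a phantom image with known ground truth
#'
#' Builds the piecewise-constant true image from the spec geometry and
#' class means, multiplies by the smooth bias field, adds Gaussian noise,
#' and clips to \[0, 255\] (a warning reports the clipped fraction if any
#' pixel clips; the bundled specs never clip).
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `ls_phantom`: list with `image`,
#'   `true_labels`, `true_bias` (mean-normalized), `true_means`,
#'   `clip_fraction`, and the originating `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec)
  bias <- phantom_bias(spec)
  jtrue <- matrix(spec$class_means[labels], spec$shape[1], spec$shape[2])
  noise <- 0
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    noise <- matrix(stats::rnorm(length(jtrue), 0, spec$noise_sd),
                    spec$shape[1], spec$shape[2])
  }
  img <- bias * jtrue + noise
  clipped <- mean(img < 0 | img > 255)
  if (clipped > 0) {
    warning(sprintf("%.2f%% of phantom pixels clipped to [0, 255]",
                    100 * clipped))
    img <- pmin(pmax(img, 0), 255)
  }
  structure(
    list(
      image = img, true_labels = labels, true_bias = bias,
      true_means = spec$class_means, clip_fraction = clipped, spec = spec
    ),
    class = "ls_phantom"
  )
}

#' @export
print.ls_phantom <- function(x, ...) {
  cat(sprintf(
    "Phantom: %dx%d, %d classes (%s), bias %s [%g, %g], noise sd %g, seed %d\n",
    x$spec$shape[1], x$spec$shape[2], x$spec$n_classes, x$spec$geometry,
    x$spec$bias_kind, x$spec$bias_range[1], x$spec$bias_range[2],
    x$spec$noise_sd, x$spec$seed
  ))
  invisible(x)
}

#' Bundled phantom specifications
#'
#' A named list of phantom specs spanning both class counts, the bias
#' families, and clean/noisy conditions, all 128 x 128.  `tshape_bias`
#' (two classes, linear ramp bias 0.8--1.2, noise sd 5) and `brain_bias`
#' (three classes, Gaussian-bump bias 0.7--1.3, noise sd 5) are the
#' reference conditions for the recovery validations.
#'
#' @return Named list of `phantom_spec` objects with distinct seeds.
#' @export
default_phantom_suite <- function() {
  list(
    tshape_clean = phantom_spec(
      geometry = "tshape", class_means = c(60, 160), seed = 101L
    ),
    tshape_bias = phantom_spec(
      geometry = "tshape", class_means = c(60, 160),
      bias_kind = "linear_ramp", bias_range = c(0.8, 1.2), noise_sd = 5,
      seed = 102L
    ),
    star_highlight = phantom_spec(
      geometry = "star", class_means = c(60, 160),
      bias_kind = "gaussian_bump", bias_range = c(0.9, 1.3), noise_sd = 5,
      seed = 103L
    ),
    disks_poly = phantom_spec(
      geometry = "disks", class_means = c(80, 180),
      bias_kind = "polynomial", bias_range = c(0.85, 1.15), noise_sd = 3,
      seed = 104L
    ),
    brain_clean = phantom_spec(
      geometry = "brainlike", n_classes = 3L,
      class_means = c(160, 100, 40), seed = 105L
    ),
    brain_bias = phantom_spec(
      geometry = "brainlike", n_classes = 3L,
      class_means = c(160, 100, 40), bias_kind = "gaussian_bump",
      bias_range = c(0.7, 1.3), noise_sd = 5, seed = 106L
    )
  )
}
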