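# Image and result I/O.  Images are ingested onto a fixed 0--255 working
# scale (the default length penalty presumes it); label maps travel as
# 8-bit PNG, continuous fields as 32-bit float TIFF with an affine
# transform recorded in the JSON manifest.

#' Read a grayscale image onto the 0--255 working scale
#'
#' PNG and TIFF are supported.  Integer images are rescaled by their
#' nominal range (8-bit value 255 and 16-bit value 65535 both map to 255).
#' Floating-point images outside \[0, 1\] are min--max rescaled to
#' \[0, 255\] and the affine transform is attached as the `"rescale"`
#' attribute so class means can be mapped back.  Multi-channel images are
#' collapsed by the channel average with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (length(dim(x)) == 3L) {
    warning("multi-channel image collapsed by channel average")
    x <- apply(x, c(1, 2), mean)
  }
  x <- as.matrix(x)
  if (length(x) == 0L) stop("zero-area image", call. = FALSE)
  rng <- range(x)
  if (rng[1] >= 0 && rng[2] <= 1) {
    out <- x * 255
    attr(out, "rescale") <- c(offset = 0, scale = 255)
  } else {
    if (rng[1] == rng[2]) {
      stop("constant image has no contrast (min == max)", call. = FALSE)
    }
    out <- (x - rng[1]) / (rng[2] - rng[1]) * 255
    attr(out, "rescale") <- c(offset = rng[1],
                              scale = (rng[2] - rng[1]) / 255)
  }
  out
}

# Write a numeric field as 32-bit float TIFF, mapping the value range onto
# [0, 1]; returns the affine transform (value = offset + scale * stored).
write_field_tiff <- function(x, path) {
  rng <- range(x)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  tiff::writeTIFF((x - rng[1]) / scale, path, bits.per.sample = 32L)
  c(offset = rng[1], scale = scale)
}

#' Write a segmentation result to a directory
#'
#' Writes the label map (8-bit PNG, pixel value = class label), each level
#' set function, the bias and difference fields (32-bit float TIFF, value
#' range mapped to \[0, 1\] with the transform recorded in the manifest),
#' the corrected image (16-bit TIFF, clamped to \[0, 255\]), the energy
#' trace (CSV), and a JSON manifest of parameters and outputs.
#'
#' @param result An `ls_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
write_result <- function(result, out_dir) {
  stopifnot(inherits(result, "ls_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  png::writePNG(result$labels / 255, file.path(out_dir, "labels.png"))
  transforms <- list()
  phi_files <- character(0)
  for (i in seq_along(result$phis)) {
    fn <- sprintf("phi%d.tif", i)
    transforms[[fn]] <- write_field_tiff(result$phis[[i]],
                                         file.path(out_dir, fn))
    phi_files <- c(phi_files, fn)
  }
  transforms[["bias.tif"]] <- write_field_tiff(result$b,
                                               file.path(out_dir, "bias.tif"))
  transforms[["difference.tif"]] <-
    write_field_tiff(result$d, file.path(out_dir, "difference.tif"))
  tiff::writeTIFF(pmin(pmax(result$corrected, 0), 255) / 255,
                  file.path(out_dir, "corrected.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(
    data.frame(iteration = seq_along(result$energy_trace),
               energy = result$energy_trace),
    file.path(out_dir, "energy.csv"), row.names = FALSE
  )
  manifest <- list(
    params = result$params[!vapply(result$params, is.null, logical(1))],
    n_classes = length(result$c),
    class_means = result$c,
    iterations_run = result$iterations_run,
    converged = result$converged,
    files = c("labels.png", phi_files, "bias.tif", "difference.tif",
              "corrected.tif", "energy.csv"),
    field_transforms = transforms
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a phantom to a directory
#'
#' Writes the image (16-bit TIFF), the true labels (8-bit PNG), the true
#' bias field (32-bit float TIFF) and a JSON sidecar with the spec.
#'
#' @param phantom An `ls_phantom`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the sidecar list.
#' @export
write_phantom <- function(phantom, out_dir) {
  stopifnot(inherits(phantom, "ls_phantom"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(pmin(pmax(phantom$image, 0), 255) / 255,
                  file.path(out_dir, "image.tif"), bits.per.sample = 16L)
  png::writePNG(phantom$true_labels / 255,
                file.path(out_dir, "labels.png"))
  bias_tr <- write_field_tiff(phantom$true_bias,
                              file.path(out_dir, "bias.tif"))
  sidecar <- c(unclass(phantom$spec),
               list(clip_fraction = phantom$clip_fraction,
                    field_transforms = list(bias.tif = bias_tr)))
  jsonlite::write_json(sidecar, file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

# Known run-configuration keys and their defaults (NULL = no default).
run_config_keys <- function() {
  c("image", "output", "init", "init2", "classes", "sigma", "epsilon",
    "dt", "alpha", "beta", "max_iters", "conv_tol", "c0", "inner_steps",
    "baseline_li", "seed_positive", "seed")
}

#' Read a run configuration file
#'
#' YAML file whose keys are the [ls_params()] fields plus `image`,
#' `output`, `init`, `init2` and `classes`.  Unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), run_config_keys())
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg
}

#' Write a run configuration file
#'
#' Serializes a configuration list (keys as in [read_run_config()]) to
#' canonical YAML: known keys only, in canonical order.
#'
#' @param config Named list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_keys())
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  ordered <- config[intersect(run_config_keys(), names(config))]
  yaml::write_yaml(ordered, path)
  invisible(path)
}
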