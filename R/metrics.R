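# Segmentation overlap metrics: Jaccard similarity, Dice coefficient, and
# the false positive / false negative ratios defined on the ground-truth
# and segmented foregrounds.

#' Overlap metrics between two binary masks
#'
#' Given the ground-truth foreground `S_g` and the segmented foreground
#' `S_m` with overlap `O`:
#' \deqn{JS = \frac{|S_g \cap S_m|}{|S_g \cup S_m|},\qquad
#'       DSC = \frac{2|S_g \cap S_m|}{|S_g| + |S_m|},}
#' \deqn{RFP = \frac{|S_g \setminus O|}{|S_g|},\qquad
#'       RFN = \frac{|S_m \setminus O|}{|S_m|}.}
#' The ratio denominators are exactly as stated above (note that they are
#' not the conventional FPR/FNR denominators).  JS and DSC close to 1, and
#' RFP and RFN close to 0, indicate a good segmentation.
#'
#' @param gt_mask Logical matrix, ground-truth foreground (non-empty).
#' @param seg_mask Logical matrix, segmented foreground (non-empty), same
#'   shape.
#' @return An object of class `overlap_report`: list with `js`, `dsc`,
#'   `rfp`, `rfn`, and the pixel counts `n_gt`, `n_seg`, `n_overlap`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:4] <- TRUE   # 8 pixels
#' b <- matrix(FALSE, 4, 4); b[2:3, 1:4] <- TRUE   # 8 pixels, overlap 4
#' overlap_metrics(a, b)
#' @export
overlap_metrics <- function(gt_mask, seg_mask) {
  stopifnot(is.matrix(gt_mask), is.matrix(seg_mask),
            is.logical(gt_mask), is.logical(seg_mask),
            all(dim(gt_mask) == dim(seg_mask)))
  n_gt <- sum(gt_mask)
  n_seg <- sum(seg_mask)
  if (n_gt == 0L || n_seg == 0L) {
    stop("overlap metrics are undefined for an empty mask", call. = FALSE)
  }
  n_ov <- sum(gt_mask & seg_mask)
  structure(
    list(
      js = n_ov / (n_gt + n_seg - n_ov),
      dsc = 2 * n_ov / (n_gt + n_seg),
      rfp = (n_gt - n_ov) / n_gt,
      rfn = (n_seg - n_ov) / n_seg,
      n_gt = n_gt, n_seg = n_seg, n_overlap = n_ov
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "Overlap: JS = %.4f, DSC = %.4f, RFP = %.4f, RFN = %.4f  (|Sg| = %d, |Sm| = %d, |O| = %d)\n",
    x$js, x$dsc, x$rfp, x$rfn, x$n_gt, x$n_seg, x$n_overlap
  ))
  invisible(x)
}

#' Per-class overlap metrics from label maps
#'
#' Binarizes both label maps at `class_id` and delegates to
#' [overlap_metrics()].
#'
#' @param gt_labels,seg_labels Integer label matrices of equal shape.
#' @param class_id Class label to evaluate; must be present in both maps.
#' @return An `overlap_report`.
#' @export
multiclass_metrics <- function(gt_labels, seg_labels, class_id) {
  stopifnot(is.matrix(gt_labels), is.matrix(seg_labels),
            all(dim(gt_labels) == dim(seg_labels)))
  gt <- gt_labels == class_id
  seg <- seg_labels == class_id
  if (!any(gt) || !any(seg)) {
    stop(sprintf("class %s is absent from %s label map", class_id,
                 if (!any(gt)) "the ground-truth" else "the segmented"),
         call. = FALSE)
  }
  overlap_metrics(gt, seg)
}

#' Count intensity modes of a quantized histogram
#'
#' Bins the values at `bin_width`, drops bins holding less than `min_frac`
#' of the pixels, and counts maximal runs of retained bins separated by
#' gaps larger than `gap` bins.  A well bias-corrected piecewise-constant
#' image concentrates into at most one run per class, while a bias-smeared
#' image occupies a broad range of bins.
#'
#' @param values Numeric vector or matrix of intensities.
#' @param bin_width Width of the quantization bins.
#' @param min_frac Minimum fraction of pixels for a bin to count.
#' @param gap Maximum bin gap bridged within one mode.
#' @return Integer number of modes.
#' @export
count_intensity_modes <- function(values, bin_width = 1, min_frac = 0.005,
                                  gap = 2L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (!length(v)) return(0L)
  tab <- table(floor(v / bin_width))
  idx <- sort(as.integer(names(tab))[tab >= max(1, min_frac * length(v))])
  if (!length(idx)) return(0L)
  sum(diff(idx) > gap) + 1L
}
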