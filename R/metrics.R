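# Quantitative metric suite: envelope mean/std, l1 and l2 losses,
# normalized cross correlation (NCC), structural similarity (SSIM).
#
# All metrics operate on max-normalized envelope images (the domain in
# which the losses are defined); the population (1/N) variance convention
# is used throughout.

#' Metric configuration
#'
#' @param ssim_k1,ssim_k2 SSIM stabilization constants (defaults 0.01 and
#'   0.03); `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, `C3 = C2 / 2`.
#' @param ssim_L dynamic range of the image values (1 for normalized
#'   envelopes).
#' @param ssim_mode `"windowed"` (mean of the SSIM map over 11x11 Gaussian
#'   windows, the standard form) or `"global"` (a single evaluation of the
#'   SSIM formula over the whole image).
#' @param window_size sliding-window side length (odd, default 11).
#' @param window_sigma Gaussian window standard deviation in pixels
#'   (default 1.5).
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(ssim_k1 = 0.01, ssim_k2 = 0.03, ssim_L = 1,
                          ssim_mode = c("windowed", "global"),
                          window_size = 11L, window_sigma = 1.5) {
  if (ssim_k1 <= 0 || ssim_k2 <= 0) stop_validation("k1, k2 must be > 0")
  if (ssim_L <= 0) stop_validation("L must be > 0")
  if (window_size %% 2 == 0) stop_validation("window size must be odd")
  structure(
    list(ssim_k1 = ssim_k1, ssim_k2 = ssim_k2, ssim_L = ssim_L,
         ssim_mode = match.arg(ssim_mode),
         window_size = as.integer(window_size),
         window_sigma = window_sigma),
    class = "metric_config"
  )
}

as_pixel_matrix <- function(img) {
  v <- if (inherits(img, "envelope_image")) img$values else img
  if (!is.matrix(v) || length(v) < 1L) {
    stop_validation("expected a nonempty image matrix")
  }
  if (any(!is.finite(v))) stop_validation("image values must be finite")
  v
}

check_same_shape <- function(x, y) {
  if (!all(dim(x) == dim(y))) {
    stop_validation("image shapes differ (%s vs %s); no implicit resampling",
                    paste(dim(x), collapse = "x"),
                    paste(dim(y), collapse = "x"))
  }
}

#' Envelope mean and standard deviation
#'
#' Arithmetic mean and population (1/N) standard deviation over all pixels
#' of an envelope-detected image.
#'
#' @param img an [envelope_image()] or numeric matrix.
#' @return named numeric vector `c(mean, std)`.
#' @export
image_mean_std <- function(img) {
  v <- as_pixel_matrix(img)
  m <- mean(v)
  c(mean = m, std = sqrt(mean((v - m)^2)))
}

#' Image-to-image l1 and l2 losses
#'
#' `l1 = mean(|x - y|)` and `l2 = mean((x - y)^2)` over the N overlapping
#' pixels; both symmetric in their arguments and zero iff the images are
#' equal.
#'
#' @param x,y same-shape [envelope_image()]s or matrices.
#' @return a scalar loss.
#' @export
l1_loss <- function(x, y) {
  x <- as_pixel_matrix(x); y <- as_pixel_matrix(y)
  check_same_shape(x, y)
  mean(abs(x - y))
}

#' @rdname l1_loss
#' @export
l2_loss <- function(x, y) {
  x <- as_pixel_matrix(x); y <- as_pixel_matrix(y)
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Normalized cross correlation
#'
#' Pearson correlation between two images:
#' `sum((x - mu_x)(y - mu_y)) / sqrt(sum((x - mu_x)^2) sum((y - mu_y)^2))`.
#' Invariant under positive affine maps of either argument; lies in
#' `[-1, 1]`. A zero-variance input makes the correlation undefined and
#' raises an error rather than returning NaN (a constant beamformer output
#' should be surfaced, not masked).
#'
#' @param x,y same-shape [envelope_image()]s or matrices.
#' @return a scalar in `[-1, 1]`.
#' @export
ncc <- function(x, y) {
  x <- as_pixel_matrix(x); y <- as_pixel_matrix(y)
  check_same_shape(x, y)
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    stop_validation("undefined correlation: zero-variance input image")
  }
  r <- sum(dx * dy) / sqrt(sx * sy)
  min(1, max(-1, r))
}

#' Structural similarity index
#'
#' In `"windowed"` mode (default) the SSIM map is computed over sliding
#' Gaussian windows (size 11, sigma 1.5) fully contained in the image, and
#' its mean is returned; in `"global"` mode the collapsed formula
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' is evaluated once over the whole image. Population variances are used.
#'
#' @param x,y same-shape [envelope_image()]s or matrices with values in
#'   `[0, ssim_L]`.
#' @param cfg a [metric_config()].
#' @return a scalar in `[-1, 1]`; exactly 1 when `x == y`.
#' @export
ssim <- function(x, y, cfg = metric_config()) {
  x <- as_pixel_matrix(x); y <- as_pixel_matrix(y)
  check_same_shape(x, y)
  C1 <- (cfg$ssim_k1 * cfg$ssim_L)^2
  C2 <- (cfg$ssim_k2 * cfg$ssim_L)^2
  if (cfg$ssim_mode == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  k <- gaussian_kernel2(cfg$window_size, cfg$window_sigma)
  mx <- conv2_valid(x, k)
  my <- conv2_valid(y, k)
  vx <- conv2_valid(x * x, k) - mx^2
  vy <- conv2_valid(y * y, k) - my^2
  cxy <- conv2_valid(x * y, k) - mx * my
  # clamp tiny negative variances from floating-point cancellation
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)
  map <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(map)
}

#' Full metric report for a (ground truth, network output) pair
#'
#' Bundles the envelope mean and standard deviation of the network output
#' with the four image-to-image metrics against the ground truth.
#'
#' @param gt ground-truth [envelope_image()] (reference DAS).
#' @param out network-output [envelope_image()] of the same shape.
#' @param cfg a [metric_config()].
#' @return an object of class `metric_report` with fields `mean`, `std`
#'   (of `out`), `gt_mean`, `gt_std`, `l1`, `l2`, `ncc`, `ssim`,
#'   `n_pixels`. `ncc` is `NA` when either image has zero variance.
#' @export
metric_report <- function(gt, out, cfg = metric_config()) {
  g <- as_pixel_matrix(gt); o <- as_pixel_matrix(out)
  check_same_shape(g, o)
  ms <- image_mean_std(o)
  gms <- image_mean_std(g)
  r <- tryCatch(ncc(g, o), bp_validation_error = function(e) NA_real_)
  structure(
    list(mean = unname(ms["mean"]), std = unname(ms["std"]),
         gt_mean = unname(gms["mean"]), gt_std = unname(gms["std"]),
         l1 = l1_loss(g, o), l2 = l2_loss(g, o),
         ncc = r, ssim = ssim(g, o, cfg), n_pixels = length(g)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> mean %.4f +/- %.4f | l1 %.4g l2 %.4g | NCC %s SSIM %.4f\n",
    x$mean, x$std, x$l1, x$l2,
    if (is.na(x$ncc)) "NA" else sprintf("%.4f", x$ncc), x$ssim))
  invisible(x)
}
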