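#' Focus score of an image by Laplacian variance
#'
#' Applies the 3x3 discrete Laplacian stencil
#' `[[0,1,0],[1,-4,1],[0,1,0]]` with reflected (reflect-101) borders and
#' returns the population variance of the response. Sharper images carry
#' more high-frequency energy and score higher; this is the standard
#' autofocus measure used to pick the best in-focus plane of a z-stack.
#' Reflected borders make the response of a constant image exactly zero
#' everywhere and the score invariant to adding a constant offset.
#'
#' @param image A [fluor_image()] or numeric matrix.
#' @return Nonnegative scalar variance of the Laplacian response.
#' @export
#' @examples
#' laplacian_variance(fluor_image(matrix(1, 5, 5))) # 0: constant image
laplacian_variance <- function(image) {
  image <- as_fluor_image(image)
  lap <- laplacian_response(image)
  mean((lap - mean(lap))^2) # population variance (divide by n)
}

# 4-neighbour Laplacian response with reflect-101 borders: the out-of-image
# neighbour of a border pixel is its mirror inside the image (row 0 -> row 2),
# degenerating to the pixel itself when the image is a single row/column
laplacian_response <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  refl <- function(i, n) ifelse(i < 1L, pmin(2L - i, n), ifelse(i > n, pmax(2L * n - i, 1L), i))
  rows_up <- refl(seq_len(nr) - 1L, nr)
  rows_down <- refl(seq_len(nr) + 1L, nr)
  cols_left <- refl(seq_len(nc) - 1L, nc)
  cols_right <- refl(seq_len(nc) + 1L, nc)
  m[rows_up, , drop = FALSE] + m[rows_down, , drop = FALSE] +
    m[, cols_left, drop = FALSE] + m[, cols_right, drop = FALSE] - 4 * m
}

#' Select the best in-focus plane of a z-stack
#'
#' Scores every plane with [laplacian_variance()] and returns the plane with
#' the maximal score; ties are broken by the lowest z index.
#'
#' @param stack A [z_stack()].
#' @return A list with `plane_index` (0-based, matching `z_index`) and
#'   `image`, the selected [fluor_image()].
#' @export
select_best_focus <- function(stack) {
  if (!inherits(stack, "z_stack")) ect_error("expected a z_stack", "ect_invalid_input")
  scores <- vapply(stack$planes, laplacian_variance, numeric(1))
  k <- which.max(scores) # which.max returns the first maximum -> lowest index
  list(plane_index = k - 1L, image = stack$planes[[k]], scores = scores)
}

#' Maximum-intensity projection of a z-stack
#'
#' @param stack A [z_stack()].
#' @return A [fluor_image()] holding the per-pixel maximum across planes; the
#'   channel label is preserved.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "z_stack")) ect_error("expected a z_stack", "ect_invalid_input")
  out <- stack$planes[[1]]
  m <- unclass(out)
  for (p in stack$planes[-1]) m <- pmax(m, unclass(p))
  fluor_image(m, channel = attr(out, "channel"))
}

# Separable Gaussian blur with reflected borders; kernel truncated at 3 sigma.
# Used by the synthetic focus-stack generator to defocus planes.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(x) { # convolve each column of x with k, reflect padding
    n <- nrow(x)
    idx <- c(rev(seq_len(h)), seq_len(n), n - seq_len(h) + 1L)
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(m))))
}
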