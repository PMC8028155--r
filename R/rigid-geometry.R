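# Numerical tolerances used across the rigid-geometry layer.
.km_tol <- list(
  orthonormal = 1e-9,   # ||R'R - I|| and |det(R) - 1| for stored rotations
  inverse     = 1e-12,  # compose(T, invert(T)) round-trip
  rank        = 1e-8,   # relative 2nd-singular-value cutoff for degeneracy
  rotation_in = 1e-6    # orthonormality accepted on user-supplied matrices
)

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation in mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  if (length(t) != 3L) stop("`t` must have length 3", call. = FALSE)
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > .km_tol$rotation_in) {
    stop(sprintf("R is not orthonormal (max |R'R - I| = %.2e)", err), call. = FALSE)
  }
  if (abs(det(R) - 1) > .km_tol$rotation_in) {
    stop("R must be a proper rotation (det = +1)", call. = FALSE)
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("R:\n"); print(round(x$R, 6))
  cat("t:", sprintf("%.4f", x$t), "(mm)\n")
  if (!is.null(x$residual_rms)) cat(sprintf("residual RMS: %.6g mm (n = %d)\n",
                                            x$residual_rms, x$n))
  invisible(x)
}

#' Least-squares rigid registration of corresponding point sets
#'
#' Finds the rotation `R` and translation `t` minimising
#' \eqn{\sum_i \|R s_i + t - d_i\|^2} over proper rigid motions, using the
#' closed-form centroid-subtraction + SVD (Kabsch) solution. Reflections
#' arising from noisy or near-planar data are corrected by flipping the
#' sign of the smallest singular direction, so `det(R) = +1` always holds.
#'
#' @param src numeric `N x 3` matrix of source points (mm), `N >= 3`,
#'   spanning at least a plane.
#' @param dst numeric `N x 3` matrix of corresponding destination points.
#' @return a `rigid_fit` (subclass of [rigid_transform()]) with elements
#'   `R`, `t`, `residual_rms` (mm) and `n`.
#' @export
fit_rigid <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  n <- nrow(src)
  if (n < 3L || nrow(dst) != n) {
    stop("need at least 3 corresponding point pairs", call. = FALSE)
  }
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  sv_src <- svd(A)$d
  scale <- max(sv_src[1], 1e-12)
  if (sv_src[2] / scale < .km_tol$rank) {
    stop("degenerate geometry: source points are collinear or coincident",
         call. = FALSE)
  }
  H <- crossprod(A, B)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cd - as.vector(R %*% cs)
  resid <- dst - (src %*% t(R) + matrix(t, n, 3, byrow = TRUE))
  out <- rigid_transform(R, t)
  out$residual_rms <- sqrt(mean(rowSums(resid^2)))
  out$n <- n
  class(out) <- c("rigid_fit", class(out))
  out
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must be N x 3", call. = FALSE)
  p
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points `N x 3` matrix or length-3 vector (mm).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- as_points(points)
  q <- p %*% t(transform$R) + matrix(transform$t, nrow(p), 3, byrow = TRUE)
  if (vec && nrow(q) == 1L) as.vector(q) else q
}

#' Compose two rigid transforms
#'
#' `compose(t2, t1)` acts as "first `t1`, then `t2`".
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return their composition as a [rigid_transform()].
#' @export
compose <- function(t2, t1) {
  rigid_transform(t2$R %*% t1$R, as.vector(t2$R %*% t1$t) + t2$t)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.vector(Rt %*% transform$t))
}

#' @method tidy rigid_transform
#' @export
tidy.rigid_transform <- function(x, ...) {
  tibble::tibble(
    term = c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33",
             "tx", "ty", "tz"),
    estimate = c(as.vector(t(x$R)), x$t)
  )
}

#' @method glance rigid_fit
#' @export
glance.rigid_fit <- function(x, ...) {
  tibble::tibble(
    residual_rms = x$residual_rms,
    n_points = x$n,
    det = det(x$R),
    max_orthonormality_error = max(abs(crossprod(x$R) - diag(3)))
  )
}
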