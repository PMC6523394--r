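#' Graded radial grid on the normalised radius
#'
#' Node placement for the front-fixed coordinate `xi = r / S(t)` on `[0, 1]`.
#' The mesh is a two-zone grid with nodes `refine` times denser in the outer
#' `boundary_fraction` of the radius, where the concentration gradients that
#' drive the moving front are steepest.
#'
#' @param n_nodes Number of nodes (>= 50), endpoints included. Default 240.
#' @param refine Density ratio of the outer zone relative to the inner zone.
#' @param boundary_fraction Width of the refined outer zone in `xi`.
#' @return An object of class `radial_grid`: list with nodes `xi`, face
#'   positions `xi_face`, and spherical cell weights `w` (so that
#'   `sum(phi * w)` approximates `integral(phi * xi^2 dxi)`).
#' @export
radial_grid <- function(n_nodes = 240, refine = 3, boundary_fraction = 0.1) {
  if (n_nodes < 50) stop("`n_nodes` must be >= 50", call. = FALSE)
  if (refine < 1 || boundary_fraction <= 0 || boundary_fraction >= 1)
    stop("invalid grading parameters", call. = FALSE)
  L1 <- 1 - boundary_fraction
  # uniform spacing h inside, h / refine outside; total intervals n_nodes - 1
  h <- (L1 + refine * boundary_fraction) / (n_nodes - 1)
  n1 <- max(1L, round(L1 / h))
  n2 <- (n_nodes - 1L) - n1
  xi <- c(seq(0, L1, length.out = n1 + 1L),
          seq(L1, 1, length.out = n2 + 1L)[-1L])
  stopifnot(length(xi) == n_nodes, !is.unsorted(xi, strictly = TRUE))
  # finite-volume faces: cell i surrounds node i; last cell extends to xi = 1
  n <- n_nodes
  xi_face <- c(0, (xi[1:(n - 2L)] + xi[2:(n - 1L)]) / 2, 1)
  w <- diff(xi_face^3) / 3 # weights for nodes 1..n-1; boundary node has none
  structure(list(n_nodes = n, xi = xi, xi_face = xi_face, w = w),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("<radial_grid> %d nodes on [0, 1], min spacing %.2e\n",
              x$n_nodes, min(diff(x$xi))))
  invisible(x)
}

# One-sided second-order gradient at xi = 1 from the two outermost interior
# nodes and the boundary value. Coefficients for a non-uniform 3-point stencil.
boundary_gradient_coefs <- function(xi) {
  n <- length(xi)
  h1 <- 1 - xi[n - 1L] # distance boundary -> last interior node
  h2 <- 1 - xi[n - 2L]
  # derivative at x = 0 of the quadratic through (0, fb), (-h1, f1), (-h2, f2)
  c_b <- (h1 + h2) / (h1 * h2)
  c_1 <- -h2 / (h1 * (h2 - h1))
  c_2 <- h1 / (h2 * (h2 - h1))
  list(c_b = c_b, c_1 = c_1, c_2 = c_2)
}
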