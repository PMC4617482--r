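#' Closed-form fixture models
#'
#' Fixture models expose the same sampling/evaluation surface as ODE
#' models but score samples through a closed-form map z = g(p), so the
#' whole pipeline — partitioning, conditional densities, MIRI,
#' conditioning — can be validated fast against analytic expectations,
#' with no integrator in the loop.
#'
#' @param name fixture name.
#' @param map vectorized map: `(N x q matrix) -> numeric(N)`.
#' @param space the fixture's `parameter_space`.
#' @param driving character vector of parameter names that actually
#'   influence z (documented oracle, checked in tests).
#' @return object of class `fixture_model`.
#' @export
fixture_model <- function(name, map, space, driving = character()) {
  stopifnot(is.function(map), inherits(space, "parameter_space"))
  structure(list(name = name, map = map, space = space,
                 driving = driving,
                 parameter_names = space$names),
            class = "fixture_model")
}

#' Identity fixture: z equals one coordinate
#'
#' `z = p_j` on the unit box; every other parameter is inert.  The
#' analytic picture: conditioning on the upper/lower alpha-tail of z
#' confines p_j to the top/bottom alpha-fraction of its range (MIRI
#' near 2), while inert parameters keep uniform conditional marginals
#' (MIRI near 0).
#'
#' @param q dimension of the unit box.
#' @param driving_index which coordinate drives z.
#' @return a `fixture_model`.
#' @export
make_identity_fixture <- function(q, driving_index = 1L) {
  stopifnot(driving_index >= 1, driving_index <= q)
  nms <- paste0("p", seq_len(q))
  space <- parameter_space_bounds(nms, 0, 1)
  fixture_model("identity_fixture",
                function(m) m[, driving_index],
                space, driving = nms[driving_index])
}

#' Linear fixture: weighted sum of coordinates
#'
#' `z = sum(w_i * p_i)` on the unit box.  Larger |weight| means a
#' larger shift between the tail-conditioned marginals, hence a larger
#' MIRI; a negative weight swaps which tail concentrates the parameter
#' high versus low.
#'
#' @param weights numeric weights, at least one nonzero.
#' @return a `fixture_model`.
#' @export
make_linear_fixture <- function(weights) {
  if (all(weights == 0)) stop("all-zero weights")
  q <- length(weights)
  nms <- names(weights) %||% paste0("p", seq_len(q))
  space <- parameter_space_bounds(nms, 0, 1)
  fixture_model("linear_fixture",
                function(m) as.numeric(m[, nms, drop = FALSE] %*% weights),
                space,
                driving = nms[weights != 0])
}

#' Analytic Gaussian density pair
#'
#' Two exact normal pdfs placed on a shared grid (no kernel
#' estimation), as a quadrature oracle for [miri()]: the L1 distance
#' between N(mu1, sigma^2) and N(mu2, sigma^2) is known in closed form,
#' `2 * (2 * pnorm(|mu2 - mu1| / (2 * sigma)) - 1)`.
#'
#' @param mu1,mu2 means.
#' @param sigma common standard deviation (> 0).
#' @param grid_size number of grid points.
#' @param span half-width of the grid in units of sigma beyond the
#'   outermost mean.
#' @return list with `U` and `L` `cra_density` objects on a shared
#'   grid.
#' @export
gaussian_density_pair <- function(mu1, mu2, sigma = 1,
                                  grid_size = 4096, span = 8) {
  stopifnot(sigma > 0)
  x <- seq(min(mu1, mu2) - span * sigma, max(mu1, mu2) + span * sigma,
           length.out = grid_size)
  mk <- function(mu, src)
    structure(list(parameter = "gauss", x = x,
                   y = stats::dnorm(x, mu, sigma), bw = NA_real_,
                   source = src),
              class = "cra_density")
  list(U = mk(mu1, "U"), L = mk(mu2, "L"))
}
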