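# Beta-kernel copula density estimation (diagnostic only -- the DC score is
# computed from copula CDFs, never from a density estimate).

# Frank copula density with parameter theta (theta -> 0 is independence).
frank_density <- function(u, v, theta) {
  if (abs(theta) < 1e-8) return(rep(1, length(u) * length(v)))
  g <- function(t) expm1(-theta * t)
  num <- theta * (-g(1)) * exp(-theta * outer(u, v, "+"))
  den <- (g(1) - outer(g(u), g(v)))^2
  num / den
}

# Kendall tau of the Frank family: tau = 1 - 4/theta * (1 - D1(theta)),
# D1 the first Debye function. Inverted numerically.
frank_tau <- function(theta) {
  if (abs(theta) < 1e-8) return(theta / 9)  # small-theta expansion
  d1 <- stats::integrate(function(t) t / expm1(t), 0, abs(theta),
                         rel.tol = 1e-10)$value / abs(theta)
  tau <- 1 - 4 / abs(theta) * (1 - d1)
  sign(theta) * tau
}

frank_theta_from_tau <- function(tau) {
  if (abs(tau) < 1e-6) return(0)
  if (abs(tau) > 0.99) tau <- sign(tau) * 0.99
  uniroot(function(th) frank_tau(th) - tau,
          interval = sort(c(sign(tau) * 1e-6, sign(tau) * 500)),
          tol = 1e-9)$root
}

# Plug-in AMISE for the product beta-kernel estimator against a Frank
# reference density c:  AMISE(h) ~ h^2 * int B^2 + V / (m h), with
#   B = (1-2u) c_u + u(1-u)/2 c_uu + (1-2v) c_v + v(1-v)/2 c_vv
# (the O(h) bias of the mode-matched beta kernel in each coordinate) and
#   V = (4*pi)^-1 * int c / sqrt(u(1-u)v(1-v))
# (the leading interior variance factor). Integrals by midpoint rule on a
# coarse interior lattice; derivatives by central differences.
amise_bandwidth <- function(u, v, m) {
  theta <- frank_theta_from_tau(cor(u, v, method = "kendall"))
  g <- 41L
  s <- (seq_len(g) - 0.5) / g
  eps <- 1e-3
  cc <- frank_density(s, s, theta)
  du <- (frank_density(s + eps, s, theta) -
           frank_density(s - eps, s, theta)) / (2 * eps)
  dv <- (frank_density(s, s + eps, theta) -
           frank_density(s, s - eps, theta)) / (2 * eps)
  duu <- (frank_density(s + eps, s, theta) - 2 * cc +
            frank_density(s - eps, s, theta)) / eps^2
  dvv <- (frank_density(s, s + eps, theta) - 2 * cc +
            frank_density(s, s - eps, theta)) / eps^2
  U <- matrix(s, g, g); V <- t(U)
  B <- (1 - 2 * U) * du + U * (1 - U) / 2 * duu +
    (1 - 2 * V) * dv + V * (1 - V) / 2 * dvv
  bias2 <- mean(B^2)
  varint <- mean(cc / sqrt(U * (1 - U) * V * (1 - V))) / (4 * pi)
  obj <- function(h) h^2 * bias2 + varint / (m * h)
  optimize(obj, lower = 1 / m, upper = m^(-1 / 5))$minimum
}

#' Beta-kernel estimate of the copula density on a grid
#'
#' Diagnostic smooth of the dependence structure: the copula density is
#' estimated at each lattice point (u, v) as the average over
#' pseudo-observations of a product of beta kernels, each kernel having its
#' mode at the data point and concentration `1/h`. Beta kernels are supported
#' on \[0, 1\], so no boundary mass is lost. For density estimation the
#' pseudo-observations are rescaled by `m / (m + 1)` to keep them off the
#' corner `u = 1`.
#'
#' `bandwidth = "auto"` selects `h` by minimizing a plug-in approximation of
#' the asymptotic mean integrated squared error whose reference density is
#' the Frank copula fitted by inverting the sample Kendall tau; the search is
#' a golden-section minimization over `[1/m, m^(-1/5)]`.
#'
#' @param cop An [empirical_copula()] with at least 10 points.
#' @param bandwidth Positive smoothing parameter, or `"auto"`.
#' @param grid_size Lattice side (midpoint grid of the unit square).
#' @return Object of class `copula_density`: list with `grid`
#'   (`grid_size` x `grid_size` density values), `u`, `v` (lattice
#'   coordinates), `bandwidth`, `m`.
#' @export
beta_kernel_density <- function(cop, bandwidth = "auto", grid_size = 50) {
  stopifnot(inherits(cop, "empirical_copula"))
  if (cop$m < 10) stop("need at least 10 observations", call. = FALSE)
  if (grid_size < 2) stop("grid_size must be >= 2", call. = FALSE)
  u <- cop$u * cop$m / (cop$m + 1)
  v <- cop$v * cop$m / (cop$m + 1)
  if (identical(bandwidth, "auto")) {
    bandwidth <- amise_bandwidth(u, v, cop$m)
  } else if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
             bandwidth <= 0) {
    stop("bandwidth must be a positive scalar or \"auto\"", call. = FALSE)
  }
  s <- (seq_len(grid_size) - 0.5) / grid_size
  a_u <- u / bandwidth + 1; b_u <- (1 - u) / bandwidth + 1
  a_v <- v / bandwidth + 1; b_v <- (1 - v) / bandwidth + 1
  Ku <- vapply(seq_len(cop$m),
               function(j) dbeta(s, a_u[j], b_u[j]), numeric(grid_size))
  Kv <- vapply(seq_len(cop$m),
               function(j) dbeta(s, a_v[j], b_v[j]), numeric(grid_size))
  structure(list(grid = Ku %*% t(Kv) / cop$m, u = s, v = s,
                 bandwidth = bandwidth, m = cop$m),
            class = "copula_density")
}

#' @export
print.copula_density <- function(x, ...) {
  cat(sprintf(
    "copula_density: %d x %d grid, bandwidth %.4g (Riemann mass %.3f)\n",
    nrow(x$grid), ncol(x$grid), x$bandwidth, mean(x$grid)))
  invisible(x)
}
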