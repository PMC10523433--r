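#' Wrap angles into the half-open interval (-180, 180]
#'
#' All torsions in the package live on the circle with the convention
#' that the anti-periplanar angle is reported as +180 degrees, never -180.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector with every value in (-180, 180].
#' @examples
#' wrap_angle(c(270, -180, 540))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  w <- x - 360 * ceiling((x - 180) / 360)
  # map -180 (representable when x is an exact multiple) up to +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and resultant length of angles in degrees
#'
#' Resultant-vector summary used for per-state torsion statistics: the
#' mean direction is `atan2(mean sin, mean cos)` and the resultant length
#' is the modulus of the mean unit vector (1 for perfectly concentrated
#' samples, 0 for uniform ones).
#'
#' @param x Angles in degrees.
#' @return List with `mean` (degrees in (-180, 180]) and `resultant`
#'   (unitless, in \[0, 1\]).
#' @examples
#' circular_mean(c(170, -170))  # 180, not 0
#' @export
circular_mean <- function(x) {
  if (length(x) == 0 || all(is.na(x))) {
    return(list(mean = NA_real_, resultant = NA_real_))
  }
  x <- x[!is.na(x)]
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  r <- sqrt(s^2 + c^2)
  m <- if (r < .Machine$double.eps) NA_real_ else wrap_angle(rad2deg(atan2(s, c)))
  list(mean = m, resultant = r)
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best-Fisher (1979) rejection sampler. Used by the synthetic-trajectory
#' generator for angular emissions around a state center; written here
#' because no circular-statistics distribution is otherwise required by
#' the package.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (> 0); larger is tighter. `kappa = 0` gives
#'   the circular uniform distribution.
#' @return Numeric vector of angles in degrees, wrapped to (-180, 180].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_angle(runif(n, -180, 180)))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  # batched rejection sampling; acceptance is well above 50% for all kappa
  while (length(out) < n) {
    m <- max(16L, ceiling(1.6 * (n - length(out))))
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    u3 <- runif(m)
    th <- mu_r + sign(u3 - 0.5) * acos(f)
    out <- c(out, th[ok])
  }
  wrap_angle(rad2deg(out[seq_len(n)]))
}

# internal: place atom D given positions of A, B, C and internal
# coordinates (bond CD, angle BCD in degrees, torsion ABCD in degrees).
# Standard NeRF construction; the resulting signed torsion A-B-C-D equals
# `torsion` under the package's sign convention.
zmat_place <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) {
    abort("zmat_place: reference atoms A, B, C are collinear",
          class = "ligmode_degenerate_geometry")
  }
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# 3-vector cross product (kept local; avoids pulling in a linear-algebra
# package for one primitive)
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
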