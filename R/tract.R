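#' Vocal-tract geometry
#'
#' A tract geometry holds the spatial grid over `[0, L]` (cm, glottal end to
#' lips), the neutral diameter profile `Omega(x)` (cm) and the two mode
#' shapes `phi1(x)`, `phi2(x)` (dimensionless) that deform the diameter
#' towards a vowel. The time-varying area function is
#' \deqn{A(x,t) = \frac{\pi}{4}\,[\Omega(x) + q_1(t)\varphi_1(x) +
#'   q_2(t)\varphi_2(x)]^2 \prod_k [1 - c_k(x)\, m(t - t_k)]}
#' where each occlusion gesture `k` contributes a spatial bump `c_k` and a
#' temporal activation `m`, both reaching 1 at the occlusion place and time
#' so that the tract closes completely there: `A(x_k, t_k) = 0`.
#'
#' @param x_grid Strictly increasing positions in cm, from 0 to `L`.
#' @param omega Neutral diameter `Omega(x)` in cm, strictly positive.
#' @param phi1,phi2 Mode shapes sampled on `x_grid`.
#' @param q1_a,q2_a Mode coefficients of the target vowel /a/ (reached at the
#'   end of the utterance when the vowel trajectory is linear).
#' @return An object of class `tract_geometry`.
#' @seealso [default_tract_geometry()], [area_function()]
#' @export
tract_geometry <- function(x_grid, omega, phi1, phi2, q1_a = 0.9, q2_a = 0.95) {
  x_grid <- as.numeric(x_grid)
  n <- length(x_grid)
  if (n < 2L || any(diff(x_grid) <= 0)) stop("x_grid must be strictly increasing")
  if (x_grid[1] != 0) stop("x_grid must start at 0 (glottal end)")
  if (length(omega) != n || length(phi1) != n || length(phi2) != n) {
    stop("omega, phi1, phi2 must have the same length as x_grid")
  }
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("invalid geometry: Omega(x) must be strictly positive everywhere")
  }
  structure(
    list(x_grid = x_grid, L = x_grid[n], omega = as.numeric(omega),
         phi1 = as.numeric(phi1), phi2 = as.numeric(phi2),
         q1_a = q1_a, q2_a = q2_a),
    class = "tract_geometry"
  )
}

#' Packaged parametric tract geometry
#'
#' The diameter profile and modes of the real study come from an orthogonal
#' decomposition of MRI anatomical data that is not publicly tabulated, so
#' the package ships a smooth parametric stand-in: tract length
#' `L = 17.5` cm on `n = 101` points, a gently flaring neutral diameter
#' `Omega(x) = 1.8 - 0.4 cos(pi x / L)` cm, and half- and full-cosine modes
#' `phi1 = cos(pi x / L)`, `phi2 = cos(2 pi x / L)`. The packaged /a/
#' targets (`q1 = 0.9`, `q2 = 0.95`) concentrate the vowel deformation in
#' the velar region (a strong constriction near `0.6 L`, where the tongue
#' body shapes /a/), leave a moderate deformation at the alveolar place
#' and keep the lips nearly neutral — the deformation gradient along the
#' tract that drives the place asymmetry of the effort functional. Any
#' user-supplied geometry table (see [read_tract_geometry()]) can be
#' swapped in.
#'
#' @param L Tract length in cm.
#' @param n Number of grid points.
#' @param q1_a,q2_a Vowel /a/ mode targets.
#' @return A `tract_geometry`.
#' @export
default_tract_geometry <- function(L = 17.5, n = 101, q1_a = 0.9, q2_a = 0.95) {
  x <- seq(0, L, length.out = n)
  tract_geometry(
    x_grid = x,
    omega = 1.8 - 0.4 * cos(pi * x / L),
    phi1 = cos(pi * x / L),
    phi2 = cos(2 * pi * x / L),
    q1_a = q1_a, q2_a = q2_a
  )
}

#' Read / write a tract geometry as delimited text
#'
#' Four-column table (`x`, `omega`, `phi1`, `phi2`); the /a/ targets travel
#' in `# q1_a=` / `# q2_a=` header comments.
#'
#' @param path File path.
#' @param geometry A `tract_geometry` (for writing).
#' @return `read_tract_geometry()` returns a `tract_geometry`.
#' @export
read_tract_geometry <- function(path) {
  header <- readLines(path, n = 10L)
  grab <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), header, value = TRUE)
    if (length(hit)) as.numeric(sub(".*=", "", hit[1])) else default
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  tract_geometry(tab$x, tab$omega, tab$phi1, tab$phi2,
                 q1_a = grab("q1_a", 0.9), q2_a = grab("q2_a", 0.95))
}

#' @rdname read_tract_geometry
#' @export
write_tract_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "tract_geometry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vocal tract geometry (synthetic parametric stand-in unless replaced)",
    sprintf("# q1_a=%g", geometry$q1_a),
    sprintf("# q2_a=%g", geometry$q2_a)
  ), con)
  utils::write.table(
    data.frame(x = geometry$x_grid, omega = geometry$omega,
               phi1 = geometry$phi1, phi2 = geometry$phi2),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Neutral (relaxed) area profile
#'
#' The area of the undeformed tract, `A_Omega(x) = (pi/4) Omega(x)^2` cm^2 —
#' the zero-gesture limit of the area function.
#'
#' @param geometry A `tract_geometry`.
#' @return Numeric vector of areas (cm^2) on `geometry$x_grid`.
#' @export
neutral_area <- function(geometry) {
  stopifnot(inherits(geometry, "tract_geometry"))
  (pi / 4) * geometry$omega^2
}

#' Gestures
#'
#' `vowel_gesture()` describes the linear evolution of the mode coefficients
#' from the neutral tract (`q = 0` at `t = 0`) to their vowel targets at the
#' utterance end `T`. `occlusion_gesture()` describes one plosive closure: a
#' Gaussian spatial bump of half-width `sigma` centred at the occlusion
#' place `x_k`, activated by a raised-cosine window of total width `w`
#' centred at the occlusion time `t_k`.
#'
#' @param q1_target,q2_target Mode coefficients reached at `t = T`.
#' @param T_total Utterance duration in seconds.
#' @param x_k Occlusion place in cm.
#' @param t_k Occlusion time in seconds.
#' @param sigma Spatial half-width in cm (> 0).
#' @param w Activation total duration in seconds (> 0).
#' @return A `vowel_gesture` / `occlusion_gesture` object.
#' @export
vowel_gesture <- function(q1_target, q2_target, T_total) {
  if (!is.numeric(T_total) || T_total <= 0) stop("T must be positive")
  structure(list(q1_target = q1_target, q2_target = q2_target, T_total = T_total),
            class = "vowel_gesture")
}

#' @rdname vowel_gesture
#' @export
occlusion_gesture <- function(x_k, t_k, sigma = 1.0, w = 0.120) {
  if (sigma <= 0) stop("sigma must be positive")
  if (w <= 0) stop("activation duration w must be positive")
  structure(list(x_k = x_k, t_k = t_k, sigma = sigma, w = w),
            class = "occlusion_gesture")
}

#' Temporal activation of an occlusion
#'
#' Raised-cosine window of total width `w` centred at the occlusion time:
#' `m = 0.5 (1 + cos(2 pi (t - t_k) / w))` inside `|t - t_k| < w/2`, zero
#' outside. Peaks at exactly 1 at `t = t_k`; its time integral is `w/2`.
#'
#' @param g An `occlusion_gesture`.
#' @param t Time(s) in seconds (vectorised).
#' @return Activation value(s) in `[0, 1]`.
#' @export
occlusion_activation <- function(g, t) {
  stopifnot(inherits(g, "occlusion_gesture"))
  u <- t - g$t_k
  out <- numeric(length(u))
  inside <- abs(u) < g$w / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * u[inside] / g$w))
  out
}

#' Spatial profile of an occlusion
#'
#' Gaussian bump `c(x) = exp(-(x - x_k)^2 / (2 sigma^2))`, equal to 1 at the
#' occlusion place and symmetric about it.
#'
#' @param g An `occlusion_gesture`.
#' @param x Position(s) in cm (vectorised).
#' @return Profile value(s) in `(0, 1]`.
#' @export
occlusion_profile <- function(g, x) {
  stopifnot(inherits(g, "occlusion_gesture"))
  exp(-(x - g$x_k)^2 / (2 * g$sigma^2))
}

#' Vowel mode trajectory
#'
#' Linear interpolation of the mode coefficients from 0 at utterance onset
#' to their targets at `t = T`.
#'
#' @param v A `vowel_gesture`.
#' @param t Time(s) in `[0, T]` (vectorised).
#' @return A list with numeric components `q1` and `q2`.
#' @export
vowel_trajectory <- function(v, t) {
  stopifnot(inherits(v, "vowel_gesture"))
  if (any(t < 0 | t > v$T_total)) {
    stop("t outside the utterance interval [0, T]")
  }
  frac <- t / v$T_total
  list(q1 = v$q1_target * frac, q2 = v$q2_target * frac)
}

#' Time-varying vocal-tract area function
#'
#' Evaluates the area function on the full space-time grid: the squared
#' vowel substrate `(pi/4)[Omega + q1 phi1 + q2 phi2]^2` multiplied, for
#' each occlusion gesture, by `[1 - c_k(x) m(t - t_k)]`. The product
#' `c_k(x) m(.)` is clamped at 1 so occlusion factors never go negative.
#'
#' @param geometry A `tract_geometry`.
#' @param vowel A `vowel_gesture`.
#' @param occlusions List of `occlusion_gesture`s (possibly empty).
#' @param t_grid Times in seconds, within `[0, T]`.
#' @return An `area_field`: list with `area` (matrix, space x time, cm^2),
#'   `x_grid`, `t_grid` and `neutral` (the `A_Omega(x)` profile).
#' @export
area_function <- function(geometry, vowel, occlusions = list(), t_grid) {
  stopifnot(inherits(geometry, "tract_geometry"), inherits(vowel, "vowel_gesture"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1L) stop("t_grid must be non-empty")
  for (g in occlusions) {
    if (!inherits(g, "occlusion_gesture")) stop("occlusions must be occlusion_gesture objects")
    if (g$x_k < 0 || g$x_k > geometry$L) {
      stop("occlusion place outside the tract [0, L]: x_k = ", g$x_k)
    }
  }
  q <- vowel_trajectory(vowel, t_grid)
  # substrate: outer over (x, t)
  diam <- outer(geometry$phi1, q$q1) + outer(geometry$phi2, q$q2)
  diam <- diam + geometry$omega
  area <- (pi / 4) * diam^2
  for (g in occlusions) {
    cm <- outer(occlusion_profile(g, geometry$x_grid), occlusion_activation(g, t_grid))
    cm <- pmin(cm, 1)
    area <- area * (1 - cm)
  }
  structure(
    list(area = area, x_grid = geometry$x_grid, t_grid = t_grid,
         neutral = neutral_area(geometry)),
    class = "area_field"
  )
}

#' Export an area field as delimited text
#'
#' Dense matrix with `x` as the first column and one column per time sample
#' (times in the header row).
#'
#' @param field An `area_field`.
#' @param path Output path.
#' @export
write_area_field <- function(field, path) {
  stopifnot(inherits(field, "area_field"))
  tab <- data.frame(x = field$x_grid, field$area, check.names = FALSE)
  names(tab) <- c("x", sprintf("t=%.6f", field$t_grid))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
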