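# small shared fixtures, built in code

tiny_geometry <- function(n = 21, L = 17.5) {
  default_tract_geometry(L = L, n = n)
}

# a fast effort config for tests that only need qualitative behaviour
fast_effort_config <- function(geometry = default_tract_geometry(),
                               E0 = 1, dt_time = 0.005) {
  default_effort_config(geometry, E0 = E0, dt_time = dt_time)
}

# scalar reference evaluation of the area formula, independent of the
# vectorised implementation path
area_scalar <- function(geometry, vowel, occlusions, x, t) {
  i <- which.min(abs(geometry$x_grid - x))
  stopifnot(abs(geometry$x_grid[i] - x) < 1e-9)
  frac <- t / vowel$T_total
  diam <- geometry$omega[i] + vowel$q1_target * frac * geometry$phi1[i] +
    vowel$q2_target * frac * geometry$phi2[i]
  a <- (pi / 4) * diam^2
  for (g in occlusions) {
    m <- 0
    if (abs(t - g$t_k) < g$w / 2) m <- 0.5 * (1 + cos(2 * pi * (t - g$t_k) / g$w))
    ck <- exp(-(x - g$x_k)^2 / (2 * g$sigma^2))
    a <- a * (1 - min(ck * m, 1))
  }
  a
}

# brute-force scan of a fixation sequence for FFD / FPRT / TFT
measures_bruteforce <- function(aoi, duration, target) {
  hit <- which(!is.na(aoi) & aoi == target)
  if (!length(hit)) return(c(ffd = NA, fprt = NA, tft = NA))
  first <- hit[1]
  ffd <- duration[first]
  fprt <- 0
  for (i in first:length(aoi)) {
    if (!is.na(aoi[i]) && aoi[i] != target) break
    if (!is.na(aoi[i]) && aoi[i] == target) fprt <- fprt + duration[i]
  }
  c(ffd = ffd, fprt = fprt, tft = sum(duration[hit]))
}
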