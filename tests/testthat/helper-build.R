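# Builders for fixtures constructed in code.

make_epochs <- function(t, v, missing = rep(FALSE, length(t)), id = "a",
                        epoch_len = if (length(t) > 1) t[2] - t[1] else 60) {
  v[missing] <- NA_real_
  structure(tibble::tibble(epoch_start = t, value = v, missing = missing),
            class = c("epoch_series", class(tibble::tibble())),
            animal_id = id, epoch_len = epoch_len)
}

# days of 1-min epochs carrying a diurnal sinusoid plus noise
diurnal_epochs <- function(days, amp = 1, sigma = 0, mean_level = 2,
                           period = 86400, id = "a", t0 = 0) {
  t <- seq(t0, t0 + days * 86400 - 60, by = 60)
  v <- mean_level + amp * sin(2 * pi * t / period)
  if (sigma > 0) v <- v + stats::rnorm(length(t), 0, sigma)
  make_epochs(t, v, id = id)
}

make_trace <- function(anchor, intensity, id = "a", step = 900,
                       window_len = 7 * 86400) {
  structure(tibble::tibble(anchor = anchor, intensity = intensity,
                           coverage = ifelse(is.na(intensity), 0, 1)),
            class = c("periodicity_trace", class(tibble::tibble())),
            animal_id = id, step = step, window_len = window_len,
            target_period = 86400)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(m))
}

rotate_stream <- function(stream, R) {
  xyz <- cbind(stream$x, stream$y, stream$z) %*% t(R)
  triaxial_stream(stream$time, xyz[, 1], xyz[, 2], xyz[, 3],
                  animal_id = attr(stream, "animal_id"),
                  nominal_rate = attr(stream, "nominal_rate"))
}

# independent single-frequency fit using stats::lm (oracle for the
# cumulative-sum implementation)
lm_intensity <- function(epochs, period = 86400) {
  ok <- !epochs$missing & !is.na(epochs$value)
  t <- epochs$epoch_start[ok]; y <- epochs$value[ok]
  s <- sin(2 * pi * t / period); cc <- cos(2 * pi * t / period)
  summary(stats::lm(y ~ s + cc))$r.squared
}

# classical periodogram variance fraction at one frequency on a uniform,
# gap-free grid (brute-force DFT oracle)
periodogram_intensity <- function(epochs, period = 86400) {
  y <- epochs$value
  n <- length(y)
  t <- epochs$epoch_start
  f <- exp(-2i * pi * t / period)
  a <- sum((y - mean(y)) * f)
  # power at the target frequency relative to total variance, with the
  # half-amplitude convention of a real sinusoid
  (2 * Mod(a)^2 / n) / sum((y - mean(y))^2)
}
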