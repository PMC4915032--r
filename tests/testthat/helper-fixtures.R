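# Shared fixtures, rendered lazily and cached for the whole run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# one standard wild-type-like spine rendered without noise
noiseless_spine <- function(spine_length = 0.82, head_width = 0.44,
                            neck_width = 0.16, sagitta = 0, angle = 0) {
  key <- paste("spine", spine_length, head_width, neck_width, sagitta, angle,
               sep = "_")
  fixture(key, function() {
    ann <- single_spine_annotation(spine_length, head_width, neck_width,
                                   sagitta = sagitta, angle = angle)
    list(ann = ann,
         image = project_stack(render_stack(ann,
                                            imaging_config(noise_model = "none"))))
  })
}

# brute-force 1D forward model: chord-length profile of a fluorophore-filled
# cylinder of diameter w, convolved with a Gaussian PSF, on a fine grid
disc_psf_profile <- function(w, psf_fwhm = 0.05, dx = 0.001, half = 0.5) {
  x <- seq(-half, half, by = dx)
  r <- w / 2
  chord <- 2 * sqrt(pmax(r^2 - x^2, 0))
  sig <- psf_fwhm / (2 * sqrt(2 * log(2)))
  kx <- seq(-4 * sig, 4 * sig, by = dx)
  k <- exp(-0.5 * (kx / sig)^2)
  k <- k / sum(k)
  y <- stats::convolve(chord, rev(k), type = "open")
  drop <- (length(k) - 1) / 2
  y <- y[(drop + 1):(drop + length(x))]
  list(x = x, y = y)
}

# linear-interpolated half-max width of any sampled profile
halfmax_crossing_width <- function(x, y) {
  h <- min(y) + (max(y) - min(y)) / 2
  above <- which(y >= h)
  lo <- above[1]
  hi <- above[length(above)]
  xl <- stats::approx(y[c(lo - 1, lo)], x[c(lo - 1, lo)], xout = h)$y
  xr <- stats::approx(y[c(hi, hi + 1)], x[c(hi, hi + 1)], xout = h)$y
  xr - xl
}

# exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled observations to the two groups
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u_obs <- u_stat(a, b)
  mu <- n1 * length(b) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exhaustive two-sample KS permutation p-value
ks_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  d_stat <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(vapply(v, function(q) mean(x <= q) - mean(y <= q), numeric(1))))
  }
  d_obs <- d_stat(a, b)
  idx <- utils::combn(length(pooled), n1)
  ds <- apply(idx, 2, function(ii) d_stat(pooled[ii], pooled[-ii]))
  mean(ds >= d_obs - 1e-9)
}
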