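# Fixtures are generated in code; nothing is stored on disk.

# Small benchmark dataset used across tests (reduced grid, same protocol
# as the reference benchmark: uniform angles on [0, 180), jitter uniform
# on +/-10% of the field of view unless overridden).
smallDataset <- function(n = 32, S = 24, jitter = 0.1 * n, noise = 0,
                         seedJitter = 101, seedNoise = 102) {
  simulateDataset(defaultPhantomSpec(n), benchmarkAngles(S),
                  jitterModel(jitter, seed = seedJitter),
                  noiseModel(noise, seed = seedNoise))
}

# Exact cyclic sub-pixel translation via the Fourier shift theorem;
# independent oracle for the real-space warp and for registration.
fourierShift <- function(img, dh, dv) {
  m1 <- nrow(img); m2 <- ncol(img)
  kr <- 0:(m1 - 1); kr[kr > m1 / 2] <- kr[kr > m1 / 2] - m1
  kc <- 0:(m2 - 1); kc[kc > m2 / 2] <- kc[kc > m2 / 2] - m2
  ph <- exp(-2i * pi * (outer(kr * dv, rep(1, m2)) / m1 +
                        outer(rep(1, m1), kc * dh) / m2))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (m1 * m2)
}

# Smooth band-limited test image: Gaussian-filtered (in Fourier space)
# projection of the three-sphere phantom.
smoothTestImage <- function(n = 48, sigma = n / 8, seed = 7) {
  img <- projData(forwardProject(makePhantom(defaultPhantomSpec(n)), 30))[, , 1]
  k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
  g <- exp(-(outer(k^2, rep(1, n)) + outer(rep(1, n), k^2)) /
             (2 * (n / (2 * pi * sigma))^2))
  Re(fft(fft(img) * g, inverse = TRUE)) / n^2
}

# Dense full cross-correlation argmax: brute-force oracle for the
# integer-shift registration cases.
bruteCrossCorrPeak <- function(ref, mov, maxLag = 8) {
  best <- c(0, 0); bestVal <- -Inf
  for (dv in -maxLag:maxLag) for (dh in -maxLag:maxLag) {
    shifted <- translateImage(mov, dh, dv)
    val <- sum(ref * shifted)
    if (val > bestVal) { bestVal <- val; best <- c(dh, dv) }
  }
  best
}
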