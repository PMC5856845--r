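# Shared fixtures: small calibrations, straight-bar phantoms, and a tiny
# BMP writer used to exercise the BMP reader.

hrt_cal <- function() calibration()

small_cal <- function(n = 192L) {
  calibration(pixel_pitch_um = 400 / 384, field_width_px = n,
              field_height_px = n)
}

# A single roughly horizontal fiber spanning the field.
bar_phantom <- function(width_px, seed = 1, noise_sd = 15, amp = 120,
                        cal = hrt_cal(), gradient = c(0, 0),
                        beading_amp = 0) {
  pitch <- cal$pixel_pitch_um
  W <- cal$field_width_px; H <- cal$field_height_px
  f <- list(x = c(12, W / 4, W / 2, 3 * W / 4, W - 12),
            y = H / 2 + c(0, -10, 5, -5, 3),
            width_um = width_px * pitch, branches = list(),
            beading_amp = beading_amp, beading_period_px = 25)
  generate_plexus(plexus_spec(
    list(f), background = list(level = 40, gradient = gradient,
                               noise_sd = noise_sd),
    amplitude = amp, calibration = cal, seed = seed))
}

# Solid axis-aligned bar mask.
bar_mask <- function(height_px, rows, cols, n = 64L) {
  m <- matrix(0L, n, n)
  m[rows, cols] <- 1L
  m
}

# Minimal 8-bit grayscale BMP writer (palette + uncompressed rows).
write_bmp8 <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  row_bytes <- ((w + 3) %/% 4) * 4
  offset <- 14L + 40L + 1024L
  size <- offset + row_bytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(size, 0L, offset)), con, size = 4, endian = "little")
  writeBin(as.integer(c(40L, w, h)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 8L)), con, size = 2, endian = "little")
  writeBin(as.integer(c(0L, row_bytes * h, 2835L, 2835L, 256L, 0L)), con,
           size = 4, endian = "little")
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  writeBin(pal, con)
  for (r in h:1) {
    row <- as.raw(c(img[r, ], rep(0L, row_bytes - w)))
    writeBin(row, con)
  }
  invisible(path)
}

# Independent shifted-median Passing-Bablok oracle (loop-based, no shared
# code with the implementation).
pb_oracle <- function(x, y) {
  n <- length(x)
  S <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] == x[i]) next
      s <- (y[j] - y[i]) / (x[j] - x[i])
      if (s != -1) S <- c(S, s)
    }
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  slope <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else {
    (S[N / 2 + K] + S[N / 2 + 1 + K]) / 2
  }
  c(slope = slope, intercept = median(y - slope * x))
}

# Brute-force concordance AUC oracle (lower value = case).
auc_oracle <- function(values, is_case) {
  vc <- values[is_case]; vn <- values[!is_case]
  tot <- 0
  for (a in vc) for (b in vn) tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(vc) * length(vn))
}
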