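# Independent brute-force oracles and shared small fixtures.
# The oracles deliberately use plain loops and never call the package's
# metric implementations.

oracle_l1 <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
  s / length(x)
}

oracle_l2 <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

oracle_ncc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# single-window SSIM with population statistics and optional pixel weights
oracle_ssim_window <- function(x, y, w = NULL, k1 = 0.01, k2 = 0.03, L = 1) {
  if (is.null(w)) w <- rep(1 / length(x), length(x))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  cxy <- sum(w * (x - mx) * (y - my))
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# mean of the per-window SSIM over every fully contained Gaussian window
oracle_ssim_windowed <- function(x, y, size = 11, sigma = 1.5,
                                 k1 = 0.01, k2 = 0.03, L = 1) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  vals <- c()
  for (i in seq_len(nrow(x) - size + 1)) {
    for (j in seq_len(ncol(x) - size + 1)) {
      xs <- x[i:(i + size - 1), j:(j + size - 1)]
      ys <- y[i:(i + size - 1), j:(j + size - 1)]
      vals <- c(vals, oracle_ssim_window(as.vector(xs), as.vector(ys),
                                         as.vector(w), k1, k2, L))
    }
  }
  mean(vals)
}

# 8-connected component count over the bright pixels of a logical mask
count_components <- function(mask) {
  bright <- which(mask, arr.ind = TRUE)
  if (nrow(bright) == 0) return(0L)
  key <- function(i, j) paste(i, j)
  open <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(bright))) {
    assign(key(bright[r, 1], bright[r, 2]), TRUE, envir = open)
  }
  n <- 0L
  for (r in seq_len(nrow(bright))) {
    k0 <- key(bright[r, 1], bright[r, 2])
    if (!exists(k0, envir = open, inherits = FALSE)) next
    n <- n + 1L
    queue <- list(bright[r, ])
    rm(list = k0, envir = open)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        kk <- key(p[1] + di, p[2] + dj)
        if (exists(kk, envir = open, inherits = FALSE)) {
          rm(list = kk, envir = open)
          queue[[length(queue) + 1]] <- c(p[1] + di, p[2] + dj)
        }
      }
    }
  }
  n
}

# Desk-scale acquisition used by most tests: 32 elements, 640 samples,
# 5-20 mm depth. Properties under test are scale-free.
small_cfg <- function() {
  default_config(n_elements = 32, n_samples = 640,
                 z_range = c(5e-3, 20e-3))
}

# Simulated speckle baseline for mock-network tests (seeded).
small_speckle_data <- function(cfg, seed = 7, region = c(-4e-3, 4e-3, 8e-3, 16e-3),
                               density = 10) {
  ph <- make_speckle_phantom(region, density = density, seed = seed)
  simulate_channel_data(ph, cfg$geom, fs = cfg$sampling_rate,
                        c = cfg$sound_speed, n_samples = cfg$n_samples,
                        seed = seed)
}

random_image_pair <- function(nr, nc) {
  list(x = matrix(runif(nr * nc), nr, nc),
       y = matrix(runif(nr * nc), nr, nc))
}
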