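# Independent oracles: deliberately simple step-by-step implementations
# (loops, direct formulas, dense solves) kept free of the package's
# vectorized code paths.

# -- histogram clipping: literal two-phase procedure -----------------------
oracle_redistribute <- function(hist, clip_count) {
  out <- numeric(256)
  excess <- 0
  for (b in 1:256) {
    if (hist[b] > clip_count) {
      excess <- excess + hist[b] - clip_count
      out[b] <- clip_count
    } else out[b] <- hist[b]
  }
  per_bin <- floor(excess / 256)
  for (b in 1:256) out[b] <- out[b] + per_bin
  rem <- excess - per_bin * 256
  b <- 1
  while (rem > 0) {
    out[b] <- out[b] + 1
    rem <- rem - 1
    b <- b + 1
  }
  as.integer(out)
}

# -- global histogram equalization -----------------------------------------
oracle_global_he <- function(image) {
  n <- length(image)
  counts <- numeric(256)
  for (v in as.integer(image)) counts[v + 1] <- counts[v + 1] + 1
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min == n) return(matrix(as.integer(image), nrow(image)))
  lut <- floor(255 * (cdf - cdf_min) / (n - cdf_min) + 0.5)
  lut <- pmin(pmax(lut, 0), 255)
  matrix(as.integer(lut[as.integer(image) + 1]), nrow(image))
}

# -- brute-force per-pixel CLAHE (default package conventions) -------------
oracle_clahe <- function(image, clip_limit, tile_grid) {
  g <- max(1L, as.integer(floor(tile_grid + 0.5)))
  n <- nrow(image); m <- ncol(image)
  bounds1 <- function(len) {
    base <- len %/% g
    starts <- (0:(g - 1)) * base
    ends <- c(starts[-1], len)
    list(starts = starts, ends = ends, centers = (starts + ends - 1) / 2)
  }
  rb <- bounds1(n); cb <- bounds1(m)
  luts <- vector("list", g * g)
  for (tr in 1:g) for (tc in 1:g) {
    px <- as.integer(image[(rb$starts[tr] + 1):rb$ends[tr],
                           (cb$starts[tc] + 1):cb$ends[tc]])
    npix <- length(px)
    counts <- numeric(256)
    for (v in px) counts[v + 1] <- counts[v + 1] + 1
    if (max(counts) == npix) {
      lut <- 0:255
    } else {
      clip_count <- max(1, floor(clip_limit * npix / 256 + 0.5))
      h <- oracle_redistribute(counts, clip_count)
      cdf <- cumsum(as.numeric(h))
      cdf_min <- cdf[which(h > 0)[1]]
      if (cdf_min == npix) lut <- 0:255
      else lut <- pmin(pmax(floor(255 * (cdf - cdf_min) / (npix - cdf_min) + 0.5), 0), 255)
    }
    luts[[(tr - 1) * g + tc]] <- lut
  }
  lookup <- function(tr, tc, v) luts[[(tr - 1) * g + tc]][v + 1]
  # locate the two surrounding tile centers along one axis by scanning
  seg_of <- function(p, centers) {
    if (g == 1) return(list(i = 1, w = 0))
    i <- 1
    for (t in 1:(g - 1)) if (p >= centers[t]) i <- t
    w <- (p - centers[i]) / (centers[i + 1] - centers[i])
    list(i = i, w = min(max(w, 0), 1))
  }
  out <- matrix(0L, n, m)
  for (r in 1:n) {
    sr <- seg_of(r - 1, rb$centers)
    for (c in 1:m) {
      sc <- seg_of(c - 1, cb$centers)
      v <- image[r, c]
      if (g == 1) {
        blend <- lookup(1, 1, v)
      } else {
        blend <- (1 - sr$w) * (1 - sc$w) * lookup(sr$i, sc$i, v) +
          sr$w * (1 - sc$w) * lookup(sr$i + 1, sc$i, v) +
          (1 - sr$w) * sc$w * lookup(sr$i, sc$i + 1, v) +
          sr$w * sc$w * lookup(sr$i + 1, sc$i + 1, v)
      }
      out[r, c] <- min(max(floor(blend + 0.5), 0), 255)
    }
  }
  storage.mode(out) <- "integer"
  out
}

# -- windowed SSIM by direct per-window evaluation -------------------------
oracle_ssim <- function(x, y, window = 11, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = 255) {
  h <- (window - 1) / 2
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  W <- outer(k1, k1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2; C3 <- C2 / 2
  n <- nrow(x); m <- ncol(x)
  vals <- c()
  for (r in 1:(n - window + 1)) for (c in 1:(m - window + 1)) {
    wx <- x[r:(r + window - 1), c:(c + window - 1)]
    wy <- y[r:(r + window - 1), c:(c + window - 1)]
    mx <- sum(W * wx); my <- sum(W * wy)
    sxx <- max(sum(W * wx^2) - mx^2, 0)
    syy <- max(sum(W * wy^2) - my^2, 0)
    sxy <- sum(W * wx * wy) - mx * my
    l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
    cc <- (2 * sqrt(sxx) * sqrt(syy) + C2) / (sxx + syy + C2)
    s <- (sxy + C3) / (sqrt(sxx) * sqrt(syy) + C3)
    vals <- c(vals, l * cc * s)
  }
  mean(vals)
}

# -- exact GP posterior by dense solve -------------------------------------
oracle_gp_posterior <- function(Xs, y, xs, ls, alpha) {
  mat52 <- function(a, b) {
    r <- sqrt(sum(((a - b) / ls)^2)) * sqrt(5)
    (1 + r + r^2 / 3) * exp(-r)
  }
  n <- nrow(Xs)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- mat52(Xs[i, ], Xs[j, ])
  diag(K) <- diag(K) + alpha
  ks <- vapply(1:n, function(i) mat52(xs, Xs[i, ]), 1)
  Kinv <- solve(K)
  list(mean = sum(ks * (Kinv %*% y)),
       var = max(1 + alpha - t(ks) %*% Kinv %*% ks, 0))
}

# -- EI by Gaussian quadrature ---------------------------------------------
oracle_ei <- function(mean, sd, best, xi) {
  k <- best + xi  # integrand kink: integrate only over the smooth part
  stats::integrate(function(f) (f - k) * stats::dnorm(f, mean, sd),
                   k, max(mean + 15 * sd, k + 30 * sd),
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# -- generalized Gaussian sampler (|x|^a ~ Gamma(1/a)) ---------------------
rggd <- function(n, shape, scale = 1) {
  mag <- scale * stats::rgamma(n, shape = 1 / shape)^(1 / shape)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

# -- minimal hand-rolled PNG writer for a 16-bit grayscale fixture ---------
# (png::writePNG only emits 8-bit; the loader must rescale 16-bit input)
write_png16 <- function(values, path) {
  crc_table <- local({
    tab <- numeric(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1)) else bitwShiftR(c, 1)
      tab[i + 1] <- c
    }
    tab
  })
  crc32 <- function(bytes) {
    c <- -1L
    for (b in as.integer(bytes))
      c <- bitwXor(bitwShiftR(c, 8), crc_table[bitwAnd(bitwXor(c, b), 255L) + 1])
    bitwXor(c, -1L)
  }
  u32 <- function(x) {
    x <- as.numeric(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(crc32(body)))
  }
  h <- nrow(values); w <- ncol(values)
  ihdr <- c(u32(w), u32(h), as.raw(c(16, 0, 0, 0, 0)))
  scan <- raw(0)
  for (r in 1:h) {
    row <- as.numeric(values[r, ])
    scan <- c(scan, as.raw(0),
              as.raw(rbind(row %/% 256, row %% 256)))
  }
  idat <- memCompress(scan, "gzip")  # zlib-wrapped deflate, as PNG expects
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# -- scikit-image CLAHE reference, one python call for a batch -------------
skimage_available <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import skimage")),
            stdout = FALSE, stderr = FALSE) == 0
}

skimage_clahe_batch <- function(images, grids, clip_limits) {
  dir <- tempfile("skref")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  for (i in seq_along(images))
    utils::write.table(images[[i]], file.path(dir, sprintf("in_%d.csv", i)),
                       row.names = FALSE, col.names = FALSE, sep = ",")
  utils::write.table(cbind(seq_along(images), grids, clip_limits),
                     file.path(dir, "meta.csv"),
                     row.names = FALSE, col.names = FALSE, sep = ",")
  script <- file.path(dir, "ref.py")
  writeLines(c(
    "import numpy as np, sys",
    "from skimage.exposure import equalize_adapthist",
    sprintf("d = %s", deparse(dir)),
    "meta = np.atleast_2d(np.loadtxt(d + '/meta.csv', delimiter=','))",
    "for i, g, cl in meta:",
    "    img = np.loadtxt(d + '/in_%d.csv' % int(i), delimiter=',').astype(np.uint8)",
    "    k = img.shape[0] // int(g)",
    "    out = equalize_adapthist(img, kernel_size=(k, k), clip_limit=cl, nbins=256)",
    "    np.savetxt(d + '/ref_%d.csv' % int(i), np.round(out * 255), delimiter=',')"),
    script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("scikit-image reference run failed")
  lapply(seq_along(images), function(i)
    as.matrix(utils::read.table(file.path(dir, sprintf("ref_%d.csv", i)),
                                sep = ",")))
}
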