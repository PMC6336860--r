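# Low-level raster helpers shared by the renderer and the contour extractor.
# Images are numeric matrices indexed [row = y, col = x]; the external pixel
# coordinate convention is 0-based with pixel centers at integer coordinates,
# origin top-left, x to the right, y down. So frame[i, j] sits at
# (x, y) = (j - 1, i - 1).

# Separable Gaussian blur with edge replication, implemented as two banded
# matrix products; exact enough for the small frames used here.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(n) {
    # n x n smoothing operator with replicated edges
    m <- matrix(0, n, n)
    for (off in -rad:rad) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      m[cbind(seq_len(n), idx)] <- m[cbind(seq_len(n), idx)] + k[off + rad + 1L]
    }
    m
  }
  blur1(nrow(img)) %*% img %*% t(blur1(ncol(img)))
}

# Bilinear interpolation at 0-based coordinates (x, y); clamps to the frame.
bilinear <- function(img, x, y) {
  nx <- ncol(img); ny <- nrow(img)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    img[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    img[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    img[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# Otsu threshold on a [0, 1] image.
otsu_threshold <- function(img, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(img * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# 8-connected component labeling by scanline flood fill. Returns an integer
# matrix of labels (0 = background).
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  stack <- integer(ny * nx)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    sp <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (sp > 0L) {
      p <- stack[sp]; sp <- sp - 1L
      i <- ((p - 1L) %% ny) + 1L
      j <- ((p - 1L) %/% ny) + 1L
      for (dj in -1:1) {
        jj <- j + dj
        if (jj < 1L || jj > nx) next
        base <- (jj - 1L) * ny
        for (di in -1:1) {
          ii <- i + di
          if (ii < 1L || ii > ny) next
          q <- base + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            sp <- sp + 1L
            stack[sp] <- q
          }
        }
      }
    }
  }
  lab
}

# Fill internal holes of a binary mask: everything not reachable from the
# frame border through the complement belongs to the object.
fill_holes <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  outside <- matrix(FALSE, ny, nx)
  stack <- integer(ny * nx)
  sp <- 0L
  push <- function(q) { sp <<- sp + 1L; stack[sp] <<- q }
  for (j in c(1L, nx)) for (i in seq_len(ny)) {
    q <- (j - 1L) * ny + i
    if (!mask[q] && !outside[q]) { outside[q] <- TRUE; push(q) }
  }
  for (i in c(1L, ny)) for (j in seq_len(nx)) {
    q <- (j - 1L) * ny + i
    if (!mask[q] && !outside[q]) { outside[q] <- TRUE; push(q) }
  }
  while (sp > 0L) {
    p <- stack[sp]; sp <- sp - 1L
    i <- ((p - 1L) %% ny) + 1L
    j <- ((p - 1L) %/% ny) + 1L
    if (i > 1L) { q <- p - 1L; if (!mask[q] && !outside[q]) { outside[q] <- TRUE; sp <- sp + 1L; stack[sp] <- q } }
    if (i < ny) { q <- p + 1L; if (!mask[q] && !outside[q]) { outside[q] <- TRUE; sp <- sp + 1L; stack[sp] <- q } }
    if (j > 1L) { q <- p - ny; if (!mask[q] && !outside[q]) { outside[q] <- TRUE; sp <- sp + 1L; stack[sp] <- q } }
    if (j < nx) { q <- p + ny; if (!mask[q] && !outside[q]) { outside[q] <- TRUE; sp <- sp + 1L; stack[sp] <- q } }
  }
  !outside
}

# Binary dilation with a (2r+1)-square structuring element via blurring trick.
dilate <- function(mask, r = 1L) {
  m <- mask * 1
  for (k in seq_len(r)) {
    ny <- nrow(m); nx <- ncol(m)
    up <- rbind(m[-1, , drop = FALSE], m[ny, , drop = FALSE])
    dn <- rbind(m[1, , drop = FALSE], m[-ny, , drop = FALSE])
    m <- pmax(m, up, dn)
    lf <- cbind(m[, -1, drop = FALSE], m[, nx, drop = FALSE])
    rt <- cbind(m[, 1, drop = FALSE], m[, -nx, drop = FALSE])
    m <- pmax(m, lf, rt)
  }
  m > 0
}

# Central-difference gradient magnitude.
gradient_magnitude <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  gx <- (img[, c(2:nx, nx)] - img[, c(1, 1:(nx - 1))]) / 2
  gy <- (img[c(2:ny, ny), ] - img[c(1, 1:(ny - 1)), ]) / 2
  sqrt(gx^2 + gy^2)
}
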