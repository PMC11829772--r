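# --- small 2D filtering primitives used across the map / image modules ---

#' Reflect-pad a matrix
#'
#' Pads `x` by `m` pixels on every side by mirror reflection (edge pixel not
#' duplicated when possible). Used so filters behave sensibly at map borders.
#'
#' @param x numeric matrix.
#' @param m pad width in pixels.
#' @return padded matrix.
#' @keywords internal
pad_reflect <- function(x, m) {
  n <- nrow(x); p <- ncol(x)
  ri <- c(pmin(m:1 + 1L, n), seq_len(n), pmax(n - (1:m), 1L))
  ci <- c(pmin(m:1 + 1L, p), seq_len(p), pmax(p - (1:m), 1L))
  x[ri, ci, drop = FALSE]
}

#' Linear filtering with reflected borders
#'
#' Direct correlation of a matrix with a small kernel; borders are handled by
#' mirror reflection, so constant inputs are reproduced exactly.
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return filtered matrix, same size as `x`.
#' @keywords internal
filter2_reflect <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  m <- max(hr, hc)
  xp <- pad_reflect(x, m)
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      out <- out + w * xp[(m - hr + a - 1L) + seq_len(nrow(x)),
                          (m - hc + b - 1L) + seq_len(ncol(x)), drop = FALSE]
    }
  }
  out
}

#' @keywords internal
gaussian_kernel1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur with reflected borders
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels.
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel1d(sigma)
  x <- filter2_reflect(x, matrix(k, ncol = 1))
  filter2_reflect(x, matrix(k, nrow = 1))
}

#' 2D median filter with reflected borders
#' @param x numeric matrix.
#' @param w odd window size in pixels.
#' @keywords internal
median_filter2 <- function(x, w = 3L) {
  stopifnot(w %% 2L == 1L)
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- pad_reflect(x, h)
  n <- nrow(x); p <- ncol(x)
  stack <- array(NA_real_, c(n, p, w * w))
  s <- 1L
  for (a in seq_len(w)) {
    for (b in seq_len(w)) {
      stack[, , s] <- xp[(a - 1L) + seq_len(n), (b - 1L) + seq_len(p)]
      s <- s + 1L
    }
  }
  apply(stack, c(1, 2), stats::median)
}

#' 2D Savitzky-Golay center-point kernel
#'
#' Least-squares bivariate polynomial surface of total degree `order` fitted
#' over a `w` x `w` window; the returned kernel evaluates the fitted surface
#' at the window center, so polynomials up to `order` pass unchanged.
#'
#' @param w odd window size in pixels.
#' @param order polynomial total degree (>= 0).
#' @return `w` x `w` kernel matrix.
#' @keywords internal
sg2d_kernel <- function(w = 5L, order = 2L) {
  stopifnot(w %% 2L == 1L, order >= 0L)
  h <- (w - 1L) %/% 2L
  g <- expand.grid(dy = -h:h, dx = -h:h)
  terms <- expand.grid(p = 0:order, q = 0:order)
  terms <- terms[terms$p + terms$q <= order, , drop = FALSE]
  A <- mapply(function(p, q) g$dx^p * g$dy^q, terms$p, terms$q)
  # row of the hat matrix that evaluates the fit at (0,0): only the constant
  # term contributes there
  coef_row <- solve(crossprod(A), t(A))[which(terms$p == 0 & terms$q == 0)[1], ]
  matrix(coef_row, w, w)
}

#' Bilinear sub-pixel shift (clamped borders)
#'
#' Samples `x` at positions displaced by `(-dx, -dy)`, i.e. shifts image
#' content by `(dx, dy)` where `dx` moves along columns (x) and `dy` along
#' rows (y).
#' @keywords internal
shift_bilinear <- function(x, dx, dy) {
  n <- nrow(x); m <- ncol(x)
  fi <- seq_len(n) - dy
  fj <- seq_len(m) - dx
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0;  wj <- fj - j0
  cl <- function(idx, k) pmin(pmax(idx, 1L), k)
  a11 <- x[cl(i0, n),      cl(j0, m),      drop = FALSE]
  a21 <- x[cl(i0 + 1L, n), cl(j0, m),      drop = FALSE]
  a12 <- x[cl(i0, n),      cl(j0 + 1L, m), drop = FALSE]
  a22 <- x[cl(i0 + 1L, n), cl(j0 + 1L, m), drop = FALSE]
  a11 * ((1 - wi) %o% (1 - wj)) + a21 * (wi %o% (1 - wj)) +
    a12 * ((1 - wi) %o% wj) + a22 * (wi %o% wj)
}

#' Leave-self-out directional Gaussian smoothing
#'
#' Gaussian-weighted average along a line at `angle_deg`, computed with
#' zero padding and per-pixel weight renormalization (no border clamping),
#' and with each pixel's own kernel contribution removed. The result at a
#' pixel is therefore independent of that pixel's value, which is what
#' makes threshold-based segmentation on it selection-bias free.
#' @keywords internal
directional_smooth_loo <- function(x, angle_deg, sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  t <- seq(-h, h)
  w <- exp(-t^2 / (2 * sigma_px^2)); w <- w / sum(w)
  th <- angle_deg * pi / 180
  n <- nrow(x); m <- ncol(x)
  xp <- matrix(0, n + 2L * h, m + 2L * h)
  ip <- matrix(0, n + 2L * h, m + 2L * h)
  xp[h + seq_len(n), h + seq_len(m)] <- x
  ip[h + seq_len(n), h + seq_len(m)] <- 1
  num <- matrix(0, n + 2L * h, m + 2L * h)
  den <- matrix(0, n + 2L * h, m + 2L * h)
  for (s in seq_along(t)) {
    num <- num + w[s] * shift_bilinear(xp, t[s] * cos(th), t[s] * sin(th))
    den <- den + w[s] * shift_bilinear(ip, t[s] * cos(th), t[s] * sin(th))
  }
  num <- num[h + seq_len(n), h + seq_len(m)]
  den <- den[h + seq_len(n), h + seq_len(m)]
  w0 <- w[h + 1L]
  (num - w0 * x) / pmax(den - w0, 1e-12)
}

#' Directional (anisotropic) Gaussian smoothing
#'
#' Averages the image along a line at `angle_deg` (degrees from the x axis,
#' toward increasing row index) with Gaussian weights of scale `sigma_px`.
#' Used to accumulate evidence along the expected stripe direction.
#' @keywords internal
directional_smooth <- function(x, angle_deg, sigma_px) {
  if (sigma_px <= 0) return(x)
  h <- max(1L, ceiling(3 * sigma_px))
  t <- seq(-h, h)
  w <- exp(-t^2 / (2 * sigma_px^2)); w <- w / sum(w)
  th <- angle_deg * pi / 180
  out <- matrix(0, nrow(x), ncol(x))
  for (s in seq_along(t)) {
    out <- out + w[s] * shift_bilinear(x, t[s] * cos(th), t[s] * sin(th))
  }
  out
}

# --- binary morphology: thinning and spur pruning (skeleton-based lengths) ---

#' Zhang-Suen thinning
#'
#' Reduces a binary mask to an 8-connected, one-pixel-wide skeleton.
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @keywords internal
zhang_suen_thin <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  n <- nrow(img); m <- ncol(img)
  shift_int <- function(x, di, dj) {
    out <- matrix(0L, n, m)
    ri <- seq_len(n) + di; cj <- seq_len(m) + dj
    ok_i <- ri >= 1L & ri <= n; ok_j <- cj >= 1L & cj <= m
    out[ok_i, ok_j] <- x[ri[ok_i], cj[ok_j], drop = FALSE]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (north = smaller row index)
      p2 <- shift_int(img, -1L,  0L); p3 <- shift_int(img, -1L,  1L)
      p4 <- shift_int(img,  0L,  1L); p5 <- shift_int(img,  1L,  1L)
      p6 <- shift_int(img,  1L,  0L); p7 <- shift_int(img,  1L, -1L)
      p8 <- shift_int(img,  0L, -1L); p9 <- shift_int(img, -1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, n, m)
      for (k in 1:8) a <- a + (ring[[k]] == 0L & ring[[k + 1L]] == 1L)
      if (step == 1) {
        c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
      }
      del <- img == 1L & bsum >= 2L & bsum <= 6L & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

#' @keywords internal
neighbor_count <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  filter2_reflect(img, matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)) * img
}

#' Remove skeleton spurs shorter than `min_len` pixels
#'
#' Walks from each skeleton endpoint toward the interior; if a junction pixel
#' (>= 3 neighbours) is reached in fewer than `min_len` steps, the walked
#' pixels are deleted. Free-standing segments are never removed.
#' @keywords internal
prune_spurs <- function(skel, min_len = 3L) {
  n <- nrow(skel); m <- ncol(skel)
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb_of <- function(i, j) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= m
    ii <- ii[ok]; jj <- jj[ok]
    keep <- skel[cbind(ii, jj)]
    cbind(ii[keep], jj[keep])
  }
  nc <- round(neighbor_count(skel))
  ends <- which(skel & nc == 1, arr.ind = TRUE)
  for (e in seq_len(nrow(ends))) {
    path <- list()
    cur <- ends[e, ]
    prev <- c(NA, NA)
    hit_junction <- FALSE
    for (step in seq_len(min_len - 1L)) {
      path[[length(path) + 1L]] <- cur
      nb <- nb_of(cur[1], cur[2])
      if (nrow(nb) > 0 && !is.na(prev[1])) {
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      }
      if (nrow(nb) == 0) break                      # isolated short segment: keep
      if (nrow(nb) > 1 ||
          round(neighbor_count(skel))[nb[1, 1], nb[1, 2]] >= 3) {
        hit_junction <- TRUE
        break
      }
      prev <- cur
      cur <- nb[1, ]
    }
    if (hit_junction) {
      for (p in path) skel[p[1], p[2]] <- FALSE
    }
  }
  skel
}

#' Geodesic length of a thinned component in pixels
#'
#' Counts 8-neighbour links once each: orthogonal links weigh 1, diagonal
#' links sqrt(2). Exact for axis-aligned and 45 degree chains.
#' @keywords internal
skeleton_length_px <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  len <- 0
  img <- matrix(as.integer(mask), n, m)
  pair_count <- function(di, dj) {
    ri <- seq_len(n - abs(di)); cj <- seq_len(m - abs(dj))
    a <- img[ri + max(0, -di), cj + max(0, -dj), drop = FALSE]
    b <- img[ri + max(0, di),  cj + max(0, dj),  drop = FALSE]
    sum(a * b)
  }
  len <- len + pair_count(0L, 1L) + pair_count(1L, 0L)
  len + sqrt(2) * (pair_count(1L, 1L) + pair_count(1L, -1L))
}

#' 8-connected component labelling
#'
#' `EBImage::bwlabel` labels 4-connected sets; thinned skeletons and
#' oblique stripes need diagonal connectivity, so labels touching
#' diagonally are merged with a union-find pass.
#' @param mask logical matrix.
#' @return integer label matrix (0 = background).
#' @keywords internal
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl <= 1) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  pairs <- NULL
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(n - 1L), if (d[2] == 1L) seq_len(m - 1L) else 2:m]
    b <- lab[2:n, if (d[2] == 1L) 2:m else seq_len(m - 1L)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(nl)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
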