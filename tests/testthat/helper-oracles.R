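# Brute-force reference implementations, kept deliberately independent
# of the package's kernels: plain loops and direct definitions.

o_median3x3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (y in seq_len(H)) for (x in seq_len(W)) {
    ys <- pmin(pmax(y + (-1:1), 1), H)
    xs <- pmin(pmax(x + (-1:1), 1), W)
    out[y, x] <- stats::median(as.vector(img[ys, xs]))
  }
  out
}

# grayscale opening with the non-flat ball SE, exhaustive max-of-min;
# out-of-bounds neighbours skipped
o_ball_se <- function(radius) {
  R <- floor(radius)
  g <- expand.grid(dy = -R:R, dx = -R:R)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, ]
  g$h <- sqrt(radius^2 - g$dy^2 - g$dx^2)
  g
}

o_opening <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  se <- o_ball_se(radius)
  er <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    yy <- y + se$dy; xx <- x + se$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    er[y, x] <- min(img[cbind(yy[ok], xx[ok])] - se$h[ok])
  }
  op <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    yy <- y + se$dy; xx <- x + se$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    op[y, x] <- max(er[cbind(yy[ok], xx[ok])] + se$h[ok])
  }
  op
}

# direct (non-separable) 2D Gaussian convolution, reflective boundary,
# kernel radius ceil(4 sigma) as documented for the operator
o_gauss2d <- function(img, sigma) {
  H <- nrow(img); W <- ncol(img)
  R <- max(1, ceiling(4 * sigma))
  off <- expand.grid(dy = -R:R, dx = -R:R)
  k <- exp(-(off$dy^2) / (2 * sigma^2)) *
    exp(-(off$dx^2) / (2 * sigma^2))
  k <- k / sum(k)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
    }
    i
  }
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    yy <- refl(y + off$dy, H); xx <- refl(x + off$dx, W)
    out[y, x] <- sum(k * img[cbind(yy, xx)])
  }
  out
}

# breadth-first flood-fill 3D labelling; labels in raster first-
# encounter order
o_label3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  off <- off[!(off$dy == 0 & off$dx == 0 & off$dz == 0), ]
  if (connectivity == 6)
    off <- off[abs(off$dy) + abs(off$dx) + abs(off$dz) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i]) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      y <- (cur - 1L) %% d[1L] + 1L
      x <- ((cur - 1L) %/% d[1L]) %% d[2L] + 1L
      z <- (cur - 1L) %/% (d[1L] * d[2L]) + 1L
      yy <- y + off$dy; xx <- x + off$dx; zz <- z + off$dz
      ok <- yy >= 1 & yy <= d[1L] & xx >= 1 & xx <= d[2L] &
        zz >= 1 & zz <= d[3L]
      j <- (zz[ok] - 1L) * d[1L] * d[2L] + (xx[ok] - 1L) * d[1L] +
        yy[ok]
      j <- j[mask[j] & lab[j] == 0L]
      lab[j] <- nxt
      queue <- c(queue, j)
    }
  }
  lab
}

# exhaustive prominence-flooding maxima, same declared semantics as the
# operator: equal-value plateaus with no higher neighbour in the
# region; accepted iff value > tolerance, flood over pixels
# > value - tolerance meets no strictly higher pixel, and no reachable
# equal-value candidate has a smaller minimum linear index
o_find_maxima <- function(img, tolerance, region = NULL) {
  H <- nrow(img); W <- ncol(img)
  if (is.null(region)) region <- matrix(TRUE, H, W)
  # 8-neighbour table, one row per pixel (NA where out of bounds)
  N <- H * W
  ys <- rep(seq_len(H), W); xs <- rep(seq_len(W), each = H)
  nbmat <- matrix(NA_integer_, N, 8L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0L && dx == 0L) next
    k <- k + 1L
    yy <- ys + dy; xx <- xs + dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    nbmat[ok, k] <- (xx[ok] - 1L) * H + yy[ok]
  }
  nb <- function(i) {
    v <- as.vector(nbmat[i, , drop = FALSE])
    v[!is.na(v)]
  }
  plat <- matrix(0L, H, W)
  np <- 0L
  for (i in which(region)) {
    if (plat[i]) next
    np <- np + 1L
    queue <- i; plat[i] <- np
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      j <- nb(cur)
      j <- j[region[j] & plat[j] == 0L & img[j] == img[i]]
      plat[j] <- np
      queue <- c(queue, j)
    }
  }
  cand <- integer(0)
  for (p in seq_len(np)) {
    px <- which(plat == p)
    v <- img[px[1L]]
    if (v <= tolerance) next
    nbs <- setdiff(unique(unlist(lapply(px, nb))), px)
    nbs <- nbs[region[nbs]]
    if (!length(nbs) || all(img[nbs] <= v)) cand <- c(cand, p)
  }
  pts <- NULL
  for (p in cand) {
    px <- which(plat == p)
    v <- img[px[1L]]
    # flood over > v - tolerance
    inflood <- rep(FALSE, H * W)
    inflood[px] <- TRUE
    frontier <- px
    reject <- FALSE
    while (length(frontier) && !reject) {
      j <- setdiff(unique(unlist(lapply(frontier, nb))),
                   which(inflood))
      j <- j[region[j]]
      if (any(img[j] > v)) { reject <- TRUE; break }
      j <- j[img[j] > v - tolerance]
      inflood[j] <- TRUE
      frontier <- j
    }
    if (!reject) {
      eq <- unique(plat[which(inflood & as.vector(img == v))])
      eq <- eq[eq %in% cand & eq != p]
      if (length(eq)) {
        minidx <- vapply(c(p, eq), function(q) min(which(plat == q)),
                         0L)
        if (which.min(minidx) != 1L) reject <- TRUE
      }
    }
    if (!reject) {
      y <- (px - 1L) %% H + 1L; x <- (px - 1L) %/% H + 1L
      pts <- rbind(pts, c(mean(y), mean(x), v))
    }
  }
  if (is.null(pts))
    return(data.frame(y = numeric(), x = numeric(), value = numeric()))
  out <- data.frame(y = pts[, 1L], x = pts[, 2L], value = pts[, 3L])
  out[order(-out$value, out$y, out$x), , drop = FALSE]
}

o_overlap <- function(a, b, sel = NULL) {
  av <- as.numeric(a); bv <- as.numeric(b)
  if (!is.null(sel)) { av <- av[sel]; bv <- bv[sel] }
  s <- 0; sa <- 0; sb <- 0
  for (i in seq_along(av)) {
    s <- s + av[i] * bv[i]
    sa <- sa + av[i]^2
    sb <- sb + bv[i]^2
  }
  s / sqrt(sa * sb)
}

o_otsu <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins)
  best <- -Inf; kbest <- NA
  for (k in seq_len(nbins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- sum(!in0)
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(bin[in0]); mu1 <- mean(bin[!in0])
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; kbest <- k }
  }
  edges[kbest + 1L]
}

# exact Mann-Whitney p by enumerating group assignments and counting
# pairwise wins (+ half-ties), independent of the rank-sum formulation
o_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  ustat <- function(g1) {
    x <- pooled[g1]; y <- pooled[-g1]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  mu <- n1 * (n - n1) / 2
  obs <- abs(ustat(seq_len(n1)) - mu)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2L, ustat)
  mean(abs(us - mu) >= obs - 1e-9)
}

# exhaustive rank-permutation Spearman p; the permutation matrix is
# cached per n and rho evaluated as a single matrix product
.o_perm_cache <- new.env(parent = emptyenv())
o_all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.o_perm_cache[[key]])) return(.o_perm_cache[[key]])
  gen <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], gen(v[-i]))))
  }
  P <- gen(seq_len(n))
  .o_perm_cache[[key]] <- P
  P
}

o_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- suppressWarnings(stats::cor(rx, ry))
  P <- o_all_perms(length(y))
  ryc <- ry - mean(ry)
  rxc <- rx - mean(rx)
  M <- matrix(ryc[P], nrow(P), length(y))
  rhos <- as.vector(M %*% rxc) / sqrt(sum(rxc^2) * sum(ryc^2))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# small helper used across image tests
match_points <- function(found_y, found_x, true_y, true_x, maxDist) {
  if (!length(found_y))
    return(list(tp = 0L, fp = 0L, fn = length(true_y)))
  if (!length(true_y))
    return(list(tp = 0L, fp = length(found_y), fn = 0L))
  d2 <- outer(found_y, true_y, "-")^2 + outer(found_x, true_x, "-")^2
  list(tp = sum(apply(d2, 2L, min) <= maxDist^2),
       fp = sum(apply(d2, 1L, min) > maxDist^2),
       fn = sum(apply(d2, 2L, min) > maxDist^2))
}
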