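# Independent brute-force oracles used to cross-check the package's fast
# paths. Each deliberately re-derives the quantity from first principles.

# Exact NNLS by exhaustive active-set enumeration (feasible for few spectra):
# solve ordinary least squares on every subset of coefficients (others fixed
# at zero), keep the feasible solution with minimal RSS.
brute_nnls <- function(S, y) {
  k <- ncol(S)
  best <- list(rss = Inf, x = rep(0, k))
  for (bits in 0:(2^k - 1)) {
    act <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    x <- rep(0, k)
    if (length(act)) {
      sol <- tryCatch(qr.coef(qr(S[, act, drop = FALSE]), y),
                      error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol)) || any(sol < 0)) next
      x[act] <- sol
    }
    rss <- sum((y - S %*% x)^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, x = x)
  }
  best$x
}

# Exhaustive between-class-variance threshold search on a discretized
# histogram (the defining property of the Otsu level).
brute_otsu <- function(x, levels = 256) {
  rng <- range(x)
  g <- pmin(floor((x - rng[1]) / diff(rng) * levels), levels - 1)
  h <- tabulate(g + 1, nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- c(val = -Inf, th = NA)
  for (t in 1:(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best["val"]) best <- c(val = v, th = t)
  }
  rng[1] + best[["th"]] / levels * diff(rng)
}

# Literal per-pixel two-closest-centers search.
brute_two_closest <- function(cy, cx, ids, shape) {
  out <- matrix(0, shape[1], shape[2])
  for (yy in seq_len(shape[1])) for (xx in seq_len(shape[2])) {
    d <- (yy - cy)^2 + (xx - cx)^2
    o <- order(d, ids)[1:2]
    out[yy, xx] <- pair_key(ids[o[1]], ids[o[2]])
  }
  out
}

# Exhaustive breakpoint search with lm() per candidate: the reference for
# profiled baseline-plus-linear fitting.
brute_baseline_linear <- function(t, y) {
  best <- NULL
  for (t0 in t[2:(length(t) - 1)]) {
    ramp <- pmax(t - t0, 0)
    fit <- lm(y ~ ramp)
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(t0 = t0, slope = unname(coef(fit)[2]), rss = rss)
  }
  best
}

# Frame-by-frame nearest-centroid blob tracker (independent of the
# watershed/overlap route): label blobs per frame by connected components,
# then chain by nearest centroid.
oracle_track_blobs <- function(volume, threshold) {
  nt <- dim(volume)[3]
  prev <- NULL
  ids <- list()
  next_id <- 0
  for (f in seq_len(nt)) {
    lab <- EBImage::bwlabel(volume[, , f] > threshold)
    cen <- NULL
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      cy <- mean((idx - 1) %% nrow(lab) + 1)
      cx <- mean((idx - 1) %/% nrow(lab) + 1)
      cen <- rbind(cen, c(l, cy, cx))
    }
    assigned <- rep(NA, nrow(cen))
    if (!is.null(prev)) {
      for (i in seq_len(nrow(cen))) {
        d <- sqrt((cen[i, 2] - prev$y)^2 + (cen[i, 3] - prev$x)^2)
        j <- which.min(d)
        if (length(j) && d[j] < 10) assigned[i] <- prev$id[j]
      }
    }
    for (i in which(is.na(assigned))) {
      next_id <- next_id + 1
      assigned[i] <- next_id
    }
    prev <- data.frame(id = assigned, y = cen[, 2], x = cen[, 3])
    ids[[f]] <- prev
  }
  ids
}

# Second moments computed by literal summation over pixel coordinates.
brute_major_axis <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
  M <- cov(cbind(pts[, 1] - cy, pts[, 2] - cx)) * (nrow(pts) - 1) / nrow(pts)
  4 * sqrt(max(eigen(M, symmetric = TRUE)$values))
}
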