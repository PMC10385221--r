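# Independent brute-force oracles. These deliberately re-derive each quantity
# with plain loops / naive formulas so they share no code path with the
# package implementation.

random_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

brute_overall_brightness <- function(image, p = 2) {
  total <- 0
  for (k in 1:3) {
    s <- 0
    m <- image[, , k]
    for (v in as.vector(m)) s <- s + v^p
    total <- total + (s / length(m))^(1 / p) / 3
  }
  total
}

brute_components <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- c(ob = brute_overall_brightness(image))
  nm <- c("r", "g", "b")
  means <- contrasts <- grads <- numeric(3)
  for (k in 1:3) {
    m <- image[, , k]
    mu <- sum(m) / (H * W)
    means[k] <- mu
    contrasts[k] <- sqrt(sum((m - mu)^2) / (H * W))
    tot <- 0
    for (y in 1:H) {
      for (x in 1:W) {
        xp <- min(x + 1, W); xm <- max(x - 1, 1)
        yp <- min(y + 1, H); ym <- max(y - 1, 1)
        gx <- (m[y, xp] - m[y, xm]) / 2
        gy <- (m[yp, x] - m[ym, x]) / 2
        tot <- tot + sqrt(gx^2 + gy^2)
      }
    }
    grads[k] <- tot / (H * W)
  }
  c(out, br = means[1], bg = means[2], bb = means[3],
    cr = contrasts[1], cg = contrasts[2], cb = contrasts[3],
    gr = grads[1], gg = grads[2], gb = grads[3])
}

brute_bd <- function(cand, sb) {
  a <- unlist(as.data.frame(cand))
  b <- unlist(as.data.frame(if (inherits(sb, "standard_brightness"))
    sb$components else sb))
  nms <- c("ob", "br", "bg", "bb", "cr", "cg", "cb", "gr", "gg", "gb")
  s <- 0
  for (n in nms) s <- s + abs(a[[n]] - b[[n]])
  s
}

brute_otsu <- function(gray) {
  lev <- as.integer(pmin(pmax(floor(gray), 0), 255))
  best <- -Inf; best_T <- NA_integer_
  for (T in 0:254) {
    g0 <- lev[lev <= T]; g1 <- lev[lev > T]
    if (length(g0) == 0L || length(g1) == 0L) next
    w0 <- length(g0) / length(lev)
    v <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (v > best + 1e-9) { best <- v; best_T <- T }
  }
  best_T
}

# exhaustive candidate search replicating the published selection rule
brute_aplt_argmin <- function(image, sb) {
  sbc <- sb$components
  ob <- brute_overall_brightness(image)
  gammas <- if (ob >= sbc$ob) 1:10 else round(seq(0, 0.9, by = 0.1), 1)
  grid <- expand.grid(c = 1:10, gamma = gammas)
  grid$bd <- mapply(function(cc, g) {
    cand <- power_law_transform(image, cc, g)
    brute_bd(as.list(brute_components(cand)), sb)
  }, grid$c, grid$gamma)
  grid <- grid[order(grid$bd, abs(grid$gamma - 1), grid$c), ]
  grid[1, ]
}

brute_foreground_mean <- function(crop, mask) {
  sums <- c(0, 0, 0); n <- 0
  for (y in seq_len(nrow(mask))) {
    for (x in seq_len(ncol(mask))) {
      if (mask[y, x] == 1) {
        n <- n + 1
        for (k in 1:3) sums[k] <- sums[k] + crop[y, x, k]
      }
    }
  }
  sums / n
}
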