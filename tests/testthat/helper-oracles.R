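# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force steady 1-D multilayer bioheat finite differences on a very fine
# uniform-per-layer grid (node-centred, interface nodes shared)
fd_slab_oracle <- function(tissues, thicknesses, props, T_core = 37,
                           h_conv = 3.6, T_air = 20, n_per_cm = 800) {
  k <- props$k[match(tissues, props$name)]
  s <- (props$w_b * props$rho_b * props$c_b)[match(tissues, props$name)]
  q <- (props$Q_met + props$w_b * props$rho_b * props$c_b *
          props$T_b)[match(tissues, props$name)]
  # build node list with layer id; nodes at interfaces belong to both
  xs <- list(); lay <- list()
  x0 <- 0
  for (l in seq_along(tissues)) {
    n <- max(8, round(thicknesses[l] * n_per_cm))
    xl <- seq(x0, x0 + thicknesses[l] * 0.01, length.out = n + 1)
    xs[[l]] <- xl
    x0 <- x0 + thicknesses[l] * 0.01
  }
  x <- unique(unlist(xs))
  n <- length(x)
  A <- matrix(0, n, n); b <- numeric(n)
  lay_of <- function(xm) max(1, findInterval(xm, cumsum(c(0, thicknesses))
                                             * 0.01, left.open = TRUE))
  A[1, 1] <- 1; b[1] <- T_core
  for (i in 2:(n - 1)) {
    hl <- x[i] - x[i - 1]; hr <- x[i + 1] - x[i]
    ll <- lay_of((x[i - 1] + x[i]) / 2)
    lr <- lay_of((x[i] + x[i + 1]) / 2)
    kl <- k[ll]; kr <- k[lr]
    A[i, i - 1] <- -kl / hl
    A[i, i + 1] <- -kr / hr
    # control volume split across the interface keeps second order
    A[i, i] <- kl / hl + kr / hr + s[ll] * hl / 2 + s[lr] * hr / 2
    b[i] <- q[ll] * hl / 2 + q[lr] * hr / 2
  }
  hl <- x[n] - x[n - 1]; kl <- k[length(k)]
  A[n, n - 1] <- -kl / hl
  A[n, n] <- kl / hl + h_conv + s[length(s)] * hl / 2
  b[n] <- T_air * h_conv + q[length(q)] * hl / 2
  list(x = x / 0.01, T = solve(A, b))
}

# brute-force binary erosion/dilation with an arbitrary structuring element
brute_erode <- function(mask, se) {
  oy <- (nrow(se) + 1) %/% 2; ox <- (ncol(se) + 1) %/% 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (y in seq_len(nrow(mask))) for (x in seq_len(ncol(mask))) {
    ok <- TRUE
    for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
      if (se[i, j] == 0) next
      yy <- y + i - oy; xx <- x + j - ox
      v <- if (yy < 1 || yy > nrow(mask) || xx < 1 || xx > ncol(mask))
        FALSE else mask[yy, xx]
      if (!v) { ok <- FALSE; break }
    }
    out[y, x] <- ok
  }
  out
}

brute_dilate <- function(mask, se) {
  oy <- (nrow(se) + 1) %/% 2; ox <- (ncol(se) + 1) %/% 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (y in seq_len(nrow(mask))) for (x in seq_len(ncol(mask))) {
    hit <- FALSE
    for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
      if (se[i, j] == 0) next
      yy <- y - (i - oy); xx <- x - (j - ox)
      if (yy >= 1 && yy <= nrow(mask) && xx >= 1 && xx <= ncol(mask) &&
          mask[yy, xx]) { hit <- TRUE; break }
    }
    out[y, x] <- hit
  }
  out
}

brute_open <- function(mask, se) brute_dilate(brute_erode(mask, se), se)

# independent 8-connected component count by repeated flood fill over a
# coordinate list
brute_components8 <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (!nrow(pts)) return(0)
  seen <- rep(FALSE, nrow(pts))
  key <- paste(pts[, 1], pts[, 2])
  lookup <- seq_len(nrow(pts)); names(lookup) <- key
  comps <- 0
  for (i in seq_len(nrow(pts))) {
    if (seen[i]) next
    comps <- comps + 1
    queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      c0 <- pts[queue[1], ]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        k <- paste(c0[1] + dy, c0[2] + dx)
        j <- lookup[k]
        if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  comps
}

# small solved neck field cached per test run (coarse but valid resolution)
cached_field <- local({
  cache <- list()
  function(fat = 1.2, nodule = nodule_spec(1.0, 1.57), units = "calibrated",
           resolution = 0.05) {
    key <- paste(fat, if (is.null(nodule)) "none"
                 else paste(nodule$diameter_minor, nodule$diameter_major),
                 paste(units, collapse = "_"), resolution)
    if (is.null(cache[[key]])) {
      g <- build_neck_section(fat, nodule)
      cache[[key]] <<- list(
        geometry = g,
        field = solve_steady(pennes_problem(g, tissue_properties(units)),
                             resolution))
    }
    cache[[key]]
  }
})
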