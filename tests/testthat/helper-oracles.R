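# Independent brute-force oracles. These deliberately share no code with the
# package implementations they validate.

# per-pixel max over the discrete disk, double loop
dilate_oracle <- function(m, radius) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  offs <- expand.grid(du = -radius:radius, dv = -radius:radius)
  offs <- offs[offs$du^2 + offs$dv^2 <= radius^2, ]
  for (i in 1:H) for (j in 1:W) {
    ii <- i + offs$du; jj <- j + offs$dv
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out[i, j] <- max(m[cbind(ii[ok], jj[ok])])
  }
  out
}

# plateau flood-fill regional maxima, 8-connectivity
regmax_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  visited <- matrix(FALSE, H, W)
  for (i0 in 1:H) for (j0 in 1:W) {
    if (visited[i0, j0]) next
    v <- m[i0, j0]
    queue <- list(c(i0, j0)); visited[i0, j0] <- TRUE
    plateau <- list(); is_max <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      plateau[[length(plateau) + 1]] <- p
      for (a in -1:1) for (b in -1:1) {
        if (a == 0 && b == 0) next
        ni <- p[1] + a; nj <- p[2] + b
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (m[ni, nj] > v) is_max <- FALSE
        if (m[ni, nj] == v && !visited[ni, nj]) {
          visited[ni, nj] <- TRUE
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
    if (is_max) for (p in plateau) out[p[1], p[2]] <- TRUE
  }
  out
}

# sort-based greedy matcher: enumerate all (det, truth) pairs, ascend by
# distance, take a pair when both ends are unused; then rescue leftovers
# strictly under epsilon the same way
match_oracle <- function(det_xy, truth_xy, xi, epsilon = 6) {
  nd <- nrow(det_xy); nt <- nrow(truth_xy)
  if (nd == 0 || nt == 0)
    return(list(tp = 0L, fp = nd, fn = nt))
  grid <- expand.grid(d = 1:nd, t = 1:nt)
  grid$dist <- sqrt((det_xy[grid$d, 1] - truth_xy[grid$t, 1])^2 +
                    (det_xy[grid$d, 2] - truth_xy[grid$t, 2])^2)
  grid <- grid[order(grid$dist), ]
  used_d <- logical(nd); used_t <- logical(nt); tp <- 0L
  for (r in seq_len(nrow(grid))) {
    if (grid$dist[r] > xi) break
    if (!used_d[grid$d[r]] && !used_t[grid$t[r]]) {
      used_d[grid$d[r]] <- TRUE; used_t[grid$t[r]] <- TRUE; tp <- tp + 1L
    }
  }
  for (r in seq_len(nrow(grid))) {
    if (grid$dist[r] >= epsilon) break
    if (!used_d[grid$d[r]] && !used_t[grid$t[r]]) {
      used_d[grid$d[r]] <- TRUE; used_t[grid$t[r]] <- TRUE; tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nd - tp, fn = nt - tp)
}

# even-odd point-in-polygon test for a single pixel center
point_in_polygon_oracle <- function(y, x, poly_rc) {
  n <- nrow(poly_rc); inside <- FALSE
  for (e in 1:n) {
    e2 <- if (e == n) 1 else e + 1
    y1 <- poly_rc[e, 1]; y2 <- poly_rc[e2, 1]
    x1 <- poly_rc[e, 2]; x2 <- poly_rc[e2, 2]
    if ((y1 > y) != (y2 > y)) {
      xcross <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xcross) inside <- !inside
    }
  }
  inside
}
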