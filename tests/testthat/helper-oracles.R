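# Independent brute-force oracles used to validate the compiled kernels.
# These deliberately use a different mechanism (whole-array shifting and
# iterative flood fill in plain R) than the package's per-voxel BFS code.

# out[v] = a[v - off], background outside the grid
shift_arr <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - off[k]
    i
  })
  ok <- lapply(1:3, function(k) src[[k]] >= 1 & src[[k]] <= d[k])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

se_offsets_r <- function(se) {
  d <- dim(se)
  ctr <- (d + 1L) %/% 2L
  w <- which(se, arr.ind = TRUE)
  sweep(w, 2, ctr)
}

oracle_dilate <- function(a, se) {
  offs <- se_offsets_r(se)
  out <- array(FALSE, dim = dim(a))
  for (i in seq_len(nrow(offs))) out <- out | shift_arr(a, offs[i, ])
  out
}

oracle_erode <- function(a, se) {
  offs <- se_offsets_r(se)
  out <- array(TRUE, dim = dim(a))
  for (i in seq_len(nrow(offs))) out <- out & shift_arr(a, -offs[i, ])
  out
}

oracle_close <- function(a, se) oracle_erode(oracle_dilate(a, se), se)
oracle_open <- function(a, se) oracle_dilate(oracle_erode(a, se), se)

cross6 <- function() {
  s <- array(FALSE, dim = c(3, 3, 3))
  s[2, 2, 2] <- s[1, 2, 2] <- s[3, 2, 2] <- TRUE
  s[2, 1, 2] <- s[2, 3, 2] <- s[2, 2, 1] <- s[2, 2, 3] <- TRUE
  s
}

# flood fill of the background from the grid faces; unreached background
# becomes foreground
oracle_fill <- function(a, conn = 6) {
  d <- dim(a)
  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  reach <- border & !a
  se <- if (conn == 6) cross6() else array(TRUE, dim = c(3, 3, 3))
  repeat {
    grown <- (oracle_dilate(reach, se) & !a) | reach
    if (identical(grown, reach)) break
    reach <- grown
  }
  a | !reach
}

# plain-R BFS component count
oracle_n_components <- function(a, conn = 26) {
  d <- dim(a)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(conn), "6" = 1,
                                   "18" = 2, "26" = 3), , drop = FALSE]
  seen <- array(FALSE, dim = d)
  n <- 0L
  idx <- which(a, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    n <- n + 1L
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        w <- cur + offs[k, ]
        if (any(w < 1) || any(w > d)) next
        if (a[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  n
}

# full-enumeration Mann-Whitney oracle (doubled smaller tail, capped)
oracle_mw_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  idx <- combn(length(pooled), n_a)
  u_all <- apply(idx, 2, function(i) sum(r[i])) - n_a * (n_a + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

random_mask_arr <- function(dims, p = 0.5) {
  array(runif(prod(dims)) < p, dim = dims)
}

solid_cuboid <- function(grid, cube, offset = NULL) {
  a <- array(FALSE, dim = grid)
  if (is.null(offset)) offset <- (grid - cube) %/% 2L
  a[offset[1] + seq_len(cube[1]), offset[2] + seq_len(cube[2]),
    offset[3] + seq_len(cube[3])] <- TRUE
  a
}
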