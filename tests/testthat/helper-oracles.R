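# Plain-R reference implementations of the filter pipeline, written as
# direct loops over definitions. They share no code with the package
# kernels and serve as brute-force oracles on small volumes.

reflect_idx <- function(i, n) {
  # symmetric (half-sample) mirror, 1-based
  j <- i - 1L
  while (any(j < 0L) || any(j >= n)) {
    j <- ifelse(j < 0L, -1L - j, j)
    j <- ifelse(j >= n, 2L * n - 1L - j, j)
  }
  j + 1L
}

mirror_pad_r <- function(arr, m) {
  d <- dim(arr)
  ix <- reflect_idx(seq_len(d[1] + 2L * m) - m, d[1])
  iy <- reflect_idx(seq_len(d[2] + 2L * m) - m, d[2])
  iz <- reflect_idx(seq_len(d[3] + 2L * m) - m, d[3])
  arr[ix, iy, iz, drop = FALSE]
}

# box mean / sample variance over full (2rB+1)^3 windows; NA where the
# window does not fit
oracle_box_stats <- function(up, rB) {
  d <- dim(up)
  bm <- array(NA_real_, d); bv <- array(NA_real_, d)
  nb <- (2 * rB + 1)^3
  for (z in (1 + rB):(d[3] - rB))
    for (y in (1 + rB):(d[2] - rB))
      for (x in (1 + rB):(d[1] - rB)) {
        w <- up[(x - rB):(x + rB), (y - rB):(y + rB), (z - rB):(z + rB)]
        bm[x, y, z] <- mean(w)
        bv[x, y, z] <- sum((w - mean(w))^2) / (nb - 1)
      }
  list(bm = bm, bv = bv)
}

# the full preprocessing chain: padded stats, residual, locally averaged
# squared residual, search-volume minimum, calibration
oracle_precompute <- function(u, p) {
  d <- dim(u)
  m <- p$rV + max(p$rP, 2L * p$rB)
  up <- mirror_pad_r(u, m)
  st <- oracle_box_stats(up, p$rB)
  R2 <- (up - st$bm)^2
  nb <- (2 * p$rB + 1)^3
  gam <- nb / (nb - 1) * mcdenoise::sigma_calibration_factor(p$rV, p$rB)
  dp <- dim(up)
  s2 <- array(NA_real_, dp)
  for (z in (1 + 2 * p$rB):(dp[3] - 2 * p$rB))
    for (y in (1 + 2 * p$rB):(dp[2] - 2 * p$rB))
      for (x in (1 + 2 * p$rB):(dp[1] - 2 * p$rB))
        s2[x, y, z] <- mean(R2[(x - p$rB):(x + p$rB),
                               (y - p$rB):(y + p$rB),
                               (z - p$rB):(z + p$rB)])
  sig <- array(NA_real_, d)
  s2core <- array(NA_real_, d)
  for (z in seq_len(d[3]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[1])) {
        px <- x + m; py <- y + m; pz <- z + m
        w <- s2[(px - p$rV):(px + p$rV), (py - p$rV):(py + p$rV),
                (pz - p$rV):(pz + p$rV)]
        sig[x, y, z] <- max(gam * min(w), p$min_sigma^2)
        s2core[x, y, z] <- gam * s2[px, py, pz]
      }
  list(up = up, bm = st$bm, bv = st$bv, sigma2 = sig, s2core = s2core, m = m)
}

oracle_preselect <- function(bm, bv, pi, pj, p, tiny_m, tiny_v) {
  rat <- function(a, b, lo, hi, tiny) {
    if (b <= tiny) return(a <= tiny)
    if (a <= tiny) return(FALSE)
    r <- a / b
    r >= lo && r <= hi
  }
  rat(bm[pi[1], pi[2], pi[3]], bm[pj[1], pj[2], pj[3]],
      p$presel_mean_ratio, 1 / p$presel_mean_ratio, tiny_m) &&
    rat(bv[pi[1], pi[2], pi[3]], bv[pj[1], pj[2], pj[3]],
        p$presel_var_low, p$presel_var_high, tiny_v)
}

# naive quadruple-loop nonlocal means pass; returns the filtered volume
# and the maximum deviation of any voxel's normalised weight sum from 1
oracle_filter_pass <- function(u, p) {
  d <- dim(u)
  pre <- oracle_precompute(u, p)
  up <- pre$up; m <- pre$m
  tiny_m <- 1e-12 * max(pre$bm, na.rm = TRUE)
  tiny_v <- 1e-12 * max(pre$bv, na.rm = TRUE)
  np <- (2 * p$rP + 1)^3
  rician <- p$noise_model == "rician"
  out <- array(NA_real_, d)
  worst_norm <- 0
  for (z in seq_len(d[3]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[1])) {
        s2 <- pre$sigma2[x, y, z]
        ui <- u[x, y, z]
        if (s2 <= 0) { out[x, y, z] <- if (rician) ui^2 else ui; next }
        ci <- c(x, y, z) + m
        Pi <- up[(ci[1] - p$rP):(ci[1] + p$rP),
                 (ci[2] - p$rP):(ci[2] + p$rP),
                 (ci[3] - p$rP):(ci[3] + p$rP)]
        h2 <- 2 * p$beta * s2
        ws <- 0; vs <- 0; wmax <- 0
        for (tz in -p$rV:p$rV) for (ty in -p$rV:p$rV) for (tx in -p$rV:p$rV) {
          if (tx == 0 && ty == 0 && tz == 0) next
          cj <- ci + c(tx, ty, tz)
          if (!oracle_preselect(pre$bm, pre$bv, ci, cj, p, tiny_m, tiny_v))
            next
          Pj <- up[(cj[1] - p$rP):(cj[1] + p$rP),
                   (cj[2] - p$rP):(cj[2] + p$rP),
                   (cj[3] - p$rP):(cj[3] + p$rP)]
          d2 <- sum((Pi - Pj)^2) / np
          w <- exp(-d2 / h2)
          uj <- up[cj[1], cj[2], cj[3]]
          ws <- ws + w
          vs <- vs + w * (if (rician) uj^2 else uj)
          wmax <- max(wmax, w)
        }
        wc <- if (wmax > 0) wmax else 1
        zi <- ws + wc
        out[x, y, z] <- (vs + wc * (if (rician) ui^2 else ui)) / zi
        worst_norm <- max(worst_norm, abs((ws + wc) / zi - 1))
      }
  list(filtered = out, worst_norm = worst_norm)
}

subband_names_all <- function() {
  g <- expand.grid(x = c("L", "H"), y = c("L", "H"), z = c("L", "H"),
                   stringsAsFactors = FALSE)
  paste0(g$x, g$y, g$z)
}

random_volume <- function(n, seed, offset = 1) {
  set.seed(seed)
  mcdenoise::volume3d(array(offset + stats::runif(n^3), c(n, n, n)))
}
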