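# Independent brute-force oracles used across tests. These deliberately use
# different algorithms from the package internals (direct sums, plain BFS,
# exhaustive enumeration) so the two routes cross-check each other.

# direct O(n^2) discrete convolution of y with exp(-rate t) on a uniform grid,
# trapezoid rule
oracle_exp_conv <- function(y, dt, rate) {
  n <- length(y)
  t <- (seq_len(n) - 1) * dt
  out <- numeric(n)
  for (i in 2:n) {
    s <- y[1:i] * exp(-rate * (t[i] - t[1:i]))
    out[i] <- sum((s[-1] + s[-i]) / 2) * dt
  }
  out
}

# sort-based midpoint-convention quantile ((k - 0.5)/n positions,
# linear interpolation, flat extrapolation)
oracle_quantile_mid <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  pos <- (seq_len(n) - 0.5) / n
  vapply(p, function(pp) {
    if (pp <= pos[1]) return(x[1])
    if (pp >= pos[n]) return(x[n])
    k <- max(which(pos <= pp))
    x[k] + (pp - pos[k]) / (pos[k + 1] - pos[k]) * (x[k + 1] - x[k])
  }, numeric(1))
}

# plain queue-based BFS 6-connected flood fill + threshold segmentation
oracle_segment <- function(image, search, threshold_frac) {
  d <- dim(image)
  vmax <- max(image[search])
  thr <- threshold_frac * vmax
  ok <- search & (image >= thr)
  start <- which(search & image == vmax)[1]
  comp <- array(FALSE, d)
  queue <- c(start)
  comp[start] <- TRUE
  nxyz <- function(i) arrayInd(i, d)
  while (length(queue) > 0) {
    cur <- nxyz(queue[1]); queue <- queue[-1]
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- as.integer(cur) + off
      if (any(nb < 1) || any(nb > d)) next
      if (ok[nb[1], nb[2], nb[3]] && !comp[nb[1], nb[2], nb[3]]) {
        comp[nb[1], nb[2], nb[3]] <- TRUE
        queue <- c(queue, (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1])
      }
    }
  }
  comp
}

# exhaustive SUVpeak: every mask voxel as a centre, explicit distance loop
oracle_suv_peak <- function(image, mask, dose_Bq, weight_g, voxel_size_mm,
                            sphere_ml = 1) {
  d <- dim(image)
  radius <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  suv <- image / (dose_Bq / weight_g)
  centres <- which(mask, arr.ind = TRUE)
  all_vox <- which(array(TRUE, d), arr.ind = TRUE)
  cent_mm <- sweep(all_vox - 0.5, 2, voxel_size_mm, `*`)
  best <- -Inf
  for (i in seq_len(nrow(centres))) {
    c_mm <- (centres[i, ] - 0.5) * voxel_size_mm
    d2 <- rowSums(sweep(cent_mm, 2, c_mm)^2)
    best <- max(best, mean(suv[d2 <= radius^2]))
  }
  best
}

# coarse grid search over (R1, k2, BP_ND) minimising the weighted SRTM RSS
oracle_srtm_grid <- function(lesion, reference, R1s, k2s, bps) {
  g <- expand.grid(R1 = R1s, k2 = k2s, bp = bps)
  obj <- vapply(seq_len(nrow(g)), function(i) {
    pred <- srtm_predict(list(R1 = g$R1[i], k2 = g$k2[i], bpnd = g$bp[i]),
                         reference)
    sum(lesion$weight * (lesion$conc_Bq_ml - pred$conc_Bq_ml)^2)
  }, numeric(1))
  g[which.min(obj), ]
}

# derivative-free oracle for the SRTM optimum: exhaustive coarse grid search
# followed by Nelder-Mead simplex refinement from the best grid point, on the
# natural parameter scale (independent of the package's Levenberg-Marquardt
# route and its log transforms)
oracle_srtm_optim <- function(lesion, reference, R1s, k2s, bps) {
  wrss <- function(p) {
    if (p[2] <= 0 || p[3] <= -1) return(Inf)
    pred <- srtm_predict(list(R1 = p[1], k2 = p[2], bpnd = p[3]), reference)
    sum(lesion$weight * (lesion$conc_Bq_ml - pred$conc_Bq_ml)^2)
  }
  g <- oracle_srtm_grid(lesion, reference, R1s, k2s, bps)
  o <- stats::optim(c(g$R1, g$k2, g$bp), wrss, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-12))
  list(R1 = o$par[1], k2 = o$par[2], bpnd = o$par[3], wrss = o$value,
       grid_wrss = wrss(c(g$R1, g$k2, g$bp)))
}

# balanced two-method ANOVA estimator of the variance-components CCC
oracle_vc_ccc <- function(x, y) {
  n <- length(x)
  d <- x - y
  m <- (x + y) / 2
  s2e <- sum((d - mean(d))^2) / (2 * (n - 1))
  s2s <- max(var(m) - s2e / 2, 0)
  s2m <- mean(d)^2 / 2
  s2s / (s2s + s2m + s2e)
}
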