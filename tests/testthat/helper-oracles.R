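# Independent oracles used by the tests. These deliberately share no code
# with the package internals they check.

# Exhaustive search over all contiguous partitions of the sorted data into k
# classes; returns the minimal within-cluster sum of squares and boundaries.
brute_force_cluster <- function(x, k, fixed_top_class_size = NULL) {
  xs <- sort(x)
  n <- length(xs)
  wcss_of <- function(groups) {
    sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  }
  if (!is.null(fixed_top_class_size)) {
    t <- fixed_top_class_size
    top <- xs[(n - t + 1):n]
    rest <- brute_force_cluster(xs[1:(n - t)], k - 1)
    return(list(wcss = rest$wcss + sum((top - mean(top))^2),
                sizes = c(rest$sizes, t)))
  }
  if (k == 1) return(list(wcss = wcss_of(list(xs)), sizes = n))
  breaks <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- NULL
  for (b in breaks) {
    cuts <- c(0, b, n)
    groups <- lapply(seq_len(k), function(q) xs[(cuts[q] + 1):cuts[q + 1]])
    w <- wcss_of(groups)
    if (is.null(best) || w < best$wcss) {
      best <- list(wcss = w, sizes = vapply(groups, length, integer(1)))
    }
  }
  best
}

# Profile residual sum of squares of the shared-Kd global quadratic model,
# scanned over a log10(Kd) grid. Per curve and per trial Kd, DT is optimised
# by 1-D search and (c, Ymax) by lm() — an independent route to the same
# objective the global fitter minimises.
profile_rss_scan <- function(data, log10kd_grid, n = 1) {
  curves <- split(data, data$curve_id)
  frac <- function(conc, kd, dt) {
    a <- n + conc / dt + kd / dt
    disc <- pmax(a^2 - 4 * n * conc / dt, 0)
    (a - sqrt(disc)) / (2 * n)
  }
  rss_curve_at <- function(d, kd, ldt) {
    f <- frac(d$conc_M, kd, 10^ldt)
    fit <- stats::lm(d$signal ~ f)
    sum(stats::resid(fit)^2)
  }
  vapply(log10kd_grid, function(lkd) {
    kd <- 10^lkd
    sum(vapply(curves, function(d) {
      stats::optimize(function(ldt) rss_curve_at(d, kd, ldt),
                      lower = -12, upper = -6)$objective
    }, numeric(1)))
  }, numeric(1))
}

# Monte-Carlo solvent-excluded volume of two spheres, using the closed-form
# distance from an interior point to the complement of the union of the two
# probe-enlarged balls (radial exits and the intersection circle).
mc_ses_two_spheres <- function(c1, c2, r1, r2, probe, n_pts, seed) {
  R1 <- r1 + probe; R2 <- r2 + probe
  axis <- c2 - c1; dcc <- sqrt(sum(axis^2)); axis <- axis / dcc
  set.seed(seed)
  lo <- pmin(c1 - R1, c2 - R2); hi <- pmax(c1 + R1, c2 + R2)
  pts <- cbind(stats::runif(n_pts, lo[1], hi[1]),
               stats::runif(n_pts, lo[2], hi[2]),
               stats::runif(n_pts, lo[3], hi[3]))
  d1 <- sqrt(rowSums(sweep(pts, 2, c1)^2))
  d2 <- sqrt(rowSums(sweep(pts, 2, c2)^2))
  in_union <- d1 < R1 | d2 < R2
  scale1 <- R1 / pmax(d1, 1e-12)
  scale2 <- R2 / pmax(d2, 1e-12)
  z1 <- sweep(sweep(pts, 2, c1) * scale1, 2, c1, `+`)
  z2 <- sweep(sweep(pts, 2, c2) * scale2, 2, c2, `+`)
  z1_ok <- sqrt(rowSums(sweep(z1, 2, c2)^2)) >= R2
  z2_ok <- sqrt(rowSums(sweep(z2, 2, c1)^2)) >= R1
  dcirc <- rep(Inf, n_pts)
  if (abs(R1 - R2) < dcc && dcc < R1 + R2) {
    a <- (dcc^2 + R1^2 - R2^2) / (2 * dcc)
    rc <- sqrt(R1^2 - a^2)
    rel <- sweep(pts, 2, c1)
    u <- as.vector(rel %*% axis)
    rho <- sqrt(pmax(rowSums(rel^2) - u^2, 0))
    dcirc <- sqrt((u - a)^2 + (rho - rc)^2)
  }
  dist_comp <- pmin(ifelse(z1_ok, R1 - d1, Inf),
                    ifelse(z2_ok, R2 - d2, Inf), dcirc)
  mean(in_union & dist_comp > probe) * prod(hi - lo)
}

# small synthetic PDB file (a few atoms) for structure-based tests
write_synthetic_pdb <- function(path) {
  lines <- c(
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            1, "C", "GLY", 1, 0.000, 0.000, 0.000, "C"),
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            2, "O", "GLY", 1, 1.000, 0.000, 0.000, "O"),
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            3, "N", "GLY", 1, 0.500, 1.200, 0.000, "N"),
    "END")
  writeLines(lines, path)
  path
}
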