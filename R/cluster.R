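# Exact 1-D clustering. For one-dimensional data the WCSS-optimal partition
# into k classes is always contiguous in sorted order, so the global optimum
# is found exactly by dynamic programming over break points — no iterative
# k-means, no dependence on starts, fully reproducible.

# prefix-sum WCSS of sorted x over [i, j]
.tv_seg_cost <- function(cs, cs2, i, j) {
  n <- j - i + 1
  s <- cs[j + 1] - cs[i]
  (cs2[j + 1] - cs2[i]) - s * s / n
}

# DP over sorted values; returns boundaries (last index of each class) and WCSS
.tv_dp_1d <- function(xs, k) {
  n <- length(xs)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- .tv_seg_cost(cs, cs2, 1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; arg <- 0L
        for (i in q:j) {  # class q is [i, j]
          v <- cost[q - 1, i - 1] + .tv_seg_cost(cs, cs2, i, j)
          if (v < best) { best <- v; arg <- i }
        }
        cost[q, j] <- best
        back[q, j] <- arg
      }
    }
  }
  bounds <- integer(k)
  j <- n
  for (q in k:1) {
    i <- if (q == 1) 1L else back[q, j]
    bounds[q] <- j
    j <- i - 1L
  }
  list(bounds = bounds, wcss = cost[k, n])
}

#' Exact one-dimensional clustering by dynamic programming
#'
#' Model-free clustering of a one-dimensional sample (here: molecular-weight
#' estimates of AFM particles) into `k` classes minimising the within-cluster
#' sum of squares. Classes of the optimal 1-D partition are contiguous
#' intervals of the sorted data, so the exact global optimum is obtained by
#' dynamic programming; results do not depend on the input order.
#' `fixed_top_class_size` constrains the top class to be exactly the given
#' number of largest observations (used when a small, visually distinct
#' heavy population is pinned and the remaining classes are re-optimised).
#'
#' @param x numeric vector of observations (e.g. masses in Da).
#' @param k number of classes, `1 <= k <= length(x)`.
#' @param fixed_top_class_size optional count: the top class is fixed to this
#'   many largest observations and the DP runs with `k - 1` classes on the
#'   remainder. Must be `< length(x)`.
#' @return object of class `"cluster1d"`: list with `k`, `assignments`
#'   (class index per observation, in input order), `centers` (increasing
#'   class means), `sizes`, `sds` (class SDs, `NA` for singletons),
#'   `withinss` (per class), `tot_withinss`, and `constraint`.
#' @examples
#' cluster1d(c(1, 2, 3, 10, 11, 12), k = 2)
#' @export
cluster1d <- function(x, k, fixed_top_class_size = NULL) {
  if (!is.numeric(x) || anyNA(x)) stop_field("x", "must be numeric without NA")
  n <- length(x)
  k <- check_count(k, "k")
  if (k > n) stop_field("k", "must be <= number of observations")
  if (!is.null(fixed_top_class_size)) {
    fixed_top_class_size <- check_count(fixed_top_class_size, "fixed_top_class_size")
    if (fixed_top_class_size >= n) {
      stop_field("fixed_top_class_size", "must be < number of observations")
    }
    if (k < 2L) stop_field("k", "must be >= 2 when the top class is fixed")
  }
  ord <- order(x)
  xs <- x[ord]
  cs <- c(0, cumsum(xs)); cs2 <- c(0, cumsum(xs^2))

  if (is.null(fixed_top_class_size)) {
    dp <- .tv_dp_1d(xs, k)
    bounds <- dp$bounds
  } else {
    t <- fixed_top_class_size
    m <- n - t
    if (k - 1L > m) stop_field("k", "too many classes for the unconstrained remainder")
    dp <- .tv_dp_1d(xs[seq_len(m)], k - 1L)
    bounds <- c(dp$bounds, n)
  }

  starts <- c(1L, bounds[-k] + 1L)
  cls_sorted <- rep(seq_len(k), bounds - starts + 1L)
  assignments <- integer(n)
  assignments[ord] <- cls_sorted
  centers <- vapply(seq_len(k), function(q) mean(xs[starts[q]:bounds[q]]), numeric(1))
  sizes <- bounds - starts + 1L
  sds <- vapply(seq_len(k), function(q) {
    if (sizes[q] > 1L) stats::sd(xs[starts[q]:bounds[q]]) else NA_real_
  }, numeric(1))
  withinss <- vapply(seq_len(k), function(q) {
    .tv_seg_cost(cs, cs2, starts[q], bounds[q])
  }, numeric(1))
  structure(list(k = k, assignments = assignments, centers = centers,
                 sizes = sizes, sds = sds, withinss = withinss,
                 tot_withinss = sum(withinss),
                 constraint = if (is.null(fixed_top_class_size)) "none"
                              else sprintf("top class fixed to %d largest", fixed_top_class_size)),
            class = "cluster1d")
}

#' @export
print.cluster1d <- function(x, ...) {
  cat(sprintf("1-D optimal clustering: k = %d, total WCSS = %.6g\n", x$k, x$tot_withinss))
  if (x$constraint != "none") cat("  constraint:", x$constraint, "\n")
  print(data.frame(class = seq_len(x$k), center = x$centers, sd = x$sds,
                   size = x$sizes, withinss = x$withinss), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.cluster1d <- function(x, values = NULL, ...) {
  if (is.null(values)) {
    graphics::stripchart(x$centers, pch = 4, ...)
  } else {
    graphics::stripchart(values ~ factor(x$assignments), vertical = TRUE,
                         method = "jitter", pch = 16,
                         xlab = "class", ylab = "value", ...)
    graphics::points(seq_len(x$k), x$centers, pch = 4, cex = 2)
  }
  invisible(x)
}

#' Choose the number of 1-D classes by BIC
#'
#' Fits [cluster1d()] for each `k` in `k_range` and scores each partition
#' under a k-component, equal-variance Gaussian mixture with hard
#' assignments: the log-likelihood uses mixing weights `n_j / n`, class means
#' and a pooled variance `WCSS / (n - k)`; the parameter count is `2k`
#' (k means, k - 1 weights, 1 variance). Returns the `k` minimising BIC along
#' with the WCSS-vs-k elbow table. Partitions with zero WCSS (degenerate,
#' noiseless) are scored only when `k = 1` fits exactly. This is a
#' diagnostic: an explicitly requested `k` always takes precedence.
#'
#' @param x numeric observations.
#' @param k_range integer vector of candidate class counts.
#' @return list with `k` (selected), and `table` (`k`, `wcss`, `bic`).
#' @examples
#' choose_k(c(rnorm(30), rnorm(30, 8)), 1:4)$k
#' @export
choose_k <- function(x, k_range = 1:4) {
  if (!is.numeric(x) || anyNA(x)) stop_field("x", "must be numeric without NA")
  if (length(k_range) == 0L) stop_field("k_range", "must be non-empty")
  n <- length(x)
  if (any(k_range < 1L) || any(k_range > n)) {
    stop_field("k_range", "must lie within [1, n_obs]")
  }
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    cl <- cluster1d(x, k)
    wcss <- cl$tot_withinss
    if (wcss <= 0 && k < n) {
      # exact fit: only meaningful when a single class already explains the data
      bic <- if (all(x == x[1]) && k == 1L) -Inf else Inf
    } else if (n - k <= 0) {
      bic <- Inf
    } else {
      sig2 <- wcss / (n - k)
      if (sig2 <= 0) {
        bic <- Inf
      } else {
        ll <- sum(log(cl$sizes[cl$assignments] / n)) +
          sum(stats::dnorm(x, cl$centers[cl$assignments], sqrt(sig2), log = TRUE))
        bic <- -2 * ll + 2 * k * log(n)
      }
    }
    data.frame(k = k, wcss = wcss, bic = bic)
  })
  tab <- do.call(rbind, rows)
  sel <- tab$k[which.min(tab$bic)]
  list(k = sel, table = tab)
}

#' Assign stoichiometry labels to mass classes
#'
#' Maps each class mean of a [cluster1d()] result to the nearest entry of a
#' [reference_ladder()]. Ties break toward the smaller complex. When more
#' than one ladder mass lies within 10% (relative to the class mean) the call
#' is ambiguous and all candidate labels are reported — the situation of two
#' homodimers of similar mass, whose distributions overlap and cannot be
#' separated by mass alone.
#'
#' @param clusters a [cluster1d()] result on masses in Da.
#' @param ladder a [reference_ladder()].
#' @param ambiguity_rel relative mass window for ambiguous calls (default 0.1).
#' @return `data.frame` with one row per class: `class`, `mean_da`, `label`
#'   (all candidates joined with `" | "` when ambiguous), `tier`,
#'   `mass_da` (nearest ladder mass), `residual_da`, `ambiguous`.
#' @export
assign_stoichiometry <- function(clusters, ladder = reference_ladder(),
                                 ambiguity_rel = 0.1) {
  stopifnot(inherits(clusters, "cluster1d"))
  if (!nrow(ladder)) stop_field("ladder", "must be non-empty")
  out <- do.call(rbind, lapply(seq_len(clusters$k), function(q) {
    mu <- clusters$centers[q]
    d <- abs(ladder$mass_da - mu)
    # nearest entry; ties toward the smaller complex (ladder sorted by mass)
    best <- which(d == min(d))[1]
    cand <- which(d / mu <= ambiguity_rel)
    if (!length(cand)) cand <- best
    amb <- length(cand) > 1L
    data.frame(class = q, mean_da = mu,
               label = paste(ladder$label[cand], collapse = " | "),
               tier = ladder$tier[best],
               mass_da = ladder$mass_da[best],
               residual_da = abs(mu - ladder$mass_da[best]),
               ambiguous = amb, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
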