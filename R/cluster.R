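#' Build a record-by-condition feature matrix
#'
#' @param x either a [extract_cohort()] result (0/1 condition columns) or a
#'   list of token vectors (a tokenized corpus).
#' @param mode `"binary"` (0/1 indicators, the default clustering input),
#'   `"count"` (occurrence counts; identical to binary for flag input) or
#'   `"tfidf"` (counts reweighted by `idf(t) = ln((1+N)/(1+df(t))) + 1`,
#'   then each row scaled to unit Euclidean norm; all-zero rows left zero).
#' @param vocab for corpus input, the terms to use as columns (default: all
#'   observed terms, lexicographic order).
#' @return numeric matrix, rows = records, columns = conditions/terms, with
#'   `record_id` rownames when available.
#' @export
build_feature_matrix <- function(x, mode = c("binary", "count", "tfidf"),
                                 vocab = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(x)) {
    cond <- setdiff(names(x), c("record_id", "morbidity_count",
                                "burden_class"))
    m <- as.matrix(x[, cond, drop = FALSE])
    storage.mode(m) <- "double"
    if (!is.null(x$record_id)) rownames(m) <- as.character(x$record_id)
  } else if (is.list(x)) {
    if (is.null(vocab)) vocab <- sort(unique(unlist(x, use.names = FALSE)))
    m <- t(vapply(x, function(tk) {
      tabulate(factor(tk, levels = vocab), nbins = length(vocab))
    }, numeric(length(vocab))))
    colnames(m) <- vocab
  } else {
    stop("unsupported input: expected a profiles data.frame or token list",
         call. = FALSE)
  }
  if (nrow(m) == 0L) stop("no records to vectorise", call. = FALSE)
  switch(mode,
         binary = (m > 0) + 0,
         count = m,
         tfidf = {
           N <- nrow(m)
           df <- colSums(m > 0)
           w <- sweep(m, 2, log((1 + N) / (1 + df)) + 1, `*`)
           nrm <- sqrt(rowSums(w^2))
           nz <- nrm > 0
           w[nz, ] <- w[nz, , drop = FALSE] / nrm[nz]
           w
         })
}

sq_dist_to <- function(X, C) {
  # n x k matrix of squared Euclidean distances
  d <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  pmax(d, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- sq_dist_to(X, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, sq_dist_to(X, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

lloyd_once <- function(X, k, max_iter, tol, init = NULL) {
  C <- if (is.null(init)) kmeanspp_init(X, k) else init
  assign <- rep(1L, nrow(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- sq_dist_to(X, C)
    assign <- max.col(-D, ties.method = "first")
    newC <- C
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      if (length(idx) == 0L) {
        # empty cluster: relocate to the point farthest from its centroid
        far <- which.max(D[cbind(seq_len(nrow(X)), assign)])
        newC[j, ] <- X[far, ]
        assign[far] <- j
      } else {
        newC[j, ] <- colMeans(X[idx, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((newC - C)^2)))
    C <- newC
    if (shift < tol) { converged <- TRUE; break }
  }
  D <- sq_dist_to(X, C)
  assign <- max.col(-D, ties.method = "first")
  inertia <- sum(D[cbind(seq_len(nrow(X)), assign)])
  list(centroids = C, assignments = assign, inertia = inertia,
       converged = converged)
}

#' Fit k-means to a comorbidity feature matrix
#'
#' Lloyd's algorithm with k-means++ initialisation, keeping the best of
#' `n_init` restarts by inertia. Iteration stops when the largest centroid
#' shift falls below `tol` or after `max_iter` sweeps. An emptied cluster is
#' repaired deterministically by relocating its centroid to the point
#' farthest from its current centroid. Fully reproducible given
#' `(seed, n_init)`.
#'
#' @param X numeric feature matrix ([build_feature_matrix()]).
#' @param k number of clusters (1 <= k <= number of distinct rows).
#' @param seed integer RNG seed.
#' @param n_init number of random restarts (default 10).
#' @param max_iter maximum Lloyd sweeps per restart (default 300).
#' @param tol centroid-shift convergence tolerance (default 1e-4).
#' @return object of class `comorbidity_km`: list with `k`, `centroids`,
#'   `assignments` (1-based cluster ids, one per row of `X`), `inertia`,
#'   `seed`, `n_init`, `converged`, and `sizes`.
#' @export
kmeans_fit <- function(X, k, seed = 1L, n_init = 10L, max_iter = 300L,
                       tol = 1e-4) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  if (k < 1L || k > n_distinct) {
    stop("k must be between 1 and the number of distinct rows (",
         n_distinct, ")", call. = FALSE)
  }
  if (n_init < 1L) stop("n_init must be >= 1", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- lloyd_once(X, k, max_iter, tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(k = as.integer(k), centroids = best$centroids,
                 assignments = best$assignments, inertia = best$inertia,
                 seed = seed, n_init = n_init, converged = best$converged,
                 sizes = tabulate(best$assignments, nbins = k),
                 record_id = rownames(X)),
            class = "comorbidity_km")
}

#' @export
print.comorbidity_km <- function(x, ...) {
  cat("K-means comorbidity clustering: k =", x$k, ", n =",
      length(x$assignments), "\n")
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("inertia %.4g (%s, %d restarts, seed %d)\n", x$inertia,
              if (x$converged) "converged" else "max_iter reached",
              x$n_init, x$seed))
  invisible(x)
}

#' @export
summary.comorbidity_km <- function(object, ...) {
  print(object)
  cat("\nCentroids:\n")
  print(round(object$centroids, 3))
  invisible(object)
}

#' @export
fitted.comorbidity_km <- function(object, ...) object$assignments

#' Assign new records to fitted clusters
#'
#' @param object a [kmeans_fit()] model.
#' @param newdata feature matrix with the same columns as the training
#'   matrix.
#' @param ... unused.
#' @return integer vector of nearest-centroid cluster ids.
#' @export
predict.comorbidity_km <- function(object, newdata, ...) {
  D <- sq_dist_to(as.matrix(newdata), object$centroids)
  max.col(-D, ties.method = "first")
}

#' Plot cluster structure on the first two principal components
#'
#' @param x a [kmeans_fit()] model.
#' @param X the feature matrix the model was fitted on.
#' @param ... passed to [graphics::plot()].
#' @export
plot.comorbidity_km <- function(x, X, ...) {
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  graphics::plot(p$x[, 1], p$x[, 2], col = x$assignments, pch = 16,
                 xlab = "PC1", ylab = "PC2",
                 main = paste0("Comorbidity clusters (k = ", x$k, ")"), ...)
  invisible(x)
}

#' Choose the number of clusters by the elbow method
#'
#' Fits k-means for each k in `k_min:k_max` and picks the k whose point on
#' the inertia-vs-k polyline (both axes scaled to `[0, 1]`) lies farthest,
#' by perpendicular distance, from the chord joining the first and last
#' points; ties break toward smaller k. A flat curve yields `k_min` with a
#' warning. `chosen_k` can be overridden manually downstream.
#'
#' @param X feature matrix.
#' @param k_min,k_max scan range (`k_min >= 1`, `k_max` at most the number
#'   of distinct rows).
#' @param seed,n_init,max_iter,tol as in [kmeans_fit()]; each k is fitted
#'   with seed `seed + k` so the scan is reproducible. In addition to the
#'   random restarts, each k is warm-started from the previous solution's
#'   centroids plus its farthest point, which keeps the best inertia
#'   non-increasing in k.
#' @return object of class `elbow_curve`: data.frame `(k, inertia)` with
#'   attributes `chosen_k` and `models` (the fitted `comorbidity_km` per k).
#' @export
elbow_select_k <- function(X, k_min = 1L, k_max = 8L, seed = 1L,
                           n_init = 10L, max_iter = 300L, tol = 1e-4) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  if (!(k_min >= 1L && k_min < k_max)) {
    stop("need k_min >= 1 and k_min < k_max", call. = FALSE)
  }
  if (k_max > n_distinct) {
    stop("k_max exceeds the number of distinct rows (", n_distinct, ")",
         call. = FALSE)
  }
  ks <- k_min:k_max
  models <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    fit <- kmeans_fit(X, k, seed = seed + k, n_init = n_init,
                      max_iter = max_iter, tol = tol)
    if (!is.null(prev)) {
      # warm start from the previous solution plus its farthest point, so
      # the best inertia can never increase with k
      D <- sq_dist_to(X, prev$centroids)
      own <- D[cbind(seq_len(nrow(X)), prev$assignments)]
      init <- rbind(prev$centroids, X[which.max(own), ])
      warm <- lloyd_once(X, k, max_iter, tol, init = init)
      if (warm$inertia < fit$inertia) {
        fit$centroids <- warm$centroids
        fit$assignments <- warm$assignments
        fit$inertia <- warm$inertia
        fit$converged <- warm$converged
        fit$sizes <- tabulate(warm$assignments, nbins = k)
      }
    }
    models[[i]] <- fit
    prev <- fit
  }
  inertia <- vapply(models, `[[`, numeric(1), "inertia")
  rng <- diff(range(inertia))
  if (rng <= max(1e-12, 1e-9 * max(abs(inertia), 1))) {
    warning("flat inertia curve: no elbow, choosing k_min", call. = FALSE)
    chosen <- k_min
  } else {
    u <- (ks - k_min) / (k_max - k_min)
    v <- (inertia - min(inertia)) / rng
    # perpendicular distance to the chord from first to last point
    x1 <- u[1]; y1 <- v[1]; x2 <- u[length(u)]; y2 <- v[length(v)]
    dist <- abs((y2 - y1) * u - (x2 - x1) * v + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (max(dist) <= 1e-9) {
      warning("flat inertia curve: no elbow, choosing k_min", call. = FALSE)
      chosen <- k_min
    } else {
      chosen <- ks[which.max(dist)]
    }
  }
  chosen <- as.integer(chosen)
  out <- data.frame(k = ks, inertia = inertia)
  class(out) <- c("elbow_curve", "data.frame")
  attr(out, "chosen_k") <- chosen
  attr(out, "models") <- setNames(models, ks)
  out
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("Elbow scan, chosen k =", attr(x, "chosen_k"), "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.elbow_curve <- function(x, ...) {
  graphics::plot(x$k, x$inertia, type = "b", pch = 16, xlab = "k",
                 ylab = "inertia", main = "Elbow curve", ...)
  graphics::abline(v = attr(x, "chosen_k"), lty = 2)
  invisible(x)
}

#' Characterise clusters by within-cluster condition prevalence
#'
#' @param model a [kmeans_fit()] model.
#' @param profiles the profiles (or any data.frame of 0/1 condition
#'   columns) the model was fitted on, same row order.
#' @param top_m conditions to list per cluster (default 10).
#' @return named list: cluster id -> data.frame `(condition, prevalence)`,
#'   descending prevalence, lexicographic tie-break.
#' @export
characterize_clusters <- function(model, profiles, top_m = 10L) {
  cond <- setdiff(names(profiles), c("record_id", "morbidity_count",
                                     "burden_class"))
  m <- as.matrix(profiles[, cond, drop = FALSE])
  out <- lapply(seq_len(model$k), function(j) {
    idx <- model$assignments == j
    prev <- colMeans(m[idx, , drop = FALSE])
    ord <- order(-prev, names(prev))
    utils::head(data.frame(condition = names(prev)[ord],
                           prevalence = unname(prev[ord]),
                           stringsAsFactors = FALSE), top_m)
  })
  names(out) <- paste0("cluster_", seq_len(model$k))
  out
}

#' Per-cluster outcome risk with pairwise comparisons
#'
#' Computes each cluster's outcome risk (events / n) and, for every cluster
#' pair, the continuity-corrected chi-square p-value of the 2x2 table
#' (membership in A vs B) x outcome — the same statistic used in the
#' association screen.
#'
#' @param model a [kmeans_fit()] model.
#' @param outcome_flags 0/1 vector, one per assigned record (e.g. GDM).
#' @return object of class `cluster_risk_table`: list with `risk`
#'   (data.frame: cluster, n, events, risk) and `pairwise_p` (symmetric k x
#'   k matrix, NA diagonal).
#' @export
cluster_outcome_risk <- function(model, outcome_flags) {
  if (length(outcome_flags) != length(model$assignments)) {
    stop("need one outcome flag per assigned record", call. = FALSE)
  }
  o <- as.integer(outcome_flags)
  k <- model$k
  n <- tabulate(model$assignments, nbins = k)
  ev <- vapply(seq_len(k), function(j) sum(o[model$assignments == j]),
               integer(1))
  keep <- n > 0L
  if (any(!keep)) warning("excluding empty cluster(s): ",
                          paste(which(!keep) - 1L, collapse = ", "),
                          call. = FALSE)
  risk <- data.frame(cluster = seq_len(k) - 1L, n = n, events = ev,
                     risk = ifelse(n > 0, ev / n, NA_real_))[keep, ]
  pw <- matrix(NA_real_, k, k,
               dimnames = list(paste0("cluster_", seq_len(k) - 1L),
                               paste0("cluster_", seq_len(k) - 1L)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!keep[i] || !keep[j]) next
      sel <- model$assignments %in% c(i, j)
      t <- contingency_2x2(as.integer(model$assignments[sel] == j), o[sel])
      if (all(c(t$r1, t$r2, t$c1, t$c2) > 0)) {
        pw[i, j] <- pw[j, i] <- chi2_pvalue_1df(chi_square_corrected(t))
      }
    }
  }
  structure(list(risk = risk, pairwise_p = pw),
            class = "cluster_risk_table")
}

#' @export
print.cluster_risk_table <- function(x, ...) {
  cat("Per-cluster outcome risk\n")
  print(transform(x$risk, risk = round(risk, 4)), row.names = FALSE)
  cat("\nPairwise corrected chi-square p-values:\n")
  print(round(x$pairwise_p, 4))
  invisible(x)
}
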