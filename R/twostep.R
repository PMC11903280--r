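# SPSS-style two-step cluster analysis for continuous variables:
# CF-style pre-clustering with the log-likelihood distance, agglomerative
# merging, and automatic cluster-number selection by the BIC-change /
# distance-change ratio rules.

# cluster summary: count + per-variable sum and sum of squares (mergeable)
.cf_new <- function(x) list(n = 1, s = x, ss = x^2)
.cf_merge <- function(a, b) list(n = a$n + b$n, s = a$s + b$s,
                                 ss = a$ss + b$ss)
.cf_var <- function(cf, floor = 1e-8) {
  pmax(cf$ss / cf$n - (cf$s / cf$n)^2, floor)
}

# log-likelihood contribution xi of one cluster: -n * sum_k 0.5 *
# log(sigma_k^2 + sigma_vk^2), with sigma_k^2 the overall per-variable
# variance (1 after standardization) regularizing the within variance.
.cf_xi <- function(cf, overall_var, floor = 1e-8) {
  -cf$n * sum(0.5 * log(overall_var + .cf_var(cf, floor)))
}

# log-likelihood distance between two summaries
.cf_dist <- function(a, b, overall_var, floor = 1e-8) {
  .cf_xi(a, overall_var, floor) + .cf_xi(b, overall_var, floor) -
    .cf_xi(.cf_merge(a, b), overall_var, floor)
}

#' Pre-cluster cases into CF-style leaf entries
#'
#' Sequential insertion: each case joins the nearest existing leaf entry if
#' the log-likelihood distance increase is below `threshold`, else it starts
#' a new entry. If the number of entries exceeds `leaf_cap`, the entries are
#' rebuilt (re-inserted as units) with a doubled threshold seeded by the
#' smallest observed inter-entry distance. Deterministic given the case
#' order.
#'
#' @param x numeric matrix of standardized cases (rows) x variables.
#' @param threshold initial distance threshold (0 = every distinct case its
#'   own entry until the cap forces coarsening).
#' @param leaf_cap maximum number of leaf entries.
#' @param overall_var per-variable overall variances (regularizer in the
#'   distance); defaults to 1 (standardized data).
#' @param var_floor variance floor guarding `log(0)`.
#' @return list of cluster summaries, each `list(n, s, ss, members)`.
#' @export
precluster <- function(x, threshold = 0, leaf_cap = 100,
                       overall_var = rep(1, ncol(x)), var_floor = 1e-8) {
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (anyNA(x)) stop_vg("precluster: missing values must be excluded upstream")
  insert_all <- function(units, thr) {
    leaves <- list()
    for (u in units) {
      if (!length(leaves)) { leaves[[1]] <- u; next }
      d <- vapply(leaves, function(l) .cf_dist(l, u, overall_var, var_floor),
                  numeric(1))
      j <- which.min(d)
      if (d[j] <= thr) {
        merged <- .cf_merge(leaves[[j]], u)
        merged$members <- c(leaves[[j]]$members, u$members)
        leaves[[j]] <- merged
      } else {
        leaves[[length(leaves) + 1L]] <- u
      }
    }
    leaves
  }
  units <- lapply(seq_len(nrow(x)), function(i) {
    u <- .cf_new(x[i, ]); u$members <- i; u
  })
  leaves <- insert_all(units, threshold)
  while (length(leaves) > leaf_cap) {
    dmin <- Inf
    for (i in seq_along(leaves)) {
      for (j in seq_len(i - 1L)) {
        dmin <- min(dmin, .cf_dist(leaves[[i]], leaves[[j]], overall_var,
                                   var_floor))
      }
    }
    threshold <- max(2 * threshold, 2 * dmin, 1e-12)
    leaves <- insert_all(leaves, threshold)
  }
  leaves
}

# BIC of a partition (list of summaries). Free parameters: a mean and a
# variance per cluster and variable, plus k - 1 mixing proportions (the
# standard Gaussian-mixture count).
.cf_bic <- function(clusters, overall_var, N, var_floor = 1e-8) {
  K <- length(overall_var)
  k <- length(clusters)
  ll <- sum(vapply(clusters, .cf_xi, numeric(1), overall_var, var_floor))
  -2 * ll + (2 * K * k + (k - 1)) * log(N)
}

#' Two-step cluster analysis
#'
#' Hybrid clustering of continuous variables: cases are first condensed into
#' leaf entries by a distance threshold ([precluster]), then merged
#' agglomeratively under the log-likelihood distance, and the number of
#' clusters is selected automatically. Selection follows the two-stage
#' ratio rule: (1) if the BIC change from 1 to 2 clusters is non-negative,
#' k = 1; otherwise the coarse estimate is the largest k whose BIC-change
#' ratio relative to the first change exceeds `bic_ratio`; (2) among the
#' remaining candidates, the ratio of minimum inter-cluster merge distances
#' refines the choice: if the largest distance-ratio jump exceeds
#' `dist_ratio` times the second largest, its k wins, else the larger k of
#' the two. Final assignments are by smallest log-likelihood distance to the
#' selected clusters. Variables are z-standardized internally; cases are
#' processed in input order, so callers should fix a stable order (e.g.
#' subject id).
#'
#' @param data data frame or matrix of continuous variables (complete
#'   cases required; drop missing upstream).
#' @param k_max maximum number of clusters evaluated (>= 1).
#' @param threshold,leaf_cap pre-clustering controls ([precluster]).
#' @param bic_ratio,dist_ratio selection thresholds (published defaults
#'   0.04 and 1.15).
#' @param standardize z-score the variables first (default TRUE).
#' @param var_floor variance floor in the log-likelihood distance.
#' @return object of class `twostep_cluster`: `k` (selected), `assignments`
#'   (integer vector), `bic` (data frame k, bic, dbic), `centers` (selected
#'   cluster means on the original scale), `merge_distances`,
#'   `standardization` (means/sds used), `n`.
#' @export
twostep_cluster <- function(data, k_max = 5, threshold = 0, leaf_cap = 100,
                            bic_ratio = 0.04, dist_ratio = 1.15,
                            standardize = TRUE, var_floor = 1e-8) {
  if (k_max < 1) stop_vg("k_max must be >= 1")
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop_vg("missing values: exclude incomplete cases upstream")
  N <- nrow(x)
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero <- sds < 1e-12
  if (standardize && any(zero)) {
    stop_vg("zero-variance variable(s): ",
            paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
  }
  z <- if (standardize) scale(x, ctr, sds) else x
  overall_var <- apply(z, 2, function(v) mean(v^2) - mean(v)^2)

  leaves <- precluster(z, threshold, leaf_cap, overall_var, var_floor)

  # agglomerative merging by minimum log-likelihood distance, recording the
  # partition and the merge distance at each cluster count
  partitions <- list()
  merge_dist <- rep(NA_real_, length(leaves)) # merge_dist[k]: distance of the merge k -> k-1
  cur <- leaves
  partitions[[length(cur)]] <- cur
  while (length(cur) > 1) {
    k <- length(cur)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k)) {
      for (j in seq_len(i - 1L)) {
        d <- .cf_dist(cur[[i]], cur[[j]], overall_var, var_floor)
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    merged <- .cf_merge(cur[[best[2]]], cur[[best[3]]])
    merged$members <- c(cur[[best[2]]]$members, cur[[best[3]]]$members)
    cur <- c(cur[-c(best[2], best[3])], list(merged))
    merge_dist[k] <- best[1]
    partitions[[length(cur)]] <- cur
  }

  kk <- seq_len(min(k_max, length(leaves)))
  bic <- vapply(kk, function(k) .cf_bic(partitions[[k]], overall_var, N,
                                        var_floor), numeric(1))
  dbic <- c(NA, diff(bic))
  k_sel <- 1L
  if (length(kk) > 1 && dbic[2] < 0) {
    r1 <- dbic / dbic[2]
    cand <- kk[!is.na(dbic) & r1 > bic_ratio]
    k1 <- max(cand)
    if (k1 <= 2L) {
      k_sel <- k1
    } else {
      # distance-change ratio for k = 2..k1: ratio of the merge distance
      # closing k clusters to the one closing k+1 clusters
      ks <- 2:k1
      r2 <- vapply(ks, function(k) merge_dist[k] / merge_dist[k + 1L],
                   numeric(1))
      ks <- ks[is.finite(r2)]
      r2 <- r2[is.finite(r2)]
      ord <- order(-r2)
      if (!length(ks)) {
        k_sel <- k1
      } else if (length(ks) == 1L) {
        k_sel <- ks[1]
      } else if (r2[ord[1]] > dist_ratio * r2[ord[2]]) {
        k_sel <- ks[ord[1]]
      } else {
        k_sel <- max(ks[ord[1]], ks[ord[2]])
      }
    }
  }

  final <- partitions[[k_sel]]
  assign_of <- function(xi) {
    u <- .cf_new(xi)
    d <- vapply(final, function(cl) .cf_dist(cl, u, overall_var, var_floor),
                numeric(1))
    which.min(d)
  }
  assignments <- vapply(seq_len(N), function(i) assign_of(z[i, ]),
                        integer(1))
  centers_z <- t(vapply(final, function(cl) cl$s / cl$n,
                        numeric(ncol(z))))
  centers <- sweep(sweep(centers_z, 2, if (standardize) sds else 1, "*"),
                   2, if (standardize) ctr else 0, "+")
  colnames(centers) <- colnames(x)
  structure(list(
    k = k_sel, assignments = assignments,
    bic = data.frame(k = kk, bic = bic, dbic = dbic),
    centers = centers, merge_distances = merge_dist,
    n_leaves = length(leaves),
    standardization = list(center = ctr, scale = sds,
                           standardize = standardize),
    n = N
  ), class = "twostep_cluster")
}

#' @export
print.twostep_cluster <- function(x, ...) {
  cat(sprintf("<twostep_cluster> n = %d, %d leaf entries, selected k = %d\n",
              x$n, x$n_leaves, x$k))
  print(round(x$bic, 2), row.names = FALSE)
  cat("cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cluster composition by study group
#'
#' Cross-tabulates final cluster assignments against study-group labels and
#' reports, per cluster, the percentage of each group it captures plus the
#' observed variable ranges.
#'
#' @param model a [twostep_cluster] fit.
#' @param labels group labels aligned with the clustered cases.
#' @param data optional data used in the fit, for per-cluster ranges.
#' @return list with `counts` (clusters x groups), `group_pct` (percentage
#'   of each group falling in each cluster) and `ranges` (per cluster and
#'   variable min/max), the latter `NULL` without `data`.
#' @export
cluster_report <- function(model, labels, data = NULL) {
  stopifnot(inherits(model, "twostep_cluster"))
  if (length(labels) != model$n) {
    stop_vg("labels length does not match number of clustered cases")
  }
  cl <- factor(model$assignments, levels = seq_len(model$k))
  counts <- table(cluster = cl, group = labels)
  group_pct <- sweep(counts, 2, colSums(counts), "/") * 100
  ranges <- NULL
  if (!is.null(data)) {
    d <- as.data.frame(data)
    ranges <- do.call(rbind, lapply(seq_len(model$k), function(k) {
      sub <- d[model$assignments == k, , drop = FALSE]
      do.call(rbind, lapply(names(sub), function(v) {
        data.frame(cluster = k, variable = v,
                   min = min(sub[[v]]), max = max(sub[[v]]))
      }))
    }))
  }
  list(counts = counts, group_pct = group_pct, ranges = ranges)
}
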