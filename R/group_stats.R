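#' One-sample t-test against zero, per cell
#'
#' Vectorized one-sample t-statistics and two-sided p-values for a
#' participants x cells matrix (cells are channels, or channel-time
#' pairs). Cells with zero variance get `t = NA` and `p = 1`.
#'
#' @param x numeric matrix, participants x cells (or a vector, treated
#'   as one cell).
#' @return List with `t`, `p`, `df`, `mean`, `sd` (per cell).
#' @export
one_sample_t <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 2L) stop("one-sample t-test needs at least 2 participants")
  m <- colMeans(x)
  s <- sqrt(colSums(sweep(x, 2L, m)^2) / (n - 1L))
  tt <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tt), df = n - 1L, lower.tail = FALSE)
  degenerate <- !is.finite(s) | s == 0
  tt[degenerate] <- NA_real_
  p[degenerate] <- 1
  list(t = tt, p = p, df = n - 1L, mean = m, sd = s)
}

#' Bonferroni significance mask
#'
#' @param p numeric vector of raw p-values.
#' @param alpha family-wise alpha (default 0.05).
#' @return Logical vector: `p < alpha / length(p)`.
#' @export
bonferroni_mask <- function(p, alpha = 0.05) {
  stopifnot(length(p) >= 1L)
  p < alpha / length(p)
}

#' Channel adjacency from positions
#'
#' Builds a symmetric, irreflexive channel x channel neighbor relation
#' by thresholding pairwise Euclidean distance. When `threshold` is
#' omitted it is chosen as the smallest distance at which the median
#' neighbor count falls in `[4, 8]` (or the closest achievable).
#'
#' @param positions channels x 2 or channels x 3 coordinate matrix.
#' @param threshold neighbor distance threshold, or `NULL` to auto-pick.
#' @return Logical adjacency matrix with channel dimnames.
#' @export
adjacency_from_positions <- function(positions, threshold = NULL) {
  positions <- as.matrix(positions)
  d <- as.matrix(stats::dist(positions))
  if (is.null(threshold)) {
    cand <- sort(unique(round(d[upper.tri(d)], 10)))
    med_deg <- vapply(cand, function(th)
      stats::median(rowSums(d <= th + 1e-12) - 1), 1)
    ok <- which(med_deg >= 4 & med_deg <= 8)
    threshold <- if (length(ok)) cand[ok[1L]] else
      cand[which.min(abs(med_deg - 6))]
  }
  adj <- d <= threshold + 1e-12
  diag(adj) <- FALSE
  dimnames(adj) <- dimnames(d)
  adj
}

# connected components of candidate cells on the channels x time grid:
# neighbors are (adjacent channels, same time) and (same channel,
# adjacent time). Returns an integer label matrix (0 = not candidate).
cluster_components <- function(cand, adj) {
  nch <- nrow(cand); nt <- ncol(cand)
  idx <- which(cand)
  if (!length(idx)) return(matrix(0L, nch, nt))
  # edges along time
  e_time <- which(cand[, -nt, drop = FALSE] & cand[, -1L, drop = FALSE])
  from_t <- ((e_time - 1L) %/% nch) * nch + ((e_time - 1L) %% nch) + 1L
  edges <- cbind(from_t, from_t + nch)
  # edges across neighboring channels at the same time
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      both <- which(cand[pairs[k, 1L], ] & cand[pairs[k, 2L], ])
      if (length(both)) {
        base <- (both - 1L) * nch
        edges <- rbind(edges, cbind(base + pairs[k, 1L],
                                    base + pairs[k, 2L]))
      }
    }
  }
  vmap <- match(seq_len(nch * nt), idx)   # cell -> vertex id (NA if not cand)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(vmap[edges[, 1L]], vmap[edges[, 2L]]))
  }
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, nch, nt)
  lab[idx] <- comp
  lab
}

#' Spatio-temporal cluster-based bootstrap correction
#'
#' Family-wise corrected inference for a participants x channels x time
#' statistic (e.g. pooled BPI time courses) against zero. Candidate
#' cells with raw one-sample p below `cluster_alpha` are grouped into
#' spatio-temporally connected clusters (channel neighbors at the same
#' time point, adjacent time points at the same channel); each cluster's
#' mass is the sum of |t| over its cells. The null distribution of the
#' maximal cluster mass is built by centering every participant's map
#' (subtracting the group mean map) and resampling participants with
#' replacement `n_boot` times; a cluster is significant when its mass
#' exceeds the `1 - alpha` quantile of the null maxima.
#'
#' @param x numeric array, participants x channels x time (a matrix is
#'   treated as one time point).
#' @param adjacency logical channels x channels neighbor matrix
#'   (symmetric, irreflexive); required.
#' @param alpha cluster-level family-wise alpha (default 0.05).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param cluster_alpha cluster-forming threshold on the raw two-sided p
#'   (default 0.05).
#' @param seed integer seed for the resampling; required so results are
#'   reproducible.
#' @return An object of class `bb_statmap`: `t`, `p_raw`, `significant`
#'   (channels x time matrices), `cluster_id`, `cluster_mass`,
#'   `null_quantile`, `null_max`, plus method metadata.
#' @export
cluster_bootstrap <- function(x, adjacency, alpha = 0.05, n_boot = 1000,
                              cluster_alpha = 0.05, seed) {
  if (missing(seed)) stop("`seed` is required for the bootstrap")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1L]; nch <- dim(x)[2L]; nt <- dim(x)[3L]
  if (n < 2L) stop("need at least 2 participants")
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == nch, ncol(adjacency) == nch)
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop("adjacency must be symmetric")
  flat <- matrix(x, n, nch * nt)           # cells ordered channel-fastest
  obs <- one_sample_t(flat)
  t_obs <- matrix(obs$t, nch, nt)
  p_obs <- matrix(obs$p, nch, nt)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1L)
  cand <- !is.na(t_obs) & abs(t_obs) > tcrit
  lab <- cluster_components(cand, adjacency)
  n_clust <- max(lab)
  mass <- if (n_clust) vapply(seq_len(n_clust), function(k)
    sum(abs(t_obs[lab == k])), 1) else numeric(0)

  # null: center each participant's map, resample participants
  centered <- sweep(flat, 2L, colMeans(flat))
  tc <- t(centered)                         # cells x participants
  tc2 <- tc^2
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  null_max <- numeric(n_boot)
  for (bidx in seq_len(n_boot)) {
    w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    mb <- as.numeric(tc %*% w) / n
    sb <- as.numeric(tc2 %*% w) / n - mb^2
    sb <- sb * n / (n - 1L)
    tb <- mb / sqrt(sb / n)
    cb <- matrix(is.finite(tb) & abs(tb) > tcrit, nch, nt)
    if (!any(cb)) next
    lb <- cluster_components(cb, adjacency)
    tb_m <- matrix(abs(tb), nch, nt)
    null_max[bidx] <- max(vapply(seq_len(max(lb)), function(k)
      sum(tb_m[lb == k]), 1))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  qthr <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  sig_clusters <- which(mass > qthr)
  significant <- matrix(FALSE, nch, nt)
  if (length(sig_clusters))
    significant[lab %in% sig_clusters] <- TRUE
  structure(list(t = t_obs, p_raw = p_obs, significant = significant,
                 cluster_id = lab, cluster_mass = mass,
                 null_quantile = qthr, null_max = null_max,
                 method = "cluster_bootstrap", alpha = alpha,
                 cluster_alpha = cluster_alpha, n_boot = n_boot,
                 seed = seed),
            class = "bb_statmap")
}

#' One-sample group inference for a scalar channel map
#'
#' Pools a participants x channels matrix, runs per-channel one-sample
#' t-tests against zero and applies Bonferroni correction.
#'
#' @param x participants x channels numeric matrix.
#' @param alpha family-wise alpha (default 0.05).
#' @return A `bb_statmap` with `method = "bonferroni"`.
#' @export
group_t_map <- function(x, alpha = 0.05) {
  res <- one_sample_t(x)
  structure(list(t = res$t, p_raw = res$p,
                 significant = bonferroni_mask(res$p, alpha),
                 mean = res$mean, method = "bonferroni", alpha = alpha),
            class = "bb_statmap")
}

#' @export
print.bb_statmap <- function(x, ...) {
  cat(sprintf("<bb_statmap> %s, alpha = %g: %d of %d cells significant\n",
              x$method, x$alpha, sum(x$significant),
              length(x$significant)))
  invisible(x)
}

#' Export a stat map as a delimited table
#' @param map a `bb_statmap`.
#' @param path output path.
#' @param labels optional channel labels.
#' @export
write_statmap <- function(map, path, labels = NULL) {
  tmat <- as.matrix(map$t)
  nch <- nrow(tmat)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch))
  df <- data.frame(
    channel = rep(labels, ncol(tmat)),
    time_idx = rep(seq_len(ncol(tmat)), each = nch),
    t = as.vector(tmat),
    p_raw = as.vector(as.matrix(map$p_raw)),
    significant = as.vector(as.matrix(map$significant)))
  if (!is.null(map$cluster_id)) df$cluster_id <- as.vector(map$cluster_id)
  utils::write.table(df, path, sep = "\t", row.names = FALSE)
  invisible(path)
}
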