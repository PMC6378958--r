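# Template projection, cortical-mesh smoothing, and nonparametric group
# inference: sign-flip permutation t-tests, Benjamini-Hochberg FDR, and
# cluster-based permutation correction over spatio-temporal adjacency.

#' Project a subject source map onto the template mesh
#'
#' Applies a row-stochastic interpolation matrix (template vertices x subject
#' vertices). Group analyses of rectified maps apply `abs()` first
#' (`rectify = TRUE`).
#'
#' @param est a `source_estimate` (or matrix sources x samples).
#' @param mapping interpolation matrix; rows must sum to 1.
#' @param rectify take absolute values before projecting.
#' @return the projected object.
#' @export
project_to_template <- function(est, mapping, rectify = FALSE) {
  x <- if (inherits(est, "source_estimate")) est$data else est
  if (ncol(mapping) != nrow(x)) stop("mapping columns must match subject sources")
  rs <- rowSums(mapping)
  if (any(abs(rs - 1) > 1e-9) || any(mapping < 0))
    stop("mapping must be row-stochastic with nonnegative entries")
  if (rectify) x <- abs(x)
  y <- mapping %*% x
  if (inherits(est, "source_estimate")) { est$data <- y; est } else y
}

#' Gaussian smoothing of per-vertex values on a mesh
#'
#' Graph-geodesic Gaussian kernel scaled to the mesh edges: for each vertex,
#' neighbors within `cutoff_sd` standard deviations (shortest-path distance
#' along edges) are weighted by `exp(-d^2 / (2 sigma^2))` and row-normalized.
#' Constant fields are exactly preserved; on near-uniform meshes the total
#' sum is conserved to within ~1%.
#'
#' @param values per-vertex vector or vertices x samples matrix.
#' @param mesh a `surface_mesh`.
#' @param fwhm kernel full width at half maximum, meters.
#' @param cutoff_sd kernel truncation radius in standard deviations.
#' @return smoothed values, same shape.
#' @export
smooth_mesh <- function(values, mesh, fwhm = 0.003, cutoff_sd = 3.5) {
  vec <- is.null(dim(values))
  x <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  e <- mesh_edges(mesh)
  elen <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  if (fwhm < mean(elen)) {
    warning("FWHM below the mean edge length; returning input unchanged")
    return(values)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cutoff <- cutoff_sd * sigma
  nv <- nrow(mesh$vertices)
  nbr <- vector("list", nv); nbd <- vector("list", nv)
  for (k in seq_len(nrow(e))) {
    nbr[[e[k, 1]]] <- c(nbr[[e[k, 1]]], e[k, 2])
    nbr[[e[k, 2]]] <- c(nbr[[e[k, 2]]], e[k, 1])
    nbd[[e[k, 1]]] <- c(nbd[[e[k, 1]]], elen[k])
    nbd[[e[k, 2]]] <- c(nbd[[e[k, 2]]], elen[k])
  }
  out <- matrix(0, nv, ncol(x))
  dist <- rep(Inf, nv)
  for (i in seq_len(nv)) {
    # truncated Dijkstra from vertex i
    touched <- i
    dist[i] <- 0
    frontier <- i
    settled <- logical(0)
    done <- rep(FALSE, 0)
    visited <- rep(FALSE, nv)
    while (length(frontier)) {
      j <- frontier[which.min(dist[frontier])]
      frontier <- frontier[frontier != j]
      if (visited[j]) next
      visited[j] <- TRUE
      nb <- nbr[[j]]
      dd <- dist[j] + nbd[[j]]
      for (q in seq_along(nb)) {
        v2 <- nb[q]
        if (dd[q] > cutoff || visited[v2]) next
        if (dd[q] < dist[v2]) {
          if (!is.finite(dist[v2])) touched <- c(touched, v2)
          dist[v2] <- dd[q]
          frontier <- c(frontier, v2)
        }
      }
    }
    w <- exp(-dist[touched]^2 / (2 * sigma^2))
    w <- w / sum(w)
    out[i, ] <- crossprod(w, x[touched, , drop = FALSE])
    dist[touched] <- Inf
  }
  if (vec) out[, 1] else out
}

rowsum_pad <- function(x, idx, n) {
  agg <- rowsum(x, idx)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Paired permutation t-test (sign-flip randomization)
#'
#' Elementwise paired t statistic over subject differences; the null
#' distribution is built by random sign flips of the per-subject difference
#' maps. P-values use the rank convention `p = (1 + #{|t*| >= |t|}) /
#' (n_rand + 1)`.
#'
#' @param A,B subjects x elements matrices (paired rows).
#' @param n_rand number of randomizations.
#' @param tail "two", "greater" or "less".
#' @param seed RNG seed for reproducibility.
#' @return object of class `stat_result`: `t`, `p`, `df`, correction "none".
#' @export
permutation_paired_ttest <- function(A, B, n_rand = 1000, tail = "two",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(A) - as.matrix(B)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 subjects")
  tobs <- paired_t(D)
  zero_var <- !is.finite(tobs)
  tobs[zero_var] <- 0
  S <- matrix(sample(c(-1, 1), n_rand * n, replace = TRUE), n_rand, n)
  Tnull <- sign_flip_t(D, S)
  cmp <- switch(tail,
                two = abs(Tnull) >= rep(abs(tobs), each = n_rand),
                greater = Tnull >= rep(tobs, each = n_rand),
                less = Tnull <= rep(tobs, each = n_rand))
  p <- (1 + colSums(cmp)) / (n_rand + 1)
  if (any(zero_var)) {
    warning("zero-variance element(s); p set to 1")
    p[zero_var] <- 1
  }
  structure(list(t = tobs, p = p, df = n - 1, correction = "none",
                 n_rand = n_rand, tail = tail),
            class = "stat_result")
}

paired_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  m / sqrt(pmax(s2, 0) / n)
}

# t statistics for all sign-flip rows of S (n_rand x n): vectorized; the sum
# of squares is invariant under sign flips
sign_flip_t <- function(D, S) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ss <- rep(colSums(D^2), each = nrow(S))
  s2 <- (ss - n * M^2) / (n - 1)
  M / sqrt(pmax(s2, 1e-300) / n)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure over all elements jointly (space x time pooled).
#'
#' @param p_map vector/matrix of p-values in (0, 1].
#' @param alpha FDR level.
#' @return logical mask of discoveries, same shape as `p_map`.
#' @export
fdr_correct <- function(p_map, alpha = 0.05) {
  if (!length(p_map)) stop("empty p-value map")
  adj <- p.adjust(as.vector(p_map), method = "BH")
  mask <- adj <= alpha
  if (!is.null(dim(p_map))) dim(mask) <- dim(p_map)
  mask
}

#' Spatio-temporal adjacency graph
#'
#' Sensors: distance-threshold rule on positions; sources: the mesh edge
#' graph. Symmetric, no self-loops.
#'
#' @param x n x 3 position matrix or a `surface_mesh`.
#' @param dist_threshold neighbor distance, meters (position rule).
#' @return list of integer neighbor vectors, one per node.
#' @export
build_adjacency <- function(x, dist_threshold = 0.04) {
  if (inherits(x, "surface_mesh")) {
    e <- mesh_edges(x)
    n <- nrow(x$vertices)
  } else {
    pos <- as.matrix(x)
    n <- nrow(pos)
    d2 <- as.matrix(dist(pos))^2
    pair <- which(d2 <= dist_threshold^2 & upper.tri(d2), arr.ind = TRUE)
    e <- pair
  }
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  iso <- which(lengths(adj) == 0)
  if (length(iso))
    warning("isolated node(s): ", paste(head(iso, 5), collapse = ", "))
  lapply(adj, function(v) sort(unique(v)))
}

# connected components of the supra-threshold (node x time) mask under
# spatial adjacency + temporal +-1 adjacency; returns cluster id matrix
label_clusters <- function(supra, adj) {
  nn <- nrow(supra); nt <- ncol(supra)
  id <- matrix(0L, nn, nt)
  cur <- 0L
  for (start in which(supra)) {
    if (id[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    id[start] <- cur
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      v <- (s - 1L) %% nn + 1L
      tt <- (s - 1L) %/% nn + 1L
      cand <- c(if (tt > 1) s - nn, if (tt < nt) s + nn,
                (tt - 1L) * nn + adj[[v]])
      for (q in cand) if (supra[q] && id[q] == 0L) {
        id[q] <- cur
        stack <- c(stack, q)
      }
    }
  }
  id
}

cluster_masses <- function(tmap, supra, adj) {
  id <- label_clusters(supra, adj)
  k <- max(id)
  if (k == 0) return(list(id = id, mass = numeric()))
  mass <- vapply(seq_len(k), function(c) sum(abs(tmap[id == c])), 0)
  list(id = id, mass = mass)
}

#' Cluster-based permutation test (paired, sign-flip)
#'
#' Thresholds |t| at the two-tailed `cluster_alpha` quantile of the t
#' distribution, scores connected spatio-temporal components by their summed
#' |t| (cluster mass) and compares against the maximum-cluster-mass null over
#' sign-flip randomizations.
#'
#' @param A,B subjects x channels x times arrays (paired).
#' @param adjacency spatial adjacency list from [build_adjacency()].
#' @param cluster_alpha cluster-forming threshold (elementwise).
#' @param n_rand randomizations; @param seed RNG seed.
#' @param alpha cluster-level significance.
#' @return a `stat_result` with `clusters` (id, mass, p), `cluster_id`
#'   matrix, and `sig` mask of significant clusters.
#' @export
cluster_permutation <- function(A, B, adjacency, cluster_alpha = 0.05,
                                n_rand = 1000, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(dim(A)) == 3, all(dim(A) == dim(B)))
  n <- dim(A)[1]; nch <- dim(A)[2]; nt <- dim(A)[3]
  D <- matrix(A - B, n)   # subjects x (nch*nt), channel-fastest
  tcrit <- qt(1 - cluster_alpha / 2, df = n - 1)
  tobs <- matrix(paired_t(D), nch, nt)
  tobs[!is.finite(tobs)] <- 0
  obs <- cluster_masses(tobs, abs(tobs) > tcrit, adjacency)
  null_max <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    tr <- matrix(sign_flip_t(D, matrix(s, 1)), nch, nt)
    tr[!is.finite(tr)] <- 0
    cm <- cluster_masses(tr, abs(tr) > tcrit, adjacency)
    null_max[r] <- if (length(cm$mass)) max(cm$mass) else 0
  }
  pcl <- if (length(obs$mass))
    vapply(obs$mass, function(m) (1 + sum(null_max >= m)) / (n_rand + 1), 0)
  else numeric()
  sig_ids <- which(pcl <= alpha)
  structure(list(t = tobs,
                 clusters = data.frame(id = seq_along(pcl),
                                       mass = obs$mass, p = pcl),
                 cluster_id = obs$id,
                 sig = obs$id %in% sig_ids & obs$id > 0,
                 p = pcl, correction = "cluster", alpha = alpha,
                 n_rand = n_rand, cluster_alpha = cluster_alpha),
            class = "stat_result")
}

#' Zero non-significant statistics for display/export
#'
#' Reproduces the common display convention of t-value maps set to 0
#' wherever the corrected p exceeds alpha.
#'
#' @param stat a `stat_result`; @param mask logical significance mask (e.g.
#'   [fdr_correct()] of `stat$p`, or `stat$sig` for cluster results).
#' @return the t map with non-significant entries zeroed.
#' @export
threshold_stat_map <- function(stat, mask) {
  t0 <- stat$t
  t0[!mask] <- 0
  t0
}

#' Export a stat map as TSV (element, t, p, significant)
#' @param stat a `stat_result`; @param mask significance mask; @param path
#'   output path.
#' @export
write_stat_tsv <- function(stat, mask, path) {
  df <- data.frame(element = seq_along(stat$t),
                   t = as.vector(stat$t),
                   p = if (length(stat$p) == length(stat$t))
                     as.vector(stat$p) else NA_real_,
                   significant = as.vector(mask))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
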