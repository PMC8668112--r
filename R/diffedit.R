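## Differential editing across stages and trajectory clustering.

#' Build a sites x samples editing-ratio matrix
#'
#' @param sites editing-site table from [editing_sites()] (wide per-sample
#'   `ratio_<sample>` columns), or a long per-site/sample table with
#'   columns `chrom`, `pos`, `sample_id`, `ratio` (e.g. from
#'   [site_sample_counts()]).
#' @param design design table (`sample_id`, `stage`); every design sample
#'   must be present in the sites input.
#' @return Numeric matrix (rows = `chrom:pos` site ids, columns = design
#'   sample ids) with NA wherever the coverage mask failed upstream.
#' @export
build_matrix <- function(sites, design) {
  design <- as_design(design)
  sites <- data.table::as.data.table(sites)
  if ("sample_id" %in% names(sites) && "ratio" %in% names(sites)) {
    long <- sites[, .(site_id = site_key(chrom, pos), sample_id, ratio)]
  } else {
    rcols <- paste0("ratio_", design$sample_id)
    missing <- setdiff(rcols, names(sites))
    if (length(missing)) {
      stop(sprintf("design sample(s) absent from sites table: %s",
                   paste(sub("^ratio_", "", missing), collapse = ", ")))
    }
    long <- data.table::melt(
      sites[, c("chrom", "pos", rcols), with = FALSE],
      id.vars = c("chrom", "pos"), variable.name = "sample_id",
      value.name = "ratio", variable.factor = FALSE)
    long[, sample_id := sub("^ratio_", "", sample_id)]
    long[, site_id := site_key(chrom, pos)]
  }
  if (!all(design$sample_id %in% long$sample_id) && nrow(long)) {
    stop(sprintf("design sample(s) absent from sites table: %s",
                 paste(setdiff(design$sample_id, long$sample_id),
                       collapse = ", ")))
  }
  ids <- unique(long$site_id)
  m <- matrix(NA_real_, length(ids), nrow(design),
              dimnames = list(ids, design$sample_id))
  if (nrow(long)) {
    long <- long[sample_id %in% design$sample_id]
    m[cbind(match(long$site_id, ids),
            match(long$sample_id, design$sample_id))] <- long$ratio
  }
  m
}

#' One-way ANOVA for differential editing across stages
#'
#' Per site, a fixed-effects one-way ANOVA of the editing ratio on stage is
#' computed over non-NA cells; values in stages with fewer than two
#' observations are dropped first and sites with fewer than two usable
#' stages are reported untested (NA statistics). P-values are adjusted
#' across tested sites with Benjamini-Hochberg; `is_differential` means
#' q < `fdr`.
#'
#' @param mat matrix from [build_matrix()].
#' @param design design table matching the matrix columns.
#' @param fdr q-value cutoff (default 0.05).
#' @return data.table with `site_id`, `F`, `p`, `q`, `is_differential` and
#'   per-stage mean ratios (`mean_<stage>` columns).
#' @export
anova_stages <- function(mat, design, fdr = 0.05) {
  design <- as_design(design)
  stopifnot(identical(colnames(mat), design$sample_id))
  g_all <- as.character(design$stage)
  stages <- levels(design$stage)
  n <- nrow(mat)
  Fv <- pv <- rep(NA_real_, n)
  means <- matrix(NA_real_, n, length(stages),
                  dimnames = list(NULL, paste0("mean_", stages)))
  for (i in seq_len(n)) {
    y <- mat[i, ]
    ok <- !is.na(y)
    sm <- tapply(y[ok], factor(g_all[ok], levels = stages), mean)
    means[i, ] <- as.numeric(sm)
    cnt <- table(factor(g_all[ok], levels = stages))
    usable <- names(cnt)[cnt >= 2L]
    keep <- ok & g_all %in% usable
    if (length(usable) < 2L) next
    yy <- y[keep]
    gg <- factor(g_all[keep])
    if (sd(yy) == 0) { Fv[i] <- 0; pv[i] <- 1; next }
    fit <- stats::anova(stats::lm(yy ~ gg))
    Fv[i] <- fit[["F value"]][1]
    pv[i] <- fit[["Pr(>F)"]][1]
    # zero between-group variance underflows to F ~ 0: report p = 1
    if (!is.finite(pv[i])) pv[i] <- NA_real_
  }
  qv <- rep(NA_real_, n)
  tested <- !is.na(pv)
  qv[tested] <- stats::p.adjust(pv[tested], method = "BH")
  out <- data.table::data.table(site_id = rownames(mat), F = Fv, p = pv,
                                q = qv,
                                is_differential = !is.na(qv) & qv < fdr)
  cbind(out, data.table::as.data.table(means))
}

## Lance-Williams agglomerative clustering -----------------------------------

lw_coefficients <- function(method, ni, nj, nk) {
  switch(method,
    average = list(ai = ni / (ni + nj), aj = nj / (ni + nj), b = 0, g = 0),
    single = list(ai = 0.5, aj = 0.5, b = 0, g = -0.5),
    complete = list(ai = 0.5, aj = 0.5, b = 0, g = 0.5),
    ward = list(ai = (ni + nk) / (ni + nj + nk),
                aj = (nj + nk) / (ni + nj + nk),
                b = -nk / (ni + nj + nk), g = 0),
    stop("unknown linkage method: ", method))
}

#' Agglomerative hierarchical clustering via the Lance-Williams recurrence
#'
#' Direct implementation of the Lance-Williams distance update
#' d(ij,k) = ai*d(i,k) + aj*d(j,k) + b*d(i,j) + g*|d(i,k) - d(j,k)|
#' for single, complete and average (UPGMA) linkage; `ward` applies the
#' recurrence to squared distances and reports square-root merge heights
#' (the Ward.D2 convention).
#'
#' @param d a `dist` object.
#' @param method one of `"average"`, `"single"`, `"complete"`, `"ward"`.
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
lance_williams_hclust <- function(d, method = c("average", "single",
                                                "complete", "ward")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least two observations to cluster")
  if (method == "ward") dm <- dm^2
  diag(dm) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)                       # hclust singleton convention
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    sub <- which(alive)
    block <- dm[sub, sub, drop = FALSE]
    w <- which.min(block)
    i <- sub[(w - 1L) %% length(sub) + 1L]
    j <- sub[(w - 1L) %/% length(sub) + 1L]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    hij <- dm[i, j]
    height[step] <- if (method == "ward") sqrt(hij) else hij
    merge[step, ] <- sort(c(id[i], id[j]))
    ks <- setdiff(sub, c(i, j))
    if (length(ks)) {
      co <- lw_coefficients(method, size[i], size[j], size[ks])
      dm[i, ks] <- dm[ks, i] <-
        co$ai * dm[i, ks] + co$aj * dm[j, ks] + co$b * hij +
        co$g * abs(dm[i, ks] - dm[j, ks])
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    alive[j] <- FALSE
    dm[j, ] <- dm[, j] <- Inf
  }
  order <- local({      # leaf order by recursive traversal of the tree
    walk <- function(node) {
      if (node < 0) return(-node)
      c(walk(merge[node, 1]), walk(merge[node, 2]))
    }
    walk(n - 1L)
  })
  structure(list(merge = merge, height = height, order = order,
                 labels = attr(d, "Labels"), method = method,
                 call = match.call(),
                 dist.method = attr(d, "method") %||% "euclidean"),
            class = "hclust")
}

#' Cluster differential-editing trajectories
#'
#' Computes per-site stage-mean curves (sites lacking coverage in any stage
#' are excluded and reported), z-scores each curve so shape rather than
#' amplitude drives grouping, clusters with the Lance-Williams recurrence
#' on Euclidean distances, and cuts the tree at `k`. Cluster labels are
#' renumbered in decreasing size order.
#'
#' @param mat editing matrix from [build_matrix()], typically restricted to
#'   differential sites.
#' @param design design table matching the matrix columns.
#' @param k number of clusters (default 3).
#' @param linkage linkage method (default `"average"`).
#' @return List of class `ed_clusters`: `assignments` (site_id, cluster),
#'   `curves` (per cluster and stage: mean, sd, n), `excluded` site ids,
#'   and the `hclust` tree.
#' @export
cluster_trajectories <- function(mat, design, k = 3L,
                                 linkage = "average") {
  design <- as_design(design)
  stopifnot(identical(colnames(mat), design$sample_id))
  stages <- levels(design$stage)
  g <- as.character(design$stage)
  sm <- t(apply(mat, 1L, function(y) {
    tapply(y, factor(g, levels = stages), mean, na.rm = TRUE)
  }))
  ok <- rowSums(is.na(sm) | is.nan(sm)) == 0
  excluded <- rownames(mat)[!ok]
  sm <- sm[ok, , drop = FALSE]
  if (nrow(sm) < k) {
    stop(sprintf("fewer usable sites (%d) than clusters (%d)",
                 nrow(sm), k))
  }
  z <- t(apply(sm, 1L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  if (nrow(z) == k) {
    cl <- setNames(seq_len(k), rownames(z))
  } else {
    hc <- lance_williams_hclust(dist(z), method = linkage)
    cl <- stats::cutree(hc, k = k)
  }
  # relabel clusters by decreasing size (ties broken by first appearance)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  cl <- relabel[as.character(cl)]
  assignments <- data.table::data.table(site_id = rownames(z),
                                        cluster = as.integer(cl))
  curves <- data.table::rbindlist(lapply(seq_len(k), function(ci) {
    rows <- sm[assignments$cluster == ci, , drop = FALSE]
    data.table::data.table(cluster = ci, stage = stages,
                           mean = colMeans(rows),
                           sd = apply(rows, 2, sd),
                           n = nrow(rows))
  }))
  res <- list(assignments = assignments, curves = curves,
              excluded = excluded,
              tree = if (exists("hc", inherits = FALSE)) hc else NULL)
  class(res) <- "ed_clusters"
  res
}

#' @export
print.ed_clusters <- function(x, ...) {
  tab <- table(x$assignments$cluster)
  cat(sprintf("<ed_clusters> %d sites in %d clusters (%s)%s\n",
              nrow(x$assignments), length(tab),
              paste(sprintf("c%s: %d", names(tab), tab), collapse = ", "),
              if (length(x$excluded))
                sprintf("; %d excluded", length(x$excluded)) else ""))
  invisible(x)
}
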