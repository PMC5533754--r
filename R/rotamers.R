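## Rotamer-state analysis on the (chi1, chi2) torus.
##
## Density-based clustering with a wrap-aware metric
##   d = sqrt(dc(chi1)^2 + dc(chi2)^2),  dc = circular difference,
## so clusters straddling +/-180 are never split. Centroids are medoids
## (the member minimizing summed circular distance to the others), hence
## always a real observed conformation.

## angles: n x 2 matrix. Pairwise toroidal distance between row sets.
.torus_dist <- function(a, b) {
  d1 <- abs(wrap180(outer(a[, 1], b[, 1], "-")))
  d2 <- abs(wrap180(outer(a[, 2], b[, 2], "-")))
  sqrt(d1^2 + d2^2)
}

## Grid-binned DBSCAN region queries: candidate neighbours come from the
## 3x3 block of eps-sized bins around a point, with wrap at the torus edge.
.torus_neighbours <- function(ang, eps) {
  n <- nrow(ang)
  nb <- max(3L, floor(360 / eps))
  w <- 360 / nb
  bx <- (floor((ang[, 1] + 180) / w)) %% nb
  by <- (floor((ang[, 2] + 180) / w)) %% nb
  cell <- bx * nb + by
  by_cell <- split(seq_len(n), cell)
  neigh <- vector("list", n)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  for (i in seq_len(n)) {
    cand_cells <- ((bx[i] + off$dx) %% nb) * nb + ((by[i] + off$dy) %% nb)
    cand <- unlist(by_cell[as.character(unique(cand_cells))],
                   use.names = FALSE)
    d <- sqrt(wrap180(ang[cand, 1] - ang[i, 1])^2 +
                wrap180(ang[cand, 2] - ang[i, 2])^2)
    neigh[[i]] <- cand[d <= eps]
  }
  neigh
}

## Classic DBSCAN on precomputed neighbour lists; returns integer labels
## (0 = noise), clusters in discovery order.
.dbscan_labels <- function(neigh, min_members) {
  n <- length(neigh)
  labels <- rep(0L, n)
  assigned <- rep(FALSE, n)
  is_core <- lengths(neigh) >= min_members
  cl <- 0L
  for (i in seq_len(n)) {
    if (assigned[i] || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl; assigned[i] <- TRUE
    queue <- neigh[[i]]
    inq <- rep(FALSE, n); inq[queue] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (!assigned[j]) {
        labels[j] <- cl; assigned[j] <- TRUE
        if (is_core[j]) {
          new <- neigh[[j]][!inq[neigh[[j]]]]
          inq[new] <- TRUE
          queue <- c(queue, new)
        }
      }
    }
  }
  labels
}

## Medoid under the toroidal metric; deterministic candidate thinning keeps
## the cost bounded for very large clusters.
.torus_medoid <- function(ang, max_candidates = 3000L) {
  m <- nrow(ang)
  if (m == 1L) return(1L)
  cand <- if (m > max_candidates) {
    unique(round(seq(1L, m, length.out = max_candidates)))
  } else seq_len(m)
  d <- .torus_dist(ang[cand, , drop = FALSE], ang)
  cand[which.min(rowSums(d))]
}

#' Cluster side-chain rotamers on the (chi1, chi2) torus
#'
#' Density-based clustering with the toroidal metric; points in no dense
#' region are labelled noise (cluster 0). Clusters are numbered by
#' descending occupancy, ties broken by ascending centroid chi1.
#'
#' @param chi1,chi2 numeric vectors (degrees), or `DihedralSeries` holding
#'   a single residue column; frames pooled across trajectories are fine.
#' @param eps neighbourhood radius (degrees) on the torus, default 30.
#' @param min_members minimum neighbourhood size (the point itself
#'   included) for a core point, default 10.
#' @return object of class `RotamerClusters`: data.frame `clusters`
#'   (id, n_members, occupancy, centroid_chi1, centroid_chi2,
#'   representative_frame), `labels` per frame (0 = noise),
#'   `noise_fraction`, and the call parameters.
#' @export
cluster_rotamers <- function(chi1, chi2, eps = 30, min_members = 10L) {
  if (eps <= 0) stop("eps must be positive")
  if (min_members < 1L) stop("min_members must be >= 1")
  chi1 <- .chi_vector(chi1); chi2 <- .chi_vector(chi2)
  if (length(chi1) != length(chi2)) stop("chi1/chi2 length mismatch")
  ok <- is.finite(chi1) & is.finite(chi2)
  ang <- cbind(wrap180(chi1[ok]), wrap180(chi2[ok]))
  labels_ok <- .dbscan_labels(.torus_neighbours(ang, eps), min_members)
  labels <- rep(NA_integer_, length(chi1))
  labels[ok] <- labels_ok
  n_tot <- sum(ok)
  ids <- sort(unique(labels_ok[labels_ok > 0L]))
  rows <- lapply(ids, function(id) {
    jj <- which(labels_ok == id)
    med <- jj[.torus_medoid(ang[jj, , drop = FALSE])]
    data.frame(id = id, n_members = length(jj),
               occupancy = length(jj) / n_tot,
               centroid_chi1 = ang[med, 1], centroid_chi2 = ang[med, 2],
               representative_frame = which(ok)[med])
  })
  cl <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(id = integer(), n_members = integer(), occupancy = numeric(),
               centroid_chi1 = numeric(), centroid_chi2 = numeric(),
               representative_frame = integer())
  ## renumber by occupancy desc, ties by centroid chi1 asc
  if (nrow(cl) > 0L) {
    ord <- order(-cl$occupancy, cl$centroid_chi1)
    remap <- integer(max(cl$id))
    remap[cl$id[ord]] <- seq_along(ord)
    cl <- cl[ord, , drop = FALSE]
    cl$id <- seq_len(nrow(cl))
    rownames(cl) <- NULL
    pos <- labels > 0L & !is.na(labels)
    labels[pos] <- remap[labels[pos]]
  }
  structure(list(clusters = cl, labels = labels,
                 noise_fraction = if (n_tot > 0) sum(labels_ok == 0L) / n_tot
                 else NA_real_,
                 eps = eps, min_members = min_members),
            class = "RotamerClusters")
}

.chi_vector <- function(x) {
  if (inherits(x, "DihedralSeries")) {
    if (ncol(x$values) != 1L) {
      stop("pass a single-residue DihedralSeries or a numeric vector")
    }
    as.numeric(x$values[, 1])
  } else as.numeric(x)
}

#' @export
print.RotamerClusters <- function(x, ...) {
  cat("RotamerClusters:", nrow(x$clusters), "cluster(s), noise fraction",
      round(x$noise_fraction, 4), "\n")
  if (nrow(x$clusters) > 0L) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Label frames against existing rotamer clusters
#'
#' Each frame is assigned the cluster of the nearest centroid within
#' `eps` (toroidal distance), otherwise noise (0).
#'
#' @param chi1,chi2 numeric vectors (degrees).
#' @param clusters a `RotamerClusters` (or its `clusters` data.frame).
#' @param eps assignment radius (degrees); defaults to the radius stored
#'   in `clusters`.
#' @return integer labels (0 = noise, NA for missing angles).
#' @export
assign_states <- function(chi1, chi2, clusters, eps = NULL) {
  cl <- if (inherits(clusters, "RotamerClusters")) clusters$clusters else
    clusters
  if (nrow(cl) == 0L) stop("no clusters to assign against")
  if (is.null(eps)) {
    eps <- if (inherits(clusters, "RotamerClusters")) clusters$eps else 30
  }
  chi1 <- .chi_vector(chi1); chi2 <- .chi_vector(chi2)
  labels <- rep(NA_integer_, length(chi1))
  ok <- is.finite(chi1) & is.finite(chi2)
  d <- .torus_dist(cbind(wrap180(chi1[ok]), wrap180(chi2[ok])),
                   cbind(cl$centroid_chi1, cl$centroid_chi2))
  nearest <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(nrow(d)), nearest)]
  labels[ok] <- ifelse(dmin <= eps, cl$id[nearest], 0L)
  labels
}

#' Count transitions between rotamer states
#'
#' Counts consecutive-frame label changes i -> j within one contiguous
#' trajectory (pass a list of label vectors for several trajectories;
#' changes are never counted across a boundary). Self-transitions are not
#' counted; changes into/out of noise are tallied separately.
#'
#' @param labels integer label vector (0 = noise), or a list of them.
#' @return object of class `TransitionMatrix`: `counts` (square matrix over
#'   cluster ids), `noise_in`, `noise_out`, `n_changes`.
#' @export
transition_counts <- function(labels) {
  segs <- if (is.list(labels)) labels else list(labels)
  ids <- sort(unique(unlist(lapply(segs, function(l) l[!is.na(l) & l > 0L]))))
  k <- length(ids)
  counts <- matrix(0L, k, k, dimnames = list(ids, ids))
  noise_in <- 0L; noise_out <- 0L
  for (l in segs) {
    l <- l[!is.na(l)]
    if (length(l) < 2L) next
    a <- l[-length(l)]; b <- l[-1L]
    chg <- which(a != b)
    for (i in chg) {
      if (a[i] == 0L) noise_out <- noise_out + 1L
      else if (b[i] == 0L) noise_in <- noise_in + 1L
      else counts[as.character(a[i]), as.character(b[i])] <-
          counts[as.character(a[i]), as.character(b[i])] + 1L
    }
  }
  structure(list(counts = counts, noise_in = noise_in, noise_out = noise_out,
                 n_changes = sum(counts) + noise_in + noise_out),
            class = "TransitionMatrix")
}

#' @export
print.TransitionMatrix <- function(x, ...) {
  cat("TransitionMatrix:", x$n_changes, "label changes (",
      x$noise_in, "into noise,", x$noise_out, "out of noise )\n")
  print(x$counts)
  invisible(x)
}

#' Write rotamer-analysis tables
#'
#' @param clusters a `RotamerClusters`.
#' @param transitions optional `TransitionMatrix`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_rotamer_tables <- function(clusters, transitions = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "rotamer_clusters.tsv")
  utils::write.table(clusters$clusters, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, "rotamer_labels.tsv")
  utils::write.table(data.frame(frame = seq_along(clusters$labels),
                                label = clusters$labels),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(transitions)) {
    p3 <- file.path(dir, "rotamer_transitions.tsv")
    utils::write.table(transitions$counts, p3, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
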