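pool_coord_list <- function(pool, atom_subset) {
  if (atom_subset == "ca") {
    keys <- NULL
    mats <- lapply(pool$structure, ca_coords)
    key_list <- lapply(pool$structure, function(s) {
      ca <- s[s$atom == "CA" & s$element != "H", ]
      paste(ca$res_idx[!duplicated(ca$res_idx)], "CA")
    })
  } else {
    mats <- lapply(pool$structure, function(s) {
      h <- s[s$element != "H", ]
      as.matrix(h[, c("x", "y", "z")])
    })
    key_list <- lapply(pool$structure, function(s) {
      h <- s[s$element != "H", ]
      paste(h$res_idx, h$atom)
    })
  }
  ref <- key_list[[1]]
  same <- vapply(key_list, function(k) identical(k, ref), logical(1))
  if (!all(same)) {
    abort(paste0("inconsistent atom sets across pool members: ",
                 paste(pool$id[!same], collapse = ", ")))
  }
  mats
}

#' RMSD-radius clustering of a decoy pool
#'
#' Deterministic leader-then-Lloyd clustering under superposed RMSD,
#' emulating an MMTSB kclust invocation with centroid-distance
#' assignment: members are visited in lexicographic id order and assigned
#' to the first centroid within `radius`, else seed a new cluster; then
#' centroids are recomputed as the coordinate mean of their members after
#' least-squares fitting each member onto the current centroid, members
#' are reassigned to the nearest centroid (seeding a fresh cluster when
#' none is within `radius`), and the cycle repeats until membership is
#' stable or `max_iter` is reached. Centroids are mathematical constructs,
#' not pool members.
#'
#' @param pool A pool tibble.
#' @param radius Cluster radius in Angstrom (default 1.0).
#' @param atom_subset `"heavy"` (default, all non-hydrogen atoms) or
#'   `"ca"`.
#' @param max_iter Maximum refinement iterations (default 10).
#' @return An object of class `cluster_set`: list with `assignments`
#'   (tibble `id`, `cluster`, `rmsd_to_centroid`), `centroids` (list of
#'   M x 3 matrices), `radius`, `atom_subset`, `iterations_run`.
#' @export
kclust <- function(pool, radius = 1.0, atom_subset = c("heavy", "ca"),
                   max_iter = 10L) {
  atom_subset <- match.arg(atom_subset)
  if (nrow(pool) == 0) abort("empty pool")
  ord <- order(pool$id, method = "radix")
  pool <- pool[ord, ]
  mats <- pool_coord_list(pool, atom_subset)
  n <- length(mats)

  # leader pass
  centroids <- list(mats[[1]])
  assign <- integer(n)
  assign[1] <- 1L
  for (i in seq_len(n)[-1]) {
    d <- rmsd_cross_cpp(mats[i], centroids)[1, ]
    j <- which(d <= radius)
    if (length(j) > 0) {
      assign[i] <- j[1]
    } else {
      centroids[[length(centroids) + 1]] <- mats[[i]]
      assign[i] <- length(centroids)
    }
  }

  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    # centroid update: mean of members fitted onto the current centroid
    centroids <- lapply(seq_along(centroids), function(k) {
      members <- mats[assign == k]
      if (length(members) == 0) return(NULL)
      fit_mean_cpp(members, centroids[[k]])
    })
    keep <- !vapply(centroids, is.null, logical(1))
    centroids <- centroids[keep]
    # reassign each member (in order) to the nearest centroid, seeding a
    # fresh cluster when none is within the radius; newly seeded clusters
    # are visible to later members of the same sweep
    n_old <- length(centroids)
    d <- rmsd_cross_cpp(mats, centroids)
    new_assign <- max.col(-d, ties.method = "first")
    mind <- d[cbind(seq_len(n), new_assign)]
    for (i in seq_len(n)) {
      if (length(centroids) > n_old) {
        dnew <- rmsd_cross_cpp(mats[i],
                               centroids[(n_old + 1):length(centroids)])[1, ]
        if (min(dnew) < mind[i]) {
          mind[i] <- min(dnew)
          new_assign[i] <- n_old + which.min(dnew)
        }
      }
      if (mind[i] > radius) {
        centroids[[length(centroids) + 1]] <- mats[[i]]
        new_assign[i] <- length(centroids)
      }
    }
    changed <- !identical(relabel_by_first(new_assign),
                          relabel_by_first(assign))
    assign <- new_assign
    if (!changed) break
  }

  # drop empty clusters, relabel in first-appearance order
  centroids <- centroids[unique(assign)]
  assign <- relabel_by_first(assign)
  # final member-to-centroid distances
  rmsd_to_centroid <- numeric(n)
  for (k in sort(unique(assign))) {
    idx <- which(assign == k)
    rmsd_to_centroid[idx] <- rmsd_cross_cpp(mats[idx],
                                            centroids[k])[, 1]
  }

  out <- list(
    assignments = tibble(id = pool$id, cluster = assign,
                         rmsd_to_centroid = rmsd_to_centroid),
    centroids = centroids,
    radius = radius,
    atom_subset = atom_subset,
    iterations_run = iterations
  )
  class(out) <- "cluster_set"
  out
}

relabel_by_first <- function(assign) {
  match(assign, unique(assign))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set: ", length(x$centroids), " clusters over ",
      nrow(x$assignments), " decoys (radius ", x$radius, " A, ",
      x$atom_subset, " atoms, ", x$iterations_run, " iteration(s))>\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.cluster_set <- function(x, ...) x$assignments

#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_clusters = length(x$centroids),
         n_members = nrow(x$assignments),
         radius = x$radius,
         atom_subset = x$atom_subset,
         iterations_run = x$iterations_run,
         max_rmsd_to_centroid = max(x$assignments$rmsd_to_centroid))
}

#' Pick one representative per cluster
#'
#' The member with the lowest RMSD to its cluster centroid (ties broken
#' by id order) is retained as the exemplar of that topology.
#'
#' @param cluster_set A [kclust()] result.
#' @param pool The pool that was clustered.
#' @return A sub-pool tibble containing one representative per cluster.
#' @export
representatives <- function(cluster_set, pool) {
  asg <- cluster_set$assignments
  reps <- asg |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_min(.data$rmsd_to_centroid, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  sub <- pool[match(reps$id, pool$id), ]
  attr(sub, "sequence") <- pool_sequence(pool)
  class(sub) <- class(pool)
  sub
}
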