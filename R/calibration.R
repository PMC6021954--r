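# Automatic feature calibration: per-training-subject G-means centroid
# profiles (cosine k-means with k-means++ seeding, Anderson-Darling
# Gaussianity splitting), Pearson matching of a new subject's vectors to
# the most correlated centroid, and translation of each vector toward it.

#' Cosine distance between two vectors
#'
#' `1 - (x . c) / (|x||c|)`, in [0, 2].
#'
#' @param x,c numeric vectors of equal length, both non-zero.
#' @return the cosine distance.
#' @export
cosine_distance <- function(x, c) {
  if (length(x) != length(c))
    stop_named("length_mismatch", "vectors must have equal length")
  nx <- sqrt(sum(x^2)); nc <- sqrt(sum(c^2))
  if (nx == 0 || nc == 0)
    stop_named("zero_norm", "cosine distance undefined for zero vectors")
  1 - sum(x * c) / (nx * nc)
}

# Cosine distances from every row of X to every centroid row of C.
cosine_dist_matrix <- function(X, C) {
  Xn <- X / sqrt(rowSums(X^2))
  Cn <- C / sqrt(rowSums(C^2))
  1 - Xn %*% t(Cn)
}

#' k-means++ initialization under the cosine distance
#'
#' First centroid uniform over rows; each subsequent centroid sampled with
#' probability proportional to the squared cosine distance to the nearest
#' centroid already chosen.
#'
#' @param X numeric matrix (rows = observations).
#' @param k number of centroids.
#' @param seed integer seed.
#' @return k x ncol(X) matrix of chosen rows.
#' @export
kmeans_pp_init <- function(X, k, seed = 0L) {
  X <- as.matrix(X)
  if (k > nrow(unique(X)))
    stop_named("too_many_clusters", "k exceeds the number of distinct rows")
  with_seed(seed, {
    idx <- sample.int(nrow(X), 1)
    for (j in seq_len(k - 1)) {
      d <- cosine_dist_matrix(X, X[idx, , drop = FALSE])
      dmin <- apply(d, 1, min)^2
      dmin[idx] <- 0
      if (sum(dmin) == 0) {
        cand <- setdiff(seq_len(nrow(X)), idx)
        idx <- c(idx, cand[sample.int(length(cand), 1)])
      } else {
        idx <- c(idx, sample.int(nrow(X), 1, prob = dmin))
      }
    }
    X[idx, , drop = FALSE]
  })
}

#' Lloyd k-means under the cosine distance
#'
#' Assignment by cosine distance, centroid update by the arithmetic mean of
#' members; empty clusters are reseeded to the point farthest from its
#' centroid. Stops when assignments are stable or after `max_iter`
#' iterations.
#'
#' @param X numeric matrix (rows = observations), no zero rows.
#' @param k number of clusters, or a matrix of initial centroids.
#' @param seed integer seed (used for the k-means++ init).
#' @param max_iter iteration cap (default 300).
#' @return list with `centroids` (k x p), `assignments` (1-based), and
#'   `objective_trace` (sum of cosine distances to assigned centroids per
#'   iteration, non-increasing).
#' @export
kmeans_cosine <- function(X, k, seed = 0L, max_iter = 300L) {
  X <- as.matrix(X)
  C <- if (is.matrix(k)) k else kmeans_pp_init(X, k, seed)
  k <- nrow(C)
  assign_old <- rep(0L, nrow(X))
  trace <- numeric(0)
  C_prev <- C
  for (it in seq_len(max_iter)) {
    D <- cosine_dist_matrix(X, C)
    assign_new <- max.col(-D, ties.method = "first")
    obj <- sum(D[cbind(seq_len(nrow(X)), assign_new)])
    if (length(trace) && obj > trace[length(trace)] + 1e-12) {
      # the arithmetic-mean update is not an exact minimizer under the
      # cosine objective; if a step degrades it, keep the previous state
      C <- C_prev
      break
    }
    trace <- c(trace, obj)
    C_prev <- C
    for (j in seq_len(k)) {
      members <- which(assign_new == j)
      if (length(members) == 0L) {
        far <- which.max(D[cbind(seq_len(nrow(X)), assign_new)])
        C[j, ] <- X[far, ]
        assign_new[far] <- j
      } else {
        C[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
  }
  D <- cosine_dist_matrix(X, C)
  assign_new <- max.col(-D, ties.method = "first")
  list(centroids = C, assignments = assign_new, objective_trace = trace)
}

#' Test whether a cluster's members look Gaussian
#'
#' The G-means splitting criterion: project the members onto the direction
#' along which a 2-way split would separate them -- the principal component
#' of the member cloud, which for a genuine 2-means split of bimodal data
#' coincides with the inter-child-center direction -- standardize, and
#' Anderson-Darling-test the projection for normality. Returns `TRUE` iff
#' normality is not rejected at level `alpha`. Clusters with fewer than 8
#' members are accepted (too small to reject). The principal-component
#' direction is used rather than the realized 2-means children direction
#' because the latter is chosen to maximize separation and makes the test
#' markedly anti-conservative on genuinely Gaussian clusters.
#'
#' @param members numeric matrix of member rows.
#' @param alpha significance level (default 0.10).
#' @param seed integer seed (kept for interface stability; the projection
#'   itself is deterministic).
#' @return logical.
#' @export
gaussian_check <- function(members, alpha = 0.10, seed = 0L) {
  members <- as.matrix(members)
  if (nrow(members) < 8L) return(TRUE)
  cv <- stats::cov(members)
  if (!all(is.finite(cv)) || sum(abs(cv)) == 0) return(TRUE)
  w <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric(members %*% w)
  if (stats::sd(proj) == 0) return(TRUE)
  z <- (proj - mean(proj)) / stats::sd(proj)
  nortest::ad.test(z)$p.value >= alpha
}

#' G-means clustering
#'
#' Starts from one cluster and repeatedly replaces every cluster whose
#' members fail the Gaussianity check by its two cosine-2-means children,
#' running a global cosine k-means refinement after each round of splits,
#' until every cluster passes or `max_k` is reached.
#'
#' @param X numeric matrix of observations.
#' @param alpha Gaussianity significance level (default 0.10).
#' @param max_k cluster cap (default 16).
#' @param seed integer seed.
#' @return list with `centroids`, `sigma` (per-cluster, per-dimension
#'   sample SD of members; 0 for singletons), `member_count`,
#'   `assignments`.
#' @export
gmeans <- function(X, alpha = 0.10, max_k = 16L, seed = 0L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    return(list(centroids = matrix(X[1, ], nrow = 1),
                sigma = matrix(0, 1, ncol(X)),
                member_count = nrow(X),
                assignments = rep(1L, nrow(X))))
  }
  C <- matrix(colMeans(X), nrow = 1)
  assignments <- rep(1L, nrow(X))
  round <- 0L
  repeat {
    round <- round + 1L
    budget <- max_k - nrow(C)  # each split adds one cluster
    newC <- NULL
    split_any <- FALSE
    for (j in seq_len(nrow(C))) {
      idx <- which(assignments == j)
      members <- X[idx, , drop = FALSE]
      # key the check's randomness to the membership: a cluster that is
      # stable across refinement rounds gets one verdict, not a fresh
      # draw per round (repeated testing would inflate the split rate)
      mkey <- derive_seed(seed, "members", paste(idx, collapse = ","))
      ok <- nrow(members) < 2L || budget <= 0L ||
        gaussian_check(members, alpha, mkey)
      if (ok) {
        newC <- rbind(newC, C[j, , drop = FALSE])
      } else {
        kids <- kmeans_cosine(members, 2L, derive_seed(seed, "split", mkey))
        newC <- rbind(newC, kids$centroids)
        split_any <- TRUE
        budget <- budget - 1L
      }
    }
    if (!split_any) break
    km <- kmeans_cosine(X, newC, derive_seed(seed, "refine", round))
    C <- km$centroids
    assignments <- km$assignments
    if (nrow(C) >= max_k) break
  }
  sigma <- t(vapply(seq_len(nrow(C)), function(j) {
    m <- X[assignments == j, , drop = FALSE]
    if (nrow(m) < 2L) rep(0, ncol(X)) else apply(m, 2, stats::sd)
  }, numeric(ncol(X))))
  list(centroids = C, sigma = sigma,
       member_count = as.integer(tabulate(assignments, nrow(C))),
       assignments = assignments)
}

#' Build per-subject calibration profiles from a training feature table
#'
#' Features are first mapped to comparable scales by global training
#' min-max normalization (each feature to [0, 1]); each subject's trials
#' are then clustered by [gmeans()]. Min-max rather than z-scoring keeps
#' the normalized vectors in the positive orthant, where Pearson
#' correlations between vectors and centroids stay predominantly positive
#' and the highest-|r| matching rule behaves as a similarity search (in a
#' centered space, strongly anticorrelated opposite-class centroids would
#' dominate |r|). Each profile stores the cluster centroids and
#' per-dimension SDs in the normalized space, together with the scaler
#' needed to map new data into it.
#'
#' @param features training feature table ([extract_features_dataset()]).
#' @param alpha G-means significance level (default 0.10).
#' @param max_k per-subject cluster cap (default 16).
#' @param seed integer seed.
#' @return object of class `subject_profiles`: list of per-subject profiles
#'   (`subject_id`, `centroids`, `sigma`, `member_count`) plus `center`,
#'   `scale`, `feature_names`.
#' @export
build_profiles <- function(features, alpha = 0.10, max_k = 16L, seed = 0L) {
  fm <- feature_matrix(features)
  ctr <- apply(fm$x, 2, min)
  scl <- apply(fm$x, 2, max) - ctr
  scl[scl < 1e-12] <- 1
  Z <- scale(fm$x, center = ctr, scale = scl)
  subjects <- unique(fm$subjects)
  profs <- lapply(subjects, function(sid) {
    Xi <- Z[fm$subjects == sid, , drop = FALSE]
    if (nrow(Xi) < 4L)
      warning(sprintf("subject %s has < 4 vectors; single-cluster profile", sid))
    gm <- if (nrow(Xi) < 4L) {
      list(centroids = matrix(colMeans(Xi), nrow = 1),
           sigma = matrix(if (nrow(Xi) > 1) apply(Xi, 2, stats::sd) else 0,
                          nrow = 1, ncol = ncol(Xi)),
           member_count = nrow(Xi))
    } else {
      gmeans(Xi, alpha, max_k, derive_seed(seed, "subject", sid))
    }
    list(subject_id = sid, centroids = gm$centroids, sigma = gm$sigma,
         member_count = gm$member_count)
  })
  structure(list(profiles = profs, center = ctr, scale = scl,
                 feature_names = colnames(fm$x)),
            class = "subject_profiles")
}

#' @export
print.subject_profiles <- function(x, ...) {
  ks <- vapply(x$profiles, function(p) nrow(p$centroids), 0L)
  cat(sprintf("<subject_profiles> %d subjects, %d features, clusters per subject: %s\n",
              length(x$profiles), length(x$feature_names),
              paste(ks, collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between a feature vector and a centroid
#'
#' Sample correlation treating the N feature dimensions as paired
#' observations (sample SDs, N - 1 denominator).
#'
#' @param x,c numeric vectors of equal length N >= 2, neither constant.
#' @return r in [-1, 1].
#' @export
pearson_r <- function(x, c) {
  if (length(x) != length(c))
    stop_named("length_mismatch", "vectors must have equal length")
  if (length(x) < 2L)
    stop_named("too_short", "need at least 2 paired values")
  if (stats::sd(x) == 0 || stats::sd(c) == 0)
    stop_named("constant_vector", "Pearson correlation undefined for a constant vector")
  r <- sum((x - mean(x)) * (c - mean(c))) /
    ((length(x) - 1) * stats::sd(x) * stats::sd(c))
  min(max(r, -1), 1)
}

#' Find the training centroid most correlated with a feature vector
#'
#' Scans every cluster of every profile and returns the one maximizing
#' |r|; exact ties are broken by (subject_id, cluster index) lexicographic
#' order (the scan order).
#'
#' @param v feature vector in the profiles' standardized space.
#' @param profiles a [build_profiles()] result.
#' @return list with `subject_id`, `cluster` (index), `centroid`, `sigma`,
#'   `r`.
#' @export
match_centroid <- function(v, profiles) {
  stopifnot(inherits(profiles, "subject_profiles"))
  if (length(profiles$profiles) == 0L)
    stop_named("empty_profiles", "no profiles to match against")
  best <- NULL
  ord <- order(vapply(profiles$profiles, `[[`, "", "subject_id"))
  for (p in profiles$profiles[ord]) {
    for (j in seq_len(nrow(p$centroids))) {
      r <- pearson_r(v, p$centroids[j, ])
      if (is.null(best) || abs(r) > abs(best$r) + 1e-15) {
        best <- list(subject_id = p$subject_id, cluster = j,
                     centroid = p$centroids[j, ], sigma = p$sigma[j, ], r = r)
      }
    }
  }
  best
}

#' Translate one feature vector toward a matched centroid
#'
#' Given the matched cluster (centroid C, per-dimension SD sigma), computes
#' the Euclidean distance d from v to C and shifts v toward C. Two modes:
#' `"directional"` (default) keeps the offset direction and sets its
#' per-dimension length to one cluster SD, `Vnew = C + sigma * (v - C)/d`
#' (v itself if d = 0), which lands the vector on the cluster's SD shell
#' without overlapping the centroid. `"literal"` applies the printed
#' normalized-translation arithmetic verbatim: `dn = (d - C)/sigma`,
#' `Vnew = v - dn`.
#'
#' @param v feature vector (standardized space).
#' @param centroid,sigma matched cluster centroid and SD vectors.
#' @param mode `"directional"` or `"literal"`.
#' @param sigma_floor SD floor; components below `1e-6` are replaced by
#'   `sigma_floor` (default 0.1, i.e. a tenth of the global unit SD).
#' @return list with `v`, `v_new`, `d`, `dn` (literal normalized distance
#'   vector, NULL in directional mode), `mode`.
#' @export
calibrate_vector <- function(v, centroid, sigma,
                             mode = c("directional", "literal"),
                             sigma_floor = 0.1) {
  mode <- match.arg(mode)
  if (length(v) != length(centroid) || length(v) != length(sigma))
    stop_named("length_mismatch", "v, centroid and sigma must have equal length")
  sig <- ifelse(sigma < 1e-6, sigma_floor, sigma)
  d <- sqrt(sum((centroid - v)^2))
  if (mode == "literal") {
    dn <- (d - centroid) / sig
    v_new <- v - dn
  } else {
    dn <- NULL
    v_new <- if (d == 0) v else centroid + sig * (v - centroid) / d
  }
  list(v = v, v_new = v_new, d = d, dn = dn, mode = mode)
}

#' Calibrate a test subject's feature table against training profiles
#'
#' Each row is independently standardized by the training scaler, matched
#' to its most |r|-correlated training centroid, translated toward it, and
#' mapped back to the original feature units.
#'
#' @param features test feature table ([extract_features_dataset()]).
#' @param profiles a [build_profiles()] result.
#' @param mode `"directional"` (default) or `"literal"`.
#' @return list with `features` (calibrated table, same shape as input) and
#'   `audit` (data frame: per-row matched subject, cluster, r, d).
#' @export
calibrate_features <- function(features, profiles,
                               mode = c("directional", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profiles, "subject_profiles"))
  fm <- feature_matrix(features)
  if (!identical(colnames(fm$x), profiles$feature_names))
    stop_named("feature_mismatch", "feature columns do not match the profiles")
  out <- features
  audit <- vector("list", nrow(fm$x))
  for (i in seq_len(nrow(fm$x))) {
    z <- (fm$x[i, ] - profiles$center) / profiles$scale
    m <- match_centroid(z, profiles)
    cal <- calibrate_vector(z, m$centroid, m$sigma, mode)
    out[i, profiles$feature_names] <-
      cal$v_new * profiles$scale + profiles$center
    audit[[i]] <- data.frame(subject_id = features$subject_id[i],
                             trial_id = features$trial_id[i],
                             matched_subject = m$subject_id,
                             matched_cluster = m$cluster,
                             r = m$r, d = cal$d)
  }
  list(features = out, audit = do.call(rbind, audit))
}

## ---- Serialization ------------------------------------------------------

#' Write subject profiles to JSON
#' @param profiles a [build_profiles()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "subject_profiles"))
  obj <- list(
    feature_names = profiles$feature_names,
    center = profiles$center, scale = profiles$scale,
    profiles = lapply(profiles$profiles, function(p) {
      list(subject_id = p$subject_id,
           centroids = apply(p$centroids, 1, identity, simplify = FALSE),
           sigma = apply(p$sigma, 1, identity, simplify = FALSE),
           member_count = p$member_count)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read subject profiles from JSON
#' @param path a file written by [write_profiles()].
#' @return a `subject_profiles` object.
#' @export
read_profiles <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  profs <- lapply(seq_len(nrow(obj$profiles)), function(i) {
    cent <- obj$profiles$centroids[[i]]
    sig <- obj$profiles$sigma[[i]]
    to_mat <- function(m) {
      m <- if (is.list(m)) do.call(rbind, m) else m
      if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
    }
    list(subject_id = obj$profiles$subject_id[[i]],
         centroids = to_mat(cent), sigma = to_mat(sig),
         member_count = as.integer(unlist(obj$profiles$member_count[[i]])))
  })
  structure(list(profiles = profs,
                 center = stats::setNames(obj$center, obj$feature_names),
                 scale = stats::setNames(obj$scale, obj$feature_names),
                 feature_names = obj$feature_names),
            class = "subject_profiles")
}
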