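# k-means++ seeding (squared-distance proportional sampling)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Fit k-means connectivity states
#'
#' Squared-Euclidean k-means over pooled window features, with k-means++
#' initialisation and the best of several restarts kept by within-cluster sum
#' of squares (inertia). Deterministic for a fixed seed.
#'
#' @param features N x P matrix of pooled Fisher-z window features.
#' @param k Number of states.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param seed Integer seed.
#' @param iter_max Lloyd iterations per restart (default 100).
#' @return Object of class \code{state_model}: list with \code{centroids}
#'   (k x P), \code{k}, \code{inertia}, \code{cluster} (training labels),
#'   \code{explained_variance_fraction} and \code{archetype_labels}
#'   (filled by \code{\link{match_states_to_archetypes}}).
#' @export
fit_kmeans <- function(features, k, restarts = 10, seed = 1, iter_max = 100) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1 || k > n) stop("k must be between 1 and the number of windows")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(features, k)
    init <- init[!duplicated(init), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(features, centers = init, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  tss <- sum(sweep(features, 2, colMeans(features))^2)
  structure(list(centroids = unname(best$centers), k = nrow(best$centers),
                 inertia = best$tot.withinss,
                 cluster = unname(best$cluster),
                 explained_variance_fraction =
                   if (tss > 0) 1 - best$tot.withinss / tss else NA_real_,
                 feature_names = colnames(features),
                 archetype_labels = rep(NA_character_, nrow(best$centers))),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("State model: k =", x$k, "states,",
      sprintf("%.1f%% variance explained", 100 * x$explained_variance_fraction),
      "\n")
  if (!all(is.na(x$archetype_labels)))
    cat("  labels:", paste(x$archetype_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of states by the elbow criterion
#'
#' Fits k-means across a grid of k (shared seed schedule), records the
#' within-cluster sum of squares (WCSS), and picks the interior k maximising
#' the second difference [WCSS(k-1) - WCSS(k)] - [WCSS(k) - WCSS(k+1)]; ties
#' break toward smaller k. A non-monotone WCSS curve (restart noise) is
#' smoothed by a running minimum with a warning.
#'
#' @param features N x P matrix of pooled features.
#' @param k_grid Consecutive integers to evaluate (default 2:8).
#' @param restarts,seed,iter_max Passed to \code{\link{fit_kmeans}}.
#' @return List with \code{k_grid}, \code{within_cluster_ss},
#'   \code{explained_variance} and \code{chosen_k}.
#' @export
elbow_select <- function(features, k_grid = 2:8, restarts = 10, seed = 1,
                         iter_max = 100) {
  if (length(k_grid) < 3 || any(diff(k_grid) != 1))
    stop("k_grid must contain at least 3 consecutive values")
  fits <- lapply(seq_along(k_grid), function(i)
    fit_kmeans(features, k_grid[i], restarts, seed + i, iter_max))
  wcss <- vapply(fits, function(f) f$inertia, numeric(1))
  ev <- vapply(fits, function(f) f$explained_variance_fraction, numeric(1))
  if (any(diff(wcss) > 0)) {
    warning("WCSS not monotone over k_grid (restart noise); ",
            "using running-minimum smoothing")
    wcss_s <- cummin(wcss)
  } else wcss_s <- wcss
  interior <- 2:(length(k_grid) - 1)
  second_diff <- (wcss_s[interior - 1] - wcss_s[interior]) -
    (wcss_s[interior] - wcss_s[interior + 1])
  chosen <- k_grid[interior[which.max(second_diff)]]
  list(k_grid = k_grid, within_cluster_ss = wcss,
       explained_variance = ev, chosen_k = chosen)
}

#' Fraction of total variance explained by a state model
#'
#' 1 - inertia / total sum of squared deviations from the grand mean.
#'
#' @param features The features the model was fitted to.
#' @param model A \code{\link{fit_kmeans}} result.
#' @return Scalar in [0, 1].
#' @export
explained_variance <- function(features, model) {
  features <- as.matrix(features)
  tss <- sum(sweep(features, 2, colMeans(features))^2)
  if (tss == 0) stop("zero total variance")
  1 - model$inertia / tss
}

#' Assign windows to the nearest state centroid
#'
#' Each window gets the label of the centroid at minimal Euclidean distance;
#' ties go to the lowest cluster index.
#'
#' @param features Nw x P feature matrix (or a \code{window_series}).
#' @param model A \code{\link{fit_kmeans}} result.
#' @return Integer vector of state labels in 1..k.
#' @export
assign_states <- function(features, model) {
  if (inherits(features, "window_series")) features <- features$features
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$centroids))
    stop("feature dimension does not match centroids")
  cc <- model$centroids
  d2 <- outer(rowSums(features^2), rep(1, nrow(cc))) +
    outer(rep(1, nrow(features)), rowSums(cc^2)) -
    2 * features %*% t(cc)
  max.col(-d2, ties.method = "first")
}

#' Match fitted states to connectivity archetypes
#'
#' Finds the one-to-one assignment of cluster centroids to archetype
#' matrices by exhaustive search over permutations, minimising total
#' Euclidean distance between each centroid and the archetype's Fisher-z
#' off-diagonal vector. Distance (rather than Pearson correlation) is the
#' assignment criterion because archetypes with a flat off-diagonal pattern
#' (the weakly and strongly connected states differ only in overall level)
#' carry no pattern variance, making correlation against them undefined.
#' Pearson correlation is still reported as the match diagnostic: a matched
#' pair is labelled \code{"unmatched"} when its correlation falls below
#' \code{min_correlation}, or -- for a flat archetype, where correlation is
#' undefined -- when the root-mean-square z-distance exceeds
#' \code{max_rms_distance}.
#'
#' @param model A \code{\link{fit_kmeans}} result with k centroids.
#' @param archetypes Named list of k correlation matrices.
#' @param min_correlation Correlation threshold below which a patterned
#'   state stays unmatched (default 0.3).
#' @param max_rms_distance RMS Fisher-z distance above which a flat-pattern
#'   state stays unmatched (default 0.3).
#' @return The model with \code{archetype_labels} and
#'   \code{archetype_correlations} filled in (correlation is \code{NA} for
#'   flat-pattern archetypes).
#' @export
match_states_to_archetypes <- function(model, archetypes,
                                       min_correlation = 0.3,
                                       max_rms_distance = 0.3) {
  k <- model$k
  if (k != length(archetypes))
    stop("number of archetypes must equal k")
  P <- ncol(model$centroids)
  arch_z <- vapply(archetypes,
                   function(M) fisher_z(unname(vectorize_upper(M))),
                   numeric(P))
  cent <- model$centroids
  # rms z-distance and (possibly undefined) correlation, cluster x archetype
  D <- sqrt(sapply(seq_len(k), function(j)
    rowMeans(sweep(cent, 2, arch_z[, j])^2)))
  D <- matrix(D, k, k)
  flat <- apply(arch_z, 2, stats::sd) < 1e-8
  R <- suppressWarnings(stats::cor(t(cent), arch_z))
  R[, flat] <- NA_real_
  perms <- permutations_of(k)
  scores <- apply(perms, 1, function(p) sum(D[cbind(seq_len(k), p)]))
  best <- perms[which.min(scores), ]
  labels <- names(archetypes)[best]
  rmatch <- R[cbind(seq_len(k), best)]
  dmatch <- D[cbind(seq_len(k), best)]
  bad <- ifelse(is.na(rmatch), dmatch > max_rms_distance,
                rmatch < min_correlation)
  labels[bad] <- "unmatched"
  model$archetype_labels <- labels
  model$archetype_correlations <- rmatch
  model$archetype_distances <- dmatch
  model
}

# all permutations of 1..n (n small: used with k <= 8)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}
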