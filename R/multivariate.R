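#' Sample-by-marker feature matrix
#'
#' One feature per marker: the highest retained -10lgP score of that marker
#' in the sample, 0 when undetected. This is the input to PCA and to the
#' SOM classifier.
#'
#' @param cohort A filtered, marker-assigned `psm_cohort`.
#' @param db A `marker_db`.
#' @return Numeric matrix, samples in rows, markers in columns.
#' @export
feature_matrix <- function(cohort, db) {
  t(detection_matrix(cohort, db, value_kind = "max_score"))
}

#' Principal component analysis of marker score features
#'
#' Column-centred (not variance-scaled) PCA via the singular value
#' decomposition, as is conventional for score profiles where the score
#' magnitude itself is informative.
#'
#' @param X Samples-by-features numeric matrix (>= 2 samples).
#' @param center,scale. Passed to [stats::prcomp()]; defaults centre
#'   without scaling.
#' @return A list with `scores`, `loadings`, `explained` (variance
#'   fractions summing to 1), `center`.
#' @export
pca_features <- function(X, center = TRUE, scale. = FALSE) {
  if (nrow(X) < 2) stop("PCA requires at least 2 samples")
  p <- prcomp(X, center = center, scale. = scale.)
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation, explained = ev / sum(ev),
       center = if (isTRUE(center)) p$center else rep(0, ncol(X)))
}

grid_coords <- function(grid) {
  expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2]))
}

#' Train a self-organizing map
#'
#' Standard online SOM: at each iteration a randomly drawn sample updates
#' its best-matching unit (BMU, Euclidean distance) and its neighbours
#' under a Gaussian neighbourhood. The learning rate decays linearly from
#' `alpha[1]` to `alpha[2]`; the neighbourhood radius decays linearly from
#' half the grid diagonal to 1. Training is deterministic given the seed.
#' Features are column-centred before training (centres stored in the
#' model and applied to new samples).
#'
#' @param X Samples-by-features matrix.
#' @param grid Grid shape `c(rows, cols)` (default 4 x 4 square).
#' @param iterations Training iterations (default 10000 presentations).
#' @param seed Integer RNG seed.
#' @param alpha Start and end learning rate (default 0.05 -> 0.01).
#' @return A `som_model` list: `grid`, `codebooks` (nodes x features),
#'   `node_xy`, `centers`, `iterations`, `seed`, `features`.
#' @export
som_train <- function(X, grid = c(4, 4), iterations = 10000L, seed = 1L,
                      alpha = c(0.05, 0.01)) {
  stopifnot(nrow(X) >= 1, length(grid) == 2)
  X <- as.matrix(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  n_nodes <- grid[1] * grid[2]
  xy <- as.matrix(grid_coords(grid))
  # squared grid distances between nodes, precomputed
  gd2 <- as.matrix(stats::dist(xy))^2
  r0 <- max(sqrt(sum((grid - 1)^2)) / 2, 1)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  # init codebooks from random points within the data range
  rng <- apply(Xc, 2, range)
  W <- matrix(runif(n_nodes * ncol(Xc), rng[1, ], rng[2, ]),
              nrow = n_nodes, byrow = TRUE)
  picks <- sample.int(nrow(Xc), iterations, replace = TRUE)
  for (t in seq_len(iterations)) {
    frac <- (t - 1) / max(iterations - 1, 1)
    a <- alpha[1] + frac * (alpha[2] - alpha[1])
    r <- r0 + frac * (1 - r0)
    x <- Xc[picks[t], ]
    d2 <- rowSums(sweep(W, 2, x)^2)
    bmu <- which.min(d2)
    h <- exp(-gd2[bmu, ] / (2 * r^2))
    W <- W + (a * h) * sweep(-W, 2, x, `+`)
  }
  structure(list(grid = grid, codebooks = W, node_xy = xy,
                 centers = centers, iterations = iterations, seed = seed,
                 features = colnames(X)),
            class = "som_model")
}

#' Best-matching unit for each sample
#' @param model A `som_model`.
#' @param X Samples-by-features matrix in the model's feature space.
#' @return Integer vector of node indices.
#' @export
som_bmu <- function(model, X) {
  Xc <- sweep(as.matrix(X), 2, model$centers)
  apply(Xc, 1, function(x) {
    which.min(rowSums(sweep(model$codebooks, 2, x)^2))
  })
}

#' Elbow k-means over SOM codebook vectors
#'
#' Runs k-means for k = 1..`k_max` on the codebooks and picks k at the
#' knee of the within-cluster sum-of-squares curve, located as the maximal
#' second difference of log(WCSS) (scale-invariant elbow). Degenerate
#' inputs (all codebooks identical) give k = 1.
#'
#' @param codebooks Nodes-by-features matrix (>= 2 rows).
#' @param k_max Largest k tried (default 8, capped at the number of
#'   distinct codebooks).
#' @param seed Integer RNG seed for the k-means restarts.
#' @return A list with `k`, `labels` (cluster per node) and `wcss`.
#' @export
kmeans_elbow <- function(codebooks, k_max = 8L, seed = 1L) {
  codebooks <- as.matrix(codebooks)
  stopifnot(nrow(codebooks) >= 2)
  n_distinct <- nrow(unique(codebooks))
  if (n_distinct == 1) {
    return(list(k = 1L, labels = rep(1L, nrow(codebooks)),
                wcss = 0))
  }
  k_max <- min(k_max, n_distinct)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k) {
    kmeans(codebooks, centers = k, nstart = 20, iter.max = 100)
  })
  wcss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  if (k_max >= 3) {
    # knee of the WCSS curve: maximal second difference on the log scale
    # (scale-invariant; the raw second difference is dominated by the first
    # large drop and under-estimates k whenever clusters nest)
    lw <- log(wcss + 1e-8 * wcss[1])
    d2 <- lw[1:(k_max - 2)] - 2 * lw[2:(k_max - 1)] + lw[3:k_max]
    k <- which.max(d2) + 1L
  } else {
    k <- k_max
  }
  list(k = k, labels = fits[[k]]$cluster, wcss = wcss)
}

#' Build the modern reference classification system
#'
#' Trains PCA, the SOM and elbow k-means on a modern reference feature
#' matrix. Unknown (e.g. archaeological) samples never influence training.
#'
#' @param X Reference samples-by-markers matrix (>= 2 samples).
#' @param grid,iterations,seed,alpha Passed to [som_train()].
#' @param k_max Passed to [kmeans_elbow()].
#' @return A `cbp_classifier` list: `som`, `k`, `node_labels`, `pca`,
#'   `reference` (tibble of reference sample assignments).
#' @export
build_classifier <- function(X, grid = c(4, 4), iterations = 10000L,
                             seed = 1L, alpha = c(0.05, 0.01), k_max = 8L) {
  som <- som_train(X, grid = grid, iterations = iterations, seed = seed,
                   alpha = alpha)
  km <- kmeans_elbow(som$codebooks, k_max = k_max, seed = seed)
  pca <- pca_features(X)
  bmu <- som_bmu(som, X)
  reference <- tibble::tibble(
    sample = rownames(X) %||% as.character(seq_len(nrow(X))),
    bmu = bmu, cluster = km$labels[bmu],
    PC1 = pca$scores[, 1],
    PC2 = if (ncol(pca$scores) >= 2) pca$scores[, 2] else 0
  )
  structure(list(som = som, k = km$k, node_labels = km$labels,
                 wcss = km$wcss, pca = pca, reference = reference),
            class = "cbp_classifier")
}

#' Classify new samples with a trained reference system
#'
#' Each query sample is mapped to its BMU in the trained SOM and inherits
#' that node's k-means cluster; PCA projection coordinates are returned for
#' plotting. Query columns must be a subset of the model's marker features:
#' markers missing from the query are zero-filled with a warning, unknown
#' markers raise an error. All-zero feature vectors are assigned
#' deterministically and flagged low-information.
#'
#' @param classifier A `cbp_classifier`.
#' @param X_new Query samples-by-markers matrix.
#' @return Tibble: `sample`, `bmu`, `cluster`, `PC1`, `PC2`,
#'   `low_information`.
#' @export
classify_new <- function(classifier, X_new) {
  X_new <- as.matrix(X_new)
  feats <- classifier$som$features
  unknown <- setdiff(colnames(X_new), feats)
  if (length(unknown) > 0) {
    stop("query markers absent from the reference system: ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(feats, colnames(X_new))
  if (length(missing) > 0) {
    warning("query lacks ", length(missing),
            " reference marker(s); zero-filled")
    fill <- matrix(0, nrow = nrow(X_new), ncol = length(missing),
                   dimnames = list(rownames(X_new), missing))
    X_new <- cbind(X_new, fill)
  }
  X_new <- X_new[, feats, drop = FALSE]
  bmu <- som_bmu(classifier$som, X_new)
  proj <- sweep(X_new, 2, classifier$pca$center) %*% classifier$pca$loadings
  tibble::tibble(
    sample = rownames(X_new) %||% as.character(seq_len(nrow(X_new))),
    bmu = bmu,
    cluster = classifier$node_labels[bmu],
    PC1 = proj[, 1],
    PC2 = if (ncol(proj) >= 2) proj[, 2] else 0,
    low_information = rowSums(X_new != 0) == 0
  )
}

#' Persist a classifier as JSON
#' @param classifier A `cbp_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(classifier, path) {
  payload <- list(
    grid = classifier$som$grid,
    iterations = classifier$som$iterations,
    seed = classifier$som$seed,
    features = classifier$som$features,
    codebooks = classifier$som$codebooks,
    centers = classifier$som$centers,
    k = classifier$k,
    node_labels = classifier$node_labels
  )
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}
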