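#' The discretized perfusion grid of the classifier
#'
#' The network reports perfusion on 40 discrete levels spanning 10 to
#' 400 ml/min/100g; the default grid is linearly spaced with step 10.
#'
#' @param values Strictly increasing perfusion levels; exactly 40 values
#'   from 10 to 400.
#' @return A `perf_class_grid` object.
#' @export
perfusion_class_grid <- function(values = seq(10, 400, by = 10)) {
  check_finite_numeric(values, "values")
  if (length(values) != 40 || any(diff(values) <= 0) ||
      values[1] != 10 || values[40] != 400) {
    stop_invalid("grid must hold 40 strictly increasing values from 10 to 400")
  }
  structure(list(values = values, spacing = values[2] - values[1]),
            class = "perf_class_grid")
}

#' Map a perfusion value to its class index
#'
#' Returns the 0-based index of the nearest grid value; ties round up to the
#' larger grid value, and out-of-range perfusion clips to the end classes.
#'
#' @param f Perfusion value(s), ml/min/100g. Must be finite and positive.
#' @param grid A [perfusion_class_grid()].
#' @return Integer class indices in 0..39.
#' @examples
#' discretize_perfusion(c(10, 72.4, 75, 400))
#' @export
discretize_perfusion <- function(f, grid = perfusion_class_grid()) {
  check_finite_numeric(f, "f")
  if (any(f <= 0)) stop_invalid("`f` must be positive")
  v <- grid$values
  # count of inter-grid midpoints <= f is the 0-based nearest index with
  # ties resolved upward (f equal to a midpoint counts that midpoint)
  mids <- (v[-length(v)] + v[-1]) / 2
  idx <- findInterval(f, mids)
  as.integer(idx)
}

#' Decode a class index back to its perfusion value
#'
#' @param index Integer class indices in 0..39.
#' @param grid A [perfusion_class_grid()].
#' @return Perfusion value(s), ml/min/100g.
#' @export
class_to_perfusion <- function(index, grid = perfusion_class_grid()) {
  if (anyNA(index) || any(index != as.integer(index)) ||
      any(index < 0) || any(index > 39)) {
    stop_invalid("`index` must be integers in 0..39")
  }
  grid$values[as.integer(index) + 1]
}

#' Build the 80-element network input for one voxel
#'
#' Concatenates the 40 TC samples and the 40 AIF samples, in frame order,
#' with no normalization.
#'
#' @param tc Tissue concentration curve, 40 frames, mM.
#' @param aif Arterial input function, 40 frames, mM.
#' @return Numeric vector of length 80.
#' @export
build_feature_vector <- function(tc, aif) {
  check_finite_numeric(tc, "tc"); check_finite_numeric(aif, "aif")
  if (length(tc) != 40 || length(aif) != 40) {
    stop_invalid("`tc` and `aif` must each have exactly 40 frames")
  }
  c(tc, aif)
}

#' Network architecture and training hyperparameters
#'
#' Defaults follow the fully connected feed-forward design: seven hidden
#' layers of 70 rectified-linear nodes, a 40-class softmax output, Adam with
#' learning rate 0.001, batch size 32, 20 epochs.
#'
#' @param n_hidden_layers,nodes_per_layer Hidden-layer count and width.
#' @param n_epochs Training epochs (no early stopping).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param rng_seed Seed controlling weight initialization and batch
#'   shuffling; training is reproducible given the seed.
#' @param standardize If `TRUE`, per-feature standardization (mean/sd of the
#'   training set) is applied before the network; off by default, matching
#'   raw concatenated inputs.
#' @return A `network_config` object.
#' @export
network_config <- function(n_hidden_layers = 7, nodes_per_layer = 70,
                           n_epochs = 20, learning_rate = 0.001,
                           batch_size = 32, rng_seed = 1L,
                           standardize = FALSE) {
  counts <- c(n_hidden_layers, nodes_per_layer, n_epochs, batch_size)
  if (any(counts < 1) || learning_rate <= 0) {
    stop_invalid("network counts must be positive and learning rate > 0")
  }
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 n_epochs = as.integer(n_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed),
                 standardize = isTRUE(standardize)),
            class = "network_config")
}

#' Assemble a voxelwise training set from fitted studies
#'
#' One record per masked voxel: the 80-element (TC, AIF) feature vector and
#' the class label obtained by discretizing the fitted perfusion of the
#' chosen label source. Cohorts concatenate, so merged training groups are
#' the union of their records.
#'
#' @param studies List of `perf_study` objects.
#' @param fits List of `perf_map_fit` objects parallel to `studies`, whose
#'   perfusion estimates provide the labels.
#' @param label_source `"multigrid"` or `"regular"`; must match the mode of
#'   every fit in `fits`.
#' @param grid A [perfusion_class_grid()].
#' @param drop_nonconverged If `TRUE`, voxels whose label fit did not
#'   converge are excluded. Default `FALSE` (all voxels retained).
#' @return A `perf_training_set`: list with `features` (n x 80 matrix),
#'   `labels` (integer classes 0..39), `provenance` (tibble of contributing
#'   studies), `label_source` and `grid`.
#' @export
assemble_training_set <- function(studies, fits,
                                  label_source = c("multigrid", "regular"),
                                  grid = perfusion_class_grid(),
                                  drop_nonconverged = FALSE) {
  label_source <- match.arg(label_source)
  if (length(studies) == 0 || length(studies) != length(fits)) {
    stop_invalid("`studies` and `fits` must be non-empty parallel lists")
  }
  parts <- purrr::map2(studies, fits, function(study, fit) {
    stopifnot(inherits(study, "perf_study"), inherits(fit, "perf_map_fit"))
    if (fit$mode != label_source) {
      stop_invalid(sprintf("label map is a %s fit but label_source is %s",
                           fit$mode, label_source))
    }
    if (nrow(fit$voxels) != nrow(study$tc)) {
      stop_invalid("fit and study voxel sets differ")
    }
    keep <- if (drop_nonconverged) fit$voxels$converged else
      rep(TRUE, nrow(fit$voxels))
    feats <- cbind(study$tc[keep, , drop = FALSE],
                   matrix(study$aif, sum(keep), length(study$aif), byrow = TRUE))
    study_id <- study$dataset_id %||% NA_character_
    cohort_id <- study$cohort %||% NA_character_
    list(features = feats,
         labels = discretize_perfusion(fit$voxels$F[keep], grid),
         prov = tibble::tibble(study = study_id, cohort = cohort_id,
                               n_voxels = sum(keep)))
  })
  features <- do.call(rbind, purrr::map(parts, "features"))
  structure(list(features = features,
                 labels = unlist(purrr::map(parts, "labels")),
                 provenance = dplyr::bind_rows(purrr::map(parts, "prov")),
                 label_source = label_source, grid = grid),
            class = "perf_training_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.perf_training_set <- function(x, ...) {
  cat(sprintf("<perf_training_set> %d voxels from %d studies, %s labels\n",
              length(x$labels), nrow(x$provenance), x$label_source))
  invisible(x)
}

#' Train the perfusion classifier
#'
#' Trains the 80 -> (70 ReLU) x 7 -> 40 softmax network with Adam on the
#' cross-entropy of integer class labels, for exactly `n_epochs` passes over
#' shuffled mini-batches. Deterministic given `config$rng_seed`.
#'
#' @param train A [assemble_training_set()] result, or any list with
#'   `features` (n x 80), `labels` (0..39) and `grid`.
#' @param config A [network_config()].
#' @return A `perf_net` object: weights, biases, `grid`, `config`, per-epoch
#'   training `log` (tibble of epoch and mean loss), and provenance.
#' @export
train_network <- function(train, config = network_config()) {
  if (is.null(train$features) || nrow(train$features) == 0) {
    stop_invalid("training set is empty")
  }
  labels <- as.integer(train$labels)
  if (length(labels) != nrow(train$features) ||
      any(labels < 0) || any(labels > 39)) {
    stop_invalid("labels must parallel features and lie in 0..39")
  }
  X <- train$features
  center <- scale_sd <- NULL
  if (config$standardize) {
    center <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, sd), 1e-12)
    X <- sweep(sweep(X, 2, center), 2, scale_sd, "/")
  }
  fit <- nn_train_cpp(X, labels, config$n_hidden_layers,
                      config$nodes_per_layer, 40L, config$n_epochs,
                      config$learning_rate, config$batch_size,
                      config$rng_seed)
  structure(list(weights = fit$weights, biases = fit$biases,
                 grid = train$grid %||% perfusion_class_grid(),
                 config = config,
                 log = tibble::tibble(epoch = seq_len(config$n_epochs),
                                      loss = as.numeric(fit$epoch_loss)),
                 center = center, scale = scale_sd,
                 provenance = train$provenance %||% tibble::tibble(),
                 label_source = train$label_source %||% NA_character_),
            class = "perf_net")
}

#' @export
print.perf_net <- function(x, ...) {
  cat(sprintf(
    "<perf_net> 80 -> (%d x %d ReLU) -> 40 softmax; %d epochs, final loss %.4f\n",
    x$config$n_hidden_layers, x$config$nodes_per_layer,
    nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

net_probabilities <- function(net, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != 80) stop_invalid("features must have 80 columns")
  if (!is.null(net$center)) {
    features <- sweep(sweep(features, 2, net$center), 2, net$scale, "/")
  }
  nn_predict_cpp(net$weights, net$biases, features)
}

#' Predict perfusion for one voxel
#'
#' @param net A trained [train_network()] model.
#' @param feature 80-element feature vector from [build_feature_vector()].
#' @return List with `probabilities` (40 softmax values summing to 1),
#'   `class` (0-based argmax, ties toward the lower index) and `perfusion`
#'   (the decoded grid value, ml/min/100g).
#' @export
predict_voxel <- function(net, feature) {
  if (length(feature) != 80) stop_invalid("feature must have 80 elements")
  p <- net_probabilities(net, feature)[1, ]
  cls <- which.max(p) - 1L
  list(probabilities = p, class = cls,
       perfusion = class_to_perfusion(cls, net$grid))
}

#' Predict a perfusion map for a whole slice
#'
#' Builds per-voxel features and runs batched inference; inference is
#' deterministic and voxel-order independent. Unmasked voxels are `NA`.
#'
#' @param net A trained `perf_net`.
#' @param series 3-D concentration array (rows x cols x frames) or a
#'   masked-voxel matrix (see [fit_map()]).
#' @param mask Logical matrix of muscle voxels.
#' @param aif Arterial input function, 40 frames, mM.
#' @return A `perf_nn_map`: list with `map` (matrix of grid-valued
#'   perfusion), `voxels` (tibble with row, col, class, F) and `grid`.
#' @export
predict_map <- function(net, series, mask, aif) {
  mask <- as_mask(mask)
  tcmat <- series_to_matrix(series, mask, length(aif))
  map <- matrix(MAP_SENTINEL, dim(mask)[1], dim(mask)[2])
  if (nrow(tcmat$tc) > 0) {
    feats <- cbind(tcmat$tc, matrix(aif, nrow(tcmat$tc), length(aif),
                                    byrow = TRUE))
    probs <- net_probabilities(net, feats)
    cls <- max.col(probs, ties.method = "first") - 1L
    f <- class_to_perfusion(cls, net$grid)
    map[cbind(tcmat$pos$row, tcmat$pos$col)] <- f
    voxels <- dplyr::bind_cols(tcmat$pos,
                               tibble::tibble(class = cls, F = f))
  } else {
    voxels <- tibble::tibble(row = integer(), col = integer(),
                             class = integer(), F = numeric())
  }
  structure(list(map = map, voxels = voxels, grid = net$grid),
            class = "perf_nn_map")
}

#' Predict a perfusion map for a study
#'
#' @param net A trained `perf_net`.
#' @param study A `perf_study`.
#' @return A `perf_nn_map` (see [predict_map()]).
#' @export
predict_study <- function(net, study) {
  stopifnot(inherits(study, "perf_study"))
  predict_map(net, study$tc, study$mask, study$aif)
}

#' Serialize a trained network to a portable JSON file
#'
#' Stores architecture, weights, the perfusion grid and provenance in one
#' self-describing JSON file so inference needs nothing but this package.
#'
#' @param net A `perf_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_perf_net <- function(net, path) {
  payload <- list(
    format = "dceperf_net", version = 1L,
    grid = net$grid$values,
    label_source = net$label_source,
    config = unclass(net$config),
    log = as.list(net$log),
    center = net$center, scale = net$scale,
    weights = lapply(net$weights, identity),
    biases = lapply(net$biases, as.numeric))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized network
#'
#' @param path File written by [write_perf_net()].
#' @return A `perf_net`.
#' @export
read_perf_net <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "dceperf_net")) {
    stop_invalid("not a dceperf network file")
  }
  cfg <- do.call(network_config, x$config[c(
    "n_hidden_layers", "nodes_per_layer", "n_epochs", "learning_rate",
    "batch_size", "rng_seed", "standardize")])
  structure(list(
    weights = lapply(x$weights, as.matrix),
    biases = lapply(x$biases, as.numeric),
    grid = perfusion_class_grid(as.numeric(x$grid)),
    config = cfg,
    log = tibble::tibble(epoch = x$log$epoch, loss = x$log$loss),
    center = if (length(x$center)) as.numeric(x$center) else NULL,
    scale = if (length(x$scale)) as.numeric(x$scale) else NULL,
    provenance = tibble::tibble(),
    label_source = x$label_source %||% NA_character_),
    class = "perf_net")
}
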