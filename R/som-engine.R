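#' Square toroidal Kohonen grid
#'
#' Neuron weights live in a `side^2 x n_features` matrix; neuron `k`
#' (1-based, row-major) sits at 0-based grid coordinates
#' `(row, col) = ((k-1) %/% side, (k-1) %% side)`. The torus removes border
#' effects: opposite edges are adjacent.
#'
#' @param side grid side length (map is `side x side`), at least 2.
#' @param n_features length of each neuron's weight vector.
#' @param init `"range"` (default) draws each weight uniformly within the
#'   per-feature `[min, max]` of `data`; `"zero"` starts at zero.
#' @param data training matrix used for range initialisation.
#' @param feature_names optional names for the weight columns.
#' @return A `som_grid`: list with `side`, `weights`, `feature_names`.
#' @export
som_grid <- function(side, n_features, init = c("range", "zero"),
                     data = NULL, feature_names = NULL) {
  init <- match.arg(init)
  stopifnot(side >= 2, n_features >= 1)
  side <- as.integer(side)
  if (init == "range") {
    if (is.null(data)) stop("range initialisation needs `data`")
    lo <- apply(data, 2, min); hi <- apply(data, 2, max)
    W <- matrix(stats::runif(side^2 * n_features), side^2, n_features)
    W <- sweep(sweep(W, 2, hi - lo, "*"), 2, lo, "+")
  } else {
    W <- matrix(0, side^2, n_features)
  }
  colnames(W) <- feature_names
  structure(list(side = side, weights = W,
                 feature_names = feature_names),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$side, "x", x$side, " toroidal map, ",
      ncol(x$weights), " features per neuron\n", sep = "")
  invisible(x)
}

# Internal: neuron index (1-based, row-major) <-> 0-based coordinates.
neuron_coords <- function(k, side) {
  cbind(row = (k - 1L) %/% side, col = (k - 1L) %% side)
}
coords_neuron <- function(row, col, side) row * side + col + 1L

#' Toroidal topological distance between two neurons
#'
#' Chebyshev ring distance with wrap-around:
#' `max over axes of min(|delta|, side - |delta|)`. Square rings of
#' neighbours expand around the winning neuron on the torus.
#'
#' @param pos_j,pos_c length-2 integer vectors of 0-based `(row, col)`
#'   coordinates.
#' @param side grid side length.
#' @return non-negative integer distance.
#' @export
toroidal_distance <- function(pos_j, pos_c, side) {
  pos_j <- as.integer(pos_j); pos_c <- as.integer(pos_c)
  if (any(c(pos_j, pos_c) < 0) || any(c(pos_j, pos_c) >= side))
    stop("coordinates must lie in [0, side)")
  d <- abs(pos_j - pos_c)
  max(pmin(d, side - d))
}

#' Best matching unit
#'
#' Finds the neuron whose weight vector minimises the Euclidean distance to
#' `x`; ties are broken towards the smallest row-major neuron index.
#'
#' @param grid a [som_grid()].
#' @param x numeric vector of length `n_features`.
#' @param block_weights optional per-feature multipliers applied inside the
#'   distance (used by the supervised Kohonen network's class-block
#'   weighting).
#' @return list with `index` (1-based neuron index) and `coords`
#'   (0-based `(row, col)`).
#' @export
find_bmu <- function(grid, x, block_weights = NULL) {
  if (!all(is.finite(x))) stop("query vector must be finite")
  if (length(x) != ncol(grid$weights))
    stop("query length ", length(x), " != n_features ", ncol(grid$weights))
  diff <- sweep(grid$weights, 2, x)
  if (!is.null(block_weights)) diff <- sweep(diff, 2, block_weights, "*")
  k <- which.min(rowSums(diff^2))
  list(index = k, coords = as.integer(neuron_coords(k, grid$side)))
}

#' Triangular neighbourhood kernel
#'
#' `a(d) = max(0, 1 - d / (radius + 1))`: the winner (`d = 0`) receives the
#' full update (`a = 1`), the factor decays linearly with topological
#' distance and vanishes at `d = radius + 1`.
#'
#' @param a_distance topological distance to the winner (non-negative).
#' @param radius current neighbourhood radius (non-negative).
#' @return kernel value in `[0, 1]`.
#' @export
neighborhood <- function(a_distance, radius) {
  stopifnot(all(a_distance >= 0), radius >= 0)
  pmax(0, 1 - a_distance / (radius + 1))
}

#' One Kohonen weight update
#'
#' Applies `w_new = w_old + eta * a(d_j - d_c) * (x - w_old)` to every
#' neuron, where `d_j - d_c` is the toroidal distance to the best matching
#' unit and `a` the triangular kernel. Neurons with a vanishing kernel are
#' untouched.
#'
#' @param grid a [som_grid()].
#' @param x the presented feature vector.
#' @param bmu 0-based `(row, col)` of the winning neuron.
#' @param eta learning rate in (0, 1].
#' @param radius neighbourhood radius.
#' @return The updated `som_grid`.
#' @export
update_weights <- function(grid, x, bmu, eta, radius) {
  stopifnot(eta > 0, eta <= 1)
  side <- grid$side
  ks <- seq_len(side^2)
  pos <- neuron_coords(ks, side)
  dr <- abs(pos[, "row"] - bmu[1]); dc <- abs(pos[, "col"] - bmu[2])
  d <- pmax(pmin(dr, side - dr), pmin(dc, side - dc))
  a <- neighborhood(d, radius)
  act <- a > 0
  grid$weights[act, ] <- grid$weights[act, , drop = FALSE] +
    (eta * a[act]) * sweep(-grid$weights[act, , drop = FALSE], 2, x, "+")
  grid
}

#' Training schedule for SOM learning
#'
#' Learning rate and neighbourhood radius both decay linearly over epochs
#' from their start to their end values; within an epoch they are constant.
#'
#' @param epochs number of passes over the training set.
#' @param eta_start,eta_end learning-rate endpoints (defaults 0.5 and 0.01).
#' @param radius_start,radius_end radius endpoints; `radius_start = NULL`
#'   defers to `side / 2` at training time.
#' @param seed integer seed for weight initialisation and per-epoch
#'   presentation-order shuffling.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(epochs = 100, eta_start = 0.5, eta_end = 0.01,
                              radius_start = NULL, radius_end = 0, seed = 1) {
  stopifnot(epochs >= 1, eta_start > 0, eta_start <= 1,
            eta_end >= 0, eta_end < eta_start)
  structure(list(epochs = as.integer(epochs), eta_start = eta_start,
                 eta_end = eta_end, radius_start = radius_start,
                 radius_end = radius_end, seed = as.integer(seed)),
            class = "training_schedule")
}

#' Schedule values at a given epoch
#'
#' Linear interpolation between the start (epoch 0) and end
#' (epoch `epochs - 1`) values.
#'
#' @param schedule a [training_schedule()]; `radius_start` must be resolved.
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return list with `eta` and `radius`.
#' @export
schedule_at <- function(schedule, epoch) {
  if (epoch < 0 || epoch >= schedule$epochs) stop("epoch out of range")
  frac <- if (schedule$epochs == 1) 0 else epoch / (schedule$epochs - 1)
  list(eta = schedule$eta_start +
         frac * (schedule$eta_end - schedule$eta_start),
       radius = schedule$radius_start +
         frac * (schedule$radius_end - schedule$radius_start))
}

# Internal: resolve deferred schedule fields against a grid side.
resolve_schedule <- function(schedule, side) {
  if (is.null(schedule$radius_start)) schedule$radius_start <- side / 2
  schedule
}

# Internal: run the compiled training loop. `X` is the BMU-space data
# (n x f_bmu), `targets` the update-space data (n x f_upd); for CPANN the
# two spaces differ (Kohonen vs Kohonen+Grossberg), for SKN they coincide.
run_som_training <- function(weights, X, targets, schedule, side,
                             bmu_feature_weights) {
  sched <- resolve_schedule(schedule, side)
  epochs <- sched$epochs
  eta <- vapply(seq_len(epochs) - 1,
                function(e) schedule_at(sched, e)$eta, numeric(1))
  radius <- vapply(seq_len(epochs) - 1,
                   function(e) schedule_at(sched, e)$radius, numeric(1))
  order_mat <- withr::with_seed(sched$seed + 1L, {
    vapply(seq_len(epochs), function(e) sample.int(nrow(X)),
           integer(nrow(X)))
  })
  som_train_cpp(weights, X, targets, order_mat - 1L, eta, radius,
                as.integer(side), bmu_feature_weights)
}
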