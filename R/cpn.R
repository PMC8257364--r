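#' Training schedule for the Counterpropagation Network
#'
#' The SOM rate `alpha`, the outstar rate `gamma` and the neighbourhood
#' radius all decay linearly over the training run (t = presentation
#' counter, T = epochs x records): `alpha(t) = alpha0 * (1 - t/T)`,
#' `gamma(t) = gamma0 * (1 - t/T)`, and the radius falls linearly from
#' `radius0` to 0 over the first half of training, after which updates are
#' winner-only.
#'
#' @param epochs Number of passes over the training set (>= 0).
#' @param alpha0 Initial SOM learning rate in (0, 1].
#' @param gamma0 Initial outstar learning rate in (0, 1].
#' @param radius0 Initial neighbourhood radius; `NULL` means
#'   `max(rows, cols) / 2` of the lattice used at training time.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(epochs = 100L, alpha0 = 0.5, gamma0 = 0.1,
                              radius0 = NULL) {
  if (!is.numeric(epochs) || epochs != round(epochs) || epochs < 0) {
    stop("epochs must be a non-negative integer", call. = FALSE)
  }
  if (alpha0 <= 0 || alpha0 > 1) stop("alpha0 must be in (0, 1]", call. = FALSE)
  if (gamma0 <= 0 || gamma0 > 1) stop("gamma0 must be in (0, 1]", call. = FALSE)
  if (!is.null(radius0) && radius0 < 0) stop("radius0 must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), alpha0 = alpha0,
                 gamma0 = gamma0, radius0 = radius0),
            class = "training_schedule")
}

#' SOM unit activations (input-to-prototype distances)
#'
#' The competitive layer's net input is the Euclidean distance between the
#' input vector and each unit's prototype.
#'
#' @param x Scaled input vector.
#' @param w Prototype matrix, `units x input_dim`.
#' @return Numeric vector of non-negative distances, one per unit.
#' @export
som_activations <- function(x, w) {
  if (!is.matrix(w)) w <- matrix(w, nrow = 1L)
  if (length(x) != ncol(w)) stop("dimension mismatch", call. = FALSE)
  sqrt(colSums((t(w) - as.numeric(x))^2))
}

#' Winner-take-all competition
#'
#' @param nets Non-empty distance vector from [som_activations()].
#' @return One-hot numeric vector with 1 at the minimum distance; ties are
#'   broken toward the lowest index so replays are deterministic.
#' @export
compete <- function(nets) {
  if (length(nets) == 0L) stop("empty activation vector", call. = FALSE)
  u <- numeric(length(nets))
  u[which.min(nets)] <- 1
  u
}

#' SOM prototype update
#'
#' Pulls every unit in the neighbourhood toward the input:
#' `w_l <- w_l + alpha * (x - w_l)` for `l` in `nbrs`, other units
#' unchanged. With inputs in the unit hypercube and `alpha` in (0, 1] this
#' is a convex combination, so prototypes never leave `[0,1]^k`.
#'
#' @param x Scaled input vector.
#' @param w Prototype matrix.
#' @param nbrs Integer vector of unit indices (from [neighborhood()]).
#' @param alpha Learning rate in (0, 1].
#' @return Updated prototype matrix.
#' @export
som_update <- function(x, w, nbrs, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  x <- as.numeric(x)
  w[nbrs, ] <- w[nbrs, , drop = FALSE] +
    alpha * (matrix(x, nrow = length(nbrs), ncol = length(x), byrow = TRUE) -
               w[nbrs, , drop = FALSE])
  w
}

#' Grossberg layer output
#'
#' Each output unit equilibrates to the readout weight on the connection
#' from the winning competitive unit: `y_j = sum_l u_l z_jl = z_j,winner`.
#'
#' @param u One-hot competition vector.
#' @param z Readout weight matrix, `output_dim x units` (a plain vector is
#'   treated as a single-output row).
#' @return Numeric output vector of length `output_dim`.
#' @export
grossberg_output <- function(u, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (length(u) != ncol(z) || sum(u == 1) != 1L || any(!u %in% c(0, 1))) {
    stop("u must be one-hot over the map units", call. = FALSE)
  }
  as.numeric(z[, which(u == 1)])
}

#' Outstar readout update
#'
#' Only the winning unit's outgoing weights move, by a convex pull toward
#' the desired output: `z_j,winner <- z_j,winner + gamma * (d_j - y_j)`.
#'
#' @param z Readout weight matrix (`output_dim x units`) or vector.
#' @param u One-hot competition vector.
#' @param y Current output (from [grossberg_output()]).
#' @param d Desired output (the 0/1 diagnosis during training).
#' @param gamma Learning rate in (0, 1].
#' @return Updated readout weights, same shape as `z`.
#' @export
outstar_update <- function(z, u, y, d, gamma) {
  stopifnot(gamma > 0, gamma <= 1)
  vec <- !is.matrix(z)
  if (vec) z <- matrix(z, nrow = 1L)
  winner <- which(u == 1)
  if (length(winner) != 1L) stop("u must be one-hot", call. = FALSE)
  z[, winner] <- z[, winner] + gamma * (d - y)
  if (vec) as.numeric(z) else z
}

#' Train a Counterpropagation Network
#'
#' Features are min--max scaled on the training cohort, SOM prototypes are
#' initialized from a seeded uniform on `[0,1]` and the single Grossberg
#' output weight per unit starts at 0.5 (maximal uncertainty). Each epoch
#' presents the records in a seeded shuffled order; for every presentation
#' the winner is found by Euclidean distance, the winner's neighbourhood is
#' pulled toward the input, and the winner's readout weight is pulled
#' toward the 0/1 diagnosis — both layers train simultaneously. Rates and
#' radius decay per the [training_schedule()]. The classification threshold
#' is initialized at 0.5; see [balanced_threshold()] and [set_threshold()].
#'
#' @param train Training [cohort()] containing both classes.
#' @param subset Character vector of feature names (the network inputs).
#' @param geometry A [lattice_geometry()].
#' @param schedule A [training_schedule()].
#' @param seed Integer seed; training is deterministic given it.
#' @return An object of class `cpn_model`.
#' @export
train_cpn <- function(train, subset, geometry = lattice_geometry(),
                      schedule = training_schedule(), seed = 1L) {
  stopifnot(inherits(train, "cohort"), inherits(geometry, "lattice_geometry"),
            inherits(schedule, "training_schedule"))
  if (length(unique(train$label)) < 2L) {
    stop("training cohort must contain both classes", call. = FALSE)
  }
  scaling <- fit_scaling(train, subset)
  X <- apply_scaling(scaling, train)
  d <- as.numeric(train$label)
  n <- nrow(X)
  k <- ncol(X)
  units <- geometry$units
  radius0 <- schedule$radius0 %||% (max(geometry$rows, geometry$cols) / 2)

  set.seed(seed)
  w <- matrix(runif(units * k), nrow = units)
  z <- rep(0.5, units)

  n_pres <- schedule$epochs * n
  if (n_pres > 0L) {
    order <- unlist(lapply(seq_len(schedule$epochs),
                           function(e) sample.int(n)))
    t_seq <- seq_len(n_pres)
    alpha <- schedule$alpha0 * (1 - t_seq / n_pres)
    gamma <- schedule$gamma0 * (1 - t_seq / n_pres)
    radius <- radius0 * pmax(0, 1 - 2 * t_seq / n_pres)
    res <- cpn_train_cpp(X, d, w, z, order - 1L, alpha, gamma, radius,
                         lattice_distances(geometry))
    w <- res$w
    z <- as.numeric(res$z)
  }
  dimnames(w) <- list(NULL, subset)
  structure(list(som = list(geometry = geometry, w = w),
                 grossberg = list(z = z),
                 threshold = 0.5,
                 scaling = scaling,
                 subset = subset,
                 schedule = schedule,
                 seed = as.integer(seed)),
            class = "cpn_model")
}

#' @export
print.cpn_model <- function(x, ...) {
  g <- x$som$geometry
  cat(sprintf(
    "<cpn_model> %s | %dx%d %s %s map | threshold %.3f | seed %d\n",
    subset_label(x$subset), g$rows, g$cols, g$shape, g$wrap, x$threshold,
    x$seed))
  invisible(x)
}

#' MCI score of the network
#'
#' Scales the record(s) with the model's training scaling (clipping to the
#' training range), finds the winning SOM unit and returns its Grossberg
#' readout weight — a score in `[0,1]` interpreted as support for MCI.
#'
#' @param model A `cpn_model`.
#' @param data A [cohort()], data frame or named numeric vector.
#' @return Numeric vector of scores in `[0,1]`.
#' @export
cpn_score <- function(model, data) {
  stopifnot(inherits(model, "cpn_model"))
  X <- apply_scaling(model$scaling, data)
  w <- model$som$w
  z <- model$grossberg$z
  vapply(seq_len(nrow(X)), function(i) {
    z[which.min(som_activations(X[i, ], w))]
  }, numeric(1))
}

#' Classify records with the network
#'
#' A record is called MCI when its score is strictly greater than the
#' threshold (a score exactly at the threshold is classed control).
#'
#' @inheritParams cpn_score
#' @param threshold Decision threshold; defaults to the model's.
#' @return Integer vector of 0/1 class labels.
#' @export
cpn_classify <- function(model, data, threshold = model$threshold) {
  as.integer(cpn_score(model, data) > threshold)
}

#' Set the decision threshold of a model
#'
#' @param model A `cpn_model`.
#' @param threshold New threshold in `[0, 1]`.
#' @return The model with the threshold replaced.
#' @export
set_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "cpn_model"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  model$threshold <- threshold
  model
}

#' Serialize a model to JSON
#'
#' Writes a versioned JSON document holding the lattice geometry, schedule,
#' weight matrices, threshold, scaling spec and feature subset, so a model
#' can be stored and reloaded with [read_cpn_model()].
#'
#' @param model A `cpn_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cpn_model <- function(model, path) {
  stopifnot(inherits(model, "cpn_model"))
  doc <- list(
    format = "cpnmci-model",
    version = "1.0",
    subset = model$subset,
    threshold = model$threshold,
    seed = model$seed,
    geometry = model$som$geometry[c("shape", "wrap", "rows", "cols")],
    schedule = model$schedule[c("epochs", "alpha0", "gamma0", "radius0")],
    scaling = list(features = model$scaling$features,
                   min = vapply(model$scaling$ranges, `[[`, numeric(1), "min"),
                   max = vapply(model$scaling$ranges, `[[`, numeric(1), "max")),
    som_w = model$som$w,
    grossberg_z = model$grossberg$z
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_cpn_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `cpn_model`.
#' @export
read_cpn_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cpnmci-model")) {
    stop("not a cpnmci model file: ", path, call. = FALSE)
  }
  geometry <- lattice_geometry(doc$geometry$shape, doc$geometry$wrap,
                               doc$geometry$rows, doc$geometry$cols)
  radius0 <- doc$schedule$radius0
  if (is.null(radius0) || length(radius0) == 0L || all(is.na(radius0))) {
    radius0 <- NULL
  }
  schedule <- training_schedule(doc$schedule$epochs, doc$schedule$alpha0,
                                doc$schedule$gamma0, radius0)
  subset <- as.character(doc$subset)
  ranges <- lapply(seq_along(subset), function(i) {
    c(min = doc$scaling$min[i], max = doc$scaling$max[i])
  })
  names(ranges) <- as.character(doc$scaling$features)
  scaling <- structure(list(ranges = ranges[subset], features = subset),
                       class = "scaling_spec")
  w <- matrix(as.numeric(doc$som_w), nrow = geometry$units,
              dimnames = list(NULL, subset))
  structure(list(som = list(geometry = geometry, w = w),
                 grossberg = list(z = as.numeric(doc$grossberg_z)),
                 threshold = doc$threshold,
                 scaling = scaling,
                 subset = subset,
                 schedule = schedule,
                 seed = as.integer(doc$seed)),
            class = "cpn_model")
}
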