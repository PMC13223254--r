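# Grey Wolf Optimization over mixed continuous / integer / categorical
# hyperparameter spaces. The three best wolves (alpha, beta, delta)
# steer the pack; the exploration coefficient decays linearly from 2 to
# 0 over the run. Fitness is maximized.

#' Define a hyperparameter search space
#'
#' @param ... Named dimensions, each created with [dim_continuous()],
#'   [dim_integer()] or [dim_categorical()].
#' @return A `search_space` list of dimensions.
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L) stop("search space needs at least one dimension")
  if (is.null(names(dims)) || any(names(dims) == ""))
    stop("every dimension must be named")
  for (d in dims) if (!inherits(d, "space_dim")) stop("dimensions must be built with dim_*()")
  structure(dims, class = "search_space")
}

#' @rdname search_space
#' @param lower,upper Bounds (lower < upper).
#' @export
dim_continuous <- function(lower, upper) {
  if (!(lower < upper)) stop("need lower < upper")
  structure(list(kind = "continuous", lower = lower, upper = upper),
            class = "space_dim")
}

#' @rdname search_space
#' @export
dim_integer <- function(lower, upper) {
  if (!(lower < upper)) stop("need lower < upper")
  structure(list(kind = "integer", lower = lower, upper = upper),
            class = "space_dim")
}

#' @rdname search_space
#' @param categories Character vector of at least two categories.
#' @export
dim_categorical <- function(categories) {
  if (length(categories) < 2L) stop("need at least 2 categories")
  structure(list(kind = "categorical", lower = 1, upper = length(categories),
                 categories = as.character(categories)),
            class = "space_dim")
}

space_bounds <- function(space) {
  list(lower = vapply(space, `[[`, numeric(1), "lower"),
       upper = vapply(space, `[[`, numeric(1), "upper"))
}

#' GWO configuration
#'
#' @param n_wolves Pack size, at least 3 (the alpha, beta and delta
#'   leaders must exist). Default 10.
#' @param n_iters Number of position-update iterations. Default 20.
#' @param seed Integer seed; the whole run is reproducible.
#' @param alpha_only If `TRUE`, wolves move toward the alpha leader
#'   alone (the bare position-update rule) instead of averaging the
#'   three-leader candidates; kept for fidelity experiments.
#' @return A `gwo_config` list.
#' @export
gwo_config <- function(n_wolves = 10L, n_iters = 20L, seed = 0L,
                       alpha_only = FALSE) {
  if (n_wolves < 3L) stop("`n_wolves` must be at least 3")
  if (n_iters < 1L) stop("`n_iters` must be at least 1")
  structure(list(n_wolves = as.integer(n_wolves),
                 n_iters = as.integer(n_iters),
                 seed = as.integer(seed), alpha_only = isTRUE(alpha_only)),
            class = "gwo_config")
}

#' Initialize the wolf pack
#'
#' Positions drawn uniformly within each dimension's bounds,
#' deterministic under the configuration seed.
#'
#' @param space A [search_space()].
#' @param cfg A [gwo_config()].
#' @return Numeric matrix, `n_wolves` rows x one column per dimension.
#' @export
initialize_pack <- function(space, cfg = gwo_config()) {
  b <- space_bounds(space)
  with_seed(cfg$seed, {
    m <- matrix(runif(cfg$n_wolves * length(space)), cfg$n_wolves)
    sweep(sweep(m, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
  })
}

#' One GWO position update
#'
#' Identifies the alpha, beta and delta wolves (three best fitnesses,
#' ties broken by lowest index), computes the exploration coefficient
#' `a = 2 (1 - t / n_iters)`, and moves every wolf toward each leader
#' via the standard `B = 2 a r1 - a`, `E = |2 r2 * leader - pos|`
#' coefficients, averaging the three candidate positions (or using the
#' alpha candidate alone in `alpha_only` mode). Positions are clipped to
#' the bounds. Randomness comes from the current RNG stream; seed it via
#' [gwo_optimize()].
#'
#' @param positions Matrix of wolf positions.
#' @param fitnesses Numeric vector, one fitness per wolf (maximized).
#' @param t Iteration number, 1..`n_iters`.
#' @param space A [search_space()].
#' @param cfg A [gwo_config()].
#' @return Updated position matrix.
#' @export
update_positions <- function(positions, fitnesses, t, space, cfg = gwo_config()) {
  n <- nrow(positions); d <- ncol(positions)
  if (n < 3L) stop("at least 3 wolves required")
  b <- space_bounds(space)
  lead <- order(-fitnesses)[1:3]          # order() breaks ties by index
  a <- 2 * (1 - t / cfg$n_iters)
  cand <- array(0, dim = c(n, d, 3))
  for (k in 1:3) {
    leader <- matrix(positions[lead[k], ], n, d, byrow = TRUE)
    r1 <- matrix(runif(n * d), n, d)
    r2 <- matrix(runif(n * d), n, d)
    B <- 2 * a * r1 - a
    E <- abs(2 * r2 * leader - positions)
    cand[, , k] <- leader - B * E
  }
  new <- if (cfg$alpha_only) cand[, , 1] else (cand[, , 1] + cand[, , 2] + cand[, , 3]) / 3
  new <- pmin(pmax(new, matrix(b$lower, n, d, byrow = TRUE)),
              matrix(b$upper, n, d, byrow = TRUE))
  matrix(new, n, d)
}

#' Decode a position into a hyperparameter assignment
#'
#' Continuous coordinates pass through; integer coordinates are rounded
#' to the nearest integer and clamped; categorical coordinates are
#' rounded to an index into the category list.
#'
#' @param position Numeric vector, one coordinate per dimension.
#' @param space A [search_space()].
#' @return Named list of hyperparameter values.
#' @export
decode_position <- function(position, space) {
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (j in seq_along(space)) {
    d <- space[[j]]; v <- position[j]
    out[[j]] <- switch(d$kind,
      continuous = min(max(v, d$lower), d$upper),
      integer = as.integer(min(max(round(v), d$lower), d$upper)),
      categorical = d$categories[as.integer(min(max(round(v), 1), length(d$categories)))])
  }
  out
}

# encode an assignment back to a position (for seeding known-good points)
encode_assignment <- function(assignment, space) {
  vapply(seq_along(space), function(j) {
    d <- space[[j]]; v <- assignment[[names(space)[j]]]
    if (d$kind == "categorical") match(v, d$categories) else as.numeric(v)
  }, numeric(1))
}

#' Run Grey Wolf Optimization
#'
#' Maximizes `fitness` over the search space. The pack is evaluated once
#' after initialization and once per iteration, for
#' `n_wolves * (n_iters + 1)` fitness evaluations in total. The
#' best-so-far assignment and fitness are tracked, so `history` is
#' non-decreasing.
#'
#' @param fitness Function taking a decoded assignment (named list) and
#'   returning a scalar to maximize.
#' @param space A [search_space()].
#' @param cfg A [gwo_config()].
#' @param init Optional list of assignments (named lists) seeded into
#'   the pack as its first positions — e.g. a classifier's default
#'   hyperparameters, guaranteeing the tuned result is at least as fit.
#' @return An `opt_result` list: `best_params`, `best_fitness`,
#'   `history` (length `n_iters + 1`), `n_evals`.
#' @export
gwo_optimize <- function(fitness, space, cfg = gwo_config(), init = NULL) {
  eval_fit <- function(pos) {
    asg <- decode_position(pos, space)
    val <- tryCatch(fitness(asg), error = function(e)
      stop("fitness failed for assignment {",
           paste(names(asg), vapply(asg, format, character(1)), sep = "=",
                 collapse = ", "), "}: ", conditionMessage(e)))
    as.numeric(val)
  }
  positions <- initialize_pack(space, cfg)
  if (!is.null(init)) {
    for (k in seq_along(init))
      positions[k, ] <- encode_assignment(init[[k]], space)
  }
  with_seed(cfg$seed + 1L, {
    fit <- apply(positions, 1, eval_fit)
    best_i <- which.max(fit)
    best_pos <- positions[best_i, ]
    best_fit <- fit[best_i]
    history <- best_fit
    for (t in seq_len(cfg$n_iters)) {
      positions <- update_positions(positions, fit, t, space, cfg)
      fit <- apply(positions, 1, eval_fit)
      if (max(fit) > best_fit) {
        best_i <- which.max(fit)
        best_fit <- fit[best_i]
        best_pos <- positions[best_i, ]
      }
      history <- c(history, best_fit)
    }
    structure(list(best_params = decode_position(best_pos, space),
                   best_fitness = best_fit, history = history,
                   n_evals = cfg$n_wolves * (cfg$n_iters + 1L)),
              class = "opt_result")
  })
}

#' Random-search baseline with the same evaluation budget
#'
#' Draws `n_evals` uniform positions and returns the best decoded
#' assignment; the natural control when judging whether GWO's guided
#' search earns its keep.
#'
#' @inheritParams gwo_optimize
#' @param n_evals Number of fitness evaluations.
#' @param seed Integer seed.
#' @return An `opt_result` list.
#' @export
random_search <- function(fitness, space, n_evals, seed = 0L) {
  b <- space_bounds(space)
  with_seed(seed, {
    best_fit <- -Inf; best_asg <- NULL; history <- numeric(0)
    for (k in seq_len(n_evals)) {
      pos <- b$lower + runif(length(space)) * (b$upper - b$lower)
      asg <- decode_position(pos, space)
      v <- as.numeric(fitness(asg))
      if (v > best_fit) { best_fit <- v; best_asg <- asg }
      history <- c(history, best_fit)
    }
    structure(list(best_params = best_asg, best_fitness = best_fit,
                   history = history, n_evals = n_evals),
              class = "opt_result")
  })
}
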