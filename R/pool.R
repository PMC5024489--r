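#' Reproducible random source with independent streams
#'
#' Wraps R's RNG so that identifier drawing is reproducible from an explicit
#' seed while distinct purposes (number draws vs. key-file row shuffling) use
#' independent streams: seeding a run does not let the shuffled row order of
#' the study file leak the draw order. Each source keeps its own RNG state;
#' evaluating under a source never disturbs the global RNG or other sources.
#' With `seed = NULL` the stream is initialized from R's own entropy-based
#' seeding, giving non-reproducible draws.
#'
#' @param seed Optional non-negative integer seed.
#' @param stream Stream label; same seed + same label gives the identical
#'   draw sequence, different labels give unrelated sequences.
#' @return An `rng_source` object.
#' @examples
#' r1 <- rng_source(42, "draw")
#' r2 <- rng_source(42, "draw")
#' identical(rng_eval(r1, runif(3)), rng_eval(r2, runif(3)))
#' @export
rng_source <- function(seed = NULL, stream = "draw") {
  env <- new.env(parent = emptyenv())
  env$seed <- seed
  env$stream <- stream
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(restore_rng_state(old))
    if (is.null(seed)) {
      set.seed(NULL)
    } else {
      # fold the stream label into the seed; keep the result in 32-bit range
      h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
      set.seed((as.numeric(seed) %% 2^31 + h * 10007) %% (2^31 - 1))
    }
    get(".Random.seed", globalenv())
  })
  class(env) <- "rng_source"
  env
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @rdname rng_source
#' @param rng An `rng_source`.
#' @param expr Expression evaluated under the source's RNG state.
#' @export
rng_eval <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_source"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    restore_rng_state(old)
  })
  expr
}

#' Pool of guaranteed-unique random numbers for one layer
#'
#' A pool tracks which numbers of a layer's interval have already been issued
#' (across batches of one study) and draws new ones guaranteed distinct from
#' all previous draws. Membership is kept in a hash environment, so duplicate
#' checks cost O(1) per candidate. The pool is a mutable object: drawing
#' records the issued numbers in place.
#'
#' @param k Random-number length.
#' @param layer `"P"`, `"S"`, `"T"` or `"E"` (external: the (k+1)-digit pool).
#' @param used Optional numeric vector of numbers already issued (e.g.
#'   reconstructed from a study directory).
#' @return A `number_pool` object.
#' @seealso [draw_unique()]
#' @export
number_pool <- function(k, layer = c("P", "S", "T", "E"), used = numeric(0)) {
  layer <- match.arg(toupper(layer), c("P", "S", "T", "E"))
  iv <- if (layer == "E") external_interval(k) else layer_interval(k, layer)
  pool <- new.env(parent = emptyenv())
  pool$k <- k
  pool$layer <- layer
  pool$lower <- iv$lower
  pool$upper <- iv$upper
  pool$used <- new.env(parent = emptyenv(), size = max(29L, length(used)))
  pool$n_used <- 0L
  class(pool) <- "number_pool"
  if (length(used) > 0L) pool_record(pool, used)
  pool
}

pool_record <- function(pool, values) {
  values <- as.numeric(values)
  out <- values < pool$lower | values >= pool$upper
  if (any(out)) {
    stop("number(s) outside the ", pool$layer, " interval [",
         format(pool$lower, scientific = FALSE), "; ",
         format(pool$upper, scientific = FALSE), "): ",
         paste(format(values[out], scientific = FALSE), collapse = ", "),
         call. = FALSE)
  }
  for (v in values) {
    key <- format(v, scientific = FALSE)
    if (!exists(key, pool$used, inherits = FALSE)) {
      assign(key, TRUE, envir = pool$used)
      pool$n_used <- pool$n_used + 1L
    }
  }
  invisible(pool)
}

pool_has <- function(pool, value) {
  exists(format(value, scientific = FALSE), pool$used, inherits = FALSE)
}

pool_used_values <- function(pool) {
  as.numeric(ls(pool$used, sorted = FALSE))
}

#' @export
print.number_pool <- function(x, ...) {
  cat(sprintf("<number_pool> layer %s, [%s; %s), %s of %s used\n", x$layer,
              format(x$lower, big.mark = ",", scientific = FALSE),
              format(x$upper, big.mark = ",", scientific = FALSE),
              format(x$n_used, big.mark = ","),
              format(x$upper - x$lower, big.mark = ",")))
  invisible(x)
}

#' Draw guaranteed-unique random numbers from a pool
#'
#' Draws `n` numbers uniformly from the pool's interval, each distinct from
#' every number previously issued by this pool (and from each other), and
#' records them as used. Requests that cannot be satisfied fail before any
#' draw. Two strategies, both uniform over the unissued numbers: rejection
#' sampling while the request is small relative to the remaining capacity,
#' and direct sampling without replacement from the residual set once the
#' request exceeds half of what remains (rejection would slow down sharply as
#' the pool fills).
#'
#' @param pool A [number_pool()]; updated in place.
#' @param n Number of values to draw.
#' @param rng An [rng_source()]; defaults to an entropy-seeded one.
#' @param progress Print percentage progress for long draws.
#' @return Numeric vector of `n` distinct numbers, in draw order.
#' @examples
#' p <- number_pool(3, "P")
#' draw_unique(p, 5, rng_source(1))
#' @export
draw_unique <- function(pool, n, rng = rng_source(), progress = FALSE) {
  stopifnot(inherits(pool, "number_pool"))
  n <- as.numeric(n)
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 1) {
    stop("n must be a positive whole number", call. = FALSE)
  }
  size <- pool$upper - pool$lower
  remaining <- size - pool$n_used
  if (n > remaining) {
    stop(sprintf(
      "pool exhausted: %s requested but only %s of %s %s-layer numbers remain",
      format(n, big.mark = ","), format(remaining, big.mark = ","),
      format(size, big.mark = ","), pool$layer), call. = FALSE)
  }

  # dense request: enumerate the residual set and sample without replacement
  if (n > remaining / 2 && size <= 1e7) {
    all_vals <- seq(pool$lower, pool$upper - 1)
    residual <- if (pool$n_used > 0L) {
      all_vals[!all_vals %in% pool_used_values(pool)]
    } else all_vals
    drawn <- as.numeric(rng_eval(rng, residual[sample.int(length(residual), n)]))
    pool_record(pool, drawn)
    return(drawn)
  }

  drawn <- numeric(n)
  got <- 0L
  next_report <- 0.01
  while (got < n) {
    m <- max(64L, ceiling((n - got) * 1.3))
    cand <- rng_eval(rng, pool$lower + floor(stats::runif(m) * size))
    cand <- cand[cand < pool$upper] # guard the (measure-zero) upper edge
    for (v in cand) {
      if (got == n) break
      if (!pool_has(pool, v)) {
        pool_record(pool, v)
        got <- got + 1L
        drawn[got] <- v
        if (progress && got / n >= next_report) {
          cat(sprintf("\r  %s layer: %3.0f%%", pool$layer, 100 * got / n))
          next_report <- next_report + 0.01
        }
      }
    }
  }
  if (progress) cat("\n")
  drawn
}
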