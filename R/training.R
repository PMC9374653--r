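# private RNG streams: schedulers and sessions each own an isolated RNG
# state so draws are deterministic given (seed, response sequence) and never
# disturb the caller's RNG
new_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- withr::with_seed(as.integer(seed), .Random.seed)
  e
}

rng_eval <- function(rng, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  fn()
}

#' Configuration for a training session scheduler
#'
#' @param pools named list (one entry per category, at least two) of lists
#'   of \code{sc_stimulus}: the stimulus pool per category.
#' @param prototypes named list of the category base stimuli (prototypes),
#'   names matching \code{pools}.  Required by the prototype scheduler; used
#'   by the exemplar scheduler to purge bases from the pool.
#' @param criterion rolling-accuracy criterion in \code{(0, 1]} that triggers
#'   set-size advancement ("at or above"); default 0.80.
#' @param window number of most recent trials the rolling accuracy is
#'   computed over; advancement is only evaluated once a full window has
#'   accumulated since the last advancement.
#' @param growth_factor multiplier applied to the per-category set size on
#'   advancement (default 2: performance-dependent doubling).
#' @param max_set_size cap on the per-category set size.
#' @param seed integer seed driving all scheduler draws.
#' @return an object of class \code{sc_session_config}.
#' @export
session_config <- function(pools, prototypes = NULL, criterion = 0.8,
                           window = 20L, growth_factor = 2L,
                           max_set_size = Inf, seed = 1L) {
  if (!is.list(pools) || length(pools) < 2 || is.null(names(pools)) ||
      any(!nzchar(names(pools))))
    stop_arg("`pools` must be a named list with at least two categories")
  if (any(vapply(pools, length, integer(1)) < 1))
    stop_arg("every category pool must be nonempty")
  if (!is.null(prototypes) &&
      !setequal(names(prototypes), names(pools)))
    stop_arg("`prototypes` names must match `pools` names")
  if (!is.numeric(criterion) || criterion <= 0 || criterion > 1)
    stop_arg("`criterion` must be in (0, 1]")
  if (!is_count(window)) stop_arg("`window` must be a positive integer")
  if (!is_count(growth_factor, 2L))
    stop_arg("`growth_factor` must be an integer >= 2")
  structure(list(pools = pools, prototypes = prototypes,
                 criterion = criterion, window = as.integer(window),
                 growth_factor = as.integer(growth_factor),
                 max_set_size = max_set_size, seed = as.integer(seed)),
            class = "sc_session_config")
}

new_scheduler <- function(protocol, env) {
  structure(list(protocol = protocol,
                 next_trial = env$next_trial,
                 record = env$record,
                 state = env$state_fn),
            class = "sc_scheduler")
}

#' @export
print.sc_scheduler <- function(x, ...) {
  st <- x$state()
  cat(sprintf("<sc_scheduler> protocol = %s, trials so far = %d\n",
              x$protocol, st$trial))
  invisible(x)
}

#' Prototype-based training scheduler
#'
#' Implements the performance-dependent set-growth regime: the session
#' starts with only the category prototypes (a delayed match-to-sample
#' task), and whenever rolling accuracy over the last \code{window} trials
#' reaches the criterion ("at or above", default 80 percent) the per-category
#' set size is multiplied by \code{growth_factor}, turning the task into
#' delayed match-to-category with progressively larger, less familiar sets.
#' Pool stimuli enter the active set in order of increasing parametric
#' deviation from their prototype, so later blocks are also less similar to
#' it.  Each trial picks a category fairly at random and a stimulus
#' uniformly from that category's active set.
#'
#' The returned scheduler is stateful: call \code{$next_trial()} to get
#' \code{list(stimulus, category)}, then \code{$record(response)} with the
#' subject's category label.  \code{$state()} reports the trial count and
#' current set size.  The trial sequence is a pure function of the config
#' seed and the response sequence.
#'
#' @param config an \code{\link{session_config}} with \code{prototypes}.
#' @param similarity_order add pool stimuli in order of increasing deviation
#'   from the prototype (default) or, if \code{FALSE}, in pool order.
#' @return an \code{sc_scheduler}.
#' @export
prototype_scheduler <- function(config, similarity_order = TRUE) {
  if (!inherits(config, "sc_session_config"))
    stop_arg("`config` must come from session_config()")
  if (is.null(config$prototypes))
    stop_arg("the prototype scheduler needs `prototypes` in the config")
  cats <- names(config$pools)
  ordered <- lapply(cats, function(cn) {
    pool <- config$pools[[cn]]
    if (similarity_order) {
      key <- vapply(pool, deviation_key, numeric(1),
                    ref = config$prototypes[[cn]])
      pool <- pool[order(key)]
    }
    pool
  })
  names(ordered) <- cats
  cap <- min(config$max_set_size,
             1 + min(vapply(ordered, length, integer(1))))

  e <- new.env()
  e$rng <- new_rng(config$seed)
  e$set_size <- 1L
  e$buffer <- logical(0)
  e$trial <- 0L
  e$current <- NULL

  active_set <- function(cn) {
    k <- min(e$set_size, cap)
    c(list(config$prototypes[[cn]]), head(ordered[[cn]], k - 1L))
  }
  e$next_trial <- function() {
    if (!is.null(e$current))
      stop_arg("record() the previous trial before requesting the next")
    cn <- rng_eval(e$rng, function() sample(cats, 1))
    set <- active_set(cn)
    idx <- rng_eval(e$rng, function() sample.int(length(set), 1))
    e$current <- list(stimulus = set[[idx]], category = cn)
    e$trial <- e$trial + 1L
    e$current
  }
  e$record <- function(response) {
    if (is.null(e$current)) stop_arg("no pending trial to record")
    correct <- identical(response, e$current$category)
    e$buffer <- c(e$buffer, correct)
    advanced <- FALSE
    if (length(e$buffer) >= config$window &&
        mean(tail(e$buffer, config$window)) >= config$criterion) {
      e$set_size <- min(e$set_size * config$growth_factor, cap)
      e$buffer <- logical(0)   # fresh window for the new block
      advanced <- TRUE
    }
    rec <- list(trial = e$trial, label = e$current$stimulus$label,
                true_category = e$current$category, response = response,
                correct = correct, set_size = min(e$set_size, cap),
                advanced = advanced)
    e$current <- NULL
    invisible(rec)
  }
  e$state_fn <- function() list(trial = e$trial, set_size = min(e$set_size, cap),
                                window_fill = length(e$buffer))
  new_scheduler("prototype", e)
}

#' Exemplar-based training scheduler
#'
#' Every trial draws uniformly from the entire stimulus pool from the very
#' first trial — no training blocks, no set-size state.  The category base
#' stimuli are not part of the pool; if a base is found in a pool it is
#' removed with a warning.
#'
#' @param config an \code{\link{session_config}}.
#' @return an \code{sc_scheduler} (same interface as
#'   \code{\link{prototype_scheduler}}).
#' @export
exemplar_scheduler <- function(config) {
  if (!inherits(config, "sc_session_config"))
    stop_arg("`config` must come from session_config()")
  cats <- names(config$pools)
  pool <- list(); labs <- character(0)
  for (cn in cats) {
    ps <- config$pools[[cn]]
    if (!is.null(config$prototypes)) {
      is_base <- vapply(ps, function(s)
        isTRUE(all.equal(s$spheres, config$prototypes[[cn]]$spheres)),
        logical(1))
      if (any(is_base)) {
        warning("category base found in pool for '", cn,
                "'; removed (", sum(is_base), " stimulus)", call. = FALSE)
        ps <- ps[!is_base]
      }
    }
    pool <- c(pool, ps)
    labs <- c(labs, rep(cn, length(ps)))
  }
  if (!length(pool)) stop_arg("pool is empty after removing bases")

  e <- new.env()
  e$rng <- new_rng(config$seed)
  e$trial <- 0L
  e$current <- NULL
  e$next_trial <- function() {
    if (!is.null(e$current))
      stop_arg("record() the previous trial before requesting the next")
    idx <- rng_eval(e$rng, function() sample.int(length(pool), 1))
    e$trial <- e$trial + 1L
    e$current <- list(stimulus = pool[[idx]], category = labs[idx],
                      pool_index = idx)
    e$current
  }
  e$record <- function(response) {
    if (is.null(e$current)) stop_arg("no pending trial to record")
    correct <- identical(response, e$current$category)
    rec <- list(trial = e$trial, label = e$current$stimulus$label,
                true_category = e$current$category, response = response,
                correct = correct, set_size = NA_integer_,
                advanced = FALSE)
    e$current <- NULL
    invisible(rec)
  }
  e$state_fn <- function() list(trial = e$trial, pool_size = length(pool))
  new_scheduler("exemplar", e)
}

#' Continuum training scheduler
#'
#' Trials draw uniformly from the steps of a morph continuum; the true
#' category is the side of an arbitrary boundary.  With boundary index
#' \code{b} (0-based), steps \code{0..b} belong to the first category and
#' the rest to the second.  \code{$set_boundary(new_index)} relabels
#' subsequent trials without changing the stimuli — the boundary-relearning
#' manipulation.
#'
#' @param continuum an \code{sc_continuum} from \code{\link{morph_pair}}.
#' @param boundary_index 0-based index of the last step on the first
#'   category's side; must satisfy \code{0 <= boundary_index < n_steps - 1}.
#' @param seed integer seed for the stimulus draws.
#' @param categories length-2 character vector of category labels.
#' @return an \code{sc_scheduler} with an extra \code{$set_boundary}
#'   element.
#' @export
continuum_scheduler <- function(continuum, boundary_index, seed = 1L,
                                categories = c("A", "B")) {
  if (!inherits(continuum, "sc_continuum"))
    stop_arg("`continuum` must come from morph_pair()")
  if (length(categories) != 2) stop_arg("`categories` must have length 2")
  n <- length(continuum$steps)
  check_boundary <- function(b) {
    if (!is.numeric(b) || length(b) != 1 || b != round(b) ||
        b < 0 || b >= n - 1)
      stop_arg("`boundary_index` must be an integer in [0, ", n - 2, "]")
    as.integer(b)
  }
  e <- new.env()
  e$boundary <- check_boundary(boundary_index)
  e$rng <- new_rng(seed)
  e$trial <- 0L
  e$current <- NULL
  label_of <- function(step0) {
    if (step0 <= e$boundary) categories[1] else categories[2]
  }
  e$next_trial <- function() {
    if (!is.null(e$current))
      stop_arg("record() the previous trial before requesting the next")
    idx <- rng_eval(e$rng, function() sample.int(n, 1))
    e$trial <- e$trial + 1L
    e$current <- list(stimulus = continuum$steps[[idx]],
                      category = label_of(idx - 1L), step = idx - 1L)
    e$current
  }
  e$record <- function(response) {
    if (is.null(e$current)) stop_arg("no pending trial to record")
    correct <- identical(response, e$current$category)
    rec <- list(trial = e$trial, label = e$current$stimulus$label,
                true_category = e$current$category, response = response,
                correct = correct, set_size = NA_integer_,
                advanced = FALSE, step = e$current$step)
    e$current <- NULL
    invisible(rec)
  }
  e$state_fn <- function() list(trial = e$trial, boundary = e$boundary)
  sched <- new_scheduler("continuum", e)
  sched$set_boundary <- function(new_index) {
    e$boundary <- check_boundary(new_index)
    invisible(e$boundary)
  }
  sched
}

#' Simulated observer for desk-scale session testing
#'
#' A minimal response model so scheduler behavior and qualitative
#' learning-curve predictions can be exercised without a subject.  The
#' prototype observer scores a stimulus by its parametric deviation from
#' each category's prototype; the exemplar observer by the deviation to the
#' nearest stored exemplar of each category.  Scores are turned into choice
#' probabilities with a softmax: \code{P(c) = exp(-d_c / noise)} normalized.
#' \code{noise = 0} responds deterministically with the best category;
#' \code{noise = Inf} responds at chance.
#'
#' @param kind \code{"prototype"} or \code{"exemplar"}.
#' @param refs named list: per category, a single prototype
#'   \code{sc_stimulus} (\code{kind = "prototype"}) or a list of exemplar
#'   stimuli (\code{kind = "exemplar"}).
#' @param noise nonnegative softmax temperature in deviation units.
#' @return an object of class \code{sc_observer}: a function mapping a
#'   stimulus to a named vector of response probabilities.
#' @export
simulated_observer <- function(kind = c("prototype", "exemplar"),
                               refs, noise = 0) {
  kind <- match.arg(kind)
  if (is.null(names(refs)) || length(refs) < 2)
    stop_arg("`refs` must be a named list with at least two categories")
  if (!is.numeric(noise) || noise < 0)
    stop_arg("`noise` must be nonnegative")
  score <- if (kind == "prototype") {
    function(s) vapply(refs, function(p) deviation_key(s, p), numeric(1))
  } else {
    function(s) vapply(refs, function(ex)
      min(vapply(ex, function(p) deviation_key(s, p), numeric(1))),
      numeric(1))
  }
  f <- function(stimulus) {
    d <- score(stimulus)
    if (is.infinite(noise)) {
      p <- rep(1 / length(d), length(d))
    } else if (noise == 0) {
      p <- as.numeric(seq_along(d) == which.min(d))
    } else {
      w <- exp(-(d - min(d)) / noise)
      p <- w / sum(w)
    }
    setNames(p, names(refs))
  }
  structure(f, class = c("sc_observer", "function"), kind = kind,
            noise = noise)
}

#' Run a simulated training session
#'
#' Drives a scheduler with a simulated observer for \code{n_trials} trials
#' and returns the trial log plus a learning-curve summary.  Deterministic
#' given the scheduler's seed and \code{seed} (which drives the observer's
#' response sampling).
#'
#' @param scheduler an \code{sc_scheduler}.
#' @param observer an \code{sc_observer} (or any function mapping a stimulus
#'   to named response probabilities).
#' @param n_trials number of trials to run.
#' @param seed integer seed for response sampling.
#' @param curve_window window for the rolling-accuracy curve.
#' @return a list of class \code{sc_session}: \code{trials} (a data.frame
#'   with one row per trial: stimulus label, true category, response,
#'   correctness, current set size) and \code{summary} (overall accuracy,
#'   cumulative and rolling accuracy curves).
#' @export
run_session <- function(scheduler, observer, n_trials, seed = 1L,
                        curve_window = 20L) {
  if (!inherits(scheduler, "sc_scheduler"))
    stop_arg("`scheduler` must be an sc_scheduler")
  if (!is_count(n_trials)) stop_arg("`n_trials` must be a positive integer")
  rng <- new_rng(seed)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    tr <- scheduler$next_trial()
    probs <- observer(tr$stimulus)
    resp <- rng_eval(rng, function()
      sample(names(probs), 1, prob = probs))
    rec <- scheduler$record(resp)
    rows[[t]] <- data.frame(trial = rec$trial, label = rec$label,
                            true_category = rec$true_category,
                            response = rec$response, correct = rec$correct,
                            set_size = rec$set_size,
                            stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  cum <- cumsum(trials$correct) / seq_len(n_trials)
  roll <- vapply(seq_len(n_trials), function(t)
    mean(trials$correct[max(1, t - curve_window + 1):t]), numeric(1))
  structure(list(trials = trials,
                 summary = list(accuracy = mean(trials$correct),
                                cumulative = cum, rolling = roll,
                                curve_window = as.integer(curve_window))),
            class = "sc_session")
}

#' @export
print.sc_session <- function(x, ...) {
  cat(sprintf("<sc_session> %d trials, accuracy %.3f\n",
              nrow(x$trials), x$summary$accuracy))
  invisible(x)
}
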