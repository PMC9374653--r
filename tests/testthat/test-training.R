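make_cfg <- function(w, ...) {
  session_config(pools = list(A = w$cat_a$members, B = w$cat_b$members),
                 prototypes = list(A = w$base_a, B = w$base_b), ...)
}

# drive a scheduler with scripted correctness: TRUE feeds the true category,
# FALSE the other one
feed <- function(sched, correct_seq, cats = c("A", "B")) {
  recs <- vector("list", length(correct_seq))
  for (i in seq_along(correct_seq)) {
    tr <- sched$next_trial()
    resp <- if (correct_seq[i]) tr$category else setdiff(cats, tr$category)
    recs[[i]] <- sched$record(resp)
  }
  recs
}

test_that("the first window of prototype-protocol trials shows only prototypes", {
  w <- two_category_world()
  sched <- prototype_scheduler(make_cfg(w, window = 20, seed = 1))
  labs <- character(20)
  for (i in 1:20) {
    tr <- sched$next_trial()
    labs[i] <- tr$stimulus$label
    sched$record(tr$category)
  }
  expect_true(all(labs %in% c("protoA", "protoB")))
})

test_that("all-correct responding doubles the set size every window", {
  w <- two_category_world(n_members = 40)
  sched <- prototype_scheduler(make_cfg(w, window = 20, seed = 2))
  sizes <- integer(0)
  for (block in 1:4) {
    feed(sched, rep(TRUE, 20))
    sizes <- c(sizes, sched$state()$set_size)
  }
  expect_equal(sizes, c(2, 4, 8, 16))
  expect_equal(sched$state()$set_size, 16)  # nondecreasing power-of-2 ladder
})

test_that("advancement requires rolling accuracy at or above the criterion", {
  w <- two_category_world()
  # 0.799 < 0.80: no advancement
  sched <- prototype_scheduler(make_cfg(w, window = 1000, criterion = 0.80,
                                        seed = 3))
  # errors first, so the window that drops trial 1 gains a correct trial
  feed(sched, c(rep(FALSE, 201), rep(TRUE, 799)))
  expect_equal(sched$state()$set_size, 1)
  # one more correct answer lifts the rolling window to exactly 0.800
  rec <- feed(sched, TRUE)[[1]]
  expect_equal(sched$state()$set_size, 2)
  expect_true(rec$advanced)
})

test_that("a sub-criterion responder never advances past the prototypes", {
  w <- two_category_world()
  sched <- prototype_scheduler(make_cfg(w, window = 100, criterion = 0.80,
                                        seed = 4))
  # periodic 75% correct: every rolling window of 100 holds exactly 75
  feed(sched, rep(c(TRUE, TRUE, TRUE, FALSE), 75))
  expect_equal(sched$state()$set_size, 1)
})

test_that("set size is capped by the pool and never decreases", {
  w <- two_category_world(n_members = 5)
  sched <- prototype_scheduler(make_cfg(w, window = 10, seed = 5))
  sizes <- integer(0)
  for (block in 1:6) {
    feed(sched, rep(TRUE, 10))
    sizes <- c(sizes, sched$state()$set_size)
  }
  expect_true(all(diff(sizes) >= 0))
  expect_equal(max(sizes), 6)  # prototype + all 5 pool members
})

test_that("stimuli join the active set in order of increasing prototype deviation", {
  w <- two_category_world(n_members = 10)
  keys <- vapply(w$cat_a$members, function(m)
    sum(stimulus_deviation(m, w$base_a)$mean), numeric(1))
  nearest <- w$cat_a$members[[which.min(keys)]]$label
  sched <- prototype_scheduler(make_cfg(w, window = 5, seed = 6))
  feed(sched, rep(TRUE, 5))   # set size now 2: prototype + nearest member
  recs <- feed(sched, rep(FALSE, 200))  # all wrong: no further advancement
  labs <- vapply(recs, `[[`, "", "label")
  member_labels <- setdiff(unique(labs), c("protoA", "protoB"))
  from_a <- member_labels[member_labels %in%
                            vapply(w$cat_a$members, `[[`, "", "label")]
  expect_equal(from_a, nearest)
})

test_that("the exemplar scheduler draws uniformly and never shows the base", {
  w <- two_category_world(n_members = 25)
  # plant the base inside a pool: it must be removed with a warning
  cfg_bad <- session_config(
    pools = list(A = c(w$cat_a$members, list(w$base_a)), B = w$cat_b$members),
    prototypes = list(A = w$base_a, B = w$base_b), seed = 7)
  expect_warning(exemplar_scheduler(cfg_bad), "removed")

  cfg <- make_cfg(w, seed = 8)
  sched <- exemplar_scheduler(cfg)
  n <- 5000
  labs <- character(n)
  for (i in 1:n) {
    tr <- sched$next_trial()
    labs[i] <- tr$stimulus$label
    sched$record(tr$category)
  }
  expect_false(any(labs %in% c("protoA", "protoB")))
  counts <- table(labs)
  expect_equal(length(counts), 50)  # every pool stimulus appears
  chi <- chisq.test(counts, p = rep(1 / 50, 50))
  expect_gt(chi$p.value, 0.01)
})

test_that("schedulers replay deterministically under a fixed seed", {
  w <- two_category_world()
  run_labels <- function() {
    sched <- exemplar_scheduler(make_cfg(w, seed = 11))
    vapply(1:50, function(i) {
      tr <- sched$next_trial()
      sched$record(tr$category)
      tr$stimulus$label
    }, character(1))
  }
  expect_identical(run_labels(), run_labels())
})

test_that("continuum trials are labeled by the boundary side and relabel on demand", {
  cont <- morph_pair(random_stimulus(5, 41), random_stimulus(5, 42), k = 5)
  expect_length(cont$steps, 7)
  expect_error(continuum_scheduler(cont, boundary_index = 7), "boundary_index")
  expect_error(continuum_scheduler(cont, boundary_index = 6), "boundary_index")
  sched <- continuum_scheduler(cont, boundary_index = 3, seed = 12)
  seen <- list()
  for (i in 1:300) {
    tr <- sched$next_trial()
    expect_equal(tr$category, if (tr$step <= 3) "A" else "B")
    seen[[length(seen) + 1]] <- c(tr$step, tr$category)
    sched$record(tr$category)
  }
  # moving the boundary relabels subsequent trials without new stimuli
  sched$set_boundary(1)
  for (i in 1:100) {
    tr <- sched$next_trial()
    expect_equal(tr$category, if (tr$step <= 1) "A" else "B")
    expect_true(tr$step %in% 0:6)
    sched$record(tr$category)
  }
})

test_that("a zero-noise prototype observer is perfect on separated categories", {
  w <- two_category_world()
  obs <- simulated_observer("prototype",
                            refs = list(A = w$base_a, B = w$base_b), noise = 0)
  sched <- prototype_scheduler(make_cfg(w, window = 20, seed = 13))
  ses <- run_session(sched, obs, n_trials = 100, seed = 14)
  expect_equal(ses$summary$accuracy, 1.0)
  # doubling every window: 100 trials at window 20 end at set size 32 (capped)
  expect_equal(unique(diff(ses$trials$set_size) >= 0), TRUE)
})

test_that("an infinite-noise observer performs at chance", {
  w <- two_category_world()
  obs <- simulated_observer("prototype",
                            refs = list(A = w$base_a, B = w$base_b),
                            noise = Inf)
  sched <- exemplar_scheduler(make_cfg(w, seed = 15))
  ses <- run_session(sched, obs, n_trials = 2000, seed = 16)
  se <- 0.5 / sqrt(2000)
  expect_lt(abs(ses$summary$accuracy - 0.5), 4 * se)
})

test_that("sessions replay deterministically given both seeds", {
  w <- two_category_world()
  go <- function() {
    obs <- simulated_observer("prototype",
                              refs = list(A = w$base_a, B = w$base_b),
                              noise = 0.5)
    run_session(prototype_scheduler(make_cfg(w, seed = 17)), obs,
                n_trials = 60, seed = 18)$trials
  }
  expect_identical(go(), go())
})

test_that("prototype-protocol learning starts steeper than exemplar-protocol", {
  # matched observer and categories; the prototype protocol front-loads the
  # highly representative stimuli, so early accuracy must be higher
  w <- wide_category_world(n_members = 40, seed = 300)
  obs <- simulated_observer("prototype",
                            refs = list(A = w$base_a, B = w$base_b),
                            noise = 0.8)
  early <- function(sched, seed)
    mean(run_session(sched, obs, n_trials = 100,
                     seed = seed)$trials$correct)
  proto <- vapply(1:5, function(i)
    early(prototype_scheduler(make_cfg(w, window = 20, seed = 20 + i)),
          50 + i), numeric(1))
  exemp <- vapply(1:5, function(i)
    early(exemplar_scheduler(make_cfg(w, seed = 30 + i)), 70 + i), numeric(1))
  expect_gt(mean(proto), mean(exemp))
})
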