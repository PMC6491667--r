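fig1_vs <- function() {
  f <- fig1_fixture()
  to_visits(f$trajectory, f$space)
}

test_that("the brainstorming example reproduces its content tallies", {
  vs <- fig1_vs()
  st <- cell_stats(vs)
  expect_equal(sum(st$visits == 2), 3)
  expect_equal(sum(st$visits == 1), 4)
  expect_equal(sum(st$visits == 0), 18)
  expect_equal(sum(st$event_proportion), 1, tolerance = 1e-9)
  expect_equal(sum(st$duration_proportion), 1, tolerance = 1e-9)
  ok <- st$visits > 0
  expect_equal(st$mean_duration_per_visit[ok] * st$visits[ok],
               st$total_duration[ok], tolerance = 1e-9)
})

test_that("a single-visit trajectory concentrates all proportions", {
  cb <- toy_codebook()
  ev <- tibble::tibble(onset = 0, speaker = "A", tone = "X")
  vs <- to_visits(trajectory(ev, 5, cb), make_state_space(cb, "speaker", "tone"))
  st <- cell_stats(vs)
  expect_equal(max(st$duration_proportion), 1)
  expect_equal(dispersion(vs), 0)
  expect_equal(visit_entropy(vs), 0)
  expect_equal(duration_entropy(vs), 0)
  expect_error(transition_entropy(vs), "no transitions")
})

test_that("cell stats match the brute-force event tally on random data", {
  for (seed in 1:50) {
    fx <- random_trajectory(seed + 500)
    vs <- to_visits(fx$trajectory, fx$space)
    st <- cell_stats(vs)
    tal <- oracle_cell_tally(fx$trajectory, fx$space)
    for (k in names(tal$events)) {
      xi <- as.integer(strsplit(k, ",")[[1]][1])
      yi <- as.integer(strsplit(k, ",")[[1]][2])
      row <- st[st$x == xi & st$y == yi, ]
      expect_equal(row$events, tal$events[[k]])
      expect_equal(row$visits, tal$visits[[k]])
      expect_equal(row$total_duration, tal$duration[[k]], tolerance = 1e-9)
    }
    # unvisited cells report zeros
    expect_equal(sum(st$events), n_events(fx$trajectory))
  }
})

test_that("dispersion hits its anchors and matches the closed formula", {
  # uniform occupancy over all cells -> 1
  cb <- codebook(a = paste0("a", 1:3), b = paste0("b", 1:3))
  sp <- make_state_space(cb, "a", "b")
  grid <- expand.grid(a = cb$a, b = cb$b, stringsAsFactors = FALSE)
  ev <- tibble::tibble(onset = as.numeric(seq_len(9) - 1),
                       a = grid$a, b = grid$b)
  vs <- to_visits(trajectory(ev, 9, cb), sp)
  expect_equal(dispersion(vs), 1, tolerance = 1e-12)

  # random duration vectors against the independent formula loop
  for (i in 1:1000) {
    p <- withr::with_seed(i, {
      n <- sample(2:40, 1)
      d <- stats::rexp(n)
      list(d = d, n = n)
    })
    expect_equal(ssgrid:::dispersion_from_props(p$d / sum(p$d), p$n),
                 oracle_dispersion(p$d, p$n), tolerance = 1e-9)
  }
})

test_that("uniform visits over k cells give entropy log(k)", {
  for (k in 2:10) {
    cb <- codebook(a = paste0("a", 1:k), b = c("u", "v"))
    sp <- make_state_space(cb, "a", "b")
    ev <- tibble::tibble(onset = as.numeric(seq_len(k) - 1),
                         a = paste0("a", seq_len(k)), b = "u")
    vs <- to_visits(trajectory(ev, k, cb), sp)
    expect_equal(visit_entropy(vs), log(k), tolerance = 1e-12)
    expect_equal(duration_entropy(vs), log(k), tolerance = 1e-12)
  }
})

test_that("entropies match the oracle and respect their bounds", {
  for (seed in 1:50) {
    fx <- random_trajectory(seed + 900)
    vs <- to_visits(fx$trajectory, fx$space)
    om <- oracle_grid_measures(fx$trajectory, fx$space)
    gm <- grid_measures(vs)
    expect_equal(gm$visit_entropy, om$visit_entropy, tolerance = 1e-9)
    expect_equal(gm$duration_entropy, om$duration_entropy, tolerance = 1e-9)
    expect_equal(gm$transition_entropy, om$transition_entropy, tolerance = 1e-9)
    expect_equal(gm$dispersion, om$dispersion, tolerance = 1e-9)
    expect_equal(gm$cell_range, om$cell_range)
    expect_equal(gm$n_transitions, om$n_transitions)
    # bounds
    expect_gte(gm$visit_entropy, 0)
    expect_lte(gm$visit_entropy, log(gm$cell_range) + 1e-12)
    expect_lte(gm$duration_entropy, log(gm$cell_range) + 1e-12)
    expect_true(gm$dispersion >= 0 && gm$dispersion <= 1 + 1e-12)
  }
})

test_that("region stats aggregate columns and report sibling spread", {
  cb <- toy_codebook()
  # speaker A holds 30 of 40 s (durations 15, 5, 15, 5)
  ev <- tibble::tibble(onset = c(0, 15, 20, 35),
                       speaker = c("A", "B", "A", "B"),
                       tone = c("X", "X", "Y", "Y"))
  vs <- to_visits(trajectory(ev, 40, cb), make_state_space(cb, "speaker", "tone"))
  rs <- region_stats(vs, x = "A")
  expect_equal(rs$duration_proportion, 0.75)
  expect_equal(rs$events, 2)
  expect_equal(rs$visits, 2)

  # equal shares -> zero SD across speaker columns
  ev2 <- tibble::tibble(onset = c(0, 10), speaker = c("A", "B"), tone = "X")
  vs2 <- to_visits(trajectory(ev2, 20, cb), make_state_space(cb, "speaker", "tone"))
  expect_equal(region_stats(vs2, x = "A")$sibling_sd_pct, 0)

  # per-column event counts match a brute-force tally
  for (seed in 1:20) {
    fx <- random_trajectory(seed + 300)
    vs3 <- to_visits(fx$trajectory, fx$space)
    keys <- oracle_event_keys(fx$trajectory, fx$space)
    for (xi in seq_along(fx$space$x$categories)) {
      want <- sum(as.integer(sub(",.*", "", keys)) == xi)
      got <- region_stats(vs3, x = xi)$events
      expect_equal(got, want)
    }
  }
})

test_that("region visits count maximal runs inside the region", {
  cb <- toy_codebook()
  # A/X -> A/Y is one region visit for column A, then B, then back
  ev <- tibble::tibble(onset = 0:3, speaker = c("A", "A", "B", "A"),
                       tone = c("X", "Y", "X", "X"))
  vs <- to_visits(trajectory(ev, 4, cb), make_state_space(cb, "speaker", "tone"))
  expect_equal(region_stats(vs, x = "A")$visits, 2)
})

test_that("pooled measures reduce to single-trajectory measures", {
  fx <- random_trajectory(31)
  vs <- to_visits(fx$trajectory, fx$space)
  single <- grid_measures(vs)
  pm <- pooled_measures(trajectory_collection(list(fx$trajectory)), fx$space)
  expect_equal(pm$pooled, single)

  # two identical trajectories: proportions unchanged, counts doubled,
  # no cross-trajectory transition
  t2 <- fx$trajectory
  t2$id <- "copy"
  pm2 <- pooled_measures(trajectory_collection(list(fx$trajectory, t2)),
                         fx$space)
  expect_equal(pm2$pooled$dispersion, single$dispersion, tolerance = 1e-9)
  expect_equal(pm2$pooled$visit_entropy, single$visit_entropy, tolerance = 1e-9)
  expect_equal(pm2$pooled$n_visits, 2 * single$n_visits)
  expect_equal(pm2$pooled$n_transitions, 2 * single$n_transitions)
  expect_equal(nrow(pm2$per_trajectory), 2)
})

test_that("moving time from the fullest cell to an empty one raises dispersion", {
  for (seed in 1:20) {
    p <- withr::with_seed(seed, {
      n <- sample(4:20, 1)
      k <- sample(2:(n - 1), 1)
      d <- c(stats::rexp(k), rep(0, n - k))
      list(d = d, n = n)
    })
    d <- p$d
    i_max <- which.max(d)
    i_zero <- which(d == 0)[1]
    quantum <- d[i_max] / 4
    d2 <- d
    d2[i_max] <- d2[i_max] - quantum
    d2[i_zero] <- quantum
    expect_gt(ssgrid:::dispersion_from_props(d2 / sum(d2), p$n),
              ssgrid:::dispersion_from_props(d / sum(d), p$n))
  }
})
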