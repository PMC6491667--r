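visits_from_labels <- function(labels, durations, cats = sort(unique(labels))) {
  cb <- codebook(s = cats, t = c("u", "v"))
  onsets <- cumsum(c(0, durations[-length(durations)]))
  ev <- tibble::tibble(onset = onsets, s = labels, t = "u")
  traj <- trajectory(ev, sum(durations), cb)
  to_visits(traj, make_state_space(cb, "s", "t"))
}

test_that("excursions from a hand-enumerated sequence", {
  # A(1s) B(2s) A(1s) C(3s) A(1s), region {A}:
  # two completed excursions with return times 2 and 3 and one outside
  # visit each
  vs <- visits_from_labels(c("A", "B", "A", "C", "A"), c(1, 2, 1, 3, 1))
  rs <- return_stats(vs, x = "A")
  expect_equal(rs$n_excursions, 2)
  expect_equal(rs$n_censored, 0)
  expect_equal(rs$mean_return_time, 2.5)
  expect_equal(rs$mean_return_visits, 1.0)
})

test_that("a region never left has no excursions; trailing exits are censored", {
  vs <- visits_from_labels(c("A", "A", "A"), c(1, 2, 1))
  rs <- return_stats(vs, x = "A")
  expect_equal(rs$n_excursions, 0)
  expect_true(is.na(rs$mean_return_time))

  vs2 <- visits_from_labels(c("A", "B", "A", "B", "B"), c(1, 1, 1, 2, 2))
  rs2 <- return_stats(vs2, x = "A")
  expect_equal(rs2$n_excursions, 2)   # one completed + one censored
  expect_equal(rs2$n_censored, 1)
  expect_equal(rs2$mean_return_time, 1)  # only the completed one counts
  # completed + censored == total exits
  expect_equal((rs2$n_excursions - rs2$n_censored) + rs2$n_censored, 2)

  vs3 <- visits_from_labels(c("B", "C"), c(1, 1), cats = c("A", "B", "C"))
  expect_error(return_stats(vs3, x = "A"), "not visited")
})

test_that("return stats equal the brute-force excursion scanner", {
  for (seed in 1:50) {
    fx <- random_trajectory(seed + 700)
    vs <- to_visits(fx$trajectory, fx$space)
    region <- withr::with_seed(seed, sample(unique(vs$cell), 1))
    rs <- return_stats(vs, cells = region)
    want <- oracle_return(vs$cell, vs$start, vs$duration, region)
    expect_equal(rs$n_excursions, want$n_excursions)
    expect_equal(rs$n_censored, want$n_censored)
    expect_equal(rs$mean_return_time, want$mean_return_time, tolerance = 1e-9)
    expect_equal(rs$mean_return_visits, want$mean_return_visits,
                 tolerance = 1e-9)
    # return time can never undercut the shortest visit duration
    if (!is.na(rs$mean_return_time)) {
      expect_gte(rs$mean_return_time, min(vs$duration) - 1e-12)
    }
  }
})

test_that("top cells rank the twice-visited states of the worked example", {
  f <- fig1_fixture()
  st <- cell_stats(to_visits(f$trajectory, f$space))
  top <- top_cells(st, by = "visits", k = 3)
  expect_equal(top$visits, c(2L, 2L, 2L))
  # k beyond the visited cells returns all visited cells
  expect_equal(nrow(top_cells(st, by = "visits", k = 99)), 7)
})

test_that("rankings agree with a direct sort under every criterion", {
  for (seed in 1:20) {
    fx <- random_trajectory(seed + 40)
    st <- cell_stats(to_visits(fx$trajectory, fx$space))
    for (by in c("visits", "total_duration", "mean_duration_per_visit")) {
      got <- top_cells(st, by = by, k = 5)
      vis <- st[st$visits > 0, ]
      ord <- order(-vis[[by]], -vis$total_duration, -vis$events, vis$cell)
      expect_equal(got$cell, vis$cell[ord][seq_len(nrow(got))])
      expect_true(all(diff(got[[by]]) <= 1e-12))
    }
  }
})

test_that("uniform durations give zero heterogeneity at screen 0", {
  vs <- visits_from_labels(c("A", "B", "C", "D"), c(2, 2, 2, 2))
  w <- winnow(vs)
  expect_equal(w$screens$heterogeneity[1], 0)
  expect_equal(w$screens$n_remaining[1], 4)
})

test_that("a dominant cell survives winnowing as the attractor", {
  # 95% of duration in one cell, remainder spread over the rest
  labels <- c(rep(c("hub", "b", "hub", "c", "hub", "d"), 3), "hub")
  durs <- ifelse(labels == "hub", 95 / 10, 5 / 9)
  vs <- visits_from_labels(labels, durs)
  w <- winnow(vs)
  expect_true("hub" %in% w$attractor_cells$x_label)
  # screens strictly shrink
  expect_true(all(diff(w$screens$n_remaining) < 0))
})

test_that("winnow screen logs match the brute-force replay", {
  for (seed in 1:50) {
    fx <- random_trajectory(seed + 800)
    vs <- to_visits(fx$trajectory, fx$space)
    if (length(unique(vs$cell)) < 2) next
    w <- winnow(vs)
    st <- cell_stats(vs)
    st <- st[st$visits > 0, ]
    d <- st$total_duration
    names(d) <- paste0(st$x_label, "/", st$y_label)
    want <- oracle_winnow(d)
    expect_equal(nrow(w$screens), want$n_screens)
    expect_equal(w$screens$heterogeneity, want$heterogeneity, tolerance = 1e-9)
    expect_equal(w$selected_screen, want$selected)
    expect_setequal(paste0(w$attractor_cells$x_label, "/",
                           w$attractor_cells$y_label), want$attractors)
  }
})

test_that("winnowing is deterministic and removes duration ties together", {
  vs <- visits_from_labels(c("A", "B", "C", "D", "A"), c(1, 1, 1, 3, 5))
  w1 <- winnow(vs)
  w2 <- winnow(vs)
  expect_identical(w1$screens$heterogeneity, w2$screens$heterogeneity)
  # B and C tie at minimal duration and leave in the same screen
  expect_equal(nrow(w1$screens), 2)
  expect_setequal(w1$screens$removed[[2]], c("B/u", "C/u"))
  expect_equal(w1$screens$n_remaining, c(4, 2))
})

test_that("winnowing a planted attractor recovers it in >=95% of runs", {
  cb <- codebook(p = paste0("p", 1:5), q = c("q1", "q2"))
  sp <- make_state_space(cb, "p", "q")
  hits <- 0L
  realized <- 0L
  n_runs <- 50L
  for (run in seq_len(n_runs)) {
    # one cell holds >=80% of the duration via dwell-time contrast
    cfg <- synth_config(sp, weights = c(12, rep(1, 9)),
                        dwell_mean = c(60, rep(1, 9)),
                        n_visits = 120, seed = 6000 + run)
    vs <- to_visits(simulate_trajectory(cfg), sp)
    st <- cell_stats(vs)
    if (st$duration_proportion[1] < 0.8) next  # condition not realized
    realized <- realized + 1L
    w <- winnow(vs)
    if (1 %in% w$attractor_cells$cell) hits <- hits + 1L
  }
  expect_gte(realized, 45L)  # the planted regime almost always realizes
  expect_gte(hits / realized, 0.95)
})
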