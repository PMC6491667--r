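# Shared fixture builders for the test suite. All randomness is seeded at
# the call site via withr::with_seed.

toy_codebook <- function() {
  codebook(speaker = c("A", "B"), tone = c("X", "Y"))
}

# a random valid trajectory built directly from raw parts (independent of
# the synth module): onsets on the millisecond grid, repeats allowed so the
# event/visit distinction is exercised
random_trajectory <- function(seed, n_events = NULL, nx = NULL, ny = NULL) {
  withr::with_seed(seed, {
    nx <- nx %||% sample(2:5, 1)
    ny <- ny %||% sample(2:5, 1)
    n_events <- n_events %||% sample(5:40, 1)
    cb <- codebook(d1 = paste0("x", seq_len(nx)), d2 = paste0("y", seq_len(ny)))
    durs <- round(stats::rexp(n_events, 1 / 4), 3)
    durs <- pmax(durs, 0.001)
    onsets <- cumsum(c(0, durs))
    # sticky categorical walk so same-cell runs occur
    xs <- ys <- integer(n_events)
    xs[1] <- sample(nx, 1); ys[1] <- sample(ny, 1)
    for (i in seq_len(n_events)[-1]) {
      xs[i] <- if (stats::runif(1) < 0.4) xs[i - 1] else sample(nx, 1)
      ys[i] <- if (stats::runif(1) < 0.4) ys[i - 1] else sample(ny, 1)
    }
    ev <- tibble::tibble(onset = onsets[-length(onsets)],
                         d1 = paste0("x", xs), d2 = paste0("y", ys))
    traj <- trajectory(ev, onsets[length(onsets)], cb,
                       id = paste0("rand", seed))
    list(trajectory = traj, codebook = cb,
         space = make_state_space(cb, "d1", "d2"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_codebook_yaml <- function(path, cb = NULL) {
  cb <- cb %||% toy_codebook()
  write_codebook(cb, path)
  path
}
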