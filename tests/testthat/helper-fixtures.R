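# shared in-code fixtures; everything is generated, nothing stored

make_bt <- function() {
  behav_table(
    data = tibble::tibble(
      id = rep(c("a", "b", "c"), each = 4),
      t = rep(c(0, 60, 120, 180), 3),
      x = as.numeric(1:12),
      moving = rep(c(0, 1), 6)
    ),
    meta = tibble::tibble(
      id = c("a", "b", "c", "d"),
      genotype = c("CantonS", "CantonS", "per-short", "per-long")
    )
  )
}

# regular binary movement series for one specimen
make_series <- function(moving, bin_s = 10, id = "fly1") {
  tibble::tibble(id = id, t = (seq_along(moving) - 1) * bin_s,
                 moving = as.integer(moving))
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        genotypes = tibble::tibble(name = "CantonS", period_h = 24,
                                   n_flies = 3),
        days = 1, bin_s = 60, seed = 42
      )
      cache <<- simulate_population(cfg)
    }
    cache
  }
})
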