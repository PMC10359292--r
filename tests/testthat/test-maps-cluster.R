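test_that("baseline normalisation subtracts the pre-stimulus mean per frequency", {
  tm <- seq(-0.5, 0.999, by = 0.001)
  withr::with_seed(41, v <- array(rnorm(1500 * 24 * 2), c(1500, 24, 2)))
  st <- dyadflow:::new_tfr_stack(v, tm, coherence_freqs())
  nm <- baseline_normalize(st)
  for (k in 1:2) {
    expect_lt(max(abs(colMeans(nm$values[tm < 0, , k]))), 1e-12)
  }
  # hand subtraction on a crafted map
  crafted <- array(0, c(1500, 24, 1))
  crafted[, 3, 1] <- 2
  crafted[1:500, 3, 1] <- 1 # baseline window mean = 1 at frequency 3
  stc <- dyadflow:::new_tfr_stack(crafted, tm, coherence_freqs())
  out <- baseline_normalize(stc)$values[, 3, 1]
  expect_equal(out, c(rep(0, 500), rep(1, 1000)))
  # constant maps become all zero
  stk <- dyadflow:::new_tfr_stack(array(0.4, c(1500, 24, 1)), tm,
                                  coherence_freqs())
  expect_true(all(baseline_normalize(stk)$values == 0))
})

test_that("coherence modulation is the per-pair difference averaged across pairs", {
  tm <- seq(-0.5, 0.999, by = 0.001)
  a <- dyadflow:::new_tfr_stack(array(0.2, c(1500, 24, 2)), tm, coherence_freqs())
  expect_true(all(coherence_modulation(a, a)$observed == 0))
  v <- array(0, c(1500, 24, 2))
  v[, , 1] <- 1
  v[, , 2] <- -1
  b <- dyadflow:::new_tfr_stack(
    a$values + v, tm, coherence_freqs()
  )
  mod <- coherence_modulation(a, b)
  expect_equal(mod$diff$values, v)
  expect_true(all(abs(mod$observed) < 1e-12))
})

test_that("the subsampling null reproduces reference quantiles and is deterministic", {
  tm <- seq(-0.5, 0.999, by = 0.001)
  # all-zero input: both distributions identically zero
  z <- dyadflow:::new_tfr_stack(array(0, c(1500, 24, 12)), tm, coherence_freqs())
  nl <- subsample_null(z, n_sub = 10, n_rep = 20, seed = 5)
  expect_true(all(nl$low == 0) && all(nl$high == 0))
  # two-map stack: the diff multiset is +/-(m2 - m1); both pairings give
  # quantiles matching R's type-7 quantile of the signed difference
  withr::with_seed(42, m <- matrix(rnorm(36000 * 2), ncol = 2))
  st2 <- dyadflow:::new_tfr_stack(array(m, c(1500, 24, 2)), tm, coherence_freqs())
  n2 <- subsample_null(st2, n_sub = 2, n_rep = 8, seed = 9)
  d <- m[, 2] - m[, 1]
  qs <- rbind(quantile(d, c(0.005, 0.995), names = FALSE),
              quantile(-d, c(0.005, 0.995), names = FALSE))
  for (r in 1:8) {
    expect_true(
      isTRUE(all.equal(c(n2$low[r], n2$high[r]), qs[1, ])) ||
        isTRUE(all.equal(c(n2$low[r], n2$high[r]), qs[2, ]))
    )
  }
  # determinism under a fixed seed
  n2b <- subsample_null(st2, n_sub = 2, n_rep = 8, seed = 9)
  expect_identical(n2, n2b)
  expect_error(subsample_null(st2, n_sub = 10, n_rep = 5, seed = 1),
               "requested")
})

test_that("standard-normal stacks give percentile distributions at the theoretical location", {
  tm <- seq(-0.5, 0.999, by = 0.001)
  withr::with_seed(43, v <- array(rnorm(1500 * 24 * 60), c(1500, 24, 60)))
  st <- dyadflow:::new_tfr_stack(v, tm, coherence_freqs())
  nl <- subsample_null(st, n_sub = 40, n_rep = 40, seed = 11)
  # differences of two standard normals: N(0, 2); 0.5/99.5 percentiles at
  # -/+ 2.576 * sqrt(2) = -/+ 3.643
  expect_lt(abs(mean(nl$low) + 3.643), 0.1)
  expect_lt(abs(mean(nl$high) - 3.643), 0.1)
})

test_that("flood fill matches an igraph connected-components oracle", {
  igraph_labels <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(0L)
    edges <- list()
    key <- function(r, c) paste(r, c)
    ids <- setNames(seq_len(nrow(idx)), key(idx[, 1], idx[, 2]))
    for (v in seq_len(nrow(idx))) {
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          nb <- key(idx[v, 1] + dr, idx[v, 2] + dc)
          if (!is.na(ids[nb])) {
            edges[[length(edges) + 1]] <- c(v, ids[[nb]])
          }
        }
      }
    }
    if (length(edges) == 0) return(as.integer(nrow(idx)))
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(idx) - igraph::vcount(g)))
    igraph::components(g)$no
  }
  for (s in 1:10) {
    withr::with_seed(500 + s, mask <- matrix(runif(30 * 20) < 0.25, 30, 20))
    labels <- dyadflow:::flood_fill_label(mask)
    expect_equal(max(labels), as.integer(igraph_labels(mask)))
    # every labelled cell is a candidate and vice versa
    expect_identical(labels > 0, mask)
  }
})

test_that("cluster pruning keeps only components of at least the minimum size", {
  obs <- matrix(0, 50, 24)
  # a 12-bin blob and a 5-bin blob below the low threshold
  obs[10:13, 5:7] <- -1 # 12 bins
  obs[30:34, 10] <- -1 # 5 bins
  null <- list(low = rep(-0.5, 100), high = rep(0.5, 100))
  ct <- threshold_and_cluster(obs, null, min_cluster = 10)
  expect_equal(nrow(ct$clusters), 1)
  expect_equal(ct$clusters$n_bins, 12)
  expect_equal(sum(ct$decrease), 12)
  expect_false(any(ct$increase))
  # 3x4 rectangle plus a diagonally touching singleton: one 13-bin cluster
  obs2 <- matrix(0, 50, 24)
  obs2[5:7, 5:8] <- 2
  obs2[8, 9] <- 2 # touches (7, 8) diagonally
  ct2 <- threshold_and_cluster(obs2, null, min_cluster = 10)
  expect_equal(ct2$clusters$n_bins, 13)
  expect_equal(ct2$clusters$direction, "increase")
  # no candidate bins: empty masks
  ct0 <- threshold_and_cluster(matrix(0, 50, 24), null)
  expect_equal(nrow(ct0$clusters), 0)
  expect_false(any(ct0$decrease) || any(ct0$increase))
  expect_error(threshold_and_cluster(obs, list(low = numeric(0),
                                               high = numeric(0))), "Empty")
})
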