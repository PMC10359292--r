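#' Concatenate map stacks along the pair axis
#'
#' @param ... `tfr_stack`s with identical axes.
#' @return A single `tfr_stack`.
#' @export
stack_bind <- function(...) {
  stacks <- list(...)
  stopifnot(length(stacks) >= 1, all(vapply(stacks, inherits, TRUE, "tfr_stack")))
  v <- do.call(abind3, lapply(stacks, `[[`, "values"))
  new_tfr_stack(v, stacks[[1]]$time, stacks[[1]]$freqs,
                meaning = stacks[[1]]$meaning)
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n3 <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], n3))
  at <- 0
  for (a in arrs) {
    out[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  out
}

#' Subsampling null distributions for coherence modulation
#'
#' Builds the null used by the cluster significance test. Per repetition,
#' `n_sub` maps are drawn without replacement from the stack (both
#' conditions pooled along the pair axis), half are assigned to a simulated
#' control and half to a simulated drug condition, the control half is
#' subtracted from the drug half member-by-member, and the 0.5 and 99.5
#' percentiles over all resulting values (time x freq x n_sub/2) are
#' recorded. The two distributions of percentile values define the
#' thresholds for significant decreases and increases respectively.
#'
#' @param stack A `tfr_stack` of normalised coherence maps, both conditions
#'   concatenated along the pair axis (see [stack_bind()]).
#' @param n_sub Maps drawn per repetition. Default 200.
#' @param n_rep Repetitions. Default 1000.
#' @param seed Integer seed.
#' @return List with numeric vectors `low` and `high`, each `n_rep` long,
#'   plus the call parameters.
#' @export
subsample_null <- function(stack, n_sub = 200, n_rep = 1000, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible null.")
  stopifnot(inherits(stack, "tfr_stack"))
  np <- dim(stack$values)[3]
  if (np < n_sub) {
    abort(sprintf("Stack has %d maps but `n_sub` = %d are requested.", np, n_sub))
  }
  m <- matrix(stack$values, ncol = np) # bins x pairs
  res <- with_seed(derive_seed(seed, "subsample"), {
    subsample_percentiles_cpp(m, as.integer(n_sub), as.integer(n_rep),
                              0.005, 0.995)
  })
  list(low = res$low, high = res$high, n_sub = n_sub, n_rep = n_rep)
}

# 8-connected component labelling of a logical matrix (flood fill).
flood_fill_label <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  off <- cbind(
    rep(-1:1, times = 3), rep(-1:1, each = 3)
  )
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cell - 1L) %% nr + 1L
      c <- (cell - 1L) %/% nr + 1L
      nb_r <- r + off[, 1]
      nb_c <- c + off[, 2]
      ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb) > 0) {
        labels[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

#' Cluster significance test on an observed modulation map
#'
#' Bins of the observed map below the 0.5th percentile of the low-cut null
#' distribution are candidate decreases; bins above the 99.5th percentile of
#' the high-cut distribution are candidate increases. Candidates are grouped
#' into 8-connected components (edges or corners touching) by flood fill,
#' components smaller than `min_cluster` bins are removed, and the retained
#' components form the significant masks (reported as P < 0.01 regions).
#'
#' @param observed Time x frequency matrix (across-pair mean modulation).
#' @param null Output of [subsample_null()].
#' @param min_cluster Minimum cluster size in bins. Default 10.
#' @param time,freqs Optional axes used for reporting cluster extents.
#' @return A `cluster_test`: masks (`decrease`, `increase`), a `clusters`
#'   tibble (id, direction, n_bins, extents) and the two thresholds.
#' @export
threshold_and_cluster <- function(observed, null, min_cluster = 10,
                                  time = NULL, freqs = NULL) {
  if (length(null$low) == 0 || length(null$high) == 0) {
    abort("Empty null distributions.")
  }
  low_cut <- quantile(null$low, 0.005, names = FALSE)
  high_cut <- quantile(null$high, 0.995, names = FALSE)
  res <- list(
    thresholds = c(low = low_cut, high = high_cut),
    decrease = matrix(FALSE, nrow(observed), ncol(observed)),
    increase = matrix(FALSE, nrow(observed), ncol(observed))
  )
  clusters <- list()
  for (dir in c("decrease", "increase")) {
    cand <- if (dir == "decrease") observed < low_cut else observed > high_cut
    labels <- flood_fill_label(cand)
    if (max(labels) > 0) {
      sizes <- tabulate(labels[labels > 0])
      keep_ids <- which(sizes >= min_cluster)
      mask <- matrix(labels %in% keep_ids, nrow(observed), ncol(observed))
      res[[dir]] <- mask
      for (id in keep_ids) {
        cells <- which(labels == id, arr.ind = TRUE)
        clusters[[length(clusters) + 1]] <- tibble(
          direction = dir, n_bins = sizes[id],
          time_min = axis_at(time, min(cells[, 1])),
          time_max = axis_at(time, max(cells[, 1])),
          freq_min = axis_at(freqs, min(cells[, 2])),
          freq_max = axis_at(freqs, max(cells[, 2]))
        )
      }
    }
  }
  clusters <- if (length(clusters) > 0) {
    dplyr::bind_rows(clusters)
  } else {
    tibble(direction = character(), n_bins = integer(),
           time_min = numeric(), time_max = numeric(),
           freq_min = numeric(), freq_max = numeric())
  }
  clusters <- dplyr::mutate(clusters, id = dplyr::row_number(),
                            .before = 1)
  structure(
    c(res, list(clusters = clusters, observed = observed,
                time = time, freqs = freqs, min_cluster = min_cluster)),
    class = "cluster_test"
  )
}

axis_at <- function(axis, i) if (is.null(axis)) as.numeric(i) else axis[i]

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> thresholds [%.4g, %.4g]; %d significant cluster(s)\n",
    x$thresholds["low"], x$thresholds["high"], nrow(x$clusters)
  ))
  invisible(x)
}

#' Tidy a cluster significance test
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return The cluster table: one row per retained cluster.
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @export
glance.cluster_test <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_decrease = sum(x$clusters$direction == "decrease"),
    n_increase = sum(x$clusters$direction == "increase"),
    low_cut = unname(x$thresholds["low"]),
    high_cut = unname(x$thresholds["high"])
  )
}

#' Plot an observed modulation map with significant clusters
#'
#' Raster of the observed time-frequency modulation map (logarithmic
#' frequency axis) with retained cluster bins outlined.
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_test <- function(object, ...) {
  tm <- object$time %||% seq_len(nrow(object$observed))
  fq <- object$freqs %||% seq_len(ncol(object$observed))
  df <- tidyr::expand_grid(fi = seq_along(fq), ti = seq_along(tm))
  df <- dplyr::mutate(df,
    time = tm[.data$ti], freq = fq[.data$fi],
    value = object$observed[cbind(.data$ti, .data$fi)],
    significant = object$decrease[cbind(.data$ti, .data$fi)] |
      object$increase[cbind(.data$ti, .data$fi)]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "modulation")
  if (!is.null(object$freqs)) p <- p + ggplot2::scale_y_log10()
  if (any(df$significant)) {
    p <- p + ggplot2::geom_point(
      data = df[df$significant, ], size = 0.1, colour = "black", alpha = 0.4
    )
  }
  p
}
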