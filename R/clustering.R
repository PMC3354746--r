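#' Hard C-means clustering of scalar intensities
#'
#' Lloyd-style alternation of the hard membership rule (a value belongs to
#' the cluster whose mean is nearest, i.e. it moves from cluster `i` to `j`
#' whenever `||x - m_j||^2 < ||x - m_i||^2`) and the mean update, run until
#' no assignment changes or `max_iter` sweeps. The within-cluster sum of
#' squared errors (SSE) is non-increasing across sweeps and is recorded per
#' sweep.
#'
#' Initialisation is deterministic by default: centers are placed at the
#' `(2i - 1) / (2k)` quantiles of the data (falling back to quantiles of the
#' distinct values when ties collapse centers), so a given input and seed
#' always reproduce the same model; `init = "random"` samples k distinct
#' values instead. If a cluster empties during iteration its center is
#' re-seeded at the data point farthest from it.
#'
#' @param values Numeric vector of intensities (at least `k` distinct).
#' @param k Number of clusters.
#' @param seed Integer seed controlling random initialisation (and used even
#'   with quantile init so runs are reproducible end to end).
#' @param init `"quantile"` (default) or `"random"`.
#' @param max_iter Maximum number of sweeps (default 300).
#' @param nstart Number of starts: the first uses the chosen `init`, the
#'   rest draw k distinct values as centers, and the model with the lowest
#'   SSE wins. `"auto"` (default) uses 10 starts for small samples (up to
#'   10000 values), where Lloyd iterations from a single start are prone to
#'   local optima, and a single deterministic start at volume scale.
#' @return Object of class `c_means`: `k`, `means` (ascending), `assignment`
#'   (integer vector into `means`), `sizes`, `sse`, `iterations`,
#'   `sse_trace`.
#' @export
#' @examples
#' cm <- c_means(c(rnorm(50, 0), rnorm(50, 10)), k = 2, seed = 1)
#' cm$means
c_means <- function(values, k, seed = 1L, init = c("quantile", "random"),
                    max_iter = 300L, nstart = "auto") {
  init <- match.arg(init)
  values <- as.numeric(values)
  if (anyNA(values)) stop("values contain NA")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  ux <- unique(values)
  if (length(ux) < k)
    stop("need at least k = ", k, " distinct values, have ", length(ux))
  if (identical(nstart, "auto"))
    nstart <- if (length(values) <= 10000L) 10L else 1L
  nstart <- max(1L, as.integer(nstart))

  starts <- local_seed(seed, {
    first <- if (init == "random") {
      sort(sample(ux, k))
    } else {
      probs <- (2 * seq_len(k) - 1) / (2 * k)
      cen <- unname(quantile(values, probs = probs, type = 7))
      if (anyDuplicated(cen))
        cen <- unname(quantile(sort(ux), probs = probs, type = 1))
      sort(cen)
    }
    c(list(first),
      lapply(seq_len(nstart - 1L), function(i) sort(sample(ux, k))))
  })

  assign_nearest <- function(centers) {
    # centers ascending; boundaries at midpoints. findInterval puts a value
    # equal to a boundary into the upper cluster; ties are measure-zero and
    # the rule is deterministic either way.
    if (length(centers) == 1L) return(rep(1L, length(values)))
    bounds <- (centers[-1] + centers[-length(centers)]) / 2
    findInterval(values, bounds) + 1L
  }
  sse_of <- function(assignment, centers)
    sum((values - centers[assignment])^2)

  run_lloyd <- function(centers) {
    assignment <- assign_nearest(centers)
    trace <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # mean update
      sums <- vapply(seq_len(k), function(j) sum(values[assignment == j]), 0)
      ns <- tabulate(assignment, nbins = k)
      empty <- which(ns == 0L)
      for (j in empty) {
        # re-seed an emptied center at the point farthest from it
        far <- values[which.max(abs(values - centers[j]))]
        centers[j] <- far
      }
      full <- ns > 0L
      centers[full] <- sums[full] / ns[full]
      ord <- order(centers)
      centers <- centers[ord]
      assignment <- match(assignment, ord)

      new_assignment <- assign_nearest(centers)
      trace <- c(trace, sse_of(new_assignment, centers))
      if (identical(new_assignment, assignment) || iter >= max_iter) {
        assignment <- new_assignment
        break
      }
      assignment <- new_assignment
    }
    list(centers = centers, assignment = assignment,
         sse = sse_of(assignment, centers), iterations = iter, trace = trace)
  }

  best <- NULL
  for (st in starts) {
    fit <- run_lloyd(st)
    if (is.null(best) || fit$sse < best$sse - 1e-12 * (1 + best$sse))
      best <- fit
  }

  ns <- tabulate(best$assignment, nbins = k)
  structure(
    list(k = k, means = best$centers, assignment = best$assignment,
         sizes = ns, sse = best$sse, iterations = best$iterations,
         sse_trace = best$trace),
    class = "c_means")
}

#' @export
print.c_means <- function(x, ...) {
  cat(sprintf("<c_means> k = %d, n = %d, SSE = %.6g (%d sweeps)\n",
              x$k, length(x$assignment), x$sse, x$iterations))
  cat("means:", paste(signif(x$means, 6), collapse = ", "), "\n")
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Four-cluster intensity partition of a preprocessed volume
#'
#' Runs [c_means()] with `k = 4` over all voxels of the smoothed,
#' background-cleared volume and maps the clusters, in ascending order of
#' mean, to: darkest cluster `BACKGROUND` (air plus the darkest dense
#' voxels), brightest cluster `FAT`, and the two middle clusters `MIXED` —
#' the clusters where the skin and the internal dense tissue live, which a
#' second clustering pass and the geometric stages then disentangle.
#'
#' @param volume A preprocessed [gray_volume()].
#' @param seed Seed forwarded to [c_means()].
#' @return A [label_volume()] containing `BACKGROUND`, `MIXED` and `FAT`,
#'   with the fitted `c_means` model attached as attribute `"model"`.
#' @export
partition_4 <- function(volume, seed = 1L) {
  stopifnot(inherits(volume, "gray_volume"))
  cm <- c_means(as.vector(volume$data), k = 4L, seed = seed)
  map <- c(BG, MIXED, MIXED, FAT)  # ascending cluster mean order
  lab <- array(map[cm$assignment], dim(volume$data))
  out <- label_volume(lab, volume$spacing, allow_mixed = TRUE)
  attr(out, "model") <- cm
  out
}

#' Re-cluster the mixed clusters on original intensities
#'
#' Takes only the voxels labelled `MIXED` by [partition_4()], re-reads their
#' intensities from the *original* (unfiltered) volume, and splits them with
#' a fresh 2-cluster [c_means()] that sees neither background nor fat
#' voxels. Re-reading the original matters: the smoothing stage creates a
#' halo of intermediate intensities in the background hugging the skin, and
#' those voxels — ambiguous after filtering — are unambiguous background in
#' the original. The result is an image with a differentiated background.
#'
#' The darker sub-cluster merges to `BACKGROUND` when it is background-like
#' (its original-intensity mean lies closer to the background cluster's
#' original mean than to the brighter sub-cluster; `mapping = "auto"`,
#' the default) and otherwise stays candidate tissue. Intensity alone
#' cannot finish the skin/dense separation, so all candidate voxels are
#' handed to the geometric stage as `DENSE` and geometry decides which are
#' skin. `mapping = "background"` or `"candidate"` forces either treatment
#' of the darker sub-cluster.
#'
#' @param original A [gray_volume()] holding the unfiltered intensities.
#' @param labels A [label_volume()] from [partition_4()] (with `MIXED`).
#' @param seed Seed forwarded to [c_means()].
#' @param mapping Treatment of the darker sub-cluster: `"auto"` (default),
#'   `"background"`, or `"candidate"`.
#' @return A [label_volume()] over `BACKGROUND`/`FAT`/`DENSE` with the
#'   2-cluster model as attribute `"submodel"` and the chosen mapping as
#'   attribute `"darker_mapped_to"`. If no `MIXED` voxels exist the labels
#'   are returned unchanged with a warning.
#' @export
recluster_mixed <- function(original, labels, seed = 1L,
                            mapping = c("auto", "background", "candidate")) {
  stopifnot(inherits(original, "gray_volume"), inherits(labels, "label_volume"))
  mapping <- match.arg(mapping)
  if (!identical(dim(original$data), dim(labels$labels)))
    stop("volume and labels have different shapes")
  idx <- labels$labels == MIXED
  if (!any(idx)) {
    warning("no MIXED voxels to re-cluster; labels returned unchanged")
    return(labels)
  }
  vals <- original$data[idx]
  cm <- c_means(vals, k = 2L, seed = seed)
  darker_to_bg <- switch(mapping,
    background = TRUE,
    candidate = FALSE,
    auto = {
      bg_idx <- labels$labels == BG
      bg_mean <- if (any(bg_idx)) mean(original$data[bg_idx]) else -Inf
      abs(cm$means[1] - bg_mean) < abs(cm$means[1] - cm$means[2])
    })
  lab <- labels$labels
  lab[idx] <- if (darker_to_bg) ifelse(cm$assignment == 1L, BG, DENSE)
    else DENSE
  out <- label_volume(lab, labels$spacing, allow_mixed = FALSE)
  attr(out, "submodel") <- cm
  attr(out, "darker_mapped_to") <- if (darker_to_bg) "background" else "candidate"
  out
}
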