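#' Correlate state power maps between two models
#'
#' Computes, for every pair of states from two independently fitted models,
#' the Pearson correlation across parcels of their band-limited power maps -
#' separately per frequency band - and averages the per-band correlation
#' matrices.
#'
#' @param maps_a,maps_b tibbles from [band_maps()] over the same parcels and
#'   bands.
#' @param value which map representation to correlate: `"relative"`
#'   (difference to the state mean, comparable across models) or `"power"`.
#' @return object of class `map_correlation`: `per_band` (named list of
#'   K_A x K_B matrices) and `mean` (their average).
#' @export
power_map_correlation <- function(maps_a, maps_b, value = c("relative", "power")) {
  value <- match.arg(value)
  bands <- intersect(unique(maps_a$band), unique(maps_b$band))
  if (!length(bands)) abort("no common bands")
  wide <- function(maps, b) {
    m <- maps[maps$band == b, , drop = FALSE]
    m <- m[order(m$state, m$parcel), , drop = FALSE]
    matrix(m[[value]], nrow = dplyr::n_distinct(m$parcel),
           ncol = dplyr::n_distinct(m$state))
  }
  per_band <- list()
  joint_band <- list()
  for (b in bands) {
    A <- wide(maps_a, b)
    B <- wide(maps_b, b)
    if (nrow(A) != nrow(B)) abort("maps must share the parcel set")
    bad_a <- which(apply(A, 2, sd) == 0)
    bad_b <- which(apply(B, 2, sd) == 0)
    if (length(bad_a) || length(bad_b)) {
      abort(sprintf("constant power map (band %s, states A:%s B:%s)", b,
                    paste(bad_a, collapse = ","), paste(bad_b, collapse = ",")))
    }
    per_band[[b]] <- cor(A, B)
    joint_band[[b]] <- cor(cbind(A, B)) # all 2K states in one frame
  }
  structure(list(per_band = per_band,
                 mean = Reduce(`+`, per_band) / length(per_band),
                 joint = Reduce(`+`, joint_band) / length(joint_band),
                 K_a = nrow(per_band[[1]]), K_b = ncol(per_band[[1]])),
            class = "map_correlation")
}

#' Match states across models by hierarchical clustering
#'
#' Represents each of the `2K` states by its row of the joint (all-states)
#' mean correlation matrix, clusters the `2K` feature vectors
#' agglomeratively (Euclidean distance, Ward linkage), and reads off
#' cross-model matches greedily: the cross-model pair with the smallest
#' cophenetic merge height is matched first, both states are removed, and
#' the process repeats. Identical models therefore match at height ~0 as
#' the identity pairing. Given only a cross-model K x K matrix (no joint
#' information), each A-state is represented by its row and each B-state by
#' its column of that matrix.
#'
#' @param x a [power_map_correlation()] result or a plain K_A x K_B mean
#'   correlation matrix (K_A must equal K_B).
#' @return object of class `state_match`: `pairs` (tibble `state_a`,
#'   `state_b`, `height`), `linkage` (an `hclust` tree over the 2K states,
#'   A-states first) and the correlation matrix used.
#' @export
hierarchical_match <- function(x) {
  corr <- if (inherits(x, "map_correlation")) x$mean else as.matrix(x)
  if (!all(is.finite(corr))) abort("correlation matrix must be finite")
  Ka <- nrow(corr); Kb <- ncol(corr)
  if (Ka != Kb) abort("joint clustering requires the same K in both models")
  feats <- if (inherits(x, "map_correlation") && !is.null(x$joint)) {
    x$joint
  } else {
    rbind(corr, t(corr)) # A-state rows, then B-state rows
  }
  rownames(feats) <- c(paste0("A", seq_len(Ka)), paste0("B", seq_len(Kb)))
  hc <- stats::hclust(stats::dist(feats), method = "ward.D2")
  ch <- as.matrix(stats::cophenetic(hc))
  pairs <- list()
  free_a <- seq_len(Ka); free_b <- seq_len(Kb)
  while (length(free_a) && length(free_b)) {
    sub <- ch[free_a, Ka + free_b, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ] # tie-break by index
    a <- free_a[best[1]]; b <- free_b[best[2]]
    pairs[[length(pairs) + 1]] <- tibble(state_a = a, state_b = b,
                                         height = min(sub))
    free_a <- setdiff(free_a, a); free_b <- setdiff(free_b, b)
  }
  structure(list(pairs = dplyr::bind_rows(pairs), linkage = hc, corr = corr),
            class = "state_match")
}

#' @export
print.state_match <- function(x, ...) {
  cat("<state_match> cross-model pairs (ascending merge height):\n")
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.state_match <- function(x, ...) x$pairs
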