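#' Random partition of spectral bands into disjoint subsets
#'
#' Splits `1..D` into `n_subsets` mutually exclusive, collectively
#' exhaustive groups by random sampling; sizes differ by at most one.
#' Deterministic given `seed`.
#'
#' @param D band count.
#' @param n_subsets number of groups (default 4).
#' @param seed RNG seed.
#' @return object of class `FeaturePartition`: list `subsets` of sorted
#'   band-index vectors plus the seed.
#' @export
split_features <- function(D, n_subsets = 4L, seed = NULL) {
  if (D < n_subsets) stop("need at least one band per subset")
  perm <- with_seed(seed, sample.int(D))
  sizes <- rep(D %/% n_subsets, n_subsets)
  extra <- D %% n_subsets
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  subsets <- lapply(seq_len(n_subsets),
                    function(i) sort(perm[starts[i]:ends[i]]))
  structure(list(subsets = subsets, seed = seed), class = "FeaturePartition")
}

#' Majority vote over classification maps
#'
#' Per pixel, the modal label across voters. Ties break toward the class
#' with the highest mean probability across the voters that supplied
#' probabilities, then toward the smallest class id. Background pixels
#' (label 0 in every map) stay background.
#'
#' @param maps list of `M x N` integer matrices or [label_map()]s sharing
#'   shape and class vocabulary.
#' @param probs optional list (one per voter) of `M x N x K` probability
#'   arrays aligned with `class_ids`.
#' @param class_ids class vocabulary; defaults to the sorted positive
#'   labels present in the maps.
#' @return a [label_map()].
#' @export
majority_vote <- function(maps, probs = NULL, class_ids = NULL) {
  if (!length(maps)) stop("no maps to vote over")
  maps <- lapply(maps, function(m) if (inherits(m, "LabelMap")) m$labels else m)
  dm <- dim(maps[[1L]])
  if (!all(vapply(maps, function(m) identical(dim(m), dm), logical(1))))
    stop("maps differ in shape")
  if (is.null(class_ids))
    class_ids <- sort(unique(unlist(lapply(maps, function(m) m[m > 0L]))))
  V <- length(maps)
  stack <- vapply(maps, as.vector, integer(prod(dm)))
  if (is.null(dim(stack))) stack <- matrix(stack, nrow = 1L)
  mean_prob <- NULL
  if (!is.null(probs)) {
    K <- length(class_ids)
    mean_prob <- Reduce(`+`, lapply(probs, function(p) matrix(p, ncol = K))) /
      length(probs)
  }
  out <- integer(prod(dm))
  for (px in seq_len(prod(dm))) {
    votes <- stack[px, ]
    votes <- votes[votes > 0L]
    if (!length(votes)) next
    tab <- tabulate(match(votes, class_ids), nbins = length(class_ids))
    top <- which(tab == max(tab))
    if (length(top) > 1L && !is.null(mean_prob))
      top <- top[order(-mean_prob[px, top], class_ids[top])]
    out[px] <- class_ids[top[1L]]
  }
  label_map(matrix(out, dm[1L], dm[2L]))
}
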