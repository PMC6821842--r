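#' Split the grand matrix into single-trial test and averaged reference rows
#'
#' For every (exemplar, contact) cell one trial is chosen at random and its
#' time series concatenated across contacts into the test matrix T (one row
#' per exemplar); the remaining trials are averaged into the reference
#' matrix R. No trial contributes to both sides.
#'
#' @param G A [build_response_matrix()] array; every cell needs >= 2 trials.
#' @param seed Integer seed; chosen trial indices are reproducible from it.
#' @return List with matrices `test`, `reference` (exemplars x
#'   contacts*timepoints) and the `chosen` trial index matrix.
#' @export
split_test_reference <- function(G, seed = 1L) {
  set.seed(seed)
  d <- dim(G)
  n_e <- d[1]; n_c <- d[2]
  test <- reference <- matrix(0, n_e, n_c * d[4])
  chosen <- matrix(0L, n_e, n_c)
  for (e in seq_len(n_e)) for (ci in seq_len(n_c)) {
    avail <- which(!is.na(G[e, ci, , 1]))
    if (length(avail) < 2)
      stop("need >= 2 trials per (exemplar, contact) cell")
    pick <- avail[sample.int(length(avail), 1L)]
    chosen[e, ci] <- pick
    cols <- (ci - 1L) * d[4] + seq_len(d[4])
    test[e, cols] <- G[e, ci, pick, ]
    rest <- setdiff(avail, pick)
    rv <- matrix(G[e, ci, rest, ], nrow = length(rest))
    reference[e, cols] <- colMeans(rv)
  }
  list(test = test, reference = reference, chosen = chosen)
}

#' Greedy global-minimum assignment of test rows to reference rows
#'
#' Repeatedly finds the smallest entry of the distance matrix over the still
#' unassigned rows and columns, assigns that test row to that reference row,
#' and removes both - so each reference row is used exactly once. Ties are
#' broken by the smallest (test, reference) index pair.
#'
#' @param d Square matrix of finite distances (test rows x reference
#'   columns).
#' @return Integer permutation: `out[i]` is the reference assigned to test
#'   row i.
#' @export
greedy_assign <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!all(is.finite(d))) stop("distance matrix must be finite")
  n <- nrow(d)
  out <- integer(n)
  work <- d
  for (step in seq_len(n)) {
    m <- which(work == min(work), arr.ind = TRUE)
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE][1, ]
    out[m[1]] <- m[2]
    work[m[1], ] <- Inf
    work[, m[2]] <- Inf
  }
  out
}

euclidean_cross <- function(a, b) {
  # ||a_i - b_j|| for all row pairs
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Template-matching decoding of face exemplars
#'
#' Every iteration splits the grand matrix into single-trial test rows and
#' remaining-trial reference templates, computes all Euclidean row-to-row
#' distances, greedily assigns each test row to a reference row
#' ([greedy_assign()]), and scores the fraction of exemplars assigned to
#' their own template. Decoding accuracy is the mean over iterations.
#'
#' @param G A [build_response_matrix()] array.
#' @param n_iter Number of decoding iterations.
#' @param seed Integer seed.
#' @return Object of class `decoding_result`: `accuracy`,
#'   `per_iteration_accuracies`, `n_iterations`, `seed`.
#' @export
decode_exemplars <- function(G, n_iter = 1000, seed = 1L) {
  acc <- vapply(seq_len(n_iter), function(it) {
    sp <- split_test_reference(G, derive_seed(seed, it))
    perm <- greedy_assign(euclidean_cross(sp$test, sp$reference))
    mean(perm == seq_along(perm))
  }, numeric(1))
  structure(list(accuracy = mean(acc), per_iteration_accuracies = acc,
                 n_iterations = n_iter, permutation_p = NULL, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result: accuracy %.3f over %d iterations",
              x$accuracy, x$n_iterations))
  if (!is.null(x$permutation_p))
    cat(sprintf(" (permutation p %s)",
                if (x$permutation_p == 0)
                  sprintf("< %.3g", 1 / x$n_perm)
                else format(x$permutation_p)))
  cat("\n")
  invisible(x)
}

# shuffle single-trial exemplar labels independently within each contact:
# trials are reassigned across the exemplar-by-repetition grid, destroying
# the exemplar grouping while preserving each contact's trial pool
shuffle_exemplar_labels <- function(G) {
  out <- G
  d <- dim(G)
  for (ci in seq_len(d[2])) {
    flat <- matrix(G[, ci, , ], d[1] * d[3], d[4])
    obs <- which(!is.na(flat[, 1]))     # missing repetitions stay in place
    flat[obs, ] <- flat[obs[sample.int(length(obs))], , drop = FALSE]
    out[, ci, , ] <- array(flat, c(d[1], d[3], d[4]))
  }
  out
}

#' Permutation test for decoding accuracy
#'
#' Recomputes the decoding accuracy under single-trial exemplar-label
#' shuffles (trials reassigned across exemplars independently within each
#' contact, preserving contact marginals); p is the proportion of shuffled
#' accuracies
#' greater than or equal to the observed one. A p of 0 is reported in text
#' as `< 1/n_perm` but stored as 0.
#'
#' @param G A [build_response_matrix()] array.
#' @param n_perm Number of label shuffles (>= 1).
#' @param n_iter Decoding iterations per accuracy estimate (reduced relative
#'   to the headline run to keep the null affordable).
#' @param seed Integer seed.
#' @param observed Optional precomputed observed accuracy.
#' @return List with `p`, `observed`, `null` (vector of shuffled
#'   accuracies).
#' @export
decoding_permutation_test <- function(G, n_perm = 200, n_iter = 100,
                                      seed = 1L, observed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(observed))
    observed <- decode_exemplars(G, n_iter, derive_seed(seed, 0))$accuracy
  null <- vapply(seq_len(n_perm), function(pm) {
    set.seed(derive_seed(seed, pm))
    Gs <- shuffle_exemplar_labels(G)
    decode_exemplars(Gs, n_iter, derive_seed(seed, n_perm + pm))$accuracy
  }, numeric(1))
  list(p = mean(null >= observed), observed = observed, null = null)
}
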