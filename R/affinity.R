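#' Similarity matrix from a distance matrix
#'
#' The classic affinity-propagation convention for points in a Euclidean
#' space: similarity is negative squared distance, so similarities are
#' nonpositive and order-reversing in distance. The diagonal is left at zero
#' for later preference injection.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @return Matrix `s` with `s[i, j] = -D[i, j]^2`.
#' @export
similarities_from_distances <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D), all(D >= 0))
  s <- -D^2
  dimnames(s) <- NULL
  s
}

offdiag <- function(M) M[row(M) != col(M)]

#' Net similarity of an exemplar assignment
#'
#' Affinity propagation's objective: the sum over non-exemplar points of
#' their similarity to their exemplar, plus the preferences of the chosen
#' exemplars.
#'
#' @param s Similarity matrix (off-diagonal part used).
#' @param preference Per-point preference vector (or scalar).
#' @param exemplars Indices of the exemplar points.
#' @param labels For each point, the index of its exemplar.
#' @return Scalar objective value.
#' @export
net_similarity <- function(s, preference, exemplars, labels) {
  n <- nrow(s)
  preference <- rep_len(preference, n)
  val <- sum(preference[exemplars])
  for (i in seq_len(n))
    if (!(i %in% exemplars)) val <- val + s[i, labels[i]]
  val
}

#' Affinity propagation clustering
#'
#' Responsibility/availability message passing after Frey & Dueck, run until
#' the exemplar set is stable for `conv_window` consecutive iterations or
#' `max_iter` is reached. Deterministic: ties in the final assignment are
#' broken toward the lowest exemplar index and no noise is injected unless
#' `jitter > 0`.
#'
#' @param s Similarity matrix (diagonal ignored).
#' @param preference Scalar or per-point preference (self-similarity).
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter,conv_window Iteration budget and required stable stretch.
#' @param seed Seed used only when `jitter > 0`.
#' @param jitter Relative scale of symmetry-breaking noise added to `s`
#'   (default 0: none).
#' @return Object of class `ap_fit`: `labels` (index of each point's
#'   exemplar), `exemplars`, `clusters` (1-based cluster id per point, in
#'   order of exemplar index), `net_similarity`, `n_iter`, `converged`.
#' @export
affinity_propagation <- function(s, preference, damping = 0.9,
                                 max_iter = 1000L, conv_window = 50L,
                                 seed = 1L, jitter = 1e-6) {
  s <- as.matrix(s)
  n <- nrow(s)
  stopifnot(n >= 1, damping >= 0.5, damping < 1)
  preference <- rep_len(preference, n)
  if (n == 1L)
    return(structure(list(labels = 1L, exemplars = 1L, clusters = 1L,
                          net_similarity = preference[1], n_iter = 0L,
                          converged = TRUE),
                     class = "ap_fit"))
  S <- s
  if (jitter > 0) {
    set.seed(as.integer(seed))
    scale <- max(abs(offdiag(S)), 1e-12)
    S <- S + matrix(stats::rnorm(n * n, 0, jitter * scale), n, n)
  }
  diag(S) <- preference
  R <- A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- NULL
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    AS <- A + S
    first_idx <- max.col(AS, ties.method = "first")
    first_max <- AS[cbind(seq_len(n), first_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), first_idx)] <- -Inf
    second_max <- apply(AS2, 1L, max)
    Rnew <- S - first_max
    Rnew[cbind(seq_len(n), first_idx)] <- S[cbind(seq_len(n), first_idx)] -
      second_max
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)          # colsum - r(k,k) = sum of positive off-diag
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, prev_ex) && length(ex) > 0L) stable <- stable + 1L
    else stable <- 0L
    prev_ex <- ex
    if (stable >= conv_window) { converged <- TRUE; break }
  }
  ex <- prev_ex
  if (length(ex) == 0L)
    ex <- which.max(diag(A) + diag(R))
  if (!converged)
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; returning the current assignment")
  ex <- refine_exemplars(s, preference, unname(ex))
  labels <- ex[max.col(s[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  structure(list(labels = labels, exemplars = ex,
                 clusters = match(labels, ex),
                 net_similarity = net_similarity(s, preference, ex, labels),
                 n_iter = it, converged = converged),
            class = "ap_fit")
}

# Greedy local search on the net-similarity objective: add or drop single
# exemplars while the objective improves. Message passing can settle in a
# poor fixed point (e.g. a distant two-point cluster never accumulates
# enough self-evidence at very negative preferences); this deterministic
# polish guarantees local optimality with respect to single moves.
refine_exemplars <- function(s, preference, ex, max_pass = 25L) {
  n <- nrow(s)
  preference <- rep_len(preference, n)
  objective <- function(E) {
    if (length(E) == 0L) return(-Inf)
    best <- apply(s[, E, drop = FALSE], 1L, max)
    best[E] <- 0
    sum(best) + sum(preference[E])
  }
  cur <- objective(ex)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (j in seq_len(n)) {
      E2 <- if (j %in% ex) setdiff(ex, j) else sort(c(ex, j))
      if (length(E2) == 0L) next
      val <- objective(E2)
      if (val > cur + 1e-12) {
        ex <- E2
        cur <- val
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  sort(ex)
}

#' Two-stage affinity propagation on a window-distance matrix
#'
#' Stage 1 clusters all windows with a uniform preference equal to the
#' median off-diagonal similarity. Stage 2 re-clusters the stage-1 exemplars
#' only, using their original pairwise similarities, with preferences that
#' favour exemplars of large stage-1 clusters (see the source for the
#' anchoring rule): exemplars that unified many windows stay attractive and
#' small noise-driven clusters are absorbed. Every window inherits the
#' stage-2 label of its stage-1 exemplar.
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param damping,max_iter,conv_window,seed Passed to
#'   [affinity_propagation()].
#' @param stage2 Set `FALSE` to stop after the first pass.
#' @return Object of class `state_clustering`: `labels` (0-based consecutive
#'   state labels ordered by first occurrence in time), `exemplars`
#'   (original window index of each state's exemplar, in label order),
#'   `n_states`, `net_similarity` of the final assignment under the stage-1
#'   preferences, `stage1`/`stage2` fits, `converged`.
#' @export
two_stage_cluster <- function(D, damping = 0.9, max_iter = 1000L,
                              conv_window = 50L, seed = 1L, stage2 = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- similarities_from_distances(D)
  if (n == 1L)
    return(structure(list(labels = 0L, exemplars = 1L, n_states = 1L,
                          net_similarity = 0, stage1 = NULL, stage2 = NULL,
                          converged = TRUE),
                     class = "state_clustering"))
  if (max(D) == 0) {
    # all windows identical: a single state, no message passing needed
    return(structure(list(labels = rep(0L, n), exemplars = 1L, n_states = 1L,
                          net_similarity = 0, stage1 = NULL, stage2 = NULL,
                          converged = TRUE),
                     class = "state_clustering"))
  }
  pref1 <- stats::median(offdiag(s))
  fit1 <- affinity_propagation(s, pref1, damping, max_iter, conv_window, seed)
  ex1 <- fit1$exemplars
  sizes <- as.vector(table(factor(fit1$labels, levels = ex1)))
  # Exemplars of clearly undersized stage-1 clusters (bridge windows that
  # straddle a regime switch typically form such fragments) do not enter
  # the second pass at all: their windows follow the nearest surviving
  # exemplar. This is the strongest form of down-weighting small clusters.
  keep <- sizes >= max(2, 0.25 * stats::median(sizes))
  if (!any(keep)) keep <- rep(TRUE, length(ex1))
  if (any(!keep) && length(ex1) > 1L) {
    kept_ex <- ex1[keep]
    host <- kept_ex[max.col(s[ex1[!keep], kept_ex, drop = FALSE],
                            ties.method = "first")]
    # a fragment is only absorbed if its host is genuinely close (closer
    # than the typical between-exemplar distance); a small but distant
    # cluster is a real state and stays
    near <- s[cbind(ex1[!keep], host)] >
      stats::median(offdiag(s[ex1, ex1, drop = FALSE]))
    host <- ifelse(near, host, ex1[!keep])
    relink <- ex1
    relink[!keep] <- host
    fit1$labels <- relink[match(fit1$labels, ex1)]
    ex1 <- ex1[ex1 %in% relink]
    sizes <- as.vector(table(factor(fit1$labels, levels = ex1)))
  }
  if (!stage2 || length(ex1) == 1L) {
    final_ex_of_window <- fit1$labels
    fit2 <- NULL
  } else {
    s2 <- s[ex1, ex1, drop = FALSE]
    # Preference anchor midway between the within-state similarity scale
    # (median similarity of non-exemplar windows to their stage-1 exemplar)
    # and the between-state scale (median off-diagonal similarity among
    # exemplars): exemplars closer than the anchor merge (sub-clusters of
    # one state, noise-driven fragments), exemplars farther apart survive.
    # Scaling by sqrt(max(size)/size) leaves the largest cluster's exemplar
    # at the anchor and pushes small clusters' exemplars down, without
    # overwhelming a genuinely distant small state. The tiny upward bias
    # resolves exact ties toward keeping states separate.
    w_sims <- s[cbind(seq_len(n), fit1$labels)]
    w_sims <- w_sims[seq_len(n) != fit1$labels]
    within_scale <- if (length(w_sims)) stats::median(w_sims) else 0
    # lower quartile: robust between-state magnitude even when same-state
    # sub-cluster pairs make up half of the exemplar pairs
    between_scale <- unname(stats::quantile(offdiag(s2), 0.25))
    anchor <- (within_scale + between_scale) / 2
    pref2 <- anchor * sqrt(max(sizes) / sizes)
    pref2 <- pref2 + 1e-6 * abs(anchor)
    fit2 <- affinity_propagation(s2, pref2, damping, max_iter, conv_window,
                                 seed)
    # map each window through its stage-1 exemplar to the stage-2 exemplar
    stage2_of_ex1 <- ex1[fit2$labels]          # original index
    final_ex_of_window <- stage2_of_ex1[match(fit1$labels, ex1)]
  }
  # medoid polish: relocate each state's exemplar to the member maximising
  # within-state similarity, then re-assign windows to their best exemplar
  ex_final <- unique(final_ex_of_window)
  for (e in ex_final) {
    members <- which(final_ex_of_window == e)
    if (length(members) > 1L) {
      med <- members[which.max(colSums(s[members, members, drop = FALSE]))]
      if (med != e) {
        final_ex_of_window[members] <- med
        ex_final[ex_final == e] <- med
      }
    }
  }
  reassigned <- ex_final[max.col(s[, ex_final, drop = FALSE],
                                 ties.method = "first")]
  reassigned[ex_final] <- ex_final
  final_ex_of_window <- reassigned
  first <- unique(final_ex_of_window)          # order of first occurrence
  labels <- match(final_ex_of_window, first) - 1L
  pref_all <- rep(pref1, n)
  ns <- net_similarity(s, pref_all, first, final_ex_of_window)
  structure(list(labels = labels, exemplars = first,
                 n_states = length(first), net_similarity = ns,
                 stage1 = fit1, stage2 = fit2,
                 converged = fit1$converged &&
                   (is.null(fit2) || fit2$converged)),
            class = "state_clustering")
}
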