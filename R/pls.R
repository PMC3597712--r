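#' Assemble the PLS data matrix from a measures table
#'
#' Rows are participants within conditions within groups; columns are
#' electrodes; entries are one non-stationarity measure.
#'
#' @param measures The `averaged` table from [cohort_measures()].
#' @param which `"n_states"` or `"mean_seg_len_s"`.
#' @return List with `X` (row per subject x group x condition, column per
#'   channel) and `meta` (subject, group, condition per row).
#' @export
pls_data <- function(measures, which = c("n_states", "mean_seg_len_s")) {
  which <- match.arg(which)
  channels <- sort(unique(measures$channel))
  key <- interaction(measures$subject, measures$group, measures$condition,
                     drop = TRUE)
  rows <- split(measures, key)
  X <- t(vapply(rows, function(r) {
    v <- r[[which]][match(channels, r$channel)]
    if (anyNA(v)) stop("missing channel rows for ", r$subject[1])
    v
  }, numeric(length(channels))))
  meta <- do.call(rbind, lapply(rows, function(r)
    data.frame(subject = r$subject[1], group = r$group[1],
               condition = r$condition[1])))
  meta$group <- factor(meta$group, levels = unique(measures$group))
  meta$condition <- factor(meta$condition,
                           levels = unique(measures$condition))
  o <- order(meta$group, meta$condition, meta$subject)
  rownames(meta) <- NULL
  list(X = X[o, , drop = FALSE], meta = meta[o, ], channels = channels)
}

as_cell_factors <- function(meta) {
  g <- meta$group
  cnd <- meta$condition
  if (!is.factor(g)) g <- factor(g, levels = unique(g))
  if (!is.factor(cnd)) cnd <- factor(cnd, levels = unique(cnd))
  list(group = droplevels(g), condition = droplevels(cnd))
}

cell_id <- function(meta) {
  f <- as_cell_factors(meta)
  interaction(f$group, f$condition, drop = FALSE, lex.order = TRUE)
}

#' Within-cell mean matrix
#'
#' Column-wise means of the data matrix within each group-by-condition cell.
#'
#' @param X Row-per-participant data matrix.
#' @param meta Data frame with `group` and `condition` per row of `X`.
#' @return List with `M` (cell by electrode matrix) and `cells` (group,
#'   condition per row of `M`, groups varying slowest).
#' @export
build_cell_means <- function(X, meta) {
  f <- as_cell_factors(meta)
  id <- cell_id(meta)
  if (nlevels(id) < 2L) stop("need at least 2 group x condition cells")
  counts <- table(id)
  if (any(counts == 0L))
    stop("empty cell(s): ", paste(names(counts)[counts == 0L], collapse = ", "))
  M <- do.call(rbind, lapply(levels(id), function(l)
    colMeans(X[id == l, , drop = FALSE])))
  cells <- expand.grid(condition = levels(f$condition),
                       group = levels(f$group),
                       stringsAsFactors = FALSE)[, c("group", "condition")]
  rownames(cells) <- NULL
  list(M = M, cells = cells, n_per_cell = as.vector(counts))
}

pls_svd <- function(M) {
  sv <- svd(M)
  keep <- seq_len(min(dim(M)))
  list(d = sv$d[keep], u = sv$u[, keep, drop = FALSE],
       v = sv$v[, keep, drop = FALSE])
}

#' Mean-centered (task) PLS
#'
#' The group-by-condition cell means are centered by the grand mean of the
#' cell means per electrode, and the centered matrix is decomposed by SVD.
#' Each latent variable pairs a condition-loading vector over cells (left
#' singular vector) with an electrode-loading vector (right singular
#' vector) and a singular value.
#'
#' @inheritParams build_cell_means
#' @return Object of class `pls_fit` with `d` (singular values,
#'   non-increasing), `condition_loadings` (cells x LV), `electrode_loadings`
#'   (electrodes x LV), `cells`, `mode = "mean_centered"` and the decomposed
#'   matrix `decomposed`.
#' @export
mean_centered_pls <- function(X, meta) {
  cm <- build_cell_means(X, meta)
  R <- sweep(cm$M, 2L, colMeans(cm$M))
  sv <- pls_svd(R)
  structure(list(d = sv$d, condition_loadings = sv$u,
                 electrode_loadings = sv$v, cells = cm$cells,
                 decomposed = R, mode = "mean_centered", design = NULL),
            class = "pls_fit")
}

#' Contrast (a priori) PLS
#'
#' Projects the cell means onto mutually orthogonal, zero-sum contrasts over
#' the group-by-condition cells, and decomposes the resulting
#' contrast-by-electrode covariance matrix by SVD.
#'
#' @inheritParams build_cell_means
#' @param design Cell-by-contrast matrix; columns must be mutually
#'   orthogonal and sum to zero. Rows follow the cell order of
#'   [build_cell_means()] (groups varying slowest).
#' @return Object of class `pls_fit`; `condition_loadings` are the cell-level
#'   expressions of the latent contrasts (`design %*% u`, unit-normalised),
#'   `contrast_loadings` the raw left singular vectors.
#' @export
contrast_pls <- function(X, meta, design) {
  design <- as.matrix(design)
  cm <- build_cell_means(X, meta)
  if (nrow(design) != nrow(cm$M))
    stop("design has ", nrow(design), " rows but there are ", nrow(cm$M),
         " cells")
  if (max(abs(colSums(design))) > 1e-8)
    stop("contrasts must each sum to zero")
  gram <- crossprod(design)
  if (ncol(design) > 1L &&
      max(abs(gram[row(gram) != col(gram)])) > 1e-8)
    stop("contrasts must be mutually orthogonal")
  Cov <- crossprod(design, cm$M)
  sv <- pls_svd(Cov)
  cond <- design %*% sv$u
  cond <- sweep(cond, 2L, pmax(sqrt(colSums(cond^2)), 1e-300), "/")
  structure(list(d = sv$d, condition_loadings = cond,
                 contrast_loadings = sv$u, electrode_loadings = sv$v,
                 cells = cm$cells, decomposed = Cov, mode = "contrast",
                 design = design),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %s PLS: %d LV(s), singular values %s\n", x$mode,
              length(x$d), paste(signif(x$d, 4), collapse = ", ")))
  invisible(x)
}

refit_pls <- function(X, meta, mode, design) {
  if (mode == "mean_centered") mean_centered_pls(X, meta)
  else contrast_pls(X, meta, design)
}

# All rows of one subject get their (group, condition) cell tuples permuted.
permute_meta_within_subject <- function(meta) {
  out <- meta
  for (s in unique(meta$subject)) {
    idx <- which(meta$subject == s)
    perm <- idx[sample.int(length(idx))]
    out$group[idx] <- meta$group[perm]
    out$condition[idx] <- meta$condition[perm]
  }
  out
}

#' Permutation test for PLS latent variables
#'
#' Condition/group cell assignments are randomly reassigned within subjects,
#' the PLS is recomputed, and each latent variable's p-value is the plain
#' exceedance proportion: the fraction of permuted k-th singular values
#' strictly greater than the observed k-th singular value.
#'
#' @inheritParams build_cell_means
#' @param mode `"mean_centered"` or `"contrast"`.
#' @param design Contrast matrix (contrast mode only).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `perm_p` per LV, the observed singular values `d`, and
#'   the permutation null matrix `perm_d` (LV by permutation).
#' @export
permutation_test <- function(X, meta, mode = c("mean_centered", "contrast"),
                             design = NULL, n_perm = 500L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 100L)
  obs <- refit_pls(X, meta, mode, design)
  set.seed(as.integer(seed))
  n_per_subject <- table(meta$subject)
  log_total <- sum(lgamma(n_per_subject + 1))
  if (log_total < log(n_perm))
    warning("fewer distinct within-subject permutations (",
            round(exp(log_total)), ") than n_perm; p-values are based on ",
            "resampled permutations and may repeat")
  perm_d <- matrix(NA_real_, length(obs$d), n_perm)
  for (b in seq_len(n_perm)) {
    pm <- permute_meta_within_subject(meta)
    perm_d[, b] <- refit_pls(X, pm, mode, design)$d
  }
  perm_p <- rowMeans(perm_d > obs$d)
  list(perm_p = perm_p, d = obs$d, perm_d = perm_d)
}

#' Bootstrap ratios for electrode loadings
#'
#' Participants are resampled with replacement within each group-by-condition
#' cell, the PLS is recomputed, and each resample's electrode loadings are
#' sign-aligned to the original by the sign of their inner product per LV.
#' The bootstrap ratio is the original loading divided by the bootstrap
#' standard error; `|ratio| >= 2` is conventionally read as stable
#' (roughly a 95% confidence criterion).
#'
#' @inheritParams permutation_test
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @return List with `bsr` (electrode by LV), `se`, `loadings` (original),
#'   `zero_se` flag matrix (ratios reported as `Inf` sentinels where the
#'   bootstrap distribution collapsed).
#' @export
bootstrap_ratios <- function(X, meta, mode = c("mean_centered", "contrast"),
                             design = NULL, n_boot = 500L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_boot >= 100L)
  id <- droplevels(cell_id(meta))
  if (any(table(id) < 3L))
    stop("every cell needs at least 3 participants for the bootstrap")
  obs <- refit_pls(X, meta, mode, design)
  v0 <- obs$electrode_loadings
  set.seed(as.integer(seed))
  boots <- array(NA_real_, c(nrow(v0), ncol(v0), n_boot))
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(split(seq_len(nrow(X)), id), function(idx)
      idx[sample.int(length(idx), replace = TRUE)]), use.names = FALSE)
    fit <- refit_pls(X[take, , drop = FALSE], meta[take, ], mode, design)
    vb <- fit$electrode_loadings
    flip <- sign(colSums(vb * v0))
    flip[flip == 0] <- 1
    boots[, , b] <- sweep(vb, 2L, flip, "*")
  }
  se <- apply(boots, c(1L, 2L), stats::sd)
  zero_se <- se == 0
  bsr <- v0 / se
  bsr[zero_se] <- ifelse(v0[zero_se] >= 0, Inf, -Inf)
  list(bsr = bsr, se = se, loadings = v0, zero_se = zero_se, d = obs$d)
}

#' Linear trend contrast over ordered groups, balanced over conditions
#'
#' Convenience builder for the age-effect analysis: a single contrast that
#' increases linearly over groups and is constant over conditions, centred
#' and unit-normalised.
#'
#' @param groups,conditions Group labels in age order and condition labels.
#' @return Cell-by-1 contrast matrix in [build_cell_means()] cell order.
#' @export
linear_trend_contrast <- function(groups, conditions) {
  g <- rep(seq_along(groups), each = length(conditions))
  v <- g - mean(g)
  matrix(v / sqrt(sum(v^2)), ncol = 1)
}

#' Condition-difference contrast balanced over groups
#'
#' @inheritParams linear_trend_contrast
#' @return Cell-by-1 contrast matrix (first condition positive).
#' @export
condition_contrast <- function(groups, conditions) {
  stopifnot(length(conditions) == 2L)
  v <- rep(c(1, -1), times = length(groups))
  matrix(v / sqrt(sum(v^2)), ncol = 1)
}
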