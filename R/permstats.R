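#' @keywords internal
# p-value from a permutation null: one-tailed is the proportion of null >=
# observed (ties count toward the null, floor 1/n_perm); two-tailed doubles
# the observed direction's tail (2 * min of the two tail proportions,
# capped at 1), which keeps the two-sided size at its nominal level.
perm_pvalue <- function(observed, null, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (is.na(observed)) return(NA_real_)
  null <- null[!is.na(null)]
  n <- length(null)
  p_up <- max(mean(null >= observed), 1 / n)
  if (tails == "one") return(p_up)
  p_lo <- max(mean(null <= observed), 1 / n)
  min(2 * min(p_up, p_lo), 1)
}

# orthonormal within-subject contrast bases, one per main effect and
# interaction, built once from the cell design; effect F statistics are
# quadratic forms of the data projected onto these bases (balanced,
# one observation per participant x cell; sphericity-assumed F)
rm_anova_bases <- function(cells) {
  factors <- names(cells)
  contrast_cols <- lapply(cells, function(f) {
    f <- factor(f)
    k <- nlevels(f)
    h <- stats::contr.helmert(k)
    h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
    h[as.integer(f), , drop = FALSE]
  })
  effects <- unlist(lapply(seq_along(factors), function(m) {
    utils::combn(factors, m, simplify = FALSE)
  }), recursive = FALSE)
  n_cells <- nrow(cells)
  bases <- lapply(effects, function(ef) {
    q <- matrix(1, n_cells, 1)
    for (f in ef) {
      cols <- contrast_cols[[f]]
      q <- do.call(cbind, lapply(seq_len(ncol(cols)), function(j) {
        q * cols[, j]
      }))
    }
    # balanced design: rescale to unit-norm columns in cell space
    sweep(q, 2, sqrt(colSums(q^2)), "/")
  })
  names(bases) <- vapply(effects, paste, "", collapse = ":")
  bases
}

# F per effect from the participant x cell matrix Y and precomputed bases
rm_anova_f <- function(y, bases) {
  s <- nrow(y)
  vapply(bases, function(q) {
    z <- y %*% q                      # participants x df columns
    zbar <- colMeans(z)
    ss_effect <- s * sum(zbar^2)
    ss_error <- sum(sweep(z, 2, zbar)^2)
    d1 <- ncol(q)
    d2 <- d1 * (s - 1)
    (ss_effect / d1) / (ss_error / d2)
  }, numeric(1))
}

#' Permutation repeated-measures ANOVA
#'
#' Computes a standard fully within-subjects ANOVA (one observation per
#' participant and cell; sphericity-assumed F for every main effect and
#' interaction) and tests each F against a null built by freely permuting
#' the cell labels within each participant, independently per iteration.
#' P-values are the proportion of null F values greater than or equal to
#' the observed F (floor 1/`n_perm`).
#'
#' @param data Tidy tibble with one value per participant x cell.
#' @param value Name of the value column (string).
#' @param factors Character vector of 1-3 within-subject factor columns.
#' @param participant Name of the participant column.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `wm_perm_anova` with one row per effect:
#'   `effect`, `df1`, `df2`, `statistic` (F), `p`.
#' @export
perm_rm_anova <- function(data, value, factors, participant = "participant_id",
                          n_perm = 1000, seed = NULL) {
  stopifnot(length(factors) >= 1, length(factors) <= 3,
            all(c(value, factors, participant) %in% names(data)))
  if (!is.null(seed)) set.seed(seed)

  cells <- unique(data[factors])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  key <- do.call(paste, c(data[factors], sep = "\r"))
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  participants <- sort(unique(data[[participant]]))
  if (length(participants) < 2) stop("need at least 2 participants")

  y <- matrix(NA_real_, length(participants), nrow(cells),
              dimnames = list(participants, cell_key))
  idx <- cbind(match(data[[participant]], participants),
               match(key, cell_key))
  if (any(duplicated(idx))) {
    stop("more than one observation per participant x cell; aggregate first")
  }
  y[idx] <- data[[value]]
  if (anyNA(y)) stop("missing cells: design must be balanced")

  bases <- rm_anova_bases(cells)
  obs <- rm_anova_f(y, bases)
  s <- nrow(y)
  nc <- ncol(y)
  null <- matrix(NA_real_, n_perm, length(bases))
  for (i in seq_len(n_perm)) {
    yp <- y
    for (p in seq_len(s)) yp[p, ] <- y[p, sample.int(nc)]
    null[i, ] <- rm_anova_f(yp, bases)
  }
  p <- vapply(seq_along(obs), function(j) {
    perm_pvalue(obs[j], null[, j], "one")
  }, numeric(1))

  out <- tibble::tibble(
    effect = names(bases),
    df1 = unname(vapply(bases, ncol, integer(1))),
    df2 = unname(vapply(bases, ncol, integer(1))) * (s - 1L),
    statistic = unname(obs),
    p = unname(p)
  )
  class(out) <- c("wm_perm_anova", class(out))
  attr(out, "n_perm") <- n_perm
  out
}

#' Paired permutation t-test on run-wise condition means
#'
#' Aggregates run-wise values to a per-participant mean for each of two
#' conditions, computes the paired t statistic across participants, and
#' builds the null by shuffling the run-wise condition labels within each
#' participant. The one-tailed p-value is the proportion of null t greater
#' than or equal to the observed t (floor 1/`n_perm`); the two-tailed
#' p-value doubles the observed direction's tail (capped at 1).
#'
#' @param data Tidy tibble with run-wise values.
#' @param value,condition,run,participant Column names (strings);
#'   `condition` must have exactly two levels. The first level in sorted
#'   order is the reference: `t > 0` means the second level exceeds it.
#' @param tails `"two"` (default) or `"one"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list of class `wm_perm_ttest`: `statistic`, `p`, `null`,
#'   `by_participant`, `tails`, `n_perm`.
#' @export
perm_paired_ttest <- function(data, value, condition, run,
                              participant = "participant_id",
                              tails = c("two", "one"),
                              n_perm = 1000, seed = NULL) {
  tails <- match.arg(tails)
  stopifnot(all(c(value, condition, run, participant) %in% names(data)))
  levs <- sort(unique(data[[condition]]))
  if (length(levs) != 2) stop("`condition` must have exactly two levels")
  if (!is.null(seed)) set.seed(seed)

  by_part <- split(data, data[[participant]])
  if (length(by_part) < 2) stop("need at least 2 participants")
  part_diff <- function(d, labels) {
    m <- tapply(d[[value]], labels, mean)
    if (anyNA(m[levs])) stop("unpaired input: both conditions required per participant")
    unname(m[levs[2]] - m[levs[1]])
  }
  obs_d <- vapply(by_part, function(d) part_diff(d, d[[condition]]),
                  numeric(1))
  obs_t <- one_sample_t(obs_d)
  null <- vapply(seq_len(n_perm), function(i) {
    d_perm <- vapply(by_part, function(d) {
      part_diff(d, sample(d[[condition]]))
    }, numeric(1))
    one_sample_t(d_perm)
  }, numeric(1))
  p <- perm_pvalue(obs_t, null, tails)

  structure(
    list(statistic = obs_t, p = p, null = null,
         by_participant = tibble::tibble(
           participant_id = names(obs_d), diff = unname(obs_d)),
         conditions = levs, tails = tails, n_perm = n_perm),
    class = "wm_perm_ttest"
  )
}

#' @export
print.wm_perm_ttest <- function(x, ...) {
  cat(sprintf(
    "<wm_perm_ttest> %s vs %s: t = %.3f, p = %.4g (%s-tailed, %d perms)\n",
    x$conditions[2], x$conditions[1], x$statistic, x$p, x$tails, x$n_perm
  ))
  invisible(x)
}

#' Shuffled-training-label fidelity null
#'
#' Builds an empirical null for per-timepoint group fidelity: on each
#' iteration the training target angles are permuted within each
#' participant, the encoding model is re-estimated, test-set fidelity is
#' recomputed at every TR, and the across-participant t statistic is
#' stored. The observed t (intact labels) is compared one-tailed against
#' this null at each timepoint.
#'
#' @param datasets A list, one element per participant, each a list with
#'   `ts_train`, `angles_train`, `ts_test`, `trials_test` (and optionally
#'   `align_to`, default `"target"`).
#' @param basis A [channel_basis()].
#' @param n_perm Number of permutations (default 1000).
#' @param window Training window passed to [train_encoding_model()].
#' @param seed Integer seed.
#' @return A tibble of class `wm_fidelity_null` with one row per TR:
#'   `time`, `fidelity` (group mean), `statistic` (observed t), `p`, plus
#'   the null t matrix in attribute `"null"`.
#' @export
shuffled_label_fidelity_null <- function(datasets, basis = channel_basis(),
                                         n_perm = 1000, window = "TRAIN",
                                         seed = NULL) {
  stopifnot(length(datasets) >= 2)
  if (!is.null(seed)) set.seed(seed)

  part_fid <- function(d, angles) {
    model <- train_encoding_model(d$ts_train, angles, basis, window)
    tc <- fidelity_timecourse(d$ts_test, d$trials_test, model,
                              align_to = d$align_to %||% "target")
    tc$fidelity
  }
  obs <- vapply(datasets, function(d) part_fid(d, d$angles_train),
                numeric(length(datasets[[1]]$ts_test$tr_onsets)))
  obs_t <- apply(obs, 1, one_sample_t)

  null_t <- matrix(NA_real_, n_perm, nrow(obs))
  for (i in seq_len(n_perm)) {
    fid <- vapply(datasets, function(d) {
      part_fid(d, sample(d$angles_train))
    }, numeric(nrow(obs)))
    null_t[i, ] <- apply(fid, 1, one_sample_t)
  }
  p <- vapply(seq_len(nrow(obs)), function(t) {
    perm_pvalue(obs_t[t], null_t[, t], "one")
  }, numeric(1))

  out <- tibble::tibble(
    time = datasets[[1]]$ts_test$tr_onsets,
    fidelity = rowMeans(obs),
    statistic = obs_t,
    p = p
  )
  class(out) <- c("wm_fidelity_null", class(out))
  attr(out, "null") <- null_t
  out
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values (monotone non-decreasing in rank) and
#' rejection flags at level `q`.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return A tibble with `p`, `p_adj`, `reject`.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  tibble::tibble(p = pvalues, p_adj = adj, reject = adj <= q)
}
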