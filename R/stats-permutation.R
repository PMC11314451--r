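#' Permutation tests of group homogeneity: multivariate dispersion and
#' PERMANOVA
#'
#' The sample-homogeneity check of the analysis battery, on z-standardized
#' features in Euclidean space. (a) Dispersion test: the distance of each
#' observation to its group centroid is computed and a one-way F statistic
#' on those distances is referred to its permutation distribution — the
#' assumption check preceding PERMANOVA.  (b) PERMANOVA: the pseudo-F of
#' the between-group partition of the squared Euclidean distance matrix,
#' also referred to its permutation distribution.  Both p-values use the
#' add-one estimator `(1 + #{F* >= F}) / (1 + n_perm)` and share one seeded
#' permutation stream, so results are reproducible given
#' `(input, seed, n_perm)`.
#'
#' @param features Numeric matrix or data frame (observations x features).
#' @param groups Group labels, length `nrow(features)`; at least two groups.
#' @param n_perm Number of label permutations (>= 99; the study default is
#'   999).
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @param standardize Z-standardize each feature column first (default).
#' @param tests Which tests to run.  The dispersion test requires every
#'   group to have at least 2 members; requesting it with a singleton group
#'   is an error, while PERMANOVA alone runs with a warning.
#' @return An object of class `dietquality_permhomog` with
#'   `dispersion_F`, `dispersion_df`, `dispersion_p`, `permanova_F`,
#'   `permanova_df`, `permanova_p` and `n_permutations`.  [tidy()] and
#'   [glance()] methods are available.
#' @export
permutation_homogeneity <- function(features, groups, n_perm = 999,
                                    seed = NULL, standardize = TRUE,
                                    tests = c("dispersion", "permanova")) {
  tests <- match.arg(tests, several.ok = TRUE)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  g <- factor(groups)
  n <- nrow(x)
  a <- nlevels(g)
  if (a < 2 || n < 4 || length(g) != n) {
    rlang::abort("need >= 2 groups over >= 4 observations",
                 class = "dietquality_contract_error")
  }
  if (n_perm < 99) {
    rlang::abort("n_perm must be at least 99",
                 class = "dietquality_contract_error")
  }
  sizes <- table(g)
  if (any(sizes < 2)) {
    if ("dispersion" %in% tests) {
      rlang::abort(
        "dispersion test undefined for groups of size 1; request tests = \"permanova\"",
        class = "dietquality_contract_error"
      )
    }
    rlang::warn("group(s) of size 1 present; PERMANOVA only")
  }
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, colMeans(x))
    x <- sweep(x, 2, ifelse(sds > 0, sds, 1), "/")
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }

  d2 <- as.matrix(stats::dist(x))^2

  dispersion_F <- function(gi) {
    ng <- tabulate(gi, a)
    centroids <- rowsum(x, gi) / ng
    d <- sqrt(rowSums((x - centroids[gi, , drop = FALSE])^2))
    gmeans <- as.vector(rowsum(d, gi) / ng)
    ssb <- sum(ng * (gmeans - mean(d))^2)
    ssw <- sum((d - gmeans[gi])^2)
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  permanova_F <- function(gi) {
    sst <- sum(d2) / (2 * n)
    ssw <- 0
    for (k in seq_len(a)) {
      idx <- which(gi == k)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }

  gi <- as.integer(g)
  do_disp <- "dispersion" %in% tests
  do_perm <- "permanova" %in% tests
  obs_disp <- if (do_disp) dispersion_F(gi) else NA_real_
  obs_perm <- if (do_perm) permanova_F(gi) else NA_real_
  exc_disp <- 0L
  exc_perm <- 0L
  for (b in seq_len(n_perm)) {
    gp <- sample(gi)
    if (do_disp && dispersion_F(gp) >= obs_disp) exc_disp <- exc_disp + 1L
    if (do_perm && permanova_F(gp) >= obs_perm) exc_perm <- exc_perm + 1L
  }
  structure(
    list(
      dispersion_F = obs_disp,
      dispersion_df = if (do_disp) a - 1 else NA_integer_,
      dispersion_p = if (do_disp) (1 + exc_disp) / (1 + n_perm) else NA_real_,
      permanova_F = obs_perm,
      permanova_df = if (do_perm) a - 1 else NA_integer_,
      permanova_p = if (do_perm) (1 + exc_perm) / (1 + n_perm) else NA_real_,
      n_permutations = n_perm, n = n, n_groups = a, seed = seed
    ),
    class = "dietquality_permhomog"
  )
}
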