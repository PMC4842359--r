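# Seeded generator of morphometric-feature-like datasets with the
# NC / MCI / AD class structure, so every pipeline is testable without
# access to restricted clinical data.

#' Specification of a synthetic morphometric dataset
#'
#' Describes a class-conditional Gaussian dataset shaped like a FreeSurfer
#' morphometric feature table: five feature families — cortical volume (CV),
#' subcortical volume (SV), surface area (SA), thickness average (TA) and
#' thickness standard deviation (TS) — concatenated into `D` columns
#' (default 70/42/72/70/70, `D = 324`), with three diagnostic classes:
#' normal controls (NC), mild cognitive impairment (MCI) and Alzheimer's
#' disease (AD), with default sizes 655/825/513 (`N = 1993`).
#'
#' Only the `informative_features` carry class signal: NC and AD means are
#' separated by `effect_size` within-class standard deviations on each of
#' them, and the MCI mean sits at `mci_position` of the way from NC to AD.
#' MCI is the heterogeneous class: on the informative features its standard
#' deviation is inflated by `mci_spread_multiplier`, so it overlaps both
#' neighbours. All remaining features are pure noise.
#'
#' @param group_sizes named integer vector of feature-family sizes.
#' @param n_per_class named integer vector of class sizes (NC, MCI, AD order).
#' @param informative_features integer indices (in `1..D`) of the signal
#'   features; the default is the first 20 columns of the SV block, echoing
#'   the prominence of subcortical volumes in dementia staging.
#' @param effect_size NC-to-AD mean separation per informative feature, in
#'   within-class standard-deviation units.
#' @param mci_position where the MCI mean interpolates between NC (0) and
#'   AD (1).
#' @param mci_spread_multiplier standard-deviation inflation of MCI on the
#'   informative features (`>= 1`).
#' @param noise_cov `"identity"` for independent unit-variance noise, or
#'   `"lowrank"` for a shared 5-factor low-rank component plus unit diagonal
#'   (correlated anatomical measurements).
#' @param seed integer seed: the same spec always generates the identical
#'   dataset.
#' @return a list of class `"synthetic_spec"` with a derived `D` element.
#' @export
synthetic_spec <- function(group_sizes = c(CV = 70L, SV = 42L, SA = 72L,
                                           TA = 70L, TS = 70L),
                           n_per_class = c(NC = 655L, MCI = 825L, AD = 513L),
                           informative_features = NULL,
                           effect_size = 1.5,
                           mci_position = 0.5,
                           mci_spread_multiplier = 2,
                           noise_cov = c("identity", "lowrank"),
                           seed = 1L) {
  noise_cov <- match.arg(noise_cov)
  group_sizes <- stats::setNames(as.integer(group_sizes), names(group_sizes))
  n_per_class <- stats::setNames(as.integer(n_per_class), names(n_per_class))
  if (any(group_sizes < 1L)) stop("feature-group sizes must be positive")
  if (length(n_per_class) != 3L || any(n_per_class < 1L)) {
    stop("`n_per_class` must give three positive class counts (NC, MCI, AD)")
  }
  D <- sum(group_sizes)
  if (is.null(informative_features)) {
    sv_start <- sum(group_sizes[seq_len(which(names(group_sizes) == "SV") - 1L)])
    informative_features <- sv_start + seq_len(min(20L, group_sizes[["SV"]]))
  }
  informative_features <- as.integer(informative_features)
  if (any(informative_features < 1L) || any(informative_features > D)) {
    stop("informative feature indices must lie in 1..D = ", D)
  }
  if (!is.numeric(effect_size) || effect_size < 0) stop("`effect_size` must be >= 0")
  if (mci_position < 0 || mci_position > 1) stop("`mci_position` must be in [0, 1]")
  if (mci_spread_multiplier < 1) stop("`mci_spread_multiplier` must be >= 1")
  structure(list(group_sizes = group_sizes, n_per_class = n_per_class,
                 informative_features = informative_features,
                 effect_size = effect_size, mci_position = mci_position,
                 mci_spread_multiplier = mci_spread_multiplier,
                 noise_cov = noise_cov, seed = as.integer(seed), D = D),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset
#'
#' Draws the class-conditional Gaussian dataset described by a
#' [synthetic_spec()]. Deterministic for a given spec (including the seed).
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `"synthetic_dataset"` with `X` (`N x D` matrix,
#'   columns named `CV_001`, ..., `TS_070`), `t` (integer labels, 1 = NC,
#'   2 = MCI, 3 = AD), `feature_names`, and the generating `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  D <- spec$D
  n <- spec$n_per_class
  N <- sum(n)
  set.seed(spec$seed)

  feature_names <- unlist(lapply(names(spec$group_sizes), function(g) {
    sprintf("%s_%03d", g, seq_len(spec$group_sizes[[g]]))
  }), use.names = FALSE)

  # class means: zero everywhere except the informative block
  e <- spec$effect_size
  mu <- matrix(0, 3, D)
  mu[1, spec$informative_features] <- -e / 2
  mu[3, spec$informative_features] <- +e / 2
  mu[2, spec$informative_features] <- -e / 2 + spec$mci_position * e

  t <- rep(1:3, times = n)
  X <- matrix(stats::rnorm(N * D), N, D)
  if (spec$noise_cov == "lowrank") {
    q <- 5L
    A <- matrix(stats::rnorm(D * q, sd = 0.5), D, q)
    Z <- matrix(stats::rnorm(N * q), N, q)
    X <- X + Z %*% t(A)
  }
  # MCI heterogeneity: inflated spread on the disease-relevant features
  mci <- which(t == 2L)
  X[mci, spec$informative_features] <-
    X[mci, spec$informative_features] * spec$mci_spread_multiplier
  X <- X + mu[t, ]
  colnames(X) <- feature_names

  structure(list(X = X, t = t, feature_names = feature_names, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic morphometric dataset:", nrow(x$X), "samples x",
      ncol(x$X), "features\n")
  cat("  classes (NC/MCI/AD):", paste(x$spec$n_per_class, collapse = "/"), "\n")
  cat("  informative features:", length(x$spec$informative_features),
      "| effect size:", x$spec$effect_size, "\n")
  invisible(x)
}

#' Feature-group labels of a dataset
#'
#' @param dataset a `"synthetic_dataset"` (or anything with `feature_names`
#'   prefixed `GROUP_`).
#' @return character vector of group prefixes, one per feature.
#' @export
feature_groups <- function(dataset) {
  sub("_.*$", "", dataset$feature_names)
}

#' Fixed 12-sample toy dataset
#'
#' A hand-written 12 x 6 three-class dataset (four samples per class, two
#' informative features, four noise features) with literal constants, so
#' regression tests and serialized artifacts are identical on every platform.
#'
#' @return a `"synthetic_dataset"`-shaped list (with `spec = NULL`).
#' @export
tiny_fixture <- function() {
  X <- matrix(c(
    # f1,    f2,    f3,    f4,    f5,    f6
    -1.20, -0.80,  0.30, -0.10,  0.50, -0.40,
    -0.90, -1.10, -0.20,  0.40, -0.30,  0.20,
    -1.00, -0.70,  0.10, -0.50, -0.10,  0.60,
    -0.80, -1.30, -0.40,  0.20,  0.30, -0.20,
     0.10, -0.10,  0.50,  0.10, -0.60,  0.30,
    -0.20,  0.30, -0.30, -0.40,  0.20, -0.50,
     0.30,  0.10,  0.20,  0.60,  0.10,  0.10,
    -0.10, -0.30, -0.10, -0.20, -0.40,  0.40,
     1.10,  0.90, -0.50,  0.30,  0.20, -0.10,
     0.80,  1.20,  0.40, -0.30, -0.20,  0.50,
     1.30,  0.70,  0.10,  0.50,  0.60, -0.30,
     0.90,  1.00, -0.30, -0.10, -0.50,  0.20
  ), nrow = 12, ncol = 6, byrow = TRUE)
  colnames(X) <- c("SV_001", "SV_002", "CV_001", "CV_002", "TA_001", "TA_002")
  list(X = X, t = rep(1:3, each = 4L),
       feature_names = colnames(X), spec = NULL)
}

#' Write a dataset to CSV
#'
#' One header row (feature names then `label`), one row per sample.
#'
#' @param dataset a dataset list with `X` and `t`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$X)
  df$label <- as.integer(dataset$t)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects the layout of [write_dataset_csv()]: numeric feature columns and
#' an integer `label` column. Malformed rows are reported with their line
#' number.
#'
#' @param path CSV file with a header.
#' @return a dataset list with `X`, `t`, `feature_names`.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("CSV must contain a `label` column")
  feat <- setdiff(names(df), "label")
  for (col in feat) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop("non-numeric value in column `", col, "` at data line ", bad[1],
           " (file line ", bad[1] + 1L, ")")
    }
  }
  t <- suppressWarnings(as.numeric(df$label))
  bad <- which(!is.finite(t) | t != round(t) | t < 1)
  if (length(bad)) {
    stop("`label` must be a positive integer; offending data line ", bad[1],
         " (file line ", bad[1] + 1L, ")")
  }
  X <- as.matrix(df[, feat, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, t = as.integer(t), feature_names = feat, spec = NULL)
}
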