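#' Median fold-change trajectories per strain
#'
#' Computes the elementwise median across replicates of each strain's
#' fold-change curve. All replicates of a strain, and all strains, must
#' share the sampling grid; mismatches are an error (no silent
#' interpolation).
#'
#' @param data Long data frame (`strain`, `replicate`, `time_h`, `value`)
#'   of fold changes, or raw counts with `normalize = TRUE`.
#' @param normalize Divide each replicate by its own `t = 0` value first.
#' @return Numeric matrix, strains x time points, with time as column names.
#' @export
median_trajectories <- function(data, normalize = TRUE) {
  stopifnot(all(c("strain", "replicate", "time_h", "value") %in% names(data)))
  if (normalize) data <- normalize_fold_change(data)
  strains <- unique(data$strain)
  grid <- sort(unique(data$time_h[data$strain == strains[1]]))
  mat <- matrix(NA_real_, length(strains), length(grid),
                dimnames = list(strains, grid))
  for (s in strains) {
    ds <- data[data$strain == s, ]
    for (r in unique(ds$replicate)) {
      tr <- ds[ds$replicate == r, ]
      tr <- tr[order(tr$time_h), ]
      if (!isTRUE(all.equal(tr$time_h, grid)))
        stop("replicate ", r, " of strain ", s,
             " is not on the shared time grid; resample before calling",
             call. = FALSE)
    }
    vals <- tapply(ds$value, ds$time_h, median)
    mat[s, ] <- vals[as.character(grid)]
  }
  mat
}

#' Hierarchical clustering of growth-curve time series
#'
#' Agglomerative clustering (average linkage) with squared Euclidean
#' distance on the (optionally log10-transformed) fold-change vectors, cut
#' to `k` flat clusters. Deterministic.
#'
#' @param mat Strains x time matrix, e.g. from [median_trajectories()].
#' @param k Number of flat clusters.
#' @param transform `"log10"` (default; the curves span decades) or
#'   `"none"`.
#' @return List of class `qsg_clust`: `labels` (named integer vector),
#'   `tree` (`hclust`), `k`, `distance = "squared euclidean"`,
#'   `linkage = "average"`.
#' @export
cluster_timeseries <- function(mat, k = 3, transform = c("log10", "none")) {
  transform <- match.arg(transform)
  if (anyNA(mat)) {
    drop <- rownames(mat)[!complete.cases(mat)]
    warning("excluding strains with incomplete grids: ",
            paste(drop, collapse = ", "), call. = FALSE)
    mat <- mat[complete.cases(mat), , drop = FALSE]
  }
  if (k > nrow(mat)) stop("k exceeds the number of items", call. = FALSE)
  x <- if (transform == "log10") log10(mat) else mat
  d <- dist(x)^2
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = k,
                 distance = "squared euclidean", linkage = "average",
                 transform = transform),
            class = "qsg_clust")
}

#' Agreement between sample-level and median-trajectory clusterings
#'
#' Matches predicted labels to reference labels by exhaustive permutation
#' (k <= 4), maximizing macro accuracy, then reports macro-averaged
#' per-class accuracy (recall) and F1 under the best permutation.
#'
#' @param reference,predicted Label vectors of equal length (any atomic
#'   type; coerced to factors over the union of levels).
#' @return List: `macro_accuracy`, `macro_f1`, `permutation` (named map
#'   predicted -> reference).
#' @examples
#' clustering_agreement(c("A", "A", "B", "B"), c("A", "B", "B", "B"))$macro_f1
#' @export
clustering_agreement <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted))
  levs <- union(unique(as.character(reference)), unique(as.character(predicted)))
  if (length(levs) > 4) stop("exhaustive matching supports k <= 4", call. = FALSE)
  ref <- factor(as.character(reference), levels = levs)
  prd <- factor(as.character(predicted), levels = levs)
  perms <- permutations(levs)
  best <- NULL
  for (pi in seq_len(nrow(perms))) {
    map <- setNames(perms[pi, ], levs)
    relab <- factor(unname(map[as.character(prd)]), levels = levs)
    sc <- macro_scores(ref, relab)
    if (is.null(best) || sc$macro_accuracy > best$macro_accuracy)
      best <- c(sc, list(permutation = map))
  }
  best
}

# all permutations of a character vector (small k)
permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- permutations(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# macro-averaged per-class recall and F1 over classes present in `ref`
macro_scores <- function(ref, prd) {
  classes <- levels(ref)[levels(ref) %in% as.character(ref)]
  rec <- f1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(ref == cl & prd == cl)
    fn <- sum(ref == cl & prd != cl)
    fp <- sum(ref != cl & prd == cl)
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[ci] <- if (prec + rec[ci] > 0) 2 * prec * rec[ci] / (prec + rec[ci]) else 0
  }
  list(macro_accuracy = mean(rec, na.rm = TRUE), macro_f1 = mean(f1, na.rm = TRUE))
}

#' Phenotype table: per-strain medians and 34/66 percentiles
#'
#' Aggregates sample-level derived quantities (kinetic parameters, maximal
#' fold change, rates) to per-strain medians with 34th/66th percentile
#' brackets (linear interpolation on sorted values).
#'
#' @param samples Data frame with a `strain` column and numeric quantity
#'   columns.
#' @return List of class `qsg_phenotypes`: `median`, `p34`, `p66` (strain x
#'   quantity data frames) and `samples`.
#' @export
phenotype_table <- function(samples) {
  stopifnot("strain" %in% names(samples))
  vars <- names(samples)[vapply(samples, is.numeric, TRUE)]
  vars <- setdiff(vars, "replicate")
  agg <- function(f) {
    out <- do.call(rbind, lapply(split(samples[vars], samples$strain),
                                 function(d) vapply(d, f, 1.0)))
    as.data.frame(out)
  }
  structure(list(
    median = agg(function(x) median(x, na.rm = TRUE)),
    p34 = agg(function(x) unname(quantile(x, 0.34, na.rm = TRUE, type = 7))),
    p66 = agg(function(x) unname(quantile(x, 0.66, na.rm = TRUE, type = 7))),
    samples = samples, variables = vars
  ), class = "qsg_phenotypes")
}

#' PCA of kinetic phenotypes
#'
#' Principal component analysis of a strains x variables matrix after a
#' stated preprocessing: `"log_z"` (log10 for scale variables, then
#' per-variable z-score; default), `"z"` (z-score only) or `"none"`
#' (centering only). Reports per-axis variance fractions (percent), axis
#' loadings, projected coordinates, and each item's distance to the plane
#' spanned by the first two axes.
#'
#' @param mat Numeric matrix or data frame (items x variables).
#' @param preprocessing One of `"log_z"`, `"z"`, `"none"`.
#' @param log_vars Variables log10-transformed under `"log_z"` (default:
#'   the scale-like ones present among `K_qs`, `inv_B`, `B`, `max_fc`).
#' @return List of class `qsg_pca`: `variance_pct`, `loadings`, `scores`,
#'   `plane_deviation`, `preprocessing`.
#' @export
parameter_pca <- function(mat, preprocessing = c("log_z", "z", "none"),
                          log_vars = c("K_qs", "inv_B", "B", "max_fc")) {
  preprocessing <- match.arg(preprocessing)
  x <- as.matrix(mat)
  stopifnot(nrow(x) >= 2)
  if (preprocessing == "log_z") {
    for (v in intersect(colnames(x), log_vars)) {
      if (any(x[, v] <= 0)) stop("variable ", v, " must be positive for log10",
                                 call. = FALSE)
      x[, v] <- log10(x[, v])
    }
  }
  scale. <- preprocessing %in% c("log_z", "z")
  sds <- apply(x, 2, sd)
  if (scale. && any(sds == 0))
    stop("constant variable after preprocessing: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  dev <- if (ncol(scores) > 2)
    sqrt(rowSums(scores[, -(1:2), drop = FALSE]^2)) else rep(0, nrow(scores))
  structure(list(variance_pct = var_pct, loadings = pc$rotation,
                 scores = scores, plane_deviation = dev,
                 preprocessing = preprocessing, center = pc$center,
                 scale = if (scale.) pc$scale else NULL),
            class = "qsg_pca")
}

#' Pearson (or Spearman) correlation with test
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param method `"pearson"` (two-sided t-test p-value) or `"spearman"`.
#' @return List: `rho`, `p_value`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Phenotypic distance between two strains in trait space
#'
#' Per-parameter absolute differences after z-scoring each parameter across
#' all strains (log10 first for the scale parameters), reported in the order
#' (d, K_qs, 1/B, K_r, lambda), plus the Euclidean norm and the set of
#' parameters exceeding a separation threshold.
#'
#' @param table Data frame of per-strain medians with columns `d`, `K_qs`,
#'   `inv_B`, `K_r`, `lambda_max` (rows = strains).
#' @param a,b Row names (or indices) of the two strains.
#' @param threshold Separation threshold in z-units.
#' @return List: `per_parameter` (named, order d, K_qs, inv_B, K_r,
#'   lambda_max), `scalar`, `separating` (names above threshold).
#' @export
phenotypic_distance <- function(table, a, b, threshold = 1) {
  vars <- c("d", "K_qs", "inv_B", "K_r", "lambda_max")
  if (!all(vars %in% colnames(table)))
    stop("missing parameter column(s): ",
         paste(setdiff(vars, colnames(table)), collapse = ", "), call. = FALSE)
  x <- as.matrix(table[, vars])
  for (v in c("K_qs", "inv_B")) x[, v] <- log10(x[, v])
  sds <- apply(x, 2, sd)
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, ifelse(sds > 0, sds, 1), "/")  # constant column: zero diff
  dv <- abs(x[a, ] - x[b, ])
  names(dv) <- vars
  list(per_parameter = dv, scalar = sqrt(sum(dv^2)),
       separating = names(dv)[dv > threshold])
}

#' Dispersion statistics: coefficients of variation and pairwise KS tests
#'
#' CV = sd/mean (population sd by default) computed over all samples pooled
#' and over per-strain medians, plus a matrix of pairwise two-sample
#' Kolmogorov-Smirnov p-values across strains.
#'
#' @param values Numeric vector of sample-level values.
#' @param strain Strain labels, same length.
#' @param population_sd Use the population (divide by n) standard deviation.
#' @return List: `cv_pooled`, `cv_medians`, `ks_p` (matrix).
#' @export
dispersion_stats <- function(values, strain, population_sd = TRUE) {
  stopifnot(length(values) == length(strain), length(values) >= 2)
  cv <- function(x) {
    if (mean(x) == 0) stop("mean is zero; CV undefined", call. = FALSE)
    s <- sd(x)
    if (population_sd) s <- s * sqrt((length(x) - 1) / length(x))
    s / mean(x)
  }
  meds <- tapply(values, strain, median)
  strains <- names(meds)
  ksm <- matrix(NA_real_, length(strains), length(strains),
                dimnames = list(strains, strains))
  for (i in seq_along(strains)) for (j in seq_along(strains)) {
    if (i == j) { ksm[i, j] <- 1; next }
    ksm[i, j] <- suppressWarnings(
      ks.test(values[strain == strains[i]], values[strain == strains[j]]))$p.value
  }
  list(cv_pooled = cv(values),
       cv_medians = if (length(meds) >= 2) cv(as.numeric(meds)) else NA_real_,
       ks_p = ksm)
}

#' Full phenotype report from a sample-level parameter table
#'
#' Runs the downstream phenotype analyses the study performs on fitted
#' kinetic parameters: 3-variable PCA and correlations of (max_fc, K_qs,
#' inv_B) at strain and sample level, the 5-parameter PCA with plane
#' deviations, dispersion statistics, and pairwise archetype distances.
#' Both documented preprocessing modes are computed, since the convention
#' behind the printed variance fractions is ambiguous.
#'
#' @param samples Sample-level data frame with columns `strain`, `max_fc`,
#'   `lambda_max`, `d`, `K_qs`, `inv_B`, `K_r` (e.g. assembled from
#'   per-replicate fits).
#' @return List: `table` ([phenotype_table()]), `pca3`, `pca5` (each a list
#'   by preprocessing mode), `correlations` (strain- and sample-level),
#'   `dispersion` (per quantity).
#' @export
phenotype_report <- function(samples) {
  tab <- phenotype_table(samples)
  med <- tab$median
  modes <- c("log_z", "z")
  v3 <- c("max_fc", "K_qs", "inv_B")
  v5 <- c("lambda_max", "d", "K_qs", "inv_B", "K_r")
  pca3 <- lapply(modes, function(m) parameter_pca(med[, v3], m))
  pca5 <- lapply(modes, function(m) parameter_pca(med[, v5], m))
  names(pca3) <- names(pca5) <- modes
  corr <- list(
    strain = list(
      maxfc_kqs  = correlate(log10(med$max_fc), log10(med$K_qs)),
      maxfc_invB = correlate(log10(med$max_fc), log10(med$inv_B)),
      kqs_invB   = correlate(log10(med$K_qs), log10(med$inv_B))
    ),
    sample = list(
      maxfc_kqs  = correlate(log10(samples$max_fc), log10(samples$K_qs)),
      maxfc_invB = correlate(log10(samples$max_fc), log10(samples$inv_B)),
      kqs_invB   = correlate(log10(samples$K_qs), log10(samples$inv_B))
    )
  )
  disp <- lapply(intersect(c("lambda_max", "d", "max_fc"), names(samples)),
                 function(v) dispersion_stats(samples[[v]], samples$strain))
  names(disp) <- intersect(c("lambda_max", "d", "max_fc"), names(samples))
  list(table = tab, pca3 = pca3, pca5 = pca5, correlations = corr,
       dispersion = disp)
}
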