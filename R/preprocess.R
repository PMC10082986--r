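#' Drop genes with missing values
#'
#' @param ds An [expression_dataset()].
#' @return The dataset with every gene containing at least one missing value
#'   removed; samples are untouched.
#' @export
remove_missing_genes <- function(ds) {
  keep <- colSums(is.na(ds$matrix)) == 0L
  if (!any(keep)) abort("every gene contains missing values.",
                        class = "isoga_empty_dataset")
  if (all(keep)) return(ds)
  subset_genes(ds, which(keep))
}

#' Drop constant genes
#'
#' Genes whose values are identical across all samples (within absolute
#' tolerance `tol`) carry no class information and break standardisation.
#'
#' @param ds An [expression_dataset()] without missing values.
#' @param tol Absolute tolerance for "identical".
#' @return Dataset with constant genes removed.
#' @export
remove_constant_genes <- function(ds, tol = 1e-12) {
  if (anyNA(ds$matrix)) abort("run remove_missing_genes() first.")
  rng <- apply(ds$matrix, 2, function(x) diff(range(x)))
  keep <- rng > tol
  if (!any(keep)) abort("every gene is constant.", class = "isoga_empty_dataset")
  if (all(keep)) return(ds)
  subset_genes(ds, which(keep))
}

#' Standardize genes to mean zero, unit standard deviation
#'
#' Each gene column is centred and scaled. The centring/scaling parameters
#' are returned so that held-out samples can be standardised with the
#' training statistics (pass them back through `params`), which keeps test
#' folds untouched by training information inside cross-validation.
#'
#' @param ds An [expression_dataset()] with no constant genes.
#' @param params Optional list with `mean` and `sd` vectors from a previous
#'   call; when given, those statistics are applied instead of recomputing.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list: `dataset` (standardised) and `params` (`mean`, `sd`).
#' @export
standardize <- function(ds, params = NULL, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  X <- ds$matrix
  if (is.null(params)) {
    mu <- colMeans(X)
    s <- apply(X, 2, sd)
    if (sd_type == "population") s <- s * sqrt((ds$n - 1) / ds$n)
    if (any(s <= 0 | !is.finite(s))) {
      abort("zero-variance gene found: run remove_constant_genes() first.")
    }
    params <- list(mean = mu, sd = s)
  }
  Xs <- sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
  list(dataset = expression_dataset(Xs, ds$labels, ds$label_levels),
       params = params)
}

shannon_entropy <- function(y) {
  p <- tabulate(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

# Fayyad-Irani MDL recursive binary discretisation: returns accepted cut
# points (possibly none). Candidate cuts are midpoints between adjacent
# distinct sorted values; a cut is accepted when its information gain beats
# the MDL cost of encoding the split.
mdl_cuts <- function(values, y) {
  o <- order(values)
  v <- values[o]
  yy <- y[o]
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2) return(numeric(0))
    vs <- v[lo:hi]
    ys <- yy[lo:hi]
    ent <- shannon_entropy(ys)
    if (ent == 0) return(numeric(0))
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0) return(numeric(0))
    best_gain <- -Inf; best_i <- NA_integer_
    for (i in distinct) {
      e1 <- shannon_entropy(ys[1:i])
      e2 <- shannon_entropy(ys[(i + 1):n])
      gain <- ent - (i / n) * e1 - ((n - i) / n) * e2
      if (gain > best_gain) { best_gain <- gain; best_i <- i }
    }
    i <- best_i
    k <- length(unique(ys))
    k1 <- length(unique(ys[1:i])); k2 <- length(unique(ys[(i + 1):n]))
    e1 <- shannon_entropy(ys[1:i]); e2 <- shannon_entropy(ys[(i + 1):n])
    delta <- log2(3^k - 2) - (k * ent - k1 * e1 - k2 * e2)
    threshold <- (log2(n - 1) + delta) / n
    if (best_gain <= threshold) return(numeric(0))
    cut <- (vs[i] + vs[i + 1]) / 2
    c(recurse(lo, lo + i - 1), cut, recurse(lo + i, hi))
  }
  sort(recurse(1, length(v)))
}

#' Information gain of a gene for the class labels
#'
#' Computes `H(y) - H(y | discretize(values))` in bits. The default
#' discretiser is Fayyad-Irani MDL recursive binary partitioning, which
#' returns "no acceptable split" for label-independent genes and therefore
#' an information gain of exactly zero — the property the zero-IG filter
#' relies on. The alternative is equal-frequency binning with `bins` bins.
#'
#' @param values Numeric vector of one gene's expression across samples.
#' @param labels Integer class labels `1..C`.
#' @param binning `"mdl"` (default) or `"equalfreq"`.
#' @param bins Bin count for equal-frequency binning.
#' @return Nonnegative information gain in bits (0 for a constant gene).
#' @export
information_gain <- function(values, labels, binning = c("mdl", "equalfreq"),
                             bins = 10) {
  binning <- match.arg(binning)
  n <- length(values)
  stopifnot(n == length(labels), n >= 2)
  if (diff(range(values)) == 0) return(0)
  if (binning == "mdl") {
    cuts <- mdl_cuts(values, labels)
    if (length(cuts) == 0) return(0)
    g <- findInterval(values, cuts)
  } else {
    qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = bins + 1)))
    g <- findInterval(values, qs[-c(1, length(qs))])
  }
  hy <- shannon_entropy(labels)
  cond <- vapply(split(labels, g), function(ys) {
    length(ys) / n * shannon_entropy(ys)
  }, numeric(1))
  max(0, hy - sum(cond))
}

#' Remove genes with zero information gain
#'
#' @param ds Standardised [expression_dataset()].
#' @inheritParams information_gain
#' @return A list: `dataset` (filtered) and `report`, a tibble with one row
#'   per input gene (`gene_id`, `info_gain`, `kept`).
#' @export
filter_zero_ig <- function(ds, binning = c("mdl", "equalfreq"), bins = 10) {
  binning <- match.arg(binning)
  ig <- apply(ds$matrix, 2, information_gain, labels = ds$labels,
              binning = binning, bins = bins)
  keep <- ig > 0
  report <- tibble::tibble(gene_id = colnames(ds$matrix),
                           info_gain = unname(ig), kept = unname(keep))
  if (!any(keep)) {
    abort("information gain is zero for every gene; nothing to select from.",
          class = "isoga_empty_dataset")
  }
  list(dataset = subset_genes(ds, which(keep)), report = report)
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: missing-gene removal, constant-gene removal,
#' per-gene standardisation, zero-information-gain filtering. Samples whose
#' standardised profile contains many extreme values (|z| > 6) are flagged in
#' the report for manual inspection but never removed automatically.
#'
#' @param ds An [expression_dataset()].
#' @inheritParams information_gain
#' @inheritParams standardize
#' @return A list: `dataset` (preprocessed), `params` (standardisation
#'   statistics of the retained genes), `report` — a tibble of per-stage
#'   removal counts — `ig` (per-gene information gain of the genes that
#'   reached the IG stage), and `outlier_flags` (per-sample count of |z| > 6
#'   values).
#' @export
preprocess_expression <- function(ds, binning = c("mdl", "equalfreq"),
                                  bins = 10, sd_type = c("sample", "population")) {
  p0 <- ds$p
  ds1 <- remove_missing_genes(ds)
  ds2 <- remove_constant_genes(ds1)
  std <- standardize(ds2, sd_type = match.arg(sd_type))
  flags <- rowSums(abs(std$dataset$matrix) > 6)
  if (any(flags > 0)) {
    inform(sprintf("%d sample(s) carry |z| > 6 values; inspect manually.",
                   sum(flags > 0)))
  }
  filt <- filter_zero_ig(std$dataset, binning = match.arg(binning), bins = bins)
  report <- tibble::tibble(
    stage = c("input", "missing_removed", "constant_removed", "zero_ig_removed",
              "final"),
    genes_removed = c(0L, p0 - ds1$p, ds1$p - ds2$p,
                      std$dataset$p - filt$dataset$p, 0L),
    genes_remaining = c(p0, ds1$p, ds2$p, filt$dataset$p, filt$dataset$p)
  )
  kept_params <- list(
    mean = std$params$mean[colnames(filt$dataset$matrix)],
    sd = std$params$sd[colnames(filt$dataset$matrix)]
  )
  list(dataset = filt$dataset, params = kept_params, report = report,
       ig = filt$report, outlier_flags = flags)
}
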