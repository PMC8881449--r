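# Alpha-diversity metrics, Spearman-distance PCoA, and the one-sided
# Wilcoxon rank-sum test (exact by enumeration at small n, normal
# approximation with tie and continuity corrections otherwise).

#' Chao1 richness estimator
#'
#' `S_obs + f1^2 / (2 f2)`; when no doubletons exist, the
#' `f1 (f1 - 1) / 2` correction is used.
#'
#' @param counts integer count vector of one sample (pre-normalization).
#' @return the Chao1 estimate.
#' @export
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Abundance-based coverage richness estimator (ICE-style)
#'
#' Coverage estimator over taxa with counts at or below the rare cutoff
#' (default 10): `S_abund + S_rare / C + (F1 / C) * gamma^2`, with sample
#' coverage `C = 1 - F1 / N_rare` and the squared coefficient of variation
#' `gamma^2` truncated at zero. Falls back to [chao1()] when coverage is
#' zero (all rare taxa are singletons).
#'
#' @param counts integer count vector of one sample.
#' @param cutoff rare-taxon count threshold.
#' @return the richness estimate.
#' @export
ice <- function(counts, cutoff = 10) {
  counts <- counts[counts > 0]
  rare <- counts[counts <= cutoff]
  s_abund <- sum(counts > cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(length(counts))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) return(chao1(counts))
  g2 <- 0
  if (n_rare > 1) {
    fk <- table(rare)
    k <- as.numeric(names(fk))
    g2 <- max(s_rare / c_ace * sum(k * (k - 1) * as.numeric(fk)) /
                (n_rare * (n_rare - 1)) - 1, 0)
  }
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

#' Gini inequality coefficient of an abundance vector
#'
#' Inequality of the nonzero abundances: 0 for a perfectly even community,
#' approaching 1 under extreme dominance. (This is the inequality
#' coefficient, a distinct quantity from the Gini-Simpson index
#' `1 - sum p^2`, which is available as `gini_simpson()`.)
#'
#' @param x abundance vector (zeros are dropped).
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(x) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' @rdname gini
#' @export
gini_simpson <- function(x) {
  p <- x[x > 0]
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the subtree spanning the observed features and
#' the root.
#'
#' @param mat samples x features abundance or presence matrix.
#' @param tree a rooted `phylo` tree covering every feature (species names
#'   are matched directly or via [tree_label()]).
#' @return named numeric vector of PD per sample.
#' @export
faith_pd <- function(mat, tree) {
  feats <- colnames(mat)
  lab <- ifelse(feats %in% tree$tip.label, feats, tree_label(feats))
  missing <- feats[!lab %in% tree$tip.label]
  if (length(missing))
    stopf("features missing from the tree: %s",
          paste(missing, collapse = ", "))
  m <- (mat > 0) * 1
  colnames(m) <- lab
  if (!ape::is.rooted(tree)) tree$root.edge <- 0  # basal polytomy case
  pd <- picante::pd(m, tree, include.root = TRUE)
  setNames(pd$PD, rownames(mat))
}

#' Per-sample diversity report
#'
#' Observed species, Shannon and Simpson indices (on relative abundances),
#' Chao1 and ICE richness (on integer counts), the Gini inequality
#' coefficient, and Faith's PD (when a tree is given). An `unassigned`
#' column, if present, is ignored.
#'
#' @param rel samples x features relative abundance matrix.
#' @param counts samples x features integer count matrix (for Chao1/ICE);
#'   defaults to `rel` treated as counts when omitted.
#' @param tree optional rooted `phylo` tree for Faith's PD.
#' @param ice_cutoff rare-count threshold of the ICE estimator.
#' @return data.frame with one row per sample.
#' @export
diversity_report <- function(rel, counts = NULL, tree = NULL,
                             ice_cutoff = 10) {
  drop_un <- function(m) m[, setdiff(colnames(m), "unassigned"), drop = FALSE]
  rel <- drop_un(rel)
  counts <- if (is.null(counts)) rel else drop_un(counts)
  out <- data.frame(
    sample_id = rownames(rel),
    observed_species = as.integer(rowSums(rel > 0)),
    shannon = as.numeric(vegan::diversity(rel, index = "shannon")),
    simpson = as.numeric(vegan::diversity(rel, index = "simpson")),
    chao1 = apply(counts, 1, chao1),
    ice = apply(counts, 1, ice, cutoff = ice_cutoff),
    gini = apply(rel, 1, gini),
    stringsAsFactors = FALSE)
  if (!is.null(tree)) out$faith_pd <- as.numeric(faith_pd(rel, tree))
  rownames(out) <- NULL
  out
}

#' Principal coordinate analysis on Spearman-coefficient distances
#'
#' Distance between samples is `1 - rho` (Spearman rank correlation of
#' their feature vectors, ties mid-ranked). Classical PCoA: the squared
#' distance matrix is double-centered (`-D^2/2`, centered rows and
#' columns), eigendecomposed, and coordinates are eigenvectors scaled by
#' the square roots of the (positive) eigenvalues. Negative eigenvalues
#' are dropped with a warning; explained variance fractions are relative
#' to the positive eigenvalue total.
#'
#' @param mat samples x features abundance matrix (>= 3 samples); an
#'   `unassigned` column is ignored.
#' @return object of class `equimeta_pcoa`: `points`, `eig`, `explained`,
#'   `distance`.
#' @export
pcoa_spearman <- function(mat) {
  mat <- mat[, setdiff(colnames(mat), "unassigned"), drop = FALSE]
  if (nrow(mat) < 3) stopf("PCoA needs >= 3 samples")
  const <- apply(mat, 1, function(r) length(unique(r)) == 1)
  if (any(const))
    stopf("Spearman distance undefined for constant sample vector: %s",
          paste(rownames(mat)[const], collapse = ", "))
  rho <- cor(t(mat), method = "spearman")
  D <- 1 - rho
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D * D) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  if (any(e$values < -tol))
    warning("negative eigenvalues dropped (non-Euclidean distance)",
            call. = FALSE)
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(mat), paste0("PCo", seq_along(pos)))
  structure(list(points = coords, eig = e$values,
                 explained = e$values[pos] / sum(e$values[pos]),
                 distance = D),
            class = "equimeta_pcoa")
}

#' @export
print.equimeta_pcoa <- function(x, ...) {
  cat(sprintf("<equimeta_pcoa> %d samples, %d axes\n", nrow(x$points),
              ncol(x$points)))
  cat(sprintf("  explained: %s\n",
              paste(sprintf("%.1f%%", 100 * head(x$explained, 4)),
                    collapse = " ")))
  invisible(x)
}

#' @export
plot.equimeta_pcoa <- function(x, col = NULL, pch = 19, ...) {
  plot(x$points[, 1], x$points[, 2],
       xlab = sprintf("PCo1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PCo2 (%.1f%%)", 100 * x$explained[2]),
       col = col %||% "black", pch = pch, ...)
  invisible(x)
}

#' One-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration of all group assignments when
#' `n + m <= 12` (valid under ties); otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param alternative `"less"` (x tends smaller than y) or `"greater"`.
#' @return list with `statistic` (Mann-Whitney U of `x`), `rank_sum`,
#'   `p.value`, `method`.
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x); m <- length(y)
  if (!n || !m) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  N <- n + m
  if (length(unique(c(x, y))) == 1)
    warning("all values identical across groups; p = 1", call. = FALSE)
  if (N <= 12) {
    idx <- combn(N, n)
    sums <- colSums(matrix(r[idx], nrow = n))
    p <- if (alternative == "less") mean(sums <= W + 1e-9)
         else mean(sums >= W - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      sig <- sqrt(sig2)
      p <- if (alternative == "less") pnorm((W + 0.5 - mu) / sig)
           else 1 - pnorm((W - 0.5 - mu) / sig)
    }
    method <- "normal approximation"
  }
  list(statistic = U, rank_sum = W, p.value = min(1, p), method = method)
}
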