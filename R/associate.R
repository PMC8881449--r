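# Covariate-adjusted per-feature association: log-transformed relative
# abundances regressed on a target variable (habitat or site) plus
# adjustment covariates by ordinary least squares, Benjamini-Hochberg
# correction across features, and the signed-coefficient TransCo transform
# used to rank associated species.

#' Per-feature association with a design variable
#'
#' Fits, for every feature, `log(abundance + pc) ~ target + covariates`
#' (dummy-coded OLS), where `pc` is half the smallest nonzero abundance in
#' the matrix. For a two-level target the p-value is the t-test of its
#' coefficient; for more levels a joint F-test is used and the largest-
#' magnitude level coefficient is reported. q-values are Benjamini-Hochberg
#' across features; `trans_co = |coefficient| * B` with `B = +1/-1` by
#' coefficient sign (numerically the coefficient itself; the printed
#' formula is applied as stated). Significance tiers: `+++` q < 1e-3,
#' `++` q < 0.01, `+` q in 0.01-0.05.
#'
#' @param mat samples x features relative abundance matrix (an
#'   `unassigned` column is ignored).
#' @param design data.frame with `sample_id` and the design variables,
#'   covering every sample (row order is matched by `sample_id`).
#' @param target design variable tested (`"habitat"` or `"site"`).
#' @param adjust_for character vector of adjustment covariates.
#' @param pseudocount added before the log; default half the minimum
#'   nonzero value of `mat`.
#' @return data.frame `feature`, `coefficient`, `p_value`, `q_value`,
#'   `trans_co`, `tier`, ordered as the input features.
#' @export
associate <- function(mat, design, target = "habitat",
                      adjust_for = character(0), pseudocount = NULL) {
  mat <- mat[, setdiff(colnames(mat), "unassigned"), drop = FALSE]
  stopifnot(is.data.frame(design), "sample_id" %in% names(design))
  if (target %in% adjust_for)
    stopf("target and adjustment variables must be distinct")
  miss <- setdiff(rownames(mat), design$sample_id)
  if (length(miss))
    stopf("samples missing from design: %s", paste(miss, collapse = ", "))
  d <- design[match(rownames(mat), design$sample_id), , drop = FALSE]
  vars <- c(target, adjust_for)
  bad <- setdiff(vars, names(d))
  if (length(bad)) stopf("design lacks variables: %s", paste(bad, collapse = ", "))
  for (v in vars) d[[v]] <- factor(d[[v]])
  X <- model.matrix(stats::reformulate(vars), data = d)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stopf("confounded design: target collinear with adjustment covariates")
  target_cols <- which(attr(X, "assign") == 1)
  pc <- pseudocount %||% (min(mat[mat > 0]) / 2)
  Y <- log(mat + pc)
  n <- nrow(X)
  dfree <- n - ncol(X)
  if (dfree < 1) stopf("not enough samples for the model")
  fit <- lm.fit(X, Y)
  coefs <- fit$coefficients
  res <- as.matrix(fit$residuals)
  rss1 <- colSums(res^2)
  xtx_inv <- solve(crossprod(X))

  if (length(target_cols) == 1) {
    b <- coefs[target_cols, ]
    se <- sqrt(pmax(rss1 / dfree * xtx_inv[target_cols, target_cols], 0))
    tval <- ifelse(se > 0, b / se, 0)
    p <- ifelse(se > 0, 2 * pt(-abs(tval), dfree), 1)
    coef_out <- b
  } else {
    X0 <- X[, -target_cols, drop = FALSE]
    res0 <- as.matrix(lm.fit(X0, Y)$residuals)
    rss0 <- colSums(res0^2)
    q <- length(target_cols)
    fstat <- ifelse(rss1 > 0, ((rss0 - rss1) / q) / (rss1 / dfree), 0)
    p <- ifelse(rss1 > 0, stats::pf(fstat, q, dfree, lower.tail = FALSE), 1)
    bmat <- coefs[target_cols, , drop = FALSE]
    pick <- apply(abs(bmat), 2, which.max)
    coef_out <- bmat[cbind(pick, seq_len(ncol(bmat)))]
  }
  # features constant across samples carry no signal
  const <- apply(mat, 2, function(col) length(unique(col)) == 1)
  coef_out[const] <- 0
  p[const] <- 1
  qv <- p.adjust(p, method = "BH")
  trans_co <- abs(coef_out) * ifelse(coef_out >= 0, 1, -1)
  tier <- ifelse(qv < 1e-3, "+++",
                 ifelse(qv < 0.01, "++",
                        ifelse(qv < 0.05, "+", "")))
  data.frame(feature = colnames(mat), coefficient = as.numeric(coef_out),
             p_value = as.numeric(p), q_value = as.numeric(qv),
             trans_co = as.numeric(trans_co), tier = tier,
             stringsAsFactors = FALSE, row.names = NULL)
}
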