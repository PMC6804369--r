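# Reporting layer: correlation matrix with significance, PCA with a fixed
# sign convention, and per-day group comparisons with a letter display.

numeric_table <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  m <- as.matrix(table[, num, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop_invalid_input("variable names must be unique")
  m
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Correlates every pair of numeric variables using pairwise-complete
#' observations and reports r, r-squared and the two-sided p-value of the
#' correlation test. A constant variable has undefined correlations; its
#' entries are `NA` and its name is recorded in `flagged` (no error).
#'
#' @param table Data frame; non-numeric columns (group labels etc.) are
#'   ignored.
#' @return An object of class `trait_cor`: list of matrices `r`, `r2`,
#'   `p`, plus `n` (pairwise sample sizes) and `flagged`.
#' @export
correlation_matrix <- function(table) {
  m <- numeric_table(table)
  k <- ncol(m)
  if (k < 2L) stop_insufficient_data("need at least two numeric variables")
  if (nrow(m) < 3L) stop_insufficient_data("need at least 3 rows")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  flagged <- colnames(m)[!is.na(sds) & sds == 0]
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    p[i, i] <- 0
    n[i, i] <- sum(stats::complete.cases(m[, i]))
    for (j in seq_len(i - 1L)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3L && !is.na(r[i, j])) {
        p[i, j] <- p[j, i] <-
          stats::cor.test(m[ok, i], m[ok, j])$p.value
      }
    }
  }
  diag(r)[colnames(m) %in% flagged] <- NA_real_
  structure(list(r = r, r2 = r^2, p = p, n = n, flagged = flagged),
            class = "trait_cor")
}

#' Principal component analysis of a trait table
#'
#' PCA of the numeric variables, by default on the correlation matrix
#' (unit-variance scaling), appropriate when traits and metabolites carry
#' incommensurate units. Rows with missing values are dropped. Loading
#' signs follow a fixed convention — the first nonzero element of each
#' loading vector is positive — so results are reproducible across
#' platforms.
#'
#' @param table Data frame; non-numeric columns are carried through as
#'   row annotations of the scores.
#' @param scale Scale variables to unit variance (default `TRUE`).
#' @return An object of class `trait_pca`: `scores` (data frame with the
#'   annotation columns and PCs), `loadings` (matrix), and
#'   `variance_explained` (fractions summing to 1).
#' @export
trait_pca <- function(table, scale = TRUE) {
  m <- numeric_table(table)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop_insufficient_data("PCA needs at least 3 complete rows")
  const <- apply(m, 2, function(x) diff(range(x)) == 0)
  if (scale && any(const)) m <- m[, !const, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  # sign convention: first nonzero loading element positive
  for (j in seq_len(ncol(pc$rotation))) {
    v <- pc$rotation[, j]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) {
      pc$rotation[, j] <- -v
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ann <- table[keep, !vapply(table, is.numeric, logical(1)), drop = FALSE]
  scores <- cbind(ann, as.data.frame(pc$x))
  structure(list(scores = scores, loadings = pc$rotation,
                 variance_explained = ve,
                 center = pc$center, scale = pc$scale),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat("PCA of trait table\n")
  cat(sprintf("  %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(ve), 100 * ve[1], 100 * ifelse(length(ve) > 1, ve[2], 0)))
  invisible(x)
}

#' @export
plot.trait_pca <- function(x, groups = NULL, ...) {
  ve <- 100 * x$variance_explained
  pcs <- as.matrix(x$scores[, c("PC1", "PC2")])
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(pcs, col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", ve[1]),
                 ylab = sprintf("PC2 (%.1f%%)", ve[2]), ...)
  sc <- 0.8 * min(apply(abs(pcs), 2, max)) /
    max(abs(x$loadings[, 1:2]))
  graphics::arrows(0, 0, sc * x$loadings[, 1], sc * x$loadings[, 2],
                   length = 0.05, col = "grey50")
  invisible(x)
}

# Insert-absorb letter display: groups sharing a letter are not
# significantly different. `p` is a symmetric pairwise p-value matrix with
# group names on both dimensions.
letters_from_pmatrix <- function(p, alpha = 0.05) {
  g <- rownames(p)
  k <- length(g)
  cols <- list(rep(TRUE, k))  # letter columns as membership vectors
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    if (!is.na(p[i, j]) && p[i, j] < alpha) {
      for (ci in seq_along(cols)) {
        if (cols[[ci]][i] && cols[[ci]][j]) {
          a <- cols[[ci]]; a[i] <- FALSE
          b <- cols[[ci]]; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1L]] <- b
        }
      }
      # absorb columns that are subsets of another
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && !drop[a] && !drop[b] &&
            all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
          drop[a] <- TRUE
        if (a != b && !drop[a] && !drop[b] && identical(cols[[a]], cols[[b]]) && a > b)
          drop[a] <- TRUE
      }
      cols <- cols[!drop]
    }
  }
  ord <- order(vapply(cols, function(cc) which(cc)[1], integer(1)))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(out, g)
}

#' Compare groups with Kruskal--Wallis or ANOVA + Tukey HSD
#'
#' The non-parametric route runs a Kruskal--Wallis rank-sum test with
#' pairwise Wilcoxon tests (Holm-adjusted) for the letter display; the
#' parametric route runs one-way ANOVA with Tukey HSD pairwise
#' comparisons. Groups that share a letter do not differ significantly at
#' level `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), >= 2 groups with >= 2
#'   observations each.
#' @param method `"kruskal"` or `"anova_tukey"`.
#' @param alpha Significance level for the letter display.
#' @return A list with `p_overall`, `p_pairwise` (symmetric matrix),
#'   `letters` (named character vector) and `method`.
#' @export
group_compare <- function(values, groups, method = c("kruskal", "anova_tukey"),
                          alpha = 0.05) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop_invalid_input("values and groups must have equal length")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop_insufficient_data("need >= 2 groups with >= 2 observations each")
  g <- levels(groups)
  k <- length(g)
  pmat <- matrix(NA_real_, k, k, dimnames = list(g, g))
  if (method == "kruskal") {
    p_overall <- stats::kruskal.test(values, groups)$p.value
    if (all(tapply(values, groups, function(x) length(unique(x))) == 1L) &&
        length(unique(values)) == 1L) {
      pw <- matrix(1, k, k, dimnames = list(g, g))
      pmat[] <- 1
    } else {
      pw <- suppressWarnings(
        stats::pairwise.wilcox.test(values, groups, p.adjust.method = "holm",
                                    exact = FALSE)$p.value)
      for (i in rownames(pw)) for (j in colnames(pw))
        if (!is.na(pw[i, j])) pmat[i, j] <- pmat[j, i] <- pw[i, j]
    }
  } else {
    fit <- stats::aov(values ~ groups)
    p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    for (cmp in rownames(tk)) {
      pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[cmp, "p adj"]
    }
  }
  if (is.na(p_overall)) p_overall <- 1  # identical groups: no evidence of difference
  diag(pmat) <- 1
  list(p_overall = p_overall, p_pairwise = pmat,
       letters = letters_from_pmatrix(pmat, alpha), method = method)
}
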