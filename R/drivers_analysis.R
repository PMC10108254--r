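# Landscape-driver analysis: varimax-rotated PCA of flux and site variables,
# Pearson correlations overall and per age class, and LAI imputation from
# tree biomass.

#' PCA with varimax rotation
#'
#' Standardizes the feature table (zero mean, unit variance), performs an
#' eigen-decomposition of the correlation matrix (appropriate for drivers
#' with heterogeneous units), retains `n_components` components, and applies
#' varimax rotation with Kaiser normalization to the retained loadings. The
#' sign convention is deterministic: each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param x Numeric data frame or matrix, >= 3 variables, no missing values.
#' @param n_components Number of retained components (default 2, the usual
#'   biplot-ready choice).
#' @param rotate Apply varimax rotation (default TRUE).
#' @return Object of class `loading_matrix`: `loadings` (variables x
#'   components), `explained` (variance fractions per retained component),
#'   `eigenvalues`, `rotated`.
#' @export
pca_varimax <- function(x, n_components = 2, rotate = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need >= 3 variables")
  if (anyNA(x)) stop("missing values not allowed")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  cm <- stats::cor(x)
  eig <- eigen(cm, symmetric = TRUE)
  k <- min(n_components, ncol(x))
  load <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  rownames(load) <- colnames(x)
  rotated <- FALSE
  if (rotate && k >= 2) {
    vm <- stats::varimax(load, normalize = TRUE, eps = 1e-8)
    load <- load %*% vm$rotmat
    rotated <- TRUE
  }
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  colnames(load) <- paste0("PC", seq_len(k))
  explained <- colSums(load^2) / ncol(x)
  structure(list(loadings = load, explained = explained,
                 eigenvalues = eig$values, rotated = rotated),
            class = "loading_matrix")
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf("%s PCA loadings (%s):\n",
              if (x$rotated) "Varimax-rotated" else "Unrotated",
              paste(sprintf("%s %.1f%%", colnames(x$loadings),
                            100 * x$explained), collapse = ", ")))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Pearson correlations of fluxes with drivers, overall and per group
#'
#' Computes Pearson's r with a two-sided t-test p-value between each
#' response and each driver, for all stands pooled and within each level of
#' an optional grouping (age class). Pairs with fewer than 3 stands or zero
#' variance are marked not computed (NA).
#'
#' @param data Data frame with one row per stand.
#' @param responses Character vector of response columns (e.g. nep, npp_t).
#' @param drivers Character vector of driver columns.
#' @param group Optional grouping column name (e.g. `"age_class"`).
#' @return Long data frame: `group`, `response`, `driver`, `n`, `r`, `p`.
#' @export
pearson_by_class <- function(data, responses, drivers, group = NULL) {
  groups <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(group)) {
    for (g in unique(data[[group]])) groups[[g]] <- data[[group]] == g
  }
  rows <- list()
  for (gnm in names(groups)) {
    sel <- data[groups[[gnm]], , drop = FALSE]
    for (resp in responses) {
      for (drv in drivers) {
        xx <- sel[[drv]]; yy <- sel[[resp]]
        ok <- stats::complete.cases(xx, yy)
        n <- sum(ok)
        if (n < 3 || stats::sd(xx[ok]) == 0 || stats::sd(yy[ok]) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(xx[ok], yy[ok], method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1]] <- data.frame(
          group = gnm, response = resp, driver = drv, n = n, r = r, p = p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Impute peak-season LAI from aboveground tree biomass
#'
#' Stands without direct canopy-analyser measurements get LAI_max predicted
#' from a saturating Michaelis-Menten-type relationship
#' `LAI = L_max * B / (B + h)` least-squares fitted to the directly measured
#' (biomass, LAI) reference pairs.
#'
#' @param b_t Aboveground tree biomass to predict for, Mg ha-1 (vectorised).
#' @param reference Data frame of measured pairs: columns `b_t`, `lai_max`
#'   (>= 3 rows).
#' @return Predicted LAI_max (>= 0).
#' @export
#' @examples
#' ref <- data.frame(b_t = c(20, 50, 150), lai_max = 4 * c(20, 50, 150) /
#'                   (c(20, 50, 150) + 50))
#' impute_lai(50, ref)  # 2.0
impute_lai <- function(b_t, reference) {
  if (nrow(reference) < 3) stop("need >= 3 (biomass, LAI) reference pairs")
  fit <- minpack.lm::nlsLM(
    lai_max ~ l_max * b_t / (b_t + h), data = reference,
    start = list(l_max = max(reference$lai_max) * 1.2,
                 h = stats::median(reference$b_t)),
    lower = c(l_max = 1e-9, h = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  pmax(co[["l_max"]] * b_t / (b_t + co[["h"]]), 0)
}
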