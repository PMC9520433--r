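#' Principal components of trauma questionnaire items
#'
#' Standardizes the selected items (mean 0, variance 1) and
#' eigendecomposes their correlation matrix; scores are the standardized
#' items projected on the eigenvectors. PCA is done on the correlation
#' (not covariance) matrix because questionnaire items sit on
#' heterogeneous scales. Missing responses are mean-imputed per item
#' before standardization. Eigenvector signs are fixed so each
#' component's largest-magnitude loading is positive.
#'
#' @param items n x p numeric item matrix (rows = individuals); row names
#'   used as sample ids, column names as item ids.
#' @param category_labels Optional character vector (length p) mapping
#'   each item to one of `"childhood"`, `"adult"`, `"catastrophic"`;
#'   required when `category` is not `"full"`.
#' @param category Which item subset to analyze: `"full"` uses all items.
#' @param k Number of components to keep (default: all usable items).
#'   `k = 1` gives the PC1-only representation.
#' @param impute_missing Mean-impute missing responses (default TRUE);
#'   with FALSE, missing values are an error.
#' @return Object of class `trauma_pcs`: `scores` (n x k), `loadings`
#'   (p x k eigenvectors), `explained_share` (non-increasing, sums to 1
#'   when k = p), `eigenvalues`, `category`, `source_items`.
#' @export
compute_trauma_pcs <- function(items, category_labels = NULL,
                               category = c("full", "childhood", "adult",
                                            "catastrophic"),
                               k = NULL, impute_missing = TRUE) {
  category <- match.arg(category)
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  p_all <- ncol(items)
  item_ids <- colnames(items) %||% sprintf("item%d", seq_len(p_all))
  if (category != "full") {
    if (is.null(category_labels) || length(category_labels) != p_all)
      stop("category_labels (one per item) required for category = '",
           category, "'", call. = FALSE)
    sel <- which(category_labels == category)
  } else sel <- seq_len(p_all)
  if (length(sel) < 2)
    stop("need at least 2 items in category '", category, "'",
         call. = FALSE)
  X <- items[, sel, drop = FALSE]
  if (anyNA(X)) {
    if (!impute_missing) stop("missing item responses present", call. = FALSE)
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance item(s): ",
            paste(item_ids[sel][sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sel <- sel[sds > 0]
    if (ncol(X) < 2)
      stop("fewer than 2 usable items after dropping constants",
           call. = FALSE)
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  p <- ncol(X)
  if (is.null(k)) k <- p
  k <- check_count(k, "k")
  if (k > p) stop("k exceeds the number of usable items", call. = FALSE)
  vec <- fix_signs(eg$vectors)
  scores <- Z %*% vec[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  rownames(scores) <- rownames(items)
  structure(list(
    scores = scores,
    loadings = vec[, seq_len(k), drop = FALSE],
    explained_share = eg$values[seq_len(k)] / sum(eg$values),
    eigenvalues = eg$values[seq_len(k)],
    category = category,
    source_items = item_ids[sel]), class = "trauma_pcs")
}

#' @export
print.trauma_pcs <- function(x, ...) {
  cat(sprintf("Trauma PCs (%s): %d components from %d items\n",
              x$category, ncol(x$scores), length(x$source_items)))
  cat("  explained share:",
      paste(sprintf("%.3f", utils::head(x$explained_share, 6)),
            collapse = " "),
      if (length(x$explained_share) > 6) "..." else "", "\n")
  invisible(x)
}
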