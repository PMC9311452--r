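# Regression data container: point-referenced multivariate outcomes, fixed
# effects, latent-process loadings and the missing-data bookkeeping (the
# zero-filled noise matrix for unobserved outcomes).

#' Point-referenced multivariate regression data
#'
#' One row per (spatial location, outcome) combination.  A missing `y`
#' (`NA`) marks an unobserved outcome: its latent value is still modelled
#' (and predicted) but it contributes nothing to the likelihood — the
#' zero-filled noise-matrix convention.
#'
#' By default each row loads only its own outcome's latent value at its
#' location with coefficient `z` (a spatially-varying intercept when
#' `z = 1`).  Supplying a full loading matrix `Z` (rows x q) instead makes
#' every row load all `q` latent processes at its site
#' (spatially-varying-coefficient regression); the latent field is then laid
#' out over all site-variable combinations.
#'
#' @param coords numeric matrix (rows x 2) of spatial coordinates.
#' @param outcome integer outcome index per row (1..q).
#' @param y outcome values (`NA` = unobserved).
#' @param X optional fixed-effect design matrix (rows x p).
#' @param z optional scalar loading per row (default 1); ignored when `Z`
#'   is given.
#' @param Z optional full loading matrix (rows x q).
#' @param q number of outcomes.
#' @return A `spamtree_data` object.
#' @export
spamtree_data <- function(coords, outcome, y, X = NULL, z = NULL, Z = NULL,
                          q = max(outcome)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  outcome <- as.integer(outcome)
  q <- as.integer(q)
  n <- nrow(coords)
  stopifnot(length(outcome) == n, length(y) == n)
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
  }
  key <- paste(coords[, 1], coords[, 2], outcome, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated (location, outcome) rows")
  if (is.null(Z)) {
    locs <- expanded_locs(coords, outcome, q = q)
    obj <- list(locs = locs, y = as.numeric(y), X = X,
                z = if (is.null(z)) rep(1, n) else as.numeric(z),
                outcome = outcome, observed = !is.na(y),
                diagonal = TRUE, row_w = NULL, q = as.integer(q),
                n_rows = n)
  } else {
    Z <- as.matrix(Z)
    stopifnot(ncol(Z) == q, nrow(Z) == n)
    skey <- paste(coords[, 1], coords[, 2], sep = "\r")
    site <- match(skey, unique(skey))
    ns <- max(site)
    ucoords <- coords[!duplicated(skey), , drop = FALSE]
    wcoords <- ucoords[rep(seq_len(ns), each = q), , drop = FALSE]
    wvar <- rep(seq_len(q), times = ns)
    locs <- expanded_locs(wcoords, wvar, q = q)
    row_w <- lapply(seq_len(n), function(i) {
      idx <- (site[i] - 1L) * q + seq_len(q)
      keep <- Z[i, ] != 0
      list(w_idx = idx[keep], coef = Z[i, keep])
    })
    obj <- list(locs = locs, y = as.numeric(y), X = X, z = NULL,
                outcome = outcome, observed = !is.na(y),
                diagonal = FALSE, row_w = row_w, q = as.integer(q),
                n_rows = n)
  }
  structure(obj, class = "spamtree_data")
}

#' @export
print.spamtree_data <- function(x, ...) {
  cat(sprintf(paste0("<spamtree_data> %d rows (%d observed), q = %d, ",
                     "%d latent locations, %s loadings%s\n"),
              x$n_rows, sum(x$observed), x$q, length(x$locs),
              if (x$diagonal) "diagonal" else "full",
              if (is.null(x$X)) "" else sprintf(", p = %d covariates",
                                                ncol(x$X))))
  invisible(x)
}

# Candidate reference locations: latent locations tied to at least one
# observed row.
reference_candidates <- function(data) {
  if (data$diagonal) {
    which(data$observed)
  } else {
    sort(unique(unlist(lapply(which(data$observed),
                              function(i) data$row_w[[i]]$w_idx))))
  }
}
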